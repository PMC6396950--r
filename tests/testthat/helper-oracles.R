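# Brute-force stationary law of a (small, irreducible) generator matrix in
# the columns-sum-to-zero convention: pin one state, solve, normalize.
# Independent of the package's stationary_weights()/fsp_stationary() paths.
stationary_of_generator <- function(A, pin = 1L) {
  A <- as.matrix(A)
  n <- nrow(A)
  y <- solve(A[-pin, -pin, drop = FALSE], -A[-pin, pin])
  p <- numeric(n)
  p[pin] <- 1
  p[-pin] <- y
  p / sum(p)
}
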