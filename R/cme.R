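# Finite-epsilon ground truth: sparse truncated CME with the fast-slow block
# decomposition Lambda_eps = Lambda_tilde + eps * Lambda_hat, and a
# finite-state-projection stationary solver.

#' Assemble the truncated CME generator of a GRN
#'
#' Enumerates states `(d, x)` with `d` a global promoter configuration and
#' `x` a protein/multimer copy-number vector in a finite box, and builds the
#' sparse generator in fast-slow form: `Lambda_tilde` is block-diagonal over
#' `d` (the conditional protein chains), `Lambda_hat` holds exactly the gene
#' (binding/unbinding/switching) reaction terms, and the finite-epsilon
#' generator is `Lambda_tilde + epsilon * Lambda_hat`. Columns sum to zero
#' for interior states and to minus the boundary outflow (recorded in
#' `leak_fast`/`leak_slow`) at the box surface.
#'
#' @param spec A valid `grn_spec`.
#' @param box Integer upper copy-number bounds: named vector over the
#'   protein/multimer species (unnamed values are recycled over all of
#'   them). Default: [truncation_bound()] of the largest conditional mean of
#'   each species over all configurations.
#' @return An object of class `truncated_cme`: sparse `lambda_tilde` and
#'   `lambda_hat`, `epsilon`, `box`, `species` (protein species), `states`,
#'   `n_lattice`, and per-column leak vectors. State `(d, x)` has 1-based
#'   index `d * n_lattice + lattice_index(x)`.
#' @export
assemble_cme <- function(spec, box = NULL) {
  spec1 <- spec
  spec1$epsilon <- 1
  net <- expand_reactions(spec1)
  prot <- net$species[!startsWith(net$species, "D")]
  states <- grn_states(spec)
  L <- nrow(states)
  ids <- names(spec$genes)
  cond <- lapply(states$index, function(d)
    if (is.null(spec$diffusion)) conditional_pmf_joint(spec, d)
    else conditional_equilibrium(spec, d))
  mu_max <- apply(do.call(rbind, lapply(cond, function(cp) cp$means[prot])), 2, max)
  if (is.null(box)) box <- truncation_bound(mu_max)
  if (is.null(names(box))) box <- stats::setNames(rep_len(as.integer(box),
                                                          length(prot)), prot)
  box <- box[prot]
  if (any(mu_max > box / 2)) {
    leak_est <- max(stats::ppois(box, mu_max, lower.tail = FALSE))
    warning(sprintf(
      "box small: a conditional mean exceeds half its bound (tail mass ~ %.2e)",
      leak_est))
  }
  dims <- box + 1L
  n_lat <- prod(dims)
  strides <- c(1, cumprod(dims[-length(dims)]))
  names(strides) <- prot
  lat <- as.matrix(expand.grid(lapply(dims, function(n) 0:(n - 1))))
  colnames(lat) <- prot
  lidx <- seq_len(n_lat)

  is_prom <- startsWith(net$species, "D")
  trip <- list(tilde = list(i = integer(), j = integer(), x = numeric()),
               hat = list(i = integer(), j = integer(), x = numeric()))
  diagv <- list(tilde = numeric(L * n_lat), hat = numeric(L * n_lat))
  leak <- list(tilde = numeric(L * n_lat), hat = numeric(L * n_lat))

  for (rx in seq_len(n_reactions(net))) {
    rvec <- net$reactants[, rx]; pvec <- net$products[, rx]
    slow <- net$class[rx] == "slow_gene"
    part <- if (slow) "hat" else "tilde"
    r <- rvec[prot]; delta <- (pvec - rvec)[prot]
    w <- rep(net$rate[rx], n_lat)
    for (s in which(r > 0)) w <- w * choose(lat[, s], r[s])
    ok <- rep(TRUE, n_lat)
    for (s in which(delta != 0)) {
      xn <- lat[, s] + delta[s]
      ok <- ok & xn >= 0 & xn <= box[s]
    }
    shift <- sum(delta * strides)
    dest <- lidx + shift
    act <- w > 0
    # which promoter blocks does this reaction act in, and where does it go?
    prom_r <- which(is_prom & rvec > 0)
    if (length(prom_r) == 0L) {
      blocks_from <- states$index
      blocks_to <- states$index
    } else {
      sp <- net$species[prom_r[1]]
      code <- sub("^D([01]+)\\..*$", "\\1", sp)
      gid <- sub("^D[01]+\\.", "", sp)
      blocks_from <- states$index[states[[gid]] == code]
      prom_p <- which(is_prom & pvec > 0 & (pvec - rvec) > 0)
      if (length(prom_p)) {
        code2 <- sub("^D([01]+)\\..*$", "\\1", net$species[prom_p[1]])
        blocks_to <- vapply(blocks_from, function(d) {
          cfg <- stats::setNames(unlist(states[states$index == d, ids],
                                        use.names = FALSE), ids)
          cfg[gid] <- code2
          state_index(spec, cfg)
        }, numeric(1))
      } else blocks_to <- blocks_from
    }
    for (b in seq_along(blocks_from)) {
      off_from <- blocks_from[b] * n_lat
      off_to <- blocks_to[b] * n_lat
      keep <- act & ok
      trip[[part]]$i <- c(trip[[part]]$i, off_to + dest[keep])
      trip[[part]]$j <- c(trip[[part]]$j, off_from + lidx[keep])
      trip[[part]]$x <- c(trip[[part]]$x, w[keep])
      diagv[[part]][off_from + lidx] <- diagv[[part]][off_from + lidx] - w
      lk <- act & !ok
      leak[[part]][off_from + lidx[lk]] <- leak[[part]][off_from + lidx[lk]] + w[lk]
    }
  }
  n <- L * n_lat
  mk <- function(part) {
    Matrix::sparseMatrix(i = c(trip[[part]]$i, seq_len(n)),
                         j = c(trip[[part]]$j, seq_len(n)),
                         x = c(trip[[part]]$x, diagv[[part]]),
                         dims = c(n, n))
  }
  structure(list(
    lambda_tilde = mk("tilde"), lambda_hat = mk("hat"),
    epsilon = spec$epsilon, box = box, species = prot, states = states,
    n_lattice = n_lat, dims = dims, strides = strides,
    leak_fast = leak$tilde, leak_slow = leak$hat,
    conditionals = cond, spec = spec
  ), class = "truncated_cme")
}

#' @export
print.truncated_cme <- function(x, ...) {
  cat(sprintf("Truncated CME: %d promoter configs x %d lattice points = %d states\n",
              nrow(x$states), x$n_lattice, nrow(x$states) * x$n_lattice))
  cat("  box:", paste(sprintf("%s<=%d", x$species, x$box), collapse = ", "), "\n")
  invisible(x)
}

#' Finite-epsilon generator of a truncated CME
#'
#' @param cme A `truncated_cme`.
#' @param epsilon Time-scale ratio (default the spec's).
#' @return Sparse generator `Lambda_tilde + epsilon * Lambda_hat`.
#' @export
cme_generator <- function(cme, epsilon = cme$epsilon) {
  cme$lambda_tilde + epsilon * cme$lambda_hat
}

#' Conditional-block generator
#'
#' The diagonal block of `Lambda_tilde` for configuration `d`: the generator
#' of the protein process conditioned on `d`, on the truncated lattice.
#'
#' @param cme A `truncated_cme`.
#' @param d 0-based configuration index.
#' @return Sparse `n_lattice x n_lattice` generator.
#' @export
conditional_generator <- function(cme, d) {
  idx <- d * cme$n_lattice + seq_len(cme$n_lattice)
  cme$lambda_tilde[idx, idx]
}

#' Finite-state-projection stationary distribution
#'
#' Solves `Lambda_eps pi = 0` on the truncated space with reflecting closure
#' (boundary outflow is discarded and the column re-closed), normalized to
#' sum 1. The discarded outflow is reported as `leak_rate`.
#'
#' @param cme A `truncated_cme`.
#' @param epsilon Time-scale ratio (default the spec's).
#' @return An object of class `stationary_pmf`: list with `p` (dense vector
#'   over `(d, x)` states), `residual` (`max |Lambda_closed p|`),
#'   `leak_rate` (stationary probability flux that would leave the box),
#'   `epsilon` and the `cme`.
#' @export
fsp_stationary <- function(cme, epsilon = cme$epsilon) {
  A <- cme_generator(cme, epsilon)
  n <- nrow(A)
  leak <- cme$leak_fast + epsilon * cme$leak_slow
  A_closed <- A + Matrix::Diagonal(n, leak)
  # pin the state nearest the first conditional mean to 1 and solve the
  # remaining (nonsingular, sparsity-preserving) system, then normalize
  mu0 <- pmin(round(cme$conditionals[[1]]$means[cme$species]), cme$box)
  i0 <- as.integer(1 + sum(mu0 * cme$strides))
  p <- tryCatch({
    y <- Matrix::solve(A_closed[-i0, -i0, drop = FALSE],
                       -A_closed[-i0, i0, drop = FALSE])
    v <- numeric(n); v[i0] <- 1; v[-i0] <- as.numeric(y)
    v
  }, error = function(e)
    stop("FSP solve failed (singular beyond tolerance): ",
         conditionMessage(e)))
  p[p < 0 & p > -1e-12] <- 0
  if (any(p < 0))
    warning("FSP solution has negative entries beyond tolerance; box too small?")
  p <- p / sum(p)
  res <- max(abs(A_closed %*% p))
  structure(list(p = p, residual = res,
                 leak_rate = sum(leak * p), epsilon = epsilon, cme = cme),
            class = "stationary_pmf")
}

#' @export
print.stationary_pmf <- function(x, ...) {
  cat(sprintf("FSP stationary PMF: %d states, residual %.3e, leak %.3e\n",
              length(x$p), x$residual, x$leak_rate))
  invisible(x)
}

#' Marginal PMFs of an FSP solution
#'
#' @param fsp A `stationary_pmf`.
#' @param species Protein species to keep (marginalizing over the rest and
#'   over the promoter configuration).
#' @return For one species a named vector over `0:box`; for several, an
#'   array with one dimension per requested species.
#' @export
fsp_marginal <- function(fsp, species) {
  cme <- fsp$cme
  stopifnot(all(species %in% cme$species))
  arr <- array(fsp$p, dim = c(cme$dims, nrow(cme$states)))
  keep <- match(species, cme$species)
  m <- apply(arr, keep, sum)
  if (length(species) == 1L) names(m) <- 0:cme$box[species]
  m
}

#' Total-variation distance between two PMFs
#'
#' `0.5 * sum |p - q|` plus half the unmatched mass if the vectors have
#' different support sizes (the shorter is zero-padded).
#'
#' @param p,q Numeric PMF vectors or arrays (flattened).
#' @return Scalar in `[0, 1]`.
#' @export
tv_distance <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  n <- max(length(p), length(q))
  p <- c(p, rep(0, n - length(p)))
  q <- c(q, rep(0, n - length(q)))
  0.5 * sum(abs(p - q))
}

#' Reduced generator by direct projection of the slow matrix
#'
#' The defining (singular-perturbation) form of the reduced generator:
#' stack the extended conditional stationary PMFs into columns, apply the
#' slow matrix `Lambda_hat` on the truncated lattice, and sum each resulting
#' vector per promoter block. Serves as an independent cross-check of the
#' algorithmic [build_reduced_generator()] construction.
#'
#' @param spec A valid `grn_spec`.
#' @param box Lattice bounds as in [assemble_cme()].
#' @return Dense `L x L` generator matrix (columns-sum-to-zero convention,
#'   up to truncation leakage).
#' @export
reduced_generator_direct <- function(spec, box = NULL) {
  cme <- assemble_cme(spec, box)
  L <- nrow(cme$states)
  n_lat <- cme$n_lattice
  lat <- as.matrix(expand.grid(lapply(cme$dims, function(n) 0:(n - 1))))
  colnames(lat) <- cme$species
  block <- rep(seq_len(L), each = n_lat)
  Mr <- matrix(0, L, L)
  for (dd in seq_len(L)) {
    mu <- cme$conditionals[[dd]]$means[cme$species]
    pv <- rep(1, n_lat)
    for (s in seq_along(mu)) pv <- pv * stats::dpois(lat[, s], mu[s])
    v <- numeric(L * n_lat)
    v[(dd - 1L) * n_lat + seq_len(n_lat)] <- pv
    w <- as.numeric(cme$lambda_hat %*% v)
    Mr[, dd] <- rowsum(w, block)
  }
  Mr
}
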