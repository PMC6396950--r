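# Populations of identical toggle switches communicating by protein
# diffusion, and their high-diffusion synchronized limit.

# Identify the toggle-pair structure of a coupled-population spec; errors if
# the genes are not N identical mutually-repressing one-site pairs with
# all-pairs monomer diffusion within each family.
.coupled_structure <- function(spec) {
  genes <- spec$genes
  ids <- names(genes)
  if (length(genes) %% 2L != 0L) stop("not a population of toggle pairs")
  outputs <- vapply(genes, output_species, character(1))
  partner <- vapply(genes, function(g) {
    if (length(g$binding_sites) != 1L || identical(g$binding_sites, "constitutive"))
      stop("each gene must have exactly one TF binding site")
    ids[outputs == g$binding_sites[1]]
  }, character(1))
  if (any(partner[partner] != ids)) stop("genes do not form mutually repressing pairs")
  # family A = first gene of each pair in declaration order
  seen <- character(); famA <- character()
  for (id in ids) if (!(id %in% seen)) {
    famA <- c(famA, id)
    seen <- c(seen, id, partner[id])
  }
  famB <- partner[famA]
  all_genes <- genes[c(famA, famB)]
  ref <- all_genes[[1]]
  same <- vapply(all_genes, function(g)
    isTRUE(all.equal(g[c("alpha", "alpha_off", "production", "decay",
                         "cooperativity", "beta", "beta_off")],
                     ref[c("alpha", "alpha_off", "production", "decay",
                           "cooperativity", "beta", "beta_off")])),
    logical(1))
  if (!all(same)) stop("switches are not identical")
  N <- length(famA)
  if (N > 1L) {
    if (is.null(spec$diffusion)) stop("population of size > 1 without diffusion")
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    have <- key(spec$diffusion$from, spec$diffusion$to)
    need <- c(utils::combn(famA, 2, function(p) key(p[1], p[2])),
              utils::combn(famB, 2, function(p) key(p[1], p[2])))
    if (!all(need %in% have)) stop("diffusion must couple all pairs within each family")
    omega <- spec$diffusion$rate[1]
  } else omega <- NA_real_
  list(N = N, famA = famA, famB = famB, ref = ref, omega = omega)
}

# Conditional TF mean contributed by one family when m of its N promoters
# are unbound and the proteins are fully synchronized.
.sync_rho <- function(ref, m, N) {
  k0 <- ref$production[["0"]]
  a <- m * k0 / (N * ref$decay)
  n <- ref$cooperativity
  if (n > 1L) ref$beta / ref$beta_off * a^n / factorial(n) else a
}

#' Synchronized-limit mode structure of coupled toggle switches
#'
#' For `N` identical toggle switches coupled by all-pairs protein diffusion,
#' the full reduced model has `4^N` promoter configurations (one of them --
#' all promoters bound -- structurally weightless, leaving `4^N - 1` mixture
#' components). As the diffusion rate grows the protein copies synchronize
#' and the stationary PMF depends only on the *number* of unbound promoters
#' per gene family: the component count drops to `(N+1)^2 - 1` aggregated
#' modes at locations `(i k0/(N k_-), j k0/(N k_-))`, `i, j = 0..N`, minus
#' the weightless origin. Modes with both counts positive lie in the
#' interior and are suppressed by a large multimerization ratio.
#'
#' The minimal diffusion rate for synchronization (modes within one copy
#' number of each other) is reported as `(k0 - k_-)/N`; it is reported only,
#' never applied.
#'
#' @param spec A coupled-toggle-population `grn_spec` (see
#'   [build_fixture()]`("coupled_toggles")`); non-identical switches are
#'   rejected.
#' @return List with `N`, `full_components` (`4^N`),
#'   `full_positive_components` (`4^N - 1`), `modes` (data frame: unbound
#'   counts `i`, `j`, locations `x`, `y`, `weight`, `interior`),
#'   `total_modes`, `interior_modes`, `boundary_modes`,
#'   `extra_boundary_modes` (boundary modes beyond the two all-unbound
#'   extremes), `max_interior_weight` and `omega_min`.
#' @export
synchronized_limit <- function(spec) {
  st <- .coupled_structure(spec)
  N <- st$N; ref <- st$ref
  k0 <- ref$production[["0"]]
  u <- k0 / (N * ref$decay)
  alpha <- ref$alpha[1]; alpha_off <- ref$alpha_off[1]
  nst <- (N + 1L)^2
  idx <- function(i, j) i * (N + 1L) + j + 1L
  M <- matrix(0, nst, nst)
  for (i in 0:N) for (j in 0:N) {
    from <- idx(i, j)
    if (i > 0) M[idx(i - 1L, j), from] <- i * alpha * .sync_rho(ref, j, N)
    if (i < N) M[idx(i + 1L, j), from] <- (N - i) * alpha_off
    if (j > 0) M[idx(i, j - 1L), from] <- j * alpha * .sync_rho(ref, i, N)
    if (j < N) M[idx(i, j + 1L), from] <- (N - j) * alpha_off
  }
  diag(M) <- diag(M) - colSums(M)
  lam <- stationary_weights(M)
  grid <- expand.grid(j = 0:N, i = 0:N)[, c("i", "j")]
  modes <- data.frame(i = grid$i, j = grid$j,
                      x = grid$i * u, y = grid$j * u,
                      weight = as.numeric(lam)[idx(grid$i, grid$j)])
  modes$interior <- modes$i > 0 & modes$j > 0
  pos <- modes[modes$weight > 0, , drop = FALSE]
  boundary <- pos[!pos$interior, , drop = FALSE]
  extremes <- sum((boundary$i == N & boundary$j == 0) |
                  (boundary$i == 0 & boundary$j == N))
  list(
    N = N,
    full_components = 4^N,
    full_positive_components = 4^N - 1,
    modes = modes,
    total_modes = nrow(pos),
    interior_modes = sum(pos$interior),
    boundary_modes = nrow(boundary),
    extra_boundary_modes = nrow(boundary) - extremes,
    max_interior_weight = if (any(pos$interior)) max(pos$weight[pos$interior]) else 0,
    omega_min = (k0 - ref$decay) / N,
    omega = st$omega
  )
}
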