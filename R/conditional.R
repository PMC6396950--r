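# Conditional stationary analysis: the protein process with the promoter
# configuration frozen at d is a set of uncoupled birth-death (+ reversible
# n-merization, + linear transport) chains, whose stationary law is an exact
# product of Poissons.

# Normalize a state argument: 0-based index or character config vector.
as_config <- function(spec, d) {
  if (is.character(d)) {
    stopifnot(length(d) == length(spec$genes))
    return(stats::setNames(d, names(spec$genes)))
  }
  state_config(spec, as.integer(d))
}

#' Joint conditional stationary PMF at a frozen promoter configuration
#'
#' With the global promoter configuration frozen at `d`, the proteins and
#' multimers form independent birth-death chains whose joint stationary PMF
#' is a product of Poissons: the monomer of gene `i` has mean
#' `a_i = k_{i,d_i} / k_-i` and, for a cooperativity index `n_i > 1`, its
#' multimer has mean `b_i = (beta_i / beta_-i) * a_i^{n_i} / n_i!`.
#'
#' @param spec A `grn_spec` without diffusion couplings (use
#'   [conditional_equilibrium()] otherwise).
#' @param d Promoter configuration: 0-based index or character vector of
#'   per-gene configuration codes.
#' @return An object of class `conditional_poisson`: list with `config`,
#'   `index`, `monomer_means` (named by gene), `multimer_means` (named by
#'   multimer species; empty if none), `means` (all species) and `pmf`, a
#'   function evaluating the joint PMF at integer matrices/vectors ordered
#'   as `names(means)`.
#' @export
conditional_pmf_joint <- function(spec, d) {
  if (!is.null(spec$diffusion))
    stop("spec has diffusion couplings; use conditional_equilibrium()")
  cfg <- as_config(spec, d)
  a <- vapply(seq_along(spec$genes), function(i) {
    g <- spec$genes[[i]]
    g$production[[cfg[i]]] / g$decay
  }, numeric(1))
  names(a) <- names(spec$genes)
  b <- numeric(0)
  for (i in seq_along(spec$genes)) {
    g <- spec$genes[[i]]
    if (g$cooperativity > 1L) {
      n <- g$cooperativity
      b[output_species(g)] <- g$beta / g$beta_off * a[i]^n / factorial(n)
    }
  }
  means <- c(a, b)
  new_conditional_poisson(spec, cfg, a, b, means)
}

new_conditional_poisson <- function(spec, cfg, a, b, means) {
  structure(list(
    config = cfg,
    index = state_index(spec, cfg),
    monomer_means = a,
    multimer_means = b,
    means = means,
    pmf = function(x) {
      x <- rbind(x)
      stopifnot(ncol(x) == length(means))
      apply(x, 1, function(row) prod(stats::dpois(row, means)))
    }
  ), class = "conditional_poisson")
}

#' @export
print.conditional_poisson <- function(x, ...) {
  cat(sprintf("Conditional product-Poisson at d = %d (%s)\n", x$index,
              paste(x$config, collapse = ",")))
  print(signif(x$means, 6))
  invisible(x)
}

#' Marginal conditional Poisson means of the (non-multimerized) proteins
#'
#' Averaging the joint conditional PMF over the multimer counts leaves a
#' product of `N` Poissons with means `k_{i,d_i} / k_-i`.
#'
#' @inheritParams conditional_pmf_joint
#' @return Named numeric vector of per-gene Poisson means.
#' @export
conditional_pmf_marginal <- function(spec, d) {
  conditional_pmf_joint(spec, d)$monomer_means
}

#' Conditional stationary means for diffusion-coupled networks
#'
#' At a frozen promoter configuration the conditional reaction network
#' (productions, decays, reversible monomer transport, reversible
#' n-merization) is weakly reversible with deficiency zero, so its stationary
#' PMF is product-Poisson with means equal to the conditional deterministic
#' (complex-balanced) equilibrium. The monomer means solve the linear balance
#' `(diag(k_-) + Omega-Laplacian) a = k(d)`; multimer means follow from
#' detailed balance of the n-merization pair, `b = (beta/beta_-) a^n / n!`.
#'
#' @inheritParams conditional_pmf_joint
#' @param spec A `grn_spec`; diffusion couplings, if any, must connect
#'   monomer species only (the structural condition for the product form).
#' @return A `conditional_poisson` (see [conditional_pmf_joint()]).
#' @export
conditional_equilibrium <- function(spec, d) {
  cfg <- as_config(spec, d)
  ids <- names(spec$genes)
  k <- vapply(seq_along(spec$genes), function(i) {
    g <- spec$genes[[i]]
    g$production[[cfg[i]]]
  }, numeric(1))
  dec <- vapply(spec$genes, `[[`, numeric(1), "decay")
  A <- diag(dec, nrow = length(ids))
  dimnames(A) <- list(ids, ids)
  if (!is.null(spec$diffusion)) {
    if (!all(spec$diffusion$from %in% ids & spec$diffusion$to %in% ids))
      stop(paste("conditional network is not structurally weakly reversible",
                 "deficiency zero: diffusion must couple monomer species"))
    for (r in seq_len(nrow(spec$diffusion))) {
      i <- spec$diffusion$from[r]; j <- spec$diffusion$to[r]
      om <- spec$diffusion$rate[r]
      A[i, i] <- A[i, i] + om; A[j, j] <- A[j, j] + om
      A[i, j] <- A[i, j] - om; A[j, i] <- A[j, i] - om
    }
  }
  a <- stats::setNames(drop(solve(A, k)), ids)
  b <- numeric(0)
  for (i in seq_along(spec$genes)) {
    g <- spec$genes[[i]]
    if (g$cooperativity > 1L) {
      n <- g$cooperativity
      b[output_species(g)] <- g$beta / g$beta_off * a[i]^n / factorial(n)
    }
  }
  new_conditional_poisson(spec, cfg, a, b, c(a, b))
}

#' Conditional expectation of a TF species at a frozen configuration
#'
#' `E[TF | D = d]`: for a monomeric TF the conditional Poisson mean
#' `k_{i,d_i}/k_-i`; for an n-merized TF
#' `(beta/beta_-) (k_{i,d_i}/k_-i)^n / n!`; for diffusion-coupled networks
#' the corresponding mean of the conditional deterministic equilibrium.
#' These expectations are what the reduced promoter chain multiplies the
#' association rates by.
#'
#' @inheritParams conditional_pmf_joint
#' @param tf_species Name of the TF species (a gene's output).
#' @return Nonnegative scalar.
#' @export
expected_tf <- function(spec, d, tf_species) {
  cp <- if (is.null(spec$diffusion)) conditional_pmf_joint(spec, d)
        else conditional_equilibrium(spec, d)
  if (!tf_species %in% names(cp$means))
    stop("unknown TF species: ", tf_species)
  unname(cp$means[tf_species])
}

#' Truncation bound for PMF evaluation
#'
#' Per-species box bound `ceil(mean + 10 sqrt(mean) + 20)`, generous for a
#' Poisson tail.
#'
#' @param mean Poisson mean(s).
#' @return Integer bound(s).
#' @export
truncation_bound <- function(mean) as.integer(ceiling(mean + 10 * sqrt(mean) + 20))
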