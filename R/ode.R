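# Deterministic mass-action comparison: steady states of the averaged-out
# ODE model, with multi-start root finding and Jacobian stability.

# Deterministic mass-action flux convention rate * prod z^r / r!, so that
# the deterministic equilibrium of the n-merization pair reproduces the
# conditional Poisson multimer mean b = (beta/beta_-) a^n / n!.
.ode_system <- function(spec) {
  spec1 <- spec
  spec1$epsilon <- 1  # equilibria are invariant to the gene/protein time split
  net <- expand_reactions(spec1)
  R <- net$reactants
  Nmat <- net$products - net$reactants
  rate_eff <- net$rate / apply(R, 2, function(r) prod(factorial(r)))
  prom <- startsWith(net$species, "D")
  # reduced coordinates: drop the first promoter fraction of each gene
  drop_idx <- vapply(spec$genes, function(g)
    which(net$species == paste0("D", binding_set(g)[1], ".", g$id)), integer(1))
  gene_of <- rep(NA_integer_, length(net$species))
  for (i in seq_along(spec$genes)) {
    g <- spec$genes[[i]]
    gene_of[net$species %in% paste0("D", binding_set(g), ".", g$id)] <- i
  }
  free <- setdiff(seq_along(net$species), drop_idx)
  expand <- function(y) {
    z <- numeric(length(net$species))
    z[free] <- y
    for (i in seq_along(spec$genes))
      z[drop_idx[i]] <- 1 - sum(z[setdiff(which(gene_of == i), drop_idx[i])])
    z
  }
  rhs_full <- function(z) {
    zp <- pmax(z, 0)
    flux <- rate_eff
    for (j in seq_along(flux)) {
      nz <- which(R[, j] > 0)
      if (length(nz)) flux[j] <- flux[j] * prod(zp[nz]^R[nz, j])
    }
    as.numeric(Nmat %*% flux)
  }
  list(net = net, free = free, expand = expand,
       rhs = function(y) rhs_full(expand(y))[free],
       species = net$species, prom = prom, gene_of = gene_of,
       drop_idx = drop_idx)
}

.fd_jacobian <- function(f, y, h = 1e-6) {
  f0 <- f(y)
  J <- matrix(0, length(f0), length(y))
  for (k in seq_along(y)) {
    hk <- h * max(1, abs(y[k]))
    yk <- y; yk[k] <- yk[k] + hk
    J[, k] <- (f(yk) - f0) / hk
  }
  J
}

#' Deterministic mass-action steady states of a GRN
#'
#' Builds the averaged-out ODE model of the expanded network (promoter
#' occupancies as fractions in `[0, 1]`, proteins as continuous
#' concentrations) and locates its equilibria by multi-start search:
#' integration to near-steady-state from randomized initial conditions
#' followed by damped-Newton polishing, in reduced coordinates (one promoter
#' fraction per gene eliminated by conservation). Stability is classified by
#' the eigenvalues of the reduced Jacobian.
#'
#' @param spec A valid `grn_spec`.
#' @param n_starts Number of random starts (default 200).
#' @param seed RNG seed for the starts.
#' @param t_final Integration horizon per start (default `2000 / min(decay)`).
#' @param tol Residual norm below which a point counts as an equilibrium.
#' @return An object of class `ode_equilibria`: list with `equilibria` (data
#'   frame: one column per protein species, `stable`, `residual`),
#'   `n_stable`, `n_starts`, `n_converged`.
#' @export
ode_steady_states <- function(spec, n_starts = 200L, seed = 1L,
                              t_final = NULL, tol = 1e-8) {
  bad <- validate_grn(spec)
  if (length(bad)) stop("invalid spec:\n  ", paste(bad, collapse = "\n  "))
  sys <- .ode_system(spec)
  prot <- sys$species[!sys$prom]
  prot_free <- match(prot, sys$species[sys$free])
  kmax <- max(vapply(spec$genes, function(g)
    max(g$production) / g$decay, numeric(1)))
  if (is.null(t_final))
    t_final <- 2000 / min(vapply(spec$genes, `[[`, numeric(1), "decay"))
  set.seed(seed)
  sols <- list(); n_conv <- 0L
  deriv <- function(t, y, parms) list(sys$rhs(y))
  for (s in seq_len(n_starts)) {
    y0 <- numeric(length(sys$free))
    # promoter fractions: uniform on the simplex per gene
    for (i in seq_along(spec$genes)) {
      slots <- which(sys$gene_of[sys$free] == i)
      w <- stats::rgamma(length(slots) + 1L, 1)
      y0[slots] <- (w / sum(w))[-1L]
    }
    y0[prot_free] <- exp(stats::runif(length(prot), log(1e-2), log(10 * kmax)))
    y <- tryCatch(suppressWarnings({
      o <- deSolve::ode(y0, times = c(0, t_final / 20, t_final / 4, t_final),
                        deriv,
                        parms = NULL, method = "lsoda",
                        atol = 1e-10, rtol = 1e-8)
      as.numeric(o[nrow(o), -1])
    }), error = function(e) NULL)
    if (is.null(y) || anyNA(y)) next
    # damped Newton polish
    for (it in 1:300) {
      f <- sys$rhs(y)
      if (max(abs(f)) < tol) break
      J <- .fd_jacobian(sys$rhs, y)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        y2 <- y + lam * step
        if (all(y2[prot_free] >= 0) &&
            max(abs(sys$rhs(y2))) < max(abs(f)) || lam < 1e-4) break
        lam <- lam / 2
      }
      y <- y + lam * step
    }
    res <- max(abs(sys$rhs(y)))
    if (res > tol * 100) next
    n_conv <- n_conv + 1L
    J <- .fd_jacobian(sys$rhs, y)
    stable <- all(Re(eigen(J, only.values = TRUE)$values) < -1e-9)
    sols[[length(sols) + 1L]] <- list(y = y, stable = stable, residual = res)
  }
  # deduplicate on protein coordinates
  eq <- data.frame()
  if (length(sols)) {
    P <- do.call(rbind, lapply(sols, function(s) s$y[prot_free]))
    P[abs(P) < 1e-6] <- 0
    # dedup on protein coordinates, absolute tolerance scaled to the system
    key <- apply(P, 1, function(r)
      paste(round(r / max(1, kmax / 100), 1), collapse = "|"))
    first <- !duplicated(key)
    eq <- data.frame(P[first, , drop = FALSE])
    names(eq) <- prot
    eq$stable <- vapply(sols, `[[`, logical(1), "stable")[first]
    eq$residual <- vapply(sols, `[[`, numeric(1), "residual")[first]
    eq <- eq[order(-eq$stable, eq[[1]]), , drop = FALSE]
    rownames(eq) <- NULL
  }
  structure(list(equilibria = eq, n_stable = sum(eq$stable),
                 n_starts = n_starts, n_converged = n_conv),
            class = "ode_equilibria")
}

#' @export
print.ode_equilibria <- function(x, ...) {
  cat(sprintf("Deterministic equilibria: %d distinct (%d stable) from %d starts\n",
              nrow(x$equilibria), x$n_stable, x$n_starts))
  if (nrow(x$equilibria)) print(x$equilibria, row.names = FALSE)
  invisible(x)
}
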