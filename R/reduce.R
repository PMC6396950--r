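# The slow-promoter-kinetics limit: reduced finite Markov chain over global
# promoter configurations, mixture weights, Poisson-mixture stationary PMF,
# and mode extraction.

#' Build the reduced promoter-configuration generator
#'
#' In the slow-promoter-kinetics limit the promoter process becomes an
#' autonomous finite Markov chain on the `L` global configurations: every
#' binding transition `TF + D_j -> D_j'` of gene `i` contributes the rate
#' `alpha * E[TF | D = d]`, with the conditional expectation taken under the
#' product-Poisson law of the *current* configuration `d` (see
#' [expected_tf()]); unbinding contributes `alpha_-`, and constitutive
#' switching its plain rates. Rates are on the slow (gene) time scale, i.e.
#' not multiplied by `epsilon`.
#'
#' @param spec A valid `grn_spec`.
#' @return An object of class `reduced_generator`: list with `matrix`
#'   (`L x L`, entry `(d', d)` = rate of `d -> d'`, columns sum to zero in
#'   the `dp/dt = Lambda p` convention), `states` (the [grn_states()] table)
#'   and `spec`.
#' @export
build_reduced_generator <- function(spec) {
  bad <- validate_grn(spec)
  if (length(bad)) stop("invalid spec:\n  ", paste(bad, collapse = "\n  "))
  states <- grn_states(spec)
  L <- nrow(states)
  ids <- names(spec$genes)
  M <- matrix(0, L, L)
  trs <- lapply(spec$genes, gene_transitions)
  for (from_idx in seq_len(L)) {
    cfg <- stats::setNames(unlist(states[from_idx, ids], use.names = FALSE), ids)
    cp <- if (is.null(spec$diffusion)) conditional_pmf_joint(spec, cfg)
          else conditional_equilibrium(spec, cfg)
    for (i in seq_along(ids)) {
      g <- spec$genes[[i]]
      tr <- trs[[i]]
      here <- tr[tr$from == cfg[i], , drop = FALSE]
      for (r in seq_len(nrow(here))) {
        cfg2 <- cfg
        cfg2[i] <- here$to[r]
        to_idx <- state_index(spec, cfg2) + 1L
        s <- here$site[r]
        rate <- switch(here$kind[r],
          bind = g$alpha[s] * unname(cp$means[g$binding_sites[s]]),
          activate = g$alpha[s],
          unbind = ,
          deactivate = g$alpha_off[s])
        M[to_idx, from_idx] <- M[to_idx, from_idx] + rate
      }
    }
  }
  diag(M) <- diag(M) - colSums(M)
  structure(list(matrix = M, states = states, spec = spec),
            class = "reduced_generator")
}

#' @export
print.reduced_generator <- function(x, ...) {
  cat(sprintf("Reduced promoter-chain generator: %d states\n", nrow(x$matrix)))
  invisible(x)
}

# Dense null-space stationary law of an irreducible generator block
# (columns-sum-to-zero convention): solve with the normalization row.
.stationary_block <- function(M) {
  n <- nrow(M)
  if (n == 1L) return(1)
  A <- M
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  w <- tryCatch(solve(A, b), error = function(e) {
    ns <- svd(M)$v[, n]
    ns / sum(ns)
  })
  w[w < 0 & w > -1e-12] <- 0
  w / sum(w)
}

#' Stationary weights of the reduced promoter chain
#'
#' Solves `Lambda_r lambda = 0`, `lambda >= 0`, `sum(lambda) = 1`. For an
#' irreducible chain the solution is the unique principal null vector. If the
#' chain is reducible (e.g. non-leaky circuits, where some configurations
#' cannot be re-entered once left), the closed communicating classes are
#' identified: with exactly one closed class its stationary law -- extended
#' by zeros -- is the unique stationary distribution and is returned; with
#' several, an initial promoter distribution must be supplied and the weight
#' of each closed class is its absorption probability from `init`.
#'
#' @param gen A `reduced_generator`, or a bare square generator matrix in the
#'   columns-sum-to-zero convention.
#' @param init Optional initial probability vector over configurations (only
#'   used, and then required, when several closed classes exist).
#' @return Numeric weight vector `lambda` with attributes `unique` (logical:
#'   was the stationary law independent of `init`?) and `closed_classes`
#'   (list of 1-based state index vectors).
#' @export
stationary_weights <- function(gen, init = NULL) {
  M <- if (inherits(gen, "reduced_generator")) gen$matrix else as.matrix(gen)
  L <- nrow(M)
  if (max(abs(colSums(M))) > 1e-8 * max(abs(M)))
    stop("not a generator: columns must sum to zero")
  adj <- t(M) > 0
  diag(adj) <- FALSE
  gph <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  comp <- igraph::components(gph, mode = "strong")
  classes <- split(seq_len(L), comp$membership)
  closed <- Filter(function(cl) {
    out <- M[-cl, cl, drop = FALSE]
    all(out <= 0) || sum(out[out > 0]) == 0
  }, classes)
  closed <- unname(closed)
  lam <- numeric(L)
  if (length(closed) == 1L) {
    cl <- closed[[1L]]
    lam[cl] <- .stationary_block(M[cl, cl, drop = FALSE])
    uniq <- TRUE
  } else {
    if (is.null(init))
      stop(sprintf(paste("reducible chain with %d closed classes (kernel",
                         "dimension %d): supply an initial distribution"),
                   length(closed), length(closed)))
    stopifnot(length(init) == L, all(init >= 0))
    init <- init / sum(init)
    trans <- setdiff(seq_len(L), unlist(closed))
    for (cl in closed) {
      u <- numeric(L)
      u[cl] <- 1
      if (length(trans)) {
        At <- t(M)[trans, trans, drop = FALSE]
        bt <- -t(M)[trans, -trans, drop = FALSE] %*% u[-trans]
        u[trans] <- solve(At, bt)
      }
      p_abs <- sum(init * u)
      lam[cl] <- p_abs * .stationary_block(M[cl, cl, drop = FALSE])
    }
    uniq <- FALSE
  }
  structure(lam, unique = uniq, closed_classes = closed)
}

#' Reduced-chain transition matrix
#'
#' `Q(t) = exp(t * Lambda_r)`: column `d` holds the distribution over
#' configurations after slow time `t` starting from `d`.
#'
#' @param gen A `reduced_generator` or generator matrix.
#' @param t Nonnegative time on the slow (gene reaction) scale.
#' @return Dense column-stochastic `L x L` matrix.
#' @export
transition_matrix <- function(gen, t) {
  stopifnot(t >= 0)
  M <- if (inherits(gen, "reduced_generator")) gen$matrix else as.matrix(gen)
  as.matrix(Matrix::expm(t * Matrix::Matrix(M)))
}

#' Poisson-mixture stationary PMF in the slow-promoter-kinetics limit
#'
#' The stationary PMF of the network as `epsilon -> 0` is the mixture
#' `pi(x) = sum_d lambda_d pi_{X|d}(x)` of the `L` conditional
#' product-Poisson laws, weighted by the stationary law of the reduced
#' promoter chain.
#'
#' @param spec A valid `grn_spec`.
#' @param joint If `TRUE` the components are joint in proteins and
#'   multimers; default is the marginal over the (non-multimerized) protein
#'   process, the experimentally observable one.
#' @param init Passed to [stationary_weights()] for reducible chains with
#'   several closed classes.
#' @return An object of class `poisson_mixture`: list with `locations`
#'   (`L x n_species` matrix of component Poisson means), `weights`,
#'   `species`, `states`, and the `reduced_generator` used.
#' @export
mixture_pmf <- function(spec, joint = FALSE, init = NULL) {
  gen <- build_reduced_generator(spec)
  lam <- stationary_weights(gen, init = init)
  comps <- lapply(gen$states$index, function(d) {
    if (is.null(spec$diffusion)) conditional_pmf_joint(spec, d)
    else conditional_equilibrium(spec, d)
  })
  species <- if (joint) names(comps[[1]]$means) else names(comps[[1]]$monomer_means)
  loc <- do.call(rbind, lapply(comps, function(cp)
    if (joint) cp$means else cp$monomer_means))
  dimnames(loc) <- list(NULL, species)
  structure(list(locations = loc, weights = as.numeric(lam),
                 weight_attributes = attributes(lam),
                 species = species, states = gen$states, generator = gen,
                 joint = joint),
            class = "poisson_mixture")
}

#' @export
print.poisson_mixture <- function(x, ...) {
  cat(sprintf("Poisson mixture: %d components over (%s)\n",
              nrow(x$locations), paste(x$species, collapse = ", ")))
  df <- data.frame(index = x$states$index, x$locations,
                   weight = signif(x$weights, 6), check.names = FALSE)
  print(utils::head(df[order(-df$weight), ], 10), row.names = FALSE)
  invisible(x)
}

#' Evaluate a Poisson mixture PMF at lattice points
#'
#' @param mix A `poisson_mixture`.
#' @param x Integer vector (one point) or matrix (one point per row), columns
#'   ordered as `mix$species`.
#' @return Probability mass at each point.
#' @export
dmixture <- function(mix, x) {
  x <- rbind(x)
  stopifnot(ncol(x) == ncol(mix$locations))
  vapply(seq_len(nrow(x)), function(r) {
    sum(mix$weights * apply(mix$locations, 1, function(mu)
      prod(stats::dpois(x[r, ], mu))))
  }, numeric(1))
}

#' Evaluate a Poisson mixture on a full box `0:upper` per species
#'
#' @param mix A `poisson_mixture`.
#' @param upper Integer upper bounds, recycled over species; default the
#'   [truncation_bound()] of the largest component mean per species.
#' @return List with `grid` (array with `dim = upper + 1`) and `upper`.
#' @export
mixture_grid <- function(mix, upper = NULL) {
  p <- ncol(mix$locations)
  if (is.null(upper))
    upper <- truncation_bound(apply(mix$locations, 2, max))
  upper <- rep_len(as.integer(upper), p)
  dims <- upper + 1L
  grid <- array(0, dim = dims)
  for (c_ in seq_len(nrow(mix$locations))) {
    w <- mix$weights[c_]
    if (w == 0) next
    vecs <- lapply(seq_len(p), function(j)
      stats::dpois(0:upper[j], mix$locations[c_, j]))
    comp <- Reduce(function(a, b) outer(a, b), vecs)
    grid <- grid + w * comp
  }
  list(grid = grid, upper = upper, species = mix$species)
}

# Strict-local-maximum scan of an array on the integer lattice: a point is a
# maximum if >= all axis neighbors and > at least one.
lattice_maxima <- function(grid) {
  dims <- dim(grid)
  if (is.null(dims)) dims <- length(grid)
  nd <- length(dims)
  ge_all <- array(TRUE, dim = dims)
  gt_any <- array(FALSE, dim = dims)
  for (ax in seq_len(nd)) {
    for (dir in c(-1L, 1L)) {
      idx_self <- lapply(dims, seq_len)
      idx_nb <- idx_self
      if (dir == 1L) {
        idx_self[[ax]] <- seq_len(dims[ax] - 1L)
        idx_nb[[ax]] <- 2:dims[ax]
      } else {
        idx_self[[ax]] <- 2:dims[ax]
        idx_nb[[ax]] <- seq_len(dims[ax] - 1L)
      }
      self <- do.call(`[`, c(list(grid), idx_self, list(drop = FALSE)))
      nb <- do.call(`[`, c(list(grid), idx_nb, list(drop = FALSE)))
      geh <- array(TRUE, dim = dims); gth <- array(FALSE, dim = dims)
      sub <- do.call(`[<-`, c(list(geh), idx_self, list(self >= nb)))
      geh <- sub
      gth <- do.call(`[<-`, c(list(gth), idx_self, list(self > nb)))
      ge_all <- ge_all & geh
      gt_any <- gt_any | gth
    }
  }
  which(ge_all & gt_any, arr.ind = TRUE) - 1L
}

#' Extract the modes of a Poisson mixture
#'
#' Two notions are reported. *Component modes*: the distinct component mean
#' vectors (coincident locations merged, weights summed) carrying weight
#' above `weight_floor` -- each Poisson component of the mixture is a "mode"
#' in this sense. *Lattice maxima*: strict local maxima of the mixture PMF
#' found by exhaustive scan of the truncation box (components with nearby
#' means can merge into a single maximum).
#'
#' @param mix A `poisson_mixture`.
#' @param weight_floor Components at or below this weight are dropped
#'   (default `1e-6`, separating structurally zero-weight configurations
#'   from numerically tiny ones).
#' @param lattice Scan for lattice maxima? Skipped with a message when the
#'   box exceeds `max_lattice` points.
#' @param upper Box bounds for the lattice scan (default as in
#'   [mixture_grid()]).
#' @param max_lattice Largest box size scanned.
#' @return An object of class `mode_report`: list with `component_modes`
#'   (data frame: one location column per species, `weight`, `n_merged`),
#'   `lattice_maxima` (matrix of lattice points, or `NULL` if not scanned)
#'   and `weight_floor`.
#' @export
find_modes <- function(mix, weight_floor = 1e-6, lattice = TRUE,
                       upper = NULL, max_lattice = 2e6) {
  stopifnot(weight_floor >= 0, weight_floor < 1)
  key <- apply(mix$locations, 1, function(r)
    paste(format(r, digits = 12), collapse = "|"))
  agg_w <- tapply(mix$weights, key, sum)
  agg_n <- tapply(mix$weights, key, length)
  first <- !duplicated(key)
  locs <- mix$locations[first, , drop = FALSE]
  keys <- key[first]
  cm <- data.frame(locs, check.names = FALSE)
  cm$weight <- as.numeric(agg_w[keys])
  cm$n_merged <- as.integer(agg_n[keys])
  cm <- cm[cm$weight > weight_floor, , drop = FALSE]
  cm <- cm[order(-cm$weight), , drop = FALSE]
  rownames(cm) <- NULL
  lm <- NULL
  if (lattice) {
    if (is.null(upper))
      upper <- truncation_bound(apply(mix$locations, 2, max))
    if (prod(upper + 1) <= max_lattice) {
      mg <- mixture_grid(mix, upper)
      lm <- lattice_maxima(mg$grid)
      colnames(lm) <- mix$species
    } else {
      message("lattice scan skipped: box has more than max_lattice points")
    }
  }
  structure(list(component_modes = cm, lattice_maxima = lm,
                 weight_floor = weight_floor),
            class = "mode_report")
}

#' @export
print.mode_report <- function(x, ...) {
  cat(sprintf("Component modes (weight > %g): %d\n", x$weight_floor,
              nrow(x$component_modes)))
  print(x$component_modes, row.names = FALSE)
  if (!is.null(x$lattice_maxima))
    cat(sprintf("Lattice local maxima: %d\n", nrow(x$lattice_maxima)))
  invisible(x)
}

#' Export a PMF on a box as TSV
#'
#' Columns: one copy-number column per species, then `probability`.
#'
#' @param mix A `poisson_mixture`, or a single `conditional_poisson`
#'   (exported as a one-component mixture of its joint law).
#' @param path Output path, or `NULL` to return the data frame.
#' @param upper Box bounds (see [mixture_grid()]).
#' @return The data frame, invisibly when written.
#' @export
write_pmf_tsv <- function(mix, path = NULL, upper = NULL) {
  if (inherits(mix, "conditional_poisson"))
    mix <- structure(list(
      locations = matrix(mix$means, 1,
                         dimnames = list(NULL, names(mix$means))),
      weights = 1, species = names(mix$means)), class = "poisson_mixture")
  mg <- mixture_grid(mix, upper)
  pts <- expand.grid(lapply(mg$upper, function(u) 0:u))
  names(pts) <- mix$species
  pts$probability <- as.vector(mg$grid)
  if (is.null(path)) return(pts)
  utils::write.table(pts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pts)
}
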