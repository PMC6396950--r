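# Exact stochastic simulation (Gillespie direct method) of the expanded
# reaction network, with occupancy and mode-switching utilities.

#' Simulate a GRN by the Gillespie algorithm
#'
#' Exact continuous-time Markov-chain sampling of the full reaction network
#' (gene reactions at rate `epsilon * k`, protein reactions unscaled), with
#' the state recorded on a regular sampling grid.
#'
#' @param spec A valid `grn_spec`.
#' @param epsilon Time-scale ratio (default the spec's).
#' @param t_max Simulation end time (fast/protein time units).
#' @param sample_dt Sampling interval; default `1 / min(decay rates)`, the
#'   protein relaxation time.
#' @param init Optional named initial copy-number vector (defaults: every
#'   promoter in its first configuration, zero proteins).
#' @param seed Optional RNG seed (`set.seed()`), for reproducible paths.
#' @param max_events Safety cap on the number of reaction events.
#' @return An object of class `trajectory`: list with `time`, `states`
#'   (matrix, one column per species), `species`, `epsilon`, `seed`,
#'   `events` and `exhausted` (`TRUE` if `max_events` was hit early).
#' @export
ssa_simulate <- function(spec, epsilon = spec$epsilon, t_max, sample_dt = NULL,
                         init = NULL, seed = NULL, max_events = 5e8) {
  stopifnot(t_max > 0)
  spec2 <- spec
  spec2$epsilon <- epsilon
  net <- expand_reactions(spec2)
  if (is.null(sample_dt))
    sample_dt <- 1 / min(vapply(spec$genes, `[[`, numeric(1), "decay"))
  x0 <- stats::setNames(integer(length(net$species)), net$species)
  for (g in spec$genes) x0[paste0("D", binding_set(g)[1], ".", g$id)] <- 1L
  if (!is.null(init)) {
    stopifnot(all(names(init) %in% net$species))
    x0[names(init)] <- as.integer(init)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- ssa_core(net$reactants, net$products - net$reactants, net$rate,
                  x0, t_max, sample_dt, max_events)
  states <- res$states
  colnames(states) <- net$species
  structure(list(
    time = seq(0, by = sample_dt, length.out = nrow(states)),
    states = states, species = net$species,
    epsilon = epsilon, seed = seed, events = res$events,
    exhausted = res$exhausted
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("SSA trajectory: %d samples to t = %g (%g events, epsilon = %g)\n",
              nrow(x$states), max(x$time), x$events, x$epsilon))
  invisible(x)
}

#' Occupancy histogram of a trajectory
#'
#' Normalized time-sampled occupancy of one species (or the joint occupancy
#' of several), comparable with an FSP marginal on the same box.
#'
#' @param traj A `trajectory`.
#' @param species Species to tabulate.
#' @param upper Upper copy-number bound(s) of the histogram box (counts above
#'   are clamped into the top cell).
#' @param burn_in Samples with `time < burn_in` are discarded.
#' @return A normalized vector (one species) or array (several).
#' @export
trajectory_histogram <- function(traj, species, upper, burn_in = 0) {
  keep <- traj$time >= burn_in
  X <- traj$states[keep, species, drop = FALSE]
  upper <- rep_len(as.integer(upper), length(species))
  X <- pmin(X, rep(upper, each = nrow(X)))
  dims <- upper + 1L
  idx <- as.integer(X[, 1])
  if (length(species) > 1L)
    for (s in 2:length(species))
      idx <- idx + as.integer(X[, s]) * prod(dims[seq_len(s - 1L)])
  h <- tabulate(idx + 1L, nbins = prod(dims))
  h <- h / sum(h)
  if (length(species) == 1L) stats::setNames(h, 0:upper) else array(h, dims)
}

#' Detect dominant-protein switching events along a trajectory
#'
#' Labels each sample by the protein with the highest copy number; a
#' sustained episode is a run of at least `min_run` consecutive samples with
#' the same label, and a switch is a transition between consecutive distinct
#' episodes. For a ring circuit the cyclic fraction is the share of switches
#' that follow the cyclic successor order of `proteins` (X -> Y -> Z -> X).
#'
#' @param traj A `trajectory`.
#' @param proteins Protein species, in cyclic order.
#' @param min_run Minimum episode length in samples (default 5).
#' @param burn_in Samples with `time < burn_in` are discarded.
#' @return List with `n_switches`, `cyclic_fraction` (`NA` if no switches),
#'   `episodes` (data frame of label and length), `mean_episode` and
#'   `max_episode` (episode lengths in samples: short episodes everywhere
#'   mean dominance is never sustained, as under fast promoter kinetics).
#' @export
detect_switches <- function(traj, proteins, min_run = 5L, burn_in = 0) {
  keep <- traj$time >= burn_in
  X <- traj$states[keep, proteins, drop = FALSE]
  lab <- max.col(X, ties.method = "first")
  r <- rle(lab)
  ep <- data.frame(label = r$values, length = r$lengths)
  ep <- ep[ep$length >= min_run, , drop = FALSE]
  # merge adjacent episodes with the same label
  if (nrow(ep) > 1L) {
    same <- c(FALSE, ep$label[-1] == ep$label[-nrow(ep)])
    grp <- cumsum(!same)
    ep <- data.frame(label = tapply(ep$label, grp, `[`, 1L),
                     length = tapply(ep$length, grp, sum))
  }
  n_sw <- max(nrow(ep) - 1L, 0L)
  cyc <- NA_real_
  if (n_sw > 0L) {
    succ <- c(seq_along(proteins)[-1L], 1L)
    from <- ep$label[-nrow(ep)]; to <- ep$label[-1L]
    cyc <- mean(to == succ[from])
  }
  list(n_switches = n_sw, cyclic_fraction = cyc, episodes = ep,
       mean_episode = if (nrow(ep)) mean(ep$length) else 0,
       max_episode = if (nrow(ep)) max(ep$length) else 0)
}
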