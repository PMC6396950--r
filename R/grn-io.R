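#' Read and write GRN model files
#'
#' GRN specifications are stored as YAML with top-level keys `format`
#' (`"spkmix/1"`), `epsilon`, `genes` and optionally `diffusion`. Each entry
#' of `genes` mirrors the [gene_block()] fields: `id`, `binding_sites`,
#' `alpha`, `alpha_off`, `production` (map from configuration code to rate),
#' `decay`, `cooperativity`, `beta`, `beta_off`, `competitive`,
#' `exclude_configs`. `diffusion` is a list of `{from, to, rate}` maps.
#'
#' @param path File path.
#' @return `read_grn()`: a `grn_spec`.
#' @export
read_grn <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$format) || !identical(y$format, "spkmix/1"))
    stop("not a spkmix/1 model file: ", path)
  genes <- lapply(y$genes, function(g) {
    gene_block(
      id = g$id,
      binding_sites = if (is.null(g$binding_sites)) character() else unlist(g$binding_sites),
      alpha = unlist(g$alpha), alpha_off = unlist(g$alpha_off),
      production = unlist(g$production),
      decay = g$decay,
      cooperativity = if (is.null(g$cooperativity)) 1L else g$cooperativity,
      beta = g$beta, beta_off = g$beta_off,
      competitive = isTRUE(g$competitive),
      exclude_configs = if (is.null(g$exclude_configs)) character() else unlist(g$exclude_configs))
  })
  diffusion <- NULL
  if (!is.null(y$diffusion) && length(y$diffusion))
    diffusion <- do.call(rbind, lapply(y$diffusion, function(d)
      data.frame(from = d$from, to = d$to, rate = d$rate)))
  grn_spec(genes, diffusion = diffusion,
           epsilon = if (is.null(y$epsilon)) 1 else y$epsilon)
}

#' @rdname read_grn
#' @param spec A `grn_spec`.
#' @return `write_grn()`: `path`, invisibly.
#' @export
write_grn <- function(spec, path) {
  y <- list(
    format = "spkmix/1",
    epsilon = spec$epsilon,
    genes = unname(lapply(spec$genes, function(g) {
      out <- list(
        id = g$id,
        binding_sites = as.list(g$binding_sites),
        alpha = as.list(g$alpha), alpha_off = as.list(g$alpha_off),
        production = as.list(g$production),
        decay = g$decay,
        cooperativity = g$cooperativity)
      if (!is.null(g$beta)) { out$beta <- g$beta; out$beta_off <- g$beta_off }
      if (g$competitive) out$competitive <- TRUE
      excl <- setdiff(g$exclude_configs, if (g$competitive) "11" else character())
      if (length(excl)) out$exclude_configs <- as.list(excl)
      out
    })))
  if (!is.null(spec$diffusion))
    y$diffusion <- lapply(seq_len(nrow(spec$diffusion)), function(r)
      list(from = spec$diffusion$from[r], to = spec$diffusion$to[r],
           rate = spec$diffusion$rate[r]))
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}
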