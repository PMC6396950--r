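#' Define a gene expression block
#'
#' A gene expression block is the elementary unit of a gene regulatory
#' network (GRN): a single-copy gene whose promoter carries zero, one or two
#' transcription-factor (TF) binding sites, together with the protein
#' production, decay and (optional) multimerization reactions of its output.
#'
#' The promoter configuration set `B` is `{"0","1"}` for promoters with at
#' most one site, and a subset of `{"00","01","10","11"}` for two-site
#' promoters: the full set for independent binding, with `"11"` removed for
#' competitive binding, or with any configuration listed in `exclude_configs`
#' removed (used e.g. for circuits where one TF can only bind after another).
#' The first digit of a configuration code is the occupancy of the first
#' binding site.
#'
#' @param id Gene identifier (also the name of its monomer protein species).
#' @param binding_sites Character vector (length 0, 1 or 2). Each entry names
#'   the TF species regulating that site -- the *output* species of some gene
#'   in the network (the monomer name for cooperativity 1, or `"<id>c"` for a
#'   multimerized TF) -- or the keyword `"constitutive"` for a promoter that
#'   switches autonomously between an inactive and an active configuration
#'   without consuming a TF. `character(0)` is shorthand for a constitutive
#'   promoter.
#' @param alpha,alpha_off Per-site association and dissociation rates (slow
#'   promoter time scale; association is per TF copy). Recycled to the number
#'   of sites.
#' @param production Named numeric vector of production rates `k_j >= 0`
#'   (fast time scale), one per configuration code in `B`. Missing
#'   configurations default to 0.
#' @param decay Protein decay/dilution rate `k_- > 0` (fast time scale).
#' @param cooperativity Cooperativity index `n >= 1`: number of protein
#'   copies forming the multimer that acts as TF. If `n > 1` the gene's
#'   output species is the multimer `"<id>c"`.
#' @param beta,beta_off Multimerization forward/backward rates (fast time
#'   scale); required iff `cooperativity > 1`.
#' @param competitive For two-site promoters: if `TRUE` the doubly-bound
#'   configuration `"11"` is disallowed (the two TFs compete for the same
#'   location).
#' @param exclude_configs Character vector of two-site configuration codes to
#'   remove from `B` (transitions through them are structurally absent).
#'
#' @return An object of class `gene_block`.
#' @seealso [grn_spec()], [validate_grn()]
#' @export
gene_block <- function(id, binding_sites = character(), alpha = numeric(),
                       alpha_off = numeric(), production, decay,
                       cooperativity = 1L, beta = NULL, beta_off = NULL,
                       competitive = FALSE, exclude_configs = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  binding_sites <- as.character(binding_sites)
  if (length(binding_sites) == 0L) binding_sites <- "constitutive"
  nsites <- if (identical(binding_sites, "constitutive")) 1L else length(binding_sites)
  alpha <- rep_len(as.numeric(alpha), nsites)
  alpha_off <- rep_len(as.numeric(alpha_off), nsites)
  if (isTRUE(competitive)) exclude_configs <- union(exclude_configs, "11")
  g <- structure(list(
    id = id,
    binding_sites = binding_sites,
    alpha = alpha,
    alpha_off = alpha_off,
    production = production,
    decay = as.numeric(decay),
    cooperativity = as.integer(cooperativity),
    beta = if (is.null(beta)) NULL else as.numeric(beta),
    beta_off = if (is.null(beta_off)) NULL else as.numeric(beta_off),
    competitive = isTRUE(competitive),
    exclude_configs = as.character(exclude_configs)
  ), class = "gene_block")
  B <- binding_set(g)
  prod <- rep_len(0, length(B))
  names(prod) <- B
  if (!is.null(names(production))) {
    known <- intersect(names(production), B)
    prod[known] <- production[known]
    extra <- setdiff(names(production), B)
    if (length(extra))
      warning(sprintf("gene %s: production rates for configurations not in B dropped: %s",
                      id, paste(extra, collapse = ", ")))
  } else {
    prod[seq_along(production)] <- production
  }
  g$production <- prod
  g
}

#' Binding-configuration set of a gene block
#'
#' @param gene A `gene_block`.
#' @return Character vector of configuration codes, sorted as binary numbers.
#' @export
binding_set <- function(gene) {
  if (identical(gene$binding_sites, "constitutive") ||
      length(gene$binding_sites) <= 1L) {
    c("0", "1")
  } else {
    setdiff(c("00", "01", "10", "11"), gene$exclude_configs)
  }
}

#' Output TF species of a gene block
#'
#' The monomer species for cooperativity 1, the multimer species `"<id>c"`
#' otherwise.
#' @param gene A `gene_block`.
#' @return Species name.
#' @export
output_species <- function(gene) {
  if (gene$cooperativity > 1L) paste0(gene$id, "c") else gene$id
}

#' Assemble a gene regulatory network specification
#'
#' @param genes List of [gene_block()] objects.
#' @param diffusion Optional data frame with columns `from`, `to`, `rate`:
#'   reversible transport reactions `from <-> to` at rate `rate` in both
#'   directions (fast time scale), e.g. protein exchange between cells.
#' @param epsilon Time-scale ratio `eps > 0`: all gene (promoter) reaction
#'   rates are multiplied by `epsilon`; the slow-promoter-kinetics limit is
#'   `epsilon -> 0`.
#' @return An object of class `grn_spec`.
#' @export
grn_spec <- function(genes, diffusion = NULL, epsilon = 1) {
  stopifnot(is.list(genes), length(genes) >= 1L)
  if (!all(vapply(genes, inherits, logical(1), "gene_block")))
    stop("all elements of `genes` must be gene_block objects")
  names(genes) <- vapply(genes, `[[`, character(1), "id")
  if (anyDuplicated(names(genes)))
    stop("duplicate gene ids (each gene is present in a single copy)")
  if (!is.null(diffusion)) {
    diffusion <- as.data.frame(diffusion)
    stopifnot(all(c("from", "to", "rate") %in% names(diffusion)))
    diffusion$from <- as.character(diffusion$from)
    diffusion$to <- as.character(diffusion$to)
    diffusion$rate <- as.numeric(diffusion$rate)
  }
  structure(list(genes = genes, diffusion = diffusion,
                 epsilon = as.numeric(epsilon)),
            class = "grn_spec")
}

#' @export
print.grn_spec <- function(x, ...) {
  cat(sprintf("GRN: %d gene(s), %d promoter configuration(s), epsilon = %g\n",
              length(x$genes), n_states(x), x$epsilon))
  for (g in x$genes) {
    sites <- if (identical(g$binding_sites, "constitutive")) "constitutive"
             else paste(g$binding_sites, collapse = ", ")
    cat(sprintf("  %s: sites [%s], n = %d, B = {%s}\n", g$id, sites,
                g$cooperativity, paste(binding_set(g), collapse = ",")))
  }
  if (!is.null(x$diffusion))
    cat(sprintf("  diffusion couplings: %d\n", nrow(x$diffusion)))
  invisible(x)
}

#' Total number of global promoter configurations
#'
#' `L = prod_i |B_i|`.
#' @param spec A `grn_spec`.
#' @return Integer `L`.
#' @export
n_states <- function(spec) {
  prod(vapply(spec$genes, function(g) length(binding_set(g)), numeric(1)))
}

#' Validate a GRN specification against the structural assumptions
#'
#' Checks the structural assumptions of the slow-promoter-kinetics theory:
#' (A1) at most two binding sites per promoter; (A2) one cooperativity index
#' per TF, with multimerization rates present iff `n > 1`; (A3) single gene
#' copies (enforced by construction); (A4) the directed graph of gene
#' expression blocks (edge A -> B iff A's output is an input of B) is
#' connected; plus rate positivity and that every TF referenced by a binding
#' site is the output of some gene in the network.
#'
#' @param spec A `grn_spec`.
#' @return Character vector of violations; empty iff the spec is valid.
#' @export
validate_grn <- function(spec) {
  bad <- character()
  outputs <- vapply(spec$genes, output_species, character(1))
  for (g in spec$genes) {
    sites <- g$binding_sites
    if (!identical(sites, "constitutive")) {
      if (length(sites) > 2L)
        bad <- c(bad, sprintf(
          "A1: gene %s has %d binding sites (each promoter can have up to two TFs)",
          g$id, length(sites)))
      unknown <- setdiff(sites, outputs)
      if (length(unknown))
        bad <- c(bad, sprintf(
          "gene %s: binding site TF(s) %s are not the output of any gene in the network",
          g$id, paste(unknown, collapse = ", ")))
    }
    if (g$cooperativity < 1L)
      bad <- c(bad, sprintf("gene %s: cooperativity index must be >= 1", g$id))
    if (g$cooperativity > 1L && (is.null(g$beta) || is.null(g$beta_off) ||
                                 g$beta <= 0 || g$beta_off <= 0))
      bad <- c(bad, sprintf(
        "A2: gene %s has cooperativity %d but no positive multimerization rates",
        g$id, g$cooperativity))
    if (g$cooperativity == 1L && (!is.null(g$beta) || !is.null(g$beta_off)))
      bad <- c(bad, sprintf(
        "gene %s: multimerization rates given but cooperativity is 1", g$id))
    if (!is.finite(g$decay) || g$decay <= 0)
      bad <- c(bad, sprintf("gene %s: decay rate must be positive", g$id))
    if (any(g$production < 0) || any(!is.finite(g$production)))
      bad <- c(bad, sprintf("gene %s: production rates must be finite and >= 0", g$id))
    if (any(g$alpha < 0) || any(g$alpha_off < 0))
      bad <- c(bad, sprintf("gene %s: binding rates must be >= 0", g$id))
    B <- binding_set(g)
    if (length(B) < 2L)
      bad <- c(bad, sprintf(
        "gene %s: binding set has fewer than 2 configurations after exclusions", g$id))
  }
  if (!is.finite(spec$epsilon) || spec$epsilon < 0)
    bad <- c(bad, "epsilon must be a nonnegative number")
  if (!is.null(spec$diffusion)) {
    known <- unlist(lapply(spec$genes, function(g)
      c(g$id, if (g$cooperativity > 1L) output_species(g))))
    unk <- setdiff(c(spec$diffusion$from, spec$diffusion$to), known)
    if (length(unk))
      bad <- c(bad, sprintf("diffusion couples unknown species: %s",
                            paste(unk, collapse = ", ")))
  }
  # A4: connectivity of the block graph (as an undirected skeleton of the
  # directed wiring; an isolated constitutive gene network of size 1 is fine)
  if (length(spec$genes) > 1L) {
    ids <- names(spec$genes)
    adj <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (g in spec$genes) {
      if (identical(g$binding_sites, "constitutive")) next
      for (tf in g$binding_sites) {
        src <- ids[outputs == tf]
        if (length(src)) adj[src, g$id] <- 1
      }
    }
    if (!is.null(spec$diffusion)) {
      sp2gene <- function(s) {
        hit <- vapply(spec$genes, function(g)
          g$id == s || output_species(g) == s, logical(1))
        ids[hit][1]
      }
      for (r in seq_len(nrow(spec$diffusion))) {
        a <- sp2gene(spec$diffusion$from[r]); b <- sp2gene(spec$diffusion$to[r])
        if (!is.na(a) && !is.na(b)) adj[a, b] <- adj[b, a] <- 1
      }
    }
    gph <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
    if (igraph::components(gph)$no > 1L)
      bad <- c(bad, "A4: the graph of gene expression blocks is not connected")
  }
  bad
}

#' Enumerate all global promoter configurations
#'
#' A global configuration is `d = (d_1, ..., d_N)` with `d_i` in the binding
#' set `B_i` of gene `i`. Configurations are indexed `0 .. L-1` by a
#' mixed-radix code: the digit of gene `i` is the position of its
#' configuration in the sorted binding set, the first gene being the most
#' significant digit (the binary-number encoding when all sets are full).
#'
#' @param spec A `grn_spec`.
#' @return A data frame with one row per configuration: column `index`
#'   (0-based) and one character column per gene holding its configuration
#'   code; attribute `"radix"` holds `|B_i|`.
#' @export
grn_states <- function(spec) {
  Bs <- lapply(spec$genes, binding_set)
  radix <- vapply(Bs, length, integer(1))
  grid <- expand.grid(rev(Bs), stringsAsFactors = FALSE)[, rev(seq_along(Bs)), drop = FALSE]
  names(grid) <- names(spec$genes)
  idx <- integer(nrow(grid))
  for (i in seq_along(Bs)) {
    digit <- match(grid[[i]], Bs[[i]]) - 1L
    idx <- idx * radix[i] + digit
  }
  out <- cbind(data.frame(index = idx), grid)
  out <- out[order(out$index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "radix") <- radix
  out
}

#' Map a configuration vector to its index, and back
#'
#' @param spec A `grn_spec`.
#' @param config Character vector of per-gene configuration codes (in gene
#'   order).
#' @return `state_index()`: the 0-based index; `state_config()`: the
#'   configuration codes for a given index.
#' @export
state_index <- function(spec, config) {
  Bs <- lapply(spec$genes, binding_set)
  stopifnot(length(config) == length(Bs))
  idx <- 0L
  for (i in seq_along(Bs)) {
    digit <- match(config[i], Bs[[i]]) - 1L
    if (is.na(digit))
      stop(sprintf("'%s' is not a configuration of gene %s", config[i],
                   names(Bs)[i]))
    idx <- idx * length(Bs[[i]]) + digit
  }
  idx
}

#' @rdname state_index
#' @param index 0-based configuration index.
#' @export
state_config <- function(spec, index) {
  Bs <- lapply(spec$genes, binding_set)
  radix <- vapply(Bs, length, integer(1))
  stopifnot(index >= 0, index < prod(radix))
  out <- character(length(Bs))
  for (i in rev(seq_along(Bs))) {
    out[i] <- Bs[[i]][index %% radix[i] + 1L]
    index <- index %/% radix[i]
  }
  names(out) <- names(Bs)
  out
}

# Allowed single-site transitions of one gene: data frame of (from, to, site,
# kind) with kind "bind" (site 0 -> 1) or "unbind"; constitutive promoters use
# kind "activate"/"deactivate" with no TF.
gene_transitions <- function(gene) {
  B <- binding_set(gene)
  if (identical(gene$binding_sites, "constitutive")) {
    return(data.frame(from = c("0", "1"), to = c("1", "0"), site = 1L,
                      kind = c("activate", "deactivate"),
                      stringsAsFactors = FALSE))
  }
  nsite <- length(gene$binding_sites)
  out <- NULL
  for (from in B) for (s in seq_len(nsite)) {
    digits <- strsplit(from, "")[[1]]
    digits[s] <- if (digits[s] == "0") "1" else "0"
    to <- paste(digits, collapse = "")
    if (!to %in% B) next
    kind <- if (substr(from, s, s) == "0") "bind" else "unbind"
    out <- rbind(out, data.frame(from = from, to = to, site = s, kind = kind,
                                 stringsAsFactors = FALSE))
  }
  out
}
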