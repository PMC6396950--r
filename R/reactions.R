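#' Expand a GRN specification into an explicit stochastic reaction network
#'
#' Emits, per gene: the binding/unbinding (or autonomous switching) reactions
#' for every allowed promoter-configuration transition (class `slow_gene`,
#' rates multiplied by `epsilon`), one production reaction per configuration
#' with a positive rate (class `fast_protein`), protein decay, the reversible
#' n-merization reactions when the cooperativity index exceeds 1, and all
#' diffusion couplings (class `fast_diffusion`). Binding consumes one free TF
#' copy; the bound copy is accounted for by the promoter-configuration
#' species.
#'
#' @param spec A valid `grn_spec` (see [validate_grn()]).
#' @return An object of class `reaction_network`: list with `species`
#'   (character), `reactants` and `products` (integer stoichiometry matrices,
#'   species x reactions), `rate` (numeric; `slow_gene` entries already
#'   scaled by `epsilon`), `class` (one of `slow_gene`, `fast_protein`,
#'   `fast_diffusion`) and `label`.
#' @export
expand_reactions <- function(spec) {
  bad <- validate_grn(spec)
  if (length(bad)) stop("invalid spec:\n  ", paste(bad, collapse = "\n  "))
  species <- character()
  for (g in spec$genes) {
    species <- c(species, paste0("D", binding_set(g), ".", g$id), g$id)
    if (g$cooperativity > 1L) species <- c(species, output_species(g))
  }
  nsp <- length(species)
  reac <- list(); prod <- list(); rate <- numeric(); cls <- character()
  lab <- character()
  svec <- function(...) {
    v <- integer(nsp); names(v) <- species
    args <- c(...)
    for (s in names(args)) v[s] <- v[s] + args[s]
    v
  }
  add <- function(r, p, k, cl, l) {
    reac[[length(reac) + 1L]] <<- r
    prod[[length(prod) + 1L]] <<- p
    rate[length(rate) + 1L] <<- k
    cls[length(cls) + 1L] <<- cl
    lab[length(lab) + 1L] <<- l
  }
  eps <- spec$epsilon
  for (g in spec$genes) {
    dsp <- function(code) paste0("D", code, ".", g$id)
    tr <- gene_transitions(g)
    for (r in seq_len(nrow(tr))) {
      from <- dsp(tr$from[r]); to <- dsp(tr$to[r]); s <- tr$site[r]
      switch(tr$kind[r],
        activate = add(svec(stats::setNames(1L, from)),
                       svec(stats::setNames(1L, to)),
                       eps * g$alpha[s], "slow_gene",
                       sprintf("%s activation", g$id)),
        deactivate = add(svec(stats::setNames(1L, from)),
                         svec(stats::setNames(1L, to)),
                         eps * g$alpha_off[s], "slow_gene",
                         sprintf("%s deactivation", g$id)),
        bind = {
          tf <- g$binding_sites[s]
          add(svec(stats::setNames(1L, from), stats::setNames(1L, tf)),
              svec(stats::setNames(1L, to)),
              eps * g$alpha[s], "slow_gene",
              sprintf("%s binds %s site %d (%s->%s)", tf, g$id, s,
                      tr$from[r], tr$to[r]))
        },
        unbind = {
          tf <- g$binding_sites[s]
          add(svec(stats::setNames(1L, from)),
              svec(stats::setNames(1L, to), stats::setNames(1L, tf)),
              eps * g$alpha_off[s], "slow_gene",
              sprintf("%s unbinds %s site %d (%s->%s)", tf, g$id, s,
                      tr$from[r], tr$to[r]))
        })
    }
    for (code in binding_set(g)) {
      k <- g$production[[code]]
      if (k > 0)
        add(svec(stats::setNames(1L, dsp(code))),
            svec(stats::setNames(1L, dsp(code)), stats::setNames(1L, g$id)),
            k, "fast_protein", sprintf("%s production @%s", g$id, code))
    }
    add(svec(stats::setNames(1L, g$id)), svec(), g$decay, "fast_protein",
        sprintf("%s decay", g$id))
    if (g$cooperativity > 1L) {
      n <- g$cooperativity
      add(svec(stats::setNames(n, g$id)),
          svec(stats::setNames(1L, output_species(g))),
          g$beta, "fast_protein", sprintf("%s %d-merization", g$id, n))
      add(svec(stats::setNames(1L, output_species(g))),
          svec(stats::setNames(n, g$id)),
          g$beta_off, "fast_protein", sprintf("%s de-%d-merization", g$id, n))
    }
  }
  if (!is.null(spec$diffusion)) {
    for (r in seq_len(nrow(spec$diffusion))) {
      a <- spec$diffusion$from[r]; b <- spec$diffusion$to[r]
      om <- spec$diffusion$rate[r]
      add(svec(stats::setNames(1L, a)), svec(stats::setNames(1L, b)), om,
          "fast_diffusion", sprintf("%s -> %s diffusion", a, b))
      add(svec(stats::setNames(1L, b)), svec(stats::setNames(1L, a)), om,
          "fast_diffusion", sprintf("%s -> %s diffusion", b, a))
    }
  }
  structure(list(
    species = species,
    reactants = do.call(cbind, reac),
    products = do.call(cbind, prod),
    rate = rate, class = cls, label = lab,
    epsilon = eps
  ), class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d reactions (%d slow)\n",
              length(x$species), length(x$rate), sum(x$class == "slow_gene")))
  invisible(x)
}

#' Number of reactions in a network
#' @param net A `reaction_network`.
#' @return Integer count.
#' @export
n_reactions <- function(net) length(net$rate)

# Render one side of a reaction as "2 X + D0.X" etc.
side_string <- function(stoich, species) {
  nz <- which(stoich != 0)
  if (!length(nz)) return("0")
  paste(ifelse(stoich[nz] > 1, paste(stoich[nz], species[nz]), species[nz]),
        collapse = " + ")
}

#' Export a reaction network as a flat TSV table
#'
#' One reaction per row: reactants, products, rate constant, reaction class,
#' label. Intended for inspection, not for exchange with SBML tools.
#'
#' @param net A `reaction_network`.
#' @param path Output file path, or `NULL` to return the data frame.
#' @return The data frame, invisibly when written to file.
#' @export
write_reactions_tsv <- function(net, path = NULL) {
  df <- data.frame(
    reactants = apply(net$reactants, 2, side_string, species = net$species),
    products = apply(net$products, 2, side_string, species = net$species),
    rate = net$rate, class = net$class, label = net$label,
    stringsAsFactors = FALSE)
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
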