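test_that("structural validation flags each broken assumption", {
  expect_length(validate_grn(build_fixture("toggle_switch")), 0)

  three_site <- grn_spec(list(suppressWarnings(
    gene_block("X", c("X", "X", "X"), alpha = 1, alpha_off = 1,
               production = c("0" = 1), decay = 1))))
  expect_match(validate_grn(three_site), "A1", all = FALSE)

  disconnected <- grn_spec(list(
    gene_block("X", "X", alpha = 1, alpha_off = 1,
               production = c("0" = 1, "1" = 5), decay = 1),
    gene_block("Y", "Y", alpha = 1, alpha_off = 1,
               production = c("0" = 1, "1" = 5), decay = 1)))
  expect_match(validate_grn(disconnected), "A4", all = FALSE)

  no_beta <- grn_spec(list(
    gene_block("X", "Xc", alpha = 1, alpha_off = 1,
               production = c("0" = 1, "1" = 5), decay = 1,
               cooperativity = 2)))
  expect_match(validate_grn(no_beta), "A2", all = FALSE)

  bad_decay <- grn_spec(list(
    gene_block("X", "X", alpha = 1, alpha_off = 1,
               production = c("0" = 1, "1" = 5), decay = 0)))
  expect_match(validate_grn(bad_decay), "decay", all = FALSE)

  unknown_tf <- grn_spec(list(
    gene_block("X", "Q", alpha = 1, alpha_off = 1,
               production = c("0" = 1, "1" = 5), decay = 1)))
  expect_match(validate_grn(unknown_tf), "not the output", all = FALSE)
})

test_that("state enumeration has the right size and round-trips", {
  cases <- list(
    list(spec = build_fixture("bursting_gene"), L = 2),
    list(spec = build_fixture("cellfate_independent"), L = 16),
    list(spec = build_fixture("cellfate_pu1_gata1"), L = 9),
    list(spec = build_fixture("coupled_toggles", N = 2, omega = 1), L = 16))
  for (cs in cases) {
    st <- grn_states(cs$spec)
    expect_equal(nrow(st), cs$L)
    expect_equal(st$index, 0:(cs$L - 1))
    ids <- names(cs$spec$genes)
    for (r in seq_len(nrow(st))) {
      cfg <- unlist(st[r, ids], use.names = FALSE)
      expect_equal(state_index(cs$spec, cfg), st$index[r])
      expect_equal(unname(state_config(cs$spec, st$index[r])), cfg)
    }
  }
})

test_that("competitive and excluded configurations shrink the binding set", {
  comp <- gene_block("X", c("X", "X"), alpha = 1, alpha_off = 1,
                     production = c("00" = 1), decay = 1, competitive = TRUE)
  expect_equal(binding_set(comp), c("00", "01", "10"))
  excl <- gene_block("X", c("X", "X"), alpha = 1, alpha_off = 1,
                     production = c("00" = 1), decay = 1,
                     exclude_configs = "01")
  expect_equal(binding_set(excl), c("00", "10", "11"))
  # no transition passes through an excluded configuration
  tr <- spkmix:::gene_transitions(excl)
  expect_false(any(tr$from == "01" | tr$to == "01"))
})

test_that("reaction expansion matches the bursting-gene network exactly", {
  net <- expand_reactions(build_fixture("bursting_gene", epsilon = 0.5))
  # activation, deactivation, production (active state only), decay
  expect_equal(n_reactions(net), 4)
  expect_setequal(net$class, c("slow_gene", "fast_protein"))
  slow <- which(net$class == "slow_gene")
  expect_equal(sort(net$rate[slow]), sort(0.5 * c(1, 0.1)))  # eps-scaled
  fast <- which(net$class == "fast_protein")
  expect_equal(sort(net$rate[fast]), c(2, 20))               # unscaled
})

test_that("expansion omits multimerization for n = 1 and emits it for n = 2", {
  n1 <- expand_reactions(build_fixture("toggle_switch", n = 1))
  expect_false(any(grepl("merization", n1$label)))
  n2 <- expand_reactions(build_fixture("toggle_switch", n = 2))
  expect_equal(sum(grepl("merization", n2$label)), 4)  # 2 genes x fwd/back
  expect_true(all(c("Xc", "Yc") %in% n2$species))
})

test_that("diffusion couplings expand to reversible transport reactions", {
  ct <- build_fixture("coupled_toggles", N = 2, omega = 7)
  net <- expand_reactions(ct)
  dif <- which(net$class == "fast_diffusion")
  expect_equal(length(dif), 4)  # X1<->X2 and Y1<->Y2, both directions
  expect_true(all(net$rate[dif] == 7))
})

test_that("every reaction conserves each gene's promoter copy number", {
  for (fx in c("bursting_gene", "self_regulating_gene", "toggle_switch",
               "cellfate_pu1_gata1")) {
    spec <- build_fixture(fx)
    net <- expand_reactions(spec)
    delta <- net$products - net$reactants
    for (g in spec$genes) {
      rows <- which(net$species %in% paste0("D", binding_set(g), ".", g$id))
      expect_true(all(colSums(delta[rows, , drop = FALSE]) == 0),
                  label = sprintf("%s promoter conservation in %s", g$id, fx))
    }
    # deterministic expansion: same reaction count on re-expansion
    expect_equal(n_reactions(expand_reactions(spec)), n_reactions(net))
  }
})

test_that("model files round-trip through YAML", {
  spec <- build_fixture("cellfate_pu1_gata1", epsilon = 0.02)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_grn(spec, path)
  back <- read_grn(path)
  expect_equal(back$epsilon, spec$epsilon)
  expect_equal(names(back$genes), names(spec$genes))
  for (id in names(spec$genes))
    expect_equal(back$genes[[id]], spec$genes[[id]])
  # and a diffusion-coupled, cooperative network
  ct <- build_fixture("coupled_toggles", N = 2, omega = 3, epsilon = 0.1)
  write_grn(ct, path)
  back2 <- read_grn(path)
  expect_equal(back2$genes, ct$genes)
  expect_equal(back2$diffusion, ct$diffusion)
})

test_that("reaction TSV export is one readable row per reaction", {
  df <- write_reactions_tsv(expand_reactions(build_fixture("bursting_gene")))
  expect_named(df, c("reactants", "products", "rate", "class", "label"))
  expect_equal(nrow(df), 4)
  expect_true(any(grepl("^D1.X$", df$reactants) & df$products == "D1.X + X"))
})
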