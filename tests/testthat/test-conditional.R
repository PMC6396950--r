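test_that("conditional law of an unregulated gene matches the birth-death oracle", {
  spec <- build_fixture("bursting_gene", k = 20, decay = 2)
  cp <- conditional_pmf_joint(spec, d = 1)  # active configuration
  expect_equal(unname(cp$monomer_means), 10)
  # detailed-balance oracle pi(x) propto (k/k_)^x / x!
  x <- 0:80
  oracle <- (20 / 2)^x / factorial(x)
  oracle <- oracle / sum(oracle)
  expect_lt(tv_distance(cp$pmf(matrix(x, ncol = 1)), oracle), 1e-12)
  # zero production: point mass at 0
  cp0 <- conditional_pmf_joint(spec, d = 0)
  expect_equal(unname(cp0$pmf(0)), 1)
  expect_equal(unname(cp0$monomer_means), 0)
})

test_that("cooperative conditional means follow the multimer formula", {
  spec <- build_fixture("self_regulating_gene")  # k0=20, k_=10, beta=10, beta_=50, n=2
  cp <- conditional_pmf_joint(spec, d = 0)
  expect_equal(unname(cp$monomer_means), 2)
  expect_equal(unname(cp$multimer_means["Xc"]), (20 / 10)^2 * 10 / (2 * 50))  # 0.4
  # expected_tf agrees with both worked closed forms
  expect_equal(expected_tf(spec, 0, "Xc"), 0.4)
  noncoop <- build_fixture("self_regulating_gene", cooperative = FALSE)
  expect_equal(expected_tf(noncoop, 0, "X"), 2)           # rho = k0/k_
  nonleaky <- build_fixture("self_regulating_gene", leaky = FALSE)
  expect_equal(expected_tf(nonleaky, 0, "Xc"), 0)
  expect_error(expected_tf(spec, 0, "nope"), "unknown")
})

test_that("closed-form conditionals match brute-force stationary solves", {
  fixtures <- list(build_fixture("bursting_gene"),
                   build_fixture("self_regulating_gene"))
  for (spec in fixtures) {
    cme <- assemble_cme(spec)
    lat <- as.matrix(expand.grid(lapply(cme$dims, function(n) 0:(n - 1))))
    for (d in cme$states$index) {
      brute <- stationary_of_generator(conditional_generator(cme, d))
      cp <- conditional_pmf_joint(spec, d)
      closed <- cp$pmf(lat)
      expect_lt(tv_distance(brute, closed), 1e-6)
    }
  }
})

test_that("summing the joint over multimer counts recovers the marginal", {
  spec <- build_fixture("self_regulating_gene")
  cp <- conditional_pmf_joint(spec, d = 1)       # means: X = 10, Xc = 10
  marg <- conditional_pmf_marginal(spec, d = 1)
  x <- 0:70
  joint_summed <- vapply(x, function(xi)
    sum(cp$pmf(cbind(xi, 0:80))), numeric(1))
  expect_lt(max(abs(joint_summed - stats::dpois(x, marg["X"]))), 1e-10)
  # and the conditional PMF normalizes on its truncation box
  ub <- truncation_bound(cp$means)
  grid <- as.matrix(expand.grid(0:ub[1], 0:ub[2]))
  expect_gt(sum(cp$pmf(grid)), 1 - 1e-8)
})

test_that("conditional means ignore epsilon and the binding rates", {
  base <- conditional_pmf_joint(build_fixture("self_regulating_gene"), 1)$means
  tweaked <- conditional_pmf_joint(
    build_fixture("self_regulating_gene", alpha = 99, alpha_off = 0.01,
                  epsilon = 1e-6), 1)$means
  expect_identical(base, tweaked)
})

test_that("diffusion-coupled conditional equilibria solve the transport balance", {
  # no diffusion: reduces exactly to the product-Poisson conditional
  tg <- build_fixture("toggle_switch")
  expect_equal(conditional_equilibrium(tg, 0)$means,
               conditional_pmf_joint(tg, 0)$means)
  expect_error(conditional_pmf_joint(
    build_fixture("coupled_toggles", N = 2, omega = 1), 0), "diffusion")

  # three synchronized switches, m X-promoters unbound: mean m*k0/(N k_)
  ct <- build_fixture("coupled_toggles", N = 3, omega = 1e7, k0 = 150)
  for (m in 0:3) {
    cfg <- c(X1 = "1", Y1 = "1", X2 = "1", Y2 = "1", X3 = "1", Y3 = "1")
    if (m > 0) cfg[paste0("X", seq_len(m))] <- "0"
    ce <- conditional_equilibrium(ct, cfg)
    expect_equal(unname(ce$means[c("X1", "X2", "X3")]),
                 rep(m * 150 / 3, 3), tolerance = 1e-5)
  }

  # symmetric two-cell exchange with equal production: equal means
  two <- build_fixture("coupled_toggles", N = 2, omega = 5)
  ce2 <- conditional_equilibrium(two, c(X1 = "0", Y1 = "1",
                                        X2 = "0", Y2 = "1"))
  expect_equal(unname(ce2$means["X1"]), unname(ce2$means["X2"]))

  # structural check: diffusion on a multimer species is rejected
  bad <- build_fixture("coupled_toggles", N = 2, omega = 5)
  bad$diffusion$from[1] <- "X1c"
  expect_error(conditional_equilibrium(bad, 0), "weakly reversible")
})

test_that("diffusion-coupled conditionals agree with a brute-force CME solve", {
  # two constitutive genes exchanging protein: conditional network is a
  # linear transport chain, stationary law exactly product-Poisson
  spec <- grn_spec(list(
    gene_block("A", "constitutive", alpha = 1, alpha_off = 1,
               production = c("0" = 0, "1" = 5), decay = 1),
    gene_block("B", "constitutive", alpha = 1, alpha_off = 1,
               production = c("0" = 0, "1" = 0), decay = 1)),
    diffusion = data.frame(from = "A", to = "B", rate = 2))
  d <- state_index(spec, c("1", "0"))  # A producing, B silent
  cp <- conditional_equilibrium(spec, d)
  # transport balance: (1+2)a - 2b = 5, -2a + (1+2)b = 0  =>  a = 3, b = 2
  expect_equal(unname(cp$means[c("A", "B")]), c(3, 2))
  cme <- assemble_cme(spec, box = 25)
  brute <- stationary_of_generator(conditional_generator(cme, d))
  lat <- as.matrix(expand.grid(lapply(cme$dims, function(n) 0:(n - 1))))
  expect_lt(tv_distance(brute, cp$pmf(lat[, names(cp$means)])), 1e-6)
})
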