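test_that("bursting-gene reduced chain and weights match the closed form", {
  gen <- build_reduced_generator(build_fixture("bursting_gene"))
  expect_equal(gen$matrix, matrix(c(-1, 1, 0.1, -0.1), 2, 2))
  lam <- stationary_weights(gen)
  expect_equal(as.numeric(lam), c(0.1 / 1.1, 1 / 1.1), tolerance = 1e-12)
  expect_equal(as.numeric(lam), c(1 / 11, 10 / 11), tolerance = 1e-12)
})

test_that("self-regulating gene binds at alpha*rho and unbinds at alpha_off", {
  spec <- build_fixture("self_regulating_gene", alpha = 3, alpha_off = 7)
  gen <- build_reduced_generator(spec)
  rho <- 0.4
  expect_equal(gen$matrix[2, 1], 3 * rho)
  expect_equal(gen$matrix[1, 2], 7)
  lam <- stationary_weights(gen)
  expect_equal(as.numeric(lam),
               c(7, 3 * rho) / (3 * rho + 7), tolerance = 1e-12)
})

test_that("toggle switch: no flow into (1,1), three modes, closed-form mixture", {
  for (n in c(1, 2)) {
    spec <- build_fixture("toggle_switch", n = n)
    gen <- build_reduced_generator(spec)
    d11 <- state_index(spec, c("1", "1")) + 1
    expect_equal(unname(gen$matrix[d11, -d11]), rep(0, 3))
    mix <- mixture_pmf(spec)
    expect_equal(mix$weights[d11], 0)
    K <- 40
    rho <- if (n == 1) K else K^2 / 2
    r <- 0.005 / 1 * rho
    lam_ref <- c(1, r, r, 0) / (1 + 2 * r)      # states (0,0),(0,1),(1,0),(1,1)
    expect_equal(mix$weights, lam_ref, tolerance = 1e-12)
    mr <- find_modes(mix, lattice = FALSE)
    expect_equal(nrow(mr$component_modes), 3)
    expect_setequal(
      apply(mr$component_modes[, c("X", "Y")], 1, paste, collapse = ","),
      c("40,0", "0,40", "40,40"))
    # the displayed two-protein mixture formula, evaluated pointwise
    pi_ref <- function(x, y)
      (dpois(y, K) * dpois(x, K) + r * dpois(y, K) * (x == 0) +
         r * dpois(x, K) * (y == 0)) / (2 * r + 1)
    pts <- rbind(c(0, 40), c(40, 40), c(0, 0), c(12, 3))
    expect_equal(dmixture(mix, pts),
                 pi_ref(pts[, 1], pts[, 2]), tolerance = 1e-12)
  }
})

test_that("reducible chains resolve through their closed classes", {
  # constitutive gene that can never re-activate: absorbed in the off state
  off <- build_fixture("bursting_gene", alpha = 0)
  lam <- stationary_weights(build_reduced_generator(off))
  expect_equal(as.numeric(lam), c(1, 0))
  expect_true(attr(lam, "unique"))
  # deactivation impossible: single Poisson at k/k_
  on <- build_fixture("bursting_gene", alpha_off = 0)
  mix <- mixture_pmf(on)
  expect_equal(mix$weights, c(0, 1))
  expect_equal(nrow(find_modes(mix, lattice = FALSE)$component_modes), 1)
  # two absorbing states: weights are absorption probabilities from init
  frozen <- build_fixture("bursting_gene", alpha = 0, alpha_off = 0)
  gen <- build_reduced_generator(frozen)
  expect_error(stationary_weights(gen), "closed classes")
  lam2 <- stationary_weights(gen, init = c(0.3, 0.7))
  expect_equal(as.numeric(lam2), c(0.3, 0.7))
  expect_false(attr(lam2, "unique"))
  # transient state feeding two absorbing states at rates 1 and 3
  M <- matrix(0, 3, 3)
  M[1, 2] <- 1; M[3, 2] <- 3
  diag(M) <- -colSums(M)
  lam3 <- stationary_weights(M, init = c(0, 1, 0))
  expect_equal(as.numeric(lam3), c(0.25, 0, 0.75))
})

test_that("generator null-space identities hold across fixtures", {
  for (fx in list(build_fixture("bursting_gene"),
                  build_fixture("self_regulating_gene"),
                  build_fixture("toggle_switch", n = 2),
                  build_fixture("repressilator"),
                  build_fixture("cellfate_pu1_gata1"))) {
    gen <- build_reduced_generator(fx)
    expect_lt(max(abs(colSums(gen$matrix))), 1e-10)
    lam <- stationary_weights(gen)
    expect_lt(max(abs(gen$matrix %*% lam)), 1e-12 * max(abs(gen$matrix)))
    expect_equal(sum(lam), 1, tolerance = 1e-12)
    expect_true(all(lam >= 0))
  }
})

test_that("projection and algorithmic reduced generators agree", {
  fixtures <- list(build_fixture("bursting_gene"),
                   build_fixture("self_regulating_gene"),
                   build_fixture("toggle_switch", k0 = 20))
  for (spec in fixtures) {
    direct <- reduced_generator_direct(spec)
    algo <- build_reduced_generator(spec)$matrix
    expect_lt(max(abs(direct - algo)), 1e-8)
  }
})

test_that("multimerization ratio tunes weights but never moves locations", {
  ratios <- c(0.01, 0.1, 1, 10, 100)
  locs <- list(); center_w <- numeric()
  for (br in ratios) {
    mix <- mixture_pmf(build_fixture("toggle_switch", n = 2, beta = br,
                                     beta_off = 1))
    locs[[length(locs) + 1L]] <- mix$locations
    center_w <- c(center_w, mix$weights[1])  # the (high,high) component
  }
  for (l in locs[-1]) expect_identical(l, locs[[1]])
  expect_true(all(diff(center_w) < 0))  # monotone suppression of (high,high)
})

test_that("lattice maxima distinguish merged components from separated ones", {
  fake <- structure(list(
    locations = matrix(c(0.5, 1.5), 2, 1, dimnames = list(NULL, "X")),
    weights = c(0.5, 0.5), species = "X"), class = "poisson_mixture")
  mr <- find_modes(fake, upper = 20)
  expect_equal(nrow(mr$lattice_maxima), 1)   # peaks too close: one maximum
  expect_equal(nrow(mr$component_modes), 2)  # but still two components
  far <- structure(list(
    locations = matrix(c(1, 30), 2, 1, dimnames = list(NULL, "X")),
    weights = c(0.5, 0.5), species = "X"), class = "poisson_mixture")
  expect_equal(nrow(find_modes(far, upper = 60)$lattice_maxima), 2)
  single <- structure(list(
    locations = matrix(8, 1, 1, dimnames = list(NULL, "X")),
    weights = 1, species = "X"), class = "poisson_mixture")
  mr1 <- find_modes(single, upper = 40)
  expect_equal(nrow(mr1$component_modes), 1)
  expect_equal(mr1$component_modes$X, 8)
})

test_that("coincident component locations merge before mode counting", {
  # non-leaky self-regulating gene: both components sit at distinct spots,
  # but a flat gene (equal production in both configurations) collapses
  flat <- build_fixture("self_regulating_gene", k0 = 100, k1 = 100,
                        cooperative = FALSE)
  mr <- find_modes(mixture_pmf(flat), lattice = FALSE)
  expect_equal(nrow(mr$component_modes), 1)
  expect_equal(mr$component_modes$n_merged, 2)
  expect_equal(mr$component_modes$weight, 1)
})

test_that("reduced-chain transients relax from identity to the stationary law", {
  gen <- build_reduced_generator(build_fixture("repressilator"))
  expect_equal(transition_matrix(gen, 0), diag(8))
  Q <- transition_matrix(gen, 5e3)
  lam <- as.numeric(stationary_weights(gen))
  expect_lt(max(abs(Q - matrix(lam, 8, 8))), 1e-8)
  expect_lt(max(abs(colSums(transition_matrix(gen, 0.3)) - 1)), 1e-12)
})

test_that("the repressilator prefers the cyclic successor at small times", {
  rp <- build_fixture("repressilator")
  mix <- mixture_pmf(rp)
  lab <- apply(mix$locations, 1, function(r)
    paste0(c("X", "Y", "Z")[r > 0], collapse = ""))
  dx <- which(lab == "X"); dy <- which(lab == "Y"); dz <- which(lab == "Z")
  Q <- transition_matrix(build_reduced_generator(rp), 0.05)
  expect_gt(Q[dy, dx], Q[dz, dx])
  expect_gt(Q[dz, dy], Q[dx, dy])
  expect_gt(Q[dx, dz], Q[dy, dz])
  expect_gt(Q[dx, dx], max(Q[dy, dx], Q[dz, dx]))
})

test_that("synchronized limit reduces to the single switch at N = 1", {
  sl <- synchronized_limit(build_fixture("coupled_toggles", N = 1))
  expect_equal(sl$full_components, 4)
  expect_equal(sl$total_modes, 3)
  expect_equal(sl$interior_modes, 1)
})

test_that("three coupled switches give 15 aggregated modes at locations i*K/N", {
  ct <- build_fixture("coupled_toggles", N = 3)
  sl <- synchronized_limit(ct)
  expect_equal(sl$full_components, 64)
  expect_equal(sl$full_positive_components, 63)
  expect_equal(sl$total_modes, 15)
  expect_equal(sl$interior_modes, 9)
  expect_equal(sl$extra_boundary_modes, 4)
  bound <- sl$modes[sl$modes$weight > 0 & !sl$modes$interior, ]
  expect_setequal(paste(bound$x, bound$y),
                  c("50 0", "100 0", "150 0", "0 50", "0 100", "0 150"))
  expect_equal(sl$omega_min, (150 - 1) / 3)
  # larger multimerization ratio suppresses the interior further
  hi <- synchronized_limit(build_fixture("coupled_toggles", N = 3, beta = 100))
  expect_lt(hi$max_interior_weight, sl$max_interior_weight)
  # non-identical switches are rejected
  bad <- build_fixture("coupled_toggles", N = 2)
  bad$genes$X2$decay <- 2
  expect_error(synchronized_limit(bad), "identical")
})
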