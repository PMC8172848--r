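test_that("simulated datasets have the configured structure", {
  pars <- newt_params()
  d <- simulate_dataset(sim_config(20, 2, 4, pars, seed = 1))
  expect_equal(n_sites(d), 20)
  expect_equal(n_samples(d), 40)
  expect_true(all(d$samples$y >= 0 & d$samples$y <= 4))
  expect_setequal(d$covariates, c("cov_cont", "cov_bin"))
  expect_true(all(d$sites$cov_bin %in% 0:1))

  # deterministic chain with no noise paths: nothing can amplify
  silent <- model_params(0, 0.85, 0, 0.9, 0)
  d0 <- simulate_dataset(sim_config(50, 2, 6, silent, seed = 2))
  expect_true(all(d0$samples$y == 0))
})

test_that("simulation is reproducible from its seed", {
  pars <- newt_params()
  cfg <- sim_config(100, 2, 6, pars, seed = 77)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
  # and does not disturb the caller's RNG stream
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(simulate_dataset(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("single-sample covariate-free designs warn about identifiability", {
  pars <- newt_params()
  expect_warning(sim_config(10, 1, 12, pars, include_covariates = FALSE),
                 "identifiable")
  expect_silent(sim_config(10, 1, 12, pars, include_covariates = TRUE))
  expect_silent(sim_config(10, 2, 12, pars, include_covariates = FALSE))
})

test_that("covariate model parameters drive per-site probabilities", {
  # strong positive effect of the continuous covariate on occupancy
  cp <- covariate_model_params(
    beta_psi = c(0, 3), beta_theta11 = qlogis(0.9),
    beta_theta10 = qlogis(0.01), beta_p11 = qlogis(0.9),
    beta_p10 = qlogis(0.01),
    design = list(psi = "cov_cont", theta11 = character(0),
                  theta10 = character(0), p11 = character(0),
                  p10 = character(0)))
  d <- simulate_dataset(sim_config(4000, 1, 6, cp, seed = 8))
  z <- attr(d, "latent")$z
  x <- d$sites$cov_cont
  expect_gt(mean(z[x > 1]), mean(z[x < -1]) + 0.5)
})

test_that("empirical frequencies match the generative probabilities", {
  pars <- newt_params()
  S <- 1e5
  d <- simulate_dataset(sim_config(S, 1, 12, pars, seed = 123))
  lat <- attr(d, "latent")
  # occupancy fraction converges to psi
  se_psi <- sqrt(pars$psi * (1 - pars$psi) / S)
  expect_lt(abs(mean(lat$z) - pars$psi), 3 * se_psi)
  # amplification rate conditional on the sample's latent state
  y <- d$samples$y
  for (state in 0:1) {
    p <- if (state == 1) pars$p11 else pars$p10
    n_rep <- 12 * sum(lat$a == state)
    rate <- sum(y[lat$a == state]) / n_rep
    expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / n_rep))
  }
  # overall event frequency P(y >= 1) against the analytic marginal
  p_pos <- 1 - site_marginal_likelihood(pars, 12, 0)
  expect_lt(abs(mean(y >= 1) - p_pos), 3 * sqrt(p_pos * (1 - p_pos) / S))
})

test_that("the simulation grid is complete, keyed and deterministic", {
  pars <- newt_params()
  g <- simulate_grid(c(20, 50), c(1, 2), c(2, 4), repeats = 2, pars,
                     base_seed = 9)
  expect_length(g, 16)
  expect_true(all(grepl("^S\\d+_M\\d+_K\\d+_r\\d+$", names(g))))
  expect_equal(n_sites(g[["S50_M2_K4_r2"]]), 50)
  expect_equal(n_samples(g[["S50_M2_K4_r2"]]), 100)
  g2 <- simulate_grid(c(20, 50), c(1, 2), c(2, 4), repeats = 2, pars,
                      base_seed = 9)
  expect_identical(g, g2)
  # repeats are genuinely different draws
  expect_false(identical(g[["S20_M1_K2_r1"]]$samples$y,
                         g[["S20_M1_K2_r2"]]$samples$y))
  # singleton grid
  g1 <- simulate_grid(30, 2, 6, 1, pars, base_seed = 9)
  expect_length(g1, 1)
})

test_that("the full study grid enumerates 720 cells", {
  pars <- newt_params()
  g <- simulate_grid(c(20, 100, 500, 1000), c(1, 2, 4),
                     c(2, 4, 6, 8, 10, 12), repeats = 10, pars,
                     base_seed = 3)
  expect_length(g, 720)
  expect_equal(anyDuplicated(names(g)), 0)
})

test_that("derived seeds are deterministic, distinct and 31-bit", {
  s1 <- derive_seed(42, 500, 2, 6, 3)
  expect_identical(s1, derive_seed(42, 500, 2, 6, 3))
  keys <- expand.grid(S = c(20, 100), M = 1:3, K = c(2, 6), r = 1:10)
  seeds <- mapply(derive_seed, 42, keys$S, keys$M, keys$K, keys$r)
  expect_equal(anyDuplicated(seeds), 0)
  expect_true(all(seeds >= 0 & seeds < 2^31))
})
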