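test_that("degenerate parameter chains give certain outcomes", {
  # fully deterministic detection chain
  p1 <- model_params(1, 1, 0, 1, 0)
  expect_equal(site_marginal_likelihood(p1, 12, 12), 1.0)
  # no occupancy and no false-positive path: a positive is impossible
  p0 <- model_params(0, 0.9, 0, 0.9, 0)
  expect_equal(site_marginal_likelihood(p0, 12, 1), 0.0)
})

test_that("single-sample marginal likelihood matches enumeration", {
  pars <- newt_params()
  val <- site_marginal_likelihood(pars, 4, 2)
  expect_equal(val, brute_site_lik(pars, 4, 2), tolerance = 1e-14)
  expect_equal(val, 0.00510118236, tolerance = 1e-9)  # frozen oracle value
})

test_that("marginal likelihood equals latent-state enumeration on a sweep", {
  set.seed(42)
  for (i in 1:200) {
    pars <- rand_params()
    M <- sample(1:3, 1)
    K <- sample(1:6, M, replace = TRUE)
    y <- vapply(K, function(k) sample(0:k, 1), integer(1))
    expect_equal(site_marginal_likelihood(pars, K, y),
                 brute_site_lik(pars, K, y), tolerance = 1e-12)
  }
})

test_that("marginal likelihood is a proper distribution over outcomes", {
  set.seed(7)
  for (i in 1:10) {
    pars <- rand_params()
    # M = 2 samples with K = 4 and K = 3 replicates
    tot <- 0
    for (y1 in 0:4) for (y2 in 0:3) {
      tot <- tot + site_marginal_likelihood(pars, c(4, 3), c(y1, y2))
    }
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("dataset log likelihood sums per-site log marginals", {
  d <- toy_data()
  pars <- survey_params()
  manual <- log(brute_site_lik(pars, 12, c(0, 3))) +
    log(brute_site_lik(pars, 12, c(12, 0)))
  expect_equal(log_likelihood(pars, d), manual, tolerance = 1e-12)
})

test_that("conditional absence probability follows Bayes' rule", {
  # no false-positive path: any amplification rules out absence
  expect_equal(
    conditional_absence_probability(model_params(0.3, 0.8, 0, 0.9, 0), 1, 12),
    0)
  # unoccupiable site: absence certain wherever the outcome is possible
  p0 <- model_params(0, 0.9, 0.05, 0.9, 0.05)
  expect_equal(conditional_absence_probability(p0, c(0, 1, 6), 12),
               rep(1, 3))
  # exact agreement with the hand-enumerated ratio on three parameter sets
  for (pars in list(survey_params(), newt_params(),
                    model_params(0.5, 0.6, 0.2, 0.7, 0.3))) {
    expect_equal(conditional_absence_probability(pars, 0:12, 12),
                 brute_absence(pars, 0:12, 12), tolerance = 1e-12)
  }
  expect_error(conditional_absence_probability(survey_params(), 13, 12),
               "\\[0, K\\]")
})

test_that("absence curve is monotone and flattens at high counts", {
  set.seed(11)
  for (i in 1:25) {
    pars <- rand_params()  # oriented: theta11 > theta10, p11 > p10
    curve <- conditional_absence_probability(pars, 0:10, 10)
    expect_true(all(diff(curve) <= 1e-12))
  }
  # survey-style parameters: near 1 up to two amplifying replicates,
  # rapid change between three and five, flat above six
  curve <- conditional_absence_probability(survey_params(), 0:12, 12)
  expect_true(all(curve[1:3] > 0.9))
  expect_lt(curve[7], 0.1)
  expect_lt(abs(curve[7] - curve[13]), 0.05)
  # with uninformative stages the data say nothing: absence posterior
  # equals its prior 1 - psi at every count
  flat <- model_params(0.3, 0.7 + 1e-9, 0.7, 0.4 + 1e-9, 0.4)
  expect_equal(conditional_absence_probability(flat, 0:8, 8),
               rep(0.7, 9), tolerance = 1e-6)
})

test_that("naive occupancy counts threshold exceedances per site", {
  allzero <- toy_data(y = c(0, 0, 0, 0))
  expect_equal(naive_occupancy(allzero, 1), 0)
  d4 <- toy_data(y = c(0, 1, 2, 3), K = 12, site = c("a", "b", "c", "d"))
  expect_equal(naive_occupancy(d4, 2), 0.5)
  # monotone non-increasing in the threshold
  rates <- vapply(1:12, function(t) naive_occupancy(d4, t), numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_error(naive_occupancy(d4, 0), ">= 1")
})

test_that("naive occupancy converges to the analytic tail probability", {
  pars <- newt_params()
  d <- simulate_dataset(sim_config(2000, 1, 12, pars,
                                   include_covariates = TRUE, seed = 314))
  p_pos <- 1 - site_marginal_likelihood(pars, 12, 0)
  se <- sqrt(p_pos * (1 - p_pos) / 2000)
  expect_lt(abs(naive_occupancy(d, 1) - p_pos), 3 * se)
})

test_that("replicate spectrum tabulates the full 0..K range", {
  d <- toy_data(y = c(0, 0, 12, 1), site = c("a", "a", "b", "b"))
  sp <- replicate_spectrum(d)
  expect_equal(nrow(sp), 13)
  expect_equal(sum(sp$n_samples), 4)
  expect_equal(sp$n_samples[sp$y %in% c(0, 1, 12)], c(2, 1, 1))
  # bimodal shape at survey-style parameters: mass at 0 and K, thin middle
  pars <- newt_params()
  big <- simulate_dataset(sim_config(5000, 1, 12, pars, seed = 99))
  spec <- replicate_spectrum(big)$n_samples
  expect_gt(spec[1], sum(spec[-1]))            # y = 0 dominates
  expect_gt(spec[13], max(spec[4:11]))         # y = 12 beats every middle count
})
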