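quick_mcmc <- function(seed = 1, n_chains = 1) {
  mcmc_control(n_burnin = 300, n_iter = 600, thin = 3, n_chains = n_chains,
               seed = seed)
}

test_that("Rao-Blackwellised site occupancy matches Bayes-rule enumeration", {
  set.seed(21)
  d <- toy_data(y = c(0, 3, 12, 0), K = 12, site = c("a", "a", "b", "b"))
  for (i in 1:20) {
    pars <- rand_params()
    got <- ednafp:::dataset_site_loglik(d, pars$psi, pars$theta11,
                                        pars$theta10, pars$p11, pars$p10)
    expect_equal(got$occ_post,
                 c(brute_site_occ(pars, 12, c(0, 3)),
                   brute_site_occ(pars, 12, c(12, 0))), tolerance = 1e-12)
    expect_equal(got$log_lik,
                 log(c(brute_site_lik(pars, 12, c(0, 3)),
                       brute_site_lik(pars, 12, c(12, 0)))),
                 tolerance = 1e-12)
  }
})

test_that("saturated confirmed data drive all signal probabilities high", {
  samples <- data.frame(site_id = rep(sprintf("s%02d", 1:20), each = 2),
                        sample_id = rep(1:2, 20), K = 12, y = 12)
  sites <- data.frame(site_id = sprintf("s%02d", 1:20),
                      confirmed_present = TRUE)
  d <- edna_data(samples, sites)
  fit <- fit_full_model(d, mcmc = quick_mcmc(2))
  m <- fit$summary$posterior_mean[match(c("psi", "theta11", "p11"),
                                        fit$summary$parameter)]
  expect_true(all(m > 0.9))
  # confirmed sites report occupancy exactly 1
  expect_equal(site_occupancy_posteriors(fit)$mean, rep(1, 20))
})

test_that("posterior matches an importance-sampling oracle on tiny data", {
  d <- toy_data(y = c(2, 0, 1, 0, 0, 2), K = 2,
                site = rep(c("a", "b", "c"), each = 2))
  priors <- prior_spec()
  fit <- fit_full_model(d, priors = priors,
                        mcmc = mcmc_control(n_burnin = 500, n_iter = 4000,
                                            thin = 2, seed = 4))

  # oracle: importance sampling from the orientation-truncated prior,
  # weighted by the exact marginal likelihood
  set.seed(99)
  n <- 2e5
  psi <- runif(n)
  th11 <- rbeta(n, priors$beta$theta11[1], priors$beta$theta11[2])
  th10 <- rbeta(n, priors$beta$theta10[1], priors$beta$theta10[2])
  p11 <- rbeta(n, priors$beta$p11[1], priors$beta$p11[2])
  p10 <- rbeta(n, priors$beta$p10[1], priors$beta$p10[2])
  keep <- th11 > th10 & p11 > p10
  lw <- vapply(which(keep), function(i) {
    pr <- structure(list(psi = psi[i], theta11 = th11[i], theta10 = th10[i],
                         p11 = p11[i], p10 = p10[i]), class = "edna_params")
    log_likelihood(pr, d)
  }, numeric(1))
  w <- exp(lw - max(lw))
  for (nm in c("psi", "theta11", "p11")) {
    oracle <- sum(get(switch(nm, psi = "psi", theta11 = "th11",
                             p11 = "p11"))[keep] * w) / sum(w)
    gibbs <- fit$summary$posterior_mean[fit$summary$parameter == nm]
    expect_lt(abs(gibbs - oracle), 0.03)
  }
})

test_that("single-sample covariate-free fits warn about identifiability", {
  d <- simulate_dataset(sim_config(50, 1, 12, newt_params(),
                                   include_covariates = TRUE, seed = 31))
  expect_warning(fit_full_model(d, mcmc = quick_mcmc(3)), "single field sample")
  # covariates in the design silence the warning
  expect_silent(fit_full_model(d, mcmc = quick_mcmc(3),
                               covariates = "cov_cont",
                               save_site_posteriors = FALSE))
})

test_that("the constrained model treats any amplification as occupancy", {
  # all-zero data: occupancy posterior must fall below the flat prior mean
  d0 <- toy_data(y = rep(0, 10), K = 12, site = rep(sprintf("s%d", 1:5), 2))
  fit0 <- fit_no_false_positive_model(d0, mcmc = quick_mcmc(5))
  expect_lt(fit0$summary$posterior_mean[fit0$summary$parameter == "psi"], 0.5)
  expect_equal(fit0$summary$posterior_mean[fit0$summary$parameter == "theta10"], 0)
  expect_equal(fit0$summary$posterior_mean[fit0$summary$parameter == "p10"], 0)
})

test_that("full and constrained models agree when false positives are absent", {
  clean_pars <- model_params(0.1, 0.85, 0, 0.9, 0)
  d <- simulate_dataset(sim_config(300, 2, 4, clean_pars,
                                   include_covariates = FALSE, seed = 41))
  # priors concentrating the false-positive probabilities at zero make the
  # full model a reparameterisation of the constrained one
  tight <- prior_spec(theta10 = c(1, 5e4), p10 = c(1, 5e4))
  f_full <- fit_full_model(d, priors = tight, mcmc = quick_mcmc(6),
                           save_site_posteriors = FALSE)
  f_con <- fit_no_false_positive_model(d, priors = tight,
                                       mcmc = quick_mcmc(7),
                                       save_site_posteriors = FALSE)
  psi_full <- f_full$summary$posterior_mean[f_full$summary$parameter == "psi"]
  psi_con <- f_con$summary$posterior_mean[f_con$summary$parameter == "psi"]
  expect_lt(abs(psi_full - psi_con), 0.03)
})

test_that("ignoring false positives inflates occupancy on contaminated data", {
  d <- simulate_dataset(sim_config(500, 2, 12, newt_params(),
                                   include_covariates = FALSE, seed = 51))
  f_full <- fit_full_model(d, mcmc = quick_mcmc(8))
  f_con <- fit_no_false_positive_model(d, mcmc = quick_mcmc(9))
  psi_full <- f_full$summary$posterior_mean[f_full$summary$parameter == "psi"]
  psi_con <- f_con$summary$posterior_mean[f_con$summary$parameter == "psi"]
  expect_gt(psi_con, psi_full)

  cmp <- compare_models(f_full, f_con)
  expect_gt(cmp$frac_constrained_higher, 0.5)
  fr <- c(cmp$frac_constrained_higher, cmp$frac_constrained_wider,
          cmp$frac_pci_overlap)
  expect_true(all(fr >= 0 & fr <= 1))
  expect_equal(nrow(cmp$psi_summary), 2)

  # strong-signal sites carry near-certain occupancy posteriors
  full_sites <- site_occupancy_posteriors(f_full)
  idx <- ednafp:::sample_site_index(d)
  all_pos <- rowsum(as.numeric(d$samples$y == 12), idx)[, 1] == 2
  expect_true(all(full_sites$mean[all_pos] > 0.99))
})

test_that("a fit compared with itself reports no differences", {
  d <- simulate_dataset(sim_config(60, 2, 6, newt_params(), seed = 61))
  fit <- fit_full_model(d, mcmc = quick_mcmc(10))
  cmp <- compare_models(fit, fit)
  expect_equal(cmp$frac_constrained_higher, 0)
  expect_equal(cmp$frac_pci_overlap, 1)
})

test_that("multiple chains stack draws and report convergence diagnostics", {
  d <- simulate_dataset(sim_config(80, 2, 6, newt_params(), seed = 71))
  fit <- fit_full_model(d, mcmc = quick_mcmc(11, n_chains = 2),
                        save_site_posteriors = FALSE)
  expect_equal(nrow(fit$draws), 2 * 200)
  rh <- fit$summary$rhat[fit$summary$parameter == "psi"]
  expect_lt(rh, 1.2)
  expect_true(all(fit$summary$ess > 0))
  # interval bounds bracket the posterior mean
  expect_true(all(fit$summary$pci_lower <= fit$summary$posterior_mean + 1e-12 &
                    fit$summary$posterior_mean <= fit$summary$pci_upper + 1e-12))
})

test_that("covariate fits recover a strong occupancy effect", {
  cp <- covariate_model_params(
    beta_psi = c(qlogis(0.2), 1.5), beta_theta11 = qlogis(0.85),
    beta_theta10 = qlogis(0.01), beta_p11 = qlogis(0.9),
    beta_p10 = qlogis(0.01),
    design = list(psi = "cov_cont", theta11 = character(0),
                  theta10 = character(0), p11 = character(0),
                  p10 = character(0)))
  d <- simulate_dataset(sim_config(600, 2, 8, cp, seed = 81))
  fit <- fit_full_model(d, covariates = list(psi = "cov_cont"),
                        mcmc = mcmc_control(n_burnin = 600, n_iter = 1200,
                                            thin = 3, seed = 12),
                        save_site_posteriors = FALSE)
  slope <- fit$summary$posterior_mean[
    fit$summary$parameter == "beta_psi.cov_cont"]
  expect_gt(slope, 0.7)
  expect_lt(slope, 2.5)
  base <- fit$summary$posterior_mean[fit$summary$parameter == "psi"]
  expect_lt(abs(base - 0.2), 0.08)
})
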