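#' Prior specification for the two-stage occupancy model
#'
#' Beta priors on each probability (used directly when the probability is
#' covariate-free, and mapped through the logit link onto the intercept
#' when it is modelled with covariates), plus independent normal priors on
#' logit-scale covariate coefficients.
#'
#' The defaults are deliberately informative everywhere except occupancy.
#' `Beta(1, 19)` (mean 0.05) concentrates the false-positive
#' probabilities `theta10` and `p10` near zero, and `Beta(8, 2)` (mean
#' 0.8, a prior weight of ten observations) places the true-positive
#' probabilities `theta11` and `p11` in the high range expected of a
#' validated field protocol and qPCR assay. Informative priors are the
#' standard device that makes the false-positive occupancy model
#' identifiable from detection data alone - in particular with a single
#' field sample per site, where occupancy and stage-1 capture enter the
#' likelihood only through their compound; flat priors there leave
#' occupancy prior-dominated and invite label switching between the
#' true-signal and false-signal modes. Occupancy `psi` keeps a flat
#' `Beta(1, 1)` prior. All hyperparameters are configurable, and with
#' replication at both stages the data quickly dominate these defaults.
#'
#' @param psi,theta11,theta10,p11,p10 Length-2 numeric vectors of Beta
#'   shape hyperparameters (both strictly positive).
#' @param coef_mean,coef_sd Mean and standard deviation of the normal
#'   prior on each covariate coefficient (logit scale); `coef_sd > 0`.
#' @return An object of class `edna_priors`.
#' @export
prior_spec <- function(psi = c(1, 1), theta11 = c(8, 2), theta10 = c(1, 19),
                       p11 = c(8, 2), p10 = c(1, 19),
                       coef_mean = 0, coef_sd = 1.5) {
  beta <- list(psi = psi, theta11 = theta11, theta10 = theta10,
               p11 = p11, p10 = p10)
  for (nm in names(beta)) {
    b <- beta[[nm]]
    if (length(b) != 2L || any(!is.finite(b)) || any(b <= 0)) {
      stop("Beta hyperparameters for ", nm,
           " must be two strictly positive numbers", call. = FALSE)
    }
  }
  if (!is.finite(coef_sd) || coef_sd <= 0) {
    stop("coef_sd must be strictly positive", call. = FALSE)
  }
  structure(list(beta = beta, coef_mean = coef_mean, coef_sd = coef_sd),
            class = "edna_priors")
}

#' @export
print.edna_priors <- function(x, ...) {
  cat("Priors for the two-stage occupancy model\n")
  for (nm in names(x$beta)) {
    cat(sprintf("  %-8s ~ Beta(%g, %g)\n", nm, x$beta[[nm]][1], x$beta[[nm]][2]))
  }
  cat(sprintf("  covariate coefficients ~ Normal(%g, %g^2) on the logit scale\n",
              x$coef_mean, x$coef_sd))
  invisible(x)
}

# log density of the intercept prior induced by Beta(a, b) on the
# probability scale: if plogis(b0) ~ Beta(a, b) then
# log p(b0) = log dbeta(q) + log q + log(1 - q), q = plogis(b0)
intercept_logprior <- function(b0, shape) {
  q <- stats::plogis(b0)
  stats::dbeta(q, shape[1], shape[2], log = TRUE) + log(q) + log1p(-q)
}

#' MCMC control settings
#'
#' @param n_burnin Burn-in iterations discarded per chain.
#' @param n_iter Post-burn-in iterations per chain.
#' @param thin Thinning interval; `n_iter / thin` draws are stored per
#'   chain.
#' @param n_chains Number of independent chains.
#' @param seed Integer seed governing all randomness in the fit.
#' @return An object of class `edna_mcmc_control`.
#' @export
mcmc_control <- function(n_burnin = 1000, n_iter = 2000, thin = 10,
                         n_chains = 1, seed = 1) {
  for (v in list(n_burnin = n_burnin, n_iter = n_iter, thin = thin,
                 n_chains = n_chains)) {
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      stop("MCMC settings must be positive integers", call. = FALSE)
    }
  }
  if (n_iter %% thin != 0) {
    stop("n_iter must be a multiple of thin", call. = FALSE)
  }
  structure(list(n_burnin = as.integer(n_burnin), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed)),
            class = "edna_mcmc_control")
}
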