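#' Fit the full two-stage occupancy model with false positives
#'
#' Bayesian MCMC fit of the two-stage eDNA occupancy model by latent-state
#' data augmentation. Each sweep alternates (i) sampling every site's
#' occupancy indicator `z` from its full conditional (fixed to 1 at
#' confirmed-presence sites), (ii) sampling every field sample's
#' eDNA-capture indicator `a` from its full conditional, and (iii)
#' updating the probability parameters - from conjugate Beta full
#' conditionals when covariate-free, or by adaptive random-walk Metropolis
#' on logit-scale coefficients when modelled with covariates. The
#' identifiable orientation `theta11 > theta10`, `p11 > p10` is enforced
#' within the sampler.
#'
#' When every site has a single field sample (M = 1) and there are neither
#' covariates nor confirmed presences, occupancy and stage-1 capture are
#' confounded; the fit proceeds on the strength of the informative priors
#' but a warning is issued.
#'
#' @param data An [edna_data] dataset.
#' @param priors An [prior_spec()] object.
#' @param mcmc An [mcmc_control()] object.
#' @param covariates Covariate design: `NULL` for covariate-free
#'   probabilities; a character vector of covariate names applied to all
#'   five probabilities; or a named list with entries `psi`, `theta11`,
#'   `theta10`, `p11`, `p10` giving each linear predictor its own
#'   covariates (missing entries are covariate-free).
#' @param save_site_posteriors Store per-draw site occupancy probabilities
#'   (Rao-Blackwellised, marginalising the latent states at the current
#'   parameters)? Needed for [site_occupancy_posteriors()] and
#'   [compare_models()].
#' @return An object of class `edna_fit`; see [summary.edna_fit()].
#' @examples
#' pars <- model_params(0.1, 0.85, 0.01, 0.9, 0.01)
#' d <- simulate_dataset(sim_config(100, 2, 6, pars, seed = 7))
#' fit <- fit_full_model(d, mcmc = mcmc_control(n_burnin = 100,
#'                                              n_iter = 200, thin = 2))
#' summary(fit)
#' @export
fit_full_model <- function(data, priors = prior_spec(),
                           mcmc = mcmc_control(), covariates = NULL,
                           save_site_posteriors = TRUE) {
  run_sampler(data, priors, mcmc, covariates, variant = "full",
              save_site_posteriors = save_site_posteriors)
}

#' Fit the constrained no-false-positive multi-scale occupancy model
#'
#' Identical hierarchical structure, but with both false-positive
#' probabilities fixed to exactly zero (`theta10 = p10 = 0`): any
#' amplifying replicate forces its sample's capture state to 1, and any
#' positive sample forces its site's occupancy to 1. This is the
#' conventional multi-scale occupancy model; comparing it with the full
#' model quantifies how far ignoring false positives inflates occupancy.
#'
#' @inheritParams fit_full_model
#' @param covariates As in [fit_full_model()]; entries for `theta10` and
#'   `p10` are ignored (those probabilities are fixed at zero).
#' @return An object of class `edna_fit`.
#' @export
fit_no_false_positive_model <- function(data, priors = prior_spec(),
                                        mcmc = mcmc_control(),
                                        covariates = NULL,
                                        save_site_posteriors = TRUE) {
  run_sampler(data, priors, mcmc, covariates, variant = "no_false_positives",
              save_site_posteriors = save_site_posteriors)
}

# normalise the covariates argument to a named list over the free params
normalise_design <- function(covariates, free_params, data) {
  design <- stats::setNames(rep(list(character(0)), length(free_params)),
                            free_params)
  if (is.null(covariates)) return(design)
  if (is.character(covariates)) {
    covariates <- stats::setNames(rep(list(covariates), length(free_params)),
                                  free_params)
  }
  if (!is.list(covariates)) {
    stop("covariates must be NULL, a character vector or a named list",
         call. = FALSE)
  }
  for (nm in intersect(names(covariates), free_params)) {
    covs <- covariates[[nm]]
    missing_covs <- setdiff(covs, data$covariates)
    if (length(missing_covs)) {
      stop("unknown covariate(s) for ", nm, ": ",
           paste(missing_covs, collapse = ", "), call. = FALSE)
    }
    design[[nm]] <- covs
  }
  design
}

run_sampler <- function(data, priors, mcmc, covariates, variant,
                        save_site_posteriors) {
  stopifnot(inherits(data, "edna_data"), inherits(priors, "edna_priors"),
            inherits(mcmc, "edna_mcmc_control"))
  no_fp <- variant == "no_false_positives"
  free_params <- if (no_fp) c("psi", "theta11", "p11") else
    c("psi", "theta11", "theta10", "p11", "p10")
  design <- normalise_design(covariates, free_params, data)
  has_cov <- vapply(design, function(d) length(d) > 0, logical(1))

  M_max <- max(table(data$samples$site_id))
  if (M_max == 1 && !any(has_cov) && !any(data$sites$confirmed_present)) {
    warning("all sites have a single field sample and no covariates or ",
            "confirmed presences: occupancy and stage-1 capture are only ",
            "separated by the priors", call. = FALSE)
  }

  chains <- lapply(seq_len(mcmc$n_chains), function(ch) {
    with_local_seed(derive_seed(mcmc$seed, ch), {
      run_one_chain(data, priors, mcmc, design, no_fp, save_site_posteriors)
    })
  })

  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  chain_id <- rep(seq_len(mcmc$n_chains), each = mcmc$n_iter %/% mcmc$thin)
  site_draws <- if (save_site_posteriors) {
    do.call(rbind, lapply(chains, `[[`, "site_draws"))
  } else NULL

  prob_names <- c("psi", "theta11", "theta10", "p11", "p10")
  summ <- summarise_draws(draws, chain_id)
  site_summary <- NULL
  if (save_site_posteriors) {
    qs <- t(apply(site_draws, 2, stats::quantile, probs = c(0.025, 0.975),
                  names = FALSE))
    site_summary <- data.frame(site_id = data$sites$site_id,
                               mean = colMeans(site_draws),
                               pci_lower = qs[, 1], pci_upper = qs[, 2],
                               stringsAsFactors = FALSE)
  }

  structure(list(draws = draws, chain_id = chain_id,
                 site_draws = site_draws, site_summary = site_summary,
                 summary = summ,
                 model_variant = variant, design = design,
                 priors = priors, mcmc = mcmc,
                 site_id = data$sites$site_id,
                 prob_names = prob_names,
                 n_sites = n_sites(data), n_samples = n_samples(data)),
            class = "edna_fit")
}

run_one_chain <- function(data, priors, mcmc, design, no_fp,
                          save_site_posteriors) {
  S <- n_sites(data)
  idx <- sample_site_index(data)
  y <- data$samples$y
  K <- data$samples$K
  n <- length(y)
  conf <- data$sites$confirmed_present
  Xs <- covariate_matrix(data)              # S x ncov
  has_cov <- vapply(design, function(d) length(d) > 0, logical(1))
  free <- names(design)

  # design matrices (with intercept) per parameter, at site level
  Xmat <- lapply(design, function(covs) {
    cbind(`(Intercept)` = rep(1, S),
          if (length(covs)) Xs[, covs, drop = FALSE])
  })

  # --- state ---------------------------------------------------------
  a <- as.integer(y > 0)
  z <- as.integer(rowsum_by(a, idx, S) > 0)
  z[conf] <- 1L
  prob <- list(psi = 0.5, theta11 = 0.7, theta10 = if (no_fp) 0 else 0.05,
               p11 = 0.8, p10 = if (no_fp) 0 else 0.05)
  beta <- lapply(free, function(nm) {
    b <- c(stats::qlogis(prob[[nm]]), rep(0, length(design[[nm]])))
    names(b) <- colnames(Xmat[[nm]])
    b
  })
  names(beta) <- free
  log_scale <- stats::setNames(rep(log(0.3), length(free)), free)
  n_mh <- 2L  # metropolis proposals per parameter per sweep

  # a probability pair is updated conjugately only when neither member
  # carries covariates; otherwise both members of the pair go through
  # Metropolis so the orientation constraint stays coherent
  th_conj <- !has_cov[["theta11"]] && (no_fp || !has_cov[["theta10"]])
  p_conj <- !has_cov[["p11"]] && (no_fp || !has_cov[["p10"]])
  use_mh <- c(psi = has_cov[["psi"]],
              theta11 = !th_conj, theta10 = !no_fp && !th_conj,
              p11 = !p_conj, p10 = !no_fp && !p_conj)

  # per-site probability vectors (length S)
  pvec <- list()
  refresh_pvec <- function() {
    for (nm in c("psi", "theta11", "theta10", "p11", "p10")) {
      pvec[[nm]] <<- if (nm %in% free && use_mh[[nm]]) {
        as.vector(stats::plogis(Xmat[[nm]] %*% beta[[nm]]))
      } else rep(prob[[nm]], S)
    }
  }
  refresh_pvec()

  # Bernoulli/binomial log likelihood of a parameter's response subset
  par_loglik <- function(nm, b) {
    if (nm == "psi") {
      eta <- Xmat$psi %*% b
      return(sum(stats::dbinom(z, 1, stats::plogis(eta), log = TRUE)))
    }
    if (nm %in% c("theta11", "theta10")) {
      sel <- if (nm == "theta11") z[idx] == 1L else z[idx] == 0L
      if (!any(sel)) return(0)
      eta <- (Xmat[[nm]] %*% b)[idx[sel]]
      return(sum(stats::dbinom(a[sel], 1, stats::plogis(eta), log = TRUE)))
    }
    sel <- if (nm == "p11") a == 1L else a == 0L
    if (!any(sel)) return(0)
    eta <- (Xmat[[nm]] %*% b)[idx[sel]]
    sum(stats::dbinom(y[sel], K[sel], stats::plogis(eta), log = TRUE))
  }

  par_logprior <- function(nm, b) {
    lp <- intercept_logprior(b[1L], priors$beta[[nm]])
    if (length(b) > 1L) {
      lp <- lp + sum(stats::dnorm(b[-1L], priors$coef_mean, priors$coef_sd,
                                  log = TRUE))
    }
    lp
  }

  # orientation constraint on baseline probabilities
  orient_ok <- function(nm, b0) {
    if (no_fp) return(TRUE)
    base <- function(p) if (use_mh[[p]]) beta[[p]][1L] else
      stats::qlogis(prob[[p]])
    switch(nm,
           theta11 = b0 > base("theta10"),
           theta10 = b0 < base("theta11"),
           p11 = b0 > base("p10"),
           p10 = b0 < base("p11"),
           TRUE)
  }

  mh_step <- function(nm, sweep, adapting) {
    b <- beta[[nm]]
    lp_cur <- par_loglik(nm, b) + par_logprior(nm, b)
    for (it in seq_len(n_mh)) {
      prop <- b + exp(log_scale[[nm]]) * stats::rnorm(length(b))
      lp_prop <- if (orient_ok(nm, prop[1L])) {
        par_loglik(nm, prop) + par_logprior(nm, prop)
      } else -Inf
      acc <- log(stats::runif(1)) < lp_prop - lp_cur
      if (acc) { b <- prop; lp_cur <- lp_prop }
      if (adapting) {
        gam <- min(0.25, 2 / sqrt(sweep))
        log_scale[[nm]] <<- log_scale[[nm]] + gam * ((acc * 1) - 0.3)
      }
    }
    beta[[nm]] <<- b
  }

  # conjugate Beta draw for a probability pair subject to orientation;
  # redrawing both until ordered samples the joint truncated conditional
  draw_ordered_pair <- function(hi_shape, lo_shape) {
    for (attempt in 1:200) {
      hi <- stats::rbeta(1, hi_shape[1], hi_shape[2])
      lo <- stats::rbeta(1, lo_shape[1], lo_shape[2])
      if (hi > lo) return(c(hi, lo))
    }
    c(NA_real_, NA_real_)  # keep previous values (vanishingly rare)
  }

  n_store <- mcmc$n_iter %/% mcmc$thin
  coef_cols <- unlist(lapply(free[has_cov[free]], function(nm) {
    paste0("beta_", nm, ".", colnames(Xmat[[nm]]))
  }))
  draws <- matrix(NA_real_, n_store,
                  5L + length(coef_cols),
                  dimnames = list(NULL, c("psi", "theta11", "theta10",
                                          "p11", "p10", coef_cols)))
  site_draws <- if (save_site_posteriors) matrix(NA_real_, n_store, S) else NULL

  total <- mcmc$n_burnin + mcmc$n_iter
  store_i <- 0L
  for (sweep in seq_len(total)) {
    # --- (ii) update a | z, theta, p, y ------------------------------
    th <- ifelse(z[idx] == 1L, pvec$theta11[idx], pvec$theta10[idx])
    w1 <- th * stats::dbinom(y, K, pvec$p11[idx])
    w0 <- (1 - th) * stats::dbinom(y, K, pvec$p10[idx])
    a <- stats::rbinom(n, 1L, w1 / (w1 + w0))

    # --- (i) update z | a, psi, theta --------------------------------
    l1 <- rowsum_by(stats::dbinom(a, 1, pvec$theta11[idx], log = TRUE), idx, S)
    l0 <- rowsum_by(stats::dbinom(a, 1, pvec$theta10[idx], log = TRUE), idx, S)
    lo1 <- log(pvec$psi) + l1
    lo0 <- log1p(-pvec$psi) + l0
    pz <- 1 / (1 + exp(lo0 - lo1))
    pz[lo1 == -Inf] <- 0
    z <- stats::rbinom(S, 1L, pz)
    z[conf] <- 1L

    # --- (iii) update parameters -------------------------------------
    zs <- z[idx]  # site occupancy at sample level
    if (!has_cov[["psi"]]) {
      sh <- priors$beta$psi
      prob$psi <- stats::rbeta(1, sh[1] + sum(z), sh[2] + S - sum(z))
    } else mh_step("psi", sweep, sweep <= mcmc$n_burnin)

    if (th_conj) {
      n11 <- sum(a[zs == 1L]); d11 <- sum(zs == 1L) - n11
      sh11 <- priors$beta$theta11 + c(n11, d11)
      if (no_fp) {
        prob$theta11 <- stats::rbeta(1, sh11[1], sh11[2])
      } else {
        n10 <- sum(a[zs == 0L]); d10 <- sum(zs == 0L) - n10
        pair <- draw_ordered_pair(sh11, priors$beta$theta10 + c(n10, d10))
        if (!is.na(pair[1])) { prob$theta11 <- pair[1]; prob$theta10 <- pair[2] }
      }
    } else {
      mh_step("theta11", sweep, sweep <= mcmc$n_burnin)
      if (!no_fp) mh_step("theta10", sweep, sweep <= mcmc$n_burnin)
    }

    if (p_conj) {
      s11 <- sum(y[a == 1L]); f11 <- sum(K[a == 1L]) - s11
      sh11 <- priors$beta$p11 + c(s11, f11)
      if (no_fp) {
        prob$p11 <- stats::rbeta(1, sh11[1], sh11[2])
      } else {
        s10 <- sum(y[a == 0L]); f10 <- sum(K[a == 0L]) - s10
        pair <- draw_ordered_pair(sh11, priors$beta$p10 + c(s10, f10))
        if (!is.na(pair[1])) { prob$p11 <- pair[1]; prob$p10 <- pair[2] }
      }
    } else {
      mh_step("p11", sweep, sweep <= mcmc$n_burnin)
      if (!no_fp) mh_step("p10", sweep, sweep <= mcmc$n_burnin)
    }
    refresh_pvec()

    # --- store -------------------------------------------------------
    if (sweep > mcmc$n_burnin &&
        (sweep - mcmc$n_burnin) %% mcmc$thin == 0L) {
      store_i <- store_i + 1L
      baseline <- vapply(c("psi", "theta11", "theta10", "p11", "p10"),
                         function(nm) {
                           if (nm %in% free && use_mh[[nm]]) {
                             stats::plogis(beta[[nm]][1L])
                           } else prob[[nm]]
                         }, numeric(1))
      row <- baseline
      if (length(coef_cols)) {
        row <- c(row, unlist(beta[free[has_cov[free]]], use.names = FALSE))
      }
      draws[store_i, ] <- row
      if (save_site_posteriors) {
        sp <- dataset_site_loglik(data, pvec$psi, pvec$theta11, pvec$theta10,
                                  pvec$p11, pvec$p10)$occ_post
        site_draws[store_i, ] <- sp
      }
    }
  }
  list(draws = draws, site_draws = site_draws)
}

summarise_draws <- function(draws, chain_id) {
  qs <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE))
  data.frame(parameter = colnames(draws),
             posterior_mean = colMeans(draws),
             pci_lower = qs[, 1], pci_upper = qs[, 2],
             pci_width = qs[, 2] - qs[, 1],
             ess = apply(draws, 2, ess_mean),
             rhat = apply(draws, 2, split_rhat, chain_id = chain_id),
             row.names = NULL, stringsAsFactors = FALSE)
}

# effective sample size via the initial positive sequence of sample
# autocorrelations
ess_mean <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE,
                    demean = TRUE)$acf[-1]
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] < 0) break
    s <- s + rho[k]
  }
  n / (1 + 2 * s)
}

# split-Rhat: each chain halved, classic between/within variance ratio
split_rhat <- function(x, chain_id) {
  segs <- unlist(lapply(split(x, chain_id), function(ch) {
    h <- length(ch) %/% 2L
    if (h < 2L) return(list(ch))
    list(ch[seq_len(h)], ch[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  m <- length(segs)
  if (m < 2L) return(NA_real_)
  nseg <- min(lengths(segs))
  segs <- lapply(segs, function(s) s[seq_len(nseg)])
  means <- vapply(segs, mean, numeric(1))
  vars <- vapply(segs, stats::var, numeric(1))
  W <- mean(vars)
  B <- nseg * stats::var(means)
  if (W == 0) return(1)
  sqrt(((nseg - 1) / nseg * W + B / nseg) / W)
}

#' @export
print.edna_fit <- function(x, ...) {
  cat(sprintf("Two-stage occupancy model fit (%s)\n",
              gsub("_", " ", x$model_variant)))
  cat(sprintf("  %d sites, %d samples; %d chain(s), %d stored draws\n",
              x$n_sites, x$n_samples, x$mcmc$n_chains, nrow(x$draws)))
  print(x$summary[x$summary$parameter %in% x$prob_names,
                  c("parameter", "posterior_mean", "pci_lower", "pci_upper")],
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Summarise a fitted two-stage occupancy model
#'
#' @param object An `edna_fit` object.
#' @param ... Unused.
#' @return Data frame with posterior mean, 95\% credible interval bounds
#'   and width, effective sample size and split R-hat per parameter
#'   (probability-scale parameters are reported at the baseline site when
#'   covariates are present, alongside the logit-scale coefficients).
#' @export
summary.edna_fit <- function(object, ...) {
  object$summary
}
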