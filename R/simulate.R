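#' Simulation configuration for two-stage eDNA detection data
#'
#' @param S Number of sites (>= 1).
#' @param M Field samples per site (>= 1).
#' @param K qPCR replicates per sample (>= 1).
#' @param params An [model_params()] object (constant probabilities; any
#'   simulated covariates are decoys with zero effect) or a
#'   [covariate_model_params()] object (per-site probabilities through
#'   logistic links).
#' @param include_covariates Draw per-site covariates? A standard-normal
#'   continuous covariate (`cov_cont`, centred at zero) and a binary
#'   covariate with occurrence probability 0.5 (`cov_bin`). Required when
#'   `params` is a covariate model.
#' @param seed Integer random seed; the same seed yields an identical
#'   dataset.
#'
#' @details With a single field sample per site (`M = 1`), no covariates
#' and no confirmed presences, occupancy cannot be separated from stage-1
#' capture using the detection data alone (only their compound is
#' identified); the configuration is accepted with a warning, since
#' informative priors can still anchor a fit.
#'
#' @return An object of class `edna_sim_config`.
#' @export
sim_config <- function(S, M, K, params, include_covariates = TRUE,
                       seed = NULL) {
  if (!(inherits(params, "edna_params") || inherits(params, "edna_coef_params"))) {
    stop("params must be an edna_params or edna_coef_params object",
         call. = FALSE)
  }
  for (v in list(S = S, M = M, K = K)) {
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      stop("S, M and K must be positive integers", call. = FALSE)
    }
  }
  if (inherits(params, "edna_coef_params") && !include_covariates) {
    stop("covariate model parameters require include_covariates = TRUE",
         call. = FALSE)
  }
  if (M == 1 && !include_covariates) {
    warning("M = 1 with no covariates (and no confirmed presences) is not ",
            "identifiable from detection data alone; fits will lean on priors",
            call. = FALSE)
  }
  structure(list(S = as.integer(S), M = as.integer(M), K = as.integer(K),
                 params = params, include_covariates = include_covariates,
                 seed = seed),
            class = "edna_sim_config")
}

#' Simulate a two-stage eDNA detection dataset
#'
#' Draws data from the generative model: site occupancy
#' `z ~ Bernoulli(psi_i)`; per field sample an eDNA-capture state
#' `a ~ Bernoulli(theta11_i)` if the site is occupied, else
#' `Bernoulli(theta10_i)`; and per sample an amplification count
#' `y ~ Binomial(K, p11_i)` if the sample captured signal, else
#' `Binomial(K, p10_i)`.
#'
#' @param config An [sim_config()] object.
#' @return An [edna_data] dataset with `S` sites and `S * M` samples.
#'   Attributes `truth` (the generating parameters) and `latent` (the
#'   simulated `z` and `a` states) are attached for calibration studies.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "edna_sim_config"))
  with_local_seed(config$seed, {
    S <- config$S; M <- config$M; K <- config$K
    sites <- data.frame(site_id = sprintf("site_%04d", seq_len(S)),
                        confirmed_present = FALSE,
                        stringsAsFactors = FALSE)
    if (config$include_covariates) {
      sites$cov_cont <- stats::rnorm(S)
      sites$cov_bin <- stats::rbinom(S, 1L, 0.5)
    }
    if (inherits(config$params, "edna_coef_params")) {
      pr <- site_probabilities(config$params,
                               sites[, c("cov_cont", "cov_bin"), drop = FALSE])
    } else {
      pr <- config$params[c("psi", "theta11", "theta10", "p11", "p10")]
    }
    z <- stats::rbinom(S, 1L, rep_len(pr$psi, S))
    z_s <- rep(z, each = M)
    th <- ifelse(z_s == 1L, rep(rep_len(pr$theta11, S), each = M),
                 rep(rep_len(pr$theta10, S), each = M))
    a <- stats::rbinom(S * M, 1L, th)
    p <- ifelse(a == 1L, rep(rep_len(pr$p11, S), each = M),
                rep(rep_len(pr$p10, S), each = M))
    y <- stats::rbinom(S * M, K, p)
    samples <- data.frame(site_id = rep(sites$site_id, each = M),
                          sample_id = rep(seq_len(M), times = S),
                          K = K, y = y, stringsAsFactors = FALSE)
    out <- edna_data(samples, sites)
    attr(out, "truth") <- config$params
    attr(out, "latent") <- list(z = z, a = a)
    out
  })
}

#' Simulate a grid of datasets over (S, M, K) with repeats
#'
#' One dataset per combination of `S_list`, `M_list`, `K_list` and repeat
#' index. Every cell's seed is derived deterministically from `base_seed`
#' and the cell key `(S, M, K, repeat)`, so results are identical whatever
#' order cells are generated in.
#'
#' @param S_list,M_list,K_list Integer vectors of grid levels.
#' @param repeats Number of repeat datasets per cell (>= 1).
#' @param params Generating parameters, as in [sim_config()].
#' @param base_seed Integer base seed.
#' @param include_covariates Passed to [sim_config()].
#' @return A named list of [edna_data] datasets, keyed
#'   `S<S>_M<M>_K<K>_r<repeat>`.
#' @export
simulate_grid <- function(S_list, M_list, K_list, repeats, params,
                          base_seed, include_covariates = TRUE) {
  stopifnot(length(S_list) > 0, length(M_list) > 0, length(K_list) > 0,
            repeats >= 1)
  grid <- expand.grid(r = seq_len(repeats), K = K_list, M = M_list,
                      S = S_list)
  out <- vector("list", nrow(grid))
  names(out) <- sprintf("S%d_M%d_K%d_r%d", grid$S, grid$M, grid$K, grid$r)
  for (i in seq_len(nrow(grid))) {
    cfg <- sim_config(grid$S[i], grid$M[i], grid$K[i], params,
                      include_covariates = include_covariates,
                      seed = derive_seed(base_seed, grid$S[i], grid$M[i],
                                         grid$K[i], grid$r[i]))
    out[[i]] <- simulate_dataset(cfg)
  }
  out
}

#' Derive a reproducible sub-seed from a base seed and a key
#'
#' Counter-style integer hash (a 31-bit multiplicative congruential mix)
#' of the base seed and any number of integer key components. Independent
#' of evaluation order, so parallel or resumed runs draw identical
#' sub-streams.
#'
#' @param base_seed Integer base seed.
#' @param ... Integer key components (e.g. S, M, K, repeat index).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(base_seed, ...) {
  comps <- c(base_seed, ...)
  h <- 0
  m <- 2^31
  for (x in comps) {
    # 69069: classic MCG multiplier; products stay below 2^53 so the
    # double-precision modulus is exact
    h <- (h * 69069 + (as.numeric(x) %% m) + 1) %% m
  }
  h <- (h * 69069 + 12345) %% m
  as.integer(h)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL uses (and advances) the current stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
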