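#' Marginal likelihood of one site's qPCR replicate counts
#'
#' Computes the probability of observing the vector of positive-replicate
#' counts `y` (one entry per field sample, out of `K` replicates each) for
#' a single site, marginalising over the site's latent occupancy state and
#' every sample's latent eDNA-capture state:
#'
#' \deqn{P(y) = (1-\psi)\prod_j\left[\theta_{10} B(y_j; K_j, p_{11}) +
#'   (1-\theta_{10}) B(y_j; K_j, p_{10})\right] +
#'   \psi\prod_j\left[\theta_{11} B(y_j; K_j, p_{11}) +
#'   (1-\theta_{11}) B(y_j; K_j, p_{10})\right]}
#'
#' where \eqn{B} is the binomial pmf. The two addends correspond to the
#' unoccupied and occupied branches of the two-stage detection tree.
#'
#' @param params An `edna_params` object.
#' @param K Integer vector of replicates run per sample (recycled against
#'   `y`).
#' @param y Integer vector of positive replicates per sample.
#' @param log Return the log probability?
#' @return A single probability (or log probability).
#' @export
site_marginal_likelihood <- function(params, K, y, log = FALSE) {
  stopifnot(inherits(params, "edna_params"))
  if (length(y) == 0L) stop("a site must have at least one sample", call. = FALSE)
  n <- max(length(K), length(y))
  K <- rep_len(K, n); y <- rep_len(y, n)
  if (any(y < 0) || any(y > K)) {
    stop("y must lie in [0, K] for every sample", call. = FALSE)
  }
  b1 <- stats::dbinom(y, K, params$p11)
  b0 <- stats::dbinom(y, K, params$p10)
  s1 <- sum(log(params$theta11 * b1 + (1 - params$theta11) * b0))
  s0 <- sum(log(params$theta10 * b1 + (1 - params$theta10) * b0))
  ll <- log_mix2(log(params$psi) + s1, log1p(-params$psi) + s0)
  if (log) ll else exp(ll)
}

# log(exp(la) + exp(lb)) handling -Inf
log_mix2 <- function(la, lb) {
  m <- pmax(la, lb)
  out <- m + log(exp(la - m) + exp(lb - m))
  out[m == -Inf] <- -Inf
  out
}

# Vectorised per-site log marginal likelihood for a whole dataset, allowing
# per-site probabilities (vectors of length S) as produced by covariate
# models. Returns list(log_lik = per-site vector, occ_post = per-site
# P(z = 1 | y, params)). Confirmed-presence sites condition on z = 1.
dataset_site_loglik <- function(data, psi, theta11, theta10, p11, p10) {
  idx <- sample_site_index(data)
  S <- n_sites(data)
  th11 <- rep_len(theta11, S)[idx]
  th10 <- rep_len(theta10, S)[idx]
  pp11 <- rep_len(p11, S)[idx]
  pp10 <- rep_len(p10, S)[idx]
  y <- data$samples$y; K <- data$samples$K
  b1 <- stats::dbinom(y, K, pp11)
  b0 <- stats::dbinom(y, K, pp10)
  s1 <- rowsum_by(log(th11 * b1 + (1 - th11) * b0), idx, S)
  s0 <- rowsum_by(log(th10 * b1 + (1 - th10) * b0), idx, S)
  psi <- rep_len(psi, S)
  la <- log(psi) + s1          # occupied branch
  lb <- log1p(-psi) + s0       # unoccupied branch
  ll <- log_mix2(la, lb)
  occ <- exp(la - ll)
  occ[ll == -Inf] <- NA_real_
  conf <- data$sites$confirmed_present
  ll[conf] <- la[conf]
  occ[conf] <- 1
  list(log_lik = ll, occ_post = occ)
}

rowsum_by <- function(x, idx, S) {
  out <- numeric(S)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Dataset log likelihood of the two-stage occupancy model
#'
#' Sum of per-site log marginal likelihoods over all sites, computed in log
#' space. Sites flagged `confirmed_present` condition on occupancy.
#'
#' @param params An `edna_params` object.
#' @param data An [edna_data] dataset.
#' @return The log likelihood (scalar).
#' @export
log_likelihood <- function(params, data) {
  stopifnot(inherits(params, "edna_params"), inherits(data, "edna_data"))
  sum(dataset_site_loglik(data, params$psi, params$theta11, params$theta10,
                          params$p11, params$p10)$log_lik)
}

#' Conditional probability of species absence given x amplifying replicates
#'
#' For a single field sample analysed with `K` qPCR replicates of which
#' `x` amplified, returns the posterior probability that the site is in
#' fact unoccupied, \eqn{P(z = 0 \mid y = x)}, by Bayes' rule on the two
#' branches of the site marginal likelihood. Under the identifiable
#' orientation (`theta11 > theta10`, `p11 > p10`) the curve is monotone
#' non-increasing in `x`: the more replicates amplify, the less plausible
#' absence becomes.
#'
#' This is the single-sample (M = 1) baseline-site quantity; see
#' [absence_curve()] for the posterior-averaged version after model
#' fitting, and pass multi-sample `y` vectors to
#' [site_marginal_likelihood()] directly for the general case.
#'
#' @param params An `edna_params` object (plug-in probabilities).
#' @param x Integer vector of amplifying replicate counts, each in
#'   \[0, K\].
#' @param K Number of qPCR replicates run.
#' @return Numeric vector of absence probabilities, one per `x`.
#' @examples
#' pars <- model_params(0.26, 0.77, 0.02, 0.84, 0.02)
#' conditional_absence_probability(pars, x = 0:12, K = 12)
#' @export
conditional_absence_probability <- function(params, x, K) {
  stopifnot(inherits(params, "edna_params"))
  if (any(x < 0) || any(x > K)) stop("x must lie in [0, K]", call. = FALSE)
  b1 <- stats::dbinom(x, K, params$p11)
  b0 <- stats::dbinom(x, K, params$p10)
  la <- log(params$psi) +
    log(params$theta11 * b1 + (1 - params$theta11) * b0)
  lb <- log1p(-params$psi) +
    log(params$theta10 * b1 + (1 - params$theta10) * b0)
  ll <- log_mix2(la, lb)
  out <- exp(lb - ll)
  out[ll == -Inf] <- NA_real_   # outcome has probability zero
  out
}

#' Naive occupancy rate at a positive-replicate threshold
#'
#' The fraction of sites declared occupied by the simple rule "at least one
#' field sample with at least `threshold` positive qPCR replicates", with
#' no error modelling. Non-increasing in `threshold`.
#'
#' @param data An [edna_data] dataset.
#' @param threshold Minimum number of positive replicates in a sample for
#'   the site to count as occupied (>= 1).
#' @return Proportion of sites in \[0, 1\].
#' @export
naive_occupancy <- function(data, threshold = 1) {
  stopifnot(inherits(data, "edna_data"))
  if (threshold < 1) stop("threshold must be >= 1", call. = FALSE)
  idx <- sample_site_index(data)
  hit <- rowsum_by((data$samples$y >= threshold) * 1, idx, n_sites(data))
  mean(hit > 0)
}

#' Frequency spectrum of positive qPCR replicate counts
#'
#' Tabulates, for each replicate depth `K` present in the data, how many
#' field samples returned each possible count `y = 0..K` of amplifying
#' replicates. eDNA data sets typically show a bimodal spectrum: most mass
#' at `y = 0` and `y = K`, with a thin middle and a secondary bump at low
#' `y` attributable to false positive amplification.
#'
#' @param data An [edna_data] dataset.
#' @return A data frame with columns `K`, `y` and `n_samples`, covering
#'   the full range `0..K` for each `K`; `sum(n_samples)` equals the total
#'   number of field samples.
#' @export
replicate_spectrum <- function(data) {
  stopifnot(inherits(data, "edna_data"))
  out <- lapply(sort(unique(data$samples$K)), function(k) {
    ys <- data$samples$y[data$samples$K == k]
    data.frame(K = k, y = 0:k,
               n_samples = as.vector(table(factor(ys, levels = 0:k))))
  })
  do.call(rbind, out)
}
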