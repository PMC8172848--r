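# Shared fixtures and independent oracles. The oracles enumerate the
# latent states directly and never touch the package's likelihood code.

newt_params <- function() model_params(0.1, 0.85, 0.01, 0.9, 0.01)
survey_params <- function() model_params(0.26, 0.77, 0.02, 0.84, 0.02)

# exhaustive enumeration of P(y_1..y_M) over (z, a_1..a_M)
brute_site_lik <- function(params, K, y) {
  M <- length(y)
  K <- rep_len(K, M)
  tot <- 0
  for (z in 0:1) {
    for (code in 0:(2^M - 1)) {
      a <- as.integer(intToBits(code))[seq_len(M)]
      pz <- if (z == 1) params$psi else 1 - params$psi
      th <- if (z == 1) params$theta11 else params$theta10
      pa <- prod(ifelse(a == 1, th, 1 - th))
      py <- prod(dbinom(y, K, ifelse(a == 1, params$p11, params$p10)))
      tot <- tot + pz * pa * py
    }
  }
  tot
}

# Bayes-rule absence probability for a single sample, by direct ratio
brute_absence <- function(params, x, K) {
  num <- (1 - params$psi) *
    (params$theta10 * dbinom(x, K, params$p11) +
       (1 - params$theta10) * dbinom(x, K, params$p10))
  den <- num + params$psi *
    (params$theta11 * dbinom(x, K, params$p11) +
       (1 - params$theta11) * dbinom(x, K, params$p10))
  num / den
}

# Bayes-rule site occupancy posterior P(z = 1 | y) for a multi-sample site
brute_site_occ <- function(params, K, y) {
  M <- length(y)
  K <- rep_len(K, M)
  occ <- params$psi *
    prod(params$theta11 * dbinom(y, K, params$p11) +
           (1 - params$theta11) * dbinom(y, K, params$p10))
  occ / brute_site_lik(params, K, y)
}

# random parameters in the identifiable orientation
rand_params <- function() {
  repeat {
    v <- runif(5)
    if (v[2] > v[3] && v[4] > v[5]) {
      return(model_params(v[1], v[2], v[3], v[4], v[5]))
    }
  }
}

# small hand-built dataset
toy_data <- function(y = c(0, 3, 12, 0), K = 12,
                     site = c("a", "a", "b", "b")) {
  edna_data(data.frame(site_id = site,
                       sample_id = stats::ave(seq_along(site), site,
                                              FUN = seq_along),
                       K = K, y = y))
}
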