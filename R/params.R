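#' Probability-scale parameters of the two-stage occupancy model
#'
#' Bundles the five probabilities that define the two-stage eDNA detection
#' model: site occupancy `psi`, the stage-1 (field sampling) true and false
#' positive probabilities `theta11` and `theta10`, and the stage-2
#' (laboratory qPCR) true and false positive probabilities `p11` and `p10`.
#' The complements (stage-1 false negative `1 - theta11`, etc.) are never
#' stored; they are always derived.
#'
#' The identifiable orientation `theta11 > theta10` and `p11 > p10` is
#' enforced at construction: the "true signal" path must be more likely to
#' produce a positive than the "false signal" path, which pins down the
#' labelling of the two latent modes.
#'
#' @param psi Probability a site is occupied, in \[0, 1\].
#' @param theta11 Probability a field sample captures target DNA given the
#'   site is occupied (stage-1 true positive).
#' @param theta10 Probability a field sample "captures" signal given the
#'   site is unoccupied (stage-1 false positive).
#' @param p11 Probability a single qPCR replicate amplifies given the
#'   sample is positive (stage-2 true positive).
#' @param p10 Probability a single qPCR replicate amplifies given the
#'   sample is negative (stage-2 false positive).
#'
#' @return An object of class `edna_params`: a named list with the five
#'   probabilities.
#' @examples
#' model_params(psi = 0.1, theta11 = 0.85, theta10 = 0.01,
#'              p11 = 0.9, p10 = 0.01)
#' @export
model_params <- function(psi, theta11, theta10, p11, p10) {
  vals <- c(psi = psi, theta11 = theta11, theta10 = theta10,
            p11 = p11, p10 = p10)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("all model probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (theta11 <= theta10) {
    stop("identifiability requires theta11 > theta10 ",
         "(true positive capture must exceed false positive capture)",
         call. = FALSE)
  }
  if (p11 <= p10) {
    stop("identifiability requires p11 > p10 ",
         "(true positive amplification must exceed false positive amplification)",
         call. = FALSE)
  }
  structure(as.list(vals), class = "edna_params")
}

#' @export
print.edna_params <- function(x, ...) {
  cat("Two-stage occupancy model parameters (probability scale)\n")
  cat(sprintf("  psi     = %.4g   (site occupancy)\n", x$psi))
  cat(sprintf("  theta11 = %.4g   theta10 = %.4g   (stage 1: field sampling)\n",
              x$theta11, x$theta10))
  cat(sprintf("  p11     = %.4g   p10     = %.4g   (stage 2: qPCR replicate)\n",
              x$p11, x$p10))
  invisible(x)
}

#' Logit-scale (covariate) parameters of the two-stage occupancy model
#'
#' Represents each of the five model probabilities as a logistic regression
#' on site covariates. Each coefficient vector holds an intercept followed
#' by one slope per covariate named in the corresponding `design` entry.
#' At the baseline site (all continuous covariates 0, all binary covariates
#' at their baseline level 0) the implied probabilities are
#' `plogis(intercept)`.
#'
#' @param beta_psi,beta_theta11,beta_theta10,beta_p11,beta_p10 Numeric
#'   coefficient vectors on the logit scale: intercept first, then one
#'   entry per covariate listed for that parameter in `design`.
#' @param design Named list with elements `psi`, `theta11`, `theta10`,
#'   `p11`, `p10`, each a character vector of covariate names entering
#'   that linear predictor (may be `character(0)` for intercept-only).
#'
#' @return An object of class `edna_coef_params`.
#' @seealso [baseline_params()] for the implied baseline-site probabilities.
#' @export
covariate_model_params <- function(beta_psi, beta_theta11, beta_theta10,
                                   beta_p11, beta_p10, design) {
  betas <- list(psi = beta_psi, theta11 = beta_theta11,
                theta10 = beta_theta10, p11 = beta_p11, p10 = beta_p10)
  if (!is.list(design) || !all(names(betas) %in% names(design))) {
    stop("design must be a named list covering psi, theta11, theta10, p11, p10",
         call. = FALSE)
  }
  for (nm in names(betas)) {
    b <- betas[[nm]]
    if (!is.numeric(b) || any(!is.finite(b))) {
      stop("coefficients for ", nm, " must be finite numerics", call. = FALSE)
    }
    if (length(b) != length(design[[nm]]) + 1L) {
      stop("coefficients for ", nm, " must have length 1 (intercept) + ",
           length(design[[nm]]), " (covariates)", call. = FALSE)
    }
  }
  structure(list(beta = betas, design = design[names(betas)]),
            class = "edna_coef_params")
}

#' Baseline-site probabilities implied by covariate parameters
#'
#' The baseline site has every continuous covariate at 0 and every binary
#' covariate at its baseline level, so each probability reduces to the
#' logistic transform of its intercept.
#'
#' @param params An `edna_coef_params` object.
#' @return An `edna_params` object with the five baseline probabilities.
#' @export
baseline_params <- function(params) {
  stopifnot(inherits(params, "edna_coef_params"))
  b <- vapply(params$beta, function(x) stats::plogis(x[[1L]]), numeric(1))
  model_params(psi = b[["psi"]], theta11 = b[["theta11"]],
               theta10 = b[["theta10"]], p11 = b[["p11"]], p10 = b[["p10"]])
}

# Per-site probabilities implied by covariate params for a covariate matrix
# (sites x covariates, columns named). Returns a list of five numeric
# vectors of length nrow(X).
site_probabilities <- function(params, X) {
  stopifnot(inherits(params, "edna_coef_params"))
  out <- lapply(names(params$beta), function(nm) {
    b <- params$beta[[nm]]
    covs <- params$design[[nm]]
    eta <- rep(b[1L], nrow(X))
    if (length(covs)) {
      missing_covs <- setdiff(covs, colnames(X))
      if (length(missing_covs)) {
        stop("covariates not present in data: ",
             paste(missing_covs, collapse = ", "), call. = FALSE)
      }
      eta <- eta + as.matrix(X[, covs, drop = FALSE]) %*% b[-1L]
    }
    as.vector(stats::plogis(eta))
  })
  names(out) <- names(params$beta)
  out
}
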