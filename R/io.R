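#' Read a long-format eDNA detection CSV
#'
#' Expected dialect: UTF-8, comma-separated, header required, one row per
#' field sample. Required columns `site_id`, `sample_id`, `k_replicates`
#' and `y_positive`; optional `confirmed_present` (0/1) and
#' `inconclusive` (0/1; flagged rows - e.g. samples showing degradation
#' or PCR inhibition - are dropped with a message). Any remaining numeric
#' columns are treated as site covariates and must be constant within a
#' site.
#'
#' @param path Path to the CSV file.
#' @param covariates Optional character vector naming the covariate
#'   columns; by default every unreserved column is taken as a covariate.
#' @param quiet Suppress the dropped-row message?
#' @return An [edna_data] dataset.
#' @export
read_detection_csv <- function(path, covariates = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("site_id", "sample_id", "k_replicates", "y_positive")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if ("inconclusive" %in% names(df)) {
    drop <- df$inconclusive %in% c(1, TRUE)
    if (any(drop)) {
      if (!quiet) {
        message(sum(drop), " sample(s) flagged inconclusive removed, ",
                sum(!drop), " retained")
      }
      df <- df[!drop, , drop = FALSE]
    }
    df$inconclusive <- NULL
  }
  if (nrow(df) == 0L) stop("no samples left after filtering", call. = FALSE)
  bad <- which(df$y_positive > df$k_replicates)
  if (length(bad)) {
    stop("y_positive exceeds k_replicates at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  reserved <- c(req, "confirmed_present")
  if (is.null(covariates)) {
    covariates <- setdiff(names(df), reserved)
  } else {
    missing_covs <- setdiff(covariates, names(df))
    if (length(missing_covs)) {
      stop("covariate column(s) not in file: ",
           paste(missing_covs, collapse = ", "), call. = FALSE)
    }
  }
  samples <- data.frame(site_id = df$site_id, sample_id = df$sample_id,
                        K = df$k_replicates, y = df$y_positive,
                        stringsAsFactors = FALSE)
  site_cols <- c("confirmed_present"[("confirmed_present" %in% names(df))],
                 covariates)
  sites <- unique(cbind(data.frame(site_id = as.character(df$site_id),
                                   stringsAsFactors = FALSE),
                        df[, site_cols, drop = FALSE]))
  if (anyDuplicated(sites$site_id)) {
    stop("site-level columns (covariates / confirmed_present) vary within ",
         "a site", call. = FALSE)
  }
  edna_data(samples, sites)
}

#' Write an eDNA detection dataset to CSV
#'
#' Inverse of [read_detection_csv()]: one row per field sample with the
#' site's covariates and confirmed-presence flag repeated on each of its
#' rows. Reading the file back yields an identical dataset.
#'
#' @param data An [edna_data] dataset.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detection_csv <- function(data, path) {
  stopifnot(inherits(data, "edna_data"))
  i <- sample_site_index(data)
  df <- data.frame(site_id = data$samples$site_id,
                   sample_id = data$samples$sample_id,
                   k_replicates = data$samples$K,
                   y_positive = data$samples$y,
                   confirmed_present =
                     as.integer(data$sites$confirmed_present[i]),
                   stringsAsFactors = FALSE)
  for (cv in data$covariates) df[[cv]] <- data$sites[[cv]][i]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Standardise continuous site covariates
#'
#' Centres and scales every continuous covariate to sample mean 0 and
#' sample standard deviation 1 (the `n - 1` convention). Binary
#' covariates - columns whose values are a subset of \{0, 1\} - are left
#' untouched. The applied centres and scales are recorded in the
#' `"scaling"` attribute for back-transformation of coefficients.
#'
#' @param data An [edna_data] dataset.
#' @return The dataset with standardised covariates; attribute
#'   `"scaling"` holds a data frame with `covariate`, `center`, `scale`
#'   (binary covariates appear with center 0, scale 1).
#' @export
standardise_covariates <- function(data) {
  stopifnot(inherits(data, "edna_data"))
  rec <- data.frame(covariate = character(0), center = numeric(0),
                    scale = numeric(0), stringsAsFactors = FALSE)
  for (cv in data$covariates) {
    v <- data$sites[[cv]]
    if (all(v %in% c(0, 1))) {
      rec <- rbind(rec, data.frame(covariate = cv, center = 0, scale = 1))
      next
    }
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("covariate '", cv, "' is constant and cannot be standardised",
           call. = FALSE)
    }
    m <- mean(v)
    data$sites[[cv]] <- (v - m) / s
    rec <- rbind(rec, data.frame(covariate = cv, center = m, scale = s))
  }
  attr(data, "scaling") <- rec
  data
}

#' Write posterior results to disk
#'
#' Writes three artifacts into `dir`: `posterior_draws.csv` (one column
#' per parameter, one row per stored draw, with a `chain` column),
#' `posterior_summary.json` (posterior means and 95% credible intervals)
#' and, when available, `site_occupancy.csv` (per-site posterior
#' summaries keyed by `site_id`).
#'
#' @param fit An `edna_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "edna_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cbind(chain = fit$chain_id, as.data.frame(fit$draws)),
                   file.path(dir, "posterior_draws.csv"), row.names = FALSE)
  summ <- fit$summary
  jsonlite::write_json(
    list(model_variant = fit$model_variant,
         n_sites = fit$n_sites, n_samples = fit$n_samples,
         mcmc = unclass(fit$mcmc),
         parameters = stats::setNames(
           lapply(seq_len(nrow(summ)), function(i) {
             list(mean = summ$posterior_mean[i],
                  pci_lower = summ$pci_lower[i],
                  pci_upper = summ$pci_upper[i])
           }), summ$parameter)),
    file.path(dir, "posterior_summary.json"),
    auto_unbox = TRUE, digits = NA)
  if (!is.null(fit$site_summary)) {
    utils::write.csv(fit$site_summary,
                     file.path(dir, "site_occupancy.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read or write probability-scale parameters as flat JSON
#'
#' @param path JSON file with fields `psi`, `theta11`, `theta10`, `p11`,
#'   `p10`.
#' @return [read_params_json()]: an `edna_params` object.
#' @export
read_params_json <- function(path) {
  v <- jsonlite::fromJSON(path)
  model_params(psi = v$psi, theta11 = v$theta11, theta10 = v$theta10,
               p11 = v$p11, p10 = v$p10)
}

#' @rdname read_params_json
#' @param params An `edna_params` object.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "edna_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
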