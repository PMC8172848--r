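#' Construct an eDNA detection dataset
#'
#' The canonical container for two-stage eDNA survey data: per site, one or
#' more field samples; per field sample, the number of qPCR replicates `K`
#' run and the number `y` that amplified. Sites may carry covariates and a
#' confirmed-presence flag (a direct field observation of the species,
#' which fixes the site's latent occupancy to 1 during inference).
#'
#' @param samples Data frame with one row per field sample and columns
#'   `site_id`, `sample_id`, `K` (replicates run, >= 1) and `y` (positive
#'   replicates, `0 <= y <= K`).
#' @param sites Optional data frame with one row per site: column
#'   `site_id`, optional logical/0-1 column `confirmed_present`, and any
#'   further columns treated as site covariates. If omitted, a site table
#'   with no covariates and no confirmed presences is built from `samples`.
#'
#' @return An object of class `edna_data`: a list with elements `samples`
#'   (sample table), `sites` (site table) and `covariates` (character
#'   vector of covariate column names).
#' @examples
#' d <- edna_data(data.frame(site_id = c("a", "a", "b"),
#'                           sample_id = c(1, 2, 1),
#'                           K = 12, y = c(0, 3, 12)))
#' n_sites(d)
#' @export
edna_data <- function(samples, sites = NULL) {
  req <- c("site_id", "sample_id", "K", "y")
  if (!is.data.frame(samples) || !all(req %in% names(samples))) {
    stop("samples must be a data frame with columns site_id, sample_id, K, y",
         call. = FALSE)
  }
  if (nrow(samples) == 0L) stop("dataset has no samples", call. = FALSE)
  samples <- as.data.frame(samples)[, req]
  samples$site_id <- as.character(samples$site_id)
  if (any(!is.finite(samples$K)) || any(samples$K < 1) ||
      any(samples$K != round(samples$K))) {
    stop("K must be a positive integer for every sample", call. = FALSE)
  }
  bad_y <- !is.finite(samples$y) | samples$y < 0 | samples$y > samples$K |
    samples$y != round(samples$y)
  if (any(bad_y)) {
    stop("y must be an integer in [0, K]; offending sample row(s): ",
         paste(utils::head(which(bad_y), 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(samples$site_id, samples$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (site_id, sample_id) keys at row(s): ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "),
         call. = FALSE)
  }

  if (is.null(sites)) {
    sites <- data.frame(site_id = unique(samples$site_id),
                        confirmed_present = FALSE,
                        stringsAsFactors = FALSE)
  } else {
    if (!is.data.frame(sites) || !"site_id" %in% names(sites)) {
      stop("sites must be a data frame with a site_id column", call. = FALSE)
    }
    sites <- as.data.frame(sites)
    sites$site_id <- as.character(sites$site_id)
    if (anyDuplicated(sites$site_id)) {
      stop("duplicate site_id in site table", call. = FALSE)
    }
    if (!"confirmed_present" %in% names(sites)) {
      sites$confirmed_present <- FALSE
    }
    sites$confirmed_present <- as.logical(sites$confirmed_present)
    if (any(is.na(sites$confirmed_present))) {
      stop("confirmed_present must be logical or 0/1", call. = FALSE)
    }
    orphan <- setdiff(samples$site_id, sites$site_id)
    if (length(orphan)) {
      stop("samples reference sites missing from the site table: ",
           paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
    }
    sites <- sites[sites$site_id %in% samples$site_id, , drop = FALSE]
  }
  covariates <- setdiff(names(sites), c("site_id", "confirmed_present"))
  for (cv in covariates) {
    if (!is.numeric(sites[[cv]]) || any(!is.finite(sites[[cv]]))) {
      stop("covariate '", cv, "' must be finite numeric", call. = FALSE)
    }
  }
  # stable site order: as first encountered in the sample table
  ord <- match(unique(samples$site_id), sites$site_id)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  samples <- samples[order(match(samples$site_id, sites$site_id)), , drop = FALSE]
  rownames(samples) <- NULL

  structure(list(samples = samples, sites = sites, covariates = covariates),
            class = "edna_data")
}

#' @rdname edna_data
#' @param x An `edna_data` object.
#' @export
n_sites <- function(x) {
  stopifnot(inherits(x, "edna_data"))
  nrow(x$sites)
}

#' @rdname edna_data
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "edna_data"))
  nrow(x$samples)
}

#' @export
print.edna_data <- function(x, ...) {
  ks <- sort(unique(x$samples$K))
  cat(sprintf("eDNA detection dataset: %d sites, %d field samples, K = %s\n",
              n_sites(x), n_samples(x),
              paste(ks, collapse = "/")))
  if (length(x$covariates)) {
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  }
  nc <- sum(x$sites$confirmed_present)
  if (nc > 0) cat(sprintf("  %d site(s) with confirmed presence\n", nc))
  invisible(x)
}

# site index (1..S) for each sample row
sample_site_index <- function(data) {
  match(data$samples$site_id, data$sites$site_id)
}

# covariate matrix (S x ncov) in site-table order
covariate_matrix <- function(data) {
  as.matrix(data$sites[, data$covariates, drop = FALSE])
}
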