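#' Run the replication-design simulation grid
#'
#' The survey-design experiment: for every combination of number of sites
#' `S`, field samples per site `M` and qPCR replicates per sample `K`,
#' simulate `repeats` datasets at the generating parameters, fit the full
#' false-positive model to each, and aggregate per parameter the mean
#' bias (posterior mean minus truth, positive = over-estimation) and the
#' mean width of the 95% posterior credible interval across repeats.
#'
#' Every cell and repeat draws its seeds deterministically from
#' `base_seed` and the cell key `(S, M, K, repeat)`, so the grid can be
#' run in any order - or resumed - with identical results. With a
#' `checkpoint` file, completed cells are appended as JSON lines and
#' skipped on re-run.
#'
#' @param S_list,M_list,K_list Grid levels (numbers of sites, field
#'   samples per site, qPCR replicates per sample).
#' @param repeats Simulate-and-fit repeats per cell.
#' @param params Generating parameters ([model_params()] or
#'   [covariate_model_params()]); bias is measured against the baseline
#'   probabilities.
#' @param priors,mcmc Passed to [fit_full_model()].
#' @param base_seed Integer base seed for the whole grid.
#' @param include_covariates Simulate the decoy site covariates? (A
#'   standard-normal and a Bernoulli(0.5) covariate; they make
#'   single-sample designs identifiable.)
#' @param covariates Covariate design passed to [fit_full_model()];
#'   defaults to both simulated covariates on all five probabilities when
#'   `include_covariates` is `TRUE`, mirroring how such grids are fitted
#'   in practice.
#' @param checkpoint Optional path to a JSON-lines ledger of completed
#'   cells.
#' @param verbose Print one line per completed cell?
#' @return A data frame of class `edna_design_cells`: one row per cell
#'   with columns `S`, `M`, `K`, `repeats`, `n_failed`, and
#'   `<parameter>_bias` / `<parameter>_width` for each of `psi`,
#'   `theta11`, `theta10`, `p11`, `p10`.
#' @export
run_design_grid <- function(S_list, M_list, K_list, repeats, params,
                            priors = prior_spec(), mcmc = mcmc_control(),
                            base_seed = 1, include_covariates = TRUE,
                            covariates = NULL, checkpoint = NULL,
                            verbose = FALSE) {
  stopifnot(length(S_list) > 0, length(M_list) > 0, length(K_list) > 0,
            repeats >= 1)
  if (is.null(covariates) && include_covariates) {
    covariates <- c("cov_cont", "cov_bin")
  }
  truth <- if (inherits(params, "edna_coef_params")) {
    baseline_params(params)
  } else params
  stopifnot(inherits(truth, "edna_params"))
  prob_names <- c("psi", "theta11", "theta10", "p11", "p10")

  done <- list()
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    for (line in readLines(checkpoint, warn = FALSE)) {
      rec <- jsonlite::fromJSON(line)
      done[[cell_key(rec$S, rec$M, rec$K)]] <- as.data.frame(rec)
    }
  }

  grid <- expand.grid(K = K_list, M = M_list, S = S_list)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    S <- grid$S[i]; M <- grid$M[i]; K <- grid$K[i]
    key <- cell_key(S, M, K)
    if (!is.null(done[[key]])) {
      rows[[i]] <- done[[key]]
      next
    }
    bias <- matrix(NA_real_, repeats, 5, dimnames = list(NULL, prob_names))
    width <- bias
    n_failed <- 0L
    for (r in seq_len(repeats)) {
      res <- tryCatch({
        cfg <- sim_config(S, M, K, params,
                          include_covariates = include_covariates,
                          seed = derive_seed(base_seed, S, M, K, r))
        d <- suppressWarnings(simulate_dataset(cfg))
        fit_mcmc <- mcmc_control(n_burnin = mcmc$n_burnin,
                                 n_iter = mcmc$n_iter, thin = mcmc$thin,
                                 n_chains = mcmc$n_chains,
                                 seed = derive_seed(base_seed, S, M, K, r, 2))
        suppressWarnings(
          fit_full_model(d, priors = priors, mcmc = fit_mcmc,
                         covariates = covariates,
                         save_site_posteriors = FALSE))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_failed <- n_failed + 1L
        next
      }
      sm <- res$summary[match(prob_names, res$summary$parameter), ]
      bias[r, ] <- sm$posterior_mean - unlist(truth[prob_names])
      width[r, ] <- sm$pci_width
    }
    row <- data.frame(S = S, M = M, K = K,
                      repeats = repeats - n_failed, n_failed = n_failed)
    for (nm in prob_names) {
      row[[paste0(nm, "_bias")]] <- mean(bias[, nm], na.rm = TRUE)
      row[[paste0(nm, "_width")]] <- mean(width[, nm], na.rm = TRUE)
    }
    rows[[i]] <- row
    if (!is.null(checkpoint)) {
      cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE, digits = NA),
          "\n", sep = "", file = checkpoint, append = TRUE)
    }
    if (verbose) {
      message(sprintf("cell S=%d M=%d K=%d done (%d/%d repeats ok)",
                      S, M, K, repeats - n_failed, repeats))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("edna_design_cells", "data.frame")
  out
}

cell_key <- function(S, M, K) sprintf("S%d_M%d_K%d", S, M, K)

#' Percentage reduction in mean credible-interval width between two M levels
#'
#' How much precision is gained by collecting more field samples:
#' `100 * (width_fromM - width_toM) / width_fromM` for a chosen parameter
#' at fixed `S` and `K`. Positive values mean the interval narrowed;
#' negative values are possible if it widened.
#'
#' @param cells Output of [run_design_grid()].
#' @param parameter One of `"psi"`, `"theta11"`, `"theta10"`, `"p11"`,
#'   `"p10"`.
#' @param from_M,to_M The two field-sample levels compared.
#' @param at_S,at_K The fixed grid coordinates.
#' @return Percentage reduction (scalar).
#' @export
pci_reduction <- function(cells, parameter, from_M, to_M, at_S, at_K) {
  parameter <- match.arg(parameter,
                         c("psi", "theta11", "theta10", "p11", "p10"))
  col <- paste0(parameter, "_width")
  pick <- function(m) {
    i <- which(cells$S == at_S & cells$M == m & cells$K == at_K)
    if (length(i) != 1L) {
      stop("no unique cell with S=", at_S, ", M=", m, ", K=", at_K,
           call. = FALSE)
    }
    cells[[col]][i]
  }
  w_from <- pick(from_M)
  100 * (w_from - pick(to_M)) / w_from
}

#' Long-format bias/precision surface for one parameter
#'
#' Reshapes the design-cell table into tidy rows `(S, M, K, bias,
#' pci_width)` for a single parameter, ready for faceted plotting.
#' Lossless: the rows carry exactly the cell values for that parameter.
#'
#' @inheritParams pci_reduction
#' @return Data frame with columns `parameter`, `S`, `M`, `K`, `bias`,
#'   `pci_width`, `repeats`.
#' @export
summarize_bias_surface <- function(cells, parameter) {
  parameter <- match.arg(parameter,
                         c("psi", "theta11", "theta10", "p11", "p10"))
  if (nrow(cells) == 0L) stop("empty design-cell table", call. = FALSE)
  data.frame(parameter = parameter,
             S = cells$S, M = cells$M, K = cells$K,
             bias = cells[[paste0(parameter, "_bias")]],
             pci_width = cells[[paste0(parameter, "_width")]],
             repeats = cells$repeats, stringsAsFactors = FALSE)
}
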