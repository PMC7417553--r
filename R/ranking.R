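#' Rank algorithm configurations on simulated grid results
#'
#' Averages each configuration's score over the grid cells whose SNR falls
#' inside the selection window (the low-SNR range is where algorithms
#' actually differ; at the extremes they all collapse together), then
#' identifies the best, median and poorest performers. The median on an even
#' count is the lower-middle order statistic.
#'
#' @param grid_results data.frame with columns `config_id`, `snr_db` and
#'   `score` (one row per configuration per grid cell; extra columns such as
#'   `variant` and `seed` are allowed).
#' @param snr_window length-2 numeric, inclusive SNR range used for
#'   selection (default `c(-20, 0)`).
#' @param better `"higher"` for accuracy-like scores, `"lower"` for
#'   error-like scores.
#' @return object of class `ranking_report` with the per-config mean table
#'   and the three selections.
#' @export
rank_algorithms <- function(grid_results, snr_window = c(-20, 0),
                            better = c("higher", "lower")) {
  better <- match.arg(better)
  stopifnot(is.data.frame(grid_results),
            all(c("config_id", "snr_db", "score") %in% names(grid_results)))
  inside <- grid_results$snr_db >= snr_window[1L] &
    grid_results$snr_db <= snr_window[2L]
  if (!any(inside)) stop("no grid cells inside the SNR window")
  sub <- grid_results[inside, , drop = FALSE]
  if (length(unique(sub$config_id)) < 1L) stop("no configurations scored")
  means <- tapply(sub$score, sub$config_id, mean)
  tab <- data.frame(config_id = names(means), mean_score = as.numeric(means),
                    stringsAsFactors = FALSE)
  # ascending by quality, so the selection rules read off order statistics
  ord <- order(if (better == "higher") tab$mean_score else -tab$mean_score)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  m <- nrow(tab)
  structure(
    list(table = tab,
         best = tab$config_id[m],
         median = tab$config_id[floor((m + 1) / 2)],
         poorest = tab$config_id[1L],
         snr_window = snr_window, better = better,
         transfer = NULL),
    class = "ranking_report"
  )
}

#' Validate a simulated-data ranking on target data
#'
#' Runs the outer CV for the selected best / median / poorest
#' configurations on the target dataset and checks whether their weak order
#' is preserved (best >= median >= poorest for accuracy-like scores, the
#' reverse for error-like). Pairwise sign-flip permutation p-values across
#' the paired replications are attached.
#'
#' @param report a [rank_algorithms()] report with selections.
#' @param target_dataset the dataset to transfer to.
#' @param reg registry holding the selected configurations.
#' @param task,cv,integration,imputation,inner_folds,n_opt_iters passed to
#'   [outer_cv()].
#' @return the report with a `transfer` element: target means, the
#'   `ranking_preserved` flag and pairwise p-values.
#' @export
validate_ranking <- function(report, target_dataset, reg = NULL,
                             task = c("classification", "regression"),
                             cv = outer_cv_spec(),
                             integration = "mean", imputation = "median",
                             inner_folds = 3L, n_opt_iters = 25L) {
  task <- match.arg(task)
  if (!inherits(report, "ranking_report") || is.null(report$best) ||
      is.null(report$median) || is.null(report$poorest)) {
    stop("report lacks best/median/poorest selections; run rank_algorithms first")
  }
  if (is.null(reg)) reg <- registry(task)
  picks <- c(best = report$best, median = report$median,
             poorest = report$poorest)
  results <- lapply(picks, function(id) {
    if (!id %in% names(reg)) stop("config '", id, "' not in registry")
    outer_cv(target_dataset, reg[[id]], task = task, cv = cv,
             integration = integration, imputation = imputation,
             inner_folds = inner_folds, n_opt_iters = n_opt_iters)
  })
  means <- vapply(results, function(r) r$summary$mean, numeric(1))
  preserved <- if (report$better == "higher") {
    means[["best"]] >= means[["median"]] &&
      means[["median"]] >= means[["poorest"]]
  } else {
    means[["best"]] <= means[["median"]] &&
      means[["median"]] <= means[["poorest"]]
  }
  pvals <- c(
    best_vs_median = compare_algorithms(results$best$scores,
                                        results$median$scores,
                                        seed = cv$seed),
    median_vs_poorest = compare_algorithms(results$median$scores,
                                           results$poorest$scores,
                                           seed = cv$seed + 1L),
    best_vs_poorest = compare_algorithms(results$best$scores,
                                         results$poorest$scores,
                                         seed = cv$seed + 2L)
  )
  report$transfer <- list(means = means, ranking_preserved = preserved,
                          p_values = pvals, results = results)
  report
}

#' @export
print.ranking_report <- function(x, ...) {
  cat("ranking_report over SNR window [", x$snr_window[1L], ",",
      x$snr_window[2L], "]\n")
  cat("  best:   ", x$best, "\n  median: ", x$median,
      "\n  poorest:", x$poorest, "\n")
  if (!is.null(x$transfer)) {
    m <- x$transfer$means
    cat(sprintf("  transfer means: best %.3f, median %.3f, poorest %.3f\n",
                m[["best"]], m[["median"]], m[["poorest"]]))
    cat("  ranking preserved:", x$transfer$ranking_preserved, "\n")
  }
  invisible(x)
}
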