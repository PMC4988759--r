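#' Score differential expression calls against the simulated truth
#'
#' @param calls logical vector of DE calls.
#' @param truth logical vector of true DE status, same length.
#' @return list with `fdr` (`FP / (TP + FP)`, `NA` when nothing is
#'   called) and `tpr` (`TP / sum(truth)`, `NA` when there are no true
#'   positives to find).
#' @export
score_de_calls <- function(calls, truth) {
  if (length(calls) != length(truth))
    stop("'calls' and 'truth' must have the same length")
  calls <- as.logical(calls); truth <- as.logical(truth)
  tp <- sum(calls & truth)
  fp <- sum(calls & !truth)
  list(fdr = if (tp + fp == 0) NA_real_ else fp / (tp + fp),
       tpr = if (sum(truth) == 0) NA_real_ else tp / sum(truth))
}

#' Monte-Carlo benchmark over simulation scenarios
#'
#' For each scenario and replicate: generate a dataset
#' ([generate_dataset()] with seed `seed + replicate`), normalize, run
#' [lpe_test()], and score against the truth. Rates are aggregated as
#' mean and standard deviation in percent; replicates with no calls have
#' undefined FDR and are excluded from the FDR mean (their count is
#' reported).
#'
#' Replicate-level seeding means any single cell of the report can be
#' reproduced in isolation by re-running its scenario with the same
#' `seed`.
#'
#' @param scenarios a [simulation_scenario()] or list of them.
#' @param n_reps Monte-Carlo replicates per scenario; default `NULL` uses
#'   each scenario's own `n_reps`.
#' @param seed integer base seed.
#' @param alpha,n_bins,outlier_threshold,tau,outlier_method passed to
#'   [lpe_test()].
#' @param pseudocount,scale passed to [normalize_log2()]; the default
#'   `scale = "common"` reflects that simulated libraries are
#'   depth-matched by construction.
#' @param verbose print one line per scenario.
#' @return Data frame with one row per scenario: `delta`, `phi`, `n_de`,
#'   `m_per_class`, `n_reps`, `mean_fdr`, `sd_fdr`, `mean_tpr`, `sd_tpr`,
#'   `n_missing_fdr` (rates in percent). Per-replicate values are in
#'   `attr(x, "details")`.
#' @export
run_benchmark_grid <- function(scenarios, n_reps = NULL, seed = 1,
                               alpha = 0.05, n_bins = 100,
                               outlier_threshold = 1.2, tau = "auto",
                               outlier_method = "adaptive",
                               pseudocount = 0.5, scale = "common",
                               verbose = FALSE) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) >= 1,
            all(vapply(scenarios, inherits, logical(1), "sim_scenario")))
  rows <- vector("list", length(scenarios))
  details <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    reps <- if (is.null(n_reps)) sc$n_reps else as.integer(n_reps)
    fdr <- tpr <- numeric(reps)
    for (r in seq_len(reps)) {
      ds <- generate_dataset(sc, seed = seed + r)
      ln <- normalize_log2(ds$counts, pseudocount = pseudocount,
                           scale = scale)
      res <- lpe_test(ln, n_bins = n_bins,
                      outlier_threshold = outlier_threshold, tau = tau,
                      alpha = alpha, outlier_method = outlier_method)
      s <- score_de_calls(res$is_de, ds$de_truth)
      fdr[r] <- s$fdr; tpr[r] <- s$tpr
    }
    rows[[i]] <- data.frame(
      delta = sc$delta, phi = sc$phi, n_de = sc$n_de,
      m_per_class = sc$m_per_class, n_reps = reps,
      mean_fdr = 100 * mean(fdr, na.rm = TRUE),
      sd_fdr = 100 * stats::sd(fdr, na.rm = TRUE),
      mean_tpr = 100 * mean(tpr, na.rm = TRUE),
      sd_tpr = 100 * stats::sd(tpr, na.rm = TRUE),
      n_missing_fdr = sum(is.na(fdr)))
    details[[i]] <- data.frame(scenario = i, rep = seq_len(reps),
                               fdr = fdr, tpr = tpr)
    if (verbose)
      message(sprintf(
        "scenario %d/%d (delta=%g phi=%g n_de=%d m=%d): FDR %.2f%% TPR %.2f%%",
        i, length(scenarios), sc$delta, sc$phi, sc$n_de, sc$m_per_class,
        rows[[i]]$mean_fdr, rows[[i]]$mean_tpr))
  }
  out <- do.call(rbind, rows)
  attr(out, "details") <- do.call(rbind, details)
  out
}

#' Format a benchmark cell as "mean (sd)"
#'
#' @param mean,sd values in percent.
#' @param digits decimal places (default 2).
#' @return Character, `"NA"` when the mean is undefined.
#' @export
format_rate <- function(mean, sd, digits = 2) {
  ifelse(is.nan(mean) | is.na(mean), "NA",
         sprintf(paste0("%.", digits, "f (%.", digits, "f)"), mean, sd))
}
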