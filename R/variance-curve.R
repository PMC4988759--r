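#' Mean/difference (A/M) decomposition of two samples
#'
#' For every gene, computes the mean log2 intensity
#' \eqn{A = (v_a + v_b)/2} and the signed log2 difference
#' \eqn{M = v_a - v_b} of two samples. The variance machinery only uses
#' `m` through its (sign-invariant) spread.
#'
#' @param lognorm a [normalize_log2()] result.
#' @param sample_a,sample_b sample IDs present in `lognorm`.
#' @return An object of class `"am_pairs"`: list with `gene_ids`, `a`, `m`
#'   and `samples` (the pair that produced each value).
#' @export
compute_am_pairs <- function(lognorm, sample_a, sample_b) {
  stopifnot(inherits(lognorm, "lognorm_matrix"))
  v <- lognorm$values
  for (s in c(sample_a, sample_b))
    if (!s %in% colnames(v)) stop("unknown sample ID: ", s)
  structure(list(gene_ids = rownames(v),
                 a = (v[, sample_a] + v[, sample_b]) / 2,
                 m = v[, sample_a] - v[, sample_b],
                 samples = c(sample_a, sample_b)),
            class = "am_pairs")
}

#' Equal-frequency (quantile) binning of mean intensities
#'
#' Partitions genes into bins holding (as nearly as possible) the same
#' number of genes, by slicing the rank order of `a_values`; bin boundaries
#' are therefore sample quantiles and bin widths vary with the local
#' density of intensities. Ties share a rank and always land in the same
#' bin, so heavily tied data (e.g. the zero-count pile) may yield fewer,
#' larger bins.
#'
#' If there are fewer than `2 * n_bins` values, the number of bins is
#' reduced to `floor(n/2)` so each bin can still hold two genes.
#'
#' @param a_values numeric vector of mean log2 intensities.
#' @param n_bins target number of bins (default 100).
#' @return list with `bin` (integer bin index per gene, some indices may
#'   be unused when ties collapse bins), `edges` (upper quantile edge per
#'   bin) and `n_bins` (the value actually used).
#' @export
assign_quantile_bins <- function(a_values, n_bins = 100) {
  n <- length(a_values)
  if (length(unique(a_values)) < 2)
    stop("need at least 2 distinct intensity values to bin")
  if (!is.numeric(n_bins) || n_bins < 2) stop("'n_bins' must be >= 2")
  n_bins <- as.integer(min(n_bins, max(2L, floor(n / 2))))
  r <- rank(a_values, ties.method = "min")
  bin <- as.integer(ceiling(r * n_bins / n))
  edges <- stats::quantile(a_values, probs = seq_len(n_bins) / n_bins,
                           type = 1, names = FALSE)
  list(bin = bin, edges = edges, n_bins = n_bins)
}

#' Unbiased variance of the log2 differences in one bin
#'
#' The pooled error estimate for a bin is the sample variance of its `M`
#' values, with the usual \eqn{n - 1} denominator.
#'
#' @param m_values_in_bin numeric vector of M values.
#' @return The sample variance, or `NA_real_` for bins with fewer than two
#'   values (such bins are excluded from curve fitting).
#' @export
bin_variance <- function(m_values_in_bin) {
  if (length(m_values_in_bin) < 2) return(NA_real_)
  stats::var(m_values_in_bin)
}

#' Flag outlying genes by absolute log2 fold difference
#'
#' The simple labelling rule for the non-replicated design: a gene is an
#' outlier when the absolute log2 difference between the two classes
#' exceeds the threshold (strictly). Such genes are candidate differential
#' transcripts and are excluded from baseline variance estimation.
#'
#' @param am an [compute_am_pairs()] result.
#' @param threshold positive cut-off on `|m|` in log2 units; default 1.2.
#' @return An object of class `"outlier_flags"`: list with `gene_ids`,
#'   logical `is_outlier`, and `threshold`.
#' @export
flag_outliers <- function(am, threshold = 1.2) {
  stopifnot(inherits(am, "am_pairs"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("'threshold' must be a single positive number")
  structure(list(gene_ids = am$gene_ids,
                 is_outlier = abs(am$m) > threshold,
                 threshold = threshold),
            class = "outlier_flags")
}

# Adaptive outlier labelling for cross-class pseudo-replicates.
#
# Two components, both expressed on the M scale:
#   * a hard global cut |M - median(M)| > hard_threshold removes unambiguous
#     differential spikes (tens-fold changes) regardless of how densely they
#     pack into an intensity bin -- within-bin statistics are powerless when
#     differential genes are the local majority;
#   * an iterated per-bin fence at (0.6745 + 1.349 * D) sigma-units, the
#     normal-equivalent width of the Tukey fence [Q1 - D*IQR, Q3 + D*IQR],
#     using the MAD as scale. Quantile-based scales barely move when tails
#     are deleted, so the iteration converges instead of ratcheting the
#     variance downwards. Bins whose MAD degenerates to zero (discrete
#     low-count data) are left untouched.
adaptive_outliers <- function(a, m, bin, threshold = 1.2, hard_threshold = 5,
                              max_iter = 10L) {
  ctr <- stats::median(m)
  out <- abs(m - ctr) > hard_threshold
  k <- 0.6745 + 1.349 * threshold
  groups <- split(seq_along(m), bin)
  for (it in seq_len(max_iter)) {
    new <- out
    for (b in groups) {
      mb <- m[b][!out[b]]
      if (length(mb) < 5) next
      md <- stats::median(mb)
      s <- 1.4826 * stats::median(abs(mb - md))
      if (s > 0) new[b] <- new[b] | abs(m[b] - md) > k * s
    }
    if (identical(new, out)) break
    out <- new
  }
  out
}

#' Fit a local-pooled-error variance curve
#'
#' Bins the A values ([assign_quantile_bins()]), computes the unbiased
#' variance of M within each bin ([bin_variance()]) after dropping flagged
#' outliers, and fits a cubic smoothing spline (smoothing chosen by
#' generalized cross-validation unless `spar` is given) through the
#' per-bin points (median A, var(M)/2). The division by two converts the
#' spread of a *difference* of two replicates into the error variance of a
#' single measurement, since \eqn{Var(v_1 - v_2) = 2\sigma^2} for iid
#' replicates.
#'
#' Evaluation of the fitted curve (via [predict.variance_curve()]) clamps
#' the argument to the observed range of bin medians (constant
#' extrapolation), optionally enforces a non-increasing shape in A
#' (`monotone = TRUE`, the default: on the log2 scale, count noise
#' \eqn{\approx (1/\mu + \phi)/\ln(2)^2} decreases with abundance, and the
#' zero-count pile would otherwise report a spurious zero variance), and
#' floors the result at `variance_floor`.
#'
#' @param am an [compute_am_pairs()] result, or any list with numeric
#'   vectors `a` and `m` of equal length.
#' @param n_bins target number of intensity bins (default 100).
#' @param flags optional [flag_outliers()] result (or logical vector);
#'   flagged genes are excluded from variance estimation (they are still
#'   testable downstream).
#' @param variance_floor positive lower bound for evaluated variances.
#' @param monotone enforce a non-increasing variance-vs-intensity shape.
#' @param spar optional smoothing parameter passed to
#'   [stats::smooth.spline()]; default `NULL` selects by GCV.
#' @return An object of class `"variance_curve"`: list with `bin_stats`
#'   (data frame: bin, a_median, variance (= var(M), the raw bin value),
#'   n, n_removed), `fit` (the smoothing spline), `a_range`,
#'   `variance_floor`, `monotone`, `n_bins`.
#' @export
fit_variance_curve <- function(am, n_bins = 100, flags = NULL,
                               variance_floor = 1e-8, monotone = TRUE,
                               spar = NULL) {
  a <- am$a; m <- am$m
  stopifnot(length(a) == length(m), all(is.finite(a)), all(is.finite(m)))
  drop <- rep(FALSE, length(a))
  if (!is.null(flags)) {
    drop <- if (inherits(flags, "outlier_flags")) flags$is_outlier else as.logical(flags)
    stopifnot(length(drop) == length(a))
  }
  bins <- assign_quantile_bins(a, n_bins)
  keep <- !drop
  fb <- factor(bins$bin[keep], levels = sort(unique(bins$bin)))
  a_med <- tapply(a[keep], fb, stats::median)
  v <- tapply(m[keep], fb, bin_variance)
  n_kept <- tapply(rep(1L, sum(keep)), fb, sum)
  n_all <- tabulate(factor(bins$bin, levels = levels(fb)))
  ok <- !is.na(v) & !is.na(a_med)
  bin_stats <- data.frame(bin = as.integer(levels(fb)),
                          a_median = as.numeric(a_med),
                          variance = as.numeric(v),
                          n = as.integer(ifelse(is.na(n_kept), 0L, n_kept)),
                          n_removed = as.integer(n_all - ifelse(is.na(n_kept), 0L, n_kept)))
  x <- a_med[ok]; y <- v[ok] / 2
  if (length(unique(x)) < 4)
    stop("too few usable intensity bins (", sum(ok),
         ") for spline fitting; reduce 'n_bins'")
  fit <- if (diff(range(y)) < .Machine$double.eps^0.5) {
    # degenerate: constant variance
    list(constant = max(mean(y), 0))
  } else if (is.null(spar)) {
    suppressWarnings(stats::smooth.spline(x, y))
  } else {
    suppressWarnings(stats::smooth.spline(x, y, spar = spar))
  }
  # bake the evaluable curve onto a dense grid at fit time, so the
  # monotone transform and floor are properties of the curve itself and
  # evaluation is independent of the set of points requested
  grid_a <- seq(min(x), max(x), length.out = 512L)
  grid_v <- if (!is.null(fit$constant)) rep(fit$constant, 512L)
            else stats::predict(fit, grid_a)$y
  if (isTRUE(monotone)) grid_v <- rev(cummax(rev(grid_v)))
  grid_v <- pmax(grid_v, variance_floor)
  structure(list(bin_stats = bin_stats, fit = fit,
                 grid_a = grid_a, grid_v = grid_v,
                 a_range = range(x), variance_floor = variance_floor,
                 monotone = monotone, n_bins = bins$n_bins),
            class = "variance_curve")
}

#' Evaluate a fitted variance curve
#'
#' Returns the per-observation error variance at the given mean log2
#' intensities. Arguments outside the fitted range get the boundary value;
#' results are floored at the curve's `variance_floor`.
#'
#' @param object a [fit_variance_curve()] result.
#' @param a numeric vector of mean log2 intensities.
#' @param ... unused.
#' @return Numeric vector of variances, all `>= variance_floor`.
#' @export
predict.variance_curve <- function(object, a, ...) {
  stats::approx(object$grid_a, object$grid_v,
                xout = pmin(pmax(a, object$a_range[1]), object$a_range[2]),
                rule = 2)$y
}

#' @export
print.variance_curve <- function(x, ...) {
  cat(sprintf("variance_curve: %d bins over A in [%.2f, %.2f]%s\n",
              nrow(x$bin_stats), x$a_range[1], x$a_range[2],
              if (x$monotone) ", monotone non-increasing" else ""))
  invisible(x)
}

#' Baseline variance curve from within-class replicates
#'
#' Computes A/M values for every unordered pair of replicates within one
#' class, pools all pairs into a single cloud, and fits the variance curve.
#' No outlier removal is applied: within-class pairs carry no differential
#' signal. The curve stores per-observation variance (var(M)/2).
#'
#' @param lognorm a [normalize_log2()] result.
#' @param class_name class whose replicates to use.
#' @param n_bins number of intensity bins.
#' @param ... passed to [fit_variance_curve()].
#' @return A `"variance_curve"`.
#' @export
estimate_replicated <- function(lognorm, class_name, n_bins = 100, ...) {
  stopifnot(inherits(lognorm, "lognorm_matrix"))
  samples <- names(lognorm$class_labels)[lognorm$class_labels == class_name]
  if (length(samples) < 2)
    stop("class '", class_name, "' has ", length(samples),
         " replicate(s); use the non-replicated path (estimate_nonreplicated)")
  pairs <- utils::combn(samples, 2)
  a <- m <- numeric(0)
  for (j in seq_len(ncol(pairs))) {
    p <- compute_am_pairs(lognorm, pairs[1, j], pairs[2, j])
    a <- c(a, p$a); m <- c(m, p$m)
  }
  fit_variance_curve(list(a = a, m = m), n_bins = n_bins, ...)
}

#' Baseline variance curve from two non-replicated samples
#'
#' For the design with exactly one sample in each class, the two
#' cross-class samples are treated as pseudo-replicates. Because genuinely
#' differential transcripts then masquerade as error, outliers are labelled
#' and removed before the bin variances are evaluated.
#'
#' Two labelling strategies are available. `"adaptive"` (default) combines
#' a hard global cut at `hard_threshold` log2 units with an iterated
#' per-bin MAD fence whose width is the normal-equivalent of the Tukey
#' fence `Q3 + threshold * IQR`; it adapts to intensity-dependent spread
#' and resists bins dominated by differential transcripts. `"fold"` is the
#' plain global rule `|M| > threshold` (see [flag_outliers()]).
#'
#' @param lognorm a [normalize_log2()] result with exactly one sample in
#'   each of two classes (otherwise use [estimate_replicated()]).
#' @param n_bins number of intensity bins.
#' @param threshold fence parameter `D` (default 1.2): IQR multiplier for
#'   `"adaptive"`, absolute log2 cut-off for `"fold"`.
#' @param outlier_method `"adaptive"` or `"fold"`.
#' @param hard_threshold absolute log2 cut for the global component of the
#'   adaptive rule (default 5, i.e. 32-fold).
#' @param ... passed to [fit_variance_curve()].
#' @return A `"variance_curve"` with an extra attribute `"outliers"`
#'   (logical vector of removed genes).
#' @export
estimate_nonreplicated <- function(lognorm, n_bins = 100, threshold = 1.2,
                                   outlier_method = c("adaptive", "fold"),
                                   hard_threshold = 5, ...) {
  stopifnot(inherits(lognorm, "lognorm_matrix"))
  outlier_method <- match.arg(outlier_method)
  labs <- lognorm$class_labels
  classes <- unique(labs)
  if (length(classes) != 2)
    stop("expected exactly two classes, got ", length(classes))
  counts <- table(labs)
  if (any(counts != 1))
    stop("class(es) ", paste(names(counts)[counts != 1], collapse = ", "),
         " have replicates; use the replicated path (estimate_replicated)")
  am <- compute_am_pairs(lognorm,
                         names(labs)[labs == classes[1]],
                         names(labs)[labs == classes[2]])
  out <- if (outlier_method == "fold") {
    flag_outliers(am, threshold)$is_outlier
  } else {
    bins <- assign_quantile_bins(am$a, n_bins)
    adaptive_outliers(am$a, am$m, bins$bin, threshold, hard_threshold)
  }
  curve <- fit_variance_curve(am, n_bins = n_bins, flags = out, ...)
  attr(curve, "outliers") <- stats::setNames(out, am$gene_ids)
  curve
}
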