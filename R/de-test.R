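# Variance inflation of the sample median of n iid normals, n * Var(med_n).
# Odd n: exact (numerical integration of the order-statistic density,
# rel.tol 1e-12); even n: the median is the mean of the two central order
# statistics (2e6-draw Monte Carlo, n = 2 exact). Tends to pi/2 as n grows.
MEDIAN_VAR_INFLATION <- c(1, 1, 1.3460, 1.1924, 1.4342,
                          1.2911, 1.4731, 1.3444, 1.4949, 1.3845)

#' Variance inflation factor of the median
#'
#' The scaling factor \eqn{\tau} converts a per-observation error variance
#' into the sampling variance of a class *median*:
#' \eqn{Var(med_n) = \tau(n)\,\sigma^2/n}. For a single observation the
#' median is that observation (\eqn{\tau = 1}); asymptotically
#' \eqn{\tau \to \pi/2}.
#'
#' @param n number of replicates (positive integer).
#' @return The inflation factor.
#' @export
median_tau <- function(n) {
  stopifnot(is.numeric(n), n >= 1)
  ifelse(n <= length(MEDIAN_VAR_INFLATION),
         MEDIAN_VAR_INFLATION[pmax(1, round(n))], pi / 2)
}

#' Pooled variance of a two-class median difference
#'
#' \deqn{\sigma^2_{pooled} = \tau\left(\frac{\sigma^2_X}{n_X} +
#'   \frac{\sigma^2_Y}{n_Y}\right)}
#' floored at `variance_floor`. `tau` may have length 2, in which case the
#' two terms are scaled separately (used with the per-class
#' [median_tau()] factors).
#'
#' @param var_x,var_y non-negative per-observation variances.
#' @param n_x,n_y replicate counts (>= 1).
#' @param tau scaling factor(s), length 1 or 2.
#' @param variance_floor positive lower bound of the result.
#' @return Numeric vector of pooled variances.
#' @examples
#' pooled_variance(1, 1, 1, 1, tau = pi / 2)  # pi
#' pooled_variance(2, 4, 2, 2, tau = 1)       # 3
#' @export
pooled_variance <- function(var_x, var_y, n_x, n_y, tau = 1,
                            variance_floor = 1e-8) {
  stopifnot(all(var_x >= 0), all(var_y >= 0), n_x >= 1, n_y >= 1,
            all(tau > 0), length(tau) %in% c(1, 2))
  tx <- tau[1]; ty <- tau[length(tau)]
  pmax(tx * var_x / n_x + ty * var_y / n_y, variance_floor)
}

#' Z statistic for a two-class median difference
#'
#' @param median_x,median_y per-class medians of the log2 values.
#' @param pooled_var positive pooled variance from [pooled_variance()].
#' @return `(median_x - median_y) / sqrt(pooled_var)`.
#' @export
z_statistic <- function(median_x, median_y, pooled_var) {
  stopifnot(all(pooled_var > 0))
  (median_x - median_y) / sqrt(pooled_var)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()] after validating the
#' input range).
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

row_medians <- function(v) {
  n <- ncol(v)
  if (n == 1) return(v[, 1])
  if (n == 2) return((v[, 1] + v[, 2]) / 2)
  if (n == 3) return(v[, 1] + v[, 2] + v[, 3] -
                       pmax(v[, 1], v[, 2], v[, 3]) -
                       pmin(v[, 1], v[, 2], v[, 3]))
  apply(v, 1, stats::median)
}

#' Local-pooled-error differential expression test
#'
#' Tests every gene for differential abundance between the two classes of
#' `lognorm`. The error variance of each gene is read off an
#' intensity-dependent variance curve rather than estimated from the
#' gene's own observations, which is what makes the test usable with one,
#' two or three replicates per class:
#'
#' * both classes replicated: one curve per class from all within-class
#'   replicate pairs ([estimate_replicated()]), evaluated at the class
#'   mean intensity of the gene;
#' * both classes singletons: a single curve from the cross-class pair
#'   with outlier removal ([estimate_nonreplicated()]), evaluated at the
#'   gene's overall mean intensity and used for both classes;
#' * mixed: the replicated class uses its own within-class curve; the
#'   singleton class uses a cross-class curve pooled over its pairings
#'   with the other class's replicates (outlier-pruned), evaluated at the
#'   singleton's own value.
#'
#' The statistic is `z = (med_X - med_Y) / sqrt(pooled)` with
#' `pooled = tau_X var_X/n_X + tau_Y var_Y/n_Y`, referred to the standard
#' normal (two-sided), followed by Benjamini-Hochberg adjustment; genes
#' with adjusted p below `alpha` are called differential.
#'
#' @param lognorm a [normalize_log2()] result with exactly two classes.
#' @param n_bins intensity bins for the variance curves (default 100).
#' @param outlier_threshold fence parameter D for the non-replicated
#'   curve (default 1.2).
#' @param tau `"auto"` (default) uses the exact median variance-inflation
#'   factor for each class size ([median_tau()]); a numeric value is used
#'   for both classes as in the classical formulation (e.g. `pi/2`).
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @param variance_floor lower bound for variances (default 1e-8).
#' @param outlier_method `"adaptive"` (default) or `"fold"`; see
#'   [estimate_nonreplicated()].
#' @param ... further arguments for [fit_variance_curve()] (e.g.
#'   `monotone`, `spar`).
#' @return A data frame of class `"lpe_de"` with columns `gene_id`,
#'   `median_x`, `median_y`, `var_x`, `var_y`, `z`, `p_value`,
#'   `adj_p_value`, `is_de`, and attributes `classes`, `n_x`, `n_y`,
#'   `tau`, `alpha`, `path` (`"replicated"`, `"nonreplicated"` or
#'   `"mixed"`).
#' @export
lpe_test <- function(lognorm, n_bins = 100, outlier_threshold = 1.2,
                     tau = "auto", alpha = 0.05, variance_floor = 1e-8,
                     outlier_method = c("adaptive", "fold"), ...) {
  stopifnot(inherits(lognorm, "lognorm_matrix"))
  outlier_method <- match.arg(outlier_method)
  labs <- lognorm$class_labels
  classes <- unique(labs)
  if (length(classes) != 2)
    stop("lpe_test needs exactly two classes, got ", length(classes))
  sx <- names(labs)[labs == classes[1]]
  sy <- names(labs)[labs == classes[2]]
  nx <- length(sx); ny <- length(sy)
  vx_mat <- lognorm$values[, sx, drop = FALSE]
  vy_mat <- lognorm$values[, sy, drop = FALSE]
  med_x <- row_medians(vx_mat)
  med_y <- row_medians(vy_mat)

  taus <- if (identical(tau, "auto")) {
    c(median_tau(nx), median_tau(ny))
  } else {
    stopifnot(is.numeric(tau), all(tau > 0))
    rep(as.numeric(tau), length.out = 2)
  }

  if (nx >= 2 && ny >= 2) {
    path <- "replicated"
    cx <- estimate_replicated(lognorm, classes[1], n_bins,
                              variance_floor = variance_floor, ...)
    cy <- estimate_replicated(lognorm, classes[2], n_bins,
                              variance_floor = variance_floor, ...)
    var_x <- predict(cx, rowMeans(vx_mat))
    var_y <- predict(cy, rowMeans(vy_mat))
  } else if (nx == 1 && ny == 1) {
    path <- "nonreplicated"
    cv <- estimate_nonreplicated(lognorm, n_bins, outlier_threshold,
                                 outlier_method,
                                 variance_floor = variance_floor, ...)
    a <- (vx_mat[, 1] + vy_mat[, 1]) / 2
    var_x <- var_y <- predict(cv, a)
  } else {
    path <- "mixed"
    if (nx == 1) {
      crep <- estimate_replicated(lognorm, classes[2], n_bins,
                                  variance_floor = variance_floor, ...)
      var_y <- predict(crep, rowMeans(vy_mat))
      var_x <- predict(cross_curve(lognorm, sx, sy, n_bins,
                                   outlier_threshold, outlier_method,
                                   variance_floor = variance_floor, ...),
                       vx_mat[, 1])
    } else {
      crep <- estimate_replicated(lognorm, classes[1], n_bins,
                                  variance_floor = variance_floor, ...)
      var_x <- predict(crep, rowMeans(vx_mat))
      var_y <- predict(cross_curve(lognorm, sy, sx, n_bins,
                                   outlier_threshold, outlier_method,
                                   variance_floor = variance_floor, ...),
                       vy_mat[, 1])
    }
  }

  pooled <- pooled_variance(var_x, var_y, nx, ny, taus, variance_floor)
  z <- z_statistic(med_x, med_y, pooled)
  p <- 2 * stats::pnorm(-abs(z))
  adj <- bh_adjust(p)
  res <- data.frame(gene_id = rownames(lognorm$values),
                    median_x = med_x, median_y = med_y,
                    var_x = var_x, var_y = var_y,
                    z = z, p_value = p, adj_p_value = adj,
                    is_de = adj < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, classes = classes, n_x = nx, n_y = ny, tau = taus,
            alpha = alpha, path = path,
            class = c("lpe_de", class(res)))
}

# variance curve for a singleton sample in a mixed design: pool its A/M
# pairs against every replicate of the other class, prune outliers, fit.
cross_curve <- function(lognorm, singleton, others, n_bins, threshold,
                        outlier_method, ...) {
  a <- m <- numeric(0)
  for (s in others) {
    p <- compute_am_pairs(lognorm, singleton, s)
    a <- c(a, p$a); m <- c(m, p$m)
  }
  bins <- assign_quantile_bins(a, n_bins)
  out <- if (outlier_method == "fold") abs(m) > threshold
         else adaptive_outliers(a, m, bins$bin, threshold)
  fit_variance_curve(list(a = a, m = m), n_bins = n_bins, flags = out, ...)
}
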