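#' Log2 relative-abundance transformation of raw counts
#'
#' Converts raw counts to the log2 scale on which all local-pooled-error
#' computation happens: each count (plus a pseudocount) is divided by a
#' library-size denominator and log2-transformed,
#' \deqn{v_{ij} = \log_2\big((c_{ij} + p)/T_j\big).}
#'
#' With `scale = "sample"` (the default) the denominator \eqn{T_j} is the
#' sample's own total count, i.e. the classical total-count relative
#' abundance. With `scale = "common"` a single shared denominator (the mean
#' of the sample totals) is used; this keeps samples on a comparable scale
#' without re-weighting them individually and is appropriate when libraries
#' are depth-matched by construction (e.g. simulated data), where per-sample
#' totals would import composition bias from strong asymmetric signal.
#'
#' The pseudocount is added to the numerator only; the denominator is the
#' total of the raw counts, so with `pseudocount = 0` the transform is
#' exactly the log2 proportion (and requires strictly positive counts).
#'
#' @param x a [count_matrix()].
#' @param pseudocount non-negative value added to every count before the
#'   ratio is taken; default 0.5. Must be positive if any count is zero.
#' @param scale `"sample"` for per-sample totals, `"common"` for one shared
#'   denominator.
#' @return An object of class `"lognorm_matrix"`: list with `values`
#'   (numeric matrix, same dimnames as the counts), `class_labels`,
#'   `pseudocount`, `scale` and `lib_sizes`.
#' @examples
#' m <- matrix(c(0L, 3L), nrow = 2, dimnames = list(c("g1", "g2"), "s1"))
#' ln <- normalize_log2(count_matrix(m, c(s1 = "A")))
#' ln$values  # log2(0.5/3), log2(3.5/3)
#' @export
normalize_log2 <- function(x, pseudocount = 0.5,
                           scale = c("sample", "common")) {
  stopifnot(inherits(x, "count_matrix"))
  scale <- match.arg(scale)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0)
    stop("'pseudocount' must be a single non-negative number")
  counts <- x$counts
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  if (pseudocount == 0 && any(counts == 0))
    stop("pseudocount 0 requires strictly positive counts")
  denom <- if (scale == "sample") totals else rep(mean(totals), ncol(counts))
  values <- log2(sweep(counts + pseudocount, 2, denom, "/"))
  structure(list(values = values, class_labels = x$class_labels,
                 pseudocount = pseudocount, scale = scale,
                 lib_sizes = totals),
            class = "lognorm_matrix")
}

#' @export
print.lognorm_matrix <- function(x, ...) {
  cat(sprintf("lognorm_matrix: %d genes x %d samples (pseudocount %g, %s scaling)\n",
              nrow(x$values), ncol(x$values), x$pseudocount, x$scale))
  invisible(x)
}
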