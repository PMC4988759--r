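#' Define a two-class count simulation scenario
#'
#' Describes a synthetic transcriptome: a low-expression background of
#' zero-inflated Poisson (ZIP) transcripts and a signal fraction of
#' negative binomial transcripts whose means come from a long-tailed pool.
#' Differential transcripts are drawn from *all* transcripts and get the
#' effect size `delta` added to their mean in class Y.
#'
#' @param n_transcripts total transcripts (default 20000).
#' @param background_fraction fraction of ZIP background transcripts
#'   (default 0.7).
#' @param zip_lambda Poisson component mean of the background (default 1.25).
#' @param zip_zero_prob extra zero probability of the background
#'   (default 0.9; marginal background mean is
#'   `(1 - zip_zero_prob) * zip_lambda` = 0.125 under the defaults).
#' @param mu_pool `NULL` for the built-in long-tailed sampler
#'   ([default_mu_sampler()]), or a numeric vector of positive means that
#'   is resampled with replacement (e.g. the `mu` column of [fit_nb()]
#'   results on a real dataset).
#' @param phi NB dispersion shared by all signal transcripts (0 = Poisson).
#' @param delta additive effect size in counts on the class-Y mean of
#'   differential transcripts.
#' @param n_de number of differential transcripts.
#' @param m_per_class replicates per class (>= 1).
#' @param n_reps default Monte-Carlo replicates for [run_benchmark_grid()]
#'   (default 100).
#' @param randomize_direction if `TRUE` the up-regulated class is chosen
#'   per gene; default `FALSE` (always class Y; direction does not affect
#'   two-sided testing).
#' @param correlated_block optional `list(size =, rho =)` to embed a block
#'   of signal transcripts with correlated counts (Gaussian copula).
#' @return A validated list of class `"sim_scenario"`.
#' @export
simulation_scenario <- function(n_transcripts = 20000,
                                background_fraction = 0.7,
                                zip_lambda = 1.25, zip_zero_prob = 0.9,
                                mu_pool = NULL, phi = 0.01, delta = 500,
                                n_de = 1000, m_per_class = 1, n_reps = 100,
                                randomize_direction = FALSE,
                                correlated_block = NULL) {
  stopifnot(n_transcripts >= 1,
            background_fraction >= 0, background_fraction <= 1,
            zip_lambda > 0, zip_zero_prob >= 0, zip_zero_prob <= 1,
            phi >= 0, delta >= 0, n_de >= 0, n_de <= n_transcripts,
            m_per_class >= 1, n_reps >= 1)
  if (!is.null(mu_pool))
    stopifnot(is.numeric(mu_pool), all(mu_pool > 0))
  if (!is.null(correlated_block))
    stopifnot(is.list(correlated_block),
              correlated_block$size >= 1,
              abs(correlated_block$rho) < 1)
  structure(list(n_transcripts = as.integer(n_transcripts),
                 background_fraction = background_fraction,
                 zip_lambda = zip_lambda, zip_zero_prob = zip_zero_prob,
                 mu_pool = mu_pool, phi = phi, delta = delta,
                 n_de = as.integer(n_de),
                 m_per_class = as.integer(m_per_class),
                 n_reps = as.integer(n_reps),
                 randomize_direction = isTRUE(randomize_direction),
                 correlated_block = correlated_block),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(paste0("sim_scenario: %d transcripts (%.0f%% ZIP background),",
                     " phi = %g, delta = %g, n_de = %d, m = %d/class\n"),
              x$n_transcripts, 100 * x$background_fraction, x$phi,
              x$delta, x$n_de, x$m_per_class))
  invisible(x)
}

#' Zero-inflated Poisson background counts
#'
#' Each draw is 0 with probability `zip_zero_prob` and Poisson
#' (`zip_lambda`) otherwise; uses the current RNG state.
#'
#' @param n number of draws.
#' @param zip_lambda Poisson component mean.
#' @param zip_zero_prob extra zero probability.
#' @return Integer vector.
#' @export
sample_background <- function(n, zip_lambda = 1.25, zip_zero_prob = 0.9) {
  stopifnot(n >= 0, zip_lambda > 0, zip_zero_prob >= 0, zip_zero_prob <= 1)
  nonzero <- stats::runif(n) >= zip_zero_prob
  out <- integer(n)
  out[nonzero] <- stats::rpois(sum(nonzero), zip_lambda)
  out
}

#' Long-tailed sampler of signal-transcript means
#'
#' Default pool: `log2(mu) ~ Normal(5, 2.5)` truncated to
#' `mu` in \[1, 1e6\] (median 32), a long-tailed stand-in for the spread
#' of per-transcript mean estimates in deep RNA-seq data. If `pool` is
#' given, values are resampled from it instead.
#'
#' @param n number of draws.
#' @param pool optional numeric vector to resample (with replacement).
#' @param meanlog2,sdlog2 location and scale of the log2-normal default.
#' @param range truncation bounds on the mu scale.
#' @return Numeric vector of positive means.
#' @export
default_mu_sampler <- function(n, pool = NULL, meanlog2 = 5, sdlog2 = 2.5,
                               range = c(1, 1e6)) {
  stopifnot(n >= 0)
  if (!is.null(pool)) {
    stopifnot(all(pool > 0))
    return(sample(pool, n, replace = TRUE))
  }
  lo <- stats::pnorm(log2(range[1]), meanlog2, sdlog2)
  hi <- stats::pnorm(log2(range[2]), meanlog2, sdlog2)
  2^stats::qnorm(stats::runif(n, lo, hi), meanlog2, sdlog2)
}

rnb <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Generate a simulated two-class dataset
#'
#' Draws counts for `2 * m_per_class` samples under `scenario`:
#' background transcripts get independent ZIP draws in every sample;
#' signal transcripts get NB(mu_i, phi) draws; differential transcripts
#' have `delta` added to their mean in the up-regulated class (a
#' background transcript selected as differential draws
#' NB(marginal background mean + delta, phi) there, so its counts remain
#' NB-distributed).
#'
#' @param scenario a [simulation_scenario()].
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first so the dataset is fully reproducible.
#' @return A list of class `"simulated_dataset"`: `counts` (a
#'   [count_matrix()] with samples `X_1..X_m, Y_1..Y_m` and classes
#'   `"X"`/`"Y"`), `de_truth` (named logical vector), `scenario`.
#' @export
generate_dataset <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_transcripts
  m <- scenario$m_per_class
  n_bg <- round(scenario$background_fraction * n)
  is_bg <- logical(n)
  is_bg[sample.int(n, n_bg)] <- TRUE
  mu <- numeric(n)
  mu[!is_bg] <- default_mu_sampler(n - n_bg, pool = scenario$mu_pool)
  truth <- logical(n)
  if (scenario$n_de > 0) truth[sample.int(n, scenario$n_de)] <- TRUE
  up_in_y <- rep(TRUE, n)
  if (scenario$randomize_direction)
    up_in_y[truth] <- stats::runif(sum(truth)) < 0.5

  bg_mean <- (1 - scenario$zip_zero_prob) * scenario$zip_lambda
  phi <- scenario$phi; delta <- scenario$delta
  gene_ids <- sprintf("g%05d", seq_len(n))
  samples <- c(paste0("X_", seq_len(m)), paste0("Y_", seq_len(m)))
  counts <- matrix(0L, n, 2 * m, dimnames = list(gene_ids, samples))

  draw_class <- function(shifted) {
    # shifted: logical, transcripts whose mean carries +delta in this class
    col <- integer(n)
    zip_rows <- is_bg & !shifted
    col[zip_rows] <- sample_background(sum(zip_rows), scenario$zip_lambda,
                                       scenario$zip_zero_prob)
    nb_plain <- !is_bg & !shifted
    col[nb_plain] <- rnb(sum(nb_plain), mu[nb_plain], phi)
    if (any(shifted)) {
      base <- ifelse(is_bg[shifted], bg_mean, mu[shifted])
      col[shifted] <- rnb(sum(shifted), base + delta, phi)
    }
    col
  }
  for (j in seq_len(m))
    counts[, j] <- draw_class(truth & !up_in_y)
  for (j in seq_len(m))
    counts[, m + j] <- draw_class(truth & up_in_y)

  if (!is.null(scenario$correlated_block)) {
    blk <- scenario$correlated_block
    sig <- which(!is_bg & !truth)
    size <- min(blk$size, length(sig))
    if (size > 1) {
      rows <- sig[seq_len(size)]
      counts[rows, ] <- generate_correlated_block(size, 2 * m, mu[rows],
                                                  phi, blk$rho)
    }
  }
  structure(list(counts = count_matrix(counts,
                                       stats::setNames(rep(c("X", "Y"), each = m),
                                                       samples)),
                 de_truth = stats::setNames(truth, gene_ids),
                 scenario = scenario),
            class = "simulated_dataset")
}

#' Correlated negative binomial counts via a Gaussian copula
#'
#' Generates a `block_size` x `n_samples` count block in which transcripts
#' are equicorrelated within each sample: latent
#' `z = sqrt(rho) * w + sqrt(1 - rho) * e` with a shared factor `w` per
#' sample, mapped through NB quantiles.
#'
#' @param block_size number of transcripts in the block.
#' @param n_samples number of samples.
#' @param mu NB mean (scalar or vector of length `block_size`).
#' @param phi NB dispersion (0 = Poisson).
#' @param rho latent equicorrelation, `|rho| < 1` (negative values are
#'   only meaningful pairwise for small blocks).
#' @return Integer matrix `block_size` x `n_samples`.
#' @export
generate_correlated_block <- function(block_size, n_samples, mu, phi, rho) {
  stopifnot(block_size >= 1, n_samples >= 1, abs(rho) < 1, all(mu > 0))
  mu <- rep_len(mu, block_size)
  if (block_size == 1 || rho == 0) {
    return(matrix(rnb(block_size * n_samples, rep(mu, n_samples), phi),
                  block_size, n_samples))
  }
  w <- matrix(stats::rnorm(n_samples), block_size, n_samples, byrow = TRUE)
  e <- matrix(stats::rnorm(block_size * n_samples), block_size, n_samples)
  u <- stats::pnorm(sqrt(abs(rho)) * sign(rho) * w + sqrt(1 - abs(rho)) * e)
  q <- if (phi == 0) function(p, m) stats::qpois(p, m)
       else function(p, m) stats::qnbinom(p, mu = m, size = 1 / phi)
  out <- matrix(0L, block_size, n_samples)
  for (i in seq_len(block_size)) out[i, ] <- q(u[i, ], mu[i])
  out
}
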