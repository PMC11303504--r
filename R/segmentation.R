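# Mean-shift segmentation of the copy-number signal.
#
# The segmenter follows the mode-seeking scheme of read-depth CNV callers:
# at each bandwidth h, every bin feels a "shift" pulling it toward nearby bins
# with similar signal values (Gaussian kernels in both position and signal).
# A sign change of the shift from negative to positive between adjacent bins
# marks a boundary between attraction basins, i.e. a candidate breakpoint.
# Bins are then replaced by their segment means, statistically
# indistinguishable neighbours are merged, and the sweep repeats at the next
# (larger) bandwidth. Masked bins always split segments.

#' Caller parameters
#'
#' All knobs of the segmentation and calling stages in one list.
#'
#' @param bandwidths Increasing mean-shift bandwidths, in bins.
#' @param merge_alpha Two-sample t-test threshold above which adjacent
#'   segments merge between bandwidth sweeps.
#' @param min_cn_shift Minimum |cn - 2| for the RD-only caller to emit a call.
#' @param alpha Significance level; Bonferroni-corrected by segment count.
#' @param d_max 2D merge distance threshold: adjacent segments merge while the
#'   cheapest pair is below this.
#' @param sigma_cn Per-bin CN noise; `NULL` (default) estimates it from the
#'   data with [estimate_bin_noise()].
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(bandwidths = c(2, 4, 8, 16, 32, 64, 128),
                          merge_alpha = 0.01,
                          min_cn_shift = 0.5,
                          alpha = 0.05,
                          d_max = 9.0,
                          sigma_cn = NULL) {
  if (any(diff(bandwidths) <= 0) || any(bandwidths <= 0)) {
    usage_error("bandwidths must be positive and increasing")
  }
  stopifnot(merge_alpha > 0, min_cn_shift > 0, alpha > 0, d_max > 0)
  structure(
    list(
      bandwidths = bandwidths, merge_alpha = merge_alpha,
      min_cn_shift = min_cn_shift, alpha = alpha, d_max = d_max,
      sigma_cn = sigma_cn
    ),
    class = "caller_params"
  )
}

#' Robust per-bin noise estimate of a CN track
#'
#' Difference-based robust sigma: `1.4826 * median(|x[i+1] - x[i]|) / sqrt(2)`
#' over adjacent unmasked bin pairs within chromosomes. First differences
#' cancel the (piecewise-constant) signal, and the median ignores the few
#' differences that straddle true breakpoints.
#'
#' @param cn_track Track tibble with a `cn` column.
#' @return Scalar noise sigma (0 for a constant signal).
#' @export
estimate_bin_noise <- function(cn_track) {
  if (sum(!is.na(cn_track$cn)) < 10) data_error("need at least 10 unmasked bins to estimate noise")
  d <- cn_track %>%
    group_by(.data$chrom) %>%
    mutate(d = ifelse(.data$bin - lag(.data$bin) == 1, .data$cn - lag(.data$cn), NA_real_)) %>%
    ungroup()
  diffs <- d$d[!is.na(d$d)]
  if (length(diffs) == 0) data_error("no adjacent unmasked bin pairs")
  1.4826 * median(abs(diffs)) / sqrt(2)
}

# mean-shift vector for a signal x at bandwidth h:
# shift(i) = sum_{0<|k|<=3h} k * exp(-k^2/(2h^2)) * exp(-(x_i - x_{i+k})^2/(2 sigma^2))
mean_shift_vector <- function(x, h, sigma) {
  n <- length(x)
  shift <- numeric(n)
  s2 <- max(sigma^2, 1e-12)
  for (k in seq_len(min(3 * h, n - 1))) {
    wk <- exp(-k^2 / (2 * h^2))
    # right neighbours x[i+k]
    dr <- x[seq_len(n - k) + k] - x[seq_len(n - k)]
    shift[seq_len(n - k)] <- shift[seq_len(n - k)] + k * wk * exp(-dr^2 / (2 * s2))
    # left neighbours x[i-k]
    shift[k + seq_len(n - k)] <- shift[k + seq_len(n - k)] - k * wk * exp(-dr^2 / (2 * s2))
  }
  shift
}

# p-value that two segments share a mean. Welch t-test where possible, but
# guarded by a z-test against the global robust sigma: breakpoints sit at
# local noise extremes, so the within-segment spread of short segments
# understates the noise and the plain t-test keeps spurious splits. The
# larger of the two p-values decides.
segment_pair_pvalue <- function(a, b, sigma) {
  p_t <- if (length(a) >= 2 && length(b) >= 2 && (stats::sd(a) > 0 || stats::sd(b) > 0)) {
    tryCatch(t.test(a, b)$p.value, error = function(e) 1)
  } else {
    0
  }
  p_z <- if (sigma > 0) {
    z <- (mean(a) - mean(b)) / (sigma * sqrt(1 / length(a) + 1 / length(b)))
    2 * pnorm(-abs(z))
  } else {
    as.numeric(mean(a) == mean(b))
  }
  max(p_t, p_z)
}

# merge adjacent segments (given as a list of value vectors) until every
# adjacent pair differs at level merge_alpha after Bonferroni correction by
# the run's bin count (every bin boundary is a potential breakpoint, and the
# mean-shift stage proposes exactly the most extreme-looking ones, so
# per-pair testing alone keeps spurious splits). Least-significant pair first.
merge_segments_ttest <- function(pieces, merge_alpha, sigma, n_total) {
  repeat {
    if (length(pieces) < 2) break
    pv <- vapply(seq_len(length(pieces) - 1), function(i) {
      segment_pair_pvalue(pieces[[i]], pieces[[i + 1]], sigma)
    }, 0)
    i <- which.max(pv)
    if (pv[[i]] * n_total <= merge_alpha) break
    pieces[[i]] <- c(pieces[[i]], pieces[[i + 1]])
    pieces[[i + 1]] <- NULL
  }
  pieces
}

# segment one gap-free run of bin values; returns integer breakpoints
# (segment lengths) over the run
mean_shift_run <- function(x, params, sigma) {
  n <- length(x)
  if (n == 1) return(1L)
  xw <- x
  bounds <- c(0L, n) # breakpoints accumulate; only the t-test merge removes them
  for (h in params$bandwidths) {
    shift <- mean_shift_vector(xw, h, sigma)
    bp <- which(shift[-n] < 0 & shift[-1] > 0) # breakpoint after index i
    bounds <- sort(unique(c(bounds, bp)))
    pieces <- lapply(seq_len(length(bounds) - 1), function(i) x[(bounds[i] + 1):bounds[i + 1]])
    pieces <- merge_segments_ttest(pieces, params$merge_alpha, sigma, n)
    lens <- vapply(pieces, length, 0L)
    bounds <- c(0L, cumsum(lens))
    xw <- rep(vapply(pieces, mean, 0), lens)
  }
  diff(bounds)
}

#' Mean-shift partition of a CN track
#'
#' Sweeps the bandwidths in `params` from fine to coarse, placing breakpoints
#' at sign changes of the mean-shift vector, replacing bins by segment means
#' and t-test-merging indistinguishable neighbours between sweeps. Masked bins
#' split segments; a perfectly constant run yields a single segment.
#'
#' @param cn_track Track with a `cn` column (see [to_copy_number()]).
#' @param params [caller_params()].
#' @return Segment tibble: `chrom`, `bin_start`, `bin_end` (half-open bin
#'   indices), `n_bins`, `cn_mean`.
#' @export
mean_shift_partition <- function(cn_track, params = caller_params()) {
  sigma <- params$sigma_cn %||% estimate_bin_noise(cn_track)
  runs <- unmasked_runs(cn_track)
  out <- purrr::map_dfr(runs, function(r) {
    x <- r$cn
    lens <- mean_shift_run(x, params, sigma)
    ends <- cumsum(lens)
    starts <- c(0, head(ends, -1))
    tibble(
      chrom = r$chrom[[1]],
      bin_start = r$bin[[1]] + starts,
      bin_end = r$bin[[1]] + ends,
      n_bins = as.integer(lens),
      cn_mean = vapply(seq_along(lens), function(i) mean(x[(starts[i] + 1):ends[i]]), 0)
    )
  })
  out <- arrange(out, match(.data$chrom, unique(cn_track$chrom)), .data$bin_start)
  attr(out, "sigma_cn") <- sigma
  out
}

# split a track into maximal runs of consecutive unmasked bins
unmasked_runs <- function(cn_track) {
  t <- cn_track %>%
    filter(!is.na(.data$cn)) %>%
    group_by(.data$chrom) %>%
    mutate(run = cumsum(c(1, diff(.data$bin) != 1))) %>%
    ungroup()
  split(t, interaction(match(t$chrom, unique(t$chrom)), t$run, drop = TRUE), drop = TRUE)
}
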