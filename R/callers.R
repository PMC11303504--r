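# CNV/CNA calling on top of the segmented signals.
#
# Two callers are provided. The RD caller types segments from the read-depth
# level alone (deletion/duplication beyond a minimum CN shift, t-tested
# against the genome mean). The 2D caller merges bins bottom-up under a joint
# distance that requires BOTH the CN level and the BAF likelihood of adjacent
# segments to be compatible, then genotypes each segment into deletion,
# duplication or copy-neutral LOH with a cell fraction by inverting the
# mixture formulas
#   deletion:    CN(f) = 2 - f,  BAF(f) = (1 - f) / (2 - f)
#   duplication: CN(f) = 2 + f,  BAF(f) = 1 / (2 + f)
#   cn-LOH:      CN(f) = 2,      BAF(f) = (1 - f) / 2
# where f is the fraction of cells carrying the event.

# join contiguous same-type calls: event boundaries rarely align with the bin
# grid, so the partially covered edge bins segment apart from the event core
# (their CN is intermediate) and would otherwise be reported as separate
# events. Length-weighted cn and cell fraction; smallest p_adj.
merge_adjacent_calls <- function(calls) {
  if (nrow(calls) < 2) return(calls)
  calls <- arrange(calls, match(.data$chrom, unique(.data$chrom)), .data$start)
  grp <- cumsum(
    c(TRUE, !(calls$chrom[-1] == head(calls$chrom, -1) &
      calls$type[-1] == head(calls$type, -1) &
      calls$start[-1] == head(calls$end, -1)))
  )
  calls %>%
    mutate(.grp = grp, .len = .data$end - .data$start) %>%
    group_by(.data$.grp) %>%
    summarise(
      chrom = .data$chrom[[1]],
      start = min(.data$start),
      end = max(.data$end),
      type = .data$type[[1]],
      cn = sum(.data$cn * .data$.len) / sum(.data$.len),
      cell_fraction = if (anyNA(.data$cell_fraction)) NA_real_ else {
        sum(.data$cell_fraction * .data$.len) / sum(.data$.len)
      },
      p_adj = min(.data$p_adj),
      caller = .data$caller[[1]],
      bin_size = .data$bin_size[[1]],
      .groups = "drop"
    ) %>%
    select(-".grp")
}

empty_calls <- function() {
  tibble(
    chrom = character(), start = numeric(), end = numeric(),
    type = character(), cn = numeric(), cell_fraction = numeric(),
    p_adj = numeric(), caller = character(), bin_size = numeric()
  )
}

segment_coords <- function(segments, cn_track) {
  bs <- track_bin_size(cn_track)
  lens <- cn_track %>%
    group_by(.data$chrom) %>%
    summarise(len = max(.data$end), .groups = "drop")
  segments %>%
    left_join(lens, by = "chrom") %>%
    mutate(start = .data$bin_start * bs, end = pmin(.data$bin_end * bs, .data$len)) %>%
    select(-"len")
}

#' Call CNVs from a mean-shift segmentation (RD-only caller)
#'
#' A segment is a deletion if its mean CN is below `2 - min_cn_shift`, a
#' duplication above `2 + min_cn_shift`, and is reported only when a
#' one-sample t-test of its bins against the genome-wide mean survives
#' Bonferroni correction across segments. Cell fraction is `|cn - 2|` clamped
#' to \[0, 1\] under a single-copy-change assumption; for multi-copy
#' amplifications (|cn - 2| > 1) it is reported as `NA` (not estimable from RD
#' alone). Copy-neutral LOH cannot be seen by this caller.
#'
#' @param segments Output of [mean_shift_partition()].
#' @param cn_track Track with `cn`.
#' @param params [caller_params()].
#' @return Calls tibble (`chrom`, `start`, `end`, `type`, `cn`,
#'   `cell_fraction`, `p_adj`, `caller`, `bin_size`).
#' @export
call_rd <- function(segments, cn_track, params = caller_params()) {
  if (nrow(segments) == 0) return(empty_calls())
  sigma <- attr(segments, "sigma_cn") %||% params$sigma_cn %||% estimate_bin_noise(cn_track)
  global_mean <- mean(cn_track$cn, na.rm = TRUE)
  bs <- track_bin_size(cn_track)
  nseg <- nrow(segments)
  segs <- segment_coords(segments, cn_track)

  rows <- purrr::map_dfr(seq_len(nseg), function(i) {
    s <- segs[i, ]
    cn <- s$cn_mean
    type <- if (cn < 2 - params$min_cn_shift) "deletion"
      else if (cn > 2 + params$min_cn_shift) "duplication"
      else return(NULL)
    vals <- cn_track$cn[cn_track$chrom == s$chrom &
      cn_track$bin >= s$bin_start & cn_track$bin < s$bin_end]
    vals <- vals[!is.na(vals)]
    p <- if (length(vals) >= 2 && stats::sd(vals) > 0) {
      t.test(vals, mu = global_mean)$p.value
    } else if (sigma > 0) {
      2 * pnorm(-abs((mean(vals) - global_mean) / (sigma / sqrt(length(vals)))))
    } else {
      as.numeric(mean(vals) == global_mean)
    }
    p_adj <- min(p * nseg, 1)
    if (p_adj >= params$alpha) return(NULL)
    shift <- abs(cn - 2)
    # single-copy-change reading of the RD shift; a duplication clearly past
    # one extra copy (cn > 3 beyond noise) has no single-copy cell fraction
    multi_copy <- type == "duplication" && cn > 3 + params$min_cn_shift / 2
    tibble(
      chrom = s$chrom, start = s$start, end = s$end, type = type, cn = cn,
      cell_fraction = if (multi_copy) NA_real_ else min(shift, 1),
      p_adj = p_adj, caller = "rd", bin_size = bs
    )
  })
  if (nrow(rows) == 0) empty_calls() else merge_adjacent_calls(rows)
}

# joint RD+BAF distance between two adjacent segments:
#   (m_s - m_t)^2 / (sigma^2 (1/n_s + 1/n_t)) - 2 * ln BC(curve_s, curve_t)
# the BAF term vanishes when either side carries no het information
merge2d_distance <- function(m1, m2, n1, n2, sigma, c1, c2, h1, h2) {
  d <- (m1 - m2)^2 / (max(sigma, 1e-9)^2 * (1 / n1 + 1 / n2))
  if (h1 > 0 && h2 > 0) {
    bc <- max(likelihood_overlap(c1, c2), 1e-300)
    d <- d - 2 * log(bc)
  }
  d
}

#' Joint RD + BAF bottom-up segmentation (2D merge)
#'
#' Starts from one segment per unmasked bin and repeatedly merges the adjacent
#' pair with the smallest joint distance — a normalised CN gap plus
#' `-2 log` Bhattacharyya overlap of the BAF curves — until the cheapest merge
#' exceeds `d_max`. Segment curves are renormalised products of their bins'
#' curves. Ties break to the leftmost pair; masked bins split segments.
#'
#' @param cn_track Track with `cn`.
#' @param baf_track Matching BAF track from [bin_baf()].
#' @param params [caller_params()].
#' @return Segment tibble with `chrom`, `bin_start`, `bin_end`, `n_bins`,
#'   `cn_mean`, `n_het`, `max_baf`, and a `curve` list-column.
#' @export
merge_2d <- function(cn_track, baf_track, params = caller_params()) {
  if (!same_grid(cn_track, baf_track)) {
    data_error("cn_track and baf_track are on different grids")
  }
  sigma <- params$sigma_cn %||% estimate_bin_noise(cn_track)
  G <- attr(baf_track, "G") %||% 101
  key <- paste(baf_track$chrom, baf_track$bin)
  curve_of <- setNames(baf_track$curve, key)
  nhet_of <- setNames(baf_track$n_het, key)

  runs <- unmasked_runs(cn_track)
  out <- purrr::map_dfr(runs, function(r) {
    n <- nrow(r)
    m <- r$cn
    w <- rep(1, n)
    k <- paste(r$chrom, r$bin)
    nhet <- as.numeric(nhet_of[k])
    logc <- matrix(0, nrow = n, ncol = G)
    for (i in seq_len(n)) {
      ci <- curve_of[[k[[i]]]]
      if (!is.null(ci) && nhet[[i]] > 0) logc[i, ] <- log(pmax(ci, 1e-300))
    }
    curves <- t(apply(logc, 1, normalise_log_curve))
    lo <- seq_len(n) # first fine bin (1-based offset into run) of each segment

    dist_between <- function(i, j) {
      merge2d_distance(
        m[i], m[j], w[i], w[j], sigma,
        curves[i, ], curves[j, ], nhet[i], nhet[j]
      )
    }
    merge_pair <- function(i) {
      j <- i + 1
      m[i] <<- (m[i] * w[i] + m[j] * w[j]) / (w[i] + w[j])
      w[i] <<- w[i] + w[j]
      logc[i, ] <<- logc[i, ] + logc[j, ]
      curves[i, ] <<- normalise_log_curve(logc[i, ])
      nhet[i] <<- nhet[i] + nhet[j]
      keep <- setdiff(seq_along(m), j)
      m <<- m[keep]; w <<- w[keep]; nhet <<- nhet[keep]; lo <<- lo[keep]
      logc <<- logc[keep, , drop = FALSE]; curves <<- curves[keep, , drop = FALSE]
    }
    if (n > 1) {
      d <- vapply(seq_len(n - 1), function(i) dist_between(i, i + 1), 0)
      while (length(m) > 1) {
        i <- which.min(d) # which.min takes the first (leftmost) minimum
        if (d[[i]] > params$d_max) break
        merge_pair(i)
        d <- d[-i]
        if (i > 1) d[i - 1] <- dist_between(i - 1, i)
        if (i <= length(m) - 1) d[i] <- dist_between(i, i + 1)
      }
      # cleanup pass: the greedy stop at d_max is a fixed-width cut, but the
      # bottom-up search looked at every bin boundary, so boundaries that are
      # not Bonferroni-significant at the run's bin count are noise extremes;
      # the joint distance is ~chi-square (df 2 with BAF, 1 without) under
      # a shared (cn, baf) state
      while (length(m) > 1) {
        dd <- vapply(seq_len(length(m) - 1), function(i) dist_between(i, i + 1), 0)
        dfs <- vapply(seq_len(length(m) - 1), function(i) 1 + (nhet[i] > 0 && nhet[i + 1] > 0), 0)
        pv <- pchisq(dd, df = dfs, lower.tail = FALSE) * n
        i <- which.max(pv)
        if (pv[[i]] <= params$merge_alpha) break
        merge_pair(i)
      }
    }
    ends <- c(lo[-1] - 1, n)
    tibble(
      chrom = r$chrom[[1]],
      bin_start = r$bin[[1]] + lo - 1,
      bin_end = r$bin[[1]] + ends,
      n_bins = as.integer(w),
      cn_mean = m,
      n_het = nhet,
      max_baf = ifelse(nhet > 0, apply(curves, 1, max_baf), NA_real_),
      curve = lapply(seq_len(nrow(curves)), function(i) if (nhet[[i]] > 0) curves[i, ] else NULL)
    )
  })
  out <- arrange(out, match(.data$chrom, unique(cn_track$chrom)), .data$bin_start)
  attr(out, "sigma_cn") <- sigma
  attr(out, "G") <- G
  out
}

#' Genotype one segment into an event model with cell fraction
#'
#' Minimises the two-term squared error
#' `((cn_mean - CN(f))/sigma_m)^2 + ((max_baf - BAF(f))/sigma_b)^2`
#' over `f` in (0, 1\] for the deletion, duplication and copy-neutral-LOH
#' models (0.001 grid plus local refinement; ties prefer the smaller f).
#' Returns the neutral model when the optimum collapses to the f -> 0 boundary
#' or the neutral point (CN 2, BAF 0.5) scores within 2.0 of the best model.
#'
#' @param cn_mean Segment mean copy number.
#' @param max_baf Segment maximum-likelihood BAF in \[0, 0.5\]; `NA` if the
#'   segment has no het sites.
#' @param sigma_m,sigma_b Standard errors of `cn_mean` and `max_baf`.
#' @return List with `type` (`"deletion"`, `"duplication"`, `"cnnloh"` or
#'   `"neutral"`), model `cn`, cell fraction `f`, and the objective values.
#' @export
genotype_segment <- function(cn_mean, max_baf, sigma_m, sigma_b) {
  stopifnot(cn_mean > 0, is.na(max_baf) || (max_baf >= 0 && max_baf <= 0.5))
  models <- list(
    deletion = list(cn = function(f) 2 - f, baf = function(f) (1 - f) / (2 - f)),
    duplication = list(cn = function(f) 2 + f, baf = function(f) 1 / (2 + f)),
    cnnloh = list(cn = function(f) rep(2, length(f)), baf = function(f) (1 - f) / 2)
  )
  obj <- function(mod, f) {
    o <- ((cn_mean - mod$cn(f)) / sigma_m)^2
    if (!is.na(max_baf)) o <- o + ((max_baf - mod$baf(f)) / sigma_b)^2
    o
  }
  fgrid <- seq(0.001, 1, by = 0.001)
  best <- NULL
  for (name in names(models)) {
    mod <- models[[name]]
    vals <- obj(mod, fgrid)
    k <- which.min(vals) # first minimum -> smaller f on ties
    f0 <- fgrid[[k]]
    refine <- optimize(function(f) obj(mod, f),
      lower = max(f0 - 0.001, 1e-6), upper = min(f0 + 0.001, 1)
    )
    cand <- list(type = name, f = refine$minimum, objective = refine$objective)
    if (is.null(best) || cand$objective < best$objective - 1e-12 ||
      (abs(cand$objective - best$objective) <= 1e-12 && cand$f < best$f)) {
      best <- cand
    }
  }
  neutral_obj <- ((cn_mean - 2) / sigma_m)^2 +
    if (is.na(max_baf)) 0 else ((max_baf - 0.5) / sigma_b)^2
  at_zero <- best$f <= 0.002
  if (at_zero || neutral_obj <= best$objective + 2.0) {
    return(list(
      type = "neutral", cn = 2, f = 0,
      objective = neutral_obj, neutral_objective = neutral_obj
    ))
  }
  mod <- models[[best$type]]
  list(
    type = best$type, cn = mod$cn(best$f), f = best$f,
    objective = best$objective, neutral_objective = neutral_obj
  )
}

# likelihood-ratio statistic for allelic imbalance: twice the log-likelihood
# gap between the curve's peak and the balanced point p = 0.5. The folded
# composite likelihood of a NEUTRAL segment often peaks slightly off 0.5 (the
# fold makes 0.5 a shallow local dip under noise), so the argmax itself is a
# heavy-tailed estimator near 0.5; the depth of that dip, not the location of
# the peak, is what distinguishes true imbalance from folding noise.
baf_imbalance_lr <- function(curve) {
  G <- length(curve)
  lc <- log(pmax(curve, 1e-300))
  k_half <- which.min(abs(baf_grid(G) - 0.5))
  max(2 * (max(lc) - lc[[k_half]]), 0)
}

# BAF standard error from the curvature of the log-likelihood at its peak,
# with a floor; one-sided second difference at grid boundaries
curve_sigma_b <- function(curve, floor_sd = 0.01) {
  G <- length(curve)
  h <- 1 / (G - 1)
  lc <- log(pmax(curve, 1e-300))
  k <- which.max(curve)
  d2 <- if (k > 1 && k < G) {
    lc[k - 1] - 2 * lc[k] + lc[k + 1]
  } else if (k == 1) {
    2 * (lc[2] - lc[1])
  } else {
    2 * (lc[G - 1] - lc[G])
  }
  if (!is.finite(d2) || d2 >= 0) return(max(floor_sd, 0.5))
  max(h / sqrt(-d2), floor_sd)
}

#' Joint RD + BAF caller (2D caller)
#'
#' Runs [merge_2d()], genotypes every segment with [genotype_segment()]
#' (`sigma_m = sigma_cn / sqrt(n_bins)`, `sigma_b` from the curvature of the
#' segment's BAF curve at its peak, floored at 0.01), and keeps non-neutral
#' segments whose joint departure from (CN 2, BAF 0.5) survives Bonferroni
#' correction across segments. Segments without BAF information fall back to
#' the RD-only typing rules. With `baf_track = NULL` the function downgrades
#' to the RD caller with a warning.
#'
#' @param cn_track Track with `cn`.
#' @param baf_track BAF track on the same grid, or `NULL`.
#' @param params [caller_params()].
#' @return A `cnv_fit` object; see [tidy.cnv_fit()] / [glance.cnv_fit()].
#' @export
call_2d <- function(cn_track, baf_track, params = caller_params()) {
  if (is.null(baf_track)) {
    warn("no BAF track available; falling back to the RD-only caller")
    return(call_cnv(cn_track, NULL, params = params, method = "rd"))
  }
  sigma <- params$sigma_cn %||% estimate_bin_noise(cn_track)
  segs <- merge_2d(cn_track, baf_track, params)
  bs <- track_bin_size(cn_track)
  nseg <- nrow(segs)
  n_tests <- sum(!is.na(cn_track$cn)) # the merge searched every bin boundary
  segc <- segment_coords(segs, cn_track)

  calls <- purrr::map_dfr(seq_len(nseg), function(i) {
    s <- segc[i, ]
    sigma_m <- max(sigma / sqrt(s$n_bins), 1e-9)
    if (s$n_het > 0) {
      sigma_b <- curve_sigma_b(s$curve[[1]])
      g <- genotype_segment(s$cn_mean, s$max_baf, sigma_m, sigma_b)
      if (g$type == "neutral") return(NULL)
      # RD-or-BAF departure from (2, 0.5): normalised CN gap plus the
      # imbalance likelihood ratio (the folded argmax is noisy near 0.5)
      z2 <- ((s$cn_mean - 2) / sigma_m)^2 + baf_imbalance_lr(s$curve[[1]])
      p <- pchisq(z2, df = 2, lower.tail = FALSE)
      type <- g$type; cn <- g$cn; f <- g$f
    } else {
      # hom-only segment: RD evidence alone
      if (abs(s$cn_mean - 2) <= params$min_cn_shift) return(NULL)
      z2 <- ((s$cn_mean - 2) / sigma_m)^2
      p <- pchisq(z2, df = 1, lower.tail = FALSE)
      type <- if (s$cn_mean < 2) "deletion" else "duplication"
      cn <- s$cn_mean
      shift <- abs(s$cn_mean - 2)
      f <- if (shift > 1) NA_real_ else shift
    }
    p_adj <- min(p * n_tests, 1)
    if (p_adj >= params$alpha) return(NULL)
    tibble(
      chrom = s$chrom, start = s$start, end = s$end, type = type, cn = cn,
      cell_fraction = f, p_adj = p_adj, caller = "2d", bin_size = bs
    )
  })
  calls <- if (nrow(calls) == 0) empty_calls() else merge_adjacent_calls(calls)
  new_cnv_fit(calls, segs, params, sigma, bs, "2d", cn_track)
}

#' Run a CNV caller and return a fit object
#'
#' Front door for both callers: `method = "2d"` (default, joint RD + BAF) or
#' `method = "rd"` (mean-shift read-depth only).
#'
#' @param cn_track Track with `cn` (see [to_copy_number()]).
#' @param baf_track BAF track ([bin_baf()]); required for `"2d"`.
#' @param params [caller_params()].
#' @param method `"2d"` or `"rd"`.
#' @return A `cnv_fit` object.
#' @export
call_cnv <- function(cn_track, baf_track = NULL, params = caller_params(),
                     method = c("2d", "rd")) {
  method <- match.arg(method)
  if (method == "2d") return(call_2d(cn_track, baf_track, params))
  segs <- mean_shift_partition(cn_track, params)
  sigma <- attr(segs, "sigma_cn")
  calls <- call_rd(segs, cn_track, params)
  new_cnv_fit(calls, segs, params, sigma, track_bin_size(cn_track), "rd", cn_track)
}

new_cnv_fit <- function(calls, segments, params, sigma, bin_size, caller, cn_track) {
  structure(
    list(
      calls = calls, segments = segments, params = params,
      sigma_cn = sigma, bin_size = bin_size, caller = caller,
      cn_track = cn_track
    ),
    class = "cnv_fit"
  )
}

#' @export
print.cnv_fit <- function(x, ...) {
  cat(sprintf(
    "<cnv_fit> caller=%s bin_size=%g segments=%d calls=%d sigma_cn=%.4g\n",
    x$caller, x$bin_size, nrow(x$segments), nrow(x$calls), x$sigma_cn
  ))
  if (nrow(x$calls) > 0) print(x$calls)
  invisible(x)
}

#' Tidy the calls of a CNV fit
#'
#' @param x A `cnv_fit`.
#' @param ... Unused.
#' @return The calls tibble, one row per called event.
#' @exportS3Method generics::tidy
#' @export
tidy.cnv_fit <- function(x, ...) x$calls

#' One-row summary of a CNV fit
#'
#' @param x A `cnv_fit`.
#' @param ... Unused.
#' @return Tibble with caller, bin size, segment/call counts and noise sigma.
#' @exportS3Method generics::glance
#' @export
glance.cnv_fit <- function(x, ...) {
  tibble(
    caller = x$caller, bin_size = x$bin_size,
    n_segments = nrow(x$segments), n_calls = nrow(x$calls),
    sigma_cn = x$sigma_cn,
    n_bins = sum(!is.na(x$cn_track$cn))
  )
}
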