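# Concordance surfaces: VCF-derived versus alignment-like signals and calls.

#' Per-bin copy-number difference statistics
#'
#' Differences `cn_a - cn_b` over bins unmasked in both tracks, with the
#' summary statistics used to judge how faithfully variant-site-sampled depth
#' reproduces alignment-derived depth.
#'
#' @param track_a,track_b Tracks on the same grid, each with a `cn` column.
#' @return One-row tibble: `n_bins`, `mean`, `sd`, `q05`, `q25`, `q50`,
#'   `q75`, `q95`.
#' @export
rd_difference_stats <- function(track_a, track_b) {
  if (!same_grid(track_a, track_b)) {
    data_error("tracks are on different grids")
  }
  d <- track_a$cn - track_b$cn
  d <- d[!is.na(d)]
  if (length(d) == 0) data_error("no jointly unmasked bins")
  q <- quantile(d, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  tibble(
    n_bins = length(d), mean = mean(d), sd = stats::sd(d),
    q05 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q95 = q[5]
  )
}

#' Match two call sets by reciprocal overlap
#'
#' A reference call matches a query call on the same chromosome when the
#' shared span is at least `min_reciprocal_overlap` of BOTH lengths.
#' Assignment is one-to-one and greedy by decreasing overlap (leftmost pair on
#' ties), so a query call can match at most one reference call and recall
#' never exceeds 1 under fragmentation.
#'
#' @param calls_ref,calls_query Call tibbles with `chrom`, `start`, `end`,
#'   `type`.
#' @param min_reciprocal_overlap Fraction in (0, 1]; default 0.5.
#' @return List of class `match_report`: `n_ref`, `n_query`, `recall`,
#'   `type_concordance` (NA when nothing matched), and `pairs` (tibble of
#'   matched index pairs with types and overlap).
#' @export
match_calls <- function(calls_ref, calls_query, min_reciprocal_overlap = 0.5) {
  if (min_reciprocal_overlap <= 0 || min_reciprocal_overlap > 1) {
    usage_error("min_reciprocal_overlap must be in (0, 1]")
  }
  n_ref <- nrow(calls_ref)
  n_query <- nrow(calls_query)
  cand <- NULL
  if (n_ref > 0 && n_query > 0) {
    cand <- tidyr::crossing(i = seq_len(n_ref), j = seq_len(n_query)) %>%
      mutate(
        chrom_ok = calls_ref$chrom[.data$i] == calls_query$chrom[.data$j],
        ov = pmax(0, pmin(calls_ref$end[.data$i], calls_query$end[.data$j]) -
          pmax(calls_ref$start[.data$i], calls_query$start[.data$j])),
        len_i = calls_ref$end[.data$i] - calls_ref$start[.data$i],
        len_j = calls_query$end[.data$j] - calls_query$start[.data$j]
      ) %>%
      filter(.data$chrom_ok,
        .data$ov / .data$len_i >= min_reciprocal_overlap,
        .data$ov / .data$len_j >= min_reciprocal_overlap
      ) %>%
      arrange(dplyr::desc(.data$ov), .data$i, .data$j)
  }
  pairs <- tibble(
    ref = integer(), query = integer(), overlap = numeric(),
    type_ref = character(), type_query = character()
  )
  if (!is.null(cand) && nrow(cand) > 0) {
    used_i <- logical(n_ref)
    used_j <- logical(n_query)
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[[k]]; j <- cand$j[[k]]
      if (used_i[[i]] || used_j[[j]]) next
      used_i[[i]] <- TRUE; used_j[[j]] <- TRUE
      pairs <- bind_rows(pairs, tibble(
        ref = i, query = j, overlap = cand$ov[[k]],
        type_ref = calls_ref$type[[i]], type_query = calls_query$type[[j]]
      ))
    }
  }
  recall <- if (n_ref == 0) NA_real_ else nrow(pairs) / n_ref
  tc <- if (nrow(pairs) == 0) NA_real_ else mean(pairs$type_ref == pairs$type_query)
  structure(
    list(
      n_ref = n_ref, n_query = n_query, recall = recall,
      type_concordance = tc, pairs = pairs,
      min_reciprocal_overlap = min_reciprocal_overlap
    ),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report> ref=%d query=%d matched=%d recall=%s type_concordance=%s (min reciprocal overlap %.2f)\n",
    x$n_ref, x$n_query, nrow(x$pairs),
    format(x$recall, digits = 3), format(x$type_concordance, digits = 3),
    x$min_reciprocal_overlap
  ))
  invisible(x)
}

#' Tidy the matched pairs of a match report
#'
#' @param x A `match_report`.
#' @param ... Unused.
#' @return Tibble of matched (ref, query) pairs with types and overlap.
#' @exportS3Method generics::tidy
#' @export
tidy.match_report <- function(x, ...) x$pairs

#' One-row summary of a match report
#'
#' @param x A `match_report`.
#' @param ... Unused.
#' @return Tibble with call counts, recall and type concordance.
#' @exportS3Method generics::glance
#' @export
glance.match_report <- function(x, ...) {
  tibble(
    n_ref = x$n_ref, n_query = x$n_query, n_matched = nrow(x$pairs),
    recall = x$recall, type_concordance = x$type_concordance,
    min_reciprocal_overlap = x$min_reciprocal_overlap
  )
}
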