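# Binned read-depth signals in copy-number units.
#
# Bins are 0-based half-open [i*size, (i+1)*size); a 1-based position p falls
# in bin floor((p-1)/size). The last bin of a contig may be short. Tracks are
# tibbles over the FULL grid (masked bins present with raw = NA), so bin
# adjacency, rebinning and GC tables all align by row.

full_grid <- function(contigs, bin_size) {
  assert_contigs(contigs)
  purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    len <- contigs$length[[i]]
    nb <- ceiling(len / bin_size)
    tibble(
      chrom = contigs$name[[i]],
      bin = seq_len(nb) - 1L,
      start = (seq_len(nb) - 1) * bin_size,
      end = pmin(seq_len(nb) * bin_size, len)
    )
  })
}

track_bin_size <- function(track) {
  bs <- attr(track, "bin_size")
  if (is.null(bs)) bs <- max(track$end - track$start)
  bs
}

#' Bin per-variant read depth over a fixed genomic grid
#'
#' The raw read-depth signal of a bin is the arithmetic mean of the DP values
#' of the variant sites falling in it — a coverage-calibrated signal that does
#' not depend on SNP density. Bins containing no variant are masked
#' (`raw = NA`). Both heterozygous and homozygous sites contribute.
#'
#' @param variants Variant tibble from [read_vcf_variants()] or
#'   [simulate_sample()].
#' @param contigs Contig map (`name`, `length`).
#' @param bin_size Bin width in bp.
#' @return An RD track tibble: `chrom`, `bin`, `start`, `end`, `raw`,
#'   `corrected` (initially equal to `raw`), `n_var`. Attribute `bin_size`.
#' @export
bin_read_depth <- function(variants, contigs, bin_size) {
  grid <- full_grid(contigs, bin_size)
  lens <- setNames(contigs$length, contigs$name)
  if (nrow(variants) > 0) {
    bad <- variants$pos > lens[variants$chrom] | variants$pos < 1
    if (any(bad, na.rm = TRUE)) {
      i <- which(bad)[[1]]
      data_error(sprintf(
        "variant %s:%d lies beyond contig length %d",
        variants$chrom[[i]], as.integer(variants$pos[[i]]), as.integer(lens[[variants$chrom[[i]]]])
      ))
    }
  }
  agg <- variants %>%
    mutate(bin = floor((.data$pos - 1) / bin_size)) %>%
    group_by(.data$chrom, .data$bin) %>%
    summarise(raw = mean(.data$dp), n_var = dplyr::n(), .groups = "drop")
  out <- grid %>%
    left_join(agg, by = c("chrom", "bin")) %>%
    mutate(
      n_var = ifelse(is.na(.data$n_var), 0L, .data$n_var),
      corrected = .data$raw
    ) %>%
    select("chrom", "bin", "start", "end", "raw", "corrected", "n_var")
  attr(out, "bin_size") <- bin_size
  out
}

#' Global depth normalisation constant
#'
#' Median of the per-bin depth over unmasked autosomal bins — robust to large
#' copy-number alterations, which matters in cancer samples where a sizeable
#' genome fraction may be aneuploid.
#'
#' @param rd_track RD track tibble.
#' @param signal Which column to summarise (`"corrected"` default, or `"raw"`).
#' @param autosomes_only Drop contigs named X/Y/M/MT (with or without a `chr`
#'   prefix)? Default `TRUE`; falls back to all contigs when nothing is left.
#' @return Scalar median depth.
#' @export
global_depth <- function(rd_track, signal = c("corrected", "raw"), autosomes_only = TRUE) {
  signal <- match.arg(signal)
  x <- rd_track[[signal]]
  keep <- !is.na(x)
  if (autosomes_only && any(keep & is_autosome(rd_track$chrom))) {
    keep <- keep & is_autosome(rd_track$chrom)
  }
  if (!any(keep)) data_error("all bins are masked; cannot estimate global depth")
  median(x[keep])
}

#' Scale a depth track to copy-number units
#'
#' Adds a `cn` column with `2 * depth / global`, so a diploid baseline sits at
#' CN 2. Masked bins stay masked.
#'
#' @param rd_track RD track tibble.
#' @param global Normalisation depth; default [global_depth()] of the track.
#' @param signal Column to convert (default `"corrected"`).
#' @return The track with a `cn` column added.
#' @export
to_copy_number <- function(rd_track, global = global_depth(rd_track, signal), signal = c("corrected", "raw")) {
  signal <- match.arg(signal)
  if (!is.numeric(global) || global <= 0) data_error("global depth must be positive")
  bs <- track_bin_size(rd_track)
  out <- mutate(rd_track, cn = 2 * .data[[signal]] / global)
  attr(out, "bin_size") <- bs
  attr(out, "global_depth") <- global
  out
}

#' GC-correct a binned read-depth track
#'
#' Bins are stratified into GC classes (default width 1 percentage point);
#' each bin is rescaled by the ratio of the global mean depth to its class
#' mean, which flattens the characteristic unimodal GC bias curve while
#' conserving the global mean. Classes holding fewer than `min_bins` unmasked
#' bins are pooled with their nearest neighbouring class. Bins with missing GC
#' keep their raw value.
#'
#' @param rd_track RD track tibble.
#' @param gc_table Tibble with `chrom`, `start` (0-based bin start) and `gc`
#'   (fraction in 0..1) on the same grid; see [read_gc_table()].
#' @param class_width GC class width as a fraction (default 0.01).
#' @param min_bins Minimum unmasked bins per class before pooling (default 100).
#' @return The track with the `corrected` column filled.
#' @export
gc_correct <- function(rd_track, gc_table, class_width = 0.01, min_bins = 100) {
  if (!all(c("chrom", "start", "gc") %in% names(gc_table))) {
    data_error("gc_table needs columns chrom, start, gc")
  }
  if (any(gc_table$gc < 0 | gc_table$gc > 1, na.rm = TRUE)) {
    data_error("gc fractions must lie in [0, 1]")
  }
  bs <- track_bin_size(rd_track)
  joined <- left_join(rd_track, gc_table[, c("chrom", "start", "gc")], by = c("chrom", "start"))
  extra <- setdiff(paste(gc_table$chrom, gc_table$start), paste(rd_track$chrom, rd_track$start))
  if (length(extra) > 0) data_error("gc_table grid does not match the track grid")

  use <- !is.na(joined$raw) & !is.na(joined$gc)
  if (!any(use)) {
    out <- mutate(joined, corrected = .data$raw) %>% select(-"gc")
    attr(out, "bin_size") <- bs
    return(out)
  }
  cls <- pmin(floor(joined$gc / class_width), floor(1 / class_width) - 1)
  gm <- mean(joined$raw[use])

  # pool sparse classes with the nearest (by GC) neighbouring class
  pooled <- pool_gc_classes(cls[use], min_bins)
  class_of <- rep(NA_real_, nrow(joined))
  class_of[use] <- pooled
  cmeans <- tapply(joined$raw[use], pooled, mean)

  corr <- joined$raw
  scale <- gm / cmeans[as.character(class_of[use])]
  corr[use] <- joined$raw[use] * as.numeric(scale)
  out <- mutate(joined, corrected = .env$corr) %>% select(-"gc")
  attr(out, "bin_size") <- bs
  out
}

# merge class labels until every class has >= min_bins members; labels are
# integer GC classes, merging always into the nearest remaining class
pool_gc_classes <- function(cls, min_bins) {
  lab <- sort(unique(cls))
  assign <- setNames(lab, lab)
  counts <- table(cls)
  cnt <- setNames(as.integer(counts[as.character(lab)]), lab)
  active <- lab
  while (length(active) > 1) {
    small <- active[cnt[as.character(active)] < min_bins]
    if (length(small) == 0) break
    s <- small[[1]]
    others <- setdiff(active, s)
    nearest <- others[which.min(abs(others - s))]
    assign[names(assign)[assign == s]] <- nearest
    cnt[as.character(nearest)] <- cnt[as.character(nearest)] + cnt[as.character(s)]
    active <- setdiff(active, s)
  }
  as.integer(assign[as.character(cls)])
}

#' Read a per-bin GC table
#'
#' Three-column TSV: chromosome, 0-based bin start, GC fraction.
#'
#' @param path TSV file path.
#' @return Tibble with `chrom`, `start`, `gc`.
#' @export
read_gc_table <- function(path) {
  readr::read_tsv(path,
    col_names = c("chrom", "start", "gc"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_double(), gc = readr::col_double()
    ),
    comment = "#", progress = FALSE
  )
}

#' Coarsen an RD track by an integer factor
#'
#' Coarse raw/corrected values are the `n_var`-weighted means of the fine
#' bins; variant counts add; a coarse bin is masked iff all of its fine bins
#' are. Rebinning is associative: rebinning by a then b equals rebinning by
#' a*b.
#'
#' @param rd_track RD track tibble.
#' @param factor Positive integer.
#' @return RD track at `bin_size * factor`.
#' @export
rebin <- function(rd_track, factor) {
  if (factor < 1 || factor != round(factor)) usage_error("rebin factor must be a positive integer")
  factor <- as.integer(factor)
  bs <- track_bin_size(rd_track)
  if (factor == 1L) return(rd_track)
  wmean <- function(x, w) if (sum(w) > 0) sum(x * w, na.rm = TRUE) / sum(w) else NA_real_
  out <- rd_track %>%
    mutate(coarse = .data$bin %/% factor) %>%
    group_by(.data$chrom, coarse) %>%
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      raw = wmean(.data$raw, .data$n_var),
      corrected = wmean(.data$corrected, .data$n_var),
      n_var = sum(.data$n_var),
      .groups = "drop"
    ) %>%
    arrange(match(.data$chrom, unique(rd_track$chrom)), .data$coarse) %>%
    dplyr::rename(bin = "coarse") %>%
    mutate(bin = as.integer(.data$bin)) %>%
    select("chrom", "bin", "start", "end", "raw", "corrected", "n_var")
  attr(out, "bin_size") <- bs * factor
  out
}
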