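# Text exports. All coordinates in text outputs are 0-based half-open (BED
# convention); only VCF positions are 1-based.

#' Export an RD track as TSV
#'
#' Columns `chrom start end raw corrected n_var`, plus `cn` when present.
#'
#' @param rd_track RD track tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_rd_tsv <- function(rd_track, path) {
  cols <- intersect(c("chrom", "start", "end", "raw", "corrected", "n_var", "cn"), names(rd_track))
  readr::write_tsv(rd_track[, cols], path, progress = FALSE)
  invisible(path)
}

#' Export a BAF track as TSV
#'
#' Columns `chrom start end max_baf n_het`; full likelihood curves live only
#' in the HDF5 store.
#'
#' @param baf_track BAF track tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_baf_tsv <- function(baf_track, path) {
  readr::write_tsv(
    baf_track[, c("chrom", "start", "end", "max_baf", "n_het")], path,
    progress = FALSE
  )
  invisible(path)
}

#' Read an RD or truth-depth TSV back into a track tibble
#'
#' Accepts the output of [export_rd_tsv()] or a simulator truth-RD table;
#' reconstructs bin indices from `start` and the inferred bin size.
#'
#' @param path TSV file with at least `chrom`, `start`, `end`.
#' @return Track tibble.
#' @export
read_rd_tsv <- function(path) {
  t <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(t))) {
    data_error("RD TSV needs chrom, start, end columns")
  }
  bs <- max(t$end - t$start)
  t <- t %>% mutate(bin = as.integer(.data$start %/% bs)) %>%
    select("chrom", "bin", dplyr::everything())
  attr(t, "bin_size") <- bs
  t
}

call_colors <- c(deletion = "255,0,0", duplication = "0,0,255", cnnloh = "0,128,0")

#' Export calls as TSV, BED9 or JSON
#'
#' TSV columns mirror the call tibble; BED9 colours events by type (deletion
#' red, duplication blue, cn-LOH green); JSON is an array of call objects.
#'
#' @param calls Calls tibble.
#' @param path Output file.
#' @param format `"tsv"`, `"bed"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_calls <- function(calls, path, format = c("tsv", "bed", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(calls, path, progress = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(calls, path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  } else {
    bed <- sprintf(
      "%s\t%d\t%d\t%s\t%d\t.\t%d\t%d\t%s",
      calls$chrom, as.integer(calls$start), as.integer(calls$end),
      sprintf("%s_cn%.2f_f%s", calls$type, calls$cn,
        ifelse(is.na(calls$cell_fraction), "NA", sprintf("%.3f", calls$cell_fraction))),
      pmin(as.integer(round(-10 * log10(pmax(calls$p_adj, 1e-100)))), 1000L),
      as.integer(calls$start), as.integer(calls$end),
      call_colors[calls$type]
    )
    writeLines(bed, path)
  }
  invisible(path)
}

#' Read a calls TSV
#'
#' @param path TSV written by [export_calls()] or the simulator truth table.
#' @return Calls tibble.
#' @export
read_calls_tsv <- function(path) {
  t <- readr::read_tsv(path,
    progress = FALSE, show_col_types = FALSE,
    # caller tags like "2d" must not be number-guessed
    col_types = readr::cols(
      chrom = readr::col_character(), type = readr::col_character(),
      caller = readr::col_character(), .default = readr::col_guess()
    )
  )
  need <- c("chrom", "start", "end", "type")
  if (!all(need %in% names(t))) data_error("calls TSV needs chrom, start, end, type columns")
  t
}
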