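# internal helpers shared across modules

cnv_error <- function(msg, class) {
  abort(msg, class = c(class, "cnvlite_error"))
}

# usage/configuration errors map to CLI exit 2, data errors to exit 1
usage_error <- function(msg) cnv_error(msg, "cnvlite_usage_error")
data_error <- function(msg) cnv_error(msg, "cnvlite_data_error")

is_autosome <- function(chrom) {
  !grepl("^(chr)?(x|y|m|mt)$", tolower(chrom))
}

# chromosome ordering follows first appearance in the contig map
chrom_levels <- function(contigs) unique(contigs$name)

`%||%` <- function(a, b) if (is.null(a)) b else a

same_grid <- function(a, b) {
  nrow(a) == nrow(b) &&
    all(a$chrom == b$chrom) && all(a$bin == b$bin) &&
    all(a$start == b$start) && all(a$end == b$end)
}

assert_contigs <- function(contigs) {
  if (!all(c("name", "length") %in% names(contigs))) {
    data_error("contig map needs columns `name` and `length`")
  }
  if (anyDuplicated(contigs$name) > 0) data_error("duplicate contig names")
  if (any(contigs$length <= 0)) data_error("contig lengths must be positive")
  invisible(contigs)
}
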