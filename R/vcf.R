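#' Read contig names and lengths from a VCF header
#'
#' Parses `##contig=<ID=...,length=...>` header lines. When the header carries
#' no contig lines, lengths are inferred as the maximum observed position per
#' chromosome and the result is flagged with attribute `inferred = TRUE`.
#'
#' @param vcf Path to a VCF file (plain or gzip/bgzip).
#' @return A tibble with columns `name` and `length`, ordered as in the file.
#' @export
#' @examples
#' \dontrun{
#' contigs <- read_vcf_contigs("sample.vcf")
#' }
read_vcf_contigs <- function(vcf) {
  v <- read_vcfr(vcf)
  meta <- v@meta
  contig_lines <- grep("^##contig=", meta, value = TRUE)
  if (length(contig_lines) > 0) {
    name <- sub('.*[<,]ID=([^,>"]+).*', "\\1", contig_lines)
    len_str <- ifelse(grepl("length=", contig_lines),
      sub(".*length=([0-9]+).*", "\\1", contig_lines), NA_character_
    )
    if (anyNA(len_str)) data_error("##contig line without a length= field")
    out <- tibble(name = name, length = as.numeric(len_str))
    attr(out, "inferred") <- FALSE
    return(assert_contigs(out))
  }
  fix <- v@fix
  if (nrow(fix) == 0) data_error("VCF has no contig header lines and no records")
  pos <- as.numeric(fix[, "POS"])
  chrom <- fix[, "CHROM"]
  out <- tibble(name = chrom, pos = pos) %>%
    group_by(.data$name) %>%
    summarise(length = max(.data$pos), .groups = "drop") %>%
    arrange(match(.data$name, unique(chrom)))
  attr(out, "inferred") <- TRUE
  assert_contigs(out)
}

# read + cache-free wrapper so parse failures surface as data errors
read_vcfr <- function(vcf) {
  if (!file.exists(vcf)) data_error(paste0("VCF not found: ", vcf))
  v <- tryCatch(
    vcfR::read.vcfR(vcf, verbose = FALSE),
    error = function(e) data_error(paste0("cannot parse VCF header/body: ", conditionMessage(e)))
  )
  v
}

#' Extract biallelic SNV depth records from a VCF
#'
#' Streams one sample's GT/DP/AD fields into a variant table, the raw material
#' for both the binned read-depth and BAF signals. Multi-allelic sites, indels
#' and records missing both DP and AD are skipped (counts kept in the
#' `skipped` attribute). When DP is missing or zero, the AD sum stands in for
#' the total depth.
#'
#' @param vcf Path to a VCF file.
#' @param sample Sample name or 1-based column index; default the first sample.
#' @return A tibble with columns `chrom`, `pos` (1-based), `dp`, `ad_ref`,
#'   `ad_alt`, `is_het`, sorted by chromosome (file order) and position.
#'   Attribute `skipped` counts filtered records by reason.
#' @export
read_vcf_variants <- function(vcf, sample = NULL) {
  v <- read_vcfr(vcf)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) data_error("VCF has no sample columns")
  samples <- colnames(gt)[-1]
  sample <- sample %||% samples[[1]]
  if (is.numeric(sample)) {
    if (sample < 1 || sample > length(samples)) {
      usage_error(paste0("sample index ", sample, " out of range (", length(samples), " samples)"))
    }
    sample <- samples[[sample]]
  }
  if (!sample %in% samples) {
    usage_error(paste0(
      "sample '", sample, "' not found; available: ", paste(samples, collapse = ", ")
    ))
  }

  fix <- v@fix
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  multi <- grepl(",", alt, fixed = TRUE)
  snv <- !multi & !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_multi <- sum(multi, na.rm = TRUE)
  n_indel <- sum(!multi & !snv, na.rm = TRUE)

  fmt <- gt[, 1]
  sm <- gt[, sample]

  keep <- which(snv)
  gt_f <- extract_fmt(fmt[keep], sm[keep], "GT")
  dp_f <- suppressWarnings(as.numeric(extract_fmt(fmt[keep], sm[keep], "DP")))
  ad_f <- extract_fmt(fmt[keep], sm[keep], "AD")
  ad_split <- strsplit(ifelse(is.na(ad_f), "", ad_f), ",", fixed = TRUE)
  ad_ref <- suppressWarnings(as.numeric(vapply(ad_split, function(x) if (length(x) >= 1) x[[1]] else NA_character_, "")))
  ad_alt <- suppressWarnings(as.numeric(vapply(ad_split, function(x) if (length(x) >= 2) x[[2]] else NA_character_, "")))

  gt_core <- sub("[:].*$", "", ifelse(is.na(gt_f), "", gt_f))
  is_het <- gt_core %in% c("0/1", "1/0", "0|1", "1|0")

  has_ad <- !is.na(ad_ref) & !is.na(ad_alt)
  has_dp <- !is.na(dp_f)
  ok <- has_ad | has_dp
  n_missing <- sum(!ok)

  dp <- ifelse(has_dp & dp_f > 0, dp_f, ifelse(has_ad, ad_ref + ad_alt, dp_f))

  out <- tibble(
    chrom = chrom[keep][ok],
    pos = pos[keep][ok],
    dp = dp[ok],
    ad_ref = ad_ref[ok],
    ad_alt = ad_alt[ok],
    is_het = is_het[ok]
  )
  out <- out[order(match(out$chrom, unique(out$chrom)), out$pos), ]
  attr(out, "sample") <- sample
  attr(out, "skipped") <- c(multiallelic = n_multi, indel = n_indel, missing_depth = n_missing)
  out
}

# pull one FORMAT key from per-record FORMAT strings; NA where absent/malformed
extract_fmt <- function(fmt, sm, key) {
  fmt_keys <- strsplit(fmt, ":", fixed = TRUE)
  sm_vals <- strsplit(ifelse(is.na(sm), "", sm), ":", fixed = TRUE)
  vapply(seq_along(fmt_keys), function(i) {
    j <- match(key, fmt_keys[[i]])
    if (is.na(j) || j > length(sm_vals[[i]])) return(NA_character_)
    val <- sm_vals[[i]][[j]]
    if (identical(val, ".") || identical(val, "")) NA_character_ else val
  }, "")
}

#' Write a minimal GT:DP:AD VCF
#'
#' Emits a valid VCF 4.2 holding only the information the depth/BAF pipeline
#' consumes: `##contig` header lines and per-record GT, DP and AD. Reading the
#' file back with [read_vcf_variants()] reproduces the input table exactly.
#'
#' @param variants Tibble with `chrom`, `pos`, `dp`, `ad_ref`, `ad_alt`,
#'   `is_het`, sorted by (chromosome, position).
#' @param contigs Contig map tibble (`name`, `length`).
#' @param path Output file path.
#' @param sample Sample column name. Default `"SAMPLE"`.
#' @return `path`, invisibly.
#' @export
write_minimal_vcf <- function(variants, contigs, path, sample = "SAMPLE") {
  assert_contigs(contigs)
  if (nrow(variants) > 0) {
    ord <- order(match(variants$chrom, contigs$name), variants$pos)
    if (!identical(ord, seq_len(nrow(variants)))) {
      data_error("variants must be sorted by (chrom, pos) before writing")
    }
    if (!all(variants$chrom %in% contigs$name)) {
      data_error("variant chromosome absent from contig map")
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contigs$name, as.integer(contigs$length)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  lines <- header
  if (nrow(variants) > 0) {
    gt <- ifelse(variants$is_het, "0/1", ifelse(variants$ad_alt >= variants$ad_ref, "1/1", "0/0"))
    body <- sprintf(
      "%s\t%d\t.\tA\tC\t.\tPASS\t.\tGT:DP:AD\t%s:%d:%d,%d",
      variants$chrom, as.integer(variants$pos), gt,
      as.integer(variants$dp), as.integer(variants$ad_ref), as.integer(variants$ad_alt)
    )
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}
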