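# fixture builders shared across test files; everything generated in code

# a CN track over one chromosome from a bare numeric vector (NA = masked bin)
mk_cn_track <- function(x, bin_size = 1e5, chrom = "chr1", n_var = 10L) {
  n <- length(x)
  t <- tibble::tibble(
    chrom = chrom, bin = 0:(n - 1),
    start = (0:(n - 1)) * bin_size, end = (1:n) * bin_size,
    raw = x, corrected = x,
    n_var = ifelse(is.na(x), 0L, n_var),
    cn = x
  )
  attr(t, "bin_size") <- bin_size
  t
}

mk_contigs <- function(len = 1e6, name = "chr1") tibble::tibble(name = name, length = len)

# write a small VCF from header + body lines
write_vcf_lines <- function(body, contig_lines = "##contig=<ID=chr1,length=1000000>",
                            sample = "S1") {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    contig_lines,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", paste(sample, collapse = "\t")),
    body
  ), path)
  path
}

# exhaustive least-squares single-breakpoint oracle
ls_breakpoint_oracle <- function(x) {
  n <- length(x)
  best <- c(Inf, NA)
  for (b in 1:(n - 1)) {
    sse <- sum((x[1:b] - mean(x[1:b]))^2) + sum((x[(b + 1):n] - mean(x[(b + 1):n]))^2)
    if (sse < best[[1]]) best <- c(sse, b)
  }
  best[[2]]
}
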