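# Desk-scale replication experiments: VCF-derived versus alignment-like
# signals and calls, on simulated samples. These wrap the full pipeline
# (simulate -> minimal VCF -> ingest -> bin -> call -> compare) so the
# concordance surfaces can be recomputed from scratch with one call.

#' VCF-vs-truth read-depth concordance on a neutral genome
#'
#' Simulates a diploid (event-free) chromosome, writes and re-reads the
#' minimal VCF, bins the DP field, converts to CN units and compares per bin
#' against the alignment-like truth depth track.
#'
#' @param seed Simulation seed.
#' @param length Chromosome length in bp (default 50 Mb).
#' @param coverage Mean depth (default 30).
#' @param snp_spacing Mean het-site spacing in bp (default 1500).
#' @param bin_size Bin width (default 10 kb).
#' @return One-row tibble from [rd_difference_stats()] plus `seed`.
#' @export
rd_concordance_experiment <- function(seed, length = 50e6, coverage = 30,
                                      snp_spacing = 1500, bin_size = 10000) {
  contigs <- tibble(name = "chr1", length = length)
  spec <- sample_spec(contigs,
    coverage = coverage, snp_spacing = snp_spacing,
    seed = seed, truth_bin_size = bin_size
  )
  sim <- simulate_sample(spec)
  vcf <- tempfile(fileext = ".vcf")
  on.exit(unlink(vcf))
  write_minimal_vcf(sim$variants, contigs, vcf)
  vars <- read_vcf_variants(vcf)
  cg <- read_vcf_contigs(vcf)
  cn_vcf <- to_copy_number(bin_read_depth(vars, cg, bin_size))
  stats <- rd_difference_stats(cn_vcf, sim$truth_rd)
  dplyr::bind_cols(tibble(seed = seed), stats)
}

# non-overlapping clonal events drawn for one simulated sample: sizes uniform
# in [min_size, max_size], types cycled through the three models, placed
# left-to-right with random gaps
draw_events <- function(seed, genome_length, n_events = 10,
                        min_size = 1e6, max_size = 10e6) {
  withr::with_seed(seed, {
    sizes <- stats::runif(n_events, min_size, max_size)
    types <- sample(rep(c("deletion", "duplication", "cnnloh"), length.out = n_events))
    slack <- genome_length - sum(sizes)
    if (slack <= n_events) data_error("events do not fit the genome")
    gaps <- as.numeric(stats::rmultinom(1, size = floor(slack), prob = rep(1, n_events + 1)))
    starts <- cumsum(gaps[seq_len(n_events)]) + c(0, cumsum(sizes[-n_events]))
    tibble(
      chrom = "chr1", start = floor(starts), end = floor(starts + sizes),
      type = types, f = 1
    )
  })
}

#' VCF-vs-truth call concordance on one simulated sample
#'
#' Simulates a genome carrying clonal CNV/CNA events, then runs the 2D caller
#' twice — once on the VCF-derived binned depth, once on the alignment-like
#' truth depth (same BAF track) — and matches the two call sets by reciprocal
#' overlap, with the truth-depth calls as reference.
#'
#' @param seed Simulation seed (also drives event placement).
#' @param genome_length Genome size in bp (single chromosome; default 100 Mb).
#' @param n_events Number of clonal events (default 10, mixed types, 1–10 Mb).
#' @param coverage Mean depth (default 30).
#' @param bin_size Bin width (default 100 kb).
#' @param min_reciprocal_overlap Match threshold (default 0.5).
#' @return List: `report` ([match_calls()] result), `calls_vcf`, `calls_truth`,
#'   `events`.
#' @export
call_concordance_experiment <- function(seed, genome_length = 100e6, n_events = 10,
                                        coverage = 30, bin_size = 1e5,
                                        min_reciprocal_overlap = 0.5) {
  contigs <- tibble(name = "chr1", length = genome_length)
  events <- draw_events(seed * 2 + 1, genome_length, n_events)
  spec <- sample_spec(contigs,
    coverage = coverage, events = events, seed = seed,
    truth_bin_size = bin_size
  )
  sim <- simulate_sample(spec)
  vcf <- tempfile(fileext = ".vcf")
  on.exit(unlink(vcf))
  write_minimal_vcf(sim$variants, contigs, vcf)
  vars <- read_vcf_variants(vcf)
  cg <- read_vcf_contigs(vcf)
  cn_vcf <- to_copy_number(bin_read_depth(vars, cg, bin_size))
  baf <- bin_baf(vars, cg, bin_size)
  fit_vcf <- call_2d(cn_vcf, baf)
  fit_truth <- call_2d(sim$truth_rd, baf)
  report <- match_calls(tidy(fit_truth), tidy(fit_vcf), min_reciprocal_overlap)
  list(
    report = report, calls_vcf = tidy(fit_vcf), calls_truth = tidy(fit_truth),
    events = events
  )
}

#' Recover the cell fraction of a single subclonal duplication
#'
#' Simulates one subclonal duplication, ingests the VCF, runs the 2D caller
#' and returns the cell fraction of the call best overlapping the true event.
#'
#' @param seed Simulation seed.
#' @param f True cell fraction (default 0.06).
#' @param coverage Mean depth (default 80).
#' @param genome_length Contig size (default 40 Mb).
#' @param event_start,event_length Event placement (default 10 Mb at 20 Mb).
#' @param bin_size Bin width (default 100 kb).
#' @return List: `f_hat`, `call` (one-row tibble or NULL), `fit`.
#' @export
subclone_recovery_experiment <- function(seed, f = 0.06, coverage = 80,
                                         genome_length = 40e6,
                                         event_start = 20e6, event_length = 10e6,
                                         bin_size = 1e5) {
  contigs <- tibble(name = "chr1", length = genome_length)
  events <- tibble(
    chrom = "chr1", start = event_start, end = event_start + event_length,
    type = "duplication", f = f
  )
  spec <- sample_spec(contigs, coverage = coverage, events = events, seed = seed)
  sim <- simulate_sample(spec)
  vcf <- tempfile(fileext = ".vcf")
  on.exit(unlink(vcf))
  write_minimal_vcf(sim$variants, contigs, vcf)
  vars <- read_vcf_variants(vcf)
  cg <- read_vcf_contigs(vcf)
  cn <- to_copy_number(bin_read_depth(vars, cg, bin_size))
  baf <- bin_baf(vars, cg, bin_size)
  fit <- call_2d(cn, baf)
  calls <- tidy(fit)
  if (nrow(calls) == 0) return(list(f_hat = NA_real_, call = NULL, fit = fit))
  ov <- pmax(0, pmin(calls$end, events$end) - pmax(calls$start, events$start))
  best <- which.max(ov)
  if (ov[[best]] <= 0) return(list(f_hat = NA_real_, call = NULL, fit = fit))
  list(f_hat = calls$cell_fraction[[best]], call = calls[best, ], fit = fit)
}
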