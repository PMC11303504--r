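# Synthetic-sample generator.
#
# Emulates what a germline variant caller leaves behind in a whole-genome VCF:
# variant sites spaced with exponential gaps, per-site total depth Poisson
# around the local copy-number-scaled coverage, and per-site alt counts
# binomial around the local allele fraction, with the event-carrying
# haplotype assigned at random per site (unphased realism, which is what
# makes the folded BAF split symmetric). Alongside the VCF-style variant
# table it produces an alignment-like truth read-depth track whose variance
# is reduced by the reads-per-bin sampling factor (read_length / bin_size):
# reads tile a bin densely whereas variants sample it sparsely, and that
# variance gap is precisely what the VCF-vs-alignment concordance measures.

#' Build a simulation recipe
#'
#' @param contigs Contig map tibble (`name`, `length`).
#' @param coverage Mean diploid depth (e.g. 30).
#' @param snp_spacing Mean spacing between heterozygous sites, bp (default
#'   1500; gaps are exponential). All variant sites together are denser by the
#'   factor `1/(1 - hom_fraction)`.
#' @param hom_fraction Fraction of variant sites that are hom-alt (default
#'   1/3). Hom sites contribute depth but no BAF information.
#' @param read_length Read length in bp (150); sets the truth-RD noise scale.
#' @param events Tibble of CNV/CNA events: `chrom`, `start`, `end` (0-based
#'   half-open bp), `type` (`deletion`/`duplication`/`cnnloh`), `f` cell
#'   fraction in (0, 1]. Must not overlap within a chromosome.
#' @param seed RNG seed (integer below 2^31).
#' @param truth_bin_size Grid of the truth RD track (default 10000).
#' @param overdispersion Extra depth noise: dp is negative binomial with this
#'   coefficient of overdispersion when > 0, Poisson when 0 (default).
#' @return A validated `sample_spec` list.
#' @export
sample_spec <- function(contigs, coverage = 30, snp_spacing = 1500,
                        hom_fraction = 1 / 3, read_length = 150,
                        events = NULL, seed = 1, truth_bin_size = 10000,
                        overdispersion = 0) {
  contigs <- as_tibble(contigs)
  assert_contigs(contigs)
  events <- if (is.null(events) || nrow(events) == 0) {
    tibble(chrom = character(), start = numeric(), end = numeric(), type = character(), f = numeric())
  } else {
    as_tibble(events)
  }
  problems <- character()
  if (coverage <= 0) problems <- c(problems, "coverage must be positive")
  if (snp_spacing <= 0) problems <- c(problems, "snp_spacing must be positive")
  if (hom_fraction < 0 || hom_fraction >= 1) problems <- c(problems, "hom_fraction must be in [0, 1)")
  if (abs(seed) >= 2^31) problems <- c(problems, "seed must fit a 32-bit integer")
  if (nrow(events) > 0) {
    if (!all(events$type %in% c("deletion", "duplication", "cnnloh"))) {
      problems <- c(problems, "event types must be deletion/duplication/cnnloh")
    }
    if (any(events$f <= 0 | events$f > 1)) problems <- c(problems, "event cell fractions must be in (0, 1]")
    if (!all(events$chrom %in% contigs$name)) problems <- c(problems, "event chromosome not in contig map")
    if (any(events$end <= events$start)) problems <- c(problems, "event end must exceed start")
    # clamp to contig bounds, then check pairwise overlap per chromosome
    lens <- setNames(contigs$length, contigs$name)
    events <- events %>%
      mutate(start = pmax(.data$start, 0), end = pmin(.data$end, lens[.data$chrom])) %>%
      arrange(match(.data$chrom, contigs$name), .data$start)
    ovl <- events %>%
      group_by(.data$chrom) %>%
      summarise(bad = any(lead(.data$start) < .data$end, na.rm = TRUE), .groups = "drop")
    if (any(ovl$bad)) problems <- c(problems, "events overlap within a chromosome")
  }
  if (length(problems) > 0) {
    data_error(paste0("invalid sample spec:\n- ", paste(problems, collapse = "\n- ")))
  }
  structure(
    list(
      contigs = contigs, coverage = coverage, snp_spacing = snp_spacing,
      hom_fraction = hom_fraction, read_length = read_length,
      events = events, seed = as.integer(seed),
      truth_bin_size = truth_bin_size, overdispersion = overdispersion
    ),
    class = "sample_spec"
  )
}

#' Local copy-number state at a position
#'
#' Total copy number and minor-allele fraction implied by the event (if any)
#' covering a position at cell fraction `f`: neutral (2, 0.5); deletion
#' (2 - f, (1 - f)/(2 - f)); duplication (2 + f, 1/(2 + f)); copy-neutral LOH
#' (2, (1 - f)/2).
#'
#' @param chrom,pos Chromosome and 1-based position(s).
#' @param events Event tibble as in [sample_spec()].
#' @return Tibble with `total_cn` and `minor_fraction`, one row per position.
#' @export
local_state <- function(chrom, pos, events) {
  total_cn <- rep(2, length(pos))
  minor <- rep(0.5, length(pos))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    hit <- chrom == e$chrom & (pos - 1) >= e$start & (pos - 1) < e$end
    if (!any(hit)) next
    st <- state_of(e$type, e$f)
    total_cn[hit] <- st[[1]]
    minor[hit] <- st[[2]]
  }
  tibble(total_cn = total_cn, minor_fraction = minor)
}

state_of <- function(type, f) {
  switch(type,
    deletion = c(2 - f, (1 - f) / (2 - f)),
    duplication = c(2 + f, 1 / (2 + f)),
    cnnloh = c(2, (1 - f) / 2),
    data_error(paste0("unknown event type: ", type))
  )
}

#' Simulate a sample: variants plus ground truth
#'
#' Draws variant positions, depths and allele depths per the spec, along with
#' an alignment-like truth RD track and the truth call table. Fully
#' reproducible: the same spec (including seed) gives identical output.
#'
#' @param spec A [sample_spec()].
#' @return List of class `cnv_sim`: `variants` (tibble as from
#'   [read_vcf_variants()]), `truth_rd` (tibble `chrom`, `bin`, `start`,
#'   `end`, `cn` in CN units on the `truth_bin_size` grid), `truth_calls`
#'   (event table in call format), and the `spec`.
#' @export
simulate_sample <- function(spec) {
  stopifnot(inherits(spec, "sample_spec"))
  withr::with_seed(spec$seed, {
    variants <- purrr::map_dfr(seq_len(nrow(spec$contigs)), function(ci) {
      simulate_contig(spec, spec$contigs$name[[ci]], spec$contigs$length[[ci]])
    })
    truth_rd <- simulate_truth_rd(spec)
  })
  truth_calls <- spec$events %>%
    mutate(
      cn = purrr::map2_dbl(.data$type, .data$f, ~ state_of(.x, .y)[[1]]),
      cell_fraction = .data$f, p_adj = NA_real_, caller = "truth", bin_size = NA_real_
    ) %>%
    select("chrom", "start", "end", "type", "cn", "cell_fraction", "p_adj", "caller", "bin_size")
  structure(
    list(variants = variants, truth_rd = truth_rd, truth_calls = truth_calls, spec = spec),
    class = "cnv_sim"
  )
}

simulate_contig <- function(spec, name, len) {
  gap_mean <- spec$snp_spacing * (1 - spec$hom_fraction)
  n_target <- ceiling(len / gap_mean * 1.2) + 100
  gaps <- rexp(n_target, rate = 1 / gap_mean)
  pos <- cumsum(gaps)
  while (length(pos) > 0 && max(pos) < len) {
    gaps <- rexp(n_target, rate = 1 / gap_mean)
    pos <- c(pos, max(pos) + cumsum(gaps))
  }
  pos <- unique(pmax(1, floor(pos[pos <= len - 1])))
  n <- length(pos)
  if (n == 0) {
    return(tibble(
      chrom = character(), pos = numeric(), dp = numeric(),
      ad_ref = numeric(), ad_alt = numeric(), is_het = logical()
    ))
  }
  hom <- stats::runif(n) < spec$hom_fraction
  st <- local_state(rep(name, n), pos, spec$events)
  mu <- spec$coverage * st$total_cn / 2
  dp <- if (spec$overdispersion > 0) {
    rnbinom(n, size = 1 / spec$overdispersion, mu = mu)
  } else {
    rpois(n, mu)
  }
  # which parental haplotype carries the alt allele, i.i.d. per site
  alt_on_minor <- stats::runif(n) < 0.5
  q <- ifelse(alt_on_minor, st$minor_fraction, 1 - st$minor_fraction)
  ad_alt <- ifelse(hom, dp, rbinom(n, dp, q))
  tibble(
    chrom = name, pos = pos, dp = as.numeric(dp),
    ad_ref = as.numeric(dp - ad_alt), ad_alt = as.numeric(ad_alt),
    is_het = !hom
  )
}

simulate_truth_rd <- function(spec) {
  grid <- full_grid(spec$contigs, spec$truth_bin_size)
  # overlap-weighted mean total CN per bin, piecewise from the event table
  cn_bar <- rep(2, nrow(grid))
  for (i in seq_len(nrow(spec$events))) {
    e <- spec$events[i, ]
    ov <- pmax(0, pmin(grid$end, e$end) - pmax(grid$start, e$start))
    hit <- grid$chrom == e$chrom & ov > 0
    cn_ev <- state_of(e$type, e$f)[[1]]
    wid <- grid$end - grid$start
    cn_bar[hit] <- cn_bar[hit] + (cn_ev - 2) * ov[hit] / wid[hit]
  }
  mu <- spec$coverage * cn_bar / 2
  sd <- sqrt(mu * spec$read_length / (grid$end - grid$start))
  depth <- pmax(rnorm(nrow(grid), mu, sd), 0)
  out <- grid %>% mutate(cn = depth * 2 / spec$coverage)
  attr(out, "bin_size") <- spec$truth_bin_size
  out
}

#' Write simulator outputs to files
#'
#' Emits `<prefix>.vcf` (minimal GT:DP:AD VCF), `<prefix>_truth_rd.tsv`
#' (`chrom start end cn`) and `<prefix>_truth_calls.tsv`.
#'
#' @param sim A `cnv_sim` from [simulate_sample()].
#' @param prefix Output path prefix.
#' @param sample Sample name in the VCF.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_simulation <- function(sim, prefix, sample = "SIM") {
  stopifnot(inherits(sim, "cnv_sim"))
  vcf <- paste0(prefix, ".vcf")
  rd <- paste0(prefix, "_truth_rd.tsv")
  calls <- paste0(prefix, "_truth_calls.tsv")
  write_minimal_vcf(sim$variants, sim$spec$contigs, vcf, sample = sample)
  readr::write_tsv(sim$truth_rd[, c("chrom", "start", "end", "cn")], rd, progress = FALSE)
  readr::write_tsv(sim$truth_calls, calls, progress = FALSE)
  invisible(c(vcf = vcf, truth_rd = rd, truth_calls = calls))
}

#' Read a sample spec from JSON
#'
#' Expected shape: `contigs` as an object of name to length, scalar fields as
#' in [sample_spec()], and `events` as an array of objects with `chrom`,
#' `start`, `end`, `type`, `f`.
#'
#' @param path JSON file.
#' @return A `sample_spec`.
#' @export
read_sample_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  contigs <- tibble(name = names(j$contigs), length = as.numeric(unlist(j$contigs)))
  events <- if (!is.null(j$events) && length(j$events) > 0) as_tibble(j$events) else NULL
  sample_spec(
    contigs = contigs,
    coverage = j$coverage %||% 30,
    snp_spacing = j$snp_spacing %||% 1500,
    hom_fraction = j$hom_fraction %||% (1 / 3),
    read_length = j$read_length %||% 150,
    events = events,
    seed = j$seed %||% 1,
    truth_bin_size = j$truth_bin_size %||% 10000,
    overdispersion = j$overdispersion %||% 0
  )
}
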