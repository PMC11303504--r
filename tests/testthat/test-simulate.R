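test_that("local event state follows the mixture formulas", {
  events <- tibble::tibble(
    chrom = "chr1", start = c(1000, 5000), end = c(2000, 6000),
    type = c("deletion", "duplication"), f = c(1, 0.5)
  )
  st <- local_state(rep("chr1", 4), c(500, 1500, 5500, 9000), events)
  expect_equal(st$total_cn, c(2, 1, 2.5, 2))
  expect_equal(st$minor_fraction, c(0.5, 0, 0.4, 0.5))

  loh <- tibble::tibble(chrom = "chr1", start = 0, end = 100, type = "cnnloh", f = 0.3)
  st2 <- local_state("chr1", 50, loh)
  expect_equal(st2$total_cn, 2)
  expect_equal(st2$minor_fraction, 0.35)
})

test_that("invalid specs are rejected with a list of violations", {
  contigs <- mk_contigs(1e6)
  overlapping <- tibble::tibble(
    chrom = "chr1", start = c(0, 5e4), end = c(1e5, 2e5),
    type = c("deletion", "duplication"), f = c(1, 1)
  )
  expect_error(sample_spec(contigs, events = overlapping), "overlap")
  bad_f <- tibble::tibble(chrom = "chr1", start = 0, end = 100, type = "deletion", f = 1.5)
  expect_error(sample_spec(contigs, events = bad_f), "cell fraction")
  expect_error(sample_spec(contigs, coverage = -1), "coverage")
  expect_error(
    sample_spec(contigs, events = tibble::tibble(
      chrom = "chr9", start = 0, end = 100, type = "deletion", f = 1
    )),
    "contig"
  )
})

test_that("simulation is deterministic: same spec and seed give identical bytes", {
  contigs <- mk_contigs(2e6)
  ev <- tibble::tibble(chrom = "chr1", start = 5e5, end = 1e6, type = "duplication", f = 0.5)
  spec <- sample_spec(contigs, coverage = 20, events = ev, seed = 77)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_simulation(simulate_sample(spec), f1)
  write_simulation(simulate_sample(spec), f2)
  expect_identical(
    readLines(paste0(f1, ".vcf")),
    readLines(paste0(f2, ".vcf"))
  )
  expect_identical(
    readLines(paste0(f1, "_truth_rd.tsv")),
    readLines(paste0(f2, "_truth_rd.tsv"))
  )
})

test_that("simulated depths and allele fractions follow their laws", {
  contigs <- mk_contigs(10e6)
  sim <- simulate_sample(sample_spec(contigs, coverage = 30, seed = 11))
  v <- sim$variants
  expect_equal(mean(v$dp), 30, tolerance = 0.01 * 30)
  het <- v[v$is_het & v$dp > 0, ]
  expect_equal(mean(het$ad_alt / het$dp), 0.5, tolerance = 0.01)
  # het spacing has the requested mean
  expect_equal(mean(diff(het$pos)), 1500, tolerance = 0.05 * 1500)
  # hom sites carry only alt reads
  hom <- v[!v$is_het, ]
  expect_true(all(hom$ad_alt == hom$dp))
  expect_equal(nrow(hom) / nrow(v), 1 / 3, tolerance = 0.05)
})

test_that("clonal cnnloh pushes bin BAF to the boundary", {
  contigs <- mk_contigs(5e6)
  ev <- tibble::tibble(chrom = "chr1", start = 0, end = 5e6, type = "cnnloh", f = 1)
  sim <- simulate_sample(sample_spec(contigs, coverage = 30, events = ev, seed = 12))
  baf <- bin_baf(sim$variants, contigs, 1e5)
  expect_true(all(baf$max_baf[baf$n_het > 0] <= 0.05))
})

test_that("clonal deletion halves the depth at its het sites", {
  contigs <- mk_contigs(10e6)
  ev <- tibble::tibble(chrom = "chr1", start = 2e6, end = 8e6, type = "deletion", f = 1)
  sim <- simulate_sample(sample_spec(contigs, coverage = 30, events = ev, seed = 13))
  inside <- sim$variants[sim$variants$pos > 2e6 & sim$variants$pos <= 8e6, ]
  expect_equal(mean(inside$dp), 15, tolerance = 0.02 * 15)
  # truth track mirrors the event in CN units
  tr <- sim$truth_rd
  in_bins <- tr$start >= 2e6 & tr$end <= 8e6
  expect_equal(mean(tr$cn[in_bins]), 1, tolerance = 0.02)
  expect_equal(mean(tr$cn[!in_bins]), 2, tolerance = 0.02)
  # truth calls mirror the event table
  expect_equal(sim$truth_calls$type, "deletion")
  expect_equal(sim$truth_calls$cn, 1)
})

test_that("sample specs round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    contigs = list(chr1 = 2e6, chr2 = 1e6),
    coverage = 25, snp_spacing = 1200, seed = 5,
    events = list(list(chrom = "chr2", start = 1e5, end = 6e5, type = "cnnloh", f = 0.4))
  ), path, auto_unbox = TRUE)
  spec <- read_sample_spec(path)
  expect_equal(spec$contigs$name, c("chr1", "chr2"))
  expect_equal(spec$coverage, 25)
  expect_equal(spec$events$type, "cnnloh")
  expect_equal(spec$events$f, 0.4)
})
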