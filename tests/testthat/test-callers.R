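test_that("RD caller types segments by CN shift with Bonferroni-tested significance", {
  withr::with_seed(51, {
    x <- c(rnorm(100, 2, 0.1), rnorm(50, 1, 0.1), rnorm(50, 2, 0.1))
  })
  t <- mk_cn_track(x)
  fit <- call_cnv(t, method = "rd")
  calls <- tidy(fit)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "deletion")
  expect_equal(calls$cell_fraction, 1, tolerance = 0.1)
  expect_equal(calls$caller, "rd")

  # below min_cn_shift: no call even if significant
  segs <- tibble::tibble(
    chrom = "chr1", bin_start = 0L, bin_end = 100L,
    n_bins = 100L, cn_mean = 2.05
  )
  expect_equal(nrow(call_rd(segs, mk_cn_track(rep(2.05, 100)), caller_params(sigma_cn = 0.1))), 0)

  # large shift but hopeless significance: 3 noisy bins cannot reject
  noisy <- mk_cn_track(c(2.4, 3.6, 3.0, rep(2, 97)))
  segs3 <- tibble::tibble(
    chrom = "chr1", bin_start = 0L, bin_end = 3L, n_bins = 3L, cn_mean = 3.0
  )
  expect_equal(nrow(call_rd(segs3, noisy, caller_params(sigma_cn = 0.5))), 0)

  # multi-copy amplification: cell fraction not estimable from RD alone
  amp <- mk_cn_track(c(rep(6, 50), rep(2, 150)))
  fit_amp <- call_cnv(amp, method = "rd", params = caller_params(sigma_cn = 0.05))
  amp_calls <- tidy(fit_amp)
  expect_equal(amp_calls$type[[1]], "duplication")
  expect_true(is.na(amp_calls$cell_fraction[[1]]))
})

test_that("genotyping inverts the mixture formulas and respects the neutral guard", {
  g <- genotype_segment(1.0, 0.0, 0.05, 0.02)
  expect_equal(g$type, "deletion")
  expect_equal(g$f, 1, tolerance = 0.005)

  expect_equal(genotype_segment(2.0, 0.5, 0.05, 0.02)$type, "neutral")

  # the ~6% subclonal duplication from the use-case regime
  g6 <- genotype_segment(2.06, 1 / 2.06, 0.005, 0.01)
  expect_equal(g6$type, "duplication")
  expect_equal(g6$f, 0.06, tolerance = 0.005)
})

test_that("genotype round trip recovers every model and cell fraction", {
  models <- list(
    deletion = function(f) c(2 - f, (1 - f) / (2 - f)),
    duplication = function(f) c(2 + f, 1 / (2 + f)),
    cnnloh = function(f) c(2, (1 - f) / 2)
  )
  for (type in names(models)) {
    for (f in seq(0.1, 1, by = 0.1)) {
      truth <- models[[type]](f)
      g <- genotype_segment(truth[[1]], truth[[2]], 0.05, 0.02)
      expect_equal(g$type, type, info = sprintf("%s f=%.1f", type, f))
      expect_equal(g$f, f, tolerance = 0.005)
    }
  }
})

# quick simulated tracks for the 2D merge: n bins, given minor fraction per half
sim_2d_tracks <- function(cn_levels, q_levels, n_bins = 100, het_per_bin = 100,
                          depth = 30, sigma = 0.1, seed = 5) {
  withr::with_seed(seed, {
    half <- n_bins / 2
    cn <- c(rnorm(half, cn_levels[[1]], sigma), rnorm(half, cn_levels[[2]], sigma))
    t <- mk_cn_track(cn)
    qs <- rep(q_levels, each = half)
    curves <- lapply(seq_len(n_bins), function(i) {
      q <- qs[[i]]
      site_q <- ifelse(stats::runif(het_per_bin) < 0.5, q, 1 - q)
      dp <- rpois(het_per_bin, depth)
      dp[dp == 0] <- 1
      alt <- rbinom(het_per_bin, dp, site_q)
      bin_baf_likelihood(dp - alt, alt)
    })
    baf <- tibble::tibble(
      chrom = "chr1", bin = 0:(n_bins - 1),
      start = t$start, end = t$end,
      n_het = het_per_bin,
      max_baf = purrr::map_dbl(curves, max_baf),
      curve = curves
    )
    attr(baf, "bin_size") <- attr(t, "bin_size")
    attr(baf, "G") <- 101
    list(cn = t, baf = baf)
  })
}

test_that("2D merge splits on either signal and stays whole when homogeneous", {
  hom <- sim_2d_tracks(c(2, 2), c(0.5, 0.5), seed = 6)
  expect_equal(nrow(merge_2d(hom$cn, hom$baf, caller_params(sigma_cn = 0.1))), 1)

  baf_only <- sim_2d_tracks(c(2, 2), c(0.5, 0.2), seed = 7)
  segs_b <- merge_2d(baf_only$cn, baf_only$baf, caller_params(sigma_cn = 0.1))
  expect_equal(nrow(segs_b), 2)
  expect_equal(segs_b$bin_end[[1]], 50, tolerance = 1)

  rd_only <- sim_2d_tracks(c(2, 3), c(0.5, 0.5), seed = 8)
  segs_r <- merge_2d(rd_only$cn, rd_only$baf, caller_params(sigma_cn = 0.1))
  expect_equal(nrow(segs_r), 2)
  expect_equal(segs_r$bin_end[[1]], 50, tolerance = 1)
})

test_that("2D segments tile the unmasked bins and the merge distance is sane", {
  tr <- sim_2d_tracks(c(2, 3), c(0.5, 1 / 3), seed = 9)
  tr$cn$cn[c(10, 40, 41)] <- NA
  segs <- merge_2d(tr$cn, tr$baf, caller_params(sigma_cn = 0.1))
  expect_equal(sum(segs$n_bins), sum(!is.na(tr$cn$cn)))
  # distance symmetry and positivity on non-identical segments
  d12 <- cnvlite:::merge2d_distance(
    segs$cn_mean[[1]], segs$cn_mean[[2]], segs$n_bins[[1]], segs$n_bins[[2]],
    0.1, segs$curve[[1]], segs$curve[[2]], segs$n_het[[1]], segs$n_het[[2]]
  )
  d21 <- cnvlite:::merge2d_distance(
    segs$cn_mean[[2]], segs$cn_mean[[1]], segs$n_bins[[2]], segs$n_bins[[1]],
    0.1, segs$curve[[2]], segs$curve[[1]], segs$n_het[[2]], segs$n_het[[1]]
  )
  expect_equal(d12, d21)
  expect_gt(d12, 0)
})

test_that("end-to-end 2D calling finds clonal events and stays silent on diploid data", {
  contigs <- mk_contigs(20e6)

  run_case <- function(events, seed) {
    sim <- simulate_sample(sample_spec(contigs, coverage = 30, events = events, seed = seed))
    rd <- bin_read_depth(sim$variants, contigs, 1e5)
    cn <- to_copy_number(rd)
    baf <- bin_baf(sim$variants, contigs, 1e5)
    call_2d(cn, baf)
  }

  ev_del <- tibble::tibble(chrom = "chr1", start = 5e6, end = 10e6, type = "deletion", f = 1)
  calls <- tidy(run_case(ev_del, 42))
  dels <- calls[calls$type == "deletion", ]
  expect_equal(nrow(dels), 1)
  ov <- min(dels$end, 10e6) - max(dels$start, 5e6)
  expect_gte(ov / 5e6, 0.9)
  expect_gte(ov / (dels$end - dels$start), 0.9)

  ev_loh <- tibble::tibble(chrom = "chr1", start = 5e6, end = 10e6, type = "cnnloh", f = 1)
  calls_loh <- tidy(run_case(ev_loh, 43))
  loh <- calls_loh[calls_loh$type == "cnnloh", ]
  expect_equal(nrow(loh), 1)
  expect_equal(loh$cn, 2, tolerance = 0.1)

  flat <- tidy(run_case(NULL, 44))
  expect_equal(nrow(flat), 0)
})

test_that("the 2D entry point falls back to the RD caller without a BAF track", {
  withr::with_seed(52, x <- c(rnorm(60, 1, 0.1), rnorm(140, 2, 0.1)))
  expect_warning(fit <- call_2d(mk_cn_track(x), NULL), "falling back")
  expect_equal(fit$caller, "rd")
  expect_equal(tidy(fit)$type, "deletion")
})

test_that("fit accessors expose calls and a one-row summary", {
  withr::with_seed(53, x <- rnorm(200, 2, 0.1))
  fit <- call_cnv(mk_cn_track(x), method = "rd")
  g <- glance(fit)
  expect_equal(g$caller, "rd")
  expect_equal(g$n_bins, 200L)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_output(print(fit), "cnv_fit")
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
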