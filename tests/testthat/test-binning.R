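mk_vars <- function(pos, dp, chrom = "chr1") {
  tibble::tibble(
    chrom = chrom, pos = pos, dp = dp,
    ad_ref = floor(dp / 2), ad_alt = ceiling(dp / 2), is_het = TRUE
  )
}

test_that("binned depth is the mean DP per bin, with the floor((p-1)/size) boundary rule", {
  contigs <- mk_contigs(35000)
  vars <- mk_vars(c(1000, 2000, 3000, 10000, 25000), c(28, 30, 32, 40, 50))
  rd <- bin_read_depth(vars, contigs, 10000)
  expect_equal(nrow(rd), 4) # last bin short (30k..35k)
  # pos 10000 belongs to bin 0: floor(9999/10000)
  expect_equal(rd$raw[[1]], mean(c(28, 30, 32, 40)))
  expect_equal(rd$n_var[[1]], 4L)
  expect_true(is.na(rd$raw[[2]])) # no variants -> masked
  expect_equal(rd$n_var[[2]], 0L)
  expect_equal(rd$raw[[3]], 50)
  expect_error(
    bin_read_depth(mk_vars(40000, 30), contigs, 10000),
    "beyond contig length"
  )
})

test_that("global depth is the median over unmasked autosomal bins", {
  t <- mk_cn_track(c(10, 30, 50))
  expect_equal(global_depth(t), 30)
  expect_equal(global_depth(mk_cn_track(rep(30, 5))), 30)
  expect_equal(global_depth(mk_cn_track(42)), 42)
  # sex chromosomes excluded when autosomes exist
  t2 <- dplyr::bind_rows(mk_cn_track(c(30, 30)), mk_cn_track(c(15, 15), chrom = "chrX"))
  expect_equal(global_depth(t2), 30)
  expect_error(global_depth(mk_cn_track(c(NA_real_, NA_real_))), class = "cnvlite_data_error")
})

test_that("copy-number conversion scales diploid depth to 2 and preserves masks", {
  t <- mk_cn_track(c(30, 45, NA))
  cn <- to_copy_number(t, global = 30)
  expect_equal(cn$cn, c(2, 3, NA))
  expect_error(to_copy_number(t, global = 0), class = "cnvlite_data_error")
})

test_that("GC correction rescales by class mean and conserves the global mean", {
  # two GC classes with raw means 20 and 40, global mean 30:
  # class-1 bins x1.5, class-2 bins x0.75
  t <- mk_cn_track(c(rep(20, 4), rep(40, 4)), bin_size = 1e4)
  gc <- tibble::tibble(
    chrom = "chr1", start = t$start,
    gc = c(rep(0.355, 4), rep(0.455, 4))
  )
  out <- gc_correct(t, gc, min_bins = 1)
  expect_equal(out$corrected, c(rep(30, 8)))
  expect_equal(mean(out$corrected), mean(t$raw)) # conservation

  # single class: identity
  gc1 <- gc
  gc1$gc <- 0.4
  expect_equal(gc_correct(t, gc1, min_bins = 1)$corrected, t$raw)

  # missing GC: corrected falls back to raw for that bin
  gc2 <- gc
  gc2$gc[[1]] <- NA
  out2 <- gc_correct(t, gc2, min_bins = 1)
  expect_equal(out2$corrected[[1]], t$raw[[1]])

  # grid mismatch
  bad <- tibble::tibble(chrom = "chr1", start = 17, gc = 0.4)
  expect_error(gc_correct(t, bad), class = "cnvlite_data_error")
})

test_that("sparse GC classes pool with their nearest neighbour", {
  # class at gc=0.30 has 1 bin (< min_bins 2), pools with the 0.31 class;
  # pooled class mean = mean(10, 20, 30) = 20
  t <- mk_cn_track(c(10, 20, 30, 40, 40), bin_size = 1e4)
  gc <- tibble::tibble(chrom = "chr1", start = t$start, gc = c(0.305, 0.315, 0.315, 0.5, 0.5))
  out <- gc_correct(t, gc, min_bins = 2)
  gm <- mean(t$raw)
  expect_equal(out$corrected[1:3], t$raw[1:3] * gm / 20)
  expect_equal(out$corrected[4:5], t$raw[4:5] * gm / 40)
})

test_that("rebinning takes n_var-weighted means, sums counts, and is associative", {
  t <- mk_cn_track(c(10, 30, NA, NA, 20, 40), bin_size = 1e4)
  t$n_var <- c(1L, 3L, 0L, 0L, 2L, 2L)
  expect_equal(rebin(t, 1), t)
  r2 <- rebin(t, 2)
  expect_equal(r2$raw, c(25, NA, 30))
  expect_equal(r2$n_var, c(4L, 0L, 4L))
  expect_true(is.na(r2$raw[[2]])) # all constituents masked -> masked
  # associativity on a longer random track
  withr::with_seed(9, {
    x <- stats::runif(120, 10, 50)
    x[sample(120, 20)] <- NA
    nv <- ifelse(is.na(x), 0L, sample(1:5, 120, replace = TRUE))
  })
  tt <- mk_cn_track(x, bin_size = 1e4)
  tt$n_var <- nv
  a <- rebin(tt, 6)
  b <- rebin(rebin(tt, 2), 3)
  expect_equal(a$raw, b$raw, tolerance = 1e-12)
  expect_equal(a$n_var, b$n_var)
  expect_error(rebin(t, 2.5), class = "cnvlite_usage_error")
})

test_that("a simulated flat diploid sample lands at median CN 2", {
  contigs <- mk_contigs(10e6)
  sim <- simulate_sample(sample_spec(contigs, coverage = 30, seed = 7))
  rd <- bin_read_depth(sim$variants, contigs, 1e5)
  cn <- to_copy_number(rd)
  expect_equal(median(cn$cn, na.rm = TRUE), 2, tolerance = 0.05 / 2)
})
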