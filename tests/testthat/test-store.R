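sim_tracks_for_store <- function(seed = 19, len = 2e6) {
  contigs <- mk_contigs(len)
  sim <- simulate_sample(sample_spec(contigs, coverage = 30, seed = seed))
  rd <- bin_read_depth(sim$variants, contigs, 1e4)
  baf <- bin_baf(sim$variants, contigs, 1e4)
  list(contigs = contigs, rd = rd, baf = baf, variants = sim$variants)
}

test_that("RD and BAF tracks round-trip through the store exactly", {
  x <- sim_tracks_for_store()
  path <- withr::local_tempfile(fileext = ".h5")
  store_create(path, x$contigs, sample = "S1")
  store_save_signals(path, rd_track = x$rd, baf_track = x$baf)

  rd2 <- store_load_rd(path, "chr1", 1e4)
  expect_equal(rd2$raw, x$rd$raw) # NA-aware exact equality
  expect_equal(rd2$corrected, x$rd$corrected)
  expect_equal(rd2$n_var, x$rd$n_var)

  baf2 <- store_load_baf(path, "chr1", 1e4)
  expect_equal(baf2$n_het, x$baf$n_het)
  expect_equal(baf2$max_baf, x$baf$max_baf)
  i <- which(x$baf$n_het > 0)[[1]]
  expect_equal(baf2$curve[[i]], x$baf$curve[[i]], tolerance = 1e-12)
  j <- which(x$baf$n_het == 0)
  if (length(j) > 0) expect_null(baf2$curve[[j[[1]]]])
})

test_that("meta records every stored bin size and overwrites replace datasets", {
  x <- sim_tracks_for_store()
  path <- withr::local_tempfile(fileext = ".h5")
  store_create(path, x$contigs)
  for (factor in c(1, 10, 100)) {
    store_save_signals(path, rd_track = rebin(x$rd, factor))
  }
  expect_equal(store_meta(path)$bin_sizes, c(1e4, 1e5, 1e6))

  # overwrite same (chrom, size) with modified values
  rd_mod <- x$rd
  rd_mod$raw <- rd_mod$raw + 1
  store_save_signals(path, rd_track = rd_mod)
  expect_equal(store_load_rd(path, "chr1", 1e4)$raw, x$rd$raw + 1)
})

test_that("region queries return the overlapping bins with absolute coordinates", {
  x <- sim_tracks_for_store()
  path <- withr::local_tempfile(fileext = ".h5")
  store_create(path, x$contigs)
  store_save_signals(path, rd_track = x$rd, baf_track = x$baf)

  whole <- store_load_region(path, "chr1", 0, 2e6, 1e4, "raw")
  expect_equal(nrow(whole), nrow(x$rd))

  first <- store_load_region(path, "chr1", 0, 1e4, 1e4, "raw")
  expect_equal(nrow(first), 1)
  expect_equal(first$start, 0)

  straddle <- store_load_region(path, "chr1", 9999, 10001, 1e4, "nvar")
  expect_equal(straddle$bin, c(0, 1))

  expect_error(store_load_region(path, "chr1", 0, 1e4, 777, "raw"), "available")
  expect_error(store_load_region(path, "chrZ", 0, 1e4, 1e4, "raw"), "available|not in store")
})

test_that("call tables round-trip; missing tables load as empty", {
  x <- sim_tracks_for_store()
  path <- withr::local_tempfile(fileext = ".h5")
  store_create(path, x$contigs)
  calls <- tibble::tibble(
    chrom = "chr1", start = c(0, 5e5), end = c(2e5, 9e5),
    type = c("deletion", "cnnloh"), cn = c(1.02, 2.0),
    cell_fraction = c(1, NA), p_adj = c(1e-10, 2e-5),
    caller = "2d", bin_size = 1e4
  )
  store_save_calls(path, calls, "2d", 1e4)
  store_save_calls(path, calls[1, ], "rd", 1e4)

  back <- store_load_calls(path, "2d", 1e4)
  expect_equal(as.data.frame(back), as.data.frame(calls))
  expect_equal(nrow(store_load_calls(path, "rd", 1e4)), 1) # callers independent
  empty <- store_load_calls(path, "2d", 12345)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("chrom", "type", "cell_fraction") %in% names(empty)))
})

test_that("store listing enumerates what was written; wrong-format files are refused", {
  x <- sim_tracks_for_store()
  path <- withr::local_tempfile(fileext = ".h5")
  store_create(path, x$contigs)
  store_save_signals(path, rd_track = x$rd, baf_track = x$baf)
  listing <- store_list(path)
  expect_setequal(
    listing$signal[listing$kind == "rd"],
    c("raw", "gc", "nvar")
  )
  expect_setequal(
    listing$signal[listing$kind == "snp"],
    c("lik", "maxbaf", "nhet")
  )
  expect_true(all(listing$bin_size == 1e4))

  # an HDF5 file with a foreign format tag is not a cnvlite store
  alien <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(alien)
  rhdf5::h5createGroup(alien, "meta")
  rhdf5::h5write("someone-elses-format", alien, "/meta/format")
  rhdf5::h5closeAll()
  expect_error(store_save_signals(alien, rd_track = x$rd), class = "cnvlite_data_error")
  expect_error(store_meta(alien), class = "cnvlite_data_error")
})
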