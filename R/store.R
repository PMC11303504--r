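# Multi-resolution HDF5 signal store.
#
# Layout (format tag "cnvlite-1"):
#   /meta/format, /meta/sample, /meta/contig_names, /meta/contig_lengths,
#   /meta/bin_sizes, /meta/params (JSON string)
#   /rd/<chrom>/raw_<size>, /rd/<chrom>/gc_<size>   1-D doubles, NaN = masked
#   /rd/<chrom>/nvar_<size>                         1-D integers
#   /snp/<chrom>/lik_<size>                         2-D (bins x G), NaN rows = masked
#   /snp/<chrom>/maxbaf_<size>, /snp/<chrom>/nhet_<size>
#   /calls/<caller>_<size>                          compound table of call fields
#
# Masked bins travel as NaN inside the file and come back as NA in tibbles.
# Dataset naming is this package's own documented convention; compatibility
# with any other tool's internal HDF5 names is not claimed.

STORE_FORMAT <- "cnvlite-1"

h5_has <- function(path, name) {
  ls <- rhdf5::h5ls(path)
  full <- gsub("//", "/", paste0(ls$group, "/", ls$name))
  sub("^/*", "/", name) %in% full
}

h5_write_ds <- function(path, name, data, level = 4) {
  if (h5_has(path, name)) rhdf5::h5delete(path, name)
  if (is.matrix(data)) {
    rhdf5::h5createDataset(path, name,
      dims = dim(data), storage.mode = storage.mode(data),
      chunk = dim(data), level = level
    )
  } else if (is.numeric(data) || is.integer(data)) {
    rhdf5::h5createDataset(path, name,
      dims = length(data), storage.mode = storage.mode(data),
      chunk = max(length(data), 1), level = level
    )
  }
  rhdf5::h5write(data, path, name)
  invisible(NULL)
}

h5_ensure_group <- function(path, group) {
  if (!h5_has(path, group)) rhdf5::h5createGroup(path, group)
}

check_store_version <- function(path) {
  fmt <- tryCatch(as.character(rhdf5::h5read(path, "/meta/format")), error = function(e) NA_character_)
  if (is.na(fmt) || !identical(fmt, STORE_FORMAT)) {
    data_error(paste0(
      "file '", path, "' is not a ", STORE_FORMAT, " store (format tag: ",
      ifelse(is.na(fmt), "missing", fmt), ")"
    ))
  }
  invisible(NULL)
}

#' Create an empty signal store
#'
#' @param path Destination HDF5 file (overwritten if it exists).
#' @param contigs Contig map tibble.
#' @param sample Sample name recorded in `/meta`.
#' @param params Arbitrary creation parameters, stored as a JSON string.
#' @return `path`, invisibly.
#' @export
store_create <- function(path, contigs, sample = "SAMPLE", params = list()) {
  assert_contigs(contigs)
  if (file.exists(path)) unlink(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok)) data_error(paste0("cannot create store at '", path, "'"))
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5createGroup(path, "rd")
  rhdf5::h5createGroup(path, "snp")
  rhdf5::h5createGroup(path, "calls")
  rhdf5::h5write(STORE_FORMAT, path, "/meta/format")
  rhdf5::h5write(sample, path, "/meta/sample")
  rhdf5::h5write(contigs$name, path, "/meta/contig_names")
  rhdf5::h5write(as.double(contigs$length), path, "/meta/contig_lengths")
  rhdf5::h5write(numeric(0), path, "/meta/bin_sizes")
  rhdf5::h5write(as.character(jsonlite::toJSON(params, auto_unbox = TRUE)), path, "/meta/params")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Contig map and metadata of a store
#'
#' @param path Store file.
#' @return List with `sample`, `contigs` tibble, `bin_sizes`, `params`.
#' @export
store_meta <- function(path) {
  if (!file.exists(path)) data_error(paste0("store not found: ", path))
  check_store_version(path)
  out <- list(
    sample = as.character(rhdf5::h5read(path, "/meta/sample")),
    contigs = tibble(
      name = as.character(rhdf5::h5read(path, "/meta/contig_names")),
      length = as.numeric(rhdf5::h5read(path, "/meta/contig_lengths"))
    ),
    bin_sizes = sort(as.numeric(rhdf5::h5read(path, "/meta/bin_sizes"))),
    params = jsonlite::fromJSON(as.character(rhdf5::h5read(path, "/meta/params")))
  )
  rhdf5::h5closeAll()
  out
}

record_bin_size <- function(path, bin_size) {
  sizes <- as.numeric(rhdf5::h5read(path, "/meta/bin_sizes"))
  sizes <- sort(unique(c(sizes, bin_size)))
  rhdf5::h5delete(path, "/meta/bin_sizes")
  rhdf5::h5write(sizes, path, "/meta/bin_sizes")
}

#' Save RD and/or BAF tracks into a store
#'
#' Re-saving the same (chromosome, bin size) replaces the stored datasets.
#'
#' @param path Store created by [store_create()].
#' @param rd_track RD track tibble, or `NULL`.
#' @param baf_track BAF track tibble, or `NULL`.
#' @return `path`, invisibly.
#' @export
store_save_signals <- function(path, rd_track = NULL, baf_track = NULL) {
  if (!file.exists(path)) data_error(paste0("store not found: ", path))
  check_store_version(path)
  if (!is.null(rd_track)) {
    bs <- track_bin_size(rd_track)
    for (ch in unique(rd_track$chrom)) {
      t <- rd_track[rd_track$chrom == ch, ]
      h5_ensure_group(path, paste0("rd/", ch))
      pre <- paste0("/rd/", ch, "/")
      h5_write_ds(path, paste0(pre, "raw_", bs), na_to_nan(t$raw))
      h5_write_ds(path, paste0(pre, "gc_", bs), na_to_nan(t$corrected))
      h5_write_ds(path, paste0(pre, "nvar_", bs), as.integer(t$n_var))
    }
    record_bin_size(path, bs)
  }
  if (!is.null(baf_track)) {
    bs <- track_bin_size(baf_track)
    G <- attr(baf_track, "G") %||% length(baf_track$curve[[which(baf_track$n_het > 0)[1]]])
    for (ch in unique(baf_track$chrom)) {
      t <- baf_track[baf_track$chrom == ch, ]
      h5_ensure_group(path, paste0("snp/", ch))
      pre <- paste0("/snp/", ch, "/")
      lik <- matrix(NaN, nrow = nrow(t), ncol = G)
      for (i in which(t$n_het > 0)) lik[i, ] <- t$curve[[i]]
      h5_write_ds(path, paste0(pre, "lik_", bs), lik)
      h5_write_ds(path, paste0(pre, "maxbaf_", bs), na_to_nan(t$max_baf))
      h5_write_ds(path, paste0(pre, "nhet_", bs), as.integer(t$n_het))
    }
    record_bin_size(path, bs)
  }
  rhdf5::h5closeAll()
  invisible(path)
}

na_to_nan <- function(x) {
  x <- as.double(x)
  x[is.na(x)] <- NaN
  x
}

nan_to_na <- function(x) {
  x[is.nan(x)] <- NA_real_
  x
}

contig_grid_for <- function(path, chrom, bin_size) {
  meta <- store_meta(path)
  contig <- meta$contigs[meta$contigs$name == chrom, ]
  if (nrow(contig) == 0) {
    data_error(paste0(
      "chromosome '", chrom, "' not in store; available: ",
      paste(meta$contigs$name, collapse = ", ")
    ))
  }
  full_grid(contig, bin_size)
}

store_require <- function(path, name) {
  if (!h5_has(path, name)) {
    ls <- rhdf5::h5ls(path)
    avail <- paste0(ls$group, "/", ls$name)
    data_error(paste0(
      "dataset ", name, " not in store; available:\n  ",
      paste(avail, collapse = "\n  ")
    ))
  }
}

#' Load an RD track from a store
#'
#' @param path Store file.
#' @param chrom Chromosome name.
#' @param bin_size Stored bin size.
#' @return RD track tibble for that chromosome.
#' @export
store_load_rd <- function(path, chrom, bin_size) {
  check_store_version(path)
  grid <- contig_grid_for(path, chrom, bin_size)
  pre <- paste0("/rd/", chrom, "/")
  store_require(path, paste0(pre, "raw_", bin_size))
  out <- grid %>% mutate(
    raw = nan_to_na(as.numeric(rhdf5::h5read(path, paste0(pre, "raw_", bin_size)))),
    corrected = nan_to_na(as.numeric(rhdf5::h5read(path, paste0(pre, "gc_", bin_size)))),
    n_var = as.integer(rhdf5::h5read(path, paste0(pre, "nvar_", bin_size)))
  )
  rhdf5::h5closeAll()
  attr(out, "bin_size") <- bin_size
  out
}

#' Load a BAF track from a store
#'
#' @inheritParams store_load_rd
#' @return BAF track tibble (with `curve` list-column) for that chromosome.
#' @export
store_load_baf <- function(path, chrom, bin_size) {
  check_store_version(path)
  grid <- contig_grid_for(path, chrom, bin_size)
  pre <- paste0("/snp/", chrom, "/")
  store_require(path, paste0(pre, "lik_", bin_size))
  lik <- rhdf5::h5read(path, paste0(pre, "lik_", bin_size))
  maxbaf <- nan_to_na(as.numeric(rhdf5::h5read(path, paste0(pre, "maxbaf_", bin_size))))
  nhet <- as.integer(rhdf5::h5read(path, paste0(pre, "nhet_", bin_size)))
  rhdf5::h5closeAll()
  out <- grid %>% mutate(
    n_het = nhet,
    max_baf = maxbaf,
    curve = lapply(seq_len(nrow(grid)), function(i) {
      if (nhet[[i]] > 0) as.numeric(lik[i, ]) else NULL
    })
  )
  attr(out, "bin_size") <- bin_size
  attr(out, "G") <- ncol(lik)
  out
}

#' Slice a stored signal by genomic region
#'
#' Returns the bins overlapping `[start_bp, end_bp)` with absolute bin
#' coordinates.
#'
#' @param path Store file.
#' @param chrom Chromosome.
#' @param start_bp,end_bp Region, 0-based half-open.
#' @param bin_size Stored bin size.
#' @param signal One of `"raw"`, `"gc"`, `"nvar"`, `"maxbaf"`, `"nhet"`.
#' @return Tibble `chrom`, `bin`, `start`, `end`, `value`.
#' @export
store_load_region <- function(path, chrom, start_bp, end_bp, bin_size,
                              signal = c("raw", "gc", "nvar", "maxbaf", "nhet")) {
  signal <- match.arg(signal)
  check_store_version(path)
  if (end_bp <= start_bp) usage_error("end_bp must exceed start_bp")
  group <- if (signal %in% c("raw", "gc", "nvar")) "rd" else "snp"
  name <- paste0("/", group, "/", chrom, "/", signal, "_", bin_size)
  store_require(path, name)
  grid <- contig_grid_for(path, chrom, bin_size)
  vals <- as.numeric(rhdf5::h5read(path, name))
  rhdf5::h5closeAll()
  keep <- grid$end > start_bp & grid$start < end_bp
  out <- grid[keep, ]
  out$value <- nan_to_na(vals[keep])
  out
}

#' Save / load call tables
#'
#' Calls round-trip exactly; loading a caller/bin-size combination that was
#' never stored returns an empty call table rather than an error.
#'
#' @param path Store file.
#' @param calls Calls tibble (see [call_cnv()]).
#' @param caller Caller tag (`"rd"`, `"2d"`, ...).
#' @param bin_size Bin size the calls were made at.
#' @return `store_save_calls`: `path` invisibly. `store_load_calls`: a calls
#'   tibble (possibly empty).
#' @export
store_save_calls <- function(path, calls, caller, bin_size) {
  check_store_version(path)
  name <- paste0("/calls/", caller, "_", bin_size)
  if (h5_has(path, name)) rhdf5::h5delete(path, name)
  df <- as.data.frame(calls)
  df$cell_fraction <- na_to_nan(df$cell_fraction)
  df$p_adj <- na_to_nan(df$p_adj)
  rhdf5::h5write(df, path, name, DataFrameAsCompound = TRUE)
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname store_save_calls
#' @export
store_load_calls <- function(path, caller, bin_size) {
  check_store_version(path)
  name <- paste0("/calls/", caller, "_", bin_size)
  if (!h5_has(path, name)) return(empty_calls())
  df <- rhdf5::h5read(path, name)
  rhdf5::h5closeAll()
  out <- as_tibble(lapply(df, as.vector)) %>%
    mutate(across(c("cell_fraction", "p_adj"), nan_to_na))
  out$chrom <- as.character(out$chrom)
  out$type <- as.character(out$type)
  out$caller <- as.character(out$caller)
  out
}

#' List the contents of a store
#'
#' @param path Store file.
#' @return Tibble with `kind` (`rd`/`snp`/`calls`), `chrom` (or caller tag),
#'   `signal`, `bin_size`.
#' @export
store_list <- function(path) {
  check_store_version(path)
  ls <- rhdf5::h5ls(path)
  rhdf5::h5closeAll()
  ds <- ls[ls$otype == "H5I_DATASET" & grepl("^/(rd|snp|calls)", ls$group), ]
  purrr::map_dfr(seq_len(nrow(ds)), function(i) {
    g <- ds$group[[i]]
    nm <- ds$name[[i]]
    parts <- strsplit(sub("^/", "", g), "/")[[1]]
    kind <- parts[[1]]
    m <- regmatches(nm, regexec("^(.*)_([0-9]+)$", nm))[[1]]
    if (length(m) != 3) return(NULL)
    tibble(
      kind = kind,
      chrom = if (kind == "calls") m[[2]] else parts[[2]],
      signal = if (kind == "calls") "calls" else m[[2]],
      bin_size = as.numeric(m[[3]])
    )
  })
}
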