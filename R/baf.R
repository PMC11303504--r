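# Per-bin B-allele-frequency likelihood curves from het-site allele depths.
#
# Phase is unknown in a typical germline VCF, so each SNP contributes a FOLDED
# binomial likelihood — the sum over the two possible phase assignments —
# making every curve symmetric about 0.5 and producing the characteristic BAF
# "split" away from 0.5 under allelic imbalance. Curves are discretised on a
# regular grid over [0, 1] and normalised to sum 1; the reported
# maximum-likelihood BAF is folded into [0, 0.5].

baf_grid <- function(G) seq(0, 1, length.out = G)

#' Folded-binomial BAF likelihood of a single heterozygous site
#'
#' `L(p) ~ Binom(ad_alt; n, p) + Binom(ad_alt; n, 1 - p)` with
#' `n = ad_ref + ad_alt`, normalised to sum 1 over a `G`-point grid on
#' \[0, 1\]. Symmetric under swapping the two allele depths.
#'
#' @param ad_ref,ad_alt Reference and alternate allele read counts.
#' @param G Grid size (default 101).
#' @return Numeric vector of length `G` summing to 1.
#' @export
snp_likelihood <- function(ad_ref, ad_alt, G = 101) {
  n <- ad_ref + ad_alt
  if (n < 1) data_error("snp_likelihood needs at least one supporting read")
  p <- baf_grid(G)
  # Binom(ad_alt; n, 1-p) == Binom(ad_ref; n, p): this form keeps the swap
  # symmetry exact in floating point
  l <- dbinom(ad_alt, n, p) + dbinom(ad_ref, n, p)
  l / sum(l)
}

# log folded per-site likelihoods, unnormalised and underflow-safe;
# vectorised over sites: returns a G x n_sites matrix
sites_log_lik <- function(ad_ref, ad_alt, G = 101) {
  n <- ad_ref + ad_alt
  p <- baf_grid(G)
  ns <- length(n)
  A <- matrix(rep(ad_alt, each = G), nrow = G)
  R <- matrix(rep(ad_ref, each = G), nrow = G)
  N <- matrix(rep(n, each = G), nrow = G)
  P <- matrix(p, nrow = G, ncol = ns)
  la <- dbinom(A, N, P, log = TRUE)
  lb <- dbinom(R, N, P, log = TRUE)
  m <- pmax(la, lb)
  out <- m + log1p(exp(pmin(la, lb) - m))
  out[is.infinite(m)] <- -Inf
  out
}

#' Combined BAF likelihood of the het sites in one bin
#'
#' Pointwise product of the per-SNP folded likelihoods, computed in log space
#' and renormalised, so bins with hundreds of SNPs do not underflow.
#'
#' @param ad_ref,ad_alt Integer vectors of per-site allele depths (same length,
#'   at least one site).
#' @param G Grid size.
#' @return Normalised likelihood curve of length `G`.
#' @export
bin_baf_likelihood <- function(ad_ref, ad_alt, G = 101) {
  if (length(ad_ref) == 0) data_error("bin_baf_likelihood needs at least one het site")
  ll <- rowSums(sites_log_lik(ad_ref, ad_alt, G))
  normalise_log_curve(ll)
}

normalise_log_curve <- function(ll) {
  m <- max(ll)
  if (!is.finite(m)) return(rep(1 / length(ll), length(ll)))
  l <- exp(ll - m)
  l / sum(l)
}

#' Maximum-likelihood BAF of a curve, folded into \[0, 0.5\]
#'
#' Argmax over the grid; a peak at `p* > 0.5` reports `1 - p*`. Ties are
#' broken toward 0.5, so a flat (uninformative) curve reports 0.5.
#'
#' @param curve Normalised likelihood curve.
#' @return Scalar in \[0, 0.5\].
#' @export
max_baf <- function(curve) {
  G <- length(curve)
  p <- baf_grid(G)
  mx <- max(curve)
  cand <- p[curve >= mx - 1e-12]
  folded <- ifelse(cand > 0.5, 1 - cand, cand)
  max(folded)
}

#' Bhattacharyya overlap of two likelihood curves
#'
#' `sum(sqrt(a * b))` for two normalised discrete distributions on the same
#' grid: 1 iff identical, 0 iff disjoint support. Used as the BAF-compatibility
#' term when the 2D caller decides whether adjacent segments may merge.
#'
#' @param a,b Normalised curves of equal length.
#' @return Scalar in \[0, 1\].
#' @export
likelihood_overlap <- function(a, b) {
  if (length(a) != length(b)) data_error("likelihood curves are on different grids")
  min(sum(sqrt(a * b)), 1)
}

#' Per-bin BAF track from heterozygous variants
#'
#' Filters to heterozygous sites with total depth at least `min_dp` (shallow
#' sites give noisy allele fractions), bins them, and computes each bin's
#' combined likelihood curve and its maximum-likelihood BAF. Bins without
#' usable het sites are masked.
#'
#' @param variants Variant tibble (`chrom`, `pos`, `dp`, `ad_ref`, `ad_alt`,
#'   `is_het`).
#' @param contigs Contig map.
#' @param bin_size Bin width in bp.
#' @param G Likelihood grid size (default 101).
#' @param min_dp Minimum site depth for inclusion (default 8).
#' @return BAF track tibble: `chrom`, `bin`, `start`, `end`, `n_het`,
#'   `max_baf`, and a `curve` list-column (NULL where masked). Attributes
#'   `bin_size` and `G`.
#' @export
bin_baf <- function(variants, contigs, bin_size, G = 101, min_dp = 8) {
  grid <- full_grid(contigs, bin_size)
  het <- variants %>%
    filter(.data$is_het, !is.na(.data$ad_ref), !is.na(.data$ad_alt),
           .data$ad_ref + .data$ad_alt >= 1, .data$dp >= min_dp) %>%
    mutate(bin = floor((.data$pos - 1) / bin_size))
  curves <- het %>%
    group_by(.data$chrom, .data$bin) %>%
    summarise(
      n_het = dplyr::n(),
      curve = list(bin_baf_likelihood(.data$ad_ref, .data$ad_alt, G)),
      .groups = "drop"
    ) %>%
    mutate(max_baf = purrr::map_dbl(.data$curve, max_baf))
  out <- grid %>%
    left_join(curves, by = c("chrom", "bin")) %>%
    mutate(n_het = ifelse(is.na(.data$n_het), 0L, .data$n_het)) %>%
    select("chrom", "bin", "start", "end", "n_het", "max_baf", "curve")
  attr(out, "bin_size") <- bin_size
  attr(out, "G") <- G
  out
}
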