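---
title: "cnvlite: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cnvlite: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: what is being modelled,
which knobs exist and why their defaults are what they are, and where the
design was genuinely open and a choice had to be made.

## 1. Signals from a variant file

A whole-genome VCF records, at every variant site, the total read depth (`DP`)
and the per-allele depths (`AD`). Variant sites are dense enough in a human-like
genome (one heterozygous site every ~1.5 kb) that binned summaries of these two
fields reproduce the two classic copy-number signals without touching the
alignment.

**Read depth.** The RD value of a bin is the *arithmetic mean of `DP`* over the
variant sites falling in it — not the sum — so the signal is calibrated in
coverage units and independent of local SNP density. Both heterozygous and
homozygous-alt sites contribute: hom sites carry no allele-balance information
but their depth is as good as anyone's. Bins containing no variant are masked
and stay masked; downstream segmentation never interpolates across them. Bins
are half-open `[i·size, (i+1)·size)` with 0-based starts; a 1-based position
`p` belongs to bin `floor((p−1)/size)`.

The signal is scaled to **copy-number units** by `cn = 2·depth/global`, where
`global` is the *median* depth over unmasked autosomal bins. The median rather
than the mean keeps the baseline anchored when a sizeable genome fraction is
aneuploid (the common situation in tumors). It is not unbreakable: if a large
fraction of bins carries a shifted copy number, the median itself shifts by a
quantile offset of the bin-noise distribution. At the scales used in the tests
(≤25% of bins inside events) this biases cell-fraction estimates of subclonal
events downward by up to ~1 percentage point; see §7.

**GC correction.** Bins are stratified into GC classes of width 1 percentage
point; each bin is rescaled by (global mean)/(class mean). Classes with fewer
than 100 unmasked bins are pooled with the nearest class by GC until the
minimum is met, and bins with missing GC keep their raw value. The construction
conserves the global mean exactly. Class width and the minimum class size are
parameters of `gc_correct()`; correction requires an external per-bin GC table
(3-column TSV) because the VCF itself carries no sequence context.

**B-allele frequency.** At a heterozygous site with allele depths
`(AD_ref, AD_alt)` and `n = AD_ref + AD_alt`, the phase-unaware likelihood of a
minor-allele fraction `p` is the *folded binomial*

```
L(p) ∝ Binom(AD_alt; n, p) + Binom(AD_ref; n, p)
```

(the two terms are the two phase assignments; the second equals
`Binom(AD_alt; n, 1−p)`, and this algebraic form keeps the swap symmetry exact
in floating point). A bin's curve is the product of its sites' curves, computed
in log space and renormalised, on a grid of `G = 101` points over `[0, 1]`.
Every curve is symmetric about 0.5 by construction — that symmetry is the
familiar mirrored BAF "split" — and the reported maximum-likelihood BAF is
folded into `[0, 0.5]`, ties broken toward 0.5 so an uninformative curve reads
as balanced. Sites with `DP` below `min_dp = 8` are excluded from BAF (shallow
sites give very noisy allele fractions); they still count toward RD.

A caution that shaped the caller design: the folded product is a *composite*
likelihood, and at a true minor fraction of 0.5 its peak is not well behaved —
the fold makes 0.5 a stationary point whose curvature is noise-dominated, so
neutral bins frequently peak a few grid steps *below* 0.5. The argmax
(`max_baf`) is therefore a heavy-tailed estimator near 0.5, and any test that
treats `max_baf − 0.5` as Gaussian will over-call weak allelic imbalance. Where
the package needs to *test* imbalance it uses the likelihood-ratio
`2·(log L(peak) − log L(0.5))` instead, which measures the depth of the dip at
0.5 rather than the location of the peak (§4).

## 2. Mean-shift segmentation of the CN signal

The RD segmenter is a mode-seeking scheme. At bandwidth `h`, bin `i` feels the
shift

```
shift(i) = Σ_{0<|k|≤3h}  k · exp(−k²/(2h²)) · exp(−(x_i − x_{i+k})²/(2σ²))
```

— a pull toward nearby bins with similar values. A sign change from negative to
positive between adjacent bins (strict inequalities) separates two attraction
basins and marks a candidate breakpoint. The sweep runs over increasing
bandwidths (default 2, 4, …, 128 bins); after each sweep, bins are replaced by
their segment means and statistically indistinguishable neighbours are merged
before the next sweep. A perfectly constant run yields a single segment, and
masked bins always split segments.

Two implementation decisions matter and were validated against an exhaustive
least-squares breakpoint oracle on two-level steps:

- **Breakpoints accumulate across sweeps.** Recomputing breakpoints from
  scratch at a large bandwidth erases fine-scale structure: once `3h` spans the
  whole run, the positional kernel is flat and the sign rule responds to bin
  *counts*, not values, so a genuine step found at `h = 2` disappears at
  `h = 128`. Each sweep therefore only *adds* sign-rule breakpoints to the
  current partition; removal is the merge step's job.
- **The merge test is multiplicity-corrected and noise-guarded.** Adjacent
  segments merge unless a two-sample Welch t-test — guarded by a z-test against
  the global robust σ, taking the larger p — rejects equality at
  `merge_alpha = 0.01` after Bonferroni correction by the run's bin count.
  The correction is essential: the mean-shift stage proposes exactly the
  most extreme-looking boundaries, so per-pair testing keeps spurious splits
  (in benchmarks, most noisy steps grew 2–16 phantom segments without it; with
  it, 1 failure in 150 runs and zero false splits in 10×1000 flat bins). The
  z-guard covers short segments whose within-segment spread understates the
  noise for the same selection reason.

The per-bin noise σ is estimated as `1.4826 · median|Δx| / √2` over adjacent
unmasked pairs — first differences cancel the piecewise-constant signal, the
median ignores the few differences straddling true breakpoints.

## 3. The joint RD + BAF (2D) caller

The 2D caller starts from one segment per unmasked bin and greedily merges the
adjacent pair with the smallest joint distance

```
d(s,t) = (m_s − m_t)² / (σ²(1/n_s + 1/n_t))  −  2·ln BC(curve_s, curve_t)
```

where `BC = Σ√(a·b)` is the Bhattacharyya overlap of the segments' BAF curves
(1 for identical curves, so the term vanishes when the BAF agrees and grows
without bound as the curves separate). Segment curves are renormalised products
of their bins' curves; segments whose bins carry no het sites contribute no BAF
term. Merging stops when the cheapest pair exceeds `d_max = 9`; ties break to
the leftmost pair, so the procedure is deterministic.

`d_max` is a fixed-width cut (roughly 3σ on the RD axis), and since the
bottom-up search examines every bin boundary, boundaries at ~3.2σ survive on a
third of perfectly homogeneous chromosomes. A cleanup pass therefore merges any
remaining boundary whose joint distance is not Bonferroni-significant at the
run's bin count (χ² with df 2 when both sides carry BAF, df 1 otherwise).
Genuine RD-only or BAF-only splits carry distances orders of magnitude past
that bar and are untouched.

## 4. Genotyping and significance

Each 2D segment is genotyped by minimising

```
((cn_mean − CN(f))/σ_m)² + ((max_baf − BAF(f))/σ_b)²
```

over `f ∈ (0, 1]` for the three event models (deletion `CN = 2−f`,
`BAF = (1−f)/(2−f)`; duplication `CN = 2+f`, `BAF = 1/(2+f)`; copy-neutral LOH
`CN = 2`, `BAF = (1−f)/2`), on an `f` grid of step 0.001 with local refinement;
ties prefer the smaller `f` (parsimony). `σ_m = σ/√n_bins`; `σ_b` comes from
the curvature of the segment's log-curve at its peak, floored at 0.01. The
segment is reported neutral when the optimum collapses to the `f → 0` boundary
or the neutral point (CN 2, BAF 0.5) scores within 2.0 of the best model — a
margin of ~1.4σ on the objective scale that suppresses coin-flip genotypes.

A non-neutral segment becomes a call only if its departure from (CN 2, BAF 0.5)
is significant: the statistic is

```
z² = ((cn_mean − 2)/σ_m)²  +  2·(log L(peak) − log L(0.5))
```

— the BAF part is the imbalance likelihood-ratio of §1, not
`((max_baf − 0.5)/σ_b)²`, precisely because the folded argmax is heavy-tailed
near 0.5 (the quadratic form produced spurious few-percent cn-LOH calls on
neutral segments). `z²` is compared to χ² (df 2, or 1 without BAF) with
Bonferroni correction by the number of *unmasked bins*: the merge searched
every bin boundary, so surviving segments are selected extremes and
segment-count correction is too weak. The RD-only caller keeps the simpler
convention — one-sample t-test of the segment's bins against the genome mean,
Bonferroni by segment count — plus its own minimum effect size
`min_cn_shift = 0.5` (it has no BAF axis to distinguish a weak shift from
noise, so it does not attempt subclonal calls).

Finally, contiguous same-type calls are joined: event boundaries rarely align
with the bin grid, so the partially covered edge bin segments apart from the
event core (its CN is intermediate) and would otherwise surface as a separate
one-bin call. Joined calls report length-weighted CN and cell fraction and the
smallest adjusted p.

The RD caller reports `f = |cn − 2|` clamped to `[0, 1]` under a single-copy
assumption; duplications clearly past one extra copy (`cn > 3` beyond noise)
get `f = NA` since no single-copy cell fraction explains them.

## 5. The simulator

`simulate_sample()` emulates what a germline caller leaves in a whole-genome
VCF for a (possibly aneuploid) sample:

- variant sites with exponential gaps — mean `snp_spacing·(1−hom_fraction)`
  over all sites, so *heterozygous* sites have mean spacing `snp_spacing`
  (default 1500 bp) after a fraction `hom_fraction` (default 1/3) is marked
  hom-alt;
- per-site depth `DP ~ Poisson(coverage · CN(x)/2)` with `CN(x)` the local
  total copy number implied by the event list and its cell fractions
  (an optional negative-binomial overdispersion knob emulates lower-quality
  sequencing, default off);
- at het sites, the event-carrying haplotype is assigned i.i.d. per site with
  probability 1/2 (unphased realism — this is what makes the BAF split
  symmetric), and `AD_alt ~ Binomial(DP, q)` with `q` the minor fraction or
  its complement accordingly; hom sites carry `AD_alt = DP`;
- an *alignment-like truth RD track*: per bin,
  `depth ~ Normal(μ, √(μ·read_length/bin_size))` truncated at 0, with
  `μ = coverage · mean CN over the bin / 2`, expressed in CN units. The
  `read_length/bin_size` factor is the point: reads tile a bin densely while
  variants sample it sparsely, so the truth track has far lower variance than
  the VCF-derived track, and that variance gap is exactly what the
  VCF-vs-alignment concordance experiments measure.

Everything is reproducible from the spec's seed; the same spec yields
byte-identical outputs. Events are validated (types, fractions in (0, 1],
non-overlap per chromosome, clamping to contig bounds).

What the simulator deliberately does **not** model: GC bias (the correction is
tested on synthetic GC tables instead), mappability artifacts, sequencing
error in the allele counts, multi-subclone mixtures, and read-level detail.
Passing tests therefore demonstrate the pipeline's statistical behavior under
clean Poisson/binomial sampling, not robustness to alignment artifacts in real
data.

## 6. Storage, coordinates, determinism

Signals, likelihood curves and calls persist in an HDF5 store (gzip level 4)
under a documented layout (`/meta`, `/rd/<chrom>/{raw,gc,nvar}_<size>`,
`/snp/<chrom>/{lik,maxbaf,nhet}_<size>`, `/calls/<caller>_<size>`), format tag
`cnvlite-1`. NaN encodes masked bins inside the file; masks are reconstructed
on load, and full save→load round trips are identity (NA-aware, verified per
type). Compatibility with any other tool's internal dataset names is not
claimed.

All text outputs use 0-based half-open coordinates (BED convention); VCF
positions are 1-based. All pipeline stages are deterministic given the seed;
the CLI test asserts byte-identical call tables across repeated runs.

## 7. Problem sizes, tolerances, known limitations

The test suite and the acceptance script run entirely on simulated data at
desk scale, chosen to finish in minutes while leaving the statistics
comfortably resolved: 50-Mb neutral genomes at 30× with 10-kb bins for the RD
concordance spread (5 replicates), ten 100-Mb samples with ten clonal 1–10-Mb
events each at 100-kb bins for call recall and type concordance, and a 40-Mb
genome at 80× for the 6% subclone recovery.

Known limitations, in rough order of practical importance:

- **Median normalisation bias.** With a large fraction of bins inside events,
  the global median shifts by a quantile offset of the bin noise; at 25%
  duplicated genome this depresses recovered subclonal cell fractions by up to
  ~1 percentage point. An event-aware re-normalisation pass would remove it
  but is not implemented.
- **BAF near 0.5 is blind below the fold scale.** Allelic imbalance smaller
  than the per-site fold scale (|0.5 − q| ≲ 0.015 at 30–80×) is invisible to
  the folded composite likelihood; subclonal duplications at a few percent are
  therefore detected through RD, with BAF contributing little.
- **No multi-copy genotyping.** Amplifications beyond one extra copy are
  reported with their CN but no cell fraction; allele-specific integer
  decompositions beyond the three models are out of scope.
- **Hom-only segments** (no usable het site) are typed from RD alone and can
  never be called cn-LOH.
- The matching harness reports recall and type concordance separately; a
  fragmented event can match at most one of its fragments (one-to-one greedy
  assignment), which is the conservative reading.
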