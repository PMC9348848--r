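---
title: "Methods: quantifying transcripts in nascent germlines and testing X misregulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transcripts in nascent germlines and testing X misregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germquant)
```

germquant implements the computational core of a nascent-germline
transcriptomics study in *C. elegans*: counting single-molecule FISH
(smFISH) transcripts inside GFP-marked primordial germ cells (PGCs),
calling differential expression from ultra-low-input RNA-seq of dissected
PGC/EGC pairs, testing gene-set and X-chromosome enrichment, and
prioritizing transcription-factor candidates that may drive X-linked
misexpression. Every stage runs against synthetic data with known ground
truth, so the pipeline's statistical behaviour is testable without any
external download.

## smFISH spot counting

Each diffraction-limited focus in an smFISH image is taken to be one
transcript. The spot channel of a 3D stack is enhanced with a negated
Laplacian-of-Gaussian (LoG) filter (`log_filter()`), which acts as a
band-pass matched to spot-sized blobs: spot centres become bright local
maxima while flat background maps to zero. The filter sigma defaults to
1.5 px, the typical apparent sigma of a diffraction-limited spot at high
NA and ~100 nm pixel pitch; it should be set to the observed spot sigma.
The kernel is the 6-neighbour discrete Laplacian of a truncated Gaussian,
renormalized to sum exactly to zero so constant regions give exactly zero
response; convolution is by FFT and therefore circular, which only
matters within ~4 sigma of the volume faces.

Spots are detected as 26-connected regional maxima of the filtered image
above an intensity threshold (`count_maxima()`). A flat plateau of
connected equal-valued voxels counts once, reported at its rounded
centroid. Because a voxel's strictly greater neighbour survives every
threshold the voxel itself survives, the set of maxima at threshold *t*
is exactly the set of full-image maxima with value at least *t*; the
threshold ladder (`threshold_curve()`, 100 linearly spaced thresholds
between the filtered image's minimum and maximum) is therefore computed
from a single maxima pass, and its counts are non-increasing by
construction.

The detection threshold is chosen from the plateau of that curve: the
longest contiguous run of at least `window` thresholds (default 10) over
which the count varies by at most `tol` (default 2), taking the run's
midpoint and breaking ties toward the more stringent run
(`select_threshold()`). This automates the usual manual practice of
picking "a threshold in the stable range"; a manual override is available
in `smfish_count_stack(threshold = )` for images where no plateau exists.
Within an image set acquired on the same day with one probe set,
`batch_threshold()` averages the selected thresholds of the first five
images and applies that single value to all, mirroring how batch imaging
data are processed.

Cells are segmented in 2D (`segment_cells()`): maximum-intensity
Z-projection of the GFP channel, Gaussian blur with a large kernel
(default sigma 8 px, intentionally much wider than noise structure),
gradient-magnitude edge detection thinned by non-maximum suppression
along the gradient direction, hysteresis linking (strong threshold from
an Otsu split of the ridge gradients, weak threshold at half), then
morphological closing, hole filling, and removal of components below
`min_area_px` (default 200 px, well below a PGC cross-section at this
scale but above noise blobs). Edge thinning matters: without it the
filled mask follows the outer extent of the blurred gradient band and
overestimates the cell by roughly the blur sigma. The 2D mask is applied
to every Z slice; a spot belongs to the cell whose label sits at its
(y, x) position regardless of z (`count_per_cell()`), and the counts plus
the outside-mask remainder always sum to the number of spots. Images
with more than two labelled cells are flagged (not dropped), since PGC
fields should contain a single sister pair.

Group comparisons of per-cell counts use the Mann-Whitney rank-sum test
(`compare_groups()`), exact when the smaller group has at most 8
observations and there are no ties, otherwise the normal approximation
with continuity and tie correction.

## Low-input differential expression

Profiles from single pairs of dissected germ cells are extremely shallow
and zero-inflated, and occasional replicates fail to capture mRNA at
all. `qc_filter()` flags samples whose log10 library size or log10
genes-detected falls more than 3 MADs below the median (lower tail only,
the signature of capture failure); the MAD is floored at 0.01 log10
units so a near-constant metric cannot flag trivial fluctuations.

Size factors (`size_factors()`) come in two flavours. `median_ratio` is
the classic median-of-ratios estimator and requires genes with no zeros.
`deconvolution` is built for the zero-inflated regime: sliding pools of
samples (pool sizes 5 to min(15, n)) are summed into pseudo-samples,
each pooled profile is normalized against the average profile by a
median ratio, and the per-sample factors are recovered from the pool
equations by least squares with a light ridge tying each factor to its
library size for identifiability. Factors are rescaled to geometric
mean 1.

`fit_de()` fits a per-gene two-group negative-binomial model with
log(size factor) offsets. Gene-wise dispersions are estimated by method
of moments and shrunk toward a robust log-linear mean-dispersion trend
with a prior weight of 10 pseudo-degrees-of-freedom (`prior_df`); the
dispersion floor is 1e-8. With the dispersion fixed, the two group means
decouple, and each is fit by a vectorised Newton iteration on the log
mean — the exact NB GLM MLE for this design — with the Wald standard
error taken from the Fisher information. The statistic lfc/se is
referred to the standard normal; q-values are Benjamini-Hochberg
(`bh_adjust()`, a validated wrapper over `p.adjust`); calls are UP/DOWN
at q strictly below alpha = 0.05 using the raw LFC sign. The LFC
convention is mutant over wild type throughout. Genes with all-zero
counts are excluded from testing (NA statistics, NS call). Shrunken
LFCs (`shrink_lfc()`) are the posterior mean under a zero-centred normal
prior whose variance is estimated by moments from the raw LFCs and their
standard errors; they are reported alongside, never used for calls.

The expressed-gene background for depletion-style tests is the set of
genes with mean raw count of at least 1 in the reference group
(`expressed_background()`, inclusive threshold). Sample-level structure
is summarized by PCA on log2(count/size factor + 1) over the 500 most
variable genes (`vst_pca()`); cross-analysis concordance of fold changes
uses Spearman correlation (`spearman_lfc()`).

## Enrichment and categorical statistics

`hypergeom_enrich()` tests a hit list against a gene set within a stated
background, reporting the observed overlap, the chance expectation
n·K/N, and the upper-tail hypergeometric p (a lower-tail option covers
depletion). The background convention follows the study design:
UP-gene tests use all 20,258 protein-coding genes, DOWN-gene tests use
the expressed set, and the target set is always intersected with the
background first. `venn()` gives exact inclusion-exclusion region
counts; `percent()` rounds half away from zero, matching how count pairs
are quoted (21 of 168 is 13%, not 12%); `fisher_full()` collapses
germline-health scores to full vs not-full and applies the exact
two-sided Fisher test (point-probability criterion), reporting the
sample odds ratio with a 0.5 correction when a cell is zero.

## Transcription-factor prioritization

Promoters are the 500 bp strictly upstream of the TSS, strand-resolved,
0-based half-open, clipped at chromosome bounds (`build_promoters()`).
A TF targets a gene iff any ChIP peak overlaps the promoter by at least
1 bp; multiple experiments per TF are unioned (`assign_peaks()`, backed
by interval trees, with a brute-force scan as the test oracle).

`scan_pwm()` emulates a FIMO scan: windows on both strands are scored by
the sum of log2(p_motif/p_background) with a 1e-3 pseudocount, and a
window is a hit when the exact p-value of its score under the 0-order
background is at most 1e-4. The null score distribution is computed by
dynamic programming over per-column score distributions discretized to a
0.01-bit grid, and windows are scored with the same discretized matrix,
so reported p-values are exact for the scores actually used. Because
the score support is discrete, the realized tail probability at the
applied cutoff can sit below the nominal threshold; the scan records it
(`realized_tail` attribute) and the calibration test checks the
empirical hit rate against that realized value, with the nominal
threshold as an upper bound. The background defaults to base frequencies
estimated from the scanned sequences.

Candidates are filtered on three criteria (`prioritize()`): the TF gene
is itself X-linked UP in PGCs and/or EGCs; the TF binds promoters of at
least 25% of X UP genes; the TF's motif is enriched among X UP promoters
relative to all X genes (hypergeometric p < 0.05). Any criterion
qualifies; the output is ranked by criteria met, then binding fraction.

## Synthetic data: what it emulates, and what it does not

`gen_counts()` draws NB counts (variance mu + alpha·mu², default alpha
0.2, typical of low-input replicates) around log-normal baseline means,
with: the real protein-coding chromosome layout (chrI 2888, chrII 3508,
chrIII 2670, chrIV 3300, chrV 5084, chrX 2808; 20,258 genes); a planted
DE fraction (default 3%, matching the order of magnitude of observed
misregulation) at a configurable log2 fold change (default 2) with 70%
of planted genes on the X (the observed X dominance); log-uniform
library scalings in [0.5, 2]; independent Bernoulli dropout applied
after sampling (default 10%); and failed replicates whose library is
scaled down 20-fold. `gen_image()` renders cells as filled ellipses in
the GFP channel (two cells of radius 30 px in a 24x160x160 stack by
default, kept at least ~3 blur-sigmas apart so they are resolvable) and
isotropic Gaussian spots (sigma 1.5 px, amplitude 500 over background
100 with noise SD 50, i.e. SNR 10) rejection-sampled inside cells with
at least 6 sigma pairwise separation; voxels are 16-bit unsigned,
clipped, never wrapped. `gen_regulome()` plants exact-consensus motif
instances at recorded promoter offsets and places peaks over target
promoters. All generators are pure functions of their config, including
the seed.

These generators reproduce the statistical structure each stage assumes
— NB noise, dropout, planted effects, resolvable spots, cells brighter
than background — not the physics of real data: no PSF asymmetry or
photobleaching, no chromatic shift, no alignment artifacts, no
correlated gene-gene structure, no touching cells. Passing the planted
recovery suites therefore demonstrates that the algorithms are correct
and calibrated under their stated assumptions, not that real images or
libraries meet those assumptions.

## Problem sizes and numerical choices

The validation suites use problem sizes chosen to give tight Monte-Carlo
error at interactive runtimes: 100 seeded stacks for spot recovery
(recovery is required in at least 95), a 5000-gene 12 vs 12 null for
type-I calibration (the p < 0.05 fraction must sit in [0.03, 0.07]),
1000 uniform-null replicates for the BH false-discovery proportion
(required at most 0.06), 24 samples with known scalings for size-factor
recovery (Pearson r at least 0.95, all factors within 10%), and a
200-gene regulome for the TF end-to-end check. Exact-test equivalence
is established against brute-force enumeration over systematic sweeps of
all small instances (hypergeometric to N = 12, all 2x2 tables with cells
up to 5, every rank split with at most 8 observations).

Numerical details worth knowing: plateau ties break toward the stringent
side; regional-maxima plateaus are resolved by flood fill only when an
equal-valued neighbour exists (continuous-valued images almost never
trigger it); the Newton fit floors group means at half a pseudo-count
per total size factor so all-zero groups stay finite; dispersion
shrinkage uses a robust (M-estimator) trend fit; and the JSON report
serializes floats at 6 significant digits with a versioned schema.

## Limitations

Calls are made against a simplified NB Wald pipeline, not a bit-exact
reproduction of any published toolchain, so gene lists from real data
will differ in detail even when the statistical behaviour matches. The
automated plateau rule stands in for a human choice "within the stable
range". Segmentation assumes bright convex cells over darker
background; touching PGCs are merged and flagged rather than split.
Motif q-values (multiple-testing across motifs) are not computed; the
per-window p-value threshold plays FIMO's default role.
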