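---
title: "Methods and design notes for ribotranskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for ribotranskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical models the package implements, the
choices made where the design was genuinely open, and what the synthetic
benchmark does and does not establish about real data.

## Coordinate conventions and site assignment

All internal coordinates are 0-based half-open; GFF3 and SAM stay 1-based
at the file boundary and are converted exactly once, in the `io` layer.
This keeps every off-by-one in a single place.

Footprint A-sites are located from the 3′ end of the read, the usual
convention for bacterial ribosome-protected fragments, whose 3′ boundary is
sharper than the 5′ one. The default displacement is 11 nt for every read
length; `calibrate_offset()` can override it per length by maximizing, over
displacements 0–17, the fraction of reads whose assigned A-site lands in
frame 0 of an annotated *sense* codon. Two details matter:

* The fraction is computed over **all** reads of a length, not only in-CDS
  ones. Displacements congruent modulo 3 are otherwise indistinguishable;
  a wrong-by-one-codon displacement pushes boundary reads off the coding
  span and loses mass, which resolves the degeneracy.
* Stop codons are excluded from the target: the A-site over a stop codon is
  engaged in termination, not decoding, so a displacement that shifts
  A-sites onto the stop should not be rewarded.

When fewer than 500 footprints overlap CDS, or no displacement reaches a
frame-0 fraction of 0.45 (against the 1/3 baseline of aperiodic data), the
default rule is returned with a warning rather than a spurious calibration.

## The simulator

The generator is first-class, tested code; it encodes the statistical
structure every downstream stage assumes:

* per-gene footprint counts are Poisson with mean
  `depth_per_gene × tx_rate × te_multiplier(condition)`;
* A-site codons are multinomial over the gene's sense codons, weighted by
  condition-specific pause factors;
* the A-site frame is 0 with probability `frame0_prob` (default 0.85, a
  typical frame-0 share for a good bacterial library), else 1 or 2
  uniformly;
* read ends are placed deterministically from the sampled A-site, read
  length (24–32 nt by default) and the 3′ offset, so the matching offset
  rule recovers the intended A-site for 100% of reads — this makes offset
  calibration exactly testable;
* RNA-seq reads are uniform along genes with counts following the
  transcription rate only, so planted TE differences are purely
  translational.

Defaults: 50 genes of 60–250 codons, 30% sORFs (< 100 codons), 100-nt
intergenic spacers (≥ 40 nt is enforced so that footprints anchored at gene
boundaries stay on the reference). Every generator is deterministic for a
fixed seed, and `make_benchmark_bundle()` emits byte-identical files on
repeat runs.

What the simulator does **not** emulate: sequencing errors, soft-clipped
alignments, rRNA/tRNA contamination, ramp or 5′-bias effects, origin-
spanning reads on circular replicons, and operonic overlap between genes.
Passing the planted-effect tests therefore shows the estimators are
correct under their own model assumptions, not that they are robust to
every artefact of real libraries.

## Moderated two-group testing

DiffTE and DiffCO share one engine. For feature *g* with group means
m1, m2 and pooled residual variance s²_g on d_g degrees of freedom, the
posterior variance is

    s²_post = (d0·s0² + d_g·s²_g) / (d0 + d_g)

and t = (m2 − m1) / (s_post·√(1/n1 + 1/n2)) is referred to a t
distribution on d0 + d_g df. The prior (d0, s0²) is fitted by
moment-matching of log sample variances against the scaled-F prior, using
a Newton inversion of the trigamma function. Two forced limits are exposed
because they pin the implementation down: `d0 = 0` reproduces the
classical pooled t-test exactly, and `d0 = Inf` the fully pooled z-like
limit; the test suite verifies both, and cross-checks the default
estimator against an independent implementation of the same empirical
Bayes construction. Zero-variance features are floored at 1e-12 before
shrinkage so exact ties in simulated data do not produce infinite t.

Hits use |log2FC| ≥ 1.5 (inclusive) and unadjusted p < 0.05 (strict); a
Benjamini–Hochberg column is emitted for callers who prefer controlled
FDR, but does not drive the default classification. No trend or robust
variants are fitted.

## DiffTE specifics

TMM normalization (via edgeR, the canonical implementation) is applied to
the Ribo and RNA tables independently; RPKM uses the TMM-effective library
size; TE is the per-pair ratio of Ribo to RNA RPKM. Genes need ≥ 10 summed
raw counts in each assay before TE is computed — low-count log-ratios are
otherwise unstable — and genes with RNA RPKM below 0.1 in a pair are masked
in that pair rather than yielding huge or infinite ratios. Both thresholds
are arguments. Single-replicate groups are permitted with a warning; the
variance then rests entirely on the prior.

## DiffCO specifics

Only reads whose A-site falls in frame 0 of a CDS contribute
(triplet-phase filtering); the first and last 15 codons of each gene are
excluded against initiation/termination edge effects, and genes shorter
than 2×15+6 codons are skipped. For a retained position *j* with density
*d*, the codon "read" at the E/P/A/A+1..A+3 site is the codon at index
j−2/j−1/j/j+1..j+3; positions whose site index leaves the retained window
are skipped.

The expression-level normalizer is the open design point: the per-position
contribution is d divided by the gene's **mean retained per-codon
density** by default, which makes the uniform-density identity exact
(every codon's occupancy is 1, to machine precision) and is stable at
moderate depth. A site-relative alternative — the mean density over codons
j+4 .. j+4+W — is available via `downstream_window`, for users who want
the normalizer strictly downstream of the site. Occupancy per codon
identity is the **mean** of normalized contributions (a sum would scale
with codon frequency and break the identity). Stop codons are excluded:
the table has exactly 61 rows per site. For testing, occupancies are
log2-transformed after flooring at 1e-3, because rare codons at low depth
produce legitimate zeros.

Gene-mean normalization slightly attenuates strong pauses: a planted
factor k on a codon occupying fraction q of a gene is measured as about
k/(1+q(k−1)) (≈ 4.7 for k = 5 at q ≈ 1.6%). The recovery tests account for
this attenuation being below their tolerance.

## ORF enumeration and ORFscore

Valid ORFs start with ATG/GTG/TTG, end at the nearest in-frame
TAA/TAG/TGA, have length divisible by 3 and no internal stop; all nested
starts sharing a stop are emitted, since start-resolved candidates are
what model-training consumes. Lengths count the stop codon, so the
"< 180 nt" MS-candidate bound and the "< 300 nt" sORF report bound both
refer to total ORF length. Non-ATG initiators translate to M.

ORFscore counts A-sites in the three frames of the ORF after trimming one
codon from each end, and applies the chi-square-periodicity form
log2(1 + Σ(Fᵢ−F̄)²/F̄), negated when frame 1 is not strictly maximal, zero
when no reads. Peptide support is exact substring matching, optionally
with tryptic boundary checks (preceding residue K/R or protein start;
match ends at K/R or protein end); in-silico digestion with missed
cleavages is out of scope.

## The prediction models

No deep-learning framework is available to R in this package's dependency
tier, and the models are the analytical core, so the layers — 1-D
convolution, residual blocks, layer norm, sinusoidal positional encoding,
multi-head self-attention (softmax(QKᵀ/√d_k)V), nearest-neighbour
upsampling, dense heads — are implemented directly with explicit
backpropagation and Adam. Every gradient is validated against central
finite differences in the development checks, and training is exactly
reproducible for a fixed seed.

**sORFPred** consumes 73-nt TIS fragments: 50 nt upstream of the start
codon, the codon, and 20 nt downstream of its last base (the geometry is
fixed; fragments lacking full flanks are skipped). Positives come from
annotated ATG/GTG/TTG starts, negatives from genome-wide CTG occurrences.
Architecture: two conv blocks (64 channels, kernel 7, max-pool 2) → 2
transformer encoder layers (model dim 64, 4 heads) → mean-pool → sigmoid.

**sORFPredRibo** consumes fixed windows (default 303 nt, padded with N /
truncated) of one-hot sequence plus per-base A-site coverage normalized to
the window mean (zero vector when no reads). Positives are annotated CDS
windows with mean coverage above `cov_min` (default 0, the plain
presence/absence reading); negatives are reverse complements (carrying the
opposite strand's own, near-zero coverage) and the same genomic window
shifted by +1/+2 nt, sampled to 2 negatives per positive. Per-modality
conv stems are concatenated, passed through residual blocks, downsampled
by 3 (one token per codon), encoded by the transformer, then split into a
pooled classification head and an upsampling coverage decoder restoring
the input length. The decoder upsamples sub-pixel style — one channel per
intra-codon offset, reshaped to positions — because a repeat-and-convolve
decoder cannot express sub-token phase directly and learned the triplet
pattern unreliably. The joint loss is cross-entropy + λ·MSE with λ = 1 by
default. Pretraining is the same routine on pooled examples from several
independently seeded genomes; fine-tuning continues from those weights.

Splits are 0.8/0.1/0.1 after seeded shuffling. Evaluation: accuracy,
precision, recall, F1 at a 0.5 threshold; ROC-AUC by trapezoidal
integration over unique score cutoffs, which equals the
pairwise-concordance probability with ties counted one half (the suite
checks this equality against a brute-force oracle); PR-AUC by trapezoid
over the precision–recall curve; MSE, MAE and Pearson r for the coverage
head.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the planted effects are comfortably
identifiable: 20-gene fixtures at 500 footprints/gene for codon-occupancy
recovery (5 seeds), a 500-gene fixture with 3 replicate pairs per group
and 20 genes at a planted 4-fold TE shift for DiffTE, 2000-feature
Gaussian simulations for the moderated-t calibration, and a few hundred
training examples with reduced layer sizes (32/16 channels, 1 transformer
layer) for the models. The model fixtures are constructed to be separable
— a planted Shine-Dalgarno-like 8-mer for TIS fragments, Poisson-sampled
triplet-periodic versus flat coverage at 100 reads/codon for ORF windows —
so they measure whether training works, not how the models would rank on
real genomes. Reproducing published benchmark performance on real species
would require the original accessions and GPU-scale training, which is
deliberately out of scope here.

Degenerate inputs are handled explicitly rather than by accident: empty
read sets give zero counts and empty profiles; genes with zero retained
density are excluded from occupancy aggregation; single-class training
data, unpaired samples, disjoint gene sets, zero-length genes and
offsets outside the read span raise errors naming the problem.

## Known limitations

* Site-based counting (A-site for Ribo, midpoint for RNA) is one of
  several defensible conventions; span-based counting would differ
  slightly at gene boundaries.
* The A-site offset convention of any particular published pipeline may
  differ; exact replication of third-party site calls is not promised —
  the rule object isolates the choice.
* Reads spanning the boundaries of overlapping same-strand genes are
  discarded with a counter, not fractionally assigned.
* The negative-binomial alternative to the moderated-t engine for DiffTE
  is not implemented; with 2–3 replicates the moderated linear model is
  the more powerful choice and is the one implemented.
* Multi-factor designs, covariates and precision weights are out of scope
  for the testing engine.
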