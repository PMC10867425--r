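---
title: "Methods: predicting and stratifying chromosomal-instability-aiding variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting and stratifying chromosomal-instability-aiding variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(civaR)
```

`civaR` packages a three-stage analysis — predict candidate variants,
predict their protein-level consequences, and stratify their cellular
impact from live-cell imaging — together with the synthetic-data
generators used to validate every stage. This vignette documents the
models, the tunable parameters with their defaults and units, the
numerical conventions, and the design decisions that were genuinely open,
so that a user (or reviewer) can see exactly what the package assumes.

## 1. The variant screen

### Consequence model

Protein-level HGVS notation is parsed into one of six classes:
stop-gain (`Q1012*`), frameshift with new-frame stop (`L7Qfs*21`),
start-loss (`M1?`), missense, synonymous, and a catch-all `other`
(deletions, duplications and other syntaxes are accepted with a warning
rather than rejected, since database exports mix dialects). Both
one-letter and three-letter residue codes and optional `p.`/parenthesis
wrappers are accepted. Truncation arithmetic is fixed by the notation
semantics: a stop at residue k retains k−1 wild-type residues; `fs*N` at
residue k retains k−1 wild-type residues and appends N−1 novel residues.
These derived lengths drive both the LoF classification (stop-gain and
frameshift are truncating) and the isoform reports of stage 2.

### The prevalence filter

A CIVa candidate is a truncating variant carried by at least
`min_individuals` people (default 2: a variant seen once may be a
sequencing artifact; independent recurrence is the cheapest evidence of a
real, transmissible allele). Carriers are *individuals* (het + hom), not
alleles. When a variant appears in several databases, the default carrier
count is the **maximum single-source count**, not the sum: population
databases overlap (the same genome can be in more than one cohort), so
summation can double-count. `sum_sources = TRUE` enables pooling for
databases known to be disjoint. Whether recurrence must be at the *same*
residue is another open point; the package requires it (candidates are
keyed by gene and normalized variant), which is the conservative reading.

Allele frequency uses the diploid convention
q = (het + 2·hom)/(2·n), monotone in both counts and zero only for
zero carriers.

### Exports

The lollipop table aggregates per (residue, category) with categories
truncating / missense / other, summing carriers across sources for
display. The JSON database document has a `genes` map plus a
`uniprot_index`, so an entry resolves by either key, and round-trips
through `civa_db_export()`/`civa_db_import()`.

## 2. Isoform prediction

### Kozak scanning

Only **in-frame downstream ATGs** are reported: an out-of-frame start
cannot produce an N-terminally truncated isoform of the annotated
protein. Context strength follows the classical hierarchy: *strong* =
purine at −3 and G at +4; *adequate* = exactly one of the two; *weak* =
neither. The full `(gcc)gccRccATGG` context contributes a reported match
score (0–7 over the informative non-ATG positions) but not the
strong/adequate call, because the −3/+4 positions dominate initiation
efficiency. The default stringency is `strong`; positions within 6 nt of
the 5′ end or 1 nt of the 3′ end are evaluated with the available context
only, with missing positions counting as mismatches. Coordinates are
1-based and CDS-relative with the A of ATG at +1, so codon c sits at
nt = 3(c−1)+1.

`synthetic_spag5_cds()` provides a deterministic, clearly synthetic
SPAG5-like test sequence (1193 codons) whose only downstream in-frame
starts are two planted strong sites at nt 454 (codon 152) and nt 823
(codon 275) — the alternative-start geometry relevant to N-terminal
frameshifts in Astrin. It is a constructed stand-in, not the RefSeq
sequence, and is labelled as such wherever it is used.

### Truncation reports and masses

A feature is *removed* if its interval extends beyond the retained
wild-type length k — partial loss counts as removed, since epitopes and
folded domains rarely survive partial deletion. Predicted masses use
average (not monoisotopic) residue masses with one water per chain, the
right scale for comparison against gel migration; fusion of chains costs
one water per junction, making mass additive up to 18.02 Da.

## 3. Kinetochore quantification

### Detection

The reference (centromere-marker) channel is segmented by: Gaussian
smoothing (`edge_sigma`, default 2 px), Sobel gradient magnitude, Otsu
threshold on the normalized edge response (or an absolute override),
binary closing (brush 3 px), hole filling, watershed splitting on the
distance map (tolerance 0.5), and a size filter. Three choices deserve
comment:

* **edge_sigma = 2 px.** For diffraction-limited spots of σ ≈ 1.5 px
  this acts as a matched filter. At 1 px the detector is exact on clean
  data but collapses below SNR ≈ 5; at 2 px it remains exact at SNR 10
  and usable at SNR 3.
* **Size limits.** The minimum size (`min_size_px`, default 4) is
  applied to a particle's *bright core* — raw-intensity pixels above the
  midpoint between the component's peak and the image median — because
  the edge detector inflates even a single-pixel impulse into a ~9 px
  filled contour. The maximum size (default 400 px) discards the filled
  outline of the whole cell, which enters the edge response whenever the
  reference channel has visible cytoplasmic signal.
* **Watershed.** Sister kinetochores approach ~0.9 µm at minimum
  separation; their edge contours fuse, and without splitting the pair is
  labelled as one particle.

### Intensity measurement

Measured ratios use **aperture photometry**: each detected particle is
replaced by a circular aperture of fixed radius (default 3 px ≈ 2 spot
sigmas) centred on its detected centroid, and mean intensities are taken
over the aperture in both channels. The mean over a raw morphological
mask depends on how far the mask extends down the Gaussian flank, which
varies with noise and threshold; a fixed aperture removes that bias and
makes ratios comparable across spots, frames and conditions.
`measure_in_mask()` itself measures over any mask, so the raw-mask
convention is available by passing `aperture_radius_px = NULL`.

The cytoplasm proxy is a ring: erosion of the cell mask by 5 px minus
erosion by 15 px, with detected particles (dilated by 3 px) excluded.
The cell mask comes from the smoothed (σ = 4 px) measurement channel,
Otsu threshold, largest connected component, holes filled. Background is
the modal intensity outside the cell (kernel-density peak, robust to
Poisson skew) and is subtracted from both numerator and denominator —
otherwise the ratio depends on the camera offset. Setting
`background = 0` reproduces the no-subtraction convention.

For multi-plane stacks, `quantify_stack()` uses the **mean** Z-projection
by default although `project_stack()` defaults to max: the maximum of
several noisy planes adds a positive bias to the ring and background
estimates (enough to push ratio recovery outside a 5% band at SNR 10),
while the mean is unbiased, and because defocus attenuates kinetochore
and cytoplasm signal alike the ratio is preserved.

Crescent scoring maps ratios to `none < low < medium < high` through a
monotone step function; thresholds default to the quartiles of a
wild-type control distribution, making the score a relative,
distribution-anchored measure.

### Tracking, pairing and stretch

Linking is greedy mutual-nearest-neighbour between consecutive frames
with a hard displacement cap (`max_disp_px`, default 5 px) and no gap
closing: at ~24 well-separated spots per frame and 6-min cadence,
ambiguity is rare, and a missed detection should end a track rather than
bridge silently. Sister pairing takes mutual nearest neighbours with
separation inside 0.5–2.5 µm, a window bracketing published metaphase
inter-kinetochore distances; each particle joins at most one pair.

Inter-centromere distance series are Euclidean centroid distances in µm
over the common frames of a pair. T0 normalization divides by the
distance at the **minimum-distance frame** (earliest frame on ties),
n(t) = d(t)/d(T0), which makes n(T0) = 1 exactly. The "unstretched
state" has no formal definition, so `mode = "first"` (first frame) is
provided for sensitivity analysis. Summaries report d_max, n_max and
track duration per pair.

## 4. Mitotic timing statistics

t50 reads the empirical cumulative step function at 0.5 **without
interpolation**, honouring the acquisition grid (6-min frames): the
smallest observed duration t with #(durations ≤ t)/n_total ≥ 0.5. Cells
that never complete remain in the denominator by default, matching
cumulative-frequency curves that plateau below 100%; a completers-only
estimate is available by passing `n_total = length(durations)`. Whether
published t50 curves use all-cells or completers-only denominators is
often unstated, so both are computed by the pipeline and labelled.
Event fractions are computed per replicate and summarized as the mean of
replicate fractions (one dot per independent experiment) alongside the
pooled fractions.

`compare_groups()` wraps the standard two-sided tests: Mann-Whitney U
(exact when both n ≤ 8 and tie-free, otherwise normal approximation with
tie correction), chi-square without continuity correction, paired t, and
one-way ANOVA with Dunnett contrasts against the first (control) group.
The implementations delegate to base R and multcomp; the test suite
cross-checks Mann-Whitney against exhaustive enumeration of all group
assignments for n ≤ 6 and chi-square against its 2×2 closed form.

## 5. The synthetic-data generators

All generators are pure functions of their configuration including the
seed: identical configs give bit-identical outputs.

### Image stacks

A disk cell (radius 90 px at 0.1 µm/px by default) sits on an integer
camera offset (100). Sister-pair spots are isotropic 2-D Gaussians
(σ = 1.5 px) whose separation breathes sinusoidally,
d(t) = 1.2 µm + 0.3 µm · sin(2πt/10 frames + φ), with per-pair random
phase; 3 Z-planes 0.6 µm apart receive Gaussian focal attenuation; noise
is Poisson on the signal, then Gaussian read noise (default σ = 40,
i.e. SNR 10 against the 400-count reference spots), then the offset.
Pairs are laid out on a metaphase-plate-like grid sharing a spindle-axis
orientation (±10° jitter), with spacing chosen so every spot's nearest
neighbour is its sister and neighbouring spots never come closer than
~4 px: random isotropic placement produced unresolvable overlaps that
contradict the resolvability premise of the detection benchmarks.

Measurement-channel spot amplitudes are **calibrated per spot over the
analysis aperture**, so that the configured kinetochore/cytoplasm ratio
is exact in discrete, noise-free arithmetic — the generator and the
pipeline share the aperture convention deliberately, making "recovered
ratio = true ratio" a meaningful identity rather than an approximation.
`true_ratio` may be a per-frame vector, imposing e.g. a linear decay of
kinetochore-bound signal for dynamic-readout checks.

What the generator does *not* emulate: realistic point-spread functions
(no Airy rings, no axial elongation), spot shape anisotropy, cytoplasmic
texture, photobleaching, cell movement and deformation, out-of-focus
light from neighbouring cells, and chromatic misregistration between
channels. Passing the synthetic benchmarks therefore demonstrates the
correctness of the algorithms under the stated noise model, not
readiness for any particular microscope; on real data the configuration
knobs (edge scale, threshold, ring geometry, pairing window) exist
precisely because these unmodelled features move the optima.

### Variant tables

Allele frequencies are drawn from Beta(0.5, 100) truncated to (0, 0.05]
— rare LoF territory. Genotypes follow inbreeding-adjusted frequencies
(AA: (1−q)² + q(1−q)F; Aa: 2q(1−q)(1−F); aa: q² + q(1−q)F), emulating
cohorts with elevated homozygosity; F defaults to 0.05. The default
scale (135 genes, 3 variants each, 10,000 individuals) mirrors a
chromosome-segregation-gene screen. The truth table flags exactly the
variants satisfying the CIVa rule, so filter correctness is testable by
identity rather than statistically. No linkage or haplotype structure is
simulated.

### Timing data

Durations are drawn from an exponential (rate log 2 / median, default
median 60 min), lognormal or degenerate distribution, rounded **up** to
the 6-min frame grid (an event between frames is first seen at the next
frame) and censored at a 10-h window, with censored cells retained as
non-completers. At n = 500 the empirical median carries a standard error
of roughly one frame, which sets the tolerance used in the tests.

## 6. Problem sizes and runtime

The test suite and acceptance script run the benchmarks at: 12 sister
pairs (24 spots) per frame for detection/ratio recovery (5 seeds); 25
pairs × 30 frames × 20 seeds for tracking and pairing (ground-truth point
sets; rendering is exercised separately); 100 random 200-row tables for
the filter oracle; 1,000 random CDSs (≤ 1,000 codons) for the Kozak
oracle; 20 seeds × 500 cells for t50. These sizes keep the full suite
under a couple of minutes per stage while leaving the statistical
tolerances meaningful.

## 7. Known limitations

* Consequence calling starts from HGVS p. strings; there is no
  genomic-coordinate annotation, liftover or transcript handling.
* Detection and tracking are 2-D after projection; severely overlapping
  spots in Z are not separated, and there is no gap closing, so a missed
  detection splits a track.
* The Kozak model scores local context only; it does not model ribosome
  scanning, uORFs, or nonsense-mediated decay, so a predicted strong
  downstream start is a hypothesis about isoform rescue, not a
  demonstration.
* `t50` is undefined (NA, flagged) when fewer than half the cells
  complete; this is a property of the estimand, not a failure mode.
* The stratification step labels conditions by comparing the mean
  recovered ratio against a configurable threshold (default 1.0, i.e.
  kinetochore signal at cytoplasm level); it is a triage rule, not a
  pathogenicity call.
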