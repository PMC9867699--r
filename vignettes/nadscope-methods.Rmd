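---
title: "Calling and characterising nucleolus-associated domains with nadscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterising nucleolus-associated domains with nadscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadscope)
```

## The problem

Nucleoli organise a large fraction of repressive heterochromatin:
specific genomic regions — nucleolus-associated domains (NADs) — are
reproducibly found at the nucleolar periphery. Two sequencing readouts
expose them: the depth ratio of a nucleolus-enriched library over a
whole-genome (or in situ Hi-C) control, and the contact structure of
nucleolar Hi-C matrices. `nadscope` implements the downstream analysis:
segmenting NADs from paired depth tracks with a two-state hidden Markov
model, filtering high-confidence NADs (hNADs), and characterising their
cis/trans contact organisation — compartments, trans-interaction
groups, centromere and lamina relationships, ribosomal DNA (rDNA)
repeat-unit contacts, insulation/TAD structure, and microscopy-based
FISH-to-nucleolus distances.

Everything is exercised on synthetic data with planted ground truth, so
each stage's recovery behaviour is measurable without any external
download.

## Enrichment ratio and HMM segmentation

Both depth tracks are scaled to reads per million (RPM) and the per-bin
enrichment ratio is

  ER = log2((treatment_rpm + pc) / (control_rpm + pc)),

with pseudocount `pc = 1` RPM by default. Bins with zero depth in both
libraries are flagged unmappable (`NA`); they split the HMM observation
chains rather than being imputed, so no state information is propagated
across assembly gaps.

Segmentation uses a two-state Gaussian-emission HMM fitted by
Baum-Welch EM jointly over all chromosomes (shared parameters). The
Gaussian family is a modelling choice: ER is a log-ratio and
approximately symmetric within each state. Initialisation is
deterministic and scale-free — state means at the 25th/75th ER
percentiles, state variances from the median split of the values,
transition stay-probability 0.95 — with convergence at an absolute
log-likelihood change below `1e-6` (cap 500 iterations). If a state
captures under 1% of bins the fit is retried from a wider (10th/90th
percentile) initialisation. State labels are assigned after fitting:
the larger-mean state is "NAD". The Viterbi path defines the
segmentation; contiguous NAD-state bins merge into NAD intervals, and
the per-bin posterior NAD probability is retained. The implementation
is validated against exhaustive enumeration of all `2^n` state paths on
short tracks.

### hNAD filter

The high-confidence subset keeps NADs with at least `min_bins = 1` bin
of ER above `threshold = 1` (a two-fold depth ratio). Published hNAD
definitions differ on whether one or more than one qualifying bin is
required; the single-bin reading is the default and the stricter
variant is `min_bins = 2`. Neither gap-bridging nor a minimum NAD
length is applied by default; both exist as explicit post-filters the
user can opt into.

Set overlaps (e.g. hNADs vs LADs) are scored as base-pair overlap
fraction, base-pair Jaccard, and an upper-tail hypergeometric p-value
on bin counts (population = mappable bins), checked in the tests
against direct combinatorial evaluation.

## Contact matrices

Matrices are stored as upper-triangle sparse triplets on a fixed genome
binning (HiC-Pro matrix + bed dialect on disk; 1-based ids converted on
read). One binning may carry a per-chromosome bin-size override — used
for the rDNA artificial chromosome, which is binned at 1 kb while the
genome is binned at 10-100 kb.

**ICE balancing** finds per-bin weights equalising balanced row sums
over retained bins (relative deviation below `1e-5` by default). Bins
with log coverage more than 3 MADs below the median are masked first,
the common guard against sparse rows; masked bins get `NA` weights and
are excluded downstream.

**Compartments.** Per chromosome, the balanced cis matrix is converted
to observed/expected by diagonal means, then to a Pearson correlation
matrix whose leading eigenvector is the compartment score (PC1) —
the standard formulation for A/B calling. The eigenvector sign is
arbitrary, so it is oriented per chromosome against a reference track;
when none is supplied the pipeline uses the negated ER track, since
nucleolar enrichment marks the inactive B compartment. A (PC1 > 0) and
B (PC1 < 0) labels follow.

**Saddle strength.** Bins are ranked genome-wide by PC1 into 10
quantiles; the saddle is the mean cis O/E per quantile pair and
strength is `sqrt(AA x BB) / AB` over the extreme 20% corners. Two
caveats worth knowing: (i) corner means computed from the same sparse
matrix that produced the PC1 ranking are upward-biased at low
sequencing depth (ranking correlates with the bins' own noise), so
strength estimates need realistic per-bin depth — the recovery tests
use ~500 contacts per bin, comparable to a usable 100 kb Hi-C map; (ii)
with block-structured compartment profiles the corner statistic is
only approximately the generative boost. Calibration of the estimator
itself is tested under the null with an independent ranking track,
where strength is ~1.

## Trans analysis

The hNAD-by-hNAD interaction matrix is the summed contact count
between the bins of each hNAD pair, in RPM, divided by the number of
bin pairs — invariant to library size. Chromosome-level clustering
(average linkage on Euclidean distances between chromosome interaction
profiles, self-entries treated as missing) reproduces the expected
grouping of strongly interacting NOR-bearing chromosomes in the
simulations.

hNADs are grouped into G1/G2/G3 by hierarchical clustering of their
trans-only profiles. The design here deviates from a correlation
distance deliberately: the three groups differ foremost in interaction
*level* (G2 near-silent, G3 a hub, G1 moderate and mostly G3-coupled),
which any correlation distance is scale-blind to — on the
three-archetype simulation, correlation/average-linkage clustering is
near-chance while Euclidean/Ward recovers the planted labels
essentially perfectly. Groups are then renamed canonically by mean
trans level (G2 lowest, G3 highest), so the labels are stable and
carry the intended semantics regardless of cluster indices.

Centromere distances are edge-to-edge gaps (0 for overlap, `NA` when a
chromosome lacks a centromere record), and per-bin NAD-trans contact
sums are tested against centromere distance with a two-sided Pearson
test; the planted `exp(-d/d0)` proximity factor yields the expected
negative distance correlation. LAD overlap is base-pair based.

## rDNA repeat unit

The 43 kb rDNA repeat is carried as one artificial chromosome at 1 kb
bins, split at 13.3 kb (the canonical pre-rRNA transcript length; the
split is configurable) into the transcribed region (TR) and intergenic
spacer (IGS). Reported quantities: total/cis/trans contact accounting
(cis + trans = total by construction), the cis fraction, per-million
fold enrichment between two libraries, per-chromosome trans contacts
normalised per Mb and per million pairs (the exact normalisation
behind such plots is rarely printed; this one is scale-free in both
library size and chromosome length), and the within-unit TR/IGS block
contrast `mean(within-TR, within-IGS) / mean(TR-IGS)`.

## Insulation and TADs

Diamond insulation at each bin is the mean balanced signal in the
`w x w` square upstream-by-downstream of the bin edge (default
`w = 10` bins, i.e. 200 kb at 20 kb resolution), log2-normalised by
the chromosome mean — chromosome-level rather than genome-level
normalisation absorbs coverage differences between chromosomes.
Boundaries are local minima with prominence (mean flanking maxima
minus minimum) of at least 0.1; TADs are the intervals between
boundaries. NAD edges are matched to the nearest boundary within a
bin tolerance, and |insulation| at hNAD vs other-NAD edges is compared
with a two-sided Wilcoxon test. Between two conditions, each
adjacent-TAD pair contributes `log2` of the inter/intra O/E ratio
change, stratified by whether the shared boundary is an hNAD edge.

## Imaging

Nucleolus segmentation follows the per-frame recipe: Otsu
binarisation, removal of clusters under 4 pixels, closing with a
5-pixel-radius disk, hole filling. One guard is added: the effective
threshold is floored at the stack-wide Otsu threshold, because on
frames containing no nucleolus at all a per-frame Otsu merely splits
the background noise into a spurious mask. FISH foci are pixels
exceeding the 9x9 mean-filtered image by 50%, components under 4
pixels dropped, linked across frames by overlap; clusters must span
more than 3 consecutive frames ("more than three" is read strictly as
at least 4; `min_z_frames` covers the other reading). An optional
cluster-level total-intensity threshold removes residual non-specific
clusters, mirroring the stated intensity/area cleanup. Distances are
anisotropy-corrected 3D Euclidean distances from the intensity-weighted
centroid to the nearest mask voxel (0 inside); a per-frame 2D reading
of the distance is not implemented because the 3D form subsumes it at
matched voxel sizes.

## The synthetic generator

`sim_config()` fixes every study condition; all generators are
deterministic given `seed`. It emulates, with planted truth:

- depth tracks: Poisson counts around a flat mean (default 100
  reads/bin), `nad_depth_fold = 4` inside planted NADs, lognormal
  per-bin noise of CV 0.3 — the regime in which the depth ratio is
  clearly bimodal;
- contacts: cis decay `distance^-1`, checkerboard compartment blocks
  (10 bins) boosted x2 for same-sign pairs, TAD blocks (10 bins)
  boosted x2, flat trans background boosted x3 between planted hNAD
  bins, optional `exp(-d/d0)` centromere proximity, ~75% cis share;
- NADs are forced into the B compartment, as nucleolar heterochromatin
  is;
- ActD (Pol I inhibition) as a mixing parameter `lambda` that shrinks
  hNAD-specific boosts toward 1, releases hNAD chromatin into new
  one-ended trans contacts, and adds a cross-boundary boost at
  hNAD-edge TAD boundaries — reproducing the known directions of
  nucleolus-disassembly effects;
- an rDNA unit with TR/IGS blocks (contrast = 1/coupling) and a 0.76
  within-unit contact fraction;
- two-channel image stacks: spherical nucleoli with a soft edge
  centred on the planted radius, 3D Gaussian foci at planted surface
  distances, Gaussian background. FISH amplitude is the focus SNR; the
  nucleolus channel has its own (higher) amplitude, as
  immunofluorescence of nucleolar proteins is a strong signal.

What it does not emulate: read-level artefacts, restriction-fragment
geometry, translocations, copy-number variation, irregular compartment
block lengths, chromatic aberration, or optical PSF anisotropy beyond
the voxel grid. Passing recovery tests therefore demonstrate
correctness of the estimators under the stated generative model, not
robustness to every artefact of real libraries.

### Problem sizes

Tests and the acceptance script run on toy genomes of 2-8 chromosomes
of 5-10 Mb (200-800 bins at 100 kb; 5,000 bins at 10 kb for NAD
calling), 1e5-4e5 contacts per matrix, and 160x160x31-voxel image
stacks — sizes chosen so per-bin depth matches usable real matrices
while a full run stays in seconds.

## Known limitations

- The HMM assumes Gaussian within-state ER; heavy-tailed depth noise
  would motivate a t emission, which is not implemented.
- Saddle strength from self-estimated PC1 is biased upward on shallow
  matrices (see above); compare conditions at matched depth.
- The G1/G2/G3 cut is fixed at k = 3 by design; no model selection on
  k is attempted.
- Translocation and hotspot artefacts are not detected; they must be
  masked upstream.
- Chromosome-level exclusions (chrY, unplaced contigs) are the
  caller's responsibility via the chrom.sizes input: any chromosome
  absent from it is rejected, not silently dropped.
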