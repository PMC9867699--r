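# nadscope

Nucleolus-associated domain (NAD) calling and nucleolar Hi-C downstream
analysis in R.

Nucleoli gather a large share of repressive heterochromatin at their
periphery. Sequencing assays expose this in two ways: nucleolus-enriched
libraries (nucleolar Hi-C, nucleolus sequencing) show elevated read
depth over NADs relative to a whole-genome or in situ Hi-C control, and
the contact matrices of such libraries are enriched for B-compartment
and inter-chromosomal heterochromatin interactions. `nadscope`
implements the full downstream analysis of such experiments:

- **NAD segmentation** — per-bin enrichment ratio
  `ER = log2((treatment_RPM + pc) / (control_RPM + pc))`, segmented by
  a two-state Gaussian hidden Markov model (Baum–Welch EM + Viterbi,
  validated against exhaustive path enumeration). NADs with a bin of
  `ER > 1` (a two-fold depth ratio) are flagged high-confidence NADs
  (hNADs).
- **Contact model** — ICE matrix balancing, A/B compartments from the
  leading eigenvector (PC1) of the cis O/E correlation matrix, saddle
  plots with compartment strength `sqrt(AA·BB)/AB`, and cis/trans
  A-B interaction partitions.
- **Trans analysis** — hNAD×hNAD normalized interaction matrices,
  chromosome clustering, G1/G2/G3 hNAD grouping by trans-interaction
  profile, centromere-distance correlation, LAD overlap percentages.
- **rDNA** — the 43 kb rDNA repeat unit as an artificial chromosome:
  cis/trans accounting, fold enrichment, per-chromosome normalized
  contacts, and the TR/IGS sub-domain contact map.
- **Insulation** — diamond insulation scores, prominence-based TAD
  boundary calling, NAD/TAD boundary coincidence, inter-TAD interaction
  change between conditions (e.g. Actinomycin-D nucleolar disassembly).
- **Imaging** — 3D FISH-to-nucleolus distances: per-frame Otsu
  nucleolus segmentation with morphological cleanup, FISH focus
  detection with z-persistence filtering, anisotropy-corrected
  distances.
- **Synthetic data** — a first-class generator (`sim_config()` and the
  `simulate_*()` family) that plants NADs, compartments, TADs, trans
  boosts, an rDNA unit and image stacks with known truth, so every
  stage is testable end to end.

Standard formats are used throughout: bedGraph, BED4/5, chrom.sizes,
HiC-Pro matrix + bed contact triplets.

## Worked example

Call NADs on a synthetic dataset with 20 planted NADs (fold 4 depth
enrichment, CV 0.3 noise) on a 50 Mb toy genome at 10 kb bins:

```r
library(nadscope)

cfg <- sim_config(seed = 7, n_chroms = 5, chrom_length_bp = 10e6,
                  bin_size = 10e3, nads_per_chrom = 4,
                  nad_length_bp = 500e3, nad_depth_fold = 4,
                  depth_noise_cv = 0.3)
tracks <- simulate_depth_tracks(cfg)
er     <- compute_er(tracks$treatment, tracks$control)
model  <- fit_hmm(er)
print(model)
#> Two-state Gaussian HMM: inter mean -0.682 (sd 0.634), NAD mean 1.319 (sd 0.613)
#>   transition stay-probabilities: 0.995 / 0.979; loglik -4992.85 (13 iterations)

call <- filter_hnads(viterbi_segment(er, model), er)
print(call)
#> NADCall: 20 NADs (20 hNADs), 10.0 Mb total

ov <- overlap_stats(hnad_set(call), cfg$planted_nads, cfg$binning)
cat(sprintf("overlap with planted NADs: %.1f%% (hypergeometric p = %.3g)\n",
            100 * ov$overlap_fraction, ov$hypergeom_p))
#> overlap with planted NADs: 99.7% (hypergeometric p = 0)
```

The two state means differ by ~2 log2 units — the planted four-fold
depth ratio — and all 20 planted NADs are recovered and pass the hNAD
filter. `run_pipeline()` chains the same stages (plus compartments,
grouping, insulation and rDNA accounting when a contact matrix is
supplied) from files on disk into a deterministic `report.json`;
`inst/cli/nadscope.R` is a thin shell wrapper over the same functions.

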