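---
title: "Methods: differential proximity-labeling analysis in proxidiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential proximity-labeling analysis in proxidiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxidiff)
```

## The experiment the pipeline models

In-vivo BioID proximity labeling compares a bait fusion (an Ezrin-BioID
construct, `EZR`) against a soluble cytosolic BioID control (`CYT`) in two
genotypes, wild type (`WT`) and a mutant (`GS`), with three biological
replicates per genotype x construct — 12 biological samples — plus three
injections of a study-pool QC (`SPQC`) pooled from equal volumes of every
sample. Label-free quantification yields a peptide x sample intensity
matrix with intensity-dependent missingness. The scientific question is
two-staged: which proteins are near the bait at all (EZR vs CYT within a
genotype), and which of those change their proximity with genotype
(GS-EZR vs WT-EZR)?

## Processing stages

The stages run in a fixed order; each returns a matrix tagged with a stage
marker so they cannot be composed out of order.

1. **Filter.** A peptide is kept only if observed at least twice across
   all samples and in at least 50% of the replicates of some biological
   group. Peptides seen only in SPQC pools fail the group clause and are
   removed; SPQC columns still count toward the twice-overall clause.
2. **Total-intensity normalization.** Each sample is scaled so its summed
   observed intensity equals the across-sample mean total. This corrects
   gross loading differences before any imputation that depends on
   intensity magnitudes.
3. **Imputation** (three branches, per peptide x biological group):
   * *binned normal* — when less than half the group is missing, missing
     entries are drawn from a normal distribution fitted to all observed
     values in the log10-intensity bin (20 equal-width bins spanning all
     observed values) containing the peptide-group's observed mean;
   * *misaligned zero* — when at least half the group is missing and the
     observed mean exceeds 5e6, the feature is treated as a chromatographic
     misalignment (a spuriously matched high-intensity feature) and every
     entry of that peptide in that group, measured ones included, is set
     to 0;
   * *low value* — all remaining missing entries get the 2% quantile of
     all detected values, a deterministic left-censoring floor.
4. **Trimmed-mean normalization.** Per sample, the mean of positive
   intensities after discarding the top and bottom 10% (by rank,
   `floor(0.1 n)` per tail) is equalized across samples.
5. **Protein inference and roll-up.** Shared peptides are razor-assigned
   to the candidate with more identified peptides; proteins identified by
   exactly the same peptide set are merged into a group labeled by a
   master accession; assigned peptide intensities are summed per protein
   and sample. Intensity is conserved exactly at this step.
6. **Statistics.** Per-protein two-tailed Welch (heteroscedastic) t-tests
   on log2 intensities, with the log2 fold-change defined as the
   difference of group means of log2 values. Fold-changes are reported as
   signed ratios (`+r` for `r >= 1`, `-1/r` otherwise), so thresholds read
   "> 1.5 or < -1.5". Benjamini-Hochberg adjusted p-values are reported
   alongside (`p_adjusted`), but the screen deliberately uses the
   unadjusted p to favor discovery.
7. **Interactor calling.** Stage one: bait enrichment per genotype
   (EZR vs CYT, signed FC > 1.5, p < 0.05). Stage two: the genotype
   contrast of bait samples (GS-EZR vs WT-EZR). *Gained* proteins are
   GS-enriched with contrast FC > 1.5 and p < 0.05; *lost* proteins are
   WT-enriched with contrast FC < -1.5 and p < 0.05. The opposite-sign
   requirements make the sets disjoint.
8. **QC.** Per-protein %CV (100 x sd/mean, linear scale, n-1 denominator)
   over SPQC injections (technical precision) and within biological groups
   (biological + technical variability), and a PCA of samples on
   log2-transformed, per-protein-centered protein intensities.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `fc_threshold` | 1.5 | signed fold-change screen (ratio units) |
| `p_threshold` | 0.05 | unadjusted p screen |
| `trim_fraction` | 0.10 | per-tail trim in trimmed-mean normalization |
| `n_bins` | 20 | log10-intensity bins for binned-normal imputation |
| `misaligned_cutoff` | 5e6 | intensity above which a mostly-missing group is zeroed |
| `low_percentile` | 0.02 | left-censoring floor quantile |
| `missing_dialect` | blank_is_missing | how the input table encodes missing values |
| `seed` | — | required; fixes the imputation draws |

The missing-value dialect is explicit configuration and never inferred:
exported intensity tables mix true missing values with deliberate zeros
(the misaligned branch writes them), and the two must stay
distinguishable. Intensities stay on the linear scale through every
normalization and roll-up; log2 happens only inside the statistics.

## Numerical choices

* **Bins are equal-width in log10 intensity** over the global observed
  range. Intensities span several decades; linear bins would put nearly
  all mass into one bin and starve the rest.
* **The misaligned trigger compares the group's observed mean** to the
  cutoff on the post-total-normalization scale; a single per-group summary
  is needed and the mean is the least arbitrary.
* **The low-value floor is a quantile point**, not a random draw from the
  bottom tail — determinism matters more than imitation of noise at the
  censoring limit.
* **Branch-2 zeros survive roll-up sums.** For log2 statistics, values
  at or below zero are floored at half the low-value quantile
  (`zero_floor`), since log2(0) is undefined; the floor sits below every
  genuine intensity so zeroed features land at the bottom of the scale.
* **Truncated draws:** binned-normal imputation rejects draws <= 0 and
  resamples (up to 50 rounds, then the low-value floor), keeping imputed
  intensities positive. Bins holding fewer than two observed values fall
  back to the global mean/sd; the audit records the fallback.
* **Degenerate tests:** a protein with zero variance in both groups
  resolves to p = 1 when the means are equal and p = 0 otherwise —
  imputation floors can create exact ties, and an error would abort a
  whole contrast for one constant row.
* **Tie-breaks are lexicographic on accession** everywhere (razor
  assignment, master selection), making results independent of row order
  and platform.
* **SPQC columns form their own imputation group** and only receive the
  low-value branch: the pools are technical replicates of a mixture, and
  fitting binned-normal draws across heterogeneous pool values would
  fabricate variance.
* **PCA sign convention:** within each component the loading of largest
  magnitude is made positive, so embeddings are reproducible across
  platforms and sample orders.

Razor peptide counts are computed over filter-surviving peptides, the
dataset the analysis actually sees. Protein grouping operates on the
candidate (identification) peptide sets: two accessions matched by exactly
the same surviving peptides are indistinguishable and merge, with the
master chosen by % coverage when protein lengths are supplied (peptide
length = `nchar(peptide_id)`, i.e. ids-as-sequences) and by identified
peptide count, then accession, otherwise.

## The synthetic-data generator

`synth_params()` / `simulate_bioid()` generate the full design with ground
truth, so every stage is testable without any external download.

* Protein base abundances are lognormal (meanlog `log(2e6)`, sdlog 1.2 —
  roughly 2.5 decades of dynamic range at 2 sd); each protein carries 2-13
  peptides (mean ~7.5, the typical peptide-to-protein ratio of a deep
  label-free study) with fixed lognormal ionizability (sdlog 0.8).
* Bait-proximal proteins (10% of proteins by default) are enriched
  4-fold in EZR columns; 20% of those are genotype-modulated, split evenly
  into gained (x3 in GS-EZR) and lost (/3 in GS-EZR).
* Biological noise (CV 16.5%) applies per protein x biological sample,
  technical noise (CV 11%) per protein x injection, so the protein-level
  group CV is about 20% and the SPQC CV about 11% — the scale of
  variability a well-behaved affinity-purification LC-MS study reports.
  Both noises act at the protein level and are inherited by the protein's
  peptides; peptide-level variation enters only through the fixed
  ionizability factor. This is a deliberate simplification: it makes
  protein-level %CV match the generating CVs exactly, at the cost of
  unrealistically correlated peptides within a protein.
* SPQC columns are the noiseless mean of the 12 biological columns times
  technical noise — a pool of equal volumes.
* Dropout is logistic in log10 intensity (midpoint 1e5, steepness 2 per
  decade), a missing-not-at-random left-censoring mechanism that yields
  ~10-15% missingness at the default abundance scale.
* Misaligned features (1% of peptides) get one spurious high intensity
  (log-uniform over 2e7-1e8) in one column of one biological group while
  the group's other columns go missing — exactly the mostly-missing,
  high-intensity pattern the zeroing branch targets.
* 5% of peptides are additionally mapped to a second random protein to
  exercise the razor rules.

Everything is fixed by `seed`; `apply_missingness()` uses an offset seed
so it is reproducible standalone.

What the generator does **not** emulate: peptide-level variance structure
(all peptides of a protein fluctuate together), retention-time or m/z
structure, interference/chimeric spectra, batch drift across the run
order, contaminant proteins, and the spiked internal standards. Passing
recovery tests on this generator therefore demonstrates that the pipeline
implements its rules correctly and recovers planted effects under
realistic noise, dropout and misalignment — not that it is robust to every
pathology of real LC-MS data.

## Validation problem sizes

The packaged tests validate rule implementations against brute-force
evaluators on hundreds of randomized small fixtures, check closed-form
values (Welch t on {2,4,8} vs {16,32,64}: t = -3.674, df = 4; BH on
(0.01, 0.02, 0.03, 0.04): all 0.04; 10% trimmed mean of 1..10: 5.5; %CV of
(9,10,11): 10%), and run the full pipeline at 2000 proteins over 20 seeds
for both a null calibration and planted-truth recovery (observed: mean
sensitivity ~0.97, mean false-discovery proportion ~0.09, and complete
EZR/CYT separation on PC1).

One calibration property deserves a caveat. Under a complete null the
two-stage caller still produces occasional false calls (about one per
2000-protein dataset): the bait-enrichment test and the genotype contrast
share the GS-EZR group, so their statistics are correlated (rho = 0.5), and
the joint probability of passing both screens is ~2e-4 per protein rather
than the ~6e-4 squared-marginal one might expect under independence — small,
but not negligible at thousands of proteins. A workflow that needs a
strictly empty null list should screen the second stage on the adjusted
p-value instead; with the published thresholds the expected
false-discovery proportion among called proteins remains below 10% at the
simulated effect sizes.

## Known limitations

* The Welch test at n = 3 is conservative (null p < 0.05 fraction ~0.035);
  no moderated-variance (empirical Bayes) alternative is provided, by
  design — the pipeline mirrors plain heteroscedastic t-tests.
* Coverage-based master selection needs protein lengths and
  sequence-like peptide ids; without them the peptide-count/accession
  fallback is used.
* The misaligned-zero branch erases a whole peptide-group on a single
  intensity summary; a feature legitimately present in only one replicate
  at high intensity is indistinguishable from a misalignment and will be
  zeroed.
* Group-level imputation assumes the genotype x construct groups are the
  right exchangeability units; designs with batch structure inside groups
  are not modeled.
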