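# clockprot

Classification of clock-dependent proteomes from multiplexed TMT
experiments.

## What this is for

Peripheral-tissue protein abundance is controlled jointly by the local
circadian clock (the transcription activator BMAL1), the clock system of the
rest of the body, and daily feeding-fasting behavior. Experiments that
profile liver and muscle proteomes from wild-type (WT), whole-body
*Bmal1*-knockout (KO) and tissue-reconstituted (RE) mice under ad libitum
(AL) or time-restricted feeding (TRF) can apportion control between these
layers -- if the statistics are done carefully. `clockprot` implements that
analysis as a tested, reusable R pipeline:

* **Normalization** (`filter_features`, `reference_normalize`): Perseus-style
  removal of decoy / contaminant / single-oxidized-peptide entries, then
  log2 ratios to the pooled reference channel of each TMT plex with
  per-sample median centering. The ratio to the in-plex reference cancels
  plex batch factors exactly.
* **QC** (`abundance_pca`, `flag_outliers`): PCA on centered log2 values and
  a parametric distance rule that flags samples far from their
  (genotype, feeding) group in PC1/2. Flags are reported, never silently
  applied.
* **Differential abundance** (`pairwise_ttest`, `bh_adjust`,
  `two_way_anova_tukey`): pooled-variance Student's *t* per protein with
  Benjamini-Hochberg *q* values per contrast; type-II two-way ANOVA with
  Tukey-Kramer pairwise comparisons.
* **Decision rules** (`call_dependent`, `classify_rescue`,
  `call_feeding_responsive`, `cross_tissue_overlap`,
  `secreted_fraction_test`, `subunit_set_average`): a protein is
  *Bmal1-dependent* if q < 0.05 for WT vs KO under AL; *rescued* if the
  rescue genotype differs from KO (q < 0.05) but not from WT (q >= 0.05);
  *feeding-responsive* if q < 0.05 for AL vs TRF within a genotype.
* **Rhythmicity** (`fit_harmonic_models`, `fit_mean_models`,
  `rhythm_analysis`, `peak_phase_filter`): two-group cosinor model
  enumeration (five hypotheses, 24 h period) selected by BIC weights, plus
  shared-vs-distinct mean models for differential daily average expression.
* **Concordance** (`join_omes`, `concordance_fractions`, `reverse_lookup`):
  which protein changes have a transcriptional counterpart, and which
  dark-phase-peaking rhythmic genes have altered proteins.
* **Enrichment** (`ora`): hypergeometric overrepresentation of gene sets
  (GMT) against the detected proteome.
* **Synthetic data** (`sim_params`, `generate_design`, `simulate_proteome`,
  `simulate_transcriptome`): a generator with planted ground truth -- known
  dependent/rescued/feeding-responsive proteins, rhythmic and mean-shifted
  genes, batch effects, an optional corrupted sample -- used throughout the
  tests to verify recovery.

The model at the core of the rhythm module: expression
`y = mesor + A*cos(2*pi*(t - phase)/24) + noise`, fit per gene and genotype
under five hypotheses (no rhythm / one group only x2 / shared / distinct),
compared by `BIC = n*log(RSS/n) + (k+1)*log(n)` and weights
`softmax(-BIC/2)`.

## Worked example

```r
library(clockprot)

params <- sim_params(n_proteins = 2000, n_genes = 1000, seed = 7)
design <- generate_design(params)
sim    <- simulate_proteome(design, params)

am   <- filter_features(sim$matrix)          # drops flagged entries
norm <- reference_normalize(am, design)      # log2 ratios to pooled reference

dep <- call_dependent(pairwise_ttest(norm, design, "WT_AL", "KO_AL"))
lab <- classify_rescue(dep,
         pairwise_ttest(norm, design, "RE_AL", "KO_AL"),
         pairwise_ttest(norm, design, "WT_AL", "RE_AL"))

tx   <- simulate_transcriptome(params, protein_truth = sim$truth)
fits <- rhythm_analysis(tx$expression)
recs <- join_omes(lab, fits,
                  data.frame(protein_id = am$features$protein_id,
                             gene = am$features$gene))
```

Output printed by this run:

```
filter_features: removed 45 of 2000 features
dependent: 199 of 1955 = 10.18 %
rescued: 71  nonrescued: 128
rhythmic in WT (models 3-5): 312 of 1000
join_omes: 167 dependent protein(s) joined, 32 unmapped
mRNA mean change among dependent proteins: 51.5 %
window-rhythmic genes with altered protein: 20.95 % of 105
```

Reading: 10.18% of detected proteins are called clock-dependent (the
generator planted 12% with a 1 log2-unit effect at noise SD 0.25; the
BH-limited power of a pooled t at n = 4 recovers ~85% of them here).
Rescued + nonrescued (71 + 128) exactly partition the dependent set. About
half of the dependent proteins have a corresponding mRNA mean change
(planted concordance was 55%), and ~21% of dark-phase-peaking rhythmic
genes have an altered protein -- the two concordance directions the
pipeline is designed to quantify.

The same analysis runs end to end from a config with `run_pipeline()`
(stages: simulate/load, filter, normalize, QC, contrasts, classify, rhythm,
concordance, enrichment), writing per-stage TSVs and a deterministic
`summary.json`; a thin CLI lives at `inst/cli/clockprot.R`
(`simulate` / `run-all` subcommands).

## Notes

See `vignettes/clockprot-methods.Rmd` for the statistical model, the
synthetic world, numerical choices (RSS flooring in BIC, half-up rounding,
strict thresholds), and two documented calibration limits of the stated
test world (dependence-call recall under BH adaptivity; scale-free outlier
thresholds).
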