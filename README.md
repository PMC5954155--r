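# crispritox

Analysis of pooled CRISPRi (dCas9) fitness screens in bacteria, built for
the questions such screens raise in *E. coli*-like genomes: which guides
deplete, and is each depletion an on-target effect, an operon polar
effect, a seed-match off-target, or the sequence-intrinsic "bad-seed"
toxicity carried by particular 5-nt PAM-proximal seeds?

The package provides, as composable functions under `R/` driven by the
numbered scripts in `analysis/`:

* **Guide handling** — NGG PAM scanning on both strands (0-based,
  forward-strand coordinates), 20-nt spacer extraction, annotation with
  gene context and orientation (`coding` = protospacer on the gene's
  sense strand, the orientation that blocks transcription elongation).
* **Fold changes** — median-of-ratios size factors, per-replicate
  `log2((end/sf + 1)/(start/sf + 1))` anchored to a control guide, and
  the <20-total-reads discard rule.
* **Region segmentation** — an orientation-stratified 1-D regression
  tree over PAM position; leaves predicting log2FC < −3.5 are the
  "important regions", the rest the neutral set. Rolling averages and a
  reverse-polar window test (0–100 vs 100–200 nt past isolated
  essential-gene ends) complete the positional analyses.
* **Sequence model** — a locally connected network (hidden layers
  40/20/10/5, each unit wired to the 5 proximal units of the previous
  layer, tanh, Adam, MSE + L2, patience-2 early stopping,
  validation-selected restarts) predicting log2FC from the one-hot
  spacer, with in-silico saturation mutagenesis (per-position effect
  std over 1000 random sequences) and a pairwise interaction matrix
  (mean Euclidean distance between double-mutation effects Eij and
  summed singles Ei + Ej over 100 random sequences).
* **Seed statistics** — per-5-mer group summaries, one-sided one-sample
  t-tests against the template-strand reference mean with Bonferroni
  correction over 1024 seeds, and cross-strain OLS of per-seed means.
* **Off-targets** — a PAM-proximal k-mer index of all NGG sites, maximal
  seed-match extension, importance rules aware of orientation and operon
  polarity, the k = 6..15 detection-rate sweep with its difference
  curve, and a Fisher exact test for off-target enrichment among
  unexpected-defect guides.
* **A synthetic screen generator** (`sim_config()`, `simulate_screen()`)
  that plants all of the above — strand-dependent essential-gene
  depletion, polar and weak reverse-polar effects, toxic seeds with
  dose-dependent τ, exact-k off-targets, negative-binomial counts — and
  records a per-guide ground-truth ledger for parameter-recovery
  validation.

## Worked example

```r
library(crispritox)

sim <- simulate_screen(sim_config(rng_seed = 1))     # ~7k guides, 50 kb
res <- analyze_screen(sim)                           # full pipeline

screen_report(res, sim)
```

On the default conditions this prints (seed 1):

```
$n_guides                      7062
$n_discarded                   60
$n_neutral_guides              5556
$n_significant_seeds           20
$offtarget_argmax_k            9
$fisher_p                      1.78e-72
$frac_template_neutral_defect  0.0683
$model_test_pearson            0.803
$model_test_rmse               1.012
$seed_block_interaction_ratio  34.2
$bad_seed_recall               1
$bad_seed_false_positive_rate  0
$per_seed_effect_pearson       0.998
```

Reading it: all 20 planted toxic seeds are recalled at Bonferroni
p < 0.01 with no false positives, and the recovered per-seed means track
the planted toxicities at r = 0.998. About 6.8% of template-strand
guides in neutral genes show an unexpected strong defect; the
detection-rate difference curve peaks at a seed identity of 9 nt, the
planted off-target length, and defect guides are massively enriched for
important-region off-targets (Fisher p ≈ 1e-72). The sequence model
explains the neutral-region fitness variation at r = 0.80 on held-out
guides, and its attribution concentrates on spacer positions 16–20 — the
5 PAM-proximal seed bases — with an interaction density in that block
~34× the rest of the matrix.

The `analysis/` scripts run the same stages as a narrative workflow over
a written run directory (`01_simulate.R` → `08_dose_response.R`), saving
fitness tables, tree leaves, detection curves and the cross-strain
per-seed comparison under `results/`.

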