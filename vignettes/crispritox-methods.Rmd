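---
title: "Models and methods behind crispritox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crispritox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`crispritox` analyses pooled CRISPRi (dCas9) fitness screens in bacteria.
A guide library is grown competitively; deep sequencing of the guide locus
at the start and end of the competition yields per-guide read counts, and
the analysis asks which guides depleted, why, and what that reveals about
dCas9 itself: strand-dependent repression of essential genes, operon
polarity, seed-match off-targets, and a sequence-intrinsic toxicity shared
by guides with particular 5-nt PAM-proximal seeds.

Because the interesting claims are causal ("this guide depleted *because*
of its seed"), every stage is validated on a synthetic screen whose causes
are planted and recorded. The generator is first-class, tested code, not a
fixture.

# The measured quantity

For guide $g$ in replicate $r$,

$$\mathrm{log2FC}_{g,r} = \log_2\frac{e_{g,r}/s^{\mathrm{end}}_r + p}
{b_{g,r}/s^{\mathrm{start}}_r + p} \;-\; (\text{same for the control guide}),$$

where $b,e$ are start/end read counts, $s_r$ are median-of-ratios size
factors estimated jointly over all samples, and $p = 1$ is a pseudocount
on normalized counts (end counts of lethal guides are legitimately 0 and
must not produce infinities). The reported value is the mean over
replicates. Guides with fewer than 20 reads in total across samples are
discarded. The control guide (spacer `TGAGACCAGTCTAGGTCTCG`, targeting
nothing of consequence) anchors the scale: its log2FC is identically 0.

Two numerical caveats are worth recording. First, median-of-ratios medians
are averaged on the log scale for even group sizes, which makes the
estimator agree with `DESeq2::estimateSizeFactorsForMatrix` to machine
precision. Second, rescaling one of $m$ samples by a constant $c$ rescales
the joint geometric-mean reference by $c^{1/m}$, so with a pseudocount the
log2FC values are depth-invariant only up to a residual of order
$p\,\Delta(1/\mathrm{count})$ — about $10^{-4}$–$10^{-3}$ at counts of a
few hundred. The property test asserts the achievable bound ($2\times
10^{-3}$), not an idealized zero.

# Positional structure: the region tree

A 1-D CART regression tree (exhaustive variance-reduction splits, leaf
prediction = member mean) is fitted to log2FC against PAM position,
separately within each orientation class (`coding`, `template`,
`promoter`, `intergenic`). Orientation is defined operationally:
*coding* means the protospacer and PAM lie on the targeted gene's sense
strand, the orientation in which dCas9 blocks transcription elongation.
The tree's leaves partition the genome per orientation; leaves predicting
log2FC below −3.5 (the strong-defect threshold used throughout) are the
"important regions", and guides in the remaining leaves are the
neutral-region set used for sequence modelling and seed statistics.

Defaults `min_leaf = 10`, `max_depth = 14` let leaves resolve single
genes on genomes from tens of kb to several Mb without chasing individual
guides. The tree is implemented in the package (prefix-sum exhaustive
search) so that leaf intervals are available exactly; `rpart` reproduces
its splits and is used as an independent cross-check in the test suite.

Rolling averages (centered windows over sorted coordinates) and the
reverse-polar window test complete the positional analyses. The latter
compares coding-strand guides 0–100 nt and 100–200 nt past the ends of
isolated essential/fitness genes (genes with no other essential/fitness
gene body within 200 nt downstream) against the mean of template-strand
guides in gene bodies, by two-sided one-sample t-tests. Guides in
annotated promoters are excluded from the windows — initiation block of
the downstream operon is a different, strong effect — and the workflow
additionally masks important-region guides out of the windows, because in
a dense genome the far window frequently lands in polar conduits of the
next operon. Even so, the reference population (template-strand guides)
carries the bad-seed and off-target tail, so its mean sits slightly below
a clean neutral baseline; the far window can therefore deviate mildly on
the *positive* side. The supported conclusion is directional: near-window
guides are depleted relative to both the reference and the far window.

# The sequence model

The locally connected regressor maps the one-hot spacer (position-major,
channels A, C, G, T) to log2FC through hidden layers of 40, 20, 10 and 5
tanh units and a dense linear scalar output. Unit $i$ of a layer with $n$
units over a previous layer of $m$ units connects to units
$\lfloor (i-1)\,m/n \rfloor + 1 + \{-2,\dots,2\}$ (clipped), so locality
follows sequence order and each unit carries at most 5 incoming weights —
about 7% of the dense parameter count, asserted structurally in the
tests. Training minimizes MSE with L2 penalty ($\lambda = 10^{-4}$) by
Adam (batch 64, at most 200 epochs) and stops when validation loss has
not improved for more than 2 epochs, restoring the best weights.

Two training choices deserve their rationale:

* **Learning rate $10^{-2}$.** With patience-2 early stopping, smaller
  rates stall: runs halt on a noisy plateau long before the validation
  asymptote (validation MSE ~2.2 at $10^{-3}$ vs ~1.1 at $10^{-2}$ on the
  default simulation). The rate was selected on validation loss alone.
* **Eight validation-selected restarts.** A 75-unit sparse network has
  large run-to-run variance, and the early stop leaves a heavy right tail
  of validation losses. `train_model` runs independently initialized
  restarts and keeps the one with the lowest validation MSE. Test-set
  metrics never enter the selection.

Data are split 80/10/10 stratified by the 5-nt seed, so every seed group
is represented proportionally in each split; the split and all training
randomness are controlled by a single recorded seed, and training is
exactly reproducible (and locale-independent — all grouping and ordering
uses locale-free comparisons).

# Attribution by in-silico mutagenesis

For 1000 random uniform sequences, every position is mutated to each of
the 3 alternative bases and the change in prediction recorded; the
standard deviation of these changes per position is the positional
importance profile. For 100 random sequences, all $\binom{20}{2}$
position pairs are doubly mutated: for pair $(i,j)$ the 9-vector of
double-mutation effects $E_{ij}$ is compared with the 9-vector of summed
single effects $E_i + E_j$ by Euclidean distance, averaged over
sequences. Any model additive across positions gives an exactly zero
matrix, which is the calibration point used in the tests (a linear
predictor yields entries below $10^{-12}$). A 20-nt model reported in
60-nt target-window coordinates has identically zero importance outside
the spacer.

# Seed statistics and bad-seed calling

Guides are grouped by their 5 PAM-proximal bases (1024 possible seeds).
Within the neutral-region restriction, each seed group's mean log2FC is
tested against the mean of template-strand guides in gene bodies by a
one-sided (lower) one-sample t-test, Bonferroni-corrected by 1024; a seed
is called at corrected $p < 0.01$ when its mean is below the reference.
Groups under 3 guides are reported but marked insufficient. The
cross-strain comparison regresses per-seed means in a low-dCas9 strain on
those in the reference strain by OLS; a slope below 1 quantifies
attenuation of the seed-specific toxicity.

# Off-target detection

Every NGG site in the genome is indexed by its PAM-proximal k-mer read
outward from the PAM. A guide's off-targets at minimum identity $k$ are
the sites whose maximal base-by-base PAM-proximal extension matches at
least $k$ nt (no gaps, PAM always required), excluding the guide's own
site. A site can silence an important region if it falls in a gene body
in coding orientation where the gene or anything downstream in its operon
is essential/fitness, or in the promoter of an operon containing an
essential/fitness gene (either orientation); an orientation-blind variant
is available. The detection-rate sweep computes, for $k = 6..15$, the
fraction of unexpected-defect guides (template strand of neutral genes,
log2FC < −3.5) and of no-defect guides with at least one important-region
hit; the difference curve estimates the fraction of defects explained by
off-targets, and its argmax identifies the minimal identity that
functions in vivo. A Fisher exact test on the 2×2 defect × hit table
accompanies the curve.

# The synthetic screen

The generator emulates the structure the analyses assume, with defaults
fixed as the package's study conditions:

* **Genome**: 50 kb i.i.d.-uniform ACGT, 40 genes of 600–1000 nt in
  operons of 1–4 (probabilities 0.45/0.30/0.15/0.10), 60-nt promoters on
  operon-leading genes, 25% essential / 15% fitness genes. At uniform
  composition a genome carries ~2L/16 NGG sites, so the default library
  (every extractable site plus planted sites) is ~7,000 guides — the
  natural capacity of this genome size.
* **Effects** (end-vs-start log2 units, the screen's measured scale):
  silencing an essential gene costs −8, a fitness gene −4; coding-strand
  guides silence their gene and everything downstream in the operon;
  promoter guides (either orientation) silence the whole operon; a weak
  reverse-polar effect of −0.5 applies to coding-strand guides 0–100 nt
  past an essential/fitness gene end, none at 100–200 nt.
* **Bad seeds**: 20 seeds are drawn and each planted at 40 sites in
  neutral intergenic zones by writing the seed directly 5' of a created
  PAM; toxicity $\tau_s = -\max(3, |N(4,1)|)$ scales linearly with the
  dCas9 level (level 1.0 = the reference high-expression strain, 0.4 ≈ a
  strain expressing ~2.5-fold less). Incidental carriers of a planted
  seed elsewhere in the genome inherit the effect, as they must.
* **Off-targets**: 60 template-strand guides in neutral genes (about a
  quarter to a third of the eventual unexpected-defect set) each donate
  their 9 PAM-proximal bases, which are copied with an NGG into an
  essential/fitness gene body in coding orientation; the 10th base is
  forced to mismatch so the planted identity is exactly 9 nt. Off-target
  effects scale as $\mathrm{level}^{0.5}$ — attenuated at low dCas9 like
  the bad-seed effect but retained more strongly, which mirrors the
  observed asymmetry between the two phenomena.
* **Counts**: start abundances are Dirichlet-uniform, except the control
  guide, which enters at exactly average abundance (it is a designed
  spike-in; drawing it from the clone-share tail would hand its sampling
  noise to every anchored value). End abundances are start × $2^{\text{effect}}$,
  renormalized as in a competitive pool; counts are negative-binomial
  (dispersion 0.05) at 500 reads/guide/sample — a desk-scale stand-in for
  the millions of reads of a real screen — over 3 replicates. Screens of
  the same library at different dCas9 levels share the genome and all
  planted structure but draw independent sequencing noise, as independent
  experiments do.

What the generator does *not* model: PCR jackpots and bottlenecks,
guide-to-guide on-target efficacy variation, growth-phase dynamics within
the 17 generations, or any mechanism for *why* particular seeds are
toxic. Passing the recovery tests therefore shows the analysis correctly
inverts this generative structure at realistic noise — not that real
screens contain no further structure.

# Problem sizes and determinism

The default end-to-end analysis (simulation, fold changes, tree, seed
statistics, off-target sweep, model training with 8 restarts, both
mutagenesis scans) runs in roughly a minute on one CPU; the test suite
uses the same default conditions once and smaller fixtures elsewhere.
Every random stage funnels through recorded integer seeds, so reruns are
byte-identical; the count-noise seed is derived from (seed, dCas9 level)
so paired strains are reproducible yet independent.

# Known limitations

* The per-seed group sizes of incidental (non-planted) seeds are small
  (~6 at this genome size), so the bad-seed test's power statement is
  about planted seeds; null seeds contribute the false-positive estimate.
* The reference population for seed testing and the polar test inherits
  the screen's own defect tail (as in the source protocol); comparisons
  against it are conservative for bad-seed calling and can push the far
  polar window slightly positive.
* Exact DESeq2 parity is limited to size factors; no dispersion shrinkage
  is performed, since downstream analyses consume point log2FC only.
* The locally connected topology fixes the proportional anchoring of the
  connectivity; other plausible "5 proximal units" mappings exist and
  would change weights but not the analysis design.
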