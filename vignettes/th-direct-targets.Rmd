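---
title: "Methods: identifying TH direct response genes and their TREs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying TH direct response genes and their TREs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thtargets)
```

# The experimental logic

Thyroid hormone acts through the TR/RXR heterodimer bound to DR4 thyroid
response elements in target promoters. Its transcriptional program has two
tiers: direct targets, transactivated by liganded TR itself, and late
targets, which require proteins encoded by the first tier. Cycloheximide
(CHX) blocks translation, so in a factorial design — control, TH, CHX,
TH+CHX — a gene that responds to TH both with and without CHX needs no new
protein synthesis and is classified a direct target. `thtargets` implements
that inference and the downstream promoter analysis, together with a
simulator of the design so every claim is testable against known truth.

# Differential expression model

Counts for gene $g$ in sample $j$ are modelled as negative binomial with
mean $s_j \mu_{gc(j)}$ and variance $\mu + \alpha\mu^2$, where $s_j$ is a
sample size factor and $c(j)$ the sample's condition. For one contrast
(conditions $A$, $B$, each with $\ge 2$ replicates):

1. **Normalization.** Median-of-ratios size factors over the contrast's
   samples: the reference is the per-gene geometric mean over samples
   (genes observed in every sample), and $s_j$ is the median ratio to it.
   Library size for FPKM is the raw column sum; alignment-based "mapped
   read" totals are not available at the count-matrix level, so the column
   sum stands in for them.
2. **Dispersion.** Per-gene method of moments on normalized counts pooled
   within conditions: $\hat\alpha_g = (\hat v_g - \hat m_g)/\hat m_g^2$,
   floored at $10^{-8}$, with $\hat v_g$ the pooled within-condition sample
   variance. With four replicates this estimator has only six degrees of
   freedom and frequently undershoots, which would make a plug-in Wald test
   anti-conservative (we measured an empirical type-I rate of ~0.10 at
   nominal 0.05). We therefore apply the sharing rule classical NB
   differential-expression tools use: a parametric trend
   $\alpha(\mu) = a_0 + a_1/\mu$ is fitted across genes and each gene uses
   $\max(\hat\alpha_g, \alpha(\hat\mu_g))$. The maximum (rather than the
   trend alone) keeps genuinely noisy genes conservative. The tests verify
   the resulting type-I rate is within $0.05 \pm 0.02$ on a 2000-gene null.
3. **Effect and test.** $\log_2\mathrm{FC} = \log_2\frac{\bar k_B + 0.5}
   {\bar k_A + 0.5}$ on normalized counts; the pseudo-count 0.5 keeps
   zero-mean genes finite. The Wald statistic divides by the delta-method
   standard error from the NB variance; p-values are two-sided normal,
   adjusted by Benjamini–Hochberg. Genes with zero counts in every sample
   get missing p-values and are excluded from the BH denominator.

The **DET filter** is exactly the published rule: $|\log_2\mathrm{FC}|
\ge 1$ (inclusive) and adjusted $p < 0.05$ (strict).

# Target classification

Given DET sets for TH-vs-control and TH_CHX-vs-CHX over the same gene
universe:

* `direct_up` / `direct_down` — DE in **both** focal contrasts with the
  **same sign**. Direction concordance is required: the direct class is
  defined by genes *commonly* up- or downregulated across the two
  comparisons, and a sign flip under CHX is biologically a different
  phenomenon. Genes DE in both contrasts with opposite signs are flagged
  `discordant` and excluded from the direct class rather than silently
  dropped.
* `late` — DE in TH-vs-control only (CHX-sensitive response).
* `chx_response` — DE in CHX-vs-control but not TH-vs-control; this class
  is a labelled convention for genes the translation block itself perturbs
  (CHX rapidly upregulates ribosome-biogenesis genes, among others).
* `null` — everything else. Labels partition the universe.

The TH_CHX-vs-control contrast is computed and persisted by the pipeline
for inspection but plays no role in labelling.

The package ships the published 45-gene direct-target table (39 up, 6 down)
with its printed statistics; feeding those through `call_dets` and
`classify_targets` reproduces the printed counts exactly, which pins the
filter and overlap semantics independently of any model fitting.

# TRE scanning and the consensus motif

The DR4 element is searched as the degenerate pattern `AGGTCANNNNAGGTCA`
over a promoter window (default 5,000 bp upstream). Choices that the
original text-pattern search left open, and how we fixed them:

* **Mismatch budget applies to the 12 half-site positions only** (default
  4). The four spacer positions are explicitly unconstrained in the DR4
  geometry, so counting mismatches there would conflate spacer composition
  with half-site fidelity. An `N` in the *sequence* counts as a mismatch at
  half-site positions (it cannot be confirmed to match).
* **Both strands are scanned by default**: TR/RXR elements function in
  either orientation. `strands = "forward_only"` mimics a literal text
  search. Reverse-strand hits report the reverse-complement 16-mer as read
  on the matching strand, with `start` on the forward coordinate system.
* **Coordinates are 0-based, half-open** in the BED-like output.
* Promoters shorter than the window are scanned in full; longer sequences
  are truncated to the window adjacent to the transcription start site.
* `best_per_gene` tie-breaking is fixed (fewest mismatches, then leftmost,
  then + strand) so outputs are deterministic.

The scanner is verified against a naive oracle that enumerates every
window × strand and counts Hamming mismatches — 100 random 1-kb sequences,
budgets 0–4, both strand modes, exact hit-list identity.

The consensus model stacks the (N-free) hit 16-mers into per-position base
counts. Information content is $2 + \sum_b f_b \log_2 f_b$ bits (2 =
invariant, 0 = uniform). The consensus letter is the modal base, uppercase
at frequency $\ge 0.75$, lowercase at $\ge 0.5$, else `n`; the thresholds
are exposed because the mixed-case convention (`AGGTCAnnTnAGGTCA`) has no
single published rule. Ties break in A,C,G,T order, deterministically.

# Enrichment, qPCR, length statistics

* **Over-representation** is a plain upper-tail hypergeometric test
  $P(X \ge k)$ per term with BH adjustment, terms intersected with the
  universe first. The universe is the set of genes with a defined adjusted
  p-value in the focal contrast, not all annotated genes. A `weights` hook
  is reserved for length-bias correction but unused: the weighting scheme
  requires per-gene selection probabilities we do not model.
* **qPCR** fold changes use $2^{-\Delta\Delta Ct}$ with a reference gene
  and a calibrator group; calibrator $\Delta Ct$ is aggregated by
  arithmetic mean (a geometric mean on the linear scale), so calibrator
  folds have geometric mean 1 by construction. Group significance is a
  routine one-way ANOVA (`stats::aov`).
* **N50/N90** follow the assembly-stats convention: the first length, in
  descending order, at which the cumulative base count reaches 50% (90%)
  of the total. Length bins are half-open with an open-ended tail,
  matching the usual 0–1/1–2/2–3/>3 kb reporting.

# The simulator: what it emulates and what it does not

`sim_config()` defaults encode the study-like design: 4 replicates per
condition, 1000 genes, planted classes 2% `direct_up`, 1% `direct_down`,
5% `late`, 10% `chx_response`, effect size 3 log2 units, shared NB
dispersion $\alpha = 0.1$, baseline means log-uniform on
$[\log 20, \log 2000]$ (a realistic bulk expression range), 5,000-bp
promoters. Direct genes shift in TH and (relative to the CHX baseline) in
TH_CHX; late genes shift only in TH; `chx_response` genes shift up in every
CHX-containing condition. Promoter backgrounds are uniform over A/C/G/T —
deliberately, so scanner false-positive rates are analytically computable —
and each direct gene carries exactly one planted element with a controlled
number of half-site mismatches on a recorded strand. Counts and promoters
draw from separate RNG streams derived from the master seed, so changing
the gene count does not perturb the sequences.

What it does **not** emulate: per-gene dispersion heterogeneity (a shared
$\alpha$ is the default; real data are more variable), GC/length biases,
isoform structure, correlated replicates, non-uniform promoter composition
(CpG islands, repeats) and TREs of other geometries (DR0, palindromes).
Passing the recovery tests therefore demonstrates the inference chain is
correct under its stated model, not that real-data performance will match;
the effect-size knob is a simulation parameter, not an estimate of real
effect magnitudes.

# Problem sizes and determinism

The shipped tests and the acceptance script use 1000-gene simulations with
4 replicates for recovery, a 2000-gene null for calibration, 100 random
1-kb sequences for the scanner oracle and 500-length samples for the N50
oracle — sizes at which the Monte-Carlo bands asserted (sensitivity and
precision $\ge 0.90$, type-I within $0.05 \pm 0.02$) are stable across
seeds. Every stochastic step is seeded; `run_pipeline` records the master
seed and all thresholds in its JSON summary, and re-running any stage from
the persisted TSV intermediates reproduces the end-to-end result.

# Known limitations

* The DE stand-in is a deliberately compact NB-Wald procedure; it honours
  the same filter semantics and model family as the classical tools but
  does not reproduce any specific tool's p-values line for line.
* Classification operates on transcript identifiers; paralog collapsing or
  transcript-to-gene mapping is upstream of this package.
* The scanner is a pattern matcher, not a PWM log-odds scorer; it cannot
  rank hits beyond mismatch count.
* Enrichment ignores the GO DAG (no term propagation) and length bias.
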