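---
title: "Methods: miRNA-mRNA interactome inference with mirweave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-mRNA interactome inference with mirweave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirweave)
```

## The problem

MicroRNAs repress their target mRNAs, so a miRNA that is up-regulated in a
disease condition should tend to have down-regulated targets, and the two
profiles should be negatively correlated across samples. `mirweave`
implements the downstream analysis used to build such a miRNA-mRNA
regulatory interactome from paired bulk RNA-seq count matrices of a small
two-group design (disease cases versus controls — the motivating setting is
arrhythmogenic cardiomyopathy in right-ventricle autopsy tissue, four cases
against three controls): differential expression on both matrices,
over-representation analysis of the differential genes, and a cascade of
evidence filters that whittles predicted miRNA-target pairs down to a final
set of anti-correlated, validated interactions.

## Differential expression

Counts are modelled per feature as negative binomial with mean
$\mu_{fj} = s_j q_f 2^{\beta_f x_j}$, where $x_j$ indicates a case sample,
$s_j$ is a sample size factor and $\beta_f$ the log2 fold change.

**Size factors** use the median-of-ratios estimator: over features with
strictly positive counts in every sample,
$s_j = \mathrm{median}_f\, c_{fj} / (\prod_k c_{fk})^{1/n}$. Even-length
medians take the arithmetic midpoint. Size factors are identified only up
to a common constant, so the meaningful invariant is that scaling one
sample's column by $c$ scales its factor *relative to the others* by $c$.

**Dispersion** is estimated per feature by method of moments on
normalized counts: $\hat\alpha_f = \max(\text{floor},
(\hat v_f - \hat\mu_f)/\hat\mu_f^2)$ with $\hat v_f$ the pooled
within-group variance ($n - 2$ degrees of freedom for two groups) and
$\hat\mu_f$ the grand mean. The floor (`1e-8`) catches constant and
under-dispersed features. There is deliberately no shrinkage toward a
mean-dispersion trend, no outlier refitting and no independent filtering:
this engine is a transparent, self-contained stand-in for the usual
DESeq2-style stage, and is validated by its statistical behaviour
(calibration, power, recovery) rather than by replicating another tool's
output.

**Testing.** The two-group log-link NB GLM with offset $\log s_j$ is fitted
by iteratively reweighted least squares (vectorized across features; the
one-covariate design reduces each IRLS step to weighted group means), and
the condition coefficient is tested with the Wald statistic
$W = \hat\beta / \mathrm{se}(\hat\beta)$. Because the dispersion entering
the standard error is estimated from only $n - 2$ residual degrees of
freedom, referring $W$ to the asymptotic standard normal is markedly
anticonservative in small designs — at 4 vs 3 the realized type-I error at
nominal 0.05 is about 0.11, essentially $P(|t_5| > 1.96)$. The default
reference is therefore $t_{n-2}$, which restores calibration (measured
type-I error ≈ 0.05 in the package's null simulations); the asymptotic
normal reference remains available via `de_config(wald_ref = "normal")`.

**Calling.** The default rule calls a feature at BH-adjusted $q \le 0.05$
and $|\log_2 FC| \ge 0.5$, the rule attached to the motivating study's
reported differential sets. That study's methods text also mentions an
alternative raw $p < 0.05$ with fold change $> 2$; this is selectable with
`de_config(call_rule = "raw_p")` but is not the default, since the reported
results were produced under the FDR rule. Features with total count below
10 are dropped before testing (configurable), which stabilizes the moments
dispersion estimate at $n = 7$. A feature with an all-zero group is refitted
with a pseudocount (default 1) added to its counts and flagged rather than
returned as infinite.

## Over-representation analysis

For a selected gene list of size $n$ inside a universe of size $N$, a set
with $K$ members in the universe and overlap $k$ is scored with the
hypergeometric upper tail $P(X \ge k)$, BH-adjusted over the collection.
Two conventions deliberately exposed as options:

* **Significance rule.** The field convention (and the motivating study's
  stated rule) is raw $p < 0.05$; that is the default even though it is
  anticonservative, and `use_q = TRUE` switches to the BH rule.
* **Universe.** The default background is the set of features actually
  tested for differential expression (post pre-filter), the standard
  background correction; the collection's own universe can be kept with
  `universe_from_de = FALSE`. Up- and down-regulated genes are tested
  jointly by default.

Live GO/KEGG annotation retrieval is out of scope — database snapshots are
version-dependent and irreproducible — so collections are supplied as GMT
files (synthetic collections are generated for tests and the pipeline's
synthetic mode).

## The interactome cascade

Candidate pairs are DEM × DEG combinations from a prediction table (one
row per miRNA-gene-tool triple, mirroring the eight classical prediction
tools). Filters apply in a fixed order:

1. **Consensus**: at least `min_tools` (default 3) distinct tools predict
   the pair.
2. **Validation**: the pair appears in a validation table (any source),
   when `require_validated` (default on).
3. **Shared target**: the gene is paired with at least `min_sharing`
   (default 2) distinct miRNAs *within the surviving candidate set* — the
   criterion is read as a property of the reported candidate list, not of
   the raw prediction universe.
4. **Anti-correlation**: Pearson $r < r_{\max}$ (default $-0.7$) *and*
   two-sided $p < p_{\max}$ (default 0.05), with
   $t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$ degrees of freedom; plus opposite
   differential-expression signs for the miRNA and the gene when
   `require_anticorrelation_sign` is on.

The three evidence criteria are conjunctive, and correlation is applied
last; every criterion can be disabled individually, and a strictly more
stringent configuration always yields a subset of the laxer edge set
(regression-tested on random inputs).

**What the correlation is computed on.** The source analyses do not state
the correlation input; the default is $\log_2(\text{count}/s_j + 1)$ across
*all* samples (cases and controls pooled, $n = 7$ in the motivating
design), because the log transform tempers the NB mean-variance coupling.
Raw and normalized-count alternatives are exposed. Sidedness interacts with
the sign constraint in a transparent way: at $n = 7$, requiring both
$r < -0.7$ and two-sided $p < 0.05$ is equivalent to the single cutoff
$r \le -0.7545$ (inverting the $t_5$ quantile), so a pair at $r = -0.72$ is
rejected by the $p$ criterion alone.

Edges are sorted by ($r$ ascending, miRNA, gene) and exported either as a
TSV carrying all evidence columns or as a bipartite GraphML (node attribute
`type` ∈ {mirna, gene}; edge attributes `tool_count`, `validated`, `r`,
`p`).

## The synthetic-data generator

The simulator emulates the data-generating process the cascade assumes:

* NB counts with log-normal size factors (`size_factor_log_sd` = 0.15,
  a realistic spread of library sizes after scaling) and dispersion 0.05,
  typical of bulk RNA-seq of homogeneous tissue; baseline means log-uniform
  between $10^{1.5}$ and $10^{3.5}$ counts.
* Planted differential expression: 60 of 2000 genes and 8 of 300 miRNAs at
  $|\log_2 FC| = 2$, balanced signs.
* Planted regulatory pairs: 24 pairs laid out as 12 target genes with two
  same-signed miRNA partners each, so that the shared-target filter is
  satisfiable by construction; the gene's fold change takes the opposite
  sign.
* Prediction/validation tables: each tool lists a true pair independently
  with sensitivity 0.95 and any non-true combination with false-positive
  rate 0.02; validated fraction 1 by default, contamination configurable.

**How anti-correlation is planted.** Each planted miRNA carries an i.i.d.
standard-normal latent deviation per sample, scaled by `latent_log2_sd`
(default 0.4 log2 units) and added to its log2 mean. A planted gene's
deviation is a linear mix of its partners' deviations with the weight
chosen so the *within-condition latent* correlation of each pair equals
`pair_correlation` (default $-0.9$). Two consequences are documented rather
than hidden: (i) with two independent partners the achievable per-pair
latent correlation is capped at $-1/\sqrt{2}$, and the truth object records
the achieved target per pair; (ii) observed count correlations are
attenuated by counting noise but reinforced, across the pooled groups, by
the opposite-signed condition effects. The latent scale of 0.4 was chosen
once as a realistic magnitude of shared regulatory variation — comparable
to the counting-noise scale at these depths, and small against the planted
2-unit fold change, so planted features remain detectable while still
carrying a strong correlation signal.

The default design is 8 vs 8 rather than the motivating 4 vs 3, so that
pipeline-recovery benchmarks are adequately powered; a `paper_scale` preset
reproduces the 4 vs 3 shape for illustration. Each generator
(counts, predictions, validation, gene sets) seeds its own RNG stream from
`seed` plus a fixed offset, so adding one call never perturbs another's
output.

**What the simulator does not model:** sequence-level structure (seed
matches, hairpins), cellular composition (fibro-fatty replacement changes
cell-type proportions, which can induce correlations with no direct
regulation), batch effects, and miRNA-miRNA latent structure beyond the
planted blocks. Passing recovery benchmarks therefore demonstrates that the
cascade's statistics behave as designed under its assumed model — not that
real-tissue confounding is handled.

## Numerical choices

* Median ties: arithmetic midpoint (note that a log-scale median, as some
  implementations use, gives the geometric midpoint on even counts).
* Dispersion floor `1e-8`; correlation values clamped to $[-1, 1]$ against
  rounding before the $t$ transform; zero-variance profiles yield an
  undefined correlation and are excluded downstream with a logged count.
* IRLS: initialized at $\mu = \max(y, 0.5)$, at most 50 iterations,
  convergence at $10^{-10}$ on the coefficients; the update is symmetric in
  the group labels, so swapping case/control exactly negates fold changes.
* TSV outputs format numbers with `%.10g`, which makes pipeline re-runs
  under a fixed seed byte-identical.
* Identifier matching is exact string match after whitespace trimming
  (gene symbols for mRNA, miRBase mature names for miRNA); no alias
  resolution is attempted.

## Problem sizes used by the checks

The bundled checks run at desk scale: null calibration uses 2000 features ×
7 samples × 10 seeds; power uses 500 planted features; recovery runs the
full pipeline on 2300 features × 16 samples over 20 seeds; oracle
equivalences use hundreds of small random instances. The dataset-level
counts of the motivating study (hundreds of differential genes, the
specific 304-pair and 11-pair sets) depend on the deposited sequencing data
and version-pinned prediction databases and are not reproduced here; the
printed 59 × 7 miRNA count table ships as a fixture and its fold-change
directions are checked exactly.

## Known limitations

* The Wald engine is not DESeq2-output-compatible by design (no dispersion
  shrinkage, no Cook's-distance handling); at very low counts the moments
  dispersion estimate is noisy and the pre-filter is doing real work.
* The anti-correlation screen pools cases and controls; with strong group
  effects the pooled correlation partly reflects differential expression
  itself rather than within-group co-variation. This matches the source
  procedure, but a within-group correlation option would disentangle the
  two.
* ORA with the raw-p rule is anticonservative; the `use_q` option exists
  for a reason.
* The 11 published interaction pairs ship as a fixture for network-export
  examples; reproducing their selection end-to-end requires the original
  expression matrices, which are not redistributable here.
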