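---
title: "Methods: multi-cohort expression meta-analysis with planted-effect validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort expression meta-analysis with planted-effect validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(metacohort)
```

# The problem

Transcriptomic studies of the same perturbation — here, two-arm
control-versus-treated expression cohorts such as cancer cell lines exposed
to cold atmospheric plasma — are individually small (often 1–16 samples per
arm) and technically heterogeneous. Two complementary strategies are
implemented:

* **standardized single-cohort re-analysis**: identical preprocessing and
  differential-expression thresholds applied to every cohort, followed by
  counting genes deregulated in several cohorts; and
* **multi-cohort meta-analysis**: per-gene standardized effect sizes pooled
  across cohorts under a random-effects model, with directional p-value
  combination, signature selection, and validation scoring in cohorts too
  small to enter the meta-analysis.

Because real multi-cohort collections cannot be redistributed, the package
ships a synthetic multi-cohort generator with known ground truth; every
statistical claim made by the test suite is a claim about recovery of
quantities that the generator planted.

# Per-cohort preprocessing

`ensure_log2()` applies `log2(x + offset)` to raw-intensity matrices. When
the scale is not declared, a matrix maximum above 50 is treated as raw —
the common convention for deposited microarray series, whose log2 values
rarely exceed 20 while raw intensities are in the thousands.

`quantile_normalize()` forces every sample onto the across-sample mean of
order statistics. Tie handling is pinned explicitly because dialects differ
between implementations: tied values within a column receive the *mean of
the reference values over their tied ranks*. On tie-free matrices this
matches `limma::normalizeQuantiles` exactly (asserted in the tests).

`collapse_probes()` averages probe rows per gene on the log2 scale, the
standard reduction when a platform measures a gene with several probes.
Collapsing follows normalization and precedes differential expression.

`pca_explained()` reports explained-variance fractions with samples as
observations, genes centered and unscaled — the usual convention for log
expression. All genes enter the decomposition (no variance pre-filter).

# Single-cohort differential expression

`moderated_t()` computes, per gene, the treated-minus-control mean
difference on the log2 scale (`log2fc`) and a variance-moderated t
statistic. Gene-wise pooled variances $s^2_g$ (df $= n_t + n_c - 2$) are
shrunk toward a scaled inverse chi-squared prior,

$$\tilde s^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d},$$

with $(d_0, s_0^2)$ fitted across genes by method of moments on
$\log s^2_g$ (digamma/trigamma moment equations; the trigamma inverse is
solved by Newton iteration). The statistic
$t_g = \mathrm{log2fc}_g / (\tilde s_g \sqrt{1/n_t + 1/n_c})$ is referred to
a t distribution with $d + d_0$ degrees of freedom. With shrinkage disabled
this is exactly the pooled two-sample t (oracle equality at 1e-10 in the
tests); with shrinkage it tracks limma's empirical-Bayes statistics to
within the difference between the two prior-fitting methods. Genes with
zero variance in both arms cannot be tested: they keep their fold change
and are assigned p = 1 rather than crashing the pipeline.

`call_degs()` applies the two-tier thresholds: *stringent* (BH-adjusted
p ≤ 0.05 and |log2FC| ≥ 1), falling back under `mode = "auto"` to *relaxed*
(raw p ≤ 0.05) when no gene passes cohort-wide, and to *fold-change-only*
when an arm has a single sample and no test is possible. The fallback is
applied per cohort. `count_shared_degs()` then counts, per gene, the
cohorts calling it a DEG in either direction, preserving mixed directions.

# The meta-analysis engine

For gene $g$ in cohort $i$, `hedges_g()` computes the standardized mean
difference $d = (\bar x_t - \bar x_c)/s_p$ with the df-weighted pooled SD,
corrected by $J = 1 - 3/(4\,\mathrm{df} - 1)$ to Hedges' adjusted
$g = J d$, with the large-sample sampling variance

$$\widehat{\mathrm{var}}(g) = \frac{n_t + n_c}{n_t n_c} +
  \frac{g^2}{2(n_t + n_c)}.$$

Alternative small-sample variance variants exist; this form is pinned and
used consistently for pooling and for the one-sided p-values below.

`dl_pool()` pools one gene's effects by DerSimonian–Laird: fixed weights
$w_i = 1/\widehat{\mathrm{var}}(g_i)$ give Cochran's
$Q = \sum_i w_i (g_i - \bar g_w)^2$ and
$\hat\tau^2 = \max\!\big(0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w)\big)$;
random-effects weights $1/(\widehat{\mathrm{var}}(g_i) + \hat\tau^2)$ give
the pooled effect and its SE. The implementation matches
`metafor::rma(method = "DL")` to 1e-10 (cross-checked in the tests, never
substituted). `cochran_q()` refers $Q$ to $\chi^2_{k-1}$.

Directional combination: the per-cohort one-sided p-values are the normal
tails of $z = g/\sqrt{\widehat{\mathrm{var}}(g)}$ (the construction is a
package decision, following standard large-sample practice; alternatives
such as one-sided t-test p-values converge to it as arms grow). `fisher_combine()` evaluates
$X = -2\sum_i \ln p_i$ against $\chi^2_{2k}$, separately for the up and the
down family, and BH correction is applied within each family across genes.
Zero p-values are clamped to a configurable floor (default 1e-300) with a
warning.

`run_meta()` applies the chain to every gene measured in at least
`min_cohorts_measured` cohorts (default 5), matching symbols
case-insensitively across cohorts. Internally the per-gene math is
vectorized across the gene dimension for speed; the tests assert exact
equality with the scalar operations gene by gene, so the scalar functions
remain the contract. Genes with zero pooled variance in a cohort are
dropped from that cohort's effects and counted; genes present in a single
cohort are passed through flagged, never silently pooled.

`select_signature()` keeps genes with |pooled ES| ≥ 1, directional Fisher
FDR ≤ 0.05 and measurement in ≥ 5 cohorts. The FDR comparison at exactly
0.05 is inclusive (≤). "In at least five studies" is read as a measurement
requirement — a per-study FDR reading would be incompatible with a single
combined FDR per gene.

`geometric_mean_score()` scores each sample by the mean log2 expression
over the signature genes present — the log2 of the geometric mean of
linear-scale values — which is how a meta-analysis signature is validated
in cohorts too small for effect-size estimation.

# Over-representation and ancestor roll-up

`hypergeom_ora()` tests a query gene list against catalog sets with the
inclusive upper hypergeometric tail $P(X \ge \mathrm{overlap})$, after
intersecting each set with the universe. The universe is **all genes
measured** (post-collapsing / post-meta), not the genome: a genome-wide
universe inflates significance for platform-constrained measurements.
Pathway catalogs are file-based (GMT plus a child→parent relations TSV), so
no network access is ever needed; a toy catalog ships under
`inst/extdata/`. `rollup_ancestors()` maps each enriched pathway to all
root ancestors by upward traversal (a DAG pathway under several roots
counts once per root; pathways absent from the hierarchy fall into a
reserved `unclassified` root with a warning).

# The synthetic generator

`generate_multicohort()` emulates log2-scale microarray intensity matrices
from K cohorts:

* per-gene baselines $\mathcal N(\mu_0, \sigma_0^2)$ with defaults
  $\mu_0 = 7.5$, $\sigma_0 = 1.5$ — a typical location/spread for
  quantile-normalized log2 intensities;
* per-gene, per-cohort sample noise SDs drawn from a scaled inverse
  chi-squared spread ($s_0 = 0.5$, $d_0 = 10$), so gene-wise variances are
  heterogeneous and variance moderation is non-trivial. The variance
  structure of real cohorts is not recoverable from summary statistics;
  this spread is a modeling choice;
* planted signature genes shift the treated arm by
  $\delta_{gk}\,\sigma_{gk}$ with
  $\delta_{gk} \sim \mathcal N(\delta, \tau^2)$ — standardized effects with
  optional between-cohort heterogeneity. Plants are up-regulated by
  default (matching a positively-regulated signature); a
  `mixed_directions` flag exercises the down-direction branch;
* each gene is expanded into `probes_per_gene` probes (default 3) with
  independent probe noise of SD 0.1 on the log2 scale — large enough that
  collapsing matters, small enough not to dominate;
* a `probe_dropout` flag simulates cohort-specific probe subsets to
  exercise missing-gene handling.

Default study conditions are 5 cohorts of 4+4 samples, 1000 genes, 50
plants, $\delta = 2$, $\tau^2 = 0$. What the generator does **not** emulate:
raw probe-level intensities, background correction, batch effects,
platform-specific annotation quirks, or correlated gene modules. Passing
tests therefore demonstrate statistical correctness of the pipeline under a
clean Gaussian model, not robustness to those real-data artifacts.

# Numerical and design notes

**Quantile normalization attenuates one-sided plants.** With 5% of genes
shifted upward only in treated samples, forcing all columns onto a common
distribution deflates the planted effect (measured ≈ 0.12 on the pooled ES
at the default conditions). This is a real property of quantile
normalization under asymmetric differential expression, not an artifact of
the generator. Parameter-recovery checks therefore feed the meta-engine
probe-collapsed cohorts without quantile normalization — the generator
plants no column-to-column technical artifact for it to remove — while the
full pipeline including normalization is exercised end to end elsewhere.

**Inverse-variance pooling of standardized effects is biased downward.**
Because $\widehat{\mathrm{var}}(g)$ grows with $g^2$, cohorts whose
observed effect is randomly large get down-weighted: the pooled estimate is
negatively correlated with the sampling error. At the default conditions
(k = 5 cohorts of 4+4, $\delta = 2$) the expectation of the pooled ES is
≈ 1.83 even though per-cohort $g$ is nearly unbiased (mean ≈ 2.02). A
companion effect makes the pooled SE slightly anti-conservative: measured
95% CI coverage stabilizes near 92.7%. Both are intrinsic to the
DerSimonian–Laird/Hedges formula chain (the pure-model expectation was
verified against the exact noncentral-t sampling distribution of $g$) and
are reported as-is by the acceptance script rather than corrected, since
the formula chain is the method under study.

**Q is slightly over-dispersed at small n.** With sampling variances
*estimated* from 4+4 samples, the null distribution of Cochran's Q deviates
mildly from $\chi^2_{k-1}$ (Kolmogorov–Smirnov distance from uniform
p-values ≈ 0.055 at 2000 genes). Heterogeneity p-values should be read as
approximate at these sample sizes.

**Other pinned choices.** Pooled (not Welch) variances, for determinism of
the df bookkeeping; k = 1 genes flagged, never pooled; p = 0 inputs to
Fisher clamped at 1e-300; gene symbols matched case-insensitively across
cohorts (platforms disagree on casing) with first-seen casing reported;
TSV everywhere with `.` decimals for byte-stable reruns.

# Problem sizes

The test suite and acceptance script run the generator at 300–2000 genes,
5–6 cohorts and up to 20 replicate seeds per check — sizes chosen so each
Monte-Carlo estimate has at least ~200 effective observations (the scale at
which the asserted bands are meaningful) while a full run stays in the
range of a few minutes on one core. The analysis scripts under `analysis/`
use an eight-cohort design with arm sizes 1–16 to exercise the eligibility
split between meta-analysis and held-out validation.

# Known limitations

* The moderated-t prior fit uses moment matching on $\log s^2$; limma's
  F-distribution fit can differ slightly in $(d_0, s_0^2)$, hence in
  borderline p-values.
* One-sided p-values use the normal approximation to $z = g/\sqrt{var}$;
  at 2–3 samples per arm the tails are noticeably heavier than normal.
* The DEG auto-fallback is per cohort; designs with several treatment
  contrasts per cohort are out of scope (single two-arm contrast only).
* Enrichment is overlap-based (ORA); rank-based or topology-aware methods
  are deliberately not implemented.
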