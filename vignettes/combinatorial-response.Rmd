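---
title: "Detecting combinatorial responses to paired signals: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting combinatorial responses to paired signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combsig)
```

## The question and the design

Bacteria such as *Pseudomonas aeruginosa* communicate through quorum-sensing
(QS) signal molecules — here two N-acyl homoserine lactones, 3-oxo-C12-HSL
and C4-HSL, sensed by distinct receptors. A signal *combination* is
"combinatorial" when the transcriptional response to both signals together
differs from the sum of the responses to each signal alone. The experimental
design that isolates this is a four-treatment factorial on a signal-negative
(synthase double mutant) strain: no signal, signal A, signal B, and both,
with replicate cultures per treatment (duplicates in the motivating design,
so N = 8 arrays).

For gene $g$ with per-treatment means $\bar y_{g,\mathrm{ctrl}},
\bar y_{g,A}, \bar y_{g,B}, \bar y_{g,AB}$ on standardized expression,
the treatment effects are $e_T = \bar y_{g,T} - \bar y_{g,\mathrm{ctrl}}$ and
the test statistic is the squared deviance from additivity

$$D_g = \delta_g^2, \qquad
\delta_g = e_{AB} - (e_A + e_B)
        = \bar y_{AB} - \bar y_{A} - \bar y_{B} + \bar y_{\mathrm{ctrl}},$$

i.e. $\delta_g$ is the classical interaction contrast of the 2×2 factorial.
$\delta_g > 0$ means the combined response exceeds the additive expectation.

## Pipeline stages and the choices behind them

1. **Quantile normalization** (`quantile_normalize()`): all arrays are forced
   onto the mean-of-order-statistics reference distribution (ties get the
   mean of the reference values they span). This removes monotone
   between-array intensity distortions and precedes everything else.
2. **Regulated gene set** (`fit_group_means()`, `ebayes_moderate()`,
   `select_regulated()`): one-way layout cell means with pooled residual
   variance on $N-4$ df; gene variances are shrunk toward an empirical prior
   by the scaled-F / inverse-chi-square moment-matching estimator on log
   variances (digamma/trigamma matching), giving moderated t-statistics with
   $d_0 + d$ df. Each of the three treatment-vs-control contrasts is its own
   BH-FDR family (the standard moderated-t workflow); a gene is *regulated*
   when any contrast has $q < 0.05$. Differential expression runs on
   quantile-normalized values, not standardized ones — z-scoring first would
   distort the variance estimates the moderation depends on.
3. **Per-gene standardization** (`per_gene_standardize()`): each gene is
   centred and scaled to SD 1 over *all* samples pooled (sample $n-1$
   denominator), so deviances are in units of the gene's own SD and
   comparable across genes. Standardization is applied to every gene
   retained at this stage, not only the regulated ones; since it is
   per-gene, the two orders give identical values for the tested genes.
   Zero-variance genes (a real possibility after quantile normalization: a
   gene ranked top in every array becomes exactly constant) are excluded
   with a warning and recorded, not silently dropped.
4. **Permutation null** (`permutation_pvalues()`): sample-to-treatment
   labels are shuffled across all N samples, independently per gene and
   permutation, and $D^*$ recomputed. Three modes:
   * `pooled` (default): all genes' null deviances form one reference;
     $p_g = (\#\{D^* \ge D_g\} + 1)/(GB + 1)$. Pooling assumes the
     standardized null deviances are exchangeable across genes and buys
     p-value resolution far below $1/(B+1)$.
   * `per_gene`: each gene against its own $B$ relabelings.
   * `exact_per_gene`: full enumeration of the $N!/\prod_t r_t!$ distinct
     assignments (2520 for duplicates) with the exact tail proportion.
5. **Holm correction and direction** (`holm_adjust()`,
   `classify_direction()`): family-wise control over the tested genes;
   flagged genes are classified `positive` ($\delta > 0$, observed
   combination exceeds the sum) or `negative`.
6. **Enrichment** (`enrichment_test()`): the count of genes with
   $p_\mathrm{perm} < \alpha$ among $n$ tested is referred to an exact
   binomial tail test against $p_0 = \alpha$ (one-sided "greater" — the
   question is whether there are *more* sub-threshold genes than chance
   produces), with a two-sided Clopper–Pearson 95% interval for the
   proportion. The exact interval, not the Normal approximation, is what
   reproduces published intervals of this analysis type.

### p-value conventions

Monte-Carlo p-values use the add-one formula $(r+1)/(B+1)$, so no p-value
is ever zero, and ties count toward the tail ($D^* \ge D$). Both choices are
deliberately conservative: a permutation that reproduces the observed
labeling reproduces the observed deviance *exactly* and must not be counted
as "more extreme by chance zero times". Because floating-point summation
order can perturb an exact tie by a few ulps, ties are detected with a
relative tolerance of $10^{-9}$. The observed labeling is not forced into
the null sample; the add-one term plays that role.

`synergy_test()` warns when the smallest achievable p-value cannot undercut
the Holm threshold $\alpha/n$ — with $n$ genes and per-gene permutations
this needs $B \ge n/\alpha$ (e.g. $B \ge 5280$ for 264 genes at
$\alpha = 0.05$), one reason pooled mode is the default.

## Resolution limits of the duplicate design

Two structural properties of the statistic matter for interpreting results
from an $r = 2$ (N = 8) design; both are consequences of arithmetic, not of
implementation, and both are exercised by the package's tests.

**The identity-relabeling atom.** $\delta$ depends on a relabeling only
through which samples land in the positively-weighted groups
$\{\mathrm{ctrl}, \mathrm{both}\}$. With duplicates there are
$\binom{8}{4} = 70$ such splits, and two of them (the observed split and its
complement) reproduce $\pm\delta_\mathrm{obs}$, hence $D_\mathrm{obs}$,
exactly. Every gene's permutation null therefore contains an atom of mass
$2/70 \approx 0.029$ *at* its own observed deviance. Consequences:

* per-gene and exact modes can never give $p < 2/70$, so no Holm threshold
  below 0.029 is reachable — at $n$ tested genes the family-wise stage is
  inert for any $n > 1$;
* in pooled mode each strongly interacting gene deposits $\approx 2B/70$
  null values at its own observed deviance, so with $m$ comparably strong
  genes the $k$-th strongest has $p \gtrsim (2/70)\,k/G$; Holm can then
  flag at most the one or two most extreme genes regardless of how large
  the interactions are.

The sensitive instrument at this design size is therefore the *enrichment*
test on the count of genes beating the nominal threshold, not the per-gene
Holm flags. A Monte-Carlo convention that drops the add-one term and counts
only strict exceedances would instead return $p = 0$ for any gene whose
observed split happens to be its extreme one — about 3% of *null* genes by
chance — and such zero p-values pass every family-wise threshold; this
package's conventions exclude that artifact by construction, at the cost of
the resolution floor above.

**Standardization bounds the statistic.** Because $\delta$ is computed on
rows scaled to SD 1, $|\delta|$ is bounded (about $\sqrt{28}$ at $r = 2$),
and the bound is approached only by "antisymmetric" response geometries in
which control and combination deviate jointly against the two single
signals (e.g. each single signal represses, the combination activates). A
pure AND-gate gene — no single-signal response, strong combined response —
saturates at $|\delta| \le \sqrt{16/3} \approx 2.31$ as the interaction
grows, because the interaction itself inflates the row SD; such genes can
beat the nominal 0.05 cut but can never reach family-wise significance in
any mode. Interaction geometry, not just interaction size, determines
detectability. Larger replicate counts relax both limits quickly (the atom
mass is $2/\binom{4r}{2r}$: 1/462 at $r = 3$, 1/6435 at $r = 4$).

## The generator as a model of the experiment

`generate_dataset()` draws

$$y_{gi} = \mu_g + \beta_A \mathbf{1}[i \in \{A, AB\}]
  + \beta_B \mathbf{1}[i \in \{B, AB\}] + \gamma\, \mathbf{1}[i \in AB]
  + \varepsilon_{gi}, \qquad \varepsilon_{gi} \sim N(0, \sigma^2_g),$$

with $\sigma^2_g \sim d_0 s_0^2 / \chi^2_{d_0}$ — the same scaled inverse
chi-square family the variance moderation assumes, so hyperparameter
recovery is testable against truth ($d_0 = 4$, $s_0^2 = 0.05$ by default,
prior mean variance 0.1 on the log2 scale). Defaults describe the
motivating experiment once and are not tuned per analysis: 5570 genes
(genome scale for *P. aeruginosa* PAO1), duplicates, 5% regulated
(≈ the published 264/5570), 7% of responders synergistic (≈ 18/264),
main effects $N(0, 1)$ and interactions $N(0, 1)$ in log2 units, baseline
$\mu_g \sim N(8, 2)$. `synergy_snr` optionally plants
$|\gamma| = \mathrm{snr}\cdot\sigma_g$ for power studies at controlled
signal-to-noise. The per-array distortion is a random strictly increasing
cubic (slope $1 + U(-0.15, 0.15)$, cubic coefficient $U(0, 0.01)$, offset
$N(0, 0.3)$): strong enough that quantile normalization is doing real work,
weak enough to preserve ranks.

What the generator does *not* emulate: probe-level structure and
multi-probe summarization, spatial or dye artifacts of two-color arrays,
correlated regulons (genes are independent given the design), and
non-Normal noise. Passing tests on synthetic data therefore validate the
statistical machinery, not array physics.

Choices the motivating analysis left open, decided here and logged in run
metadata: standardization uses the pooled-sample SD (not within-treatment);
differential expression is gene-level (one row per gene); the per-gene
permutation p-value is the standard tail proportion; the binomial test is
one-sided. The published description of its permutation scheme is ambiguous
about pooling; pooled mode is the default here because a per-gene null at
N = 8 cannot resolve family-wise thresholds at all (see above), and
per-gene / exact modes are retained for sensitivity analysis.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at desk scale, chosen
so the whole suite runs in well under a minute of simulation time per
check: null calibration on 20 datasets of 500 genes with $B = 1000$
(nominal-level fraction inside exact binomial 99% bounds; Holm flags
nothing in ≥ 95% of runs); planted recovery with 50 interactions at
$|\gamma| = 4\sigma$ among 1000 genes with $B = 2000$; variance-prior
recovery from 20,000 genes ($d_0$ within 10%, $s_0^2$ within 5%);
multiple-testing and binomial-test implementations against brute-force
definitional oracles; and quantile normalization against a hand-computed
example. The planted-recovery check documents the resolution analysis
above: with duplicate cultures the pipeline's Holm stage recovers at most
one or two of the planted genes however strong the interaction, while the
enrichment stage detects the excess decisively.

## Known limitations

* The permutation shuffles raw labels, so a regulated-but-additive gene's
  null deviances are inflated by its own main effects; pooling such genes
  makes the pooled reference conservative for everyone else. A
  residual-permutation scheme would avoid this but is a different test.
* At $r = 2$, gene-level family-wise flags are close to uninformative (see
  the resolution analysis); design recommendations should be based on the
  enrichment test, or on more replicates.
* GEO series-matrix ingestion is a best-effort text extraction; the
  sample-to-treatment mapping must be supplied by the user.
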