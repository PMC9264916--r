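---
title: "Hub-grouped discovery of lethal dependencies from loss-of-function screens"
author: "ledscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub-grouped discovery of lethal dependencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Genome-wide loss-of-function screens (CRISPR-Cas9 or RNAi) quantify, for
every knocked-out gene in every assayed cancer cell line, how much the
line's viability depends on that gene. The resulting essentiality score
(DEMETER- or CERES-like) is more negative the more essential the gene is.
A *lethal dependency* (LED) is an association between the alteration
status of one gene (the biomarker) and the essentiality of another (the
target): cells carrying the alteration are systematically more sensitive —
or more resistant — to the knockout. LEDs generalise synthetic lethality
and directly suggest biomarker-guided therapies.

Finding LEDs means testing every (knockout, biomarker) pair: with
tens of thousands of knockouts and hundreds to thousands of recurrently
altered genes, the multiple-testing burden runs into the millions of
hypotheses, and pooled corrections (Bonferroni, Holm, Benjamini–Hochberg,
pooled Storey–Tibshirani q-values) leave few or no discoveries.

The empirical observation this package exploits is the *hub effect*: in
every tumour type, a small number of gene alterations are associated with
essentiality changes of *many* knockouts at once. If the tests are grouped
by biomarker, hub biomarkers produce p-value histograms with a tall spike
near zero while alteration-free biomarkers produce flat histograms.
Judging each group against its own histogram — rather than drowning hub
signal in a pooled set — recovers far more dependencies at the same
nominal false discovery rate.

## The statistical model

Let $D$ be the $e \times n$ essentiality matrix ($d_{ij}$ = score of
knockout $i$ in line $j$) and $m$ the $m \times n$ binary alteration
matrix ($m_{gj} = 1$ when line $j$ is mutant, MUT, for biomarker $g$; $0$
for wild-type, WT). For each pair, within a cohort of $n'$ lines, the null
hypothesis is

$$H_0 : \; E[d \mid \mathrm{MUT}] = E[d \mid \mathrm{WT}],$$

i.e. the expected essentiality of the knockout is identical in mutant and
wild-type lines. The effect size is the *increment of essentiality*
$\Delta = \bar d_{\mathrm{MUT}} - \bar d_{\mathrm{WT}}$; negative
$\Delta$ means the alteration sensitises to the knockout.

`moderatedTTest()` tests each pair with an empirical-Bayes moderated
t-statistic: the pooled within-pair variance $s_i^2$ (on $d_i$ residual
degrees of freedom) is shrunk toward a prior,

$$\tilde s_i^2 = \frac{d_0 s_0^2 + d_i s_i^2}{d_0 + d_i},
\qquad t_i = \frac{\Delta_i}{\sqrt{\tilde s_i^2 (1/n_\mathrm{MUT} +
1/n_\mathrm{WT})}},$$

with $(d_0, s_0^2)$ estimated by `fitVariancePrior()` through moment
matching of $\log s_i^2$ against a scaled-F model (the standard
hierarchical model in which $s_i^2 \sim s_0^2 F(d_i, d_0)$), and $t_i$
referred to a t law on $d_i + d_0$ degrees of freedom. Moderation is
performed within each biomarker's family of knockout tests by default
(`moderation = "global"` pools everything); the pooling scope is exposed
because neither choice is canonical for this design. With `priorDf = 0`
the statistic reduces exactly to the ordinary pooled-variance t, and
`anovaTest()` (the classical baseline; $F = t^2$ for two groups) gives
identical p-values — a relationship the test suite asserts.

Pairs with fewer than `minGroupSize` (default 2) mutant or wild-type
lines are reported with a `skipped` flag rather than dropped, so the
test universe is auditable.

## The hub-grouped correction

The p-values are split into one group per biomarker. Within each group,
`estimatePi0()` estimates the proportion of true nulls $\pi_0$ from the
excess of p-values above a tuning point $\lambda$
($\hat\pi_0(\lambda) = \#\{p > \lambda\} / (n(1-\lambda))$), by default
choosing $\lambda$ on the grid $0.05, 0.10, \ldots, 0.95$ with the
closed-form bootstrap mean-squared-error criterion; the estimate is
clamped to $[1/n, 1]$. `localFdr()` then computes the per-test local
false discovery rate

$$\mathrm{lfdr}(p) = \min\!\left(1, \frac{\pi_0 f_0(p)}{f(p)}\right),
\qquad f_0 = U(0,1),$$

the posterior probability that the null holds given the observed p-value.
The mixture density $f$ is estimated by the Grenander estimator — the
slopes of the least concave majorant of the empirical CDF of the
p-values — which is monotone non-increasing by construction, integrates
to exactly 1, and therefore yields lfdr values in $(0, 1]$ that are
non-decreasing in $p$ without ad-hoc clipping. Its one pathology is the
extreme left boundary, where the first hull segment can overshoot; under
a pure null this touches a handful of tests in ten thousand, which the
test suite bounds explicitly. Degenerate groups (all p identical) fall
back to $\mathrm{lfdr} = \pi_0$ with a warning.

`groupedLocalFdr()` applies this machinery independently per biomarker
group. Groups smaller than `minGroupTests` (default 50) are too small for
stable $\pi_0$ estimation and fall back to the pooled all-tests model,
flagged in the output; per-group diagnostics ($\pi_0$, size, fraction of
p below 0.05 — the histogram-spike summary) are attached to the result.

`covariateBH()` is the companion set-level procedure: a single-split,
group-weighted Benjamini–Hochberg correction in the spirit of independent
hypothesis weighting. Each group receives a weight proportional to its
estimated alternative fraction $1 - \hat\pi_0^{(g)}$, normalised so the
average weight over tests is 1, and BH runs on $p_i / w_{g(i)}$. Because
the weights are learned on the same p-values they are applied to (no
cross-fitting), the plug-in estimate is debiased by subtracting
`conservatism` (default 2) standard errors of the $\lambda = 0.5$
tail-count estimator and flooring at zero: groups without demonstrable
signal get weight 0, and when no group shows signal all weights are 1 and
the procedure is plain BH. The known cost of weighting is diffuse signal:
when alternatives are spread thinly over all groups the learned weights
are worse than uniform and the procedure can underperform plain BH — it is
designed for the hub-structured regime.

## LED calling, typology and the relation filter

`callLeds()` keeps pairs with p-value $< 0.05$, local FDR $\le 0.6$ and
$|\Delta| > 2$ (all configurable; the magnitude-2 gate is the
conventional threshold for a strong dependency on the DEMETER scale) and
ranks by p ascending, ties broken by $|\Delta|$ descending then
lexicographic ids — the tie rule used by every rank-based step in the
package. `classifyLeds()` assigns the dependency typology: $\Delta < 0$
is a positive lethal dependency (pLED; the alteration marks sensitivity),
$\Delta > 0$ a negative one (nLED; resistance), and a biomarker whose
called partners span both signs forms a dual dependency (dLED) — the
therapeutically interesting case where the same alteration dictates
opposite treatment choices. `relationFilter()` optionally requires the
pair to be related in a scored gene–gene edge list (combined score
$\ge 400$, inclusive, the conventional medium-confidence cutoff; direct
edge or shared neighbour), with self-pairs always passing; it is off by
default and on in the AML-style preset, since demanding prior annotation
defeats the search for novel relationships.

## Essential-gene selection

`selectEssentialGenes()` restricts the knockout universe before testing.
A knockout qualifies when (i) it is essential (score $\le -2$) in at
least 20% of cohort lines (25% in the AML preset), (ii) it is specific —
essential in at most 10% of non-cohort lines, and (iii) it is expressed
(TPM $> 1$) in at least 75% of cohort lines before the knockout
experiment. The specificity fraction quantifies a criterion that is
usually stated only qualitatively; 10% is this package's default and is
configurable. Expression is evaluated on cohort samples only, because the
criterion exists to ensure the gene was expressed in the assayed cells.
All three fractions are reported per gene so any re-thresholding is
possible downstream.

## Data handling choices

Readers accept TSV/CSV, plain or gzipped, with empty cells, `NA` and
`NaN` as missing sentinels; written output always uses `NA`. Sample ids
are matched case-sensitively after whitespace trimming. The variant table
is a deliberately minimal MAF-like dialect; dichotomization keeps a
(sample, gene) mutant when at least one variant survives the filters
(allelic fraction $\ge 0.1$; silent, non-coding, common-polymorphism and
putative-neutral variants excluded by default — placeholders for
panel-specific curation, all configurable and logged). `knnImpute()`
fills missing essentiality entries from the `k = 10` nearest knockout
rows, with row–row distance the root mean squared difference over
co-observed columns (so sparsely co-observed rows are not favoured),
deterministic index-order tie-breaks, and a row-mean fallback when no
neighbour observes the column.

## The simulator and what it does (not) emulate

`simulateScreen()` generates the package's reference study conditions: 60
cell lines, 100 knockouts, 100 biomarkers of which 5 are hubs with 40
true target knockouts each (the remaining 95 carry no signal), mutation
status Bernoulli(0.3) per biomarker and line, scores = baseline +
homoscedastic Gaussian noise (sd 1), and a $\pm 3$ shift of mutant lines
for every true pair, signs drawn 50/50 so all three LED types occur. A
Student-t (5 df) noise option stresses the moderated test under heavy
tails. Expression defaults to a constant 10 TPM so the expression filter
is inert unless exercised on purpose. These sizes keep the full test
suite and the acceptance script in the minutes range while leaving
thousands of null tests per screen.

The generator emulates the two-group shift model and the hub structure;
it does **not** emulate screen-level realities such as off-target
structure, copy-number confounding, heteroscedastic noise across
knockouts, or correlated co-mutation patterns. One emergent property
deserves emphasis, because it is a feature of the model itself rather
than a simplification: with independent Bernoulli mutation columns, a
null biomarker's column can correlate appreciably with a hub's column in
finite samples ($|r|$ up to $\sim 0.35$ at $n = 60$), and the hub's
planted shifts then leak into the null biomarker's tests. Those tests are
*statistically* non-null (the leak inflates their t by a factor that
depends only on effect/noise and prevalence, not on sample size) while
being *false* with respect to the planted truth. Consequences measured by
the acceptance suite: procedures whose rejection regions demand extreme
evidence (pooled BH/Storey–Tibshirani) or a large effect (the
p/lfdr/$|\Delta|$ calling gates) keep planted-truth FDR at or below
nominal, but group-weighted set-level procedures — which lower the
evidence bar precisely inside signal-bearing groups — exceed their
nominal 20% level on planted-truth FDR (about 41% under the reference
conditions), and no function of the p-values alone can separate a
leak-contaminated group from a true hub. The same confounding arises in
real screens as co-mutation; there the "leaked" associations are real
statistical dependencies a practitioner may even want. Interpret
set-level weighted discoveries accordingly, and prefer the gated calling
for biomarker-level claims.

## Numerical and design choices

* $\pi_0$ bootstrap uses the closed-form MSE criterion (no resampling),
  so every estimate is deterministic; the smoother variant fits a cubic
  spline over the $\lambda$ grid. Fewer than 20 p-values fall back to
  fixed $\lambda = 0.5$ with a warning. On mixtures with slowly decaying
  alternative densities (e.g. Beta(0.1, 1)), all $\lambda$-tail
  estimators inherit the alternative's tail mass — for a 50/50 mixture
  the analytic expectation is $\approx 0.55$, not $0.5$; recovery tests
  use a 15% relative band for this reason.
* Variance-prior moment matching follows the standard digamma/trigamma
  equations with a Newton trigamma inverse; no spread beyond sampling
  noise gives $d_0 = \infty$ (complete pooling), fewer than two usable
  variances gives the flagged ordinary-t fallback $d_0 = 0$.
* All rank-based procedures break p ties by $|\Delta|$ descending, then
  ids; imputation breaks distance ties by row index. Reruns are
  byte-identical given identical inputs and configuration.
* Thresholds are applied exactly as written: p strictly below, lfdr at or
  below, $|\Delta|$ strictly above, edge score at or above.

## Limitations

* No covariate adjustment (tissue, mutational burden) inside the linear
  model; confounded associations are reported as found.
* The weighted BH is single-split by design — reproducible and cheap, but
  without cross-fitting its FDR guarantee degrades under the leakage
  described above and under diffuse signal.
* No empirical null estimation: $f_0$ is uniform, appropriate for
  well-calibrated tests only.
* Validation against a knowledge base (`matchKnowledgeBase()`, `rocPr()`,
  `fisherEnrichment()`) is only as good as the curated associations and
  the caller-supplied disease synonym expansion.

## Reference pipeline

```r
library(ledscreen)
cfg <- ledPipelineConfig(
  "aml",
  essentialityPath = "essentiality.tsv",
  mutationPath     = "mutations.tsv",
  expressionPath   = "expression.tsv",
  edgesPath        = "edges.tsv",
  cohortLabel      = "AML",
  cohortSamples    = c("AML_line_1", "AML_line_2", "..."))
res <- runLedPipeline(cfg, "run-aml")
```

The run directory contains the essential-gene report, the full test
table, per-group diagnostics, the ranked LED table, a bipartite
variant–knockout graph (JSON) and a manifest recording every threshold
applied. `inst/scripts/ledscreen.R` exposes each stage as a shell
subcommand.
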