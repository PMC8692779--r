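---
title: "Immune subclasses, antagonist screening and the TREM-1 target panel: methods"
author: "tremscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune subclasses, antagonist screening and the TREM-1 target panel: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremscreen)
```

This vignette is the package's own account of the statistical procedures it
implements, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and the
numerical decisions made where the design was genuinely open.

## Immune subclassification

Each of the three effector immune signatures (T/NK, B/P, M/D) is scored per
tumor as the arithmetic mean of the log2 expression values of its genes.
This equals the log2 of the geometric mean of the linear-scale intensities
and is therefore rank-equivalent to the linear geometric mean; since
subclass assignment depends only on within-cohort ranks, the two scales are
interchangeable and the log scale avoids overflow and keeps the score in
familiar expression units. Signature genes absent from a matrix are dropped
with a warning (a geometric mean over the present genes is the only
defensible default without platform mapping information); a signature with
no present genes is an error rather than a silent zero.

Tertiles are **cohort-relative**: recomputed for every input cohort, never
frozen from a reference population. Consequently subclass labels are
invariant to any global shift or monotone rescaling of the matrix, and a
sample's label can change when the surrounding cohort changes — that is the
intended semantics of a population-tertile rule.

The label rule is: FID iff all three tertiles are 3; PID iff any tertile is
1; WID otherwise. Under independent signature scores the expected FID
fraction is $(1/3)^3 \approx 3.7\%$ and the PID fraction
$1-(2/3)^3 \approx 70.4\%$; real cohorts sit far from this independence
limit because immune signatures are strongly positively correlated, which
is why the bulk generator defaults to correlated latent factors (below).

### Quantile binning and ties

`quantileBin(scores, k)` places the item of rank $r$ (of $n$) in the
smallest bin $b$ with $r \le \lceil bn/k \rceil$, so e.g. 10 items split
into tertiles of sizes 4, 3, 3. Ranks are computed with
`ties.method = "max"`, which has two consequences we consider essential for
a classification rule: tied scores can never straddle a bin boundary, and a
tied group is assigned the bin of its highest-ranked member (a tied block
at the top of the distribution is top-tertile for every member). For
distinct scores this is exactly the ceiling rule. The binning is invariant
to strictly monotone transforms of the scores.

## The gene-by-subclass interaction screen

The screen asks: which genes, when highly expressed, *cancel* the response
advantage that immunologically hot tumors otherwise enjoy under neoadjuvant
chemotherapy?

1. **Detection filter.** Keep genes whose mean expression is strictly
   greater than the median of all gene means. The strict inequality is
   deliberate: it makes the filter deterministic and drops median ties,
   retaining just under half the genes.
2. **Dichotomization.** Each retained gene is split at its cohort median,
   again strictly (`high` iff above the median); a gene constant across the
   cohort therefore has no high group and is not fit.
3. **Model.** Logistic regression of binary response on ordinal subclass
   (PID = 0, WID = 1, FID = 2), continuous age, the dichotomized gene, and
   the single product term `gene_high x subclass_ord`. The fit is IRLS with
   tolerance 1e-8 and at most 100 iterations.
4. **Ranking.** The screen statistic is the **signed** Wald
   $Z = \hat\beta_{int}/\mathrm{se}(\hat\beta_{int})$ (with $\chi^2 = Z^2$
   available), ranked ascending so the most antagonistic genes come first;
   ties are broken lexicographically by gene identifier so the ranking is
   total and reproducible. Genes with $Z \le -2.0$ (inclusive) are flagged.

Two codings are supported. The default ordinal coding yields one product
term, reads the subclasses as an immunologic continuum, and concentrates
power in one degree of freedom. A dummy coding (separate WID and FID
contrasts, FID x gene reported) is available via `coding = "dummy"` for
users who prefer not to assume ordinality. The gene's main effect is always
included: an interaction without its main effect confounds the product term
with the marginal gene effect.

**Non-convergence and separation.** Fits that fail to converge, are rank
deficient, or show quasi-complete separation (fitted probabilities pinned
at 0 or 1) are excluded from ranking and carry no Z or p. Exclusion is
transparent and avoids importing a penalized-likelihood remedy with its own
tuning; at typical screen sizes (hundreds of samples, median-dichotomized
genes) separation is rare.

Under the null generator at 400 samples x 2,000 genes the screen's Z values
are close to standard normal (the acceptance suite checks a type-I rate
near 5% at $|Z| \ge 1.96$ and a Kolmogorov-Smirnov distance below 0.05),
and a planted antagonistic interaction of log-odds $-1.2$ is flagged in
well over 90% of seeded replicates.

## Survival analyses

The endpoint is distant metastasis-free survival censored at a 10-year
horizon: follow-up beyond 10 years is administratively censored at 10, and
an event at exactly 10 years **counts as an event** ("within 10 years" read
inclusively — the boundary case is tested explicitly).

Kaplan-Meier curves and the $k$-group log-rank test come from the
`survival` package; Cox models use Efron tie handling (accurate for
moderately tied times and the standard default), Wald 95% intervals per
term, and a likelihood-ratio p at the model level. Constant covariates are
excluded with a flag; aliased (collinear) terms are flagged rather than
silently dropped. The per-gene DMFS screen fits univariable Cox models on
continuous expression and applies BH with significance at adjusted
p < 0.1; `splitCohort` provides the seeded half/half cohort split (sizes
differ by at most one) used for split-sample replication.

The stratified focal-gene analysis takes externally supplied per-sample
cell-fraction scores (deconvolution itself is out of scope) and a benefit
label, defines fraction-high as quartiles 3-4 combined, and within each
benefit x fraction stratum splits expression at the **within-stratum**
median before a two-group log-rank — matching the stratification logic of
split-then-dichotomize designs.

## Single-cell analysis and the target panel

QC removes cells with fewer than 400 detected genes (count >= 1) or more
than 20% mitochondrial counts; both boundaries are kept (exactly 400 and
exactly 20% pass), mitochondria are identified by the "MT-" prefix
convention, and the filter is idempotent. Positivity for any gene is a
raw-count >= 1 rule — equivalent to any positive linear normalized value —
and is deliberately independent of normalization.

Differential expression between cell groups uses the two-sided Wilcoxon
rank-sum test on library-size-normalized (counts per 10,000, log1p)
expression with BH adjustment and significance at FDR < 0.01. A single
rank-based test replaces the negative-binomial exact / asymptotic beta test
pair used by upstream single-cell toolchains: it is distribution-robust,
reproducible without reimplementing those toolchains, and preserves the
FDR < 0.01 decision rule. The reported effect is the log2 ratio of
normalized group means with a pseudocount of 1 (effect sizes and displays
only; tests are rank-based, positivity is raw).

The exact branch of the rank-sum test is used only when both groups have at
most 8 observations and no ties; otherwise the normal approximation with
tie correction and **no continuity correction** is used, so identical
groups give p = 1 exactly. A consequence worth knowing: with 11 samples per
arm the two-sided approximation cannot go below about $7\times 10^{-5}$,
so in an 11-pair activation design BH significance at FDR 0.01 is only
reachable when the induced gene set is not tiny — which is the regime of
real activation experiments.

`assemblePanel` takes three DE tables on a shared gene universe and returns
the conjunction: genes significantly **up** in focal-positive myeloid cells
in both tumor datasets and significantly induced in the activation dataset.
The result is invariant to gene order and to swapping the two tumor tables.
`tumorProfile` then reports, per tumor, the percentage of focal-positive
cells within the myeloid compartment only, and mean normalized panel
expression per compartment, ranked by descending positivity.

## Synthetic-data generators

Every generator is a pure function of its parameters and seed (the RNG
state is restored afterwards), so all outputs are byte-reproducible.

* `makeBulkCohort` (defaults 400 samples x 2,000 genes): log2-normal
  background (mean 7, sd 1; residual sd 0.7); three 10-gene signature
  blocks driven by latent per-sample factors with pairwise correlation
  **0.6** — chosen because effector immune signatures are strongly
  positively correlated in real tumors, which yields realistic subclass
  proportions (FID around 13-15%) rather than the 3.7% independence limit;
  and a focal gene plus 10-gene myeloid cluster on a shared latent factor
  with loading 1.2 over residual sd 0.5, giving within-cluster correlations
  above 0.8 (comfortably past the > 0.6 co-expression regime the cluster is
  meant to emulate).
* `makeResponse`: Bernoulli under exactly the screen's logistic model, so
  planted interactions are recoverable by construction.
* `makeSurvival`: exponential event times under a proportional-hazards
  linear predictor (baseline 0.08/year) with independent uniform censoring
  on (0, 12] years — closed-form truth for hazard-ratio recovery, roughly
  40% events, and censoring monotone in the window width.
* `makeSinglecellTumors` (defaults 3 tumors x 500 cells x 1,000 genes):
  negative-binomial counts (size 2), exact compartment sizes (40% myeloid,
  40% cancer, 20% fibroblast), 15 marker genes per compartment (6-fold),
  and a per-tumor focal-positive fraction tied to subtype (TNBC 0.45,
  HER2+ 0.30, ER+ 0.15 — the decreasing order seen in clinical subtype
  comparisons). Focal-gene expression is planted directly (zero-truncated
  NB in positive cells, zero otherwise) so the realized positive fraction
  is binomial around the configured value; planted target genes are
  up-shifted 4-fold in focal-positive cells.
* `makeActivationPairs` (defaults 11 pairs): correlated per-subject
  baselines (sd 0.5) with residual sd 0.5 and an additive log2 fold change
  of **3** (8-fold) on induced genes — the magnitude typical of
  agonist-antibody cytokine induction in monocytes, and necessary for any
  rank-sum + BH analysis of an 11-pair design (see the p-floor note above).
* `makePanelSuite` wires two independent tumor datasets and one activation
  dataset over a shared universe, planting the true panel plus tumor-only
  and activation-only decoys so the three-way conjunction is genuinely
  exercised.

**What the generators do not emulate:** microarray probe-level artifacts,
batch effects, platform mapping, doublets, ambient RNA, cell-type
misclassification, or non-proportional hazards. Passing tests therefore
demonstrate the correctness and calibration of the procedures under their
own model assumptions — not robustness to the full messiness of real
cohorts.

## Numerical choices and edge cases

* Wald Z is emitted **signed** ($\hat\beta/\mathrm{se}$) with
  $\chi^2 = Z^2$ alongside: antagonists are defined by the sign.
* The Yates chi-square correction is clamped at zero
  ($\max(0, |O-E|-0.5)$), preventing the correction from inflating the
  statistic on near-null tables; a table with identical rows gives
  statistic 0, p = 1.
* Kruskal-Wallis on all-identical values (tie correction degenerate)
  returns H = 0, p = 1 by definition rather than NaN.
* Spearman p-values use the t-approximation
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$; a constant vector leaves the
  correlation undefined and is flagged, never silently numeric.
* Over-representation is the one-sided upper hypergeometric tail
  $P(X \ge \text{overlap})$; zero overlap gives p = 1.
* In `tumorProfile`, binomial sampling of which myeloid cells are
  focal-positive means realized per-tumor frequencies (and hence panel
  means) can swap adjacent ranks on a fine planted gradient; the monotone
  coupling is near-perfect (Spearman rho >= 0.95 across seeds) but not
  guaranteed to be exactly 1 at finite cell counts.

## Problem sizes used by the tests and acceptance script

The suites exercise the study-scale conditions directly: the classifier
limits at n = 9,999; the screen's null calibration at 400 samples x 2,000
genes and its power over 50 seeded replicates of the planted -1.2
interaction; hazard-ratio recovery on two arms of 1,000; and panel recovery
over 20 seeded suites of two 3-tumor x 500-cell datasets plus 11 activation
pairs. Oracle-equivalence tests run the brute-force references (direct
likelihood maximization, exhaustive rank-sum enumeration, closed forms) at
small n where they are exact and fast. `scripts/acceptance.R` reports the
recovered hazard ratio as the mean over 10 seeded replicates, reporting the
method's recovery rather than a single Monte Carlo draw.

## Known limitations

Cell-type labels are inputs (no clustering or embedding is performed);
leukocyte fractions are accepted from external deconvolution tools;
benefit-class labels (e.g. IBE/IBD) are inputs; the screen applies no
multiple-testing correction by design (it is a ranking procedure — its
outputs are candidates, not discoveries); and the rank-sum DE test, while
robust, is less powerful than count-model tests for very low-count genes.
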