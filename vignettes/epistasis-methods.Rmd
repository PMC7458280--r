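---
title: "Methods: detecting SNP-SNP epistasis in case-control panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting SNP-SNP epistasis in case-control panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistasisr)
```

`epistasisr` analyses a case-control cohort genotyped at a small panel of
candidate SNPs for pairwise epistasis. This vignette is the package's
account of the statistical machinery: what each stage assumes, which knobs
matter, how degenerate inputs are handled, and where we made design choices
that genuinely could have gone another way.

## Data model

The universal input is a subject-by-SNP table: a unique `sample` id, a
binary `status` (1 = case, 0 = control), and one column per SNP holding the
minor (derived) allele count 0/1/2, `NA` for a failed call. This single
canonical 0/1/2 encoding is deliberate: display codings (e.g. ranking
genotypes as disfavorable / heterozygous / favorable for a sport phenotype)
depend on a model orientation and are applied only at presentation time
(`recode_genotypes()`), which prevents orientation bugs from leaking into
the statistics. Subjects with a missing genotype are dropped *per analysis*
(pairwise deletion), never globally, and every function counts what it
dropped.

## Quality control

`minor_allele_frequency()` is the allele proportion `(2 n2 + n1)/2N`,
flipped (and flagged) if the nominal minor allele exceeds 0.5.
`hwe_test()` is the plain Pearson chi-square of the observed genotype
counts against `(p^2, 2pq, q^2)` at the sample allele frequency, df 1, no
continuity correction, with equilibrium declared at the fixed threshold
6.635 (the 0.01 upper quantile). Two conventions exist for which subjects
feed the test; we default to the pooled sample and expose
`hwe_group = "control"` for the control-only alternative, since a true
disease association distorts case genotype frequencies. A monomorphic locus
gets chi-square 0 with a `monomorphic` flag rather than an error: it is in
trivial equilibrium, but the flag matters because such a locus carries no
information downstream. The test's type-I error at the 6.635 threshold is
calibrated by simulation in the test suite (10,000 HWE-true multinomial
draws at N = 300, allele frequency 0.3).

## Inheritance-model selection

From the 2x3 case/control table we form per-genotype odds
`odd_g = cases_g / controls_g` and the two adjacent odds ratios
`OR1 = odd(Mm)/odd(MM)`, `OR2 = odd(mm)/odd(Mm)`. Any empty cell triggers
the Haldane-Anscombe +0.5 correction on all six cells (flagged) — the
standard fix that keeps the ratios finite without biasing large cells.

Each classical one-locus model pins `OR_mm = OR1 * OR2` to a constraint:

| model          | constraint          |
|----------------|---------------------|
| dominant       | OR2 = 1             |
| recessive      | OR1 = 1             |
| over-dominant  | OR1 * OR2 = 1       |
| multiplicative | OR2 = OR1           |
| additive       | OR1 * OR2 = 2 OR1 − 1 |

`select_model()` scores each constraint by its squared deviation on the
log-odds-ratio scale and returns the argmin. The log scale makes the score
symmetric in protective vs risk directions; the additive model is excluded
(and flagged) when its predicted odds ratio `2 OR1 − 1` is non-positive,
where the constraint has no log-scale representation. No closed decision
rule is universal here — near-ties occur in real data (e.g. OR1 = 0.749,
OR2 = 0.570 scores additive and multiplicative within a factor of ~3 of
each other) — so all residuals are returned for audit rather than hidden
behind the label.

## Information-theoretic analysis

All entropies are in bits. The information gain of attribute A about class
C is the mutual information `IG = H(C) − H(C|A)`, computed as
`H(A) + H(C) − H(A,C)` (the chain-rule identity is asserted to 1e-12 in the
tests). Its significance uses the likelihood-ratio statistic
`G² = 2 N ln(2) IG` with `df = (|C|−1)(|A|−1)` degrees of freedom. For a
3-genotype SNP against a binary class, df = 2 and the chi-square p-value
has the closed form `exp(−G²/2)`. Percent displays are bits x 100 by
convention; `percent_of_class_entropy = TRUE` switches to normalizing by
H(C), the other convention in circulation. We deliberately treat the
`(G², p)` pair as the authoritative output of this stage: it is internally
consistent by construction, while "normalized information gain" columns in
the literature are often computed under an unstated normalization.

Interaction information is
`I(A;B;C) = IG(A×B;C) − IG(A;C) − IG(B;C)`, with the Cartesian product
attribute built over *observed* cells only (an empty cell is an absent
category, no pseudo-counts). Positive values are synergy, negative values
redundancy; the value is symmetric in A and B and bounded below by
`−min(IG(A;C), IG(B;C))`. It is computed on the full data set by default —
it is a descriptive decomposition, not a model being selected, so holding
out data would only add variance.

The attribute dendrogram clusters SNPs on the Rajski distance
`d = 1 − I(A;B)/H(A,B)` (0 = informationally identical, 1 = independent; a
constant pair is defined as distance 0). Agglomeration uses our own
Lance-Williams recurrence with Ward coefficients
(`alpha_i = (n_i+n_k)/(n_i+n_j+n_k)`, `beta = −n_k/(...)`, `gamma = 0`);
ties in the minimum distance break toward the earliest pair in index
order. The merge heights are cross-checked in the tests against
`hclust(method = "ward.D")`, which implements the same recurrence, and the
tree is exported as Newick through `ape`.

## Multifactor Dimensionality Reduction

MDR pools the multilocus genotype cells of a candidate SNP combination into
high- and low-risk classes and treats the resulting partition as a
classifier. With unbalanced classes the raw case:control cell ratio is
misleading, so we use class-balanced weighting: a cell is high-risk when
`cases_cell / (controls_cell * n_cases/n_controls) >= 1`, i.e. its ratio
meets the overall training ratio. Ties go to high — the convention that
errs toward sensitivity for the rarer case class. Cells unseen in training
predict control by default (`unseen_policy` also offers `case` and
`abstain`, the latter excluding those subjects from metrics with a count).

`mdr_search()` evaluates every combination of order `1..max_k` under
stratified k-fold cross-validation (folds assigned by a seeded shuffle
within each class). Within each order k, the combination with the best
*training* balanced accuracy in a fold earns one CVC point for that fold;
the final ranking across orders is by mean *test* balanced accuracy with
CVC as tiebreak. Selecting on balanced accuracy (not raw accuracy) is what
makes the procedure meaningful at a ~1:3.4 case:control ratio. A
combinatorial guard refuses exhaustive searches over more than 20
attributes at `max_k > 4` unless forced.

Significance uses a label-permutation test: the phenotype vector is
permuted, folds re-stratified, and the combination's mean test balanced
accuracy recomputed; the add-one estimator
`p = (1 + #{perm >= obs}) / (1 + n_perm)` keeps p away from an impossible
zero. The statistic is the same mean test balanced accuracy being ranked —
a sign-test variant on fold-wise wins was considered and rejected because
it discards the magnitude of each fold's result.

## Weighted-effect-coded logistic regression

Dummy coding measures effects against one reference category; effect
coding against the unweighted category mean. With a 1:3.4 class ratio and
very unequal genotype frequencies, weighted effect coding (WEC) is the
coding in which "no main effect" means what it should: effects are
deviations from the *frequency-weighted* mean, and the fitted category
effects satisfy `sum_g n_g b_g = 0`. The main-effect column for category g
is 1 on g, `−n_g/n_ref` on the reference, 0 elsewhere.

The interaction block generalizes both zero sums to the A x B cell
surface: `sum_i n_ij b_ij = 0` for every column j and
`sum_j n_ij b_ij = 0` for every row i. Our construction gives the column
of non-reference cell (i, j) the values 1 at (i,j), `−n_ij/n_aj` at the
reference row, `−n_ij/n_ib` at the reference column, `+n_ij/n_ab` at the
reference cell, 0 elsewhere — each basis column satisfies both families of
constraints by inspection, the nine cell effects are recoverable from the
four estimated ones (`wec_cell_effects()`), and the span is independent of
which cell is the reference. That last point is the operative property: the
log-likelihood and the effects of cells shared between reference choices
are invariant, which is asserted to 1e-8 in the tests. Because the
constraints kill all weighted marginal structure, a model with *only*
interaction columns (plus intercept) represents pure epistasis — signal
that no additive model can absorb. An empty A x B cell makes the surface
unidentifiable, so `build_wec_interaction()` refuses with the offending
cells named rather than silently imputing.

Fitting is Newton-Raphson on the Bernoulli log-likelihood with step
halving; convergence requires the gradient max-norm below 1e-8 within 100
iterations, else the fit is flagged. Standard errors come from the inverse
observed information; Wald 95% CIs are `b ± 1.96 SE`; the LR chi-square
and McFadden `R² = 1 − LL/LL₀` are against the intercept-only null, whose
MLE is closed-form (`b0 = log(n1/n0)`). Rank deficiency is an error naming
the collinear columns; a coefficient beyond |15| raises a separation flag
(at that magnitude the fitted probabilities are saturated to ~3e-7). The
additive comparison model codes each SNP as a numeric 0/1/2 dose — one df
per SNP, so the additive-vs-interaction contrast is 2 vs 4 df and the two
models are not nested in each other; both are compared through their own
null and via AIC, while full vs interaction-only is a proper 4-df LR test.

## ROC evaluation

`roc_curve()` sweeps all distinct score thresholds (case at
`score >= t`), computes the trapezoid AUC — identical to the Mann-Whitney
concordance probability with ties counted 1/2, asserted exactly against a
brute-force pairwise count in the tests — and the Hanley-McNeil standard
error with its normal CI truncated to [0, 1]. The Youden cutoff maximizes
`TPF − FPF` over observed thresholds, ties broken toward the larger
threshold (higher specificity): when several cutoffs classify equally
well, the conservative choice calls fewer people cases. Constant scores
yield AUC 0.5 with a `degenerate` flag.

## The synthetic-data generator

`generate_genotypes()` draws loci independently under Hardy-Weinberg
proportions at the configured MAFs and assigns status by rejection
sampling against a penetrance surface until the requested case and control
quotas fill — exact for a case-control design with fixed margins, with no
retrospective-sampling algebra to get wrong. `study_like_config()`
packages the shape of a small sports-genomics panel: 73 cases vs 245
controls (1:3.36), seven loci named after familiar performance-related rs
numbers with MAFs from 0.165 to 0.5 (the lower bound mirroring the weakest
locus such panels typically retain), and an embedded epistatic pair on the
stand-ins for rs1815739 and rs362584.

The embedded surface is the XOR-parity pattern: penetrance `high` where
the two genotype parities differ, `low` elsewhere. At MAF 0.5 each locus
is heterozygous with probability exactly 1/2, so both marginal penetrances
are flat and the pair is invisible to any single-locus statistic — the
cleanest possible test bed for interaction detection, verified both in
closed form (`theoretical_pair_distribution()`) and by simulation. The
default contrast is `high = 0.4, low = 0.1`: a within-cell odds ratio of
6, the effect size at which a 318-subject panel detects the pair reliably
and which matches the magnitude of association such studies report. At the
study's unequal MAFs the marginals are only approximately flat — that is a
property of real loci too, not a defect.

What the generator does **not** emulate: linkage disequilibrium between
loci (candidate panels place SNPs on different genes), covariates and
population stratification, genotyping error, and missingness. Passing
tests on these data therefore demonstrate correctness of the algorithms
under the stated sampling model, not robustness to confounding — on real
cohorts, stratification control remains the analyst's job.

## Problem sizes and numerical tolerances

The test suite exercises: exact information identities at 1e-12 on
randomized tables; MDR recovery of XOR epistasis at N = 2000 with
penetrance contrast 0.8/0.2 (the pair must rank first at k = 2 with CVC
10/10, single loci near 0.5 balanced accuracy); HWE type-I calibration
over 10,000 replicates; Wald CI coverage over 200 replicates at N = 5000;
and WEC/reference-invariance contracts at 1e-8, matching the fitter's
gradient tolerance. These sizes keep each property in the
seconds-to-a-minute range while leaving Monte-Carlo error well inside the
asserted bands.

## Known limitations

- Only two-way interactions: interaction information and the WEC
  interaction block are pairwise; k-way generalizations change sign
  conventions and are out of scope.
- The exact HWE test (small-sample) is not implemented; at candidate-panel
  sizes the chi-square is adequate and its calibration is tested.
- No penalized or Firth regression: near-separated cells flag rather than
  shrink.
- The model-selection rule among inheritance models is a nearest-constraint
  heuristic; genuinely ambiguous OR patterns exist and the exposed
  residuals are the honest output in those cases.
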