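---
title: "Genotype-level case-control meta-analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-level case-control meta-analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
```

## The statistical problem

A candidate-gene association study types one biallelic variant (here the
CXCR2 C1208T polymorphism, risk allele T) in a group of cancer cases and
a group of controls and reports the three genotype counts per arm.
A meta-analysis of such studies must (i) decide which studies are usable,
(ii) reduce each genotype triple to a 2×2 exposure table under one or
more genetic models, (iii) pool the resulting odds ratios, and (iv) probe
the stability of the pooled estimate. `snpmeta` implements that pipeline
end to end, with the eleven published C1208T studies (4,909 cases, 5,884
controls) bundled as the worked dataset.

## Genetic models

Five contrasts are supported, and only these five — an additive
(Cochran–Armitage) trend model is deliberately out of scope, since the
collection this package targets was analysed with exactly these
contrasts:

| model | exposed | unexposed | table total |
|---|---|---|---|
| allelic | T allele | C allele | 2 × subjects |
| heterozygous | TC | CC | subjects − TT carriers |
| homozygous | TT | CC | subjects − TC carriers |
| dominant | TT+TC | CC | subjects |
| recessive | TT | TC+CC | subjects |

The allelic contrast counts each person as two independent alleles. That
ignores the within-person correlation of alleles (it is exact only under
HWE in both arms); it is nevertheless the universal convention for the
"allelic" model and is what published allelic ORs mean. The risk allele
is fixed as T; the package never re-orients to the minor allele, because
a frequency-based flip would silently invert ORs in populations where T
is the major allele (T frequency is about 0.65 in East Asian reference
panels, versus 0.08 in African ones).

## Hardy–Weinberg QC

The inclusion rule is the field's standard: controls must be compatible
with Hardy–Weinberg equilibrium; a control-arm p below `alpha_hwe`
(default 0.05) excludes the study. Case-arm deviation is reported but
never excludes — under a true association the case arm is not expected
to be in equilibrium.

Two tests are provided:

- `hwe_chisq()` — 1-df goodness of fit of the observed triple against
  (p², 2pq, q²) at the observed allele frequency, no continuity
  correction. This is the package default: the reference p-values
  shipped with the bundled dataset (both arms, all 11 studies) are
  reproduced to all three printed decimals by this test, which
  identifies it as the test actually behind those published values, even
  though the accompanying text described an exact test. The discrepancy
  is documented here rather than resolved.
- `hwe_exact()` — the conditional exact test: given the allele counts,
  heterozygote counts of matching parity are enumerated and all
  configurations no more probable than the observed one contribute to p.
  Monomorphic samples return p = 1, flagged.

## Effect sizes and pooling

Per-study effects are log odds ratios with Woolf variances
`1/a + 1/b + 1/c + 1/d`. If any cell is zero, 0.5 is added to **all
four** cells of that table before both the estimate and the variance
(the Woolf–Haldane convention, applied per table). The uncorrected cells
are kept alongside, because Mantel–Haenszel pooling handles zeros
without correction; corrected cells feed only the Woolf weights. The
bundled dataset has no zero cells, so the correction never fires there —
a fact asserted in the test suite.

Three pooled estimators are implemented, by hand, as the package's core:

- **Mantel–Haenszel fixed effects** (the reporting fixed-effect method):
  `OR = Σ(aᵢdᵢ/nᵢ) / Σ(bᵢcᵢ/nᵢ)` with the Robins–Breslow–Greenland
  variance for the log OR.
- **Inverse-variance fixed effects**: the Woolf-weighted mean of log
  ORs. It exists as the weighting basis of Cochran's Q and τ², not as a
  reporting method.
- **DerSimonian–Laird random effects**: moment estimator
  `τ² = max(0, (Q − df)/C)`, `C = Σw − Σw²/Σw`, from the IV-centered Q;
  random weights `1/(seᵢ² + τ²)`.

Model selection follows the heterogeneity rule: compute Q about the
IV-fixed estimate; if `p_het < alpha_het` (default 0.05) report
DerSimonian–Laird, otherwise Mantel–Haenszel. One study bypasses
selection.

### The two centers of Q

A subtle reporting convention matters for exact reproduction of
published grids produced by the classic commercial meta-analysis
packages, and `snpmeta` mirrors it. Q used for *selection* and for τ² is
always centered at the inverse-variance fixed estimate (the classical
definition). But the Q/I² *reported next to* a Mantel–Haenszel result is
centered at the MH estimate. The bundled collection exercises both
paths: the breast-cancer recessive I² of 36.2% only arises with the
MH-centered Q, while the European homozygous random-effects result
requires the IV-centered Q for τ². `cochran_q()` records which center
was used in its `center` field. Q about a DL estimate is never reported
— it would be nonstandard.

All significance tests on pooled estimates are two-sided Wald z-tests on
the log-OR scale with z = 1.959964 for 95% intervals; no small-sample t
intervals, no Hartung–Knapp adjustment, no Peto OR, no REML/Paule–Mandel
τ² — the scope is exactly the MH + DL toolkit.

## Robustness diagnostics

- `leave_one_out()` re-runs the *entire* selection-and-pooling procedure
  on every k−1 subset, so an omission can flip the chosen model; that
  behaviour is tested with a constructed set in which one study carries
  all heterogeneity.
- `egger_test()` is the classic unweighted OLS of standardized effect
  (ln OR/se) on precision (1/se), intercept tested with t on k−2 df.
  When all standard errors are equal the predictor is constant; the
  result is flagged degenerate with the intercept reported as the mean
  standardized effect and p = NA.
- `begg_test()` correlates the variance-stabilized deviates
  `(ln ORᵢ − pooled_IV)/√(seᵢ² − 1/Σw)` with the variances seᵢ², using
  tie-corrected Kendall τ_b and the ±1 continuity-corrected normal
  approximation; an exhaustive permutation p is available for k ≤ 8
  (8! orderings).
- Both bias tests require k ≥ 3; the analysis grid records smaller cells
  as "not assessed" rather than failing.

## The synthetic-study generator

`simulation_spec()` + `simulate_meta()` generate studies by
retrospective sampling, matching the case-control design: control
genotype probabilities are (p², 2pq, q²), optionally shifted by a
disequilibrium term d (heterozygotes get +d, each homozygote −d/2, so
the allele frequency is invariant); case probabilities are the control
probabilities times the genotype odds ratios (OR_hom, OR_het, 1),
renormalized. Counts are multinomial. Under this scheme the target ORs
are exact functionals of the sampling probabilities (`true_model_or()`
returns them in closed form), which is what makes parameter-recovery
testing clean.

Design choices:

- **Heterogeneity** (`tau`): one study-level N(0, τ) deviate is added to
  both genotype log ORs. A single shared deviate (rather than
  independent ones per genotype) keeps the between-study variance of any
  one model contrast interpretable against τ².
- **Determinism**: each study slot derives its own seed from the global
  seed and its index, so `simulate_study(spec, i)` reproduces study i of
  `simulate_meta(spec)` exactly, and serialized output is byte-identical
  across runs.
- **Publication censoring** (`censor_rule`): a *small-study*
  significance-censoring rule. Studies at or above `large_n` combined
  subjects (default 1000, the same cutoff the package uses to call a
  study "large") are always retained; smaller studies are retained only
  when one-sided significant for a positive association (α = 0.05), or
  with probability `keep_nonsig` (default 0.02 — strong selection)
  otherwise. Each slot keeps its drawn size and redraws only the
  outcome: redrawing entire studies would almost remove small studies
  from the retained set (the probability a retained study is small is
  roughly keep/(1+keep)), leaving no asymmetry for *any* funnel
  diagnostic to detect — a property of the selection regime, not of the
  tests, and one we verified applies identically to an independent
  implementation of Egger's regression. With the per-slot design and
  strong selection, Egger's test detects the induced asymmetry in well
  over half of simulated 20-study meta-analyses with per-arm sizes
  spanning 30–1000 (an order-of-magnitude size spread, comparable to the
  bundled collection's 222–3510 combined totals).

What the generator does **not** emulate: covariate structure,
population stratification/admixture, linkage with neighbouring loci,
genotyping error, or non-multinomial sampling (matched designs).
Passing recovery tests therefore demonstrate correctness of the
estimators under the idealized sampling model, not robustness to those
real-data complications.

## Validation strategy and problem sizes

The test suite validates at three levels, all at fixed seeds:

1. **Exact reproduction**: every published pooled OR/CI/p of the bundled
   collection at its printed rounding, all 22 reference HWE p-values to
   3 decimals, and the pooled T-allele frequencies (cases 0.484,
   controls 0.479).
2. **Independent oracles**: Mantel–Haenszel against an exact
   rational-arithmetic cross-product oracle on small strata and against
   `metafor::rma.mh`; DerSimonian–Laird against `metafor::rma(method =
   "DL")`; Egger against `metafor::regtest(model = "lm")`; Begg's τ
   against `metafor::ranktest` and its exact permutation p against
   `cor.test`; the exact HWE test against a multinomial enumeration
   oracle for every genotype triple of total ≤ 30.
3. **Operating characteristics**: Egger/Begg type-I error in
   [0.02, 0.08] over 1,000 null 15-study meta-analyses; HWE rejection
   rate in [0.03, 0.07] over 2,000 equilibrium-true control arms of
   n = 500; pooled-OR relative bias below 3% and CI coverage in
   [93%, 97%] over 1,000 replicates of 30 studies × 2,000 per arm at
   OR_hom = 1.5; τ² recovery within 20% of τ² = 0.09 over 300
   replicates. These sizes keep the full suite under two minutes on a
   single core while leaving Monte-Carlo error well inside the asserted
   bands.

One published cell is deliberately **not** reproduced: the large-sample
heterozygous OR of 1.26. All three large studies' heterozygous ORs are
at most 1.16, so no convex weighting can pool to 1.26; the value cannot
derive from the bundled counts (it may trace to the source's internally
inconsistent study count). The stored reference grid marks the row as a
known inconsistency and both `reproduce_fixture()` and the acceptance
tests assert that the pipeline does *not* match it.

## Known limitations

- Wald intervals throughout; no exact conditional per-study ORs, so very
  sparse tables rely on the 0.5 correction.
- The quality-of-studies stratification axis is accepted in
  `analysis_config()` but unpopulated: the bundled dataset carries no
  quality scores and no quality-stratified reference values exist.
- The African stratum of the bundled collection has a single study; its
  pooled cell is computed but has no published value to verify against.
- Egger's test on log odds ratios has a known mild size distortion when
  events are rare (estimate and variance are correlated); the null
  simulations here use a common variant (p_T = 0.45), where the
  distortion is negligible.
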