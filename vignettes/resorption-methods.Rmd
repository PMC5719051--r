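---
title: "Methods: leaf nutrient resorption, phylogenetic signal, and the synthetic community"
author: "resorb package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaf nutrient resorption and phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resorb)
```

## The scientific problem

Plants withdraw part of their leaf nutrient pool before shedding leaves.
Two complementary summaries describe this process for an element
(N, P, K, Na, Ca or Mg):

* **Resorption efficiency (RE)** — the proportional withdrawal during
  senescence.  Because senescing leaves also lose dry mass, the naive
  green-vs-senesced concentration comparison underestimates withdrawal;
  the mass loss correction factor (MLCF, the senesced/green dry-mass
  ratio) compensates:
  \[ RE = \left(1 - \frac{Nu_{senesced}}{Nu_{green}} \times MLCF\right)
     \times 100\% . \]
  RE can be negative: the element *accumulated* during senescence, the
  typical pattern for structural Ca and Mg and — in salt-compartmenting
  euhalophytes — for Na.
* **Resorption proficiency (RP)** — the terminal concentration in
  senesced leaves; a *lower* concentration means a *higher*
  proficiency.

The package asks how these metrics differ between plant groups with
contrasting sodium-regulation strategies — euhalophytes (Eu, Na
compartmentation in succulent foliage), secretohalophytes (Se, salt
glands), pseudohalophytes (Ps, Na exclusion) and glycophytes (Gl) —
and whether the traits carry phylogenetic signal, i.e. whether related
species resemble each other more than random species would.

## Comparative-methods core

**Phylogenetic variance–covariance.** Under Brownian motion (BM) the
trait covariance of two tips equals their shared root-to-tip path
length; `vcv_matrix()` builds this matrix directly from the edge list.

**Blomberg's K** (`blomberg_k()`) is a ratio of ratios.  Writing
\(\hat a = (1'C^{-1}x)/(1'C^{-1}1)\) for the GLS phylogenetic mean,
\(MSE_0\) for the ordinary mean square around \(\hat a\) and
\(MSE = (x-\hat a)'C^{-1}(x-\hat a)/(n-1)\), the observed \(MSE_0/MSE\)
is divided by its BM expectation
\([\mathrm{tr}(C) - n/(1'C^{-1}1)]/(n-1)\).  K = 1 under BM on the given
tree; K below 1 means weaker, above 1 stronger resemblance among
relatives.  On a star phylogeny the two ratios coincide and K is
exactly 1 for any non-constant trait — one of the package's exact
tests.

**Significance** (`signal_test()`) uses a tip-shuffling permutation
test with the variance of the standardized independent contrasts as the
statistic (small variance = strong signal).  The one-tailed p-value
\((1 + \#\{null \le obs\})/(n_{perm}+1)\) never falls below
\(1/(n_{perm}+1)\); the default 999 permutations follow common
practice in comparative-methods software.  Rejection at level
\(\alpha\) uses the exact-test convention \(p \le \alpha\).

**Independent contrasts** (`pic_contrasts()`) follow Felsenstein's
pruning recursion; polytomies must first be resolved to zero-length
binary nodes (`read_newick()` does this deterministically, keeping
input child order — zero-length resolution leaves the induced
covariance matrix unchanged).  Contrast-based correlations
(`pic_correlation()`) are computed through the origin because contrast
signs are arbitrary; the t statistic uses \(n-2\) degrees of freedom
with \(n\) the number of contrasts.  (A common alternative convention
uses \(n-1\) df for a through-origin correlation; with 35 contrasts the
difference is negligible, and the \(n-2\) form is used throughout.)

**Group labels as a trait.** K needs numbers, and published analyses
rarely state how a categorical group was coded.  The default is a
single integer coding in the fixed order Eu=1, Se=2, Ps=3, Gl=4
(`encode_group_trait()`); an indicator mode (four 0/1 traits) is
provided because the choice is genuinely open.  Integer coding yields
one K per grouping, matching how group-level signal is usually
reported.

## Classical statistics layer

* One-way ANOVA is the classical sums-of-squares decomposition;
  compact letters come from Tukey HSD pairwise tests via the
  insert-and-absorb algorithm, with letters assigned in descending
  group-mean order (the highest group is always "a").  Tukey HSD is a
  deliberate choice: the post-hoc procedure behind published letter
  displays is usually unstated, and HSD is the standard companion of
  one-way ANOVA at \(P < 0.05\).
* RE is tested against 0% (no net resorption) with a one-sample t
  test, and against global mass-loss-corrected averages with Welch's
  two-sample test.  Only two global reference means are widely printed
  (62.1% for N, 64.9% for P); references may be given as
  (mean, sd, n) triples for a proper Welch test, and a bare mean falls
  back to a one-sample test against it.
* PCA of the six elements runs on the **correlation** matrix: Na spans
  3–54 mg g⁻¹ across groups while P stays near 2–3, so a covariance
  PCA would be a Na axis by construction.
* Standardized major axis (SMA) fits treat both variables as
  error-laden: slope \(= \mathrm{sign}(r)\, s_y/s_x\), which makes the
  fit symmetric (reciprocal slopes multiply to 1).
* Variance partitioning uses sequential (Type I) sums of squares with
  site entered before plant group or family, so variance shared between
  soil and taxonomy is credited to soil.  The order is configurable and
  recorded in the output.  In both the emulated and the real sampling
  design soil type and plant group are partially confounded
  (glycophytes occur only on gravel soils), which makes some group
  contrasts collinear with site; the pipeline proceeds the way
  `lm()` does and documents that the shared part sits with the earlier
  factor.

## Leaf functional traits

SLA is leaf area over dry mass (cm² g⁻¹).  LDMC is implemented as dry
mass over water-saturated mass, the standard 0–1 quantity, even though
the trait is sometimes printed as its reciprocal; the 0–1 range is what
the validity checks test.  Succulence is water mass per leaf area
expressed in g m⁻², the unit in which the conventional threshold of
500 separates significantly succulent leaves.  K/Na below 1 marks
plants using Na as the major osmoticum.

Two RE definitions circulate that differ in the denominator
(green-leaf vs senesced-leaf concentration).  The pipeline implements
only the mass-loss-corrected, green-denominator form above; the
"uncorrected" variant is the same formula with MLCF = 1.  MLCF is
computed per species (whether published analyses used species- or
group-level MLCF is usually unstated; per species is the finer and
safer default).

The RE arithmetic cannot distinguish resorption from secretion: in
salt-secreting species a drop in leaf Na may be export through salt
glands, not withdrawal into storage.  The pipeline still computes the
(Se, Na) value but flags it (`caveat` column) rather than suppressing
it.

## The synthetic community

Field datasets behind this kind of study are typically available only
on request, so the package is driven by a generator with known ground
truth (`synthetic_truth()`, `generate_leaf_dataset()`).  Its defaults
*are* the emulated study design, chosen once:

* 36 species in 15 family clades on a unit-depth Yule tree; four groups
  of 10/5/11/10 species assigned as contiguous clades (clustered mode)
  so the group label carries phylogenetic signal, or uniformly at
  random (null mode);
* green-leaf concentration means per group set to the published
  reference table (e.g. green Na: Eu 53.5, Se 24.9, Ps 3.19,
  Gl 13.2 mg g⁻¹); species-level deviations act on the log scale with
  SD `tau = 0.25`, of which a fraction `phylo_weight = 0.7` is Brownian
  motion on the tree and the rest independent noise — so both the
  group structure and the phylogenetic signal of Na are reproducible;
* true RE per group and element derived from the green and senesced
  reference means at the nominal MLCF 0.8 (the mean of the
  per-species Uniform(0.6, 1.0) MLCF), plus species jitter
  (SD 0.05, truncated to (−0.49, 0.95)).  This implies, e.g., negative
  true Na RE in euhalophytes — the accumulation direction reported for
  that group;
* 5–8 tagged individuals per species, each contributing one green and
  one senesced leaf; a published total of "252 leaf samples" for 36
  species is read as 252 leaves = 126 pairs (≈3.5 pairs per species),
  reproducible with `individuals_per_species = 3:4`, while the default
  5:8 follows the stated field protocol;
* multiplicative lognormal noise everywhere (keeps concentrations
  positive; no error model is ever published for such tables), with
  mean-one correction so expectations equal the stated means:
  individual SD 0.2, site fertility SD 0.05.  Senesced concentrations
  are generated as `green_mean × (1 − RE_true)/MLCF` times their own
  noise — the exact inversion of the RE formula — so the estimated RE
  recovers the truth exactly at zero noise and in expectation
  otherwise;
* masses and areas are built from per-species SLA and LDMC drawn from
  group-typical desert-plant ranges (euhalophytes: low SLA 20–40
  cm² g⁻¹ and low LDMC 0.10–0.20, which makes their computed
  succulence exceed the 500 g m⁻² threshold); at zero noise the
  species MLCF, SLA and LDMC are recovered exactly.

`tune_group_effect()` solves analytically — from the generator's own
variance components, never from observed output — for the group-effect
scaling at which plant group accounts for a chosen fraction of the
individual-level log-Na variance; the recovery experiment in the test
suite uses the 50% setting with `clustered = FALSE` so the Brownian
species effect is independent of the group labels being recovered, and
partitions log(Na) with group as the (single) tuned factor.

**What a green test does not establish.**  The generator emulates the
*design* (sample sizes, group means, clustered groups, paired leaves),
not the full complexity of field data: there is no within-site spatial
structure, no secretion physiology behind the Se/Na numbers, no soil
chemistry (sites are labels with a scalar fertility multiplier), no
measurement error model beyond lognormal noise, and species are
exchangeable within groups apart from the BM component.  Recovery of
the truth here validates the estimators and the pipeline plumbing, not
any ecological claim about real communities.

## Numerical choices and degenerate inputs

* Trees without branch lengths default to unit lengths (logged), with
  Grafen depth scaling as the alternative; how published Phylomatic
  trees were calibrated is usually unstated, so the minimal
  reproducible choice is the default.
* K on a constant trait, SMA on a constant variable, RE at zero green
  concentration, and contrasts across an all-zero-length cherry are
  errors, not NaNs.  A zero-variance sample equal to the null mean
  returns t = 0, p = 1 with a message.
* Seeds: every stochastic entry point takes an explicit seed and
  leaves the caller's RNG untouched; the pipeline derives per-step
  seeds from the single run seed, so whole runs are byte-identical
  (run metadata deliberately records no timestamp).
* CSV output is written with 17 significant digits, so accepted rows
  and result tables round-trip bit-exactly.
* Missing values propagate pairwise in correlation tables and listwise
  in PCA (complete rows required).

## Known limitations

* No alternative signal metrics (Pagel's λ, OU models) and no
  ancestral-state machinery beyond the internal contrast recursion.
* The permutation test's null is exchangeability of tips; it is exact
  for the variance-of-contrasts statistic but does not provide
  confidence intervals for K.
* The two-sample comparison against global averages is only as good as
  the published reference summaries; with a bare mean it degrades to a
  one-sample test.
* Family assignment in the generator slices the tree at the
  15-lineage epoch; real family sizes are far more skewed.

## A worked run

```{r example, eval = FALSE}
res <- run_pipeline(run_config(seed = 42))
res$tables$group_means[res$tables$group_means$element == "Na", ]
res$tables$signal
```

Tables produced: `species_summary`, `resorption` (species- and
individual-level RE/RP), `group_means` (per element and leaf status,
with Tukey letters), `re_summary` (RE per group with tests against 0%
and the global references), `signal` (K and permutation p per trait,
including the integer-coded plant group and a pure-noise control),
`correlations` (SLA/LDMC against RE/RP at individual, species and PIC
levels), and `variance_partition` (per element, site then group or
family).
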