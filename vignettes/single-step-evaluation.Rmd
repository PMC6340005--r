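---
title: "Single-step genomic evaluation: models, matrices, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation: models, matrices, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(singlestep)
```

This vignette is the package's own account of the statistics it
implements: the four evaluation methods and their assumptions, the
relationship-matrix algebra that connects them, the knobs that matter and
why their defaults are what they are, what the simulator does and does not
emulate, and the numerical choices underneath.

## The animal model and its four covariance structures

Everything rests on one linear mixed model for phenotypic records,

$$ y = Xb + \gamma W + Zg + e, \qquad e \sim N(0, I\sigma_e^2), $$

where $b$ collects fixed-effect factor levels (herd–year–season–sex in
field data; sex–generation in simulated data), $W$ an optional covariate
(e.g. body weight), and $g$ the additive genetic effects of *all* animals,
including those without records. The four methods differ only in the
assumed covariance of $g$:

| method | covariance of $g$ | animals carried |
|---|---|---|
| BLUP | $A\sigma_g^2$ | all in pedigree |
| GBLUP | $G\sigma_a^2$ | genotyped only |
| ssGBLUP | $H\sigma_g^2$ | all in pedigree |
| two-trait ssGBLUP | $M \otimes H$ | all, both traits |

The solvers all assemble Henderson's mixed-model equations with
$\lambda = \sigma_e^2/\sigma_g^2$ and solve them by sparse Cholesky
factorisation; predicted breeding values (PBV) fall out for every animal
in the relationship matrix, so record-less validation animals are
predicted through their relatives.

**Assumptions worth stating.** Additive gene action only (no dominance or
epistasis, no maternal effects); multivariate normality of $g$ and $e$;
variance components treated as known inputs (the usual two-stage practice
in routine evaluation — EM-REML is provided to estimate them when they are
not). In the two-trait model, residuals of the two traits are correlated
only within the same animal's records; an animal observed for one trait
contributes through the corresponding sub-block of $R$, which is exactly
equivalent to treating the other trait's record as absent.

## Pedigree algebra

`build_A()` uses the tabular recurrence
$a_{xy} = \tfrac12(a_{\mathrm{sire}(x),y} + a_{\mathrm{dam}(x),y})$,
$a_{xx} = 1 + \tfrac12 a_{\mathrm{sire}(x),\mathrm{dam}(x)}$, which is
exact for any acyclic pedigree and yields inbreeding as
$F = \mathrm{diag}(A) - 1$. `inbreeding()` computes the same $F$ without
the dense matrix (Meuwissen–Luo ancestor accumulation), and
`build_A_inverse()` never forms $A$ at all: with $P$ holding $\tfrac12$ at
each (animal, parent) entry and $D$ the Mendelian-sampling variances
derived from parental $F$,

$$ A^{-1} = (I - P)' D^{-1} (I - P), $$

which is Henderson's rules with inbreeding accounted for. Whether
inbreeding should enter $D$ is genuinely ambiguous in much legacy
software; we default to including it (`use_inbreeding = TRUE`) because the
rules degrade gracefully to the non-inbred case, and expose the flag for
comparison. `build_A22()` extracts the genotyped block by two sparse
triangular solves ($A = (I-P)^{-1} D (I-P)^{-T}$, Colleau's indirect
method), so pedigrees of tens of thousands of animals never require a
dense $A$; dense `build_A()` is intended for pedigrees up to roughly
10,000.

## From G to H

`build_G()` implements VanRaden's first method,
$G = \tilde Z \tilde Z' / 2\sum_j p_j(1-p_j)$ with dosages centered at
$2p_j$. Allele frequencies default to those of the current genotyped set —
base-population frequencies are unobservable in practice — which makes
$\mathrm{mean}(\mathrm{diag}(G)) \approx 1$ by construction.

Because $G$ and $A_{22}$ refer to different base populations, their
coefficients differ in location and scale. `adjust_G()` solves the
two-equation system matching average diagonal and average off-diagonal,
giving $G_a = \beta G + \alpha$; `blend_Gw()` then forms
$G_w = w G_a + (1-w) A_{22}$. The blend serves two purposes: it guarantees
invertibility when $G$ is rank-deficient (always the case when markers are
fewer than genotyped animals), and it acknowledges that markers do not
capture all genetic variance. The default $w = 0.95$ is the conventional
weight; the literature also reports trait-specific optima anywhere from
0.25 to 0.95, so $w$ is a first-class argument. Note one genuine ambiguity
in the field's notation: some authors attach $w$ to the *pedigree* part
("the proportion of genetic variance not captured by markers"). We follow
the algebra as printed above — $w$ multiplies the genomic part — and any
$w \in (0,1]$ is accepted, so the opposite convention is obtained by
passing $1-w$.

`build_H_inverse()` then adds $G_w^{-1} - A_{22}^{-1}$ into the genotyped
block of $A^{-1}$. The dense `build_H_direct()` exists as a testing aid:
the suite verifies on random instances that the two constructions are
mutual inverses, and that setting $G_w = A_{22}$ collapses ssGBLUP onto
pedigree BLUP — at the matrix level, the PBV level, and the
cross-validation-metric level.

**GBLUP's response and matrix.** GBLUP is fit to corrected phenotypes
$y_c = \hat g + \hat e$ from a full pedigree-BLUP fit (residuals averaged
for animals with repeated records), so fixed effects are pre-absorbed. In
the evaluation pipeline GBLUP uses the adjusted and blended $G_w$ rather
than raw $G$: with desk-scale panels (hundreds of markers, up to thousands
of genotyped animals) raw $G$ is singular, and blending is the standard
remedy. `solve_gblup()` itself takes any positive-definite matrix and
errors on a singular one with advice to blend.

## Marker quality control

`qc_filter()` removes a marker when minor allele frequency < 0.05, call
rate < 0.90, or the 1-df Hardy–Weinberg chi-square p-value (observed vs
expected genotype counts among non-missing calls, no continuity
correction) falls below 1e-7 — conventional chip-QC thresholds, all
configurable. "Call frequency" is interpreted per marker; individuals are
never removed. Fixed markers slip past the HWE test by design (their
p-value is undefined) because the MAF rule removes them first. Missing
genotypes are then filled by `naive_impute()` with the marker's rounded
mean dosage: a deterministic, linkage-agnostic rule that is entirely
adequate for the low missingness left after QC, though clearly inferior to
LD-based imputation for real chip data with substantial missingness.

## The simulator

`simulate_population()` emulates a pig-breeding-like study design:

* **Genome** (defaults): 18 chromosomes of 1 Morgan, 2,834 evenly spaced
  markers each (51,012 total), 306 QTL placed at random inter-marker
  midpoints (17 per chromosome), marker/QTL mutation rates
  $1.25\times10^{-3}$ / $2.5\times10^{-3}$ per locus per meiosis
  (recurrent allele flip).
* **Burn-in**: 400 generations of 200 random-mating diploids, all loci
  starting at frequency 0.5, Poisson recombination (rate = map length,
  uniform placement, no interference) — this establishes drift-driven
  allele-frequency spectra and linkage disequilibrium between markers and
  QTL. These internals are our design choices; published forward
  simulators leave them configurable, and so do we.
* **Recent population** (defaults): 10 discrete generations of 3,000 with
  recorded pedigree, random sire/dam mating, no selection. Generation-1
  animals are pedigree founders (their burn-in ancestry is genetically
  present but unrecorded, exactly the situation A assumes away and H
  partially recovers).
* **Traits**: two, $h^2 = 0.1$ and $0.3$, genetic correlation 0.7,
  phenotypic variance 1. QTL effect pairs are i.i.d. bivariate normal
  with correlation $r_g$; TBV = QTL dosage × effects; phenotype =
  sex–generation effect (levels drawn Uniform(0,1)) + TBV + normal
  residual (residuals uncorrelated across traits by default, since only
  the genetic correlation is part of the design).

Effects are rescaled so that the TBV variance **in the final generation**
equals $h^2 \cdot \mathrm{var}_p$: the final generation is where
validation animals are drawn, so it is the natural calibration target, and
it makes the realized heritability of the evaluation population land on
the nominal value up to residual sampling noise. With a handful of QTL
(the reduced test genome has 20) the *realized genetic correlation* of
TBVs scatters around the effect correlation with a between-replicate SD
near $0.1$ — a finite-QTL sampling effect, not a bug — which is why
calibration checks average over several seeds.

**Study scenarios.** `make_scenario()` draws a fixed validation set from
the final generation (genotyped, phenotypes masked) and a genotyped,
phenotyped reference of the requested size from an earlier generation
(default two before the last, mirroring a reference at generation 8 of
10); all other animals contribute pedigree and phenotypes only.
`evaluate_reference_sizes()` replays the reference-size study; `run_cv()`
runs replicated k-fold cross-validation with fold plans shared across
methods, and masking is total — the suite verifies that perturbing masked
phenotypes cannot change any prediction.

**What the simulator does not emulate** — and hence what passing tests do
*not* show about real data: selection and non-random mating; overlapping
generations and repeated records; genotyping error and real LD structure
from a finite-marker ascertainment; the use of a multi-trait EBV as
surrogate truth (simulation scores against true breeding values, which is
cleaner than anything available in the field).

## Numerical choices and conventions

* **Identifiability**: `build_design()` uses R's treatment contrasts (one
  reference level per factor) and removes any remaining confounded
  columns by pivoted QR. Estimable quantities — PBV, fitted values,
  corrected phenotypes — are invariant to this choice; only the raw
  fixed-effect coding differs from software that drops the last level.
* **Solvers**: sparse Cholesky via the Matrix package on the full MME;
  appropriate up to a few tens of thousands of equations, which covers
  the package's intended desk-to-herd scale.
* **EM-REML**: the classic updates
  $\sigma_g^{2} \leftarrow (\hat g' K^{-1}\hat g +
  \sigma_e^2\,\mathrm{tr}(K^{-1}C^{gg}))/q$ and
  $\sigma_e^{2} \leftarrow (y'y - \hat b'X'y - \hat g'Z'y)/(n-p)$,
  implemented after absorbing the fixed effects via a one-time
  generalised eigendecomposition of $(Z'SZ, K^{-1})$, so each EM step is
  closed-form and iteration cost is linear in $q$. Convergence is
  declared at relative change $<10^{-6}$ (default) and estimates hitting
  $10^{-12}$ raise a boundary warning. EM's monotone but slow crawl near
  a boundary is inherited from the algorithm itself.
* **Ties and degenerate inputs**: unknown parents are coded "0" or empty
  and normalised to a sentinel; the topological sort is stable with
  founders first; cyclic pedigrees, self-parenting, duplicate ids,
  out-of-range dosages, all-missing markers, and singular $G$ or
  adjustment systems are rejected with targeted messages rather than
  propagated as numerical garbage.
* **Seeds**: every stochastic entry point takes a seed, sets it locally
  and restores the caller's RNG state; scenario and fold plans are pure
  functions of (ids, seed).

## Problem sizes used in the test-suite

The default test fixture is the reduced genome — 2 chromosomes × 200
markers, 20 QTL, burn-in 100 × 200 — with recent generations of a few
hundred to a few thousand animals; the full pipeline on this fixture runs
in seconds to a couple of minutes. These sizes were chosen so that every
claim is checked against a brute-force oracle (dense GLS, dense matrix
inversion, likelihood grids) where exactness is decidable, and the
statistical claims (parameter recovery, method orderings across reference
sizes) are checked as majorities or means over repeated seeds at sizes
where the expected effects dominate sampling noise.

## Known limitations

Single marker-effect variance (no Bayesian alphabet); at most two traits;
no genetic groups or metafounders; no APY or other large-scale sparse-G
approximations; dense $A_{22}$ limits the genotyped set to a few thousand;
EM-REML is univariate (two-trait covariances are inputs, from config or
simulation truth).
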