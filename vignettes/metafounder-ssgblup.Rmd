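---
title: "Metafounder single-step genomic BLUP: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metafounder single-step genomic BLUP: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaBLUP)
```

# The problem

Tree-breeding populations are typically founded on parents drawn from
several distinct wild races, naturalized landraces, and phenotypically
selected infusion populations. Treating those founders as a single
unrelated base population misstates both the relationships among
founders (individuals from one race share ancestry) and the genetic
means of their descendants. This package implements the two standard
remedies inside a single-step genomic evaluation:

* **unknown-parent groups (UPG)** — fixed genetic-group effects
  attached to missing parent slots; and
* **metafounders (MF)** — pseudo-individuals with a K×K relationship
  matrix Γ estimated from descendant genotypes, so base populations are
  related, inbred (or outbred) random effects rather than fixed shifts.

# Model

All variants fit `y = Xb + Z1 a + Z2 f + e`, with per-site fixed
effects, additive values `a`, full-sib family effects
`f ~ N(0, I σf²)` capturing non-additive plus common-environment
variance, and residuals `e ~ N(0, I σe²)`. Phenotypes are assumed
pre-adjusted for within-trial design/spatial effects and standardized
per trial to mean 0, SD 1 (`standardizeByTrial()`); the package does
not perform spatial adjustment. The residual is homogeneous across
sites by default; a named per-site `sigmaE2` vector with
`residualMode = "per-site"` weights records by site-specific precision
(the cross-site scale of the standardized data makes the homogeneous
default reasonable, and solution differences between the two choices
are small when per-site variances are similar).

`var(a)` distinguishes the variants: `A`, the UPG-adjusted `A*`
(handled by the Quaas–Pollak device, see below), `AΓ`, `H`, or `HΓ`,
with the additive variance divided by
`k = 1 + mean(diag Γ)/2 − mean(Γ)` for MF variants so that variance
components estimated under the classical parameterization remain
usable.

# Estimating Γ

`Γij = 8 cov(pi, pj)` over base allele frequencies. Frequencies are
estimated per marker by GLS from the genotyped descendants:
`p̂ = (Q' A22⁻¹ Q)⁻¹ Q' A22⁻¹ m / 2`, where `Q` holds expected
group contributions (`upgMatrix()`) and `A22` is the **plain** pedigree
relationship matrix among genotyped individuals — not the Γ-augmented
one, since Γ is the quantity being estimated.

Two deliberate choices:

* **Centering.** The "covariance" across markers needs a reference
  point. The default centers at 0.5 (a second moment about one half),
  because the 0.5-frequency genomic matrix G05 and the classical
  "uniformly distributed base frequencies give E(Γii) = 2/3" benchmark
  are both referenced to 0.5. Per-metafounder marker-mean centering
  (`center = "mean"`) is available; it yields a covariance proper and
  smaller diagonals. Neither is presented as the uniquely correct
  convention; the default keeps Γ and G05 on one base.
* **Positive semidefiniteness.** Γ̂ can be indefinite with few
  genotyped descendants. Eq-1-style inverses need Γ⁻¹, so negative
  eigenvalues are clipped at 1e-6 — silently if the caller asked for
  repair (`psdRepair = TRUE`), with a warning if it had to be applied
  automatically.

Missing parents with exactly one known parent receive half the known
parent's contribution and half the slot's metafounder indicator (the
standard UPG/MF treatment); pedigrees whose ancestry is recorded
asymmetrically will see that convention, not an inferred one.

# Relationship matrices

* `aMatrix()` uses the tabular recursion (diagonal 1 + F).
  `aGammaMatrix()` runs the same recursion with metafounders as founder
  pseudo-individuals whose mutual relationships are Γ; a founder with
  both parents in group g gets diagonal `1 + Γgg/2`.
* `aInverse()` / `aGammaInverse()` assemble the sparse inverses by
  Henderson's rules with Mendelian-sampling variances
  `d = a_ii − (a_ss + a_dd + 2 a_sd)/4` computed from the (Γ-aware)
  recursion via memoized pairwise coefficients, so the sparse inverse
  equals the dense inverse of the tabular matrix also under inbreeding
  and under Γ. The metafounder block additionally carries Γ⁻¹.
* `genomicRelationship()` is first-method VanRaden. With observed
  frequencies, monomorphic markers are dropped (they carry zero weight
  in the scaling constant); with 0.5 frequencies they are retained
  (each still contributes to `c = m/2`). Missing genotypes are
  mean-imputed per marker — a deterministic fallback, not a substitute
  for proper imputation upstream.
* `rescaleG()` matches mean diagonal and overall mean to A22 (the
  standard two-moment compatibility tuning; both raw and rescaled
  matrices remain available), and `blendG()` applies the 0.95/0.05
  blend. G05 is blended against AΓ22, because the Γ-augmented
  single-step correction subtracts AΓ22⁻¹ and the two matrices must
  share a base; this is a configurable choice, not a theorem.
* `hInverse()` / `hGammaInverse()` place `G⁻¹ − A22⁻¹` (resp.
  `G05⁻¹ − AΓ22⁻¹`) on the genotyped block, zero elsewhere — in
  particular the metafounder rows of the correction are structurally
  zero. No τ/ω scaling of the correction blocks is applied: the
  assemblies are used exactly as written above (overrides are possible
  by scaling the inputs). `hMatrix()` builds the dense H for inspection
  and testing only and refuses more than 20,000 entities.

Entities are ordered individuals-in-pedigree-order first, metafounders
last; every operation matches by id, so no contiguous
ungenotyped/genotyped block layout is required of the user.

# Solving and the Quaas–Pollak device

The mixed-model equations are assembled in precision form
(`C = W'R⁻¹W + Σ⁻¹`) with sites as a full indicator block and no
intercept, which handles fixed-effect identifiability the same way as
a reference-level drop; LR statistics use solution differences and are
unaffected by that convention. For ABLUP_UPG, group equations enter by
the Quaas–Pollak transformation — no penalty on groups, coupling
`−A⁻¹Q/σa²` — with the **last group constrained to zero**; the additive
solutions of that variant are then total merit (deviation plus expected
group contribution), and group effects are reported separately. For MF
variants the metafounder solutions sit at the tail of the additive
vector; they are deliberately not added into individual solutions,
mirroring how group and MF solutions are compared in practice.

The direct solver is a sparse Cholesky with a relative-residual check
(reported in `meta$relResidual`; typically ~1e-14, required < 1e-10);
the alternative is Jacobi-preconditioned conjugate gradients from a
zero start (tolerance 1e-10 on the relative residual, an error with
residual history on non-convergence).

# EM-REML

`emREML()` implements the classical EM updates for (σa², σf², σe²):
`σa²⁺ = (â'K⁻¹â + tr(K⁻¹C^aa))/q`, `σf²⁺ = (f̂'f̂ + tr(C^ff))/s`,
`σe²⁺ = (y'y − θ̂'W'y)/(n − rank X)`. The traces come from a dense
inverse for systems up to 1,500 unknowns and otherwise from a fixed
set of 64 Hutchinson probe vectors solved against the sparse Cholesky
factor — drawn once per call, so a run is deterministic given the RNG
state on entry, and the probe noise does not wander across iterations.
EM steps are cheap but convergence near the optimum is slow; the
defaults (maxIter 2000, tol 1e-5 on the maximum relative change) were
set so that the n = 10,000 recovery fixture converges well inside the
optimum's sampling error. A family variance collapsing to zero is held
at 1e-8 and flagged (`familyFloor`). The intended workflow mirrors
operational practice: estimate once under the base variant, then fix
the components for every variant of that population set.

# LR cross-validation

`dropFocalPhenotypes()` removes all phenotyped progeny of the chosen
focal parents; `lrStatistics()` computes, over the focal group with
n−1 divisors: ACC `= sqrt(cov(âw, âp)/((1 − F̄) σ̂a²))`, STAB
`= cor(âw, âp)`, DISP `= cov(âw, âp)/var(âp)`, BIAS
`= mean(âp) − mean(âw)` (also in genetic-SD units). Decisions worth
stating:

* The accuracy is the **square root** of the covariance ratio (the raw
  ratio is also returned as `accRatio`); a negative covariance makes
  ACC undefined and is reported as `NA` rather than silently clamped.
* `F̄` is the focal group's mean inbreeding from the **group-free** H
  diagonal, for every variant of a population set, so accuracies are
  comparable across variants.
* Focal parents for synthetic runs are drawn stratified across
  breeding programs (`sampleFocalParents()`), emulating focal groups
  that represent a diversity of origins.
* σ̂a² in ACC is the REML additive variance as estimated (not divided
  by k), again for cross-variant comparability.

# The simulator

`simPopulation()` emulates the statistical structure the analysis
assumes: K base populations whose allele frequencies drift from a
common ancestral pool (uniform on [0.05, 0.95]) along a balanced
bifurcating tree via Balding–Nichols steps, so Γ has nested structure
(a star phylogeny is the `treeDepth = 1` special case); a
multi-generation pedigree across two programs with full-sib families
and occasional cross-program matings; per-locus gene dropping; a
genotyped subset of all parents plus a fraction of progeny (emulating
operational panels that genotype parents densely and progeny sparsely);
and phenotypes built as marker-effect TBV + family + residual, spread
over sites within family and standardized per site.

Parameter defaults and why:

* **Desk preset**: K = 6 populations (20 founders each), 2 programs,
  3 generations of 40 × 25 full-sib families (~3,100 individuals),
  2,000 markers, 30% of non-parent progeny genotyped, 4 sites. Sized so
  the full pipeline — simulation, Γ, H⁻¹, five model fits, LR — runs in
  well under five minutes on one CPU while family and provenance
  structure stay estimable. The EM-REML recovery fixture instead uses
  2 × 100 × 50 families for exactly 10,000 records.
* **Divergence**: per-level Fst 0.05 over three levels (cumulative
  ≈ 0.14), emulating the modest among-race differentiation reported
  for temperate eucalypt races. Note the ancestral-uniform law bounds
  the simulated Γ diagonal below at about 0.55, higher than estimates
  from real races whose ancestral frequency spectra are concentrated
  nearer 0.5 — simulated Γ is therefore on a somewhat larger scale
  than field estimates, with the same nested geometry.
* **Variance components** default to σa² = 0.171, σf² = 0.043,
  σe² = 0.805 on the standardized scale (cross-site h² ≈ 0.17, typical
  for juvenile growth traits).
* **TBV scaling**: marker effects are drawn `N(0, σa²/(m/2))` on
  0.5-centered gene content — so population means diverge naturally
  with allele frequencies and genomic models have genuine signal — and
  then rescaled so the realized TBV variance equals σa² exactly.
  Without the rescaling the realized additive variance is roughly
  0.8 σa² whenever base frequencies are not all at one half, which
  would bias every recovery test for reasons unrelated to the
  estimators.

What the simulator does **not** emulate: linkage disequilibrium,
recombination maps or mutation (markers are independent); selection
across generations; genotype-by-environment interaction beyond site
main effects; genotyping error or missingness mechanisms; trial-design
artefacts (phenotypes are emitted already adjusted and standardized).
Passing recovery tests therefore demonstrates internal consistency of
the estimators under the assumed generative model, not robustness to
LD, selection, or spatial confounding in field data.

# Numerical choices and degenerate inputs

* Symmetry is enforced to 1e-10 at container construction; inverse
  oracles in the tests require max deviation < 1e-8 on fixtures up to
  ~500 entities.
* A singular blended G (e.g. blend weight 1 with more individuals than
  markers) is an error suggesting a smaller blend weight; a singular
  Γ̂ is an error pointing at PSD repair; a degenerate rescaling system
  (mean diagonal equal to overall mean in G) is an error rather than a
  guess.
* Matrix comparisons report `NA` correlations when an element class
  has zero variance (identity vs identity), instead of dividing by
  zero.
* UPGMA trees use `d_ij = (Γii + Γjj)/2 − Γij` clipped at zero,
  average linkage; ties fall to `hclust`'s deterministic merge order.
* Delimited-file numerics are written with 17 significant digits so a
  write–read–write cycle is byte-identical; delimiter detection
  accepts comma, tab, or whitespace and treats a mixture as an error.

# Known limitations

* Γ estimation assumes the pedigree's group assignments are correct
  and every metafounder has genotyped descendants; there is no
  model-based ancestry estimation.
* The EM-REML is a desk-scale estimator (single trait, three
  components); no AI-REML, no sampling variances of the estimates.
* Single trait, additive + family only: no dominance/epistasis
  decomposition, no multi-trait models, no spatial models.
* The one-known-parent 0.5/0.5 convention and the G05-vs-AΓ22 blending
  reference are field-standard but not uniquely determined; both are
  isolated behind single functions (`upgMatrix()`, `blendG()`) so
  alternatives can be swapped in.
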