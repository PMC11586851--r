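---
title: "Genomic evaluation of residual feed intake: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic evaluation of residual feed intake: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the science it implements: the
phenotype definitions, the statistical models, the numerical machinery, and
the design choices made where the underlying methodology leaves room. It
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## The trait

Residual feed intake (RFI) is the part of an animal's feed intake that its
energy sinks do not explain: the residual from regressing intake on
production, body size and growth. Negative RFI marks an efficient animal —
it eats less than its production predicts. Because the energy sinks are
regressed out, RFI is phenotypically independent of yield and body weight
in-sample, which is what makes it attractive as a selection target: intake
can be reduced without touching output traits.

The package derives RFI at two life stages:

* **Heifer RFI** — within each feed-conversion trial, average daily
  dry-matter intake (DMI, kg/d) is regressed on average daily gain (ADG,
  kg/d), metabolic body weight (MBW, kg^0.75) and age (d), with an
  intercept per trial. The residual is the heifer's RFI.
* **Cow RFI** — one regression across all lactating cows of test-period
  average DMI on trial (a pen-year-season factor), lactation, linear and
  quadratic days in milk (DIM) and age, average body weight (BW),
  energy-corrected milk (ECM) and BW change over the test. The residual is
  the cow's RFI. When a cow has records in two lactations, the
  first-lactation record is used.

ECM standardizes milk yield for energy content:
`ECM = 0.327·milk + 12.95·fat + 7.2·protein` (all kg). When only fat and
protein percentages are available, yields are `pct · milk / 100`.

### Daily-record screening

Cow records are daily measurements over DIM 100–240. Screening proceeds in
the order: (1) cows with fewer than 30 daily records of BW, DMI or ECM are
removed; (2) per cow and trait, an OLS of the trait on DIM supplies
residuals, and days beyond 3 SD from the mean residual are flagged; (3) a
flagged DMI day is *retained* when the DMI and milk-yield residuals exceed
3 SD in the same direction — a joint excursion of intake and yield is a
biological event (e.g., estrus, a heat wave) rather than a recording error;
(4) other flagged trait-days are removed per trait. Removal is per trait
and day, not whole-day, because the traits are recorded by independent
hardware. Cows whose residual SD is numerically zero get no removals — a
3-SD rule is meaningless without dispersion.

Two quantities need a definition the trait description does not fix:

* **MBW** is implemented as BW^0.75 (the standard metabolic scaling), with
  the exponent exposed as an argument. Heifers are weighed biweekly, so
  daily MBW is averaged over the fitted growth line rather than raw
  weighings.
* **BW change** is the per-cow OLS line of BW on DIM evaluated at the last
  minus first kept day (`delta_bw_mode = "fitted"`). Raw first/last records
  are a single-day-noise lottery; the fitted line uses every kept day. A
  `"raw"` mode is provided for comparison. Whether a published BW change
  should be read as kg-total or kg/d is often ambiguous; both readings are
  obtainable from the fitted slope.

## Relationship matrices

The pedigree numerator relationship matrix **A** is built by the tabular
method over a parents-first pedigree, with the base generation taken as
unrelated and non-inbred, and an ancestor-depth cutoff (default 10
generations). The test suite checks it against an independently written
recursive-kinship oracle and textbook values (parent–offspring 0.5,
full sibs 0.5, half sibs 0.25, full-sib-mating inbreeding 0.25).

The genomic matrix is VanRaden's first form,
`G = (M − 2P)(M − 2P)' / (2 Σ p_j (1 − p_j))`, after marker QC in the
stated order: sex chromosomes out, SNP call rate < 95% out (exactly 95%
stays), minor allele frequency < 5% out, then animals with call rate < 95%
out. Residual missing genotypes are mean-imputed as the expected dosage
2p_j; phasing-based imputation is deliberately out of scope — the
synthetic genotypes are complete, and mean imputation is the standard
fallback for the sparse residual missingness QC leaves behind.

Base-population allele frequencies are unobservable; the default is the
observed frequencies of the genotyped set, which makes the mean of
`diag(G)` close to 1, with an option to supply external frequencies. Raw G
is singular whenever animals are genotypically identical or markers are
few; `stabilize_G()` offers the two standard remedies — a diagonal shift
(default 0.01) or blending `0.95·G + 0.05·A` — and the mixed-model solver
refuses a numerically singular G rather than silently regularizing.

## Variance components: AI-REML

Variance components are estimated by average-information REML, written for
desk-scale problems (n up to a few thousand, dense algebra):

* **Univariate** animal model `y = Xb + Zu + e`, `u ~ N(0, A σ²_a)`,
  `e ~ N(0, I σ²_e)`. The covariance `V = ZAZ'σ²_a + Iσ²_e` is rotated by
  the eigendecomposition of `ZAZ'`, making V diagonal; each AI iteration is
  then O(n). RFI is fitted with only a mean, genetic effect and residual —
  the fixed effects were already removed when the RFI regression was fitted,
  and refitting them would be circular.
* **Bivariate** model with genetic covariance `A ⊗ K` (each animal
  contributes a 2×2 K block scaled by its relationship row) and residual
  `R ⊗ I`. Fixed effects are a mean per trait. Complete two-trait records
  use the same eigen-rotation (2×2-block-diagonal rotated covariance);
  animals missing one trait are handled by a generic dense-matrix AI-REML
  over observed records, intended for moderate n. A regression test asserts
  the two routes agree.

Numerical policy: AI (quasi-Newton) steps, projected onto the parameter
space (σ²_a may sit exactly at zero — flagged as a boundary estimate, not
an error), with step-halving onto an ascent path and an EM-style
gradient-scaled fallback when the AI direction fails; the restricted
log-likelihood is therefore non-decreasing by construction, and a test
asserts it. Convergence is a relative parameter change below 1e-8 (with a
log-likelihood stall criterion), capped at 200 iterations; non-convergence
is an error carrying the iteration trace. A K estimate that converges
outside the PSD cone is projected to the nearest PSD matrix and flagged.

SEs of derived parameters (h², genetic correlation) are available two
ways: the delta method on the inverse average-information matrix, and the
asymptotic-sampling estimator — 100,000 draws from
`MVN(estimates, AI⁻¹)`, the derived parameter evaluated per draw, the SD
of valid draws reported. Draws with negative variances or an out-of-range
correlation are rejected and counted; more than 50% rejections aborts,
since the normal approximation is then meaningless.

## Two-step genomic prediction

Prediction is deliberately two-step: variance components from the
pedigree-based fit are **frozen**, then the training mixed model equations
are solved on `G_TT` with `λ = σ²_e/σ²_a`. Non-phenotyped animals are
predicted indirectly, `û_P = G_PT G_TT⁻¹ û_T`, which a test proves
equivalent (to 1e-6) to solving one joint MME with the prediction
phenotypes absent.

The reliability of an indirect prediction starts from the covariance
`G_PT G_TT⁻¹ (G_TT σ²_a − C22 σ²_e) G_TT⁻¹ G_TP`, where C22 is the animal
block of the inverse MME coefficient matrix. That quadratic form is a
variance in trait units squared, not yet a reliability; it is normalized by
`g_ii σ²_a`, the animal's own genetic variance, giving the standard
squared-correlation definition rel = Var(û)/Var(u) ∈ [0, 1]. This
normalization is worth flagging prominently: omitting it leaves a quantity
on the wrong scale. Training reliabilities use the PEV form
`1 − C22_ii σ²_e / (g_ii σ²_a)`.

## Cohort analyses

Prediction animals are grouped by the closest male-ancestor generation
shared with the training population: shared sire (Group 1), grandsire only
(2), great-grandsire only (3), none (4). Only sire-line male ancestors are
compared by default — the grouping is defined through male ancestry, and
set semantics are used (any candidate ancestor matching any training
ancestor at that generation) — with an option to include maternal-line
males. Candidates with incomplete three-generation male ancestry are
excluded and reported rather than guessed.

Close relatives are training animals with genomic relationship ≥ 0.45
(inclusive), i.e. a first-degree relationship of 0.5 minus an estimation
allowance of 0.05. The reliability–relatives association is fitted as a
power curve `rel = a·(n + 1)^b`; the +1 offset keeps zero-relative animals
in the fit, and initialization is deterministic (log–log OLS start plus a
fixed exponent grid, best residual sum of squares wins), so the fit is
reproducible without a seed.

Efficiency re-ranking cross-tabs classify animals at both stages into
most/medium/least efficient (lower RFI = more efficient; the extreme
classes default to `floor(0.10·n)` animals, with explicit sizes available
because published extreme-class counts are often not exactly 10%). Ties
break by stable input order.

## The synthetic herd generator

Every analysis is exercised on simulated data, so the generator defines
the study conditions:

* **Pedigree**: founders plus equal-sized discrete generations; sexes
  balanced 50/50; a small sire set reused across dams (default one sire
  per ~20 offspring) to create the paternal half-sib families the cohort
  analyses need.
* **Genotypes**: founder allele frequencies uniform on the configured
  range (default 0.05–0.5), descent by Mendelian gene dropping. Allele
  frequencies are preserved in expectation, which the tests bound by
  binomial SEs.
* **Breeding values**: drawn from `N(0, A ⊗ K)` — the estimation model's
  own distribution — rather than from marker effects, so parameter
  recovery is a clean test of the REML machinery rather than of a genetic
  architecture assumption.
* **Cow records**: daily DMI/MY/fat%/protein%/BW over DIM 100–240 built
  from trial, lactation and day trends plus cow-level and i.i.d. day-level
  noise; intake is generated as a linear function of the cow's realized
  ECM, BW and BW change plus its genetic and environmental intake
  deviations, so the RFI regression has a correct target. Day-level noise
  is i.i.d. within cow: the analysis averages the period, so serial
  correlation is not identifiable from its model and simulating it would
  only rescale the cow-level variance. A configured fraction of days
  (default 2%, which keeps screening losses under the 5% the QC rule
  anticipates) is perturbed beyond 3 SD, including DMI–MY same-direction
  co-outliers that the screen must retain.
* **Heifer trials**: biweekly weighings over 70 d with linear growth
  (ADG mean 1.09, SD 0.24 kg/d), daily intake from ADG, MBW and age, ages
  within 206–437 d.
* **Variance structure**: cow RFI additive/residual variances default to
  1.16/1.55 kg² (h² = 0.43). The heifer RFI additive variance is not
  available as a published component; it is derived here from the heifer
  phenotypic SD of 0.86 kg/d with an assumed heifer heritability of 0.30
  (mid-range of published heifer RFI estimates): σ²_a ≈ 0.222,
  σ²_e ≈ 0.518. The default heifer–cow genetic correlation is 0.42. These
  are the generator's fixed study conditions, not tuning knobs.
* Trial-size distributions and the sire-family structure of any real herd
  are unknown; the defaults above are documented choices, not inferences.

What the generator does **not** emulate: feeding-event streams and milking
sessions (records start at the daily level), pregnancy, body-condition
dynamics, genotyping error, linkage disequilibrium beyond what gene
dropping induces, and selection (matings are random). Passing tests
therefore show the estimators are correct under the stated model, not that
the model captures every feature of commercial data.

## Problem sizes and reproducibility

Recovery studies fix one pedigree per study (three generations; 2,000
animals for the univariate study, 1,500 for the bivariate) and redraw
breeding values and residuals per replicate with seed = base + replicate
index, reusing the relationship eigendecomposition across replicates; 50
and 30 replicates give replicate-mean SEs near 0.006 and 0.02. The
bivariate study uses complete two-trait records and a diagonal residual
covariance — the two stages are measured years apart on different rations,
so a residual covariance has no design to identify it. All pipeline
randomness descends from a single integer seed through fixed per-stage
offsets; reruns are bit-identical, which the tests assert.

## Known limitations

* The cow RFI model omits energy sinks it has no data for (pregnancy,
  body-condition change, locomotion); RFI absorbs them into the residual.
* The dense missing-record bivariate path scales as O(m³) per iteration
  and is meant for hundreds, not tens of thousands, of records.
* Single-step evaluation (combining A and G in one H matrix), SNP-effect
  back-solving and deregressed proofs are out of scope.
* The reliability approximation is exact only insofar as C22 and G come
  from the same training system; the implementation errors out when the
  computed reliabilities leave [0, 1] beyond numerical tolerance, which is
  the symptom of mismatched inputs.
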