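---
title: "Genomic prediction with phenology-driven environmental covariates: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with phenology-driven environmental covariates: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecrrm)
```

`ecrrm` implements a complete two-stage genomic-prediction pipeline for
multi-environment wheat trials in which genotype-by-environment interaction
(GEI) is modelled through genotype-specific, phenology-driven environmental
covariates (ECs). This vignette explains the statistical models, the design
choices behind them, what the synthetic data generator does and does not
emulate, and the numerical behaviour of the REML engine.

## The data model

An *environment* is a (year, location, sowing window) triple. Sowing windows
follow the month-day cutoffs of the southern-hemisphere season: PRE before
May 15, OPT from May 15 to June 15 inclusive, POS after June 15. Trials are
nested in environments; elite trials are randomized complete block designs,
earlier stages resolvable alpha-lattices with incomplete blocks nested in
replicates. Environments with fewer than 25 distinct genotypes are dropped by
`filter_environments()` (strictly-less-than rule).

Marker quality control (`qc_markers()`) discards loci with minor allele
frequency below 5%, heterozygosity above 10% (wheat breeding lines are
near-fully inbred, so heterozygous calls mostly indicate genotyping error),
or more than 80% missing calls; remaining missing calls are imputed with the
per-locus mean dosage. Mean imputation is deterministic and fully adequate
for building a genomic relationship matrix; haplotype-phasing imputation is
out of scope. Filtering precedes imputation. The genomic relationship matrix
follows VanRaden: $K = ZZ^\top / (2\sum_j p_j(1-p_j))$ with $Z$ the
column-centred dosages.

## Stage 1: per-trial analysis

Per trial, genotype is fixed and the design terms are random: replicate for
RCBDs, replicate plus incomplete-block-within-replicate for alpha-lattices.
The genotype BLUEs and their standard errors provide the stage-2 response
and weights ($w_i = 1/\mathrm{SE}_i^2$). A companion fit with genotype random
gives the genotypic variance and BLUP prediction-error variances (PEV) for
Cullis' heritability,

$$H^2 = 1 - \frac{\bar v_\Delta^{\mathrm{BLUP}}}{2\hat\sigma_g^2},$$

with $\bar v_\Delta^{\mathrm{BLUP}}$ the mean PEV of BLUP differences over
genotype pairs, computed exactly from the full PEV matrix
($2(m\,\mathrm{tr}V - \mathbf 1^\top V\mathbf 1)/(m(m-1))$ for $m$
genotypes); above 2000 pairs a deterministic evenly spaced subsample of pairs
is averaged instead. When $\hat\sigma_g^2$ sits on its boundary the ratio is
undefined and $H^2$ is reported as 0 with a flag. In the balanced RCBD case
this expression collapses to the familiar
$\sigma_g^2/(\sigma_g^2+\sigma_\epsilon^2/r)$, which the tests verify.

## Phenology windows and the 45 ECs

Anthesis is proxied by heading date; the offset is the exported constant
`HEADING_TO_ANTHESIS` (0 days) so users with true anthesis records can shift
it. For each genotype in each trial the season is tiled into three closed
day-offset windows from sowing: vegetative $V=[0, h-21]$, reproductive
$R=[h-20, h+10]$ (the 31-day critical period around heading), and grain
filling $G=[h+11, \mathrm{harvest}]$. Fifteen daily-weather summaries are
computed per window — cumulative precipitation and evapotranspiration;
mean cloud cover, Tmax, Tmean, Tmin, relative humidity, solar radiation,
thermal amplitude, wind speed and photothermal quotient; and counts of frost
days and of days beyond the 25/15/4 degree thresholds — giving 45 named
columns (`VPP` ... `GWS`). Conventions the catalogue leaves open were fixed
as follows:

* frost day: Tmin at or below 0 C (meteorological frost);
* evapotranspiration aggregates by *sum* (a cumulative water flux, like
  precipitation), all other continuous variables by mean;
* photothermal quotient: mean of the daily ratios SR/Tmean, excluding days
  with Tmean at or below 0 C to avoid division blow-ups;
* temperature-count thresholds use strict inequalities (above 25; below
  15/4), frost uses at-or-below.

`compute_ec()` is the direct, day-by-day reference implementation;
`build_ec_matrix()` computes identical quantities through per-environment
cumulative arrays (O(1) per window) and the tests cross-check the two paths.

Missing heading dates are predicted (`predict_heading()`) by a mixed model
with independent random effects for genotype, year, location,
genotype-by-year and genotype-by-location, fitted per maturity class when a
class column is available and pooled otherwise. This is an ordinary IID
mixed model, so it is fitted with `lme4`; the package's own REML engine is
reserved for the structured-covariance models below. Missing cells receive
$\hat\mu+\hat g+\hat a+\hat l+\widehat{ga}+\widehat{gl}$ with absent levels
contributing zero; observed cells are never altered.

## EC selection by PLS and VIP

Univariate-response PLS is implemented directly as NIPALS (weights
$w_a \propto X_a^\top y$, scores, loadings, deflation), with the component
count chosen by 10-fold cross-validated RMSEP capped at 10. VIP scores follow
the standard projection-importance form

$$\mathrm{VIP}_j = \sqrt{p\,\sum_a SSY_a (w_{ja}/\lVert w_a\rVert)^2 \,/\,
\sum_a SSY_a},$$

so the mean squared VIP is exactly 1. The top seven ECs are selected; ties
at the boundary break lexicographically and are messaged. A
leave-one-environment-out re-selection (`loeo_select()`) reports ECs that
enter any fold's top set but not the full-data one — covariates whose
relevance a single environment can mask.

The PLS response in the pipeline is the raw genotype-by-trial BLUE vector.
We considered centring the response per environment so that selection
targets GEI-relevant variation only, and the option remains a one-line
pre-processing step; it is not the default because environment-mean yield is
itself largely weather-driven, and centring removes exactly the EC-yield
association that makes selection informative. With centred responses,
random-slope GEI contributes no *linear* EC-yield association at the
population level (slopes have mean zero), so PLS would have almost nothing
to work with.

## The REML engine

All structured models are fitted by an average-information (AI) REML engine
(`reml_fit()`) that represents every random term at the level of the data
rows: a term contributes an $n\times n$ covariance block to
$V=\sum_k\Gamma_k(\theta_k)+\sigma^2_\epsilon\,\mathrm{diag}(1/w)$.
Four structures cover all models here:

* `rt_iid()` — scaled identity over a factor;
* `rt_known()` — $\sigma^2 K$ with $K$ known (the GRM);
* `rt_fa()` — genotype-by-environment effects with covariance
  $\Sigma_E \otimes K$, $\Sigma_E=\Lambda\Lambda^\top(+\Psi)$ factor-analytic
  of rank $q$; the default is the reduced-rank form ($\Psi=0$), and a
  specific-variances mode is available. Identifiability is imposed by
  upper-triangular zeros in $\Lambda$;
* `rt_rrm()` — per-genotype random intercept and slopes with coefficient
  covariance $\Omega$ and genotype covariance $K$ combined as a matrix
  normal; cell covariance $(\Phi\,\Omega\,\Phi^\top)\circ K_{\mathrm{cells}}$.
  All genetic scale lives in $\Omega$ (no redundant $\sigma_g^2$), which
  makes the parameterisation identifiable.

Scores and AI terms never materialise $n\times n$ derivative matrices: each
structure reduces $\mathrm{tr}(P\,\partial\Gamma)$ and $\partial\Gamma\,Py$
to small matrix products against shared intermediates (block sums of $P$,
$P\circ K_{\mathrm{cells}}$, and $K_{\mathrm{cells}}$ products), so an
iteration costs a Cholesky plus a handful of $O(n^2)$ operations.

Numerical policy: proposed AI updates are step-halved until the updated $V$
is positive definite and the restricted likelihood does not decrease, so the
accepted likelihood sequence is monotone; when the full step already pays,
the line search extends by doubling (AI steps are systematically short along
weakly identified valleys); non-negative scale parameters pinned at the
floor ($10^{-10}\times$ the phenotypic variance) with an outward score are
frozen out of the update; $\Omega$ is kept positive semi-definite by
eigenvalue projection, and $\Sigma_E$ is PSD by construction. Convergence is
declared when the relative likelihood change falls below `tol_l` on a
(near-)full step, when parameters stop moving, or when the likelihood stays
flat over three consecutive damped steps (a boundary or ridge direction).
Starting values partition the OLS residual variance equally across terms;
FA loadings start from the leading eigenvectors of a crude environment
covariance of the working residuals. Non-PSD known matrices are bent by
flooring eigenvalues at $10^{-6}\times$ the mean diagonal, with a warning.

## Stage 2: the four models

All stage-2 models act on the BLUE table with residual
$\sigma^2_\epsilon\,\mathrm{diag}(\mathrm{SE}_i^2)$. By default the residual
scale is *fixed at 1* (strict known-weights mode). The alternative — a free
scale initialised at 1 — is available as `free_resid = TRUE`, but with
genotype-by-environment cells that mostly contain a single trial the free
scale is barely identified against the IID GEI variance and REML crawls
along a flat valley to a boundary; fixing the scale makes every diagonal
term identified and convergence fast. This was adopted as the default after
observing exactly that behaviour.

* **Truth model**: fixed environment; random genotype ($K$), GEI with
  reduced-rank FA(2) across environments Kronecker $K$, trial within
  environment, genotype-by-trial. The per-cell conditional genotypic value
  (genotype + GEI + genotype-by-trial BLUPs) from the *full* data is the
  reference against which all cross-validated predictions are scored; it is
  computed once and reused by every scheme.
* **GBLUP**: fixed environment; random genotype ($K$), IID GEI, trial.
* **FA model**: GBLUP with the IID GEI replaced by the FA(2) Kronecker
  structure.
* **RRM**: fixed overall mean plus global EC regressions; random genotype
  intercept and slopes ($\Omega \otimes K$), IID GEI and trial terms for
  comparability. EC columns are centred and unit-scaled with constants
  estimated from the fitted (training) rows only and stored in the model, so
  cross-validation never leaks held-out EC scales. There is no fixed
  environment effect: environments enter only through the ECs, which is what
  allows prediction into environments with no yield data.

`forward_stepwise()` grows the RRM's EC set to at most five covariates,
keeping at each size the candidate with the best median cross-validated
ability (CV1 folds by default; the full score table allows re-ranking under
other schemes); non-converging combinations are recorded and skipped.

## Cross-validation and scoring

`make_folds()` builds exact partitions: CV1 masks whole genotypes (five
folds mask exactly 20% each), CV2 masks genotype-by-environment cells, CV0
masks one environment at a time. For each plan the models are refitted on
the training rows and the masked cells predicted: GBLUP predicts the
genotype BLUP; the FA model adds the cell's GEI BLUP (borrowed through the
estimated environment covariance); the RRM predicts fixed EC part +
intercept + slopes times the cell's own ECs. Under CV0 the FA model is not
admissible (no correlation structure exists for an unseen environment);
GBLUP predicts the environment-free genotype value and the RRM uses
`predict_new_environment()` with the held-out environment's weather- and
phenology-derived ECs, setting the unknowable environment mean and IID GEI
to zero (within-environment ranking is unaffected).

Predictive ability is the Pearson correlation between predictions and truth
values within trial-within-environment groups (GBLUP/RRM) or environment
groups (FA, with group centring applied before pooling). Groups with fewer
than three pairs or zero variance are skipped with a note. Non-converged
training refits are logged and scored as missing, never zero. Each training
refit warm-starts from a single full-data fit of the same model — starting
values only shorten the optimizer's path; the REML solution still depends
only on the training rows — and is capped at 100 AI iterations.

`baseline_deviation()` tabulates each model's per-unit deviation from GBLUP
and the count of units where it wins, and `characterize()` reports the
plot-level variance decomposition (all design and interaction terms random,
fitted with `lme4`) together with k-means year groups (k = 2, 25 restarts,
seeded) on year-mean yields.

## The synthetic breeding program

The generator exists so the whole pipeline is testable end to end with a
known truth. Its generative yield model *is* the fitted reaction norm read
forward: plot yield = design terms (year, location, sowing window,
environment interaction, trial, replicate, block) + fixed EC regression +
genotype intercept + genotype slopes times standardised ECs + IID GEI +
plot error, with coefficients drawn matrix-normal with genotype covariance
$K$ (from the simulated markers) and diagonal coefficient covariance
$\Omega^*$. Parameter recovery is therefore a well-posed question. Key
choices, all fixed as the package's study conditions:

* **Scale**: ~300 genotypes, 1000 loci, 5 years x 2 locations x 2 sowing
  windows (20 environments), 50% turnover, three trial stages (preliminary /
  advanced / elite as age within the program), about 1000 genotype-trial
  cells and 2700 plots. These sizes keep a full CV sweep on one CPU in
  minutes while leaving all structures identifiable.
* **Markers**: inbred lines (F = 0.95) derived from biparental crosses among
  25 founders. Inbreeding keeps heterozygosity far below the 10% QC
  threshold (outbred HWE genotypes would be *discarded* by the wheat QC
  rules), and the founder structure creates the family relatedness that
  GBLUP exploits; unrelated lines would make genomic borrowing of slopes
  impossible and correspond to no real breeding program.
* **Variance shares** (plot level): year .22, location .04, sowing .02,
  environment interaction .12, fixed EC regression .20, trial .06, replicate
  .012, block .013, genotype intercept .012, slopes .102 (three active ECs,
  each 30% of the genetic variance), IID GEI .036, residual .165. Year
  remains the single largest component, per-trial heritability comes out
  near 0.8, and a large fixed-EC share reflects that environment quality is
  largely weather-driven — which is also what makes PLS selection
  informative. The genetic architecture is strongly GEI-driven (intercept
  10% of genetic variance): this is the regime in which reaction-norm
  models are the tool of interest, and the only reading of "slope variance
  30% of genetic variance with three active ECs" under which an EC-aware
  model can beat GBLUP by the margins the method is known for (the ratio of
  abilities is capped at $\sqrt{1/0.7}\approx 1.19$ if the three slopes
  jointly carry only 30%).
* **Misspecification switch** (`fa_gei = TRUE`): a variant world in which
  the chosen ECs under-describe the GEI — two thirds of the slope share, two thirds
  of the IID GEI and 4% of plot variance become rank-2 factor-style GEI
  unexplained by any EC. This is the condition under which the FA model's
  free covariance should overtake the EC-restricted reaction norm in CV2.
* **Weather**: seasonal harmonic daily mean temperature (southern
  hemisphere; coldest mid-July) with year/location shifts and AR(1) noise;
  non-negative half-range noise keeps Tmin <= Tmean <= Tmax identically;
  wet-day gamma precipitation; radiation follows the inverse seasonal cycle
  damped on wet days; Hargreaves-style evapotranspiration (increasing in
  radiation and temperature). What it does *not* emulate: spatial field
  trends, weather persistence beyond AR(1), soil and management, or any
  nonlinear crop-growth response — passing tests say the pipeline recovers
  the truth of a *linear* reaction-norm world, not that real wheat GEI is
  linear in these 45 ECs.
* **Phenology**: heading = trial mean + genotype effect (MVN with GRM
  covariance) + genotype-by-year + genotype-by-location + noise, rounded to
  days and clipped into the window that keeps the three phases valid;
  harvest is a fixed per-trial anchor. A small sowing-window shift (+-4
  days) on the trial mean is deliberately *outside* the heading model's
  vocabulary, so heading prediction is good but not artificially perfect;
  the study regime of near-perfect heading predictability corresponds to the
  high-heritability configuration used in the acceptance checks. Masking is
  uniform at random (30% of genotype-trial records) by default; a by-trial
  mode reproduces the breeding-record pattern of whole trials with 20-90%
  unscored.
* **Determinism**: every generator draws from its own stream, derived from
  the master seed by a fixed offset, so adding a generator never perturbs
  the others; the global RNG state is restored afterwards.

## Known limitations

* The engine is dense: fits are comfortable to a few thousand cells, which
  covers the desk-scale program; very large national datasets would need
  sparse or reduced-rank absorption that is out of scope here.
* FA prediction-error variances are not implemented (BLUPs only); Cullis
  heritability is therefore defined through IID genotype terms, as in
  stage 1.
* The FA likelihood has the usual weak identifiability between a genotype
  main effect and a common-loading direction; the engine converges on the
  flat ridge and reports the identified total genetic covariance faithfully,
  but individual components along the ridge should not be over-interpreted.
* Heading-date prediction uses independent genotype effects; borrowing
  through the GRM could only help unobserved genotypes and is left out to
  stay within the stated heading model.
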