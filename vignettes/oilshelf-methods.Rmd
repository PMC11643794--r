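---
title: "Methods: ASCA and PLS calibration for oil shelf-life NIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ASCA and PLS calibration for oil shelf-life NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`oilshelf` analyzes NIR transmission spectra of an edible oil stored under a
balanced time × temperature × packaging-material factorial. This vignette
documents the statistical models, the synthetic-data generator that stands in
for the (unpublished) instrument data, the numerical choices, and the
limitations — the way a user deciding whether to trust the package should
read it.

```{r setup}
library(oilshelf)
```

## 1. The decomposition model

Let $\mathbf{X}$ be the $n \times p$ matrix of preprocessed spectra, with one
row per measurement and one column per retained wavenumber. The
fixed-effects model is

$$\mathbf{X} = \mathbf{1}\boldsymbol\mu^\top + \mathbf{X}_{time} +
\mathbf{X}_{temp} + \mathbf{X}_{mat} + \mathbf{X}_{time\times temp} +
\mathbf{X}_{temp\times mat} + \mathbf{X}_{mat\times time} + \mathbf{E}$$

with $\boldsymbol\mu$ the grand-mean spectrum. Main-effect rows are level
means minus the grand mean; interaction rows are cell means minus both level
means plus the grand mean. Two assumptions matter:

* **Balance.** The estimators above are unbiased and the seven terms are
  mutually orthogonal *only* for a complete crossing with equal cell counts.
  `asca_decompose()` therefore refuses unbalanced designs outright rather
  than silently producing biased effect matrices. Unbalanced ASCA variants
  (ASCA+, LiMM-PCA) are out of scope.
* **Fixed effects.** Storage time, temperature and material are treated as
  chosen conditions, not random draws; replicate vials land in the residual.

Orthogonality makes the sums of squares additive, so each term can be
reported as a percentage of the total centered sum of squares ("effect %").
Each effect matrix is then decomposed by SVD (simultaneous component
analysis). Since an effect matrix has at most (levels − 1) distinct
independent rows, its rank is bounded by the design degrees of freedom: a
two-level temperature factor always yields exactly one component carrying
100% of that effect's variability, a nine-level time factor at most eight,
and a four-level material factor at most three.

**Component retention.** Components are retained at numerical rank, with
tolerance $10^{-10}$ times the leading singular value. On any dataset with
measurement noise this equals the design rank; we deliberately do not apply
a variance cut-off, because the structural component counts are themselves a
diagnostic (a lower-than-expected count signals a degenerate design).

**Spider (augmented) scores.** Scores of the effect matrix alone collapse
all replicates of a level onto its centroid. Projecting the effect-plus-
residual rows on the effect loadings instead preserves the within-level
dispersion, which is what makes the score plots readable as cluster plots.

## 2. The permutation test

Each term's significance is assessed against an empirical null obtained by
permutation, with $p = \max(\text{count}, 1)/B$ under a conservative `>=`
tie rule, so the smallest attainable p-value is $1/B$ (0.0002 at the default
$B = 5000$).

The permutation scheme was a genuinely open design decision, and the naive
choice fails. Shuffling the raw rows freely makes the null distribution of
one term absorb the variance of *all* terms: a term whose observed share of
the total is below $df/(n-1)$ can then never be significant, regardless of
how real it is. The package therefore uses:

* **Main effects — exact restricted permutation.** The tested factor's
  labels are shuffled only within the cells of the other two factors. Rows
  within such a cell are exchangeable under the null, the other factors'
  variance stays perfectly aligned (in a balanced design it cancels exactly
  from the permuted group means), and the test is exact for iid residuals.
  The suite verifies calibration empirically: on null data the rejection
  rate at the 5% level stays within binomial error of 5%.
* **Interactions — reduced-model free permutation.** No exact restricted
  scheme exists for an interaction. The test statistic is computed on the
  reduced-model matrix (the tested effect plus the residual, i.e. the data
  with all other terms projected out), with the joint pair of factor labels
  permuted freely — permutation of residuals under the reduced model. It is
  approximate; in our checks it is mildly liberal when the other terms
  consume a large fraction of the degrees of freedom, which is worth
  remembering for borderline interaction p-values.

Replicate vials enter the model as separate rows (the generator's
`n_replicates` lets either convention be tested); averaging duplicates first
would halve $n$ and remove the within-cell exchangeable unit that the
restricted permutation relies on.

## 3. Preprocessing

The fixed order is mask → baseline → center, recorded in the result's
provenance.

* **Saturation masking** removes every channel whose *mean* absorbance
  exceeds 2.5 AU, the linearity limit of a transmission measurement at a
  4 mm path. Masking on the mean spectrum (not per row) keeps all rows on a
  common grid. On the default synthetic data this removes exactly the
  4000–4440 and 5770–5875 cm⁻¹ regions.
* **Baseline correction** subtracts each spectrum's least-squares straight
  line in wavenumber. A first-degree polynomial is the simplest model of the
  offset-plus-tilt that residual turbidity adds; by construction the
  operation is invariant to adding any straight line, which the tests
  exploit. Offset-only correction would leave tilt in; higher orders would
  start eating real band structure.
* **Mean centering** subtracts the grand-mean spectrum and stores it as
  $\boldsymbol\mu$, making the reconstruction `centered + μ` exact.

Derivatives, SNV and MSC are deliberately absent: the decomposition model is
fit on minimally processed spectra to keep loadings directly interpretable
as absorbance differences.

## 4. The synthetic-data generator

No shelf-life NIR dataset of this kind is public, so the generator is a
first-class, tested module that emulates the experiment's three layers. Its
defaults encode the reference storage trial: nine sampling times over 270
days, 10 °C (dark) vs 25 °C (diffused light), four vial materials
(polypropylene PP, clear glass CG, amber glass AG, foil-wrapped amber glass
AGA), two replicate vials — 144 measurements.

**Chemistry.** The peroxide value follows rise-then-decay kinetics

$$pv(t) = pv_0 + A\,r\,(1 - e^{-g r t})\,e^{-d r t}, \qquad
r = \text{temp\_factor} \times \text{material\_factor},$$

capturing the classic primary-oxidation course: hydroperoxides accumulate,
then decompose into secondary products. K232 co-moves with PV (dienes are
primary products); K268 rises monotonically
($k268_0 + c\,r\,(1-e^{-grt})$, secondary products don't come back).
Defaults ($pv_0 = 3$, $A = 60$, $g = 0.012\,\text{d}^{-1}$,
$d = 0.002\,\text{d}^{-1}$, temp factors 0.4/1.0, material factors
1/0.6/0.45/0.15 for PP/CG/AG/AGA, $k232_0 = 4.26$, $k268_0 = 1.25$) were
chosen once so that the worst case (PP at 25 °C) peaks near 40 meq O₂/kg
around 150 days while foil-wrapped amber glass stays near baseline, and PP
at 10 °C crosses the 15 meq O₂/kg quality limit only at the end of storage —
the qualitative picture reported for hempseed oil. Gaussian measurement
noise (sd 0.5 meq O₂/kg for PV, scaled down for the extinctions) is
truncated at zero.

**Spectra.** Each spectrum is a per-sample linear baseline (random offset
and tilt, emulating turbidity), plus 16 Gaussian bands at the main NIR
absorptions of a polyunsaturated oil (C–H/C=C combinations near
4600–4700 cm⁻¹, C=O overtone at 5180, methylenic/methylic C–H overtones at
5678–5963, combinations at 7070–7260, second overtones at 8260–8580 cm⁻¹),
plus iid channel noise (sd 0.002 AU). Band amplitudes respond linearly to
the sample's oxidation state, encoded as the standardized (PV, K268) pair —
unsaturation bands lose intensity, carbonyl-related bands gain. Channels
inside the saturation regions are floored at 2.8 AU, reproducing a
flat-topped saturated detector. The grid is 4000–9000 cm⁻¹ at 8 cm⁻¹, a
plausible FT-NIR resolution.

**What the generator does *not* emulate** — and hence what green tests do
not prove about real data: multiplicative scatter, temperature-dependent
band shifts, nonlinear detector response below saturation, antioxidant
(tocopherol) depletion kinetics, drift between measurement sessions, and
any deviation from the exactly linear spectra–chemistry link. The linear
link is a feature for testing (PLS recovery is provable) but makes
calibration easier than reality; RPDs on synthetic data are upper bounds.

## 5. PLS calibration

`fit_pls()` is single-response NIPALS (PLS1): weights are the normalized
covariance $\mathbf{X}^\top \mathbf{y}$ of the deflated data, scores are
orthogonal by construction, and the one-component regression vector is
proportional to $\mathbf{X}^\top \mathbf{y}$ — both facts are verified
against independent oracles (the normal equations at full rank, the
covariance identity at one component).

Validation is leave-one-material-group-out: all rows of one packaging
material are held out together, the model is refit — centering recomputed on
the training fold only, to avoid leakage — and the held-out rows are
predicted. Holding out a whole material stresses extrapolation across the
oxygen/light regimes rather than interpolation between replicates. Reported
metrics: RMSEC, RMSECV, R²cal, R²cv, bias (mean signed cross-validation
error), and RPD = sd(reference)/RMSECV, with the standard deviation taken
over all reference values. Model size is the RMSECV minimum, ties broken to
the smaller size; RMSEC is non-increasing in size (a NIPALS invariant the
suite asserts), while RMSECV follows the usual U-shape on the default data.

## 6. Numerical choices and degenerate inputs

* Rank tolerance $10^{-10} \times$ leading singular value (SCA retention);
  reconstruction and SSQ additivity are asserted at $10^{-8}$ relative.
* Permutation ties count against the hypothesis (`>=`), and the p-value
  floor is $1/B$.
* A constant data matrix yields $p = 1$ (every permutation ties the observed
  zero); a zero effect matrix is a hard error in `sca()`; a constant
  response is reported as a "no variance" ANOVA result; a design without
  replication has no residual degrees of freedom and errors.
* `simulate_chemistry()` truncates noisy markers at zero; standardizing a
  zero-variance marker yields zeros rather than NaN.
* All simulation and permutation randomness flows through explicit seeds
  with the session RNG state restored afterwards, so identical inputs give
  bit-identical outputs.
* The specific extinction coefficient is rounded once, at output, to two
  decimals, matching how such values are conventionally reported.

## 7. Problem sizes used by the test suite

The suite exercises the default 144 × 626 dataset for the structural and
floor checks (B = 5000 for the floor, about twenty seconds for all six
effects), 150 null replicates at B = 200 on a 16-row design for the
calibration check, and small constructed designs for the hand-verifiable
identities (2 × 2 cell means, 4:1 variance splits, F = t²). These sizes were
chosen to keep the full suite under a minute while leaving every assertion
at its stated tolerance.

## 8. Known limitations

* Balanced complete designs only; no mixed or random effects.
* The interaction permutation test is approximate (Section 2).
* PLS1 only — one response at a time; no variable selection, no external
  test-set validation, no model persistence.
* CSV is the only spectra format; instrument-native formats must be
  converted upstream.
* The three-way ANOVA fits mains plus two-way interactions (the same terms
  as the spectral model); the three-way interaction is pooled into the
  residual.
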