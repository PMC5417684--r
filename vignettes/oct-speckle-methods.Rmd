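---
title: "Modelling corneal OCT speckle and its influence on noncontact tonometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling corneal OCT speckle and its influence on noncontact tonometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octspeckle)
```

## The problem

Noncontact (air-puff) tonometry estimates intraocular pressure (IOP) from
the deformation of the cornea, so the reading is confounded by corneal
structure. The macro-structure — central corneal thickness (CCT), corneal
radius (CR) and the other biometric parameters — is routinely measured and
partially corrected for. The micro-structure (the organisation of stromal
collagen and keratocytes) also modulates corneal stiffness but cannot be
measured directly in vivo.

OCT speckle offers an indirect route. Speckle is the granular interference
pattern of coherent imaging; its intensity statistics inside a homogeneous
tissue region carry information about the sub-resolution organisation of
scatterers. This package implements a complete, reproducible pipeline for
that analysis: extract a stromal region of interest (ROI) from a corneal
B-scan, model its linear-intensity histogram with the three-parameter
Generalised Gamma (GG) distribution fitted by maximum likelihood, and relate
the fitted parameters, together with biometry and age, to IOP at the cohort
level. A synthetic B-scan phantom and a synthetic cohort generator make
every stage testable without any clinical data.

## The speckle model

Pixel intensities $x > 0$ in the stromal ROI are modelled as i.i.d. draws
from the Generalised Gamma (Stacy) distribution

$$
f_{GG}(x; a, v, p) \;=\;
  \frac{p\, x^{pv-1} \exp\!\left\{-\left(x/a\right)^{p}\right\}}
       {a^{pv}\,\Gamma(v)},
$$

with scale $a > 0$ (tracking mean backscattered power, in the instrument's
arbitrary intensity units) and shapes $v, p > 0$. The family contains the
exponential ($v = p = 1$), gamma ($p = 1$) and Weibull ($v = 1$) laws. The
shape ratio $v/p$ — the *scatter density* — has been linked to the packing
density of sub-resolution scatterers and is exposed as
`scatter_density()`. If $G \sim \mathrm{Gamma}(v, 1)$ then
$a\,G^{1/p} \sim GG(a, v, p)$; this exact transform is the contract behind
`rgg()` and `qgg()`, and `pgg()` is the regularised incomplete gamma
function at $(x/a)^p$.

The printed form of the GG density in parts of the applied literature
carries a positive exponent $\exp\{(x/a)^p\}$, which is not normalisable;
the package implements the standard (negative-exponent) density throughout.
Negative powers $p < 0$ exist in the Stacy family but are excluded here:
corneal speckle estimates are firmly in the $p \in [2, 3.5]$ range and a
positive-only parameterisation permits unconstrained log-scale
optimisation.

### Maximum-likelihood fitting

`fit_gg()` maximises the log-likelihood over $(\log a, \log v, \log p)$
with BFGS and the analytic gradient. The GG likelihood surface is
notoriously flat along a $v$–$p$ ridge, so the optimiser is started from
method-of-moments values computed on $x^{p_0}$ (gamma distributed when
$p_0$ is the true power) for each $p_0 \in \{0.5, 1, 2, 3\}$, and the best
local optimum is kept. Convergence requires a per-observation gradient norm
below $10^{-8}$ (with a hard failure above $10^{-3}$). Standard errors come
from the observed information in log-parameters, delta-transformed.

Numerical contracts, tested:

* the density integrates to one (quadrature, $10^{-6}$) across random
  parameter triplets;
* fits are scale equivariant — fitting $cX$ multiplies $\hat a$ by $c$ and
  leaves $\hat v, \hat p$ unchanged;
* at $n = 10^5$ samples from corneal-like parameters
  $(a, v, p) = (0.287, 0.437, 2.80)$ each parameter is recovered within 5%;
* the fitted likelihood dominates both the generating parameters and a
  $30^3$ brute-force grid.

Exact zeros (possible after quantisation of stored images) lie outside the
GG support and are dropped, with the count reported, never jittered. A
minimum of 500 positive samples is required: below that the two shape
parameters are too poorly identified to report. Fitting always uses the raw
samples; the 20-bin histogram of `intensity_histogram()` is presentation
only.

## The B-scan phantom

`simulate_bscan()` renders the geometry the segmentation stage assumes: a
circular anterior arc (radius `anterior_radius_mm`, default 7.75 mm) with
apex at `apex_column`, a bright epithelium band, a stroma of
`cct_um - epithelium_um` filled with GG speckle, and a posterior boundary
axially parallel to the anterior one (constant per-column stromal
thickness, which keeps the construction identity
`endothelium_row - bowman_row = round((cct - epithelium)/axial_pixel)`
exact). Background pixels are Rayleigh noise (scale 0.02 a.u.), the
epithelium is a gamma-distributed band (mean 0.55, SD 0.12 a.u., clearly
brighter than the stroma whose mean at the default GG parameters is about
0.16 a.u.), so all three boundaries carry detectable axial gradients. The
defaults — 1024 A-scans of 848 pixels, 250×450-pixel ROI — mirror a typical
spectral-domain corneal acquisition.

The default pixel pitch is a deliberate design choice. With 1.5 µm axial ×
3 µm lateral pixels, (i) a 250-row ROI of pure stroma fits below Bowman's
layer at a normal CCT across the full 450-column aperture, and (ii) the
quartic term by which a circular arc departs from a parabola stays below
one pixel at the lateral image edges, so the second-order robust polynomial
used to smooth boundary curves can track the truth to sub-pixel accuracy.
Speckle is modelled statistically — there is no wave-optics simulation, no
lateral speckle correlation, no depth-dependent attenuation; what passing
tests show is that the *pipeline* is correct under the stated statistical
model, not that the model captures every property of real corneal scans.

## Segmentation, apex and ROI

Per column, the intensity profile is smoothed axially with a Gaussian
kernel ($\sigma = 2$ px) and differentiated with a centred first
difference. Boundary candidates are local maxima of the gradient magnitude
above a threshold set *relative* to the column's maximum magnitude
(default 0.2), which makes segmentation exactly invariant to adding a
constant to all intensities; a featureless image has no candidates at all
and fails loudly. The epithelium is the first candidate from the top, the
endothelium the last, and Bowman's layer the strongest gradient extremum
40–80 µm below the epithelium (the epithelium–stroma transition is a
brightness *drop*, hence the magnitude criterion). Raw per-column
detections are smoothed across columns by an order-2 Tukey-bisquare IWLS
polynomial fit, which also rejects occasional speckle-induced outliers.

The apex is the zero crossing of the first difference of the smoothed
epithelium curve (its axial minimum), with ties broken toward the span
centre; a monotone curve raises an apex-not-found error. The ROI is
centred laterally on the apex and anchored `offset_um` (default 60 µm)
below Bowman's layer *at the apex*: the offset must exceed the sag of
Bowman's layer across the ROI half-width (about 29 µm at the default
geometry), and the placement is verified against the smoothed boundaries at
*every* ROI column, erring rather than silently including epithelium or
aqueous. The anchor depth is a package choice — an acquisition protocol
only fixes the ROI size — and is configurable. An optional saturation mask
(exclude pixels above a percentile) guards against specular reflection in
real scans; it is off by default because phantoms have none.

## The synthetic cohort

`simulate_cohort()` draws the nine subject-level variables (CCT, CR, AL,
ACD, WTW, age, $GG_a$, $GG_v$, $GG_p$) independently from normal laws
truncated to physiological min–max ranges, then links pressure to structure
through

$$
IOP_{nc} = 0.0248\cdot CCT - 16.534\cdot GG_a + 6.853 + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),
$$

with $\sigma = 1.13$ mmHg by default. That noise level is derived, not
tuned: the structural variance contributed by the model is
$0.0248^2 \cdot 27.89^2 + 16.534^2 \cdot 0.035^2 \approx 0.81$ mmHg², and
$\sigma^2 = 0.81\,(1 - R^2)/R^2$ at $R^2 = 0.39$ gives
$\sigma \approx 1.13$. Tests confirm the realised large-sample $R^2$ is
0.39 within Monte-Carlo error.

Truncation changes the moments of a normal draw, so the pre-truncation mean
and SD are calibrated (a cached Nelder–Mead solve on the closed-form
truncated-normal moments, constrained to keep at least 5% of the mass in
range so rejection sampling stays efficient) such that the *truncated* law
reproduces the requested moments. One variable cannot comply: no normal
truncated to [22, 78] years can reach an SD of 19.3 years (the uniform
limit on that range is $56/\sqrt{12} \approx 16.2$), so the age calibration
weights the mean heavily — every variable's mean is honoured and the age SD
lands near the attainable ceiling. Real age distributions in such cohorts
are closer to bimodal recruitment than to a truncated normal; this is a
known limitation of the generator, not of the analysis.

The corrected pressure is emulated as
$IOP_c = IOP_{nc} - 0.0248\,(CCT - 550\,\mu m)$ — a linear stand-in for the
tonometer's proprietary pachymetry correction tables, with the slope
defaulting to the structural CCT coefficient so that the synthetic $IOP_c$
carries no residual CCT dependence, reproducing the qualitative behaviour
of a CCT-corrected reading. Variables are independent apart from the
structural link: the generator deliberately omits the weak cross-
correlations (age–CCT, CCT–$v/p$, GG–IOP beyond $GG_a$) that real cohorts
show, so cohort-level tests validate the *inference machinery*, not
epidemiology. In particular, the group-level GG-density contrast is null by
construction in synthetic cohorts.

## Cohort statistics

* **Simple regressions** (`simple_regression()`): OLS with $R^2$, the
  slope's F-test p-value and a 95% pointwise confidence band of the mean
  response — the content of the standard scatter-plus-band figure.
* **Forward stepwise** (`forward_stepwise()`): greedy entry by smallest
  partial-F p-value, entry threshold 0.05 (the conventional default; the
  greedy loop itself does not dictate one), ties broken by larger $R^2$
  then name order, collinear additions skipped with a warning. With no
  noise the procedure returns the generating coefficients exactly; across
  200 noisy 56-subject cohorts the modal selected set is {CCT, $GG_a$}.
* **Sample size** (`sample_size()`):
  $n = \sigma^2 (t_{1-\alpha,N-2} + t_{1-\beta,N-2})^2 / \Delta\mu^2$ with
  one-sided t-quantiles, as used to justify cohort sizes in this setting.
  The one-sided arguments are kept as printed in the applied usage even
  though a two-sided convention would use $1-\alpha/2$; the function makes
  both $\alpha$ and $\beta$ explicit so either convention is one argument
  away.
* **Median split and group comparison**: the cohort is split at the IOP
  median (even $n$: mean of the two central values); records equal to the
  median join the lower group with their count reported. Group contrasts
  use the two-independent-sample Wilcoxon rank-sum test with normal
  approximation and tie correction — "Wilcoxon" is interpreted as the
  unpaired test since the groups are different subjects.
* **Density contrast** (`compare_group_pdfs()`): a two-sample KS test needs
  samples, not densities, so each group's mean GG parameter set is turned
  into a deterministic pseudo-sample of its $m$ mid-quantiles
  ($m$ defaults to the group size, 28). The construction and $m$ are
  reported alongside the statistic. The resulting p-value should be read as
  a calibrated distance between fitted densities, not as a subject-level
  test.
* **Multiple testing**: none is applied; the per-parameter p-values mirror
  the reporting convention of the underlying analysis and should be
  interpreted accordingly.

`cohort_analysis()` orchestrates all of the above and `write_report()`
serialises the result (JSON report, CSV tables, per-figure CSV data).

## Numerical and testing choices

Tolerances: pdf quadrature $10^{-6}$; CDF/quantile inverse consistency
$10^{-10}$; optimizer gradient norm $10^{-8}$ per observation;
$R^2$ identities $10^{-10}$. Degenerate inputs (constant predictor,
constant histogram sample, featureless image, monotone epithelium, groups
below minimum size) raise classed errors rather than producing numbers.

Test problem sizes are chosen to keep the full suite around two minutes on
one core while leaving comfortable statistical margins: $10^5$-sample
recovery checks for the MLE, a $30^3$ likelihood grid at $n = 2000$, 20
mid-size phantoms for the pipeline acceptance check plus 100 small phantoms
for the ordering invariant, $10^3$-replicate null simulations for type-I
error and rank-sum power, and 200 cohorts of 56 subjects for stepwise
selection stability.

## Known limitations

* Speckle is statistical, not optical: no spatial correlation, attenuation
  or refraction; segmentation performance on real scans will be worse than
  on phantoms.
* The GG scale $a$ is in instrument-specific arbitrary units; absolute
  comparability across devices is not claimed.
* The synthetic corrected IOP is a documented linear stand-in for
  proprietary correction tables; corrected-IOP results on synthetic data
  reflect that stand-in.
* The cohort generator's independence assumption and its truncated-normal
  age law are simplifications, flagged above.
* No model selection among alternative speckle laws (Rayleigh, Nakagami,
  K): the GG family is fixed by prior evidence for corneal tissue.

## A minimal end-to-end run

```{r example, eval = FALSE}
b <- simulate_bscan(phantom_spec(seed = 42))
res <- fit_speckle(b)
coef(res$fit)

coh <- simulate_cohort(cohort_spec(n_subjects = 56, seed = 42))
an <- cohort_analysis(coh)
an$stepwise$predictors
```

The same pipeline is available from a shell via the `octspeckle` script
(subcommands `simulate-bscan`, `simulate-cohort`, `fit-speckle`,
`analyze-cohort`), which writes a manifest with the merged configuration,
its MD5, the seed and package versions so that any run can be reproduced
bit for bit.
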