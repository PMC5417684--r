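# octspeckle

Corneal OCT speckle statistics and their influence on noncontact tonometry,
as a tested, reproducible R pipeline.

Noncontact (air-puff) tonometry readings of intraocular pressure (IOP) are
confounded by corneal structure. The macro-structure — central corneal
thickness (CCT), corneal radius, axial length, anterior chamber depth,
white-to-white diameter — is measurable with standard biometry. The
micro-structure (stromal collagen organisation) is not directly measurable
in vivo, but it leaves a statistical fingerprint in OCT speckle.
`octspeckle` implements the full analysis chain for studying that
fingerprint:

1. **Speckle model.** Linear (non-log-compressed) pixel intensities from a
   stromal region of interest are modelled with the three-parameter
   Generalised Gamma (GG) distribution

   $$f_{GG}(x;a,v,p) = \frac{p\,x^{pv-1}\exp\{-(x/a)^p\}}{a^{pv}\Gamma(v)},
   \qquad x>0,$$

   fitted by maximum likelihood (`fit_gg()`, a classed model object with
   `print`/`summary`/`coef`/`logLik`/`vcov`/`plot`/`simulate`/`quantile`
   methods). The scale `a` tracks mean backscattered power; the shape ratio
   `v/p` is the *scatter density*. `dgg/pgg/qgg/rgg` provide the
   distribution itself.
2. **Image pipeline.** `segment_layers()` finds the epithelium, Bowman's
   layer and endothelium by gradient edge detection with robust polynomial
   smoothing; `find_apex()` locates the corneal apex; `select_roi()` places
   the 250×450-pixel stromal window; `extract_intensities()` feeds the fit.
3. **Cohort statistics.** `simple_regression()` (R², F-test p, 95%
   confidence band), `forward_stepwise()` (partial-F entry at α = 0.05),
   `sample_size()`, `median_split()`, `group_compare()` (Wilcoxon
   rank-sum), `compare_group_pdfs()` (two-sample KS contrast of group-level
   GG densities), orchestrated by `cohort_analysis()` /`write_report()`.
4. **Synthetic data.** `simulate_bscan()` renders corneal phantoms with GG
   stromal speckle and exact ground-truth boundaries; `simulate_cohort()`
   generates 56-subject cohorts whose marginals match published healthy
   values and whose pressure follows the structural model
   `IOP_nc = 0.0248·CCT − 16.534·GG_a + 6.853 + ε`. Everything downstream
   is therefore testable without clinical data.

A command-line tool (`inst/scripts/octspeckle`, subcommands
`simulate-bscan`, `simulate-cohort`, `fit-speckle`, `analyze-cohort`) ties
the stages into seeded, manifest-stamped end-to-end runs.

## Worked example

```r
library(octspeckle)

# phantom B-scan -> segmentation -> stromal ROI -> GG maximum likelihood
b   <- simulate_bscan(phantom_spec(seed = 42))   # truth: a=0.287 v=0.437 p=2.80
res <- fit_speckle(b)
res$fit
#> Generalised Gamma fit (maximum likelihood)
#>   n = 112500 (0 zero-intensity pixels dropped)
#>   parameters:
#>      a      v      p
#> 0.2879 0.4326 2.8203
#>   scatter density v/p = 0.1534
#>   log-likelihood = 106852,  KS gof = 0.001388,  converged: TRUE
```

All three parameters are recovered within ~1.5% from the 250×450 = 112,500
ROI pixels, and the KS goodness of fit (0.0014) shows the extracted window
is statistically pure stroma.

```r
coh <- simulate_cohort(cohort_spec(n_subjects = 56, seed = 42))
an  <- cohort_analysis(coh)
an$stepwise
#> Forward stepwise regression (n = 56, alpha_enter = 0.05)
#>   entered: CCT, GG_a, GG_v_over_p
#>   coefficients:
#> (Intercept)         CCT        GG_a GG_v_over_p
#>       6.886       0.034     -20.566     -25.956
#>   R^2 = 0.523
```

At n = 56 the stepwise model recovers the generating predictors CCT and
GG_a (here with one spurious extra entry — at this sample size roughly a
third of cohorts admit one noise variable at α = 0.05, which is exactly the
behaviour the selection-stability tests quantify). With the noise turned
off (`cohort_spec(noise_sd = 0)`) the procedure returns
`IOP_nc = 0.0248·CCT − 16.534·GG_a + 6.853` with R² = 1, exactly.

From a shell:

```sh
Rscript inst/scripts/octspeckle simulate-bscan --seed 13 --out out/scan
Rscript inst/scripts/octspeckle fit-speckle --out out/fit out/scan/phantom.tif
Rscript inst/scripts/octspeckle simulate-cohort --seed 13 --out out/cohort
Rscript inst/scripts/octspeckle analyze-cohort --out out/report out/cohort/cohort.csv
```

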