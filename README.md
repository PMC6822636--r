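# ssnPoro

Non-invasive imaging of the **normalized solid stress (SSn)** inside
tumors from ultrasound poroelastography, for researchers in cancer
biomechanics and elastography.

Solid stress (SSg) accumulating in a growing tumor compresses vessels,
raises interstitial fluid pressure, promotes hypoxia and blocks drug
delivery — but direct measurements are invasive. For a spherical
poroelastic tumor under creep compression, the compression-induced solid
stress (SSc) measured by poroelastography shares the spatial distribution
of SSg. Both collapse onto a single dimensionless profile in the
normalized radius r = R/a:

    SSn(r)  = 1 − sinh(α r) / (r sinh α),
    SS_n,p  = SSn(0) = 1 − α cosech α,
    α       = a √((Lp/k)(S/V)),

where Lp, k are the vascular and interstitial permeabilities and S/V the
capillary area-to-volume ratio. The compression-induced fluid pressure is
p(r) = Ψ·SSn(r), the interior stresses are σᶜ(r) = σᵃ − p(r) with boundary
scalars σᵃ from Eshelby's spherical-inclusion solution, and the
growth-induced stresses are σᵍ(r) = −Ω_b − Ω_p·SSn(r). The package
implements:

* the closed-form forward model (overflow-safe up to α = 10⁴);
* Eshelby equivalent-inclusion boundary stresses with the
  cylindrical → spherical tensor rotation and sphere-surface reductions;
* a seeded synthetic phantom: 2-D SSc maps with calibrated Gaussian noise
  and longitudinal treated/untreated cohorts of α values;
* the imaging pipeline: annular radial-profile extraction, deterministic
  multi-start least-squares estimation of α (free or known scale), SSn
  maps and peak SSn;
* Kruskal-Wallis cohort statistics (chi-square and exact-permutation p)
  with per-week summaries and significance stars;
* a CLI (`inst/cli/ssn-poro.R`) with `curves`, `simulate`, `reconstruct`
  and `stats` subcommands writing manifests for reproducible runs.

## Worked example

Simulate a 20 dB phantom (α = 5, a = 8 mm at 0.25 mm/px, σᵃ_RR = −1.2 kPa,
Ψ = 1 kPa), reconstruct α, and build the SSn map:

```r
library(ssnPoro)
ph   <- generateSscMap(PhantomConfig(snrDb = 20, seed = 1L))
prof <- extractRadialProfile(ph$map, nBins = 15)
fit  <- fitAlpha(prof, mode = "free_scale")
fit
#> RecoveryResult (free_scale): alpha = 4.57785, psi = 1.02692 kPa, sigma_a = -1.21938 kPa
#>   peak SSn = 0.905897, rss = 0.2502 over 15 bins; converged: TRUE
ssnMap(ph$map, fit)
#> ScalarMap: 96 x 96 px @ 0.25 mm (dimensionless), mask 3228 px
```

The fitted α (4.58, true value 5) is the tumor's spatial-distribution
parameter — how sharply fluid pressure and solid stress concentrate
toward the center — and peak SSn (0.906, true 0.933) is the center value
of the normalized stress profile. A longitudinal cohort analysis:

```r
co <- generateCohort(CohortSpec(seed = 0L))
weeklySummary(co, metric = "alpha")
#>   week mean_treated sd_treated n_treated mean_untreated sd_untreated n_untreated         H           p stars
#> 1    1     2.962179  0.1438449         6       3.152367    0.4573390           6 0.1025641 0.748774042  n.s.
#> 2    2     2.047731  0.1774159         6       4.543169    0.2098830           6 8.3076923 0.003947752    **
#> 3    3     1.533852  0.1061325         6       6.533242    0.6645167           6 8.3076923 0.003947752    **
```

Arms are indistinguishable at week 1 and separate sharply by week 2 as α
rises in untreated tumors and falls under treatment — the expected
treatment-response signature.

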