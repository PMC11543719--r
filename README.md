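# mosscreen

Screening analysis of trace-element deposition gradients around a point
source — typically a solid-waste incinerator — using moss (or lichen)
biomonitors. Tissue concentrations of epiphytic moss integrate atmospheric
deposition over months to years, so a transect of moss samples radiating
away from a facility is a cheap, spatially dense alternative to reference
air monitors for a first-pass screen: which elements are elevated, at what
spatial scale, and where should follow-up monitoring go?

The package takes a wide samples-by-elements ICP-MS concentration table
(ppm dry weight) with per-sample distances to the source and per-element
method detection limits (MDLs), and provides the full analysis chain:

1. **Detection-limit processing** — censored cells (`"<MDL"`) are
   substituted at MDL/2 when an element is censored in at most 20% of
   samples; elements censored in more than 20% are excluded.
2. **Distance models** — for each element, a local-linear Gaussian-kernel
   nonparametric regression of log10 concentration on log10 distance. The
   smoothing parameter ("tolerance", the s.d. of the Gaussian weighting
   function in log10-km units) is selected by maximising the leave-one-out
   cross-validated R²,

   xR² = 1 − Σᵢ (yᵢ − ŷ₍₋ᵢ₎)² / Σᵢ (yᵢ − ȳ)²,

   over a grid of tolerances at 5% steps of the predictor range, subject to
   an overfitting control on the average neighborhood size
   N*ᵢ = Σ_{j≠i} wⱼ(xᵢ). Because every prediction leaves the focal sample
   out, xR² can be negative for unpatterned elements, and is reported as
   such.
3. **Geogenic correction** — elements that track the crustal reference
   element Al (basis xR² > 0.30) and show a declining distance trend are
   residualized on Al (kernel regression; or on Ce by ordinary linear
   regression for rare earth elements), and the residuals are refit against
   distance. This separates soil-dust loading from a genuine source plume.
4. **Screening report** — samples grouped into near (< 1 km) and far
   (≥ 1 km) sites, five-number concentration summaries per element and
   group, and per-sample exceedance flags against a user-supplied
   reference-percentile table (e.g. the 95th percentiles of a prior
   city-wide survey).
5. **Synthetic transects** — a generator that emulates the study design
   (36 samples on a 0.1–32 km transect, ten within 0.5 km, replicates) and
   the field's signal taxonomy: stack-type plume elements with an
   inflection near 1 km, localized fugitive-dust peaks within ~0.2 km,
   geogenic elements co-varying with a lognormal Al field, MDL censoring.
   Everything is testable and calibratable without field data.

All user-facing functions take and return tibbles and chain with the pipe;
fitted models support `tidy()`, `glance()`, `augment()` and `autoplot()`.

## Worked example

```r
library(mosscreen)

sim <- simulate_panel(sim_config(seed = 42))   # synthetic 36-sample transect
dl  <- apply_detection_limits(sim$panel, sim$meta)

fit_panel_npr(dl$panel) |> dplyr::select(element, xr2, ave_n_star, tolerance)
#>   element       xr2 ave_n_star tolerance
#> 1 Al      -0.0706        32.0      2.41
#> 2 Hg       0.850          7.54     0.241
#> 3 Cd       0.918          3.96     0.121
#> 4 Pb       0.845          7.54     0.241
#> 5 Cr       0.447         32.0      2.41
#> 6 As      -0.000638      32.0      2.41
#> 7 Ce      -0.0669        32.0      2.41
#> 8 La      -0.0794        32.0      2.41
#> 9 Mn      -0.132         27.0      1.33
```

The stack-type elements (Hg, Cd, Pb) show strong cross-validated distance
models fitted at narrow tolerances (~0.12–0.24 log10 km — fine spatial
structure near the source), while the crustal and unpatterned elements
(Al, Ce, La, Mn) come out near or below zero: the leave-one-out penalty
keeps noise from masquerading as signal.

```r
correct_geogenic(dl$panel, basis = "Al", elements = c("Cr", "Ce")) |>
  dplyr::select(element, basis_r2, raw_xr2, adjusted_xr2, selected)
#>   element basis_r2 raw_xr2 adjusted_xr2 selected
#> 1 Cr         0.482  0.447        0.672  TRUE
#> 2 Ce         0.909 -0.0669      -0.0991 TRUE
```

Cr carries both a soil-dust loading and a plume: removing the Al-tracked
component raises its distance model from xR² 0.45 to 0.67. Ce is purely
geogenic — correction leaves no distance signal, as it should.

```r
group_and_summarize(dl$panel, cutoff_km = 1, elements = "Hg")
#>   element group     n    min     q1 median     q3   max
#> 1 Hg      near     14 0.241  0.323  0.386  0.474  0.659
#> 2 Hg      far      22 0.0352 0.0567 0.0681 0.0892 0.200
```

Near-source Hg runs roughly five-fold higher than the far group —
the pattern an incinerator plume leaves in moss tissue.

A thin command-line wrapper over the same functions ships in
`inst/cli/mosscreen.R` with subcommands `fit`, `correct`, `screen`,
`simulate`, `all` and `compare`.

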