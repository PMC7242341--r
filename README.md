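# eegrqa

Multiscale nonlinear analysis of scalp EEG: recurrence quantification and
sample entropy per wavelet frequency band, summarized as per-sensor
multiscale curves and region-level area-under-curve statistics.

## The scientific problem

Focal childhood epilepsies whose discharges localize to the centrotemporal
scalp region are easy to miss on an awake EEG: the discharges are nocturnal
and the awake trace looks visually normal. If the epileptogenic zone carries
a persistent *dynamical* signature — lower signal complexity — it should be
measurable in spike-free awake segments. `eegrqa` implements that
measurement pipeline:

- **Sample entropy** per band: SampEn = −ln(A/B), where B counts pairs of
  length-*m* subsequences within Chebyshev distance r = 0.2·SD and A counts
  those still matching at point m+1 (no self-matches). Lower = more regular.
- **Recurrence quantification** per band, on the delay-embedded signal
  (m = 3, τ = 1) with the radius ε calibrated to a fixed recurrence rate
  (0.10): maximum and mean diagonal line length (Lmax, Lmean), trapping
  time (TT, mean vertical line length), determinism, laminarity.
- **Multiscale structure**: each 30-s channel segment is decomposed into 7
  dyadic frequency bands (0–2 … 64–128 Hz at 256 Hz) by an orthogonal
  multiresolution analysis whose band signals sum exactly to the input and
  partition its energy; every measure is computed per band, giving one
  multiscale curve per sensor.
- **Region statistics**: per subject × sensor, the trapezoidal area under
  the multiscale curve (AUC) is one observation; observations pool into
  four cells — {case, contrast} × {centrotemporal (C3, C4, Cz, T7, T8, P7,
  P8), other sensors} — and a one-way ANOVA, F = MS_between/MS_within on
  (3, n−4) df, tests the region × group contrast.

A seeded synthetic cohort generator (19-channel 1/f noise + quasi-periodic
alpha-range oscillation, with a region-localized regularity deficit on case
CT channels) makes every stage verifiable without patient data, and a
simulate → extract → analyze pipeline ties it together reproducibly.

Who this is for: researchers quantifying EEG complexity on the 10–20
montage, and anyone needing tested, deterministic R implementations of
RQA / sample entropy / DFA with an honest missing-value contract.

## Worked example

```r
library(eegrqa)

spec <- syntheticCohortSpec(nCase = 4, nContrast = 4, seed = 42)
coh  <- generateCohort(spec)                      # 8 x 19-channel recordings
cfg  <- runConfig(measures = c("SampE", "TT"), analysisSamples = 768,
                  selectionSeed = 42)
ex   <- extractCohortFeatures(config = cfg, recordings = coh$recordings)
nrow(ex$features)                                 # 2128 = 8 x 19 x 7 x 2

regionANOVA(ex$features, "SampE")
#> RegionSummary SampE: F(3, 148) = 30.04, p = 3.14e-15
#>        case_CT     case_nonCT    contrast_CT contrast_nonCT
#>       4.032788       4.185550       4.207896       4.202227

multiscaleGroupCurve(ex$features, "SampE", "C3", "case")
#> MultiscaleCurve SampE @ C3 (case), 7 bands
#>         mean         ci n
#> 1 0.05511513 0.02264596 4
#> ...
```

Reading the output: the case/centrotemporal cell has the lowest mean sample
entropy AUC (4.03 vs ≈4.20 everywhere else) — the injected complexity
deficit is recovered and localized, and the ANOVA confirms the four cell
means differ (F(3, 148) = 30.0, p ≈ 3×10⁻¹⁵). The curve shows per-band
means with 95% confidence half-widths for one sensor and cohort; band 4
(8–16 Hz) dips because the regularized oscillation lives there.

The same analysis as a file-based run:

```r
runPipeline("all", "out/", spec = syntheticCohortSpec(seed = 1),
            config = runConfig())
# out/: edf/*.edf, cohort.csv, features.csv, curves_*.csv, auc_*.csv,
#       anova_*.csv, heatmap_*.csv, run_metadata.json
```

Identical configurations and seeds reproduce every output byte for byte;
each CSV records the configuration hash it was produced under.

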