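---
title: "Multiscale recurrence and entropy analysis of scalp EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale recurrence and entropy analysis of scalp EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Focal childhood epilepsies with centrotemporal spikes are routinely missed on
awake EEG because the discharges are nocturnal: the awake trace looks normal
to visual inspection. The hypothesis behind this package is that the
epileptogenic zone nonetheless carries a measurable *dynamical* signature --
lower signal complexity -- even between discharges. The package implements a
screening pipeline for that hypothesis: nonlinear dynamical measures computed
per frequency band on 30-second awake EEG segments, summarized per sensor as
multiscale curves and reduced to region-level statistics contrasting the
centrotemporal (CT) sensors C3, C4, Cz, T7, T8, P7, P8 against the rest of the
standard 10--20 montage, across a case cohort and a contrast cohort.

The pipeline has three stages, mirrored by `runPipeline()`:

1. **Data** (`readEDFRecording`, `selectAwakeSegment`): EDF recordings are
   read with each channel's stored physical calibration, labels are
   normalized to modern 10--20 names (legacy T3/T4/T5/T6 map to T7/T8/P7/P8),
   and one segment per subject is drawn uniformly on a one-second start grid.
   No filtering or artifact rejection is applied by default; an optional
   500 uV amplitude veto can exclude candidate windows.
2. **Features** (`waveletBandDecompose`, `rqaFromSignal`, `sampleEntropy`,
   `featuresForSegment`): every channel is decomposed into 7 dyadic
   frequency bands and each band signal is scored with sample entropy and
   recurrence quantification measures, producing a long-format feature table.
3. **Statistics** (`multiscaleGroupCurve`, `curveAUC`, `regionANOVA`,
   `heatmapTable`): per-sensor multiscale curves with 95% confidence bands,
   one area-under-curve (AUC) observation per subject x sensor, and a
   one-way ANOVA over the four (group, region) cells.

# The measures

**Sample entropy.** For template length $m$ (default 2) and tolerance
$r = 0.2\,\mathrm{SD}(x)$, SampEn $= -\ln(A/B)$ where $B$ counts ordered
pairs of length-$m$ subsequences within Chebyshev distance $r$ and $A$ counts
those that still match at point $m+1$; self-matches are excluded. Lower
values mean a more self-similar, more regular signal. When no pair matches
($B=0$ or $A=0$) the value is *missing with a reason*, never zero: a silent
zero would masquerade as maximal regularity and bias every downstream mean.

**Recurrence quantification.** The band signal is delay-embedded
($m = 3$, $\tau = 1$ sample by default), and the recurrence matrix
$R_{ij} = \mathbb{1}[\lVert x_i - x_j\rVert \le \varepsilon]$ is summarized
through its line structures: `Lmax` and `Lmean` (maximum / mean diagonal
line length $\ge$ 2, reflecting how long two stretches of trajectory shadow
each other), trapping time `TT` (mean vertical line length $\ge$ 2, how long
the system lingers in a state), plus determinism `DET`, laminarity `LAM` and
the recurrence rate `RR`.

Three conventions deserve explicit statement because reference
implementations differ:

* **Radius policy.** $\varepsilon$ is not fixed; it is calibrated by
  bisection per band signal so that the off-diagonal recurrence rate hits a
  target (default 0.10, tolerance $\pm 0.01$, typically converged well
  inside $\pm 0.005$). Fixing RR instead of $\varepsilon$ removes amplitude
  scale from the comparison across subjects, sensors and bands. If the
  target rate is unattainable -- the distance distribution has an atom
  spanning it, e.g. a two-point trajectory -- the calibrator
  deterministically returns the smallest radius whose rate reaches the
  target.
* **Theiler window.** `theilerW` names the half-width of the diagonal band
  excluded from diagonal statistics: offsets $|i-j| < w$ are dropped and the
  line of identity is always dropped, so both $w = 0$ and the default
  $w = 1$ exclude exactly the main diagonal. Vertical statistics use the
  full matrix.
* **Degenerate inputs.** A constant band signal has no SD (entropy) and a
  zero-diameter trajectory (recurrence); both raise errors at the kernel
  level, which `featuresForSegment` converts into missing values with reason
  codes so that one dead channel never aborts a cohort.

**DFA.** First-order detrended fluctuation analysis is available as an
optional measure: integrate the centered signal, detrend within
non-overlapping windows (default 15 log-spaced sizes from 10 to $n/10$,
chosen so the estimator is close to unbiased: simulated white noise yields
$\alpha \approx 0.50$ and integrated noise $\alpha \approx 1.50$), and take
the log--log slope of fluctuation versus window size.

# The band decomposition

Each measure is computed per dyadic frequency band; at 256 Hz with the
default 6 levels the nominal bands are 0--2, 2--4, 4--8, 8--16, 16--32,
32--64 and 64--128 Hz. Band signals are same-length time-domain
reconstructions, so the identical measure code runs on every band, and the
multiscale x-axis is the band *index* (band widths are dyadic, so a Hz axis
would be wildly nonuniform).

The decomposition must satisfy two structural contracts: the band signals
sum back to the input (so nothing is invented or lost) and their energies
partition the input energy (so "energy in band" is meaningful). The default
engine is the **Shannon multiresolution analysis** -- projection onto ideal
dyadic bandpass subspaces computed in the DFT domain. Its projections are
orthogonal and idempotent, so both contracts hold to machine precision at
any signal length, and a narrowband rhythm sits entirely inside one band.

Compactly supported Daubechies alternatives (`haar`, `db2`, `db4`, `db8`,
periodized orthogonal pyramid) are provided and tested. They were not made
the default for a concrete, measurable reason: their transition bands leak
15--27% of a rhythm lying 1 Hz above a band edge (e.g. a 9 Hz alpha-range
oscillation against the 8 Hz edge) into the neighbouring band, where the
leaked tone *adds* an incommensurate component and **raises** that band's
sample entropy. In our synthetic studies this two-tone artifact cancelled --
and for moderate effect sizes inverted -- the band-aggregated entropy
response to an injected regularity increase. The ideal filterbank has no
transition band and no decimation aliasing, so the injected direction is
preserved. Practitioners who want classical wavelets can set
`runConfig(wavelet = "db4")`; the trade-off is documented here rather than
silently absorbed.

# The synthetic cohort generator

Clinical EEGs with diagnosis labels cannot be bundled, so the generator is a
first-class module that makes every stage testable end to end. Each channel

$$x = (1-w)\,\text{colored noise}(\beta) + w\,\text{quasi-periodic sine},$$

both components standardized to unit variance before mixing. The noise is
$1/f^{\beta}$ (default $\beta = 1$, the canonical broadband EEG background),
synthesized in the frequency domain with random phases. The oscillation
(default 9 Hz, alpha range) carries random-walk phase noise (SD 0.05
rad/sample) so its recurrence structure is quasi-periodic rather than
degenerate. The mixing weight $w$ is the ground-truth complexity knob: raw
sample entropy of the generated signal falls monotonically in $w$ (verified
by `calibrateComplexityKnob()`, which sweeps $w$ and measures the generator's
output with the pipeline's own kernels).

Case subjects receive $w = \texttt{oscMix} + \texttt{ctDeficit}$ on CT
channels and `oscMix` elsewhere; contrast subjects receive `oscMix`
everywhere. Weight jitter (SD 0.02) is drawn **independently per subject x
channel**: a subject-constant jitter would inject a shared random effect
across a subject's 19 sensors, and the four-cell ANOVA -- which deliberately
pools sensors as observations (below) -- would then be miscalibrated under
its own null. Electrode-level variability is also the more physical reading
of placement and impedance differences.

**Choice of the default deficit (0.5).** The deficit must be large enough
that the *band-aggregated* entropy AUC responds in the injected direction.
Band 4 (8--16 Hz) holds the oscillation; its residual noise amplitude is
$(1-w) \cdot \sigma_{\text{noise,band4}} \approx (1-w)\,0.38$, while the
entropy tolerance is $r = 0.2\,\mathrm{SD}$. Matching the two gives
$w \approx 0.6$: below that, residual noise exceeds the tolerance and the
band's entropy barely moves. The measured response curve (mean SampEn AUC
over 12 channel draws per weight) confirms it -- flat within noise up to
$w \approx 0.3$, then decisively decreasing (about $-0.14$ AUC from
$w = 0.1$ to $0.6$). The default `ctDeficit = 0.5` therefore places case CT
channels at $w = 0.6$, the knee of the calibrated response, giving a
reliably recoverable contrast of known direction (case-CT cell lowest).

**What the generator does not emulate.** No volume conduction or
cross-channel correlation, no nonstationarity beyond phase wander, no
artifacts, no spikes (deliberately: the emulated segments are spike-free
awake EEG), no per-subject spectral idiosyncrasy. Passing the effect
recovery tests therefore demonstrates that the *pipeline* detects and
localizes a genuine regularity contrast at realistic amplitudes and sample
sizes -- it does not demonstrate that real epileptic EEG carries such a
contrast, which is exactly the clinical question the pipeline exists to ask.

# Statistical design

The multiscale curve of measure $M$ at sensor $s$ for one cohort is the
per-band mean across subjects with a 95% confidence half-width
$1.96\,\mathrm{SD}/\sqrt{n}$ (normal approximation by default; a
t-quantile version via `ci = "t"`; a single-subject band yields width 0
with a warning rather than an undefined value).

Region statistics reduce each subject x sensor curve to one trapezoidal AUC
over the band index (interior missing bands are linearly interpolated,
missing terminal bands truncate with a warning, and a curve with fewer than
two surviving bands is dropped). The AUCs pool into four cells -- case/CT,
case/nonCT, contrast/CT, contrast/nonCT -- and a classical one-way ANOVA
(`stats::lm`/`anova`) tests equality of cell means on $(3, n-4)$ degrees of
freedom. Pooling sensors within a subject is *pseudo-replication*: the
observations within a cell are not fully independent in real data. The
design keeps it deliberately, because the region contrast is defined on it
and the synthetic generator (independent channels) satisfies it; the
vignette flags it so nobody mistakes the p-value for one from a
mixed-effects analysis. p-values are reported exactly and uncorrected; a
Bonferroni table across measures is available behind the `bonferroni` flag.

# Numerical and reproducibility choices

* **Problem sizes.** The recurrence and entropy kernels are $O(n^2)$; the
  analysis window fed to them (`analysisSamples`, default 2048 samples of
  each band signal, i.e. 8 s at 256 Hz) is the package's chosen operating
  point for routine use; the validation suite runs at 512--768 samples,
  sizes at which the synthetic effect is already decisively recoverable.
  Decomposition always uses the full 30-s segment.
* **Determinism.** Every stochastic step (segment start, cohort synthesis)
  flows from explicit integer seeds through a splitmix-style derivation,
  and temporary RNG state is always restored; two runs of `runPipeline`
  with the same configuration are byte-identical, and each output CSV
  carries an FNV-1a hash of the canonical configuration JSON in a leading
  comment line.
* **EDF I/O.** The reader applies each channel's stored physical
  calibration, rejects files whose channels disagree on sampling rate (no
  silent resampling), and drops annotation channels. The writer emits
  one-second records with 16-bit quantization over the per-channel observed
  range; round-trip error is bounded by quantization (relative RMS well
  under $10^{-3}$) and the output is byte-deterministic. An external reader
  (python-mne) is used as an independent oracle in the test suite.
* **Compiled kernels.** Pairwise-distance loops (radius calibration,
  matrix-free line statistics, entropy template counting) are C++ (Rcpp);
  the plain-R matrix-level operations (`recurrenceMatrix`,
  `diagonalLineLengths`, `rqaMeasures`) remain the reference surface and
  the two routes are asserted equal in the tests.

# Known limitations

* Lmax is reported literally as the longest diagonal line; its relation to
  the largest Lyapunov exponent is conventionally inverse, and this package
  takes no position on that interpretation.
* The four-cell ANOVA inherits the pseudo-replication caveat above.
* The Shannon filterbank's band signals have infinite time-domain support
  (ringing at segment boundaries); for the segment lengths used here the
  effect on the measures is negligible, but single-band *waveform*
  inspection near the edges should use a Daubechies engine instead.
* Sampling rate is taken from the EDF header; recordings at rates other
  than 256 Hz keep the dyadic band structure but shift the nominal Hz
  ranges, so the band index, not Hz, is the comparable axis across cohorts
  with mixed rates.
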