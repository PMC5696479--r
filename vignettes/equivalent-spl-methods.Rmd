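---
title: "Estimating equivalent free-field output of middle-ear-implant actuators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating equivalent free-field output of middle-ear-implant actuators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ameispl)
```

## The problem

An active middle ear implant (AMEI) drives the ossicular chain with an
electromechanical actuator. Before clinical data exist, its output for a
given drive voltage is characterized in human cadaveric temporal bones as an
*equivalent sound pressure level*: the free-field SPL that would produce the
same cochlear input as the actuator does at a reference drive of
$E_\mathrm{max} = 1\,\mathrm{V}_\mathrm{rms}$. Two physical references can
serve as the "cochlear input":

* **Stapes vibration** (the classic ASTM-style reference), measured with a
  single-point laser Doppler vibrometer (LDV). With the acoustic-run stapes
  displacement $d_U$ at ear-canal pressure $p_T$, and the actuator-driven
  displacement $d_A$ at drive voltage $E$,
  $$L_{E_\mathrm{max}} = 20\log_{10}\!\left(\left|\frac{d_A}{E}\cdot\frac{p_T}{d_U}\right|
  \frac{E_\mathrm{max}}{2\cdot 10^{-5}\,\mathrm{Pa}}\right).$$
* **Intracochlear pressure difference (ICPD)**, the complex vector
  difference $\Delta P = P_{SV} - P_{ST}$ between scala vestibuli and scala
  tympani pressures. With the equivalent ear-canal transfer function
  $H_{ET} = (\Delta p_A/E)(p_T/\Delta p_U)$, the level is
  $20\log_{10}(|H_{ET}|E_\mathrm{max}/2\cdot10^{-5}\,\mathrm{Pa})$.

Both levels are referenced at the tympanic membrane and converted to free
field by subtracting a frequency-specific transformation $T_d(f)$,
interpolated linearly in Hz between table knots. A third, clinical route
computes the same quantity per implant recipient from paired thresholds:
the bone-conduction threshold $b$ (dB HL, converted additively to free-field
SPL $b'$) and the "direct threshold" $a$ through the implant's own drive
(dB MET, converted additively to dB V as $a'$), giving
$L_E = b' - a'$ under the assumption that loudness at both thresholds is
equal. When $b$ is missing and the preoperative air-bone gap is at most
10 dB (inclusive), the air-conduction threshold stands in for it.

The scientific interest in having *two* cadaver references is that stapes
motion becomes rotationally complex ("rocking") above roughly 1-2 kHz.
Rocking contributes to what a single-point, single-axis LDV measures but
displaces no net perilymph volume, so it should inflate stapes-referenced
output estimates while leaving ICPD-referenced estimates untouched. The
package's synthetic ear makes that mechanism explicit and testable.

## Package design

The analysis surface is deliberately small:

* `tb_output_series(record, reference, td_table)` is the central estimator.
  It takes a `tb_record` (paired acoustic and actuator runs of one bone at
  one coupling position) and returns an `eqspl_series` S3 object - a
  per-tone data frame of equivalent free-field levels with an exclusion
  mask - with `print()` and `plot()` methods.
* `clinical_output_series(record, tables)` produces the same container from
  a recipient's thresholds, so cohort summaries and statistics treat bones
  and patients uniformly.
* `amei_simulate()`, `amei_analyze()` and `amei_compare()` orchestrate the
  full study: generate cohorts, gate them, estimate output series and run
  the statistical comparisons, optionally writing each stage as CSV.

Internals are base R; S3 classes carry provenance (bone id, coupling
position, reference, $E_\mathrm{max}$) as attributes.

## Signal chain and its parameters

Acquisition is modelled as averaged complex spectra on a uniform FFT grid,
12.5 Hz spacing. The default grid spans 0-10 kHz inclusive plus three guard
lines, so that the highest stimulation tone (10 kHz) has the three
neighbours above it that the noise estimate requires. Per-tone SNR is the
ratio of the stimulation-bin amplitude to the mean amplitude of the three
FFT lines on either side; a configuration switch (`noise_average =
"power"`) averages neighbour powers instead, since published descriptions of
such LabVIEW chains rarely state which was used. SNR is capped at
$\pm 200$ dB so noiseless synthetic spectra remain finite.

The averaging protocol (`average_until_snr()`) mirrors the acquisition
rule: coherent (complex-mean) averaging until SNR $\geq$ 12 dB, at least 30
and at most 1000 averages. Responses that end below 12 dB are not deleted
but masked downstream with reason `"snr"`; the 12 dB bound is inclusive.

The 23-tone default stimulus sequence runs from 100 Hz to 10 kHz at roughly
three tones per octave, every tone an exact multiple of 12.5 Hz, augmented
with the audiometric frequencies 3 and 6 kHz so that all standard
comparison frequencies except 1.5 kHz are stimulated directly; 1.5 kHz is
filled by linear interpolation between the 1262.5 and 1587.5 Hz tones
(`interpolate_at_1500()`).

Three measurement corrections matter:

* **Renormalization to a common input.** Pressure and vibration channels
  are acquired in sequential stimulations whose inputs differ minutely
  (order 0.07 dB / 0.5 degrees). `renormalize_to_common_input()` rescales
  both runs to the complex geometric mean of their inputs - chosen as the
  symmetric target since neither sub-run is privileged - leaving every
  response/input ratio untouched to machine precision.
* **Cosine correction.** The LDV beam meets the stapes footplate normal at
  a visually estimated 30-45 degrees; measured velocities are divided by
  $\cos(\theta)$. The angle is a per-record scalar, default 37.5 degrees
  (the midpoint). Because the same angle applies to both runs it cancels in
  the level ratio; it still matters for the absolute transfer function used
  by the acceptance gate.
* **Velocity to displacement.** $d = v/(i 2\pi f)$; the level formulas use
  displacement.

The magnitude in the level formulas is taken of the full complex ratio
product; taking per-factor magnitudes gives the identical level, so this is
a presentation choice, not a numerical one.

## Acceptance gating

Bones enter the analysis only if their middle-ear transfer function
(cosine-corrected stapes displacement per Pa by default; velocity per Pa by
option) lies inside an acceptance corridor over 0.25-4 kHz. Bound
comparison is inclusive, and tones outside the band or below the SNR
threshold never influence the verdict. The corridor is configuration data:
published corridor values are not shipped, and `synthetic_corridor()`
builds a labelled synthetic one (template $\pm$ 10 dB) for simulation and
tests.

## Conversion tables are placeholders

$T_d(f)$, the dB HL $\to$ dB SPL$_{FF}$ offsets, and the dB MET $\to$ dB V
offsets are laboratory/standard calibration data that the package cannot
ship. `td_placeholder()`, `hl_to_spl_ff_placeholder()` and
`met_to_dbv_placeholder()` provide smooth, plausibly shaped stand-ins that
are clearly labelled as such; every test and simulation uses synthetic
tables, and real analyses should load calibrated tables via
`read_transform_table()`. Within the package's verification logic the
choice is immaterial: the synthetic generator inverts whatever tables it is
given, so recovery tests are exact for any table.

## The synthetic generator as the oracle

Because the study's raw cadaver and patient measurements are not available
in recomputable form, verification rests on synthesis with known ground
truth. `generate_tb()` builds one bone by *inverting* the analysis: given
an ear model ($H_{me}$, cochlear map $Z_c$), an actuator truth curve and
the $T_d$ table, it constructs actuator-run responses such that the
noiseless piston-only record analyzes to exactly the configured truth for
**both** references. This full-chain identity (generate $\to$ analyze
$\equiv$ identity, to better than $10^{-6}$ dB) is the central oracle of
the repository; everything else layers on top:

* **Rocking contamination** adds $\rho\,(f/f_\mathrm{rock})^2$ (for
  $f > f_\mathrm{rock}$) of extra measured velocity to the actuator run's
  stapes channel only - a modelling choice consistent with the hypothesis
  that actuator drive excites a different motion pattern than acoustic
  drive. It inflates the stapes-referenced estimate above the corner
  frequency and, by construction, cannot touch the pressure channels.
* **Noise** is circularly symmetric complex Gaussian per bin, with RMS
  expressed as a fraction of the channel's median tone amplitude (default
  0.02, i.e. about -34 dB, which puts median tone SNRs in the 20-60 dB
  band typical of 30-average acquisitions). Each tone is "measured" from
  its own spectrum, as in sequential stimulation; putting all tones in one
  spectrum would let closely spaced low-frequency tones contaminate each
  other's adjacent-bin noise estimates.
* **Scala pressures** are split as $P_{SV,ST} = c\,\Delta P e^{0.5i} \pm
  \Delta P/2$ with common-mode fraction $c$ (default 0.5), so the vector
  difference is exercised nontrivially.
* **Input jitter** between sequential sub-runs (uniform within
  $\pm$ 0.07 dB, $\pm$ 0.54 degrees) exercises the renormalization step
  inside every generated record.

`generate_tb_cohort()` spreads bones around the template by a smooth
log-normal (in dB) perturbation of $H_{me}$ (default SD 5 dB) and
constructs exactly `n_pass_gate` of them inside the corridor, clamping pass
bones 1 dB clear of the bounds and pushing fail bones 4 dB outside so that
measurement noise cannot flip a verdict. Note what this implies: because
the equivalent-SPL estimate is a ratio, anatomical spread of $H_{me}$
cancels, and recovered outputs vary only through noise. Real cohorts show
considerably more bone-to-bone output spread (driven by coupling
variability), which this generator deliberately does not emulate - passing
cohort-level tests here demonstrates correctness of the estimation chain,
not realism of between-bone variance.

`generate_clinical_cohort()` draws per-patient BC thresholds
(N(50, 10) dB HL by default, a typical implant-candidate population),
derives the consistent direct threshold from the configured truth, then
quantizes *both* thresholds to the audiometric 5 dB step. Per-patient
recovery error is therefore bounded by one step. The two quantization
errors are coupled (the direct threshold is a deterministic offset of the
BC threshold before quantization), which leaves the cohort *mean* unbiased
but can hold the cohort *median* a fraction of a step off the truth - an
inherent property of quantized paired thresholds, observed in the
verification runs as roughly half a decibel. The default missingness
pattern reproduces a cohort in which, e.g., only 5 of 24 recipients
contribute 0.25 kHz data; at such sparse frequencies the clinical median
carries several dB of sampling error, which is why the cohort-agreement
test applies its 3 dB band only where $N \geq 10$.

## Statistics

Cohort summaries report medians with 25th/75th percentiles computed by
linear interpolation between order statistics (`quantile(type = 7)`); the
percentile convention is documented because published figures rarely state
theirs. Normality is screened per frequency with Shapiro-Wilk. The paired
stapes-vs-ICPD comparison uses the two-sided Wilcoxon signed-rank test with
zero differences discarded before ranking (Wilcoxon's original rule; a
switch retains them) and exact p-values whenever there are no ties; a
frequency with no nonzero differences reports $p = 1$. Temporal-bone
versus clinical cohorts are compared per audiometric frequency with the
two-sided exact Mann-Whitney test after interpolating bone outputs at
1.5 kHz. Significance is flagged at 0.05 two-sided with no
multiple-testing correction - mirroring per-frequency reporting practice in
this literature, a fidelity choice rather than a statistical endorsement.
The test suite verifies both tests against brute-force enumerations of
their exact null distributions and checks their type-I error over 2000
null simulations.

## Numerical choices and degenerate inputs

* The SPL reference pressure $2\cdot10^{-5}$ Pa is the exported constant
  `PA_REF`.
* SNR caps at $\pm 200$ dB; zero noise with nonzero signal reports +200,
  zero signal with nonzero noise -200.
* Tone lookup snaps to the nearest grid line within half a spacing. On a
  12.5 Hz grid no interior frequency is farther than 6.25 Hz from a line,
  so the off-grid guard only triggers outside the grid span.
* $T_d$ interpolation is linear in Hz by default (`linear_log_hz`
  available); evaluation outside the table span is an error, never an
  extrapolation.
* Excluded tones propagate as `NA` with a reason code, never as zeros;
  all-masked series are valid objects, and all-masked frequencies drop out
  of summaries (varying per-frequency N).
* Zero denominators ($d_U$, $p_T$, $E$, $\Delta p_U$) raise errors rather
  than producing infinities.

## Problem sizes used in verification

The shipped tests and the acceptance script run entirely on synthetic
data: single bones with 23 tones, cohorts of 6-14 bones and 8-24
patients, 200 seed replicates for the clinical quantization bias, and 2000
null simulations per rank test. These sizes were chosen so the whole
verification completes in well under a minute while leaving the statistical
assertions comfortable margins.

## Worked example

```{r, eval = FALSE}
library(ameispl)
sim <- amei_simulate(seed = 1)                 # 14 bones, 24 recipients
an  <- amei_analyze(sim$records, sim$corridor, sim$td_table)
sum(an$gate$pass)                              # 10 bones enter analysis
head(an$summaries)                             # medians and quartiles
cl  <- lapply(sim$clinical, clinical_output_series, tables = sim$tables)
amei_compare(an$series, cl)                    # paired + unpaired tests
```

## Known limitations

* The ear model is a single-degree-of-freedom linear sketch: no
  multi-mode ossicular dynamics, no round-window or direct cochlear
  stimulation modes, no nonlinearity or drift.
* Between-bone output variability (coupling-force dependence) is not
  modelled; position labels are metadata, not mechanics.
* Placeholder conversion tables make absolute levels from the defaults
  illustrative only; conclusions about real hardware require calibrated
  $T_d$, HL and MET tables.
* The clinical generator assumes the loudness-equality premise exactly;
  the pipeline cannot test that premise, only propagate it.
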