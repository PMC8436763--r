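---
title: "Methods: FLIM-based quantification of presynaptic calcium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FLIM-based quantification of presynaptic calcium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimca)
```

`flimca` decodes absolute presynaptic free-Ca²⁺ concentrations from
time-correlated single-photon-counting (TCSPC) fluorescence-lifetime data
and estimates spike-evoked Ca²⁺ entry with a saturation correction. This
vignette is the package's account of the underlying model, the numerical
and design choices, and what the synthetic-data tests do and do not
demonstrate.

## 1. The generative model

### Indicator photophysics

The indicator (OGB-1 by default) is modelled as a two-state system: Ca-free
molecules fluoresce with lifetime `tau_free` and relative brightness 1;
Ca-bound molecules with lifetime `tau_bound` and brightness `gamma`. With
single-site equilibrium binding, `f = ca / (ca + kd)`, a detected photon
originates from the bound state with probability

```
w(ca) = gamma * f / (gamma * f + (1 - f))
```

and the decay density is the `w`-weighted mixture of the two truncated
exponentials on the inter-pulse window. Summing the two brightness terms
shows the total fluorescence obeys

```
F(ca)  proportional to  (ca + kd / gamma) / (ca + kd)
```

— the same single-wavelength saturation law the evoked-entry estimator
inverts. Simulator and estimator therefore share one law by construction;
this internal consistency, not photophysical exactness, is what the package
needs to validate the analysis chain.

Parameters, units and defaults:

| parameter    | meaning                               | default | why |
|--------------|---------------------------------------|---------|-----|
| `kd`         | dissociation constant (nM)            | 240     | OGB-1 affinity |
| `gamma`      | dynamic range F_max/F_min             | 6       | OGB-1 |
| `tau_free`   | Ca-free lifetime (ns)                 | 0.7     | fast component; gives strong NTC contrast |
| `tau_bound`  | Ca-bound lifetime (ns)                | 3.7     | slow component, well inside the window |
| `rep_window` | laser inter-pulse window (ns)         | 12.5    | 80 MHz Ti:Sapphire source |

The two lifetimes are simulator parameters, not literature constants; both
are configurable and every analysis result is benchmarked against the
generator's own ground truth, never against assumed photophysics.

A closed-form consequence worth recording: because the smoothed peak and
the window sum are both linear in `w`, the noiseless NTC-vs-[Ca²⁺] relation
is an *exact* hill-1 logistic in log₁₀[Ca²⁺] with midpoint
`E50 = kd * (P_free / P_bound) / gamma`, where `P_free/P_bound` is the
peak-height ratio of the two pure components (≈ 5 here, giving E₅₀ ≈
190 nM). The 4-parameter fit is still carried with a free slope so that it
remains correct for data whose decay model is not exactly two-state.

### Instrument response and binning

Excitation is treated as a delta function at the origin bin: the source
pulse (~100–200 ps) is two orders of magnitude shorter than the lifetimes
and the 0.05 ns bins. The default time base is 250 × 0.05 ns = 12.5 ns.
NTC is bin-width dependent, so calibration and experiment must share one
binning; serialized calibrations carry a fingerprint of theirs
(`binning_hash()`) and `decode_timeline()` refuses a mismatch.

### Scan geometry and the photon budget

The spiral ("tornado") scan is abstracted to `n_pixels` equal-dwell pixels
per cycle (default cycle 1 ms); all spatial structure is summed away before
analysis, so no point-spread or diffusion model is included. Per cycle, the
expected photon flux is `photon_rate * F(ca(t)) / F(ca0)` — lifetime *and*
intensity respond to Ca²⁺ through the same law — and counts are independent
Poisson draws per (bin, pixel, cycle).

### The transient and the population

A trial's ground-truth Ca²⁺ course is: constant `ca0`; a linear rise of
`delta_ca` over `rise_ms` (≤ 3 ms, the diffusion-equilibration scale)
starting at `ap_time_ms` (≥ 500 ms, so a full basal window exists); then
exponential relaxation with `decay_tau_ms` (default 400 ms, a typical
single-AP clearance scale for this indicator load).

Populations are generated as
`truth = order mean × condition effect + cell effect + bouton noise`
(truncated at 0), with cell and bouton effects drawn once per bouton and
shared across conditions, so condition contrasts are paired within boutons
and cell identity supports the two-factor analysis. Default order means —
resting (31, 45, 34) nM and evoked (42, 76, 101) nM for branch orders 1–3 —
and the default condition effects (evoked entry × 0.31 under transporter
block; resting × 23/31 and evoked × 66/140 under mGluR block; no effect
under subthreshold depolarization) reproduce the group structure of the
recordings this pipeline was designed for.

## 2. Decoding choices

**NTC origin and peak.** The origin is the argmax of the 3-bin
moving-average-smoothed histogram, and the 9 ns integration window starts
there. The normalizing peak is the smoothed maximum by default
(`smooth = FALSE` restores the raw maximum): at realistic per-bin counts
the raw maximum is upward-biased by shot noise, which would bias NTC — and
hence decoded Ca²⁺ — downward at low counts.

**Low-signal and out-of-range policy.** Histograms below 1000 photons
(configurable) are flagged `low_signal`, not decoded: the decay tail
(8–12 ns post-pulse) otherwise carries too few counts to constrain NTC.
NTC values outside the open interval between the fitted asymptotes are
flagged `out_of_range`; the logistic is never extrapolated and flagged bins
are excluded, never clamped.

**Calibration fit.** Levenberg–Marquardt least squares on the 4-parameter
logistic in log₁₀[Ca²⁺]; nominally zero-Ca solutions are floored at 1 nM to
stay in the log domain (any floor ≪ the first decade of sensitivity gives
the same fit to numerical precision). A fit whose slope and asymptote
ordering disagree is refused as non-monotone. Uncertainty on decoded Ca²⁺
uses the closed-form inverse's derivative and a Poisson delta-method NTC
variance; because the peak bins are part of the window sum,
`var(NTC)/NTC² ≈ 1/(3·peak) − 1/sum` for the 3-bin smoothed peak, which
Monte-Carlo checks reproduce to ~20%.

## 3. Evoked-entry estimation

`F_rest` is the intensity-trace mean over the ~500 ms basal window, and
[Ca²⁺]₀ the photon-weighted mean of the decoded timeline over the same
window. The two printed saturation relations then give `F_max` and
[Ca²⁺]_peak; Δ[Ca²⁺] follows by subtraction. A guard at
`f_peak ≤ 0.95 · F_max` flags saturating transients instead of reporting a
divergent concentration, and boutons whose peak estimation fails keep their
resting estimate and enter only the resting-level analyses.

**Peak location — a deliberate design choice.** The conventional estimator
takes the maximum of the (optionally 2-cycle smoothed) trace within ~20 ms
after the stimulus. The maximum of noisy cycles is, however, positively
biased: under a null trial (no transient) it exceeds the baseline by
roughly 1.7 cycle-SDs, which a 20-run confidence interval resolves easily —
the estimator would "detect" entry where none occurred. The default is
therefore `peak_method = "window"`: the trace mean over a fixed window from
`ap + 3 ms` (past diffusion equilibration) to `ap + 8 ms`. This is unbiased
under the null, and with a 400 ms decay constant it underestimates a true
peak by well under 2%. `peak_method = "max"` remains available for real
low-SNR data where the stimulus-to-peak latency is uncertain.

## 4. Quality control and cross-validation

Trial-to-trial stability uses the coefficient of variation (sample SD over
mean) across trials with a 20% failure threshold; a single trial passes
with an explicit `single_trial` flag. The lifetime-vs-intensity
cross-check amplitude-normalizes both post-stimulus decays (rest → 0,
segment peak → 1) on the timeline's grid, restricted to bins decoded at or
below the linear range (default 120 nM = K_d/2), and scores their RMS
difference; the score is exactly invariant to intensity rescaling, and a
constant trace scores infinite. The default cutoff (0.3) sits several-fold
above the score simulated matched trials attain.

## 5. Statistics

* Branch order: Kruskal–Wallis (single factor) plus a two-way ANOVA with
  branch order and cell identity, **no interaction, Type II sums of
  squares** — the design is unbalanced (1–4 boutons/cell) and only main
  effects are of interest. A Shapiro–Wilk test on within-group residuals is
  recorded to document why the rank-based test is carried alongside.
* Paired manipulations: Shapiro–Wilk on the paired differences at α = .05
  gates between the paired *t*-test and the Wilcoxon signed-rank test. The
  signed-rank test uses the Pratt treatment of zero differences (zeros are
  ranked, then their ranks discarded) with a tie- and zero-corrected normal
  approximation and continuity correction; with no zeros it coincides with
  the standard normal-approximation test.
* A fully tied response returns H = 0 with p = 1 (no evidence either way)
  rather than a division-by-zero.
* No multiple-testing correction is applied; all p-values are reported raw.

## 6. What the synthetic tests show — and what they cannot

The generator reproduces the *statistical structure* the analysis assumes:
Poisson photon noise on a two-state decay, a shared saturation law, the
fast-rise/slow-decay transient, nested sampling with paired conditions.
Passing tests therefore demonstrate that the decoding and estimation chain
is unbiased and correctly calibrated *given that structure*. Real
recordings add effects the generator deliberately omits — instrument
response width and afterpulsing, background and autofluorescence,
bleaching, dye diffusion kinetics inside the axon, motion, and
multi-exponential photophysics — so recovery percentages quoted by the test
suite are not error bars for microscope data. The optional Gaussian IRF
blur and the configurable lifetimes exist precisely to probe robustness to
such deviations.

Problem sizes used by the test suite and the reproduction script (chosen as
a desk-scale study: enough photons and seeds for the assertions' tolerances
while keeping a full run in minutes): 10⁶-photon calibration histograms on
a 7-level ladder; 10⁵ photons per 7-ms analysis bin for recovery checks
(20 seeds per condition); a 3 × 3 (resting × evoked) scenario grid of
545-ms trials; 200-run power and 2000-run type-I simulations for the
statistics; 10-cycle stability series.

## 7. Known limitations

* The two-state decay model makes NTC exactly hill-1 logistic; real OGB-1
  calibrations need the free slope the fitter already provides.
* The delta-method uncertainty ignores origin-detection noise and the
  max-selection in peak smoothing; it is accurate to tens of percent, and
  intended for weighting and flagging, not for formal inference.
* Cube-level pooling of repeated trials assumes stationarity across trials;
  an estimate-level average is available but the pooled-cube route is the
  default because it preserves Poisson statistics at low counts.
* The statistics module treats boutons as the experimental unit with cell
  as a fixed factor; no mixed-effects or animal-level clustering is
  attempted.
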