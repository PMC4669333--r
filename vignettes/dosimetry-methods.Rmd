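---
title: "Methods: whole-body PET internal dosimetry in petdosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body PET internal dosimetry in petdosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petdosim)
```

## Scope and model

`petdosim` estimates human organ absorbed doses for a positron-emitting
radiotracer from dynamic whole-body PET biodistribution data, following
the MIRD schema. The chain is:

1. **Acquisition timing.** A whole-body frame is a sweep over bed
   positions (default: 8 frames × 5 beds, 12-s inter-bed gap, frame
   starts 0–106 min, per-bed times 15–300 s growing to offset decay).
   Every measurement is referenced to its bed midtime; organs spanning two
   beds use the midpoint of the two midtimes.
2. **TACs.** Reconstructed VOI totals arrive decay-corrected to injection
   time. Each frame is recovery-corrected by the ratio of the whole-body
   VOI to the injected activity, the decay correction is reversed at the
   midtime, and the result is divided by the injected activity, giving the
   physical fraction of injected dose per organ and time.
3. **Residence times.** Trapezoid integration from injection (a (0, 0)
   point is prepended — activity is zero at injection; the blood curve
   already carries a pre-injection zero) to the last frame, plus a tail
   `f_last / lambda_p` that assumes purely physical decay afterwards.
   Ignoring further biologic clearance is deliberately conservative.
4. **Special organs.** Bladder: increase-to-maximum fit
   `F (1 - e^{-lambda_b t})` to the decay-corrected cumulative curve
   (no voiding occurs during the scan), then a dynamic voiding model
   (below). Blood: whole-blood curve = per-gram samples × blood mass
   (5.4 % of body mass); red marrow takes `0.19/(1-0.39)` of the blood
   residence time (marrow blood fraction over 1 − hematocrit), the spleen
   1.5 %. Remainder: `T_1/2 / ln 2` minus all measured entries — the set
   then sums to the theoretical maximum exactly, which the code asserts.
5. **Doses.** `D(T) = sum_S tau(S) S(T<-S)` through a user-supplied or
   bundled S-value matrix; sphere-model self-dose for salivary glands;
   ICRP-60 effective dose and ICRP-26 effective dose equivalent.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| half-life (F-18) | 109.77 | min | decay bookkeeping everywhere |
| positron yield / mean beta energy | 0.967 / 0.2498 | – / MeV | sphere-model energy per decay |
| injected activity | 24.93 | MBq/kg | typical preclinical NIS-tracer dose |
| blood mass fraction | 0.054 | – | whole-blood conversion of per-gram draws |
| marrow rule constants | 0.19, 0.39 | – | hematocrit-based marrow blood share |
| spleen blood share | 0.015 | – | spleen share of blood residence time |
| voiding interval | 2.4 | h | standard dynamic-bladder assumption |
| gland masses | 18, 9.9 | g | parotid / submandibular (per-gland, unit density) |
| sphere-fit mass grid | 1–100 | g | range bracketing salivary glands |
| gonad rule | mean | – | hermaphrodite-phantom convention is ambiguous; the mean of testes/ovaries is the neutral choice, and all four options are exposed |
| recovery normalisation | injected | – | whole-body VOI over injected activity; `first_frame` provided as the alternative reading |

The note about the maximum residence time: with 109.77 min the theoretical
total is 2.6394 h; published work rounding the half-life to 1.83 h prints
2.635–2.640 h. Tolerances of ±0.5 % absorb this everywhere.

## The dynamic bladder model

Urine enters the bladder at the biologic rate `F lambda_b e^{-lambda_b t}`
(physical inflow `F lambda_b e^{-(lambda_b+lambda_p)t}`); content decays
physically and is reset to zero at every multiple of the voiding interval.
Within interval *k* the content is
`A(t) = F e^{-lambda_p t}(e^{-lambda_b t_k} - e^{-lambda_b t})`, whose
integral is closed-form; intervals are summed until a term falls below
1e-12. Properties verified in the tests: the no-voiding limit equals
`F lambda_b / (lambda_p (lambda_b + lambda_p))`; instantaneous filling
with no voiding gives `1/lambda_p`; the residence time decreases strictly
as the voiding interval shortens; and the closed form agrees with an
independent explicit time-stepping simulation (dt = 0.1 s) to better than
0.1 %.

The inflow fraction `F` defaults to the fitted plateau; the alternative
`stomach_complement` mode sets `F = 1 −` stomach fraction at scan end
(complete urinary clearance except for gastric trapping). The mode used is
recorded in the run log.

## The sphere model

Salivary glands are absent from the reference adult phantom, so their
self-dose uses a unit-density sphere of the gland mass with uniform
activity: `d = (Delta_beta · phi_beta + Delta_gamma · phi_gamma(m)) / m`,
`Delta_beta = 0.2498 × 0.967` MeV/decay, `Delta_gamma = 2 × 0.511 × 0.967`
MeV/decay. `phi_beta = 1` (the positron range is millimetres against
centimetre-scale spheres). For `phi_gamma` no published 511-keV
sphere absorbed-fraction table is redistributable here, so the package
uses a mean-chord exponential-absorption approximation
`phi_gamma = 1 - exp(-mu_en · 3r/4)` with `mu_en/rho = 0.0330` cm²/g
(water, 511 keV), flagged as approximate. Two external consistency checks
pass: the coefficients implied by dividing published gland doses by
published gland residence times (8.8 and 15.7 mGy/(MBq·h) at 18 and
9.9 g) are matched within ~2 %, and the fitted power-law exponent over
1–100 g is −0.960, inside the self-dose-dominated expectation
[−1.05, −0.85]. Doses are `a·m^b × tau`, with the log-log fit exact for
power-law inputs.

## Effective-dose conventions

ICRP-60 weights with: colon = 0.57·ULI wall + 0.43·LLI wall (mass
weights); esophagus surrogated by thymus; gonads per the configured rule;
remainder (w = 0.05) as the mass-weighted mean dose of adrenals, brain,
small intestine, kidneys, muscle, pancreas, spleen, thymus and uterus
(stylised-phantom masses). ICRP-26: gonads 0.25, breast 0.15, marrow and
lung 0.12, thyroid and bone surface 0.03, plus the five highest-dosed
remaining organs at 0.06 each — skin is excluded (as ICRP-26 excludes
skin and lens from the remainder), as are total body and non-phantom
sphere-model organs. Applied to the bundled reference dose table these
conventions reproduce the published 2.47e-2 mSv/MBq (ICRP-60, within 1 %
for the mean-gonad rule and 5 % for every rule) and 2.21e-2 mSv/MBq
(ICRP-26, within 4 % for every rule).

## What the synthetic generator emulates — and does not

The generator (`make_phantom`, `sample_biodistribution`, `sample_blood`)
produces the kinetic *structure* the analysis assumes: early vascular
peaks with washout (heart contents, lungs, kidneys, brain — the brain
keeps a small constant component for residual blood pool/choroid-plexus
trapping), accumulation to a plateau (stomach largest, salivary glands,
olfactory mucosa, esophagus), a stable thyroid fraction, cumulative
bladder filling, and a declining bi-exponential blood curve sampled at the
standard draw times with a pre-injection zero. Activities are emitted as a
reconstruction would report them (decay-corrected), scaled by a per-frame
recovery fraction, with mean-one multiplicative log-normal noise on VOI
totals (VOIs aggregate many voxels, so relative Gaussian-like error is the
right default; voxel-level Poisson simulation is out of scope). Identical
(configuration, seed) pairs give bit-identical datasets.

Parameter choices that were genuinely open: amplitudes and biologic rates
are plausible-shape values, *not* fits to any published figure. The fast
vascular components use biologic half-times of 6–10 min rather than 1–3
min: a feasibility scan of the default sampling grid showed that the
trapezoid estimator's convexity bias for 2-min components exceeds 6 %,
which would contradict the generator's contract that noise-free estimates
recover the closed-form residence times within 5 % on the default
schedule. The slow components use 15–30 min half-times so that the
physical-decay-only tail (which ignores ongoing biologic clearance) stays
a small overestimate. These were fixed once, before the tests were
written, and are not tuned thereafter.

A green synthetic test therefore establishes that the *estimators* are
correct and stable — not that the defaults reproduce any real animal's
numbers. Real-data effects deliberately absent: partial-volume and
spill-over beyond the global recovery scaling, motion, reconstruction
bias, inhomogeneous organ uptake, anaesthesia effects on NIS organs.

## Numerical choices

- Trapezoid integration prepends (0, 0) only when the first sample is
  after injection; blood curves already include the t = 0 draw.
- The bladder fit profiles `F` out analytically (linear for fixed
  `lambda_b`) and optimises the 1-D profile with `stats::optimize`
  (tol 1e-12) on [1e-4, 200] /h — robust to poor starts, exact on
  noiseless data to ~1e-7. An all-zero curve returns `F = 0` flagged
  `unidentifiable`; a decreasing trend warns.
- The voiding sum truncates when an interval contributes < 1e-12 h.
- Recovery > 1.05 warns (calibration drift) on real data; the simulated
  path suppresses that warning since its noise is known.
- A negative remainder (organ set exceeding the theoretical total) is an
  error, not a clamp.

## Known limitations

- The bundled S-value matrix is synthetic (deterministic, physically
  plausible, labelled as such); absolute organ doses from the default
  configuration exercise the machinery and are not phantom-accurate.
  Supply a real phantom matrix as CSV for production use.
- The sphere-model photon absorbed fraction is an analytic approximation
  (above), adequate at the few-percent level for gram-to-hectogram masses.
- No NIfTI I/O: voxel-mode inputs are in-memory arrays; file interchange
  is CSV/JSON.
- Single-nuclide (beta/photon) weighting: mSv/MBq equals mGy/MBq
  numerically; no radiation weighting beyond 1 is implemented.
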