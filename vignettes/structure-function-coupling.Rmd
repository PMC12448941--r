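---
title: "Methods: linking LFP transmission features to diffusion tractography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking LFP transmission features to diffusion tractography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`lfpcoupling` quantifies how intrinsic signal transmission between deep-brain
nuclei, measured from depth-electrode local field potentials (LFPs), relates
to the microstructure of the white-matter pathways connecting them, measured
by diffusion tractography. The pipeline has four stages:

1. **Conditioning** of multichannel depth recordings: harmonic notch
   filtering, high-pass filtering, and an adjacent-contact bipolar montage.
2. **Transfer-function estimation** between every ordered pair of bipolar
   channels, and extraction of two transmission features — maximum gain and
   the peak-to-floor (PF) ratio.
3. **Structural summaries** per pathway: fractional anisotropy (FA), axial
   diffusivity (Ad), fibre count per unit area (N), and fibre length (L).
4. **Association**: a linear mixed-effects (LME) model per transmission
   outcome with a random intercept per subject, preceded by outlier and
   peak-frequency filters and a variance-inflation-factor (VIF)
   collinearity screen.

Because clinical depth recordings and patient imaging cannot be
redistributed, the package ships a first-class synthetic-data module that
generates all three kinds of input with known ground truth, so every stage
is testable end to end.

# Signal model and conditioning

A recording session is a channels-by-time matrix at a single sampling rate
(clinical systems sample these leads at 24 kHz) with per-channel metadata:
subject, hemisphere, lead, anatomical region, and contact index along the
lead shaft.

**Notch filtering.** Mains contamination at 60 Hz and its harmonics
(120–360 Hz, i.e. five harmonics above the fundamental) is removed with a
cascade of second-order constrained IIR notches. Each biquad has quality
factor `q = 30` (bandwidth `f0/30`), and the cascade runs forward-backward,
so the net phase shift is zero. At this `q`, frequencies 5 Hz or more away
from any notch are altered by well under 0.5 dB, while each notch attenuates
its target far beyond 20 dB.

**High-pass filtering.** Drift is removed with a 4th-order Butterworth
high-pass at 1 Hz, also applied forward-backward. A decade above the cutoff
the gain is within 1% of unity. One numerical caveat, stated because it sets
test tolerances: a 4th-order recursion with a cutoff three decades below the
sampling rate is ill-conditioned in transfer-function (b, a) form, so DC
rejection is finite (≈0.1–0.5% residual) rather than exact.

**Bipolar montage.** Within each lead, contacts are sorted by contact index
and neighbouring contacts are subtracted (derived channel *k* =
contact*k* − contact*k+1*). Any component shared by the whole lead —
reference drift, volume-conducted common mode — cancels exactly, to machine
precision. "Adjacent" is defined along the shaft ordering carried by the
metadata; the physical 2–3-contacts-per-row geometry of real leads is not
reconstructed, because contact coordinates are not part of the session
container. Single-contact leads are skipped with a warning.

**Decimation.** All analysis features live far below 1 kHz, so sessions are
decimated (8th-order Butterworth anti-alias at 80% of the target Nyquist,
zero phase, default factor 8: 24 kHz → 3 kHz) before spectral estimation.
The decimated Nyquist must stay above a configurable analysis band
(`min_band`, default 500 Hz).

# Empirical transfer functions

For an ordered pair of bipolar channels (x → y) the frequency response is
estimated as

$$H(\omega) = \frac{\mathrm{CPSD}(x, y)}{\mathrm{PSD}(x) + \varepsilon},$$

with Welch-averaged spectra: Hann windows, 50% overlap, segment length
4 s at the decimated rate (0.25 Hz resolution). The 0.25 Hz grid is chosen
so that the 1.5 Hz peak-frequency exclusion applied later sits on a
meaningful grid. The regularizer defaults to
$\varepsilon = 10^{-6}\,\mathrm{median}\,\mathrm{PSD}(x)$ — small enough to
leave the response untouched wherever the input has power, large enough to
keep $|H|$ finite everywhere. Only the magnitude is analysed; phase and
delay are out of scope.

From $|H(\omega)|$ four quantities are extracted:

* **Peak gain** $|H(\omega_p)|$, the grid maximum (reported both linear and
  in dB), and its frequency $\omega_p$.
* **DC gain**, the magnitude at the lowest grid frequency. True DC is
  unobservable behind the 1 Hz high-pass; the 0 Hz Welch bin is the
  operational stand-in.
* **Roll-off frequency** $\omega_f$: the first frequency at which the
  magnitude falls 3 dB below the DC gain (half power). The crossing is
  located by linear interpolation of log-magnitude between the straddling
  bins; the first downward crossing is used, with ties broken toward the
  lower frequency. A response that never crosses −3 dB (e.g. flat or
  rising) yields an `NA` roll-off and PF ratio with an explicit
  `rolloff_defined = FALSE` flag, not an error.
* **PF ratio** $\log_{10}(|H(\omega_p)| / |H(\omega_f)|)$, the
  peak-to-floor transmission statistic. When the peak sits at DC this is
  3/20 = 0.15 by construction.

Per pathway (ordered region pair, within hemisphere), features are computed
for every bipolar channel pair and aggregated by a configurable reducer.
The default is the mean over pairs (undefined roll-offs excluded); median
and max are provided because the field has no canonical choice. Per-pair
records are always retained for audit.

Maximum gain is stored both as linear magnitude and in dB, and the PF ratio
in log10 units, so either reporting convention can be reproduced downstream.

# Structural measures

Diffusion tensors enter pre-fitted, as symmetric 3×3 matrices or eigenvalue
triples; no tensor fitting from raw diffusion signals, tracking, or
registration is performed. From sorted eigenvalues
$\lambda_1 \ge \lambda_2 \ge \lambda_3$:

$$FA = \sqrt{\tfrac12}\,
  \frac{\sqrt{(\lambda_1-\lambda_2)^2 + (\lambda_2-\lambda_3)^2 +
  (\lambda_3-\lambda_1)^2}}{\sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}}
  \in [0, 1],$$

with 0 isotropic and 1 the degenerate single-axis limit; axial diffusivity
is $\lambda_1$. Fibre length is the polyline arc length; fibre density N is
the streamline count divided by the effective seed area, fixed to the disc
of the 3 mm effective micro-contact diameter
($\pi \cdot 1.5^2 \approx 7.07$ mm²). Per-pathway FA and Ad are unweighted
means over per-streamline tensor samples — the simplest defensible reducer;
length- or volume-weighting is deliberately not applied because no weighting
scheme is canonical at the tract level. Eigenvalue units are treated as
given (mm²/s in whatever power-of-ten convention the source uses); FA is
scale-invariant, so the convention only affects Ad's scale.

# Association stage

The central fit, `tf_coupling()`, consumes one row per (subject,
hemisphere, pathway) carrying the four structural measures and the two
transmission outcomes, and proceeds:

1. **Observation filters** (single pass): per subject, rows whose outcome
   features lie beyond 3 SD from that subject's mean are removed; rows
   whose peak-gain frequency is below 1.5 Hz are removed, because the
   response near the 1 Hz high-pass cutoff is distorted. Means and SDs are
   computed once on the incoming table — iterative re-trimming would change
   the sample unpredictably — which makes the filter idempotent on its own
   output. The SD rule screens the outcome features, not the predictors;
   both the multiplier and the feature list are configurable. Every removal
   is logged with its reason.
2. **Collinearity screen**: VIFs over the candidate predictors (FA, Ad, N,
   L), threshold 5. FA and Ad are mechanically related through the tensor
   eigenvalues and always flag together; the default policy drops Ad and
   retains FA, the more interpretable integrity measure. A generic
   largest-VIF policy is available; perfectly collinear predictors report
   `Inf` rather than raising.
3. **Mixed-effects fits**: for each outcome, REML estimation of
   `outcome ~ fa + n_per_area + length + (1 | subject)` via `lme4`, with
   coefficient t-tests on Satterthwaite degrees of freedom via `lmerTest` —
   established machinery rather than a hand-rolled approximation. 95%
   confidence intervals use the Satterthwaite-df t quantile. Slope p-values
   are Bonferroni-adjusted; the default multiplier is the number of
   retained fixed-effect slopes (3), applied per outcome, since no
   convention across outcomes is universal. Boundary fits (zero
   random-intercept variance) are allowed and reproduce ordinary least
   squares; a single-subject table falls back to OLS with a notice.

R² is reported as **marginal** R²: the variance of the fixed-effect
predictions over fixed + random-intercept + residual variance. This choice
is stated explicitly because "R²" for mixed models is ambiguous
(conditional R² and squared correlations are other common readings); the
variance components needed to compute the alternatives are all stored on
the fitted object.

# The synthetic-data module

The generator is the package's stand-in for patient recordings and imaging;
its defaults encode the study scale the pipeline targets.

**LFP sessions.** Two leads (regions "GPi" and "VoaVop" by default), four
contacts each, 60 s at 24 kHz. Neural sources are 1/f ("pink") noise —
matching the spectral slope of real LFP; a white option exists because the
slope affects Welch variance but not the estimator's expectation. Desired
bipolar-level signals are telescoped into contact-level signals along each
shaft, so the montage recovers them exactly; the second lead's bipolar
signals are the first lead's sources passed through known resonant
band-pass filters (first-order Butterworth band-pass, quality factor 5,
peak magnitudes 2/3/1.5 at 12/20/30 Hz by default, rescaled so the
dense-grid peak equals the nominal gain exactly). The narrow band matters:
a maximally-flat passband has no well-defined peak frequency, whereas a
Q = 5 resonance pins the peak to within one Welch bin. Contamination is
added last: a shared per-lead common-mode component, independent per-contact
sensor noise, and 60 Hz mains plus harmonics with per-contact amplitude and
phase jitter (so the notch stage, not just the montage, is exercised). The
generating filters, with their analytic peak gain and peak frequency, are
returned as ground truth.

**Tract sets.** Prolate tensors ($\lambda_2 = \lambda_3$) are solved in
closed form from $\lambda_1$ (default 1.35) and the target FA, then
perturbed by a lognormal scale jitter (SD 0.05) — FA is scale-invariant, so
every streamline hits the target FA to 1e-9 while Ad varies realistically.
Streamlines are smooth random walks with arc length drawn uniformly in the
10–200 mm tracking window. A zero-streamline set is a valid "no connection"
object.

**Coupled datasets.** 12 subjects × 73 pathway rows (~880 observations)
by default. FA is uniform on [0.2, 0.6] — a plausible spread for
pallidothalamic tracts; Ad is derived from FA at a mean diffusivity of 0.7
with 5% lognormal jitter, which makes the FA–Ad sample correlation ≈ 0.9
arise mechanically from tensor geometry rather than from an arbitrary
correlation knob. N comes from a Poisson(45) count over the contact disc,
and lengths are uniform on 12–25 mm (tract-scale, inside the tracking
window). Outcomes follow the generating mixed model
$y = \beta_0 + \beta_{FA} FA + \beta_N N + \beta_L L + b_i + \epsilon$
with independent random effects per outcome. The default fixed effects are
(34.63, 6.12, 1.44, −0.01) for the PF-ratio outcome and
(26.31, 6.77, 1.19, 0.0) for maximum gain — the coefficient scale this
analysis operates on. The random-intercept SD (2) and residual SD (4) are
set so that subject clustering is visible (ICC ≈ 0.2) and the FA effect is
detectable but noisy — moderate-noise conditions under which the
mixed-effects machinery, not the data, must do the work. With these
defaults, 200 replicate fits show β_FA bias around 1% and 95% CI coverage
of ~0.95.

**What the generator does not emulate** — and hence what green tests do
*not* establish about clinical data: non-stationarity and state changes
during recording, movement and electrode artifacts beyond stationary
common-mode noise, nonlinear or time-varying transmission, real lead
geometry (contact rows around the shaft), crossing-fibre effects on the
tensor model, and any systematic structure-function miscoupling. Raw
diffusion-weighted images are never simulated; tensors enter at the
eigenvalue level.

# Numerical choices and degenerate inputs

* Welch segments are mean-detrended and Hann-windowed (periodic window);
  one-sided densities double interior bins.
* `epsilon = 0` is allowed but raises a division-degeneracy error when the
  input has zero-power bins.
* An all-zero magnitude raises a degenerate-response error; a flat response
  returns undefined roll-off, not an error.
* Filtering uses odd-reflection edge padding (3 × filter order) before the
  forward-backward pass, so record ends are usable.
* FA is clamped to [0, 1] against last-bit roundoff at the closed bounds;
  an all-zero triple is a domain error.
* The closed-form prolate solve switches to its analytic limit at
  FA² = 1/2 to avoid the removable singularity; target FA = 1 is rejected
  (it requires degenerate zero eigenvalues).
* Tensor symmetry is checked to a relative 1e-8 before eigendecomposition.
* Seeds: every generator takes an explicit integer seed and restores the
  caller's RNG state; the pipeline derives stage seeds as small offsets of
  the run seed. Identical configuration and seed reproduce every product
  byte-for-byte, including `report.json`.

# Test and pipeline problem sizes

Unit tests run the generators at 2 kHz / 10–30 s (always ≥ 2¹⁴ samples)
and 4–10 subjects, sizes chosen as the smallest at which Welch variance and
mixed-model stability leave clean margins around the assertions. The
parameter-recovery study uses 200 seeded replicates at the full default
scale (12 × 73). The estimator-versus-oracle checks use ≥ 60 Welch
averages at 0.25 Hz resolution, where residual Welch bias on a smooth
band-pass response is well under the 5% assertion.

# Known limitations

* The transfer function assumes linear time-invariant transmission; brain
  dynamics are neither, and the estimator characterizes only the LTI
  component. Phase/delay information is computed but deliberately unused.
* A large gain between two sites does not by itself imply directed
  transmission through the connecting tract — a common driver produces the
  same signature; the association stage is correlational by design.
* The along-shaft reading of "adjacent contacts" is one of two defensible
  montage definitions (the other being within-row neighbours); it is the
  one the metadata supports.
* The supported signal format is the package's own serialized session
  container plus TSV tables; clinical-format ingestion (e.g. EDF) is out
  of scope for this package and would slot in at `read_session()`.
* Single-pass outlier trimming is one of several reasonable conventions;
  the multiplier, feature set and pass structure are all visible in the
  audit log, so the choice is checkable.
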