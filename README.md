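# lfpcoupling

Structure–function coupling of deep-brain LFP signal transmission and
diffusion tractography.

## The problem

Depth electrodes implanted for deep-brain-stimulation (DBS) evaluation
record local field potentials (LFPs) from basal-ganglia and thalamic
nuclei (GPi, STN, VIM, VoaVop, VA, ...). The same patients undergo
diffusion tensor imaging, from which the white-matter tracts connecting
those nuclei can be reconstructed and characterized. The scientific
question this package operationalizes: **does the microstructural
integrity of a tract predict how strongly intrinsic neural activity is
transmitted and amplified along it?**

It is written for electrophysiologists and imaging researchers who have
(a) multichannel depth recordings with lead/contact/region metadata and
(b) tract-level diffusion summaries, and who want a tested, reproducible
path from raw signals and tensors to a mixed-effects coupling analysis.
Because clinical recordings cannot be redistributed, a seeded
synthetic-data module generates all inputs with known ground truth, so
the entire pipeline runs — and is tested — without any patient data.

## The method

**Functional side.** Recordings are notch-filtered at 60 Hz and its
harmonics (120–360 Hz), high-pass filtered at 1 Hz, re-referenced to an
adjacent-contact bipolar montage (which cancels lead-wide common-mode
noise exactly), and decimated. For each ordered pair of bipolar channels
the empirical transfer function is estimated by Welch cross-spectral
averaging:

    H(w) = CPSD(x, y) / (PSD(x) + eps)

Two transmission features summarize the magnitude response |H(w)|:

* **maximum gain** |H(wp)| — the peak amplification, at frequency wp;
* **PF ratio** log10(|H(wp)| / |H(wf)|), where the roll-off frequency wf
  is the first point 3 dB below the DC gain (half power).

**Structural side.** From sorted tensor eigenvalues l1 >= l2 >= l3:

    FA = sqrt(1/2) * sqrt((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2)
                   / sqrt(l1^2 + l2^2 + l3^2)

plus axial diffusivity Ad = l1, fibre count per unit area N
(streamlines / contact-disc area), and fibre length L (polyline arc
length).

**Association.** Per outcome (PF ratio, maximum gain), a REML linear
mixed-effects model

    outcome ~ FA + N + L + (1 | subject)

after per-subject 3-SD outlier removal, exclusion of observations whose
gain peak lies below 1.5 Hz, and a VIF collinearity screen that drops Ad
(mechanically collinear with FA). Coefficient t-tests use Satterthwaite
degrees of freedom (`lmerTest`); slope p-values are Bonferroni-adjusted;
marginal R² is reported.

## Worked example

Simulate the default subject-clustered dataset (12 subjects × 73 pathway
observations, generating fixed effects (34.63, 6.12, 1.44, −0.01) for
the PF-ratio outcome) and fit the coupling model:

```r
library(lfpcoupling)

cfg <- sim_config()
dat <- simulate_coupled_dataset(cfg, seed = 7)
fit <- tf_coupling(dat$observations)
fit
#> Structure-function coupling model (random-intercept LME)
#>   observations: 873 (3 filtered out), subjects: 12
#>   fixed effects: fa, n_per_area, length  [dropped collinear: ad]
#>   pf_ratio: marginal R^2 = 0.0832
#>   peak_gain: marginal R^2 = 0.0895

summary(fit)
#> Collinearity screen (VIF):
#>         fa n_per_area     length
#>      1.003      1.001      1.004
#> dropped: ad
#>
#> Outcome: pf_ratio  (n = 873, subjects = 12)
#>         term estimate         95% CI      t    df     p_adj sig
#>  (Intercept)   36.747 [33.87, 39.63] 25.303  99.9         -
#>           fa    5.524   [3.16, 7.89]  4.584 858.7 1.571e-05   *
#>   n_per_area    1.317   [1.05, 1.58]  9.778 858.4 5.285e-21   *
#>       length   -0.039  [-0.11, 0.03] -1.053 858.7    0.8779
#>   marginal R^2 = 0.0832; random-intercept SD = 2.82; residual SD = 4.02
```

Reading the output: three rows were filtered (outcome outliers or
low-frequency gain peaks, itemized in `fit$filter_audit`); Ad was
flagged by the VIF screen (FA–Ad correlation ≈ 0.9 in the generator, as
in real tensors) and dropped; the FA slope estimate 5.524 [3.16, 7.89]
brackets the generating value 6.12 and is significant after Bonferroni
adjustment, while fibre length is not.

The signal side runs the same way from a simulated session:

```r
sim <- simulate_lfp_session(cfg, seed = 1)     # 2 leads x 4 contacts
bip <- preprocess_session(sim$session)          # notch, HP, montage, decimate
pf  <- pathway_features(bip, "GPi", "VoaVop")   # all SISO pairs, aggregated
pf$aggregate
```

An end-to-end run (`run_pipeline(pipeline_config(seed = 1), "run")`)
writes `features.tsv`, `tracts.tsv`, `observations.tsv`, `report.json`,
a Table-2-style TSV, the filter audit, the ground truth, and the
resolved configuration into the run directory; identical configuration
and seed reproduce `report.json` byte-for-byte. A thin CLI over the same
functions lives at `inst/cli/lfpcoupling.R`
(`simulate | preprocess | tf | dti | associate | run-all`).

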