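# aslregsim

Simulation-based evaluation of arterial spin labeling (ASL) to T1-weighted
image registration, and of the regional perfusion statistics that depend on
it.

## The problem

ASL perfusion MRI yields low-resolution, low-SNR cerebral blood flow (CBF)
maps that must be aligned to a structural T1w image before any regional
analysis. How much do downstream results — inter-subject consistency of
cortical CBF maps, region-of-interest (ROI) hypoperfusion statistics in
patient groups — depend on the registration strategy? Answering that on real
data is hard because the true alignment is unknown. This package builds a
synthetic cohort in which the truth is known by construction: every phantom
participant has an analytic gray/white (GM–WM) boundary surface, a known
rigid ASL→T1w transform, a known regional hypoperfusion pattern, and a known
severity coupling. Against that ground truth it evaluates three registration
strategies:

* **manual** — an emulated interactive alignment: the true transform
  perturbed by operator error (default 1 mm / 1° per axis);
* **FLIRT-style rigid** — 6-DOF intensity-based registration of the mean CBF
  image to the T1w image (correlation-ratio cost, multi-resolution pattern
  search);
* **boundary-based refinement (BBR)** — starting from either of the above,
  minimises a cost integrated along the GM–WM boundary surface,
  `mean_v [1 − tanh(s·Q_v)]` with percent contrast
  `Q_v = 100 (I_out − I_in) / (½(I_out + I_in) + ε)` sampled at ±d mm along
  each vertex normal, giving the `manual+BBR` and `FLIRT+BBR` variants.

The pipeline around them implements the full experiment: pseudo-continuous
ASL (pCASL) forward simulation (14 label/control pairs, 64×64×34 at
3.75 mm, with a pair-cancelling "ringing" artifact), single-compartment
kinetic-model quantification

    CBF = 6000 λ ΔM e^{PLD/T1b} / (2 α T1b M0 (1 − e^{−τ/T1b}))

(τ = PLD = 1.8 s, α = 0.72, T1b = 1.65 s, λ = 0.9 mL/g), a quality
evaluation index (QEI) gate with strict threshold 0.4, projection of CBF to
the boundary surface, a 219-parcel surface parcellation, the pairwise
inter-subject Pearson-correlation (CC) consistency framework with
per-participant mean CC, and ROI-wise two-sample t-tests with Bonferroni
family-wise control plus per-ROI severity regressions.

## Worked example

```r
library(aslregsim)

cfg <- experiment_config(
  spec = phantom_spec(structural_shape = c(48, 48, 48), structural_spacing = 4,
                      seed = 42),
  n_per_group = c(control = 8, tau_like = 5, tdp_like = 5),
  seed = 42)
rep <- run_experiment(cfg)
print(rep)
```

prints (as produced by `analysis/03_cohort_experiment.R`):

```
experiment_report: 18 kept / 0 excluded by QEI / 0 registration failures
  manual       mean participant CC 0.3046
  manual+BBR   mean participant CC 0.7003
  FLIRT+BBR    mean participant CC 0.6992
```

Reading: with operator error larger than the automated residuals, the
emulated-manual registration produces much less consistent inter-subject
CBF maps (mean participant CC 0.30) than either BBR variant (0.70), and the
two BBR variants agree regardless of initialization — the qualitative
pattern the consistency framework is designed to expose. The same report
carries the ROI statistics: in this run the BBR-based methods recover all
5 injected tau-pattern parcels and all 8 TDP-pattern parcels at Bonferroni
pFWE < 0.05 while the manual registration finds only subsets (2 and 5).

The numbered scripts under `analysis/` run the full study: phantom and
acquisition checks (`01`), ground-truth registration recovery (`02`), the
cohort experiment above (`03`), and the statistical calibration of the ROI
engine (`04`). Each writes its tables under `results/`.

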