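# gridls — grid-like signal (hexadirectional) fMRI analysis

Entorhinal grid cells fire on a hexagonal lattice, and fMRI studies look
for their population signature as a 60-degree-periodic (6-fold) modulation
of BOLD activity by movement direction φ — the *grid-like signal* (GLS).
`gridls` implements the standard split-half, two-stage quadrature GLM
estimate of this signal, together with everything needed to validate it
end to end on data with known ground truth:

* **Trajectory generator** for passive virtual-navigation designs: 112
  translation segments balanced over 10° direction bins (3–4 per bin),
  shortest-arc rotations in [10°, 170°], a 160 × 160 vm room at 15 vm/s /
  50°/s, exactly 620 s per run, plus disc-and-cone coverage maps.
* **Synthetic BOLD** with planted k-fold modulation: voxel orientations
  von Mises-concentrated around a group orientation θ*, canonical
  double-gamma HRF, linear drift, AR(1) noise, optional midpoint
  orientation drift.
* **Two-stage GLM.** GLM1 on the estimation half with sin(kφ)/cos(kφ)
  parametric modulators gives per-voxel orientations
  θ_v = atan2(β₁, β₂)/k and amplitudes √(β₁² + β₂²), combined by
  amplitude-weighted circular averaging into φ̄; GLM2 on the test half
  scores cos(k(φ − φ̄)), and its voxel-mean coefficient is the
  cross-validated GLS magnitude. Folds 1, 5 and 7 run as controls through
  the identical machinery.
* **Stability & QC**: temporal stability (±15° across halves, 50% chance
  level), spatial stability (Rayleigh Z = nR̄² on kθ_v), tSNR screening
  (Q1 − 1.5 IQR fence).
* **Group statistics**: one-sided one-sample and Welch t tests, Cohen's d,
  two-sided JZS Bayes factors (Cauchy prior, r = √2/2 ≈ 0.707), Bonferroni
  families, Pearson correlations with Fisher-z intervals.

## Worked example

```r
library(gridls)

traj <- generate_trajectory(environment_config(), seed = 20101)
sim  <- simulation_config(group_orientation = 23, modulation_amplitude = 0.5,
                          orientation_concentration = 8, n_voxels = 20,
                          noise_sd = 1, mask_labels = rep(c("left", "right"), each = 10))
run  <- simulate_bold(traj, sim, seed = 42)

res <- run_participant(list(run), list(traj$events),
                       masks = list(left = 1:10, right = 11:20),
                       folds = c(5, 6, 7))
res$participant_level
```

```
  participant hemisphere fold   magnitude n_runs
1         p01       left    5 -0.09781524      1
2         p01      right    5 -0.14604686      1
3         p01       left    6  0.44192421      1
4         p01      right    6  0.48696353      1
5         p01       left    7 -0.03171259      1
6         p01      right    7 -0.03392990      1
```

The planted 6-fold amplitude (0.5) is recovered in both hemispheres, while
the 5- and 7-fold control analyses stay near zero. The per-cell table
(`res$cells`) also carries the estimated mean orientation `phi_bar` —
here 24.9°/22.2° against the planted 23° — and the resultant length of the
voxel orientations.

The numbered drivers under `analysis/` run the same machinery at cohort
scale and write their tables under `results/`:

1. `01_trajectory_design.R` — the two fixed run trajectories, their design
   statistics and coverage (≈ 78% of the room);
2. `02_simulate_cohort.R` — a 24-participant, two-group demo cohort through
   the full pipeline (group 6-fold tests significant at the Bonferroni
   0.025 threshold; controls not);
3. `03_parameter_recovery.R` — orientation recovery (median error 0.61° in
   60°-space at κ = 8, amplitude 0.5, noise SD 1) and fold specificity;
4. `04_stability_qc.R` — stability and tSNR summaries;
5. `05_group_statistics.R` — published statistics recomputed from printed
   (t, n) inputs, e.g. t(109) = 0.728 → one-sided p = 0.234, d = 0.07,
   bf01 = 7.31.

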