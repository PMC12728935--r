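# halopi

Tools for modelling **sigma-hole halogen–pi interactions** between
halobenzenes (C6H5X, X = Cl, Br, I) and benzene, the standard model for
the phenylalanine side chain. Directional halogen bonds onto aromatic
faces matter in medicinal chemistry, but accurate interaction energies
normally require correlated quantum chemistry (MP2/triple-zeta level,
itself a validated stand-in for CCSD(T)). `halopi` implements the
machine-learning pipeline that replaces those calculations with a
feed-forward network over simple geometric descriptors, end to end:

* **Pose generation** — the systematic grid over one quadrant of the
  benzene plane (x, z in [0, 5] Å step 0.25; plane distances
  2.75–4.50 Å step 0.25; rotations about the C–X axis 0/45/90/135°;
  C–X tilts −40…40° step 10° about four in-plane axes;
  21·21·8·4·4·9 = **508,032 poses per halobenzene**) and the random
  test-set protocol (x, z in [−5, 5] Å, y in [1.5, 5] Å, tilt 0–60°).
* **Descriptors** — a 30-component vector: 24 sorted atom-pair
  distances (halogen, ipso and both ortho carbons, each to the six ring
  carbons), halogen/ipso-to-centroid distances, the perpendicular
  halogen-plane distance d(X···π-plane), and three angles including
  α(C–X···⊥π-plane), where 0° is ideal sigma-hole alignment. Exactly
  invariant under rigid motion and benzene relabelling.
* **Model** — hidden layers 64/32/16, Leaky-ReLU, Adam (initial
  learning rate 0.01, halved after 10 stagnant epochs down to 1e-4),
  batch 128, imbalance-weighted MSE with elastic-net penalties, early
  stopping; compiled training core (RcppArmadillo). Energies follow the
  supermolecular convention ΔE = E(complex) − E(donor) − E(acceptor) in
  kJ/mol, model error reported as ΔΔE = ΔE_calc − ΔE_pred.
* **Applicability domain** — Mahalanobis distance
  D_M(x) = √((x−μ)ᵀΣ⁻¹(x−μ)) in scaled feature space, thresholded at
  the 95th percentile of the training distances.
* **PDB mining** — finds halogenated aryl ligands (≥6 heavy atoms,
  halogen bonded to a planar 5/6-ring) within 5 Å of phenylalanine
  rings, applies the sigma-hole filters (α < 50°, d(X···ring) ≥ 1 Å,
  C–X pointing at the plane) and rebuilds matched halobenzene–benzene
  model complexes with the halogen matched exactly.
* **Surrogate energies** — an analytic stand-in for the ~1.4 M
  quantum-chemical single points (attractive well + cos² directionality
  + Born–Mayer wall + noise) so the whole pipeline trains and tests at
  desk scale; external QM energy tables drop in via `adduct_energy()` /
  `read_energy_table()`.

## Worked example

```r
library(halopi)

# an iodobenzene 3.3 Å above benzene, tilted 10°, offset 0.5 Å
cx <- build_pose(list(halogen = "I", x = 0.5, z = 0, d = 3.3,
                      y_rot = 0, tilt_axis = "x", tilt_dev = 10))
unlist(measure_pose(cx))
#> d_plane   alpha   r_off
#>     3.3    10.0     0.5
round(extract_features(cx)[c("d_x_b1", "d_x_b6", "d_x_plane",
                             "a_cx_normal")], 4)
#>      d_x_b1      d_x_b6   d_x_plane a_cx_normal
#>      3.4179      3.8029      3.3000     10.0000
surrogate_energy(cx, surrogate_params(sigma_noise = 0))
#> [1] -6.8867   # kJ/mol; negative = attractive
```

The nearest and farthest halogen–carbon distances (3.42 / 3.80 Å), the
plane distance and the tilt angle feed the network; −6.89 kJ/mol is the
surrogate adduct formation energy of this pose (a typical iodine
sigma-hole well; chlorine is shallower, bromine in between).

Training the published architecture on a reduced systematic grid
(52,272 poses, three halogens) recovers the noiseless surrogate with
held-out R² = 0.9994 and RMSE = 0.10 kJ/mol, and with 0.05 kJ/mol
simulated noise reaches RMSE = 0.13 kJ/mol — within 2.6× the noise
floor (numbers from `scripts/acceptance.R --seed 1`):

```r
poses <- data.table::rbindlist(lapply(c("Cl", "Br", "I"), function(h)
  enumerate_systematic(grid_spec(xz_step = 0.5, y_rotations = c(0, 90),
                                 tilt_axes = "x"), h)))
data.table::setattr(poses, "kind", "grid")
dat <- generate_dataset(poses, surrogate_params(sigma_noise = 0, seed = 2))
fit <- train_energy_model(dat, model_config(seed = 1))
fit$report$r2; fit$report$rmse
predict(fit$model, dat[1:5, ])           # kJ/mol
save_checkpoint(fit$model, "model.json")
```

Scanning PDB files:

```r
res <- scan_pdb("structures/", model = load_checkpoint("model.json"))
res$contacts[, c("ligand", "residue", "d_plane", "alpha", "pass",
                 "energy_pred", "relative_md")]
```

A command-line front end covers the same pipeline
(`generate-grid`, `generate-random`, `simulate-energies`, `train`,
`predict`, `evaluate`, `applicability`, `scan-pdb`); see
`inst/cli/halopi` and `run_cli()`.

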