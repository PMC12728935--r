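---
title: "Modelling sigma-hole halogen-pi interactions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sigma-hole halogen-pi interactions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Halogen bonds to aromatic pi-systems — a chlorine, bromine or iodine
substituent pointing its sigma-hole at the face of a phenylalanine ring —
are directional, pharmaceutically exploitable, and expensive to score:
reliable interaction energies require correlated quantum chemistry
(MP2 with a triple-zeta basis, itself standing in for CCSD(T)). `halopi`
implements the full machine-learning pipeline that replaces those
calculations with a feed-forward network over simple geometric
descriptors, for the halobenzene-benzene model system (benzene being the
standard surrogate for the phenylalanine side chain):

1. systematic and random rigid-body pose generation over the benzene
   plane (`grid_spec()`, `random_spec()`, `enumerate_systematic()`,
   `generate_random()`);
2. a 30-component translation/rotation-invariant descriptor
   (`extract_features()`), min-max scaled (`fit_scaler()`);
3. an energy regressor with the published architecture
   (`train_energy_model()`): hidden layers 64/32/16, Leaky-ReLU, Adam,
   initial learning rate 0.01 halved after 10 stagnant epochs down to
   1e-4, batch 128, weighted-MSE loss with elastic-net penalties, early
   stopping;
4. a Mahalanobis-distance applicability domain thresholded at the 95th
   percentile of the training distances (`fit_md()`, `flag_outliers()`);
5. a PDB miner that finds halogenated aryl ligands near phenylalanine
   rings, applies sigma-hole geometry filters, and rebuilds matched
   halobenzene-benzene model complexes (`scan_pdb()`).

Because the ~1.4 million MP2/TZVPP energies behind the original model
cannot be regenerated at desk scale, the package ships a synthetic
surrogate energy generator (`surrogate_energy()`, `generate_dataset()`)
with the same statistical structure, plus an ingestion path
(`adduct_energy()`, `read_energy_table()`) so user-supplied QM energy
tables can replace it without code changes.

## Coordinate and measurement conventions

The acceptor benzene is fixed with its ring in the xz-plane, centroid at
the origin, plane normal +y; donors always sit at y > 0 (benzene symmetry
makes the lower half-space redundant). A pose is parameterized by the
halogen position (x, d, z) — `d` being the perpendicular
halogen-to-plane distance — a rotation of the donor about its own C-X
axis, and a tilt of the C-X axis about an in-plane axis through the
halogen. `measure_pose()` reports `d_plane` (via the foot of the normal
through the halogen), `alpha` (the angle between the X-to-ipso-carbon
direction and the ring normal oriented toward the donor; 0 degrees is
ideal sigma-hole alignment, and the published geometry filters use the
same 0-is-ideal convention), and `r_off` (in-plane offset of the
halogen's foot point from the ring centroid).

Monomer geometries are idealized (C-C 1.39 A, C-H 1.08 A, C-X 1.74 /
1.90 / 2.10 A for Cl / Br / I) because the MP2-optimized coordinates
behind the published features are not distributed; all bond lengths are
arguments of the builders, and users with their own monomers can supply
XYZ files. Absolute feature values therefore differ slightly from the
original work; nothing downstream depends on the exact lengths.

## The descriptor

The 30 features are: the 6 halogen-to-ring-carbon distances, the
corresponding 6 distances from the ipso carbon and from each of the two
ortho carbons (24 atom-pair distances), the halogen- and
ipso-to-centroid distances, the perpendicular halogen-plane distance,
and three angles (C-X to ring centre, C-X to plane normal, ortho-ortho
vector to plane normal). The full published feature list lives in
supplementary material that is not part of the main text; the three
non-atom-pair distances here are the geometrically natural completion and
the schema is versioned (`xb30-v1`) so an alternative layout can be
swapped in.

Ring carbons are ordered by ascending halogen distance and the same
permutation is applied to every per-carbon block. Symmetric poses make
that sort ill-defined (on-axis poses tie all six halogen distances), so
ties are broken lexicographically by the ipso and then ortho distances,
with keys rounded at 1e-9 A so floating-point jitter from rigid motions
cannot flip genuinely tied columns. This makes the descriptor exactly
invariant under global rigid motion and under 60-degree self-rotations
of the benzene.

Scaled features are not clipped to [0, 1] at prediction time:
out-of-domain inputs are the applicability module's business. Feature
columns that are constant in the fit set (within 1e-9 relative) map to 0;
without that guard, a column constant up to rounding noise would be
amplified by ~1e14 and dominate every prediction.

## The surrogate energy generator

The generator emulates what the network must learn from real QM data,
with an analytic form in the pose measures:

E = -D_X exp(-(d - d0_X)^2 / 2 sigma_d^2) cos^m(min(alpha, 90)) \
    exp(-r_off^2 / 2 sigma_r^2) + A_rep * sum_ij exp(-r_ij / rho) + eps

with per-halogen depths D = 6/9/13 kJ/mol (Cl/Br/I) at optimum distances
3.1/3.2/3.3 A, radial width 0.45 A, lateral width 1.2 A, angular
exponent 2, a Born-Mayer wall (A_rep = 1e5 kJ/mol, rho = 0.3 A) summed
over all intermolecular atom pairs, and Gaussian noise of 0.05 kJ/mol
drawn once per dataset under the parameter seed. This preserves the
qualitative physics: directionality, a distance well, halogen ordering
Cl < Br < I, steep short-range repulsion, decay to zero at long range.

One consequence worth stating: at these parameters the repulsive wall
contributes ~8 kJ/mol at 3.1 A, so the shallow chlorine well is net
positive at its nominal d0 and only attractive at its displaced
effective minimum near 3.5 A. The tests assert the generator-computed
truth (ordering, attractive Br/I wells, an attractive Cl minimum) rather
than a nominal expectation; the parameters were set once and not tuned.

What a green test does establish: the published architecture and
schedule can recover a smooth, low-dimensional energy surface from the
descriptor to near the noise floor. What it does not establish: accuracy
on real MP2 data (electronic substituent effects, secondary pi-pi /
C-H-pi contributions, and the true repulsive wall shape are all absent
from the surrogate), nor the published headline numbers (validation
R^2 = 0.9979, RMSE = 0.158 kJ/mol), which require the original dataset.

## Training design

* **Splits.** Stratified by halogen crossed with the plane distance (the
  grid's own 8 distances, or 0.25 A bins for random data): 80/20
  train/test, then 80/20 train/validation inside the training part, and
  a stratified 5-fold assignment helper for cross-validation. Exact
  published split sizes are not reproduced (they are not exact 80/20
  arithmetic and depend on the original stratifier's internals).
* **Loss.** Weighted MSE plus small elastic-net penalties (1e-6). The
  published loss "addresses data imbalance" without printing its
  parameters. Raw inverse-frequency weights over 1 kJ/mol energy bins
  concentrate most of the loss mass on sparsely populated repulsive-wall
  bins and measurably degrade bulk accuracy (held-out RMSE ~0.21 kJ/mol
  on the noiseless surrogate instead of ~0.13). The default is therefore
  tempered: weights proportional to (inverse frequency)^0.5, with
  energies pooled above the +10 kJ/mol repulsion-exclusion threshold
  (beyond which predictions are filtered out in application anyway) and
  capped at 20x. Raw weighting is one configuration away
  (`imbalance_gamma = 1`, `imbalance_clip = NA`).
* **Schedule.** Adam from 0.01; halved after 10 epochs without
  validation improvement, floored at 1e-4 (the published rule). Early
  stopping is the package's own choice where the source is silent:
  patience 30 epochs, minimum improvement 1e-4 kJ/mol, restore best
  weights. The target is standardized internally for conditioning and
  mapped back at prediction; reported RMSEs are kJ/mol.
* **Determinism.** Weight init and shuffling run on a dedicated
  Mersenne-Twister stream seeded from the config; runs are
  bit-reproducible on one platform, not guaranteed across BLAS builds.

## Applicability domain

Mahalanobis distance in the scaled feature space, sqrt((x - mu)' Sigma^-1
(x - mu)), with a ridge of 1e-8 * trace/dim on the covariance (chosen
over a pseudo-inverse for determinism), constant columns dropped with a
warning, and the square-root form thresholded at the 95th percentile of
the training distances (threshold choices are monotone-equivalent
between root and squared forms). "Relative MD" — undefined in the source
beyond a colour scale — is distance divided by that percentile, so 1.0
marks the domain boundary.

## PDB mining

The scanner is deliberately geometric, not electronic: preprocessing
drops hydrogens, non-primary altLocs and metal ions; ligands are
hetero-compounds (not polymer building blocks) with at least 6 heavy
atoms; bonds are perceived at covalent-radius sum + 0.45 A; "aromatic"
means a planar 5/6-ring (RMS < 0.1 A) containing the halogen-bearing
carbon. Contacts use the nearest phenylalanine side-chain ring atom
within 5 A; the sigma-hole filters are alpha < 50 degrees, minimum
halogen-ring-atom distance >= 1 A, and a C-X ray directed toward the
plane. Matched-pair reconstruction places the canonical halobenzene with
the halogen matched exactly and the C-X direction and ring plane
aligned; the sign of the ligand ring normal is canonicalized from the
ring's cycle order so the reconstruction is deterministic and idempotent
(the two signs correspond to mirrored ortho-carbon assignments). The
benzene replaces the side chain ring (capped at the C-gamma/C-beta bond)
by centroid + plane + spin alignment referenced to the C-gamma direction,
which is RMSD-optimal for near-ideal rings up to ring symmetry.
Corpus-level counts from the published survey are shipped as data
(`inst/extdata/pdb_contact_survey*.csv`) because they are pinned to a
specific PDB snapshot; the scanner reproduces the procedure, and
engineered fixtures provide exact count tests. No automatic clash filter
is applied (the published exclusion of two clashing structures was not
quantified).

## Numerical choices and degenerate inputs

* Rotations validated orthonormal (det +1) within 1e-8; plane fits
  reject collinear rings; incomplete phenylalanine side chains are
  skipped with a log message rather than failing a whole scan.
* Random pose uniqueness: tuples agreeing within 1e-6 in all six
  parameters are duplicates and are resampled (rounded-key comparison);
  the tilt azimuth, unstated in the source protocol, is sampled
  uniformly in [0, 360) and recorded.
* The duplicated zero-tilt poses (once per tilt axis) are kept by
  default — the published per-halobenzene count of 508,032 requires
  them — with an off-by-default `dedupe` flag.
* The +10 kJ/mol repulsion filter uses <= (boundary kept); whether it
  also applied to the systematic training grid is unstated, so it is
  not applied there by default.
* Checkpoints serialize at 17 significant digits, which round-trips
  doubles exactly; a reloaded model predicts bit-identically.

## Known limitations

Only benzene acceptors (no histidine/tyrosine/tryptophan models); no
quantum chemistry, docking integration, or mmCIF parsing; the surrogate
is a stand-in whose parameters are stated, not fitted to QM data; PDB
parsing covers standard fixed-column ATOM/HETATM records only.
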