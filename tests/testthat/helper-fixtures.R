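# Shared fixtures: small pose specs, in-memory PDB atom tables and a cached
# quickly-trained model. Everything is generated in code at test time.

small_grid <- function() {
  grid_spec(xz_step = 2.5, distances = c(2.75, 3.5),
            y_rotations = c(0, 45), tilt_axes = c("x", "c45"),
            tilt_deviations = c(-40, 0, 30))
}

noiseless_params <- function(seed = 1) surrogate_params(sigma_noise = 0, seed = seed)

ref_pose <- function(halogen = "I", x = 0, z = 0, d = 3.0, y_rot = 0,
                     tilt_axis = "x", tilt_dev = 0) {
  build_pose(list(halogen = halogen, x = x, z = z, d = d, y_rot = y_rot,
                  tilt_axis = tilt_axis, tilt_dev = tilt_dev))
}

vec_angle_test <- function(a, b) {
  180 / pi * acos(min(1, max(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
}

random_rigid_transform <- function() {
  # proper rotation via QR of a random matrix
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  rigid_transform(q, stats::rnorm(3, sd = 5))
}

transform_complex <- function(cx, tr) {
  cx$donor <- apply_transform(cx$donor, tr)
  cx$acceptor <- apply_transform(cx$acceptor, tr)
  cx
}

# ---- PDB fixture machinery ------------------------------------------------

# one PHE side-chain ring (+ CB) centred at `center`, ring in the xz-plane
phe_atoms <- function(center, serial0, resseq, chain = "A") {
  ring <- sweep(build_benzene()$coords[1:6, ], 2, -center)
  cb <- ring[1, ] + c(1.0, -1.2, 0)
  data.table::data.table(
    record = "ATOM", serial = serial0 + 0:6,
    name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CB"),
    altloc = "", resname = "PHE", chain = chain, resseq = resseq,
    x = c(ring[, 1], cb[1]), y = c(ring[, 2], cb[2]), z = c(ring[, 3], cb[3]),
    element = "C")
}

# halobenzene ligand posed against that PHE ring; flip = TRUE points the C-X
# bond away from the plane (wrong-side rejection case)
ligand_atoms <- function(center, serial0, resseq, halogen = "Br",
                         x = 0, z = 0, d = 3.2, y_rot = 0, tilt_dev = 0,
                         flip = FALSE, chain = "A") {
  cx <- build_pose(list(halogen = halogen, x = x, z = z, d = d,
                        y_rot = y_rot, tilt_axis = "x", tilt_dev = tilt_dev))
  don <- cx$donor
  if (flip) {
    # rotate the donor 180 deg about the x-axis through its halogen, so the
    # C-X vector points away from the plane while X stays in place
    xp <- don$coords[1, ]
    don$coords <- sweep(sweep(don$coords, 2, xp) %*%
                          t(rotation_about(c(1, 0, 0), 180)), 2, xp, "+")
  }
  hv <- don$elements != "H"
  co <- sweep(don$coords[hv, , drop = FALSE], 2, -center)
  data.table::data.table(
    record = "HETATM", serial = serial0 + seq_len(sum(hv)) - 1L,
    name = c(toupper(halogen), paste0("C", 1:6))[seq_len(sum(hv))],
    altloc = "", resname = "LIG", chain = chain, resseq = resseq,
    x = co[, 1], y = co[, 2], z = co[, 3],
    element = toupper(don$elements[hv]))
}

# five-membered chloro-heteroaromatic ligand (thiophene-like) in a
# sigma-hole pose against the PHE ring at `center`
five_ring_ligand_atoms <- function(center, serial0, resseq, d = 3.2) {
  side <- 1.42
  r5 <- side / (2 * sin(pi / 5))
  th <- -pi / 2 + (0:4) * 2 * pi / 5
  ring <- cbind(r5 * cos(th), r5 * sin(th) + (1.74 + r5), 0)  # ipso at index 1
  cl <- c(0, 0, 0)
  coords <- rbind(cl, ring)
  coords[, 2] <- coords[, 2] + d          # halogen at height d over centroid
  coords <- sweep(coords, 2, -center)
  data.table::data.table(
    record = "HETATM", serial = serial0 + 0:5,
    name = c("CL", "C1", "C2", "C3", "S1", "C4"),
    altloc = "", resname = "L5R", chain = "A", resseq = resseq,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    element = c("CL", "C", "C", "C", "S", "C")[c(1, 2, 3, 4, 5, 6)])
}

# a multi-site fixture structure: K engineered passes, M engineered
# rejections, widely separated so contacts never mix
fixture_structure <- function() {
  sites <- list(
    # passes
    list(kind = "pass", halogen = "Br", d = 3.2, tilt_dev = 20, x = 0.5),
    list(kind = "pass", halogen = "I", d = 3.0, tilt_dev = 0, x = 0),
    list(kind = "pass", halogen = "Cl", d = 3.4, tilt_dev = 49.9, x = 0),
    # rejections: tilted beyond 50 deg, too close, wrong-side C-X
    list(kind = "fail_alpha", halogen = "Br", d = 3.2, tilt_dev = 55, x = 0),
    list(kind = "fail_close", halogen = "Cl", d = 0.8, tilt_dev = 0, x = 1.39),
    list(kind = "fail_flip", halogen = "I", d = 3.2, tilt_dev = 0, x = 0,
         flip = TRUE))
  atoms <- list()
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    center <- c(40 * i, 0, 0)
    atoms[[length(atoms) + 1L]] <- phe_atoms(center, 1000L * i, i)
    atoms[[length(atoms) + 1L]] <- ligand_atoms(
      center, 1000L * i + 100L, 500L + i, halogen = s$halogen, x = s$x,
      d = s$d, tilt_dev = s$tilt_dev, flip = isTRUE(s$flip))
  }
  list(atoms = data.table::rbindlist(atoms),
       n_pass = sum(vapply(sites, function(s) s$kind == "pass", TRUE)),
       n_fail = sum(vapply(sites, function(s) s$kind != "pass", TRUE)))
}

# cached small trained model for tests that need predictions
.halopi_test_env <- new.env(parent = emptyenv())
get_tiny_model <- function() {
  if (is.null(.halopi_test_env$model)) {
    spec <- grid_spec(xz_step = 1.25, y_rotations = 0, tilt_axes = "x",
                      tilt_deviations = c(-30, 0, 30))
    poses <- data.table::rbindlist(
      lapply(c("Cl", "Br", "I"), function(h) enumerate_systematic(spec, h)))
    data.table::setattr(poses, "kind", "grid")
    dat <- generate_dataset(poses, noiseless_params())
    # the reduced grid keeps the ortho-ortho angle constant, so fit_md
    # warns about dropping that column; expected here
    fit <- suppressWarnings(
      train_energy_model(dat, model_config(max_epochs = 60, seed = 5),
                         split_seed = 5))
    .halopi_test_env$model <- fit$model
  }
  .halopi_test_env$model
}
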