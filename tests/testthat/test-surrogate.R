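test_that("surrogate energy has the contracted limiting behaviour", {
  p <- noiseless_params()
  # decay to zero at long range
  expect_lt(abs(surrogate_energy(ref_pose("I", d = 30), p)), 1e-6)
  # steep repulsion at contact
  expect_gt(surrogate_energy(ref_pose("I", d = 1.0), p), 0)
  # halogen ordering at the nominal optima (generator-computed truth):
  # E_I < E_Br < E_Cl; iodine and bromine wells are attractive there, the
  # shallow chlorine well only at its displaced effective minimum
  d0 <- c(Cl = 3.1, Br = 3.2, I = 3.3)
  e <- vapply(names(d0), function(h)
    surrogate_energy(ref_pose(h, d = d0[[h]]), p), numeric(1))
  expect_lt(e[["I"]], e[["Br"]])
  expect_lt(e[["Br"]], e[["Cl"]])
  expect_lt(e[["I"]], 0)
  expect_lt(e[["Br"]], 0)
  e_cl_min <- min(vapply(seq(2.8, 5.0, 0.05), function(d)
    surrogate_energy(ref_pose("Cl", d = d), p), numeric(1)))
  expect_lt(e_cl_min, 0)
})

test_that("attractive term is monotone in the deviation angle", {
  p <- noiseless_params()
  a <- halopi:::surrogate_attraction(3.3, seq(0, 90, 5), 0, "I", p)
  expect_true(all(diff(abs(a)) <= 1e-12))
  expect_equal(halopi:::surrogate_attraction(3.3, 90, 0, "I", p), 0,
               tolerance = 1e-12)
})

test_that("surrogate energy is invariant under rigid motion of the complex", {
  set.seed(23)
  p <- noiseless_params()
  cx <- ref_pose("Br", x = 1, z = 0.5, d = 3.1, tilt_dev = 20)
  e0 <- surrogate_energy(cx, p)
  for (i in 1:5) {
    e1 <- surrogate_energy(transform_complex(cx, random_rigid_transform()), p)
    expect_equal(e1, e0, tolerance = 1e-9)
  }
  cx2 <- cx
  cx2$acceptor <- apply_transform(cx$acceptor,
                                  rigid_transform(rotation_about(c(0, 1, 0), 60)))
  expect_equal(surrogate_energy(cx2, p), e0, tolerance = 1e-9)
})

test_that("dataset generation is reproducible and matches the per-pose path", {
  p <- noiseless_params()
  spec <- small_grid()
  poses <- data.table::rbindlist(
    lapply(c("Cl", "I"), function(h) enumerate_systematic(spec, h)))
  data.table::setattr(poses, "kind", "grid")
  oracle_rows <- 2L * length(spec$x) * length(spec$z) *
    length(spec$distances) * length(spec$y_rotations) *
    length(spec$tilt_axes) * length(spec$tilt_deviations)
  dt <- generate_dataset(poses, p)
  expect_identical(nrow(dt), oracle_rows)
  expect_identical(dt, generate_dataset(poses, p))

  # dual route: vectorized table vs single-pose construction
  set.seed(5)
  for (i in sample(nrow(dt), 6)) {
    cx <- build_pose(as.list(poses[i, ]))
    expect_equal(as.numeric(extract_features(cx)),
                 as.numeric(dt[i, feature_names(), with = FALSE]),
                 tolerance = 1e-9)
    expect_equal(surrogate_energy(cx, p), dt$energy[i], tolerance = 1e-9)
  }
  # same on random poses
  rs <- generate_random(random_spec(n = 12, seed = 9), "Br")
  dr <- generate_dataset(rs, p)
  for (i in c(1L, 7L)) {
    cx <- build_pose(as.list(rs[i, ]))
    expect_equal(as.numeric(extract_features(cx)),
                 as.numeric(dr[i, feature_names(), with = FALSE]),
                 tolerance = 1e-9)
    expect_equal(surrogate_energy(cx, p), dr$energy[i], tolerance = 1e-9)
  }

  # noiseless energies are a pure function of the pose parameters: the
  # duplicated 0-deg tilts across axes carry identical energies
  zero <- dt[dt$tilt_dev == 0, ]
  key <- paste(zero$halogen, zero$x, zero$z, zero$d, zero$y_rot)
  spread <- tapply(zero$energy, key, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-12)

  # noisy generation is seeded: same seed identical, different seed not
  pn1 <- surrogate_params(sigma_noise = 0.05, seed = 4)
  pn2 <- surrogate_params(sigma_noise = 0.05, seed = 5)
  expect_identical(generate_dataset(rs, pn1), generate_dataset(rs, pn1))
  expect_false(identical(generate_dataset(rs, pn1)$energy,
                         generate_dataset(rs, pn2)$energy))
})

test_that("adduct energies follow the supermolecular difference", {
  expect_equal(adduct_energy(-10, -4, -5), -1)
  expect_equal(adduct_energy(0, 0, 0), 0)
  expect_equal(adduct_energy(-1, 0, 0, unit = "hartree"), -2625.4996)
  expect_error(adduct_energy(1, 1, 1, unit = c("hartree", "kJ/mol", "hartree")),
               "mixed")
  path <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(data.table::data.table(
    id = c("g1", "g2"), e_complex = c(-10, -1), e_halobenzene = c(-4, 0),
    e_benzene = c(-5, 0), unit = "kJ/mol"), path)
  tab <- read_energy_table(path)
  expect_equal(tab$energy, c(-1, -1))
  expect_identical(tab$source, rep("external", 2))
})

test_that("repulsion filter keeps the +10 kJ/mol boundary", {
  expect_equal(filter_repulsive(c(-5, 9.9, 10.0, 10.1)), c(-5, 9.9, 10.0))
  expect_identical(filter_repulsive(numeric(0)), numeric(0))
  expect_equal(filter_repulsive(c(-3, -1)), c(-3, -1))
  dt <- data.table::data.table(id = 1:4, energy = c(-5, 9.9, 10.0, 10.1))
  expect_identical(filter_repulsive(dt)$id, 1:3)
  expect_error(filter_repulsive(c(1, NA)), "non-finite")
})
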