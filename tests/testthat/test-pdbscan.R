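test_that("candidate detection applies size, bonding and aromaticity filters", {
  fx <- fixture_structure()
  cand <- find_halogen_aryl_ligands(fx$atoms)
  expect_identical(nrow(cand), fx$n_pass + fx$n_fail)
  expect_true(all(cand$ring_size == 6L))

  # five-heavy-atom chloro fragment: rejected by the size filter
  small <- data.table::data.table(
    record = "HETATM", serial = 1:5, name = c("CL", "C1", "C2", "C3", "C4"),
    altloc = "", resname = "SML", chain = "A", resseq = 1L,
    x = c(0, 1.74, 3.1, 4.4, 5.7), y = 0, z = 0,
    element = c("CL", "C", "C", "C", "C"))
  expect_identical(nrow(find_halogen_aryl_ligands(small)), 0L)

  # aliphatic chain chloride: six heavy atoms but no ring
  chain <- data.table::data.table(
    record = "HETATM", serial = 1:6, name = c("CL", paste0("C", 1:5)),
    altloc = "", resname = "ALI", chain = "A", resseq = 2L,
    x = c(0, 1.74, 2.5, 3.9, 4.7, 6.1), y = c(0, 0, 1.2, 1.2, 0, 0), z = 0,
    element = c("CL", rep("C", 5)))
  expect_identical(nrow(find_halogen_aryl_ligands(chain)), 0L)

  # hydrogens and alternative conformations are stripped before analysis
  noisy <- data.table::copy(fx$atoms)
  h <- noisy[1:3, ]
  h$record <- "HETATM"; h$serial <- 9000:9002; h$element <- "H"
  h$name <- "H1"; h$altloc <- c("", "B", "")
  expect_identical(nrow(find_halogen_aryl_ligands(rbind(noisy, h))),
                   nrow(cand))
})

test_that("contact search respects the 5 A nearest-ring-atom cutoff", {
  mk <- function(d) {
    rbind(phe_atoms(c(0, 0, 0), 1L, 1L),
          # halogen straight above the CG carbon: nearest ring distance = d
          ligand_atoms(c(0, 0, 0), 100L, 50L, halogen = "Br",
                       x = 1.39, z = 0, d = d))
  }
  at <- mk(4.9)
  ct <- find_pi_contacts(at, find_halogen_aryl_ligands(at))
  expect_identical(nrow(ct), 1L)
  expect_equal(ct$d_x_aa, 4.9, tolerance = 1e-9)
  at2 <- mk(5.1)
  expect_identical(nrow(find_pi_contacts(at2, find_halogen_aryl_ligands(at2))),
                   0L)

  # two PHE rings within range of one halogen: two contacts
  at3 <- rbind(phe_atoms(c(0, 0, 0), 1L, 1L),
               phe_atoms(c(0, 6.5, 0), 200L, 2L),
               ligand_atoms(c(0, 0, 0), 100L, 50L, halogen = "I", d = 3.3))
  ct3 <- find_pi_contacts(at3, find_halogen_aryl_ligands(at3))
  expect_identical(nrow(ct3), 2L)

  # incomplete side chains are skipped, with a log message
  at4 <- rbind(phe_atoms(c(0, 0, 0), 1L, 1L)[1:5, ],
               ligand_atoms(c(0, 0, 0), 100L, 50L, halogen = "I", d = 3.3))
  expect_message(
    ct4 <- find_pi_contacts(at4, find_halogen_aryl_ligands(at4)),
    "incomplete PHE")
  expect_identical(nrow(ct4), 0L)
})

test_that("sigma-hole filters implement the published cutoffs", {
  base <- data.table::data.table(alpha = 20, d_x_aa = 3, directional = TRUE)
  cases <- data.table::rbindlist(list(
    data.table::data.table(alpha = 49.9, d_x_aa = 3.0, directional = TRUE),
    data.table::data.table(alpha = 50.1, d_x_aa = 3.0, directional = TRUE),
    data.table::data.table(alpha = 20.0, d_x_aa = 0.9, directional = TRUE),
    data.table::data.table(alpha = 20.0, d_x_aa = 1.0, directional = TRUE),
    data.table::data.table(alpha = 20.0, d_x_aa = 3.0, directional = FALSE)))
  out <- apply_sigma_filters(cases)
  expect_identical(out$pass, c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("fixture scan reports exactly the engineered passes", {
  fx <- fixture_structure()
  ct <- apply_sigma_filters(
    find_pi_contacts(fx$atoms, find_halogen_aryl_ligands(fx$atoms),
                     structure_id = "fix"))
  expect_identical(nrow(ct), fx$n_pass + fx$n_fail)
  expect_identical(sum(ct$pass), fx$n_pass)
  # through files and the orchestrator as well
  dir <- withr::local_tempdir()
  write_pdb(fx$atoms, file.path(dir, "fix.pdb"))
  res <- scan_pdb(dir)
  expect_identical(sum(res$contacts$pass), fx$n_pass)
  expect_length(res$complexes, fx$n_pass)
})

test_that("matched-pair reconstruction preserves the key geometry exactly", {
  fx <- fixture_structure()
  ct <- apply_sigma_filters(
    find_pi_contacts(fx$atoms, find_halogen_aryl_ligands(fx$atoms),
                     structure_id = "fix"))
  for (i in which(ct$pass)) {
    mmp <- build_mmp_complex(ct[i, ], fx$atoms)
    xp <- halopi:::coords_of(fx$atoms, ct$halogen_serial[i])
    cp <- halopi:::coords_of(fx$atoms, ct$carbon_serial[i])
    # halogen matched exactly
    expect_equal(mmp$complex$donor$coords[1, ], xp, tolerance = 1e-9)
    # C-X direction matched within 1e-6 rad
    u_lig <- (xp - cp) / sqrt(sum((xp - cp)^2))
    dd <- mmp$complex$donor$coords
    u_mod <- (dd[1, ] - dd[2, ]) / sqrt(sum((dd[1, ] - dd[2, ])^2))
    expect_lt(acos(min(1, sum(u_lig * u_mod))), 1e-6)
    # acceptor: 12 atoms, normal parallel to the PHE ring normal
    expect_identical(length(mmp$complex$acceptor$elements), 12L)
    phe <- fx$atoms[fx$atoms$record == "ATOM" &
                      halopi:::residue_key(fx$atoms) == ct$residue[i] &
                      fx$atoms$name %in% halopi:::.phe_ring_atoms, ]
    rc <- as.matrix(phe[, c("x", "y", "z")])
    sv <- svd(sweep(rc, 2, colMeans(rc)))
    n_p <- sv$v[, 3]
    n_a <- plane_and_centroid(mmp$complex$acceptor, toward = xp)$normal
    expect_lt(abs(abs(sum(n_p * n_a)) - 1), 1e-6)
    # features extract cleanly from the rebuilt complex
    expect_length(extract_features(mmp$complex), 30L)
  }
})

test_that("reconstruction is idempotent on an already-canonical complex", {
  cx <- ref_pose("Br", x = 0.4, z = 0.2, d = 3.2, tilt_dev = 15)
  atoms <- rbind(
    data.table::data.table(
      record = "ATOM", serial = 1:6,
      name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), altloc = "",
      resname = "PHE", chain = "A", resseq = 1L,
      x = cx$acceptor$coords[1:6, 1], y = cx$acceptor$coords[1:6, 2],
      z = cx$acceptor$coords[1:6, 3], element = "C"),
    data.table::data.table(
      record = "HETATM", serial = 101:107,
      name = c("BR", paste0("C", 1:6)), altloc = "", resname = "LIG",
      chain = "A", resseq = 50L,
      x = cx$donor$coords[1:7, 1], y = cx$donor$coords[1:7, 2],
      z = cx$donor$coords[1:7, 3], element = c("BR", rep("C", 6))))
  ct <- apply_sigma_filters(find_pi_contacts(atoms, find_halogen_aryl_ligands(atoms)))
  expect_identical(sum(ct$pass), 1L)
  mmp <- build_mmp_complex(ct[which(ct$pass)[1], ], atoms)
  expect_equal(mmp$complex$donor$coords, cx$donor$coords, tolerance = 1e-9)
  rmsd_acc <- sqrt(mean((mmp$complex$acceptor$coords[1:6, ] -
                           cx$acceptor$coords[1:6, ])^2))
  expect_lt(rmsd_acc, 1e-9)
})

test_that("five-ring donors feed the model through their own features", {
  model <- get_tiny_model()
  at <- rbind(phe_atoms(c(0, 0, 0), 1L, 1L),
              five_ring_ligand_atoms(c(0, 0, 0), 100L, 60L, d = 3.2))
  cand <- find_halogen_aryl_ligands(at)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$ring_size, 5L)
  ct <- apply_sigma_filters(find_pi_contacts(at, cand))
  expect_identical(sum(ct$pass), 1L)
  chk <- five_ring_feature_check(ct[ct$pass, ], at, model)
  expect_identical(nrow(chk), 1L)
  expect_true(is.finite(chk$diff))
  expect_equal(chk$diff, chk$pred_5ring - chk$pred_6ring)
  expect_equal(attr(chk, "mean"), mean(chk$diff))
  # six-ring contacts are skipped with a log message
  fx <- fixture_structure()
  ct6 <- apply_sigma_filters(
    find_pi_contacts(fx$atoms, find_halogen_aryl_ligands(fx$atoms)))
  expect_message(chk6 <- five_ring_feature_check(ct6[ct6$pass, ][1, ],
                                                 fx$atoms, model),
                 "non-five-ring")
  expect_identical(nrow(chk6), 0L)
  expect_error(five_ring_feature_check(ct[ct$pass, ], at, NULL), "required")
})

test_that("survey arithmetic reproduces shares and retention rates", {
  counts <- data.frame(group = c("a", "b"), contacts = c(75, 25),
                       interactions = c(15, 5))
  s <- contact_survey_summary(counts)
  expect_equal(s$share_pct, c(75, 25))
  expect_equal(s$retention_pct, c(20, 20))
})
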