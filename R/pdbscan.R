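# Mining PDB structures for halogen...pi contacts to phenylalanine and
# rebuilding matched halobenzene-benzene model complexes.

.covalent_radii <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                     F = 0.57, SI = 1.11, P = 1.07, S = 1.05, CL = 1.02,
                     SE = 1.20, BR = 1.20, I = 1.39)
.bond_slack <- 0.45

.std_residues <- c(
  "ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU","LYS",
  "MET","PHE","PRO","SER","THR","TRP","TYR","VAL","SEC","PYL","MSE",
  "DA","DC","DG","DT","DU","A","C","G","U","I","HOH","WAT","DOD")

.metals <- c("LI","NA","K","RB","CS","MG","CA","SR","BA","MN","FE","CO",
             "NI","CU","ZN","CD","HG","AL","GA","PB","PT","AU","AG","W",
             "MO","V","CR","YB","SM","EU","TB","GD","LU","OS","IR","RU","RH")

.phe_ring_atoms <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")

#' Read ATOM/HETATM records from a PDB file
#'
#' Minimal fixed-column reader (no pre-installed R package provides one):
#' parses record type, serial, atom name, altLoc, residue name, chain,
#' residue number, coordinates and element. ANISOU and everything else is
#' ignored. The element falls back to the atom name when columns 77-78 are
#' blank.
#'
#' @param path PDB file.
#' @return `data.table` of atoms.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[substr(lines, 1, 6) %in% c("ATOM  ", "HETATM")]
  if (!length(lines)) stop("no ATOM/HETATM records in ", path)
  el <- toupper(trimws(substr(lines, 77, 78)))
  name <- trimws(substr(lines, 13, 16))
  fallback <- toupper(gsub("[^A-Za-z].*$", "", name))
  el[el == ""] <- substr(fallback[el == ""], 1,
                         ifelse(fallback[el == ""] %in% names(.covalent_radii), 2, 1))
  data.table::data.table(
    record = trimws(substr(lines, 1, 6)),
    serial = as.integer(substr(lines, 7, 11)),
    name = name,
    altloc = trimws(substr(lines, 17, 17)),
    resname = trimws(substr(lines, 18, 20)),
    chain = trimws(substr(lines, 22, 22)),
    resseq = as.integer(substr(lines, 23, 26)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    element = el)
}

#' Write atoms to a PDB file
#'
#' Counterpart of [read_pdb()]; mainly used to build text fixtures.
#'
#' @param atoms `data.table`/data.frame with the [read_pdb()] columns.
#' @param path Output file.
#' @export
write_pdb <- function(atoms, path) {
  name_fmt <- ifelse(nchar(atoms$name) >= 4, sprintf("%-4s", atoms$name),
                     sprintf(" %-3s", atoms$name))
  lines <- sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   atoms$record, atoms$serial, name_fmt,
                   ifelse(is.na(atoms$altloc), "", atoms$altloc),
                   atoms$resname, atoms$chain, atoms$resseq,
                   atoms$x, atoms$y, atoms$z, 1.0, 0.0, atoms$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# preprocessing: drop hydrogens, non-primary alternative conformations and
# isolated metal ions
preprocess_structure <- function(atoms) {
  atoms <- atoms[!atoms$element %in% c("H", "D"), ]
  atoms <- atoms[atoms$altloc %in% c("", "A"), ]
  atoms[!(atoms$record == "HETATM" & atoms$resname %in% .metals), ]
}

residue_key <- function(atoms) paste(atoms$chain, atoms$resseq, atoms$resname)

bond_matrix <- function(coords, elements) {
  r <- .covalent_radii[toupper(elements)]
  r[is.na(r)] <- 0.77
  d <- as.matrix(stats::dist(coords))
  cut <- outer(r, r, "+") + .bond_slack
  b <- d < cut & d > 0.4
  diag(b) <- FALSE
  b
}

# simple cycles of length 5 or 6 through atom `start` in a bond graph
rings_through <- function(bonds, start) {
  n <- nrow(bonds)
  found <- list()
  path <- integer(0)
  dfs <- function(v, depth) {
    path[depth] <<- v
    for (w in which(bonds[v, ])) {
      if (w == start && depth >= 5) {
        found[[length(found) + 1L]] <<- path[1:depth]
      } else if (depth < 6 && !(w %in% path[1:depth]) && w > 0) {
        dfs(w, depth + 1L)
      }
    }
  }
  path <- integer(6)
  dfs(start, 1L)
  # deduplicate cycles found in both directions / rotations
  uniq <- list()
  seen <- character(0)
  for (r in found) {
    key <- paste(sort(r), collapse = "-")
    if (!key %in% seen) { seen <- c(seen, key); uniq[[length(uniq) + 1L]] <- r }
  }
  uniq
}

ring_planarity_rms <- function(coords) {
  ctr <- colMeans(coords)
  sv <- svd(sweep(coords, 2, ctr))
  sqrt(mean((sweep(coords, 2, ctr) %*% sv$v[, 3])^2))
}

#' Find halogenated aryl ligands in a structure
#'
#' Hetero-compound ligands (not polymer building blocks, not water or metal
#' ions) with at least six heavy atoms whose Cl/Br/I is covalently bonded
#' (distance-based bond perception: d < sum of covalent radii + 0.45 A) to
#' a carbon of a planar five- or six-membered ring (planarity RMS < 0.1 A).
#'
#' @param atoms Preprocessed atom table ([read_pdb()] output is
#'   preprocessed internally).
#' @return `data.table` of candidates: ligand id, halogen element/serial,
#'   bonded carbon serial, ring serials (list column, cycle order), ring
#'   size.
#' @export
find_halogen_aryl_ligands <- function(atoms) {
  atoms <- preprocess_structure(data.table::as.data.table(atoms))
  het <- atoms[atoms$record == "HETATM" & !atoms$resname %in% .std_residues, ]
  out <- list()
  if (nrow(het)) for (key in unique(residue_key(het))) {
    lig <- het[residue_key(het) == key, ]
    if (nrow(lig) < 6L) next
    hal_idx <- which(lig$element %in% c("CL", "BR", "I"))
    if (!length(hal_idx)) next
    bonds <- bond_matrix(as.matrix(lig[, c("x", "y", "z")]), lig$element)
    for (hi in hal_idx) {
      nb <- which(bonds[hi, ])
      nb <- nb[lig$element[nb] == "C"]
      for (ci in nb) {
        rings <- rings_through(bonds, ci)
        ring <- NULL
        for (r in rings) {
          rc <- as.matrix(lig[r, c("x", "y", "z")])
          if (ring_planarity_rms(rc) < 0.1) { ring <- r; break }
        }
        if (is.null(ring)) next
        out[[length(out) + 1L]] <- data.table::data.table(
          ligand = key,
          halogen = c(CL = "Cl", BR = "Br", I = "I")[lig$element[hi]],
          halogen_serial = lig$serial[hi],
          carbon_serial = lig$serial[ci],
          ring_serials = list(lig$serial[ring]),
          ring_size = length(ring))
      }
    }
  }
  if (!length(out))
    return(data.table::data.table(ligand = character(), halogen = character(),
                                  halogen_serial = integer(),
                                  carbon_serial = integer(),
                                  ring_serials = list(), ring_size = integer()))
  data.table::rbindlist(out)
}

coords_of <- function(atoms, serial) {
  i <- match(serial, atoms$serial)
  as.numeric(atoms[i, c("x", "y", "z")])
}

#' Find halogen...pi contacts to phenylalanine rings
#'
#' One contact per (candidate halogen, PHE ring) pair whose nearest
#' side-chain ring atom (CG/CD1/CD2/CE1/CE2/CZ) lies within `d_contact` A
#' of the halogen. Pose measures are computed against the least-squares
#' PHE ring plane with the normal oriented toward the halogen; `alpha` is 0
#' when the C-X bond points straight at the plane.
#'
#' @param atoms Atom table of the structure.
#' @param candidates Output of [find_halogen_aryl_ligands()].
#' @param d_contact Contact cutoff (A, default 5).
#' @param structure_id Label recorded in the output.
#' @return `data.table` of contacts with geometry measures.
#' @export
find_pi_contacts <- function(atoms, candidates, d_contact = 5,
                             structure_id = "structure") {
  atoms <- preprocess_structure(data.table::as.data.table(atoms))
  phe <- atoms[atoms$record == "ATOM" & atoms$resname == "PHE" &
                 atoms$name %in% .phe_ring_atoms, ]
  out <- list()
  if (nrow(phe) && nrow(candidates)) for (rk in unique(residue_key(phe))) {
    ring <- phe[residue_key(phe) == rk, ]
    if (nrow(ring) != 6L) { message("skipping incomplete PHE side chain: ", rk); next }
    rc <- as.matrix(ring[, c("x", "y", "z")])
    for (i in seq_len(nrow(candidates))) {
      xp <- coords_of(atoms, candidates$halogen_serial[i])
      cp <- coords_of(atoms, candidates$carbon_serial[i])
      d_aa <- min(sqrt(colSums((t(rc) - xp)^2)))
      if (d_aa > d_contact) next
      ctr <- colMeans(rc)
      sv <- svd(sweep(rc, 2, ctr))
      n <- sv$v[, 3]
      if (sum((xp - ctr) * n) < 0) n <- -n
      pm <- pose_measures_core(xp, cp, n, ctr)
      out[[length(out) + 1L]] <- data.table::data.table(
        structure = structure_id,
        ligand = candidates$ligand[i],
        halogen = candidates$halogen[i],
        halogen_serial = candidates$halogen_serial[i],
        carbon_serial = candidates$carbon_serial[i],
        ring_serials = list(candidates$ring_serials[[i]]),
        ring_size = candidates$ring_size[i],
        residue = rk,
        d_plane = pm$d_plane, alpha = pm$alpha, r_off = pm$r_off,
        d_x_aa = d_aa,
        directional = pm$alpha < 90)
    }
  }
  if (!length(out))
    return(data.table::data.table())
  data.table::rbindlist(out)
}

#' Apply the sigma-hole geometry filters
#'
#' A contact passes when the C-X bond points toward the ring plane with
#' alpha < `alpha_max` (published cutoff 50 degrees) and the minimum
#' halogen-to-ring-atom distance is at least `d_min` (published lower limit
#' 1 A).
#'
#' @param contacts Contact table from [find_pi_contacts()].
#' @param alpha_max,d_min Filter cutoffs.
#' @return The table with a logical `pass` column added.
#' @export
apply_sigma_filters <- function(contacts, alpha_max = 50, d_min = 1) {
  contacts <- data.table::as.data.table(contacts)
  contacts$pass <- contacts$alpha < alpha_max &
    contacts$d_x_aa >= d_min & contacts$directional
  contacts[]
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

orthonormal_frame <- function(u, n_hint) {
  u <- u / sqrt(sum(u^2))
  n <- n_hint - sum(n_hint * u) * u
  nn <- sqrt(sum(n^2))
  if (nn < 1e-8) stop("degenerate ring: normal parallel to C-X axis")
  n <- n / nn
  cbind(u, n, c(u[2] * n[3] - u[3] * n[2],
                u[3] * n[1] - u[1] * n[3],
                u[1] * n[2] - u[2] * n[1]))
}

#' Rebuild a matched halobenzene-benzene model complex from a contact
#'
#' The canonical halobenzene is placed so its halogen coincides exactly
#' with the ligand halogen, its C-X bond direction matches the ligand's,
#' and its ring plane is aligned to the ligand's aromatic ring plane. The
#' phenylalanine side chain is capped at the C-gamma/C-beta bond and
#' replaced by a canonical benzene aligned on the ring (centroid, plane,
#' and in-plane spin referenced to the CG direction).
#'
#' @param contact One contact row (single-row data.table/list) that passed
#'   the filters.
#' @param atoms Atom table of the structure.
#' @return Object of class `xb_mmp`: `complex` (an `xb_complex`) plus
#'   provenance.
#' @export
build_mmp_complex <- function(contact, atoms) {
  contact <- as.list(data.table::as.data.table(contact)[1, ])
  atoms <- preprocess_structure(data.table::as.data.table(atoms))
  xp <- coords_of(atoms, contact$halogen_serial)
  cp <- coords_of(atoms, contact$carbon_serial)
  u <- xp - cp                       # ligand C->X direction
  ring_ser <- contact$ring_serials
  if (is.list(ring_ser)) ring_ser <- ring_ser[[1]]
  lig_ring <- t(vapply(ring_ser, function(s) coords_of(atoms, s), numeric(3)))
  ctr_l <- colMeans(lig_ring)
  svl <- svd(sweep(lig_ring, 2, ctr_l))
  n_l <- svl$v[, 3]
  # canonical normal sign: cross(C->X, ipso->next-ring-atom) defines "up",
  # which makes the reconstruction deterministic and idempotent (the two
  # signs correspond to mirrored ortho-carbon assignments)
  v2 <- coords_of(atoms, ring_ser[2]) - cp
  if (sum(cross3(u, v2) * n_l) < 0) n_l <- -n_l

  # canonical donor frame: C->X = -y, ring plane normal = +z
  A <- orthonormal_frame(c(0, -1, 0), c(0, 0, 1))
  B <- orthonormal_frame(u, n_l)
  donor <- apply_transform(build_halobenzene(contact$halogen),
                           rigid_transform(B %*% t(A), xp))

  phe <- atoms[atoms$record == "ATOM" &
                 residue_key(atoms) == contact$residue &
                 atoms$name %in% .phe_ring_atoms, ]
  if (nrow(phe) != 6L) stop("incomplete PHE ring for ", contact$residue)
  rc <- as.matrix(phe[, c("x", "y", "z")])
  ctr_p <- colMeans(rc)
  svp <- svd(sweep(rc, 2, ctr_p))
  n_p <- svp$v[, 3]
  if (sum((xp - ctr_p) * n_p) < 0) n_p <- -n_p
  cg <- as.numeric(phe[phe$name == "CG", c("x", "y", "z")])
  # canonical benzene frame is the identity (C1 along +x, normal +y)
  B2 <- orthonormal_frame(cg - ctr_p, n_p)
  # orthonormal_frame returns (in-plane ref, normal, third); canonical
  # benzene has C1 = +x, normal = +y, so map (x, y, z) onto (f1, n, f1 x n)
  R2 <- B2[, c(1, 2, 3)] %*% t(orthonormal_frame(c(1, 0, 0), c(0, 1, 0)))
  acceptor <- apply_transform(build_benzene(), rigid_transform(R2, ctr_p))

  structure(list(
    complex = structure(list(donor = donor, acceptor = acceptor,
                             meta = contact[c("structure", "ligand", "residue",
                                              "halogen")]),
                        class = "xb_complex"),
    provenance = contact[c("structure", "ligand", "residue")]),
    class = "xb_mmp")
}

#' Compare predictions from five-ring vs six-ring donor features
#'
#' For contacts whose donor ring in the original ligand is five-membered,
#' recomputes the descriptor using the actual five-ring atoms (halogen,
#' bonded carbon, and that carbon's two ring neighbours) against the
#' rebuilt benzene acceptor, and reports the difference between the energy
#' predicted from those features and from the canonical six-ring model
#' features.
#'
#' @param contacts Passing contacts ([apply_sigma_filters()] output).
#' @param atoms Atom table of the structure.
#' @param model Trained `xb_model` (required).
#' @return `data.table` with per-contact prediction difference
#'   (kJ/mol, five-ring minus six-ring); attributes `mean` and `sd`.
#' @export
five_ring_feature_check <- function(contacts, atoms, model) {
  if (missing(model) || is.null(model)) stop("a trained model is required")
  contacts <- data.table::as.data.table(contacts)
  atoms_p <- preprocess_structure(data.table::as.data.table(atoms))
  rows <- list()
  for (i in seq_len(nrow(contacts))) {
    ct <- contacts[i, ]
    if (ct$ring_size != 5L) {
      message("skipping non-five-ring contact ", ct$ligand); next
    }
    mmp <- build_mmp_complex(ct, atoms)
    f6 <- extract_features(mmp$complex)
    ring_ser <- ct$ring_serials[[1]]
    # ring neighbours of the ipso carbon in cycle order
    pos <- match(ct$carbon_serial, ring_ser)
    nb <- ring_ser[c((pos - 2L) %% 5L + 1L, pos %% 5L + 1L)]
    acc_ring <- ring_coords(mmp$complex$acceptor)
    pl <- plane_and_centroid(mmp$complex$acceptor,
                             toward = coords_of(atoms_p, ct$halogen_serial))
    f5 <- feature_vector_core(coords_of(atoms_p, ct$halogen_serial),
                              coords_of(atoms_p, ct$carbon_serial),
                              coords_of(atoms_p, nb[1]),
                              coords_of(atoms_p, nb[2]),
                              acc_ring, pl$normal, pl$centroid)
    pred <- predict(model, rbind(f5, f6))
    rows[[length(rows) + 1L]] <- data.table::data.table(
      ligand = ct$ligand, residue = ct$residue,
      pred_5ring = pred[1], pred_6ring = pred[2],
      diff = pred[1] - pred[2])
  }
  out <- if (length(rows)) data.table::rbindlist(rows) else data.table::data.table()
  data.table::setattr(out, "mean", if (nrow(out)) mean(out$diff) else NA_real_)
  data.table::setattr(out, "sd", if (nrow(out) > 1) stats::sd(out$diff) else NA_real_)
  out[]
}

#' Scan PDB files for sigma-hole halogen...pi interactions
#'
#' Runs the full mining pipeline per file: preprocessing, halogenated-aryl
#' ligand detection, phenylalanine contact search, sigma-hole filters, and
#' (for passing contacts) matched-molecular-pair reconstruction with
#' optional energy prediction and applicability scoring.
#'
#' @param paths PDB file paths (or a directory, scanned for `*.pdb`).
#' @param model Optional trained `xb_model`; adds `energy_pred`, `md`,
#'   `relative_md`, `outlier` columns for passing contacts.
#' @param alpha_max,d_min Filter cutoffs.
#' @return List: `contacts` (full annotated table), `complexes` (list of
#'   `xb_mmp` for passing contacts, names matching row ids).
#' @export
scan_pdb <- function(paths, model = NULL, alpha_max = 50, d_min = 1) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.pdb$", full.names = TRUE)
  all_contacts <- list()
  complexes <- list()
  for (p in paths) {
    sid <- sub("\\.pdb$", "", basename(p))
    atoms <- read_pdb(p)
    cand <- find_halogen_aryl_ligands(atoms)
    if (!nrow(cand)) next
    ct <- find_pi_contacts(atoms, cand, structure_id = sid)
    if (!nrow(ct)) next
    ct <- apply_sigma_filters(ct, alpha_max, d_min)
    if (!is.null(model) && any(ct$pass)) {
      ct$energy_pred <- NA_real_
      ct$md <- NA_real_; ct$relative_md <- NA_real_; ct$outlier <- NA
      for (i in which(ct$pass)) {
        mmp <- build_mmp_complex(ct[i, ], atoms)
        complexes[[paste(sid, i, sep = ":")]] <- mmp
        f <- extract_features(mmp$complex)
        ct$energy_pred[i] <- predict(model, rbind(f))
        if (!is.null(model$applicability) && !is.null(model$scaler)) {
          fs <- apply_scaler(rbind(f), model$scaler)
          rel <- mahalanobis_distance(fs, model$applicability, relative = TRUE)
          ct$md[i] <- rel$md; ct$relative_md[i] <- rel$relative_md
          ct$outlier[i] <- rel$relative_md > 1
        }
      }
    } else if (any(ct$pass)) {
      for (i in which(ct$pass))
        complexes[[paste(sid, i, sep = ":")]] <- build_mmp_complex(ct[i, ], atoms)
    }
    all_contacts[[sid]] <- ct
  }
  list(contacts = if (length(all_contacts)) data.table::rbindlist(all_contacts, fill = TRUE)
                  else data.table::data.table(),
       complexes = complexes)
}

#' Published-survey contact arithmetic
#'
#' Summary percentages for a halogen...pi contact survey table: given
#' per-acceptor contact and retained-interaction counts, computes each
#' acceptor's share of contacts and retention rate. The package ships the
#' counts of a published PDB-wide survey of halogenated aryl ligands near
#' aromatic side chains as `inst/extdata/pdb_contact_survey.csv`.
#'
#' @param counts Data frame with columns `group`, `contacts`,
#'   `interactions`.
#' @return The table with `share_pct` (of summed contacts) and
#'   `retention_pct` (interactions / contacts) columns, percentages.
#' @export
contact_survey_summary <- function(counts) {
  counts <- data.table::as.data.table(counts)
  counts$share_pct <- 100 * counts$contacts / sum(counts$contacts)
  counts$retention_pct <- 100 * counts$interactions / counts$contacts
  counts[]
}
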