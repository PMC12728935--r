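#' @useDynLib halopi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Default idealized bond lengths (Angstrom). The quantum-chemically optimized
# monomer geometries behind the published energies are not distributed, so
# literature-standard values are used; all are overridable per builder call.
.geom_defaults <- list(
  cc = 1.39,                       # aromatic C-C
  ch = 1.08,                       # aromatic C-H
  cx = c(Cl = 1.74, Br = 1.90, I = 2.10)  # aryl C-X
)

#' Geometry configuration defaults
#'
#' Returns the idealized bond lengths used by the monomer builders:
#' aromatic C-C (1.39 A), aromatic C-H (1.08 A) and the aryl C-X lengths
#' (Cl 1.74, Br 1.90, I 2.10 A).
#' @return Named list with elements `cc`, `ch`, `cx`.
#' @export
geometry_defaults <- function() .geom_defaults

#' Construct a molecule
#'
#' A molecule is a labelled 3-D point set: element symbols, an n x 3
#' coordinate matrix in Angstrom and per-atom role tags used by the feature
#' extractor (`halogen`, `ipso_carbon`, `ortho_carbon`, `ring_carbon`,
#' `ring_hydrogen`).
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric n x 3 matrix (Angstrom).
#' @param roles Character vector of role tags (may be `NA`).
#' @return Object of class `xb_molecule`.
#' @export
molecule <- function(elements, coords, roles = rep(NA_character_, length(elements))) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  if (length(elements) != nrow(coords) || length(roles) != nrow(coords))
    stop("elements, coords and roles must agree in length")
  structure(list(elements = as.character(elements),
                 coords = unname(coords),
                 roles = as.character(roles)),
            class = "xb_molecule")
}

#' @export
print.xb_molecule <- function(x, ...) {
  cat(sprintf("<xb_molecule: %d atoms [%s]>\n", length(x$elements),
              paste(unique(x$elements), collapse = " ")))
  invisible(x)
}

n_atoms <- function(mol) length(mol$elements)

#' Build an idealized benzene
#'
#' Regular D6h benzene with the ring centroid at the origin and the ring in
#' the xz-plane, so the ring-plane normal is the +y axis. This coordinate
#' convention puts all donor poses at y > 0.
#'
#' @param cc Aromatic C-C bond length (A).
#' @param ch Aromatic C-H bond length (A).
#' @return `xb_molecule` with 6 C then 6 H.
#' @export
build_benzene <- function(cc = .geom_defaults$cc, ch = .geom_defaults$ch) {
  th <- (0:5) * pi / 3
  c_xyz <- cbind(cc * cos(th), 0, cc * sin(th))
  h_xyz <- cbind((cc + ch) * cos(th), 0, (cc + ch) * sin(th))
  molecule(c(rep("C", 6), rep("H", 6)),
           rbind(c_xyz, h_xyz),
           c(rep("ring_carbon", 6), rep("ring_hydrogen", 6)))
}

#' Build an idealized halobenzene in its canonical donor frame
#'
#' The canonical frame places the halogen at the origin with the C-X bond
#' along +y (ipso carbon at (0, C-X length, 0)) and the phenyl ring in the
#' xy-plane. The C->X bond vector therefore points along -y: translating the
#' molecule to y > 0 above a benzene in the xz-plane yields the ideal
#' sigma-hole approach with the halogen nearest the plane.
#'
#' Atom order: X, C_ipso, C_ortho1, C_ortho2, C_meta1, C_meta2, C_para,
#' then the five ring hydrogens.
#'
#' @param halogen One of `"Cl"`, `"Br"`, `"I"`.
#' @param cx C-X bond length (A); default from [geometry_defaults()].
#' @param cc,ch Ring bond lengths (A).
#' @return `xb_molecule` with 12 atoms, exactly one tagged `halogen`.
#' @export
build_halobenzene <- function(halogen,
                              cx = NULL,
                              cc = .geom_defaults$cc,
                              ch = .geom_defaults$ch) {
  if (!is.character(halogen) || length(halogen) != 1L ||
      !halogen %in% names(.geom_defaults$cx))
    stop("halogen must be one of: ", paste(names(.geom_defaults$cx), collapse = ", "))
  if (is.null(cx)) cx <- .geom_defaults$cx[[halogen]]
  # ring center sits above the ipso carbon along +y
  center <- c(0, cx + cc, 0)
  # ipso at beta = -90 deg (pointing back toward X); k indexes around the ring
  beta <- -pi / 2 + (0:5) * pi / 3
  ring <- cbind(center[1] + cc * cos(beta), center[2] + cc * sin(beta), 0)
  # order: ipso(k=0), ortho(k=1), ortho(k=5), meta(k=2), meta(k=4), para(k=3)
  ord <- c(1L, 2L, 6L, 3L, 5L, 4L)
  ring <- ring[ord, , drop = FALSE]
  hpos <- cbind(center[1] + (cc + ch) * cos(beta), center[2] + (cc + ch) * sin(beta), 0)
  hpos <- hpos[ord[-1], , drop = FALSE]   # no H on the ipso carbon
  molecule(c(halogen, rep("C", 6), rep("H", 5)),
           rbind(c(0, 0, 0), ring, hpos),
           c("halogen", "ipso_carbon", "ortho_carbon", "ortho_carbon",
             "ring_carbon", "ring_carbon", "ring_carbon",
             rep("ring_hydrogen", 5)))
}

#' Rigid-body transform
#'
#' @param rotation 3 x 3 proper orthonormal matrix.
#' @param translation Length-3 numeric vector (A).
#' @return Object of class `xb_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = unname(rotation),
                 translation = as.numeric(translation)),
            class = "xb_transform")
}

#' Rotation matrix about an arbitrary axis
#'
#' Right-handed rotation by `angle_deg` degrees about the (normalized) axis,
#' via the Rodrigues formula.
#'
#' @param axis Length-3 axis vector (normalized internally).
#' @param angle_deg Rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Apply a rigid transform to a molecule
#'
#' @param mol `xb_molecule`.
#' @param t `xb_transform` (validated: proper orthonormal rotation).
#' @return Transformed `xb_molecule`; all intramolecular distances preserved.
#' @export
apply_transform <- function(mol, t) {
  if (!inherits(t, "xb_transform")) t <- rigid_transform(t$rotation, t$translation)
  out <- mol
  out$coords <- mol$coords %*% t(t$rotation) +
    matrix(t$translation, n_atoms(mol), 3, byrow = TRUE)
  out
}

#' Least-squares ring plane and centroid
#'
#' Fits a plane to the ring atoms (roles `ring_carbon`, `ipso_carbon`,
#' `ortho_carbon`; all atoms if the molecule carries no role tags) by SVD of
#' the centered coordinates. The unit normal is the direction of smallest
#' variance. If `toward` is supplied the normal is oriented so that it points
#' to the side of the plane containing that reference point; otherwise its
#' largest-magnitude component is made positive (canonical benzene -> +y).
#'
#' @param mol `xb_molecule`.
#' @param toward Optional length-3 reference point for normal orientation.
#' @return List with unit `normal` and `centroid`.
#' @export
plane_and_centroid <- function(mol, toward = NULL) {
  ring <- ring_coords(mol)
  if (nrow(ring) < 3L) stop("need at least 3 ring atoms for a plane")
  ctr <- colMeans(ring)
  X <- sweep(ring, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) stop("degenerate (collinear) ring atoms")
  n <- sv$v[, 3]
  if (!is.null(toward)) {
    s <- sum((as.numeric(toward) - ctr) * n)
    if (s < 0) n <- -n
  } else {
    k <- which.max(abs(n))
    if (n[k] < 0) n <- -n
  }
  list(normal = n, centroid = ctr)
}

ring_coords <- function(mol) {
  sel <- mol$roles %in% c("ring_carbon", "ipso_carbon", "ortho_carbon")
  if (!any(sel)) sel <- rep(TRUE, n_atoms(mol))
  mol$coords[sel, , drop = FALSE]
}

role_index <- function(mol, role) which(mol$roles == role)

#' Write molecules to an XYZ file
#'
#' Standard two-line-header XYZ (atom count, comment, then
#' `element x y z` with 6 decimals, Angstrom). Multiple molecules produce a
#' multi-frame file.
#'
#' @param mols A single `xb_molecule` or list of them.
#' @param path Output file path.
#' @param comments Character vector of per-frame comment lines.
#' @export
write_xyz <- function(mols, path, comments = NULL) {
  if (inherits(mols, "xb_molecule")) mols <- list(mols)
  if (is.null(comments)) comments <- rep("", length(mols))
  lines <- unlist(lapply(seq_along(mols), function(i) {
    m <- mols[[i]]
    c(as.character(n_atoms(m)), comments[[i]],
      sprintf("%-2s %14.6f %14.6f %14.6f",
              m$elements, m$coords[, 1], m$coords[, 2], m$coords[, 3]))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ file
#'
#' @param path XYZ file (possibly multi-frame).
#' @return List of `xb_molecule` (roles are `NA`; tag downstream if needed).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed XYZ header at line ", i)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    el <- vapply(parts, `[[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    out[[length(out) + 1L]] <- molecule(el, xyz)
    i <- i + 2L + n
  }
  out
}

deg <- function(rad) rad * 180 / pi

# angle between two vectors in degrees, clamped for numeric safety
vec_angle <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  deg(acos(pmin(1, pmax(-1, ca))))
}
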