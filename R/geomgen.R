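# Pose enumeration over the benzene plane.
#
# Coordinate convention: the acceptor benzene is fixed in the xz-plane with
# centroid at the origin and plane normal +y; donor poses always sit at
# y > 0 (benzene is symmetric, so the lower half-space adds nothing).

.tilt_axes <- list(
  x      = c(1, 0, 0),
  z      = c(0, 0, 1),
  c45    = c(1, 0, 1) / sqrt(2),
  `c-45` = c(1, 0, -1) / sqrt(2)
)

#' Systematic pose-grid specification
#'
#' Defaults reproduce the published systematic scan: in-plane translations
#' x, z in \[0, 5\] A step 0.25 (one quadrant, by benzene symmetry),
#' halogen-to-plane distances 2.75 to 4.50 A step 0.25, rotations of the
#' donor about its own C-X axis of 0/45/90/135 degrees, and tilts of the
#' C-X axis about four in-plane axes (x, z, and the two 45-degree
#' diagonals) from -40 to +40 degrees in 10-degree steps. The Cartesian
#' product is 21 x 21 x 8 x 4 x 4 x 9 = 508,032 poses per halobenzene; the
#' 0-degree tilt is deliberately repeated once per axis, which that count
#' requires.
#'
#' @param x_range,z_range Length-2 numeric, A.
#' @param xz_step Grid step, A.
#' @param distances Halogen-to-plane distances, A.
#' @param y_rotations Rotations about the donor C-X axis, degrees.
#' @param tilt_axes Subset of `c("x","z","c45","c-45")`.
#' @param tilt_deviations Tilt angles of the C-X axis, degrees.
#' @param dedupe Drop the repeated 0-degree tilt across axes (default FALSE).
#' @return Object of class `xb_grid_spec`.
#' @export
grid_spec <- function(x_range = c(0, 5), z_range = c(0, 5), xz_step = 0.25,
                      distances = seq(2.75, 4.50, by = 0.25),
                      y_rotations = c(0, 45, 90, 135),
                      tilt_axes = c("x", "z", "c45", "c-45"),
                      tilt_deviations = seq(-40, 40, by = 10),
                      dedupe = FALSE) {
  if (xz_step <= 0) stop("xz_step must be > 0")
  if (!length(distances) || any(distances <= 0)) stop("distances must be positive and non-empty")
  if (!length(y_rotations) || !length(tilt_axes) || !length(tilt_deviations))
    stop("empty parameter list in grid spec")
  if (!all(tilt_axes %in% names(.tilt_axes)))
    stop("tilt_axes must be among: ", paste(names(.tilt_axes), collapse = ", "))
  structure(list(
    x = seq(x_range[1], x_range[2], by = xz_step),
    z = seq(z_range[1], z_range[2], by = xz_step),
    distances = distances, y_rotations = y_rotations,
    tilt_axes = tilt_axes, tilt_deviations = tilt_deviations,
    dedupe = dedupe), class = "xb_grid_spec")
}

#' Random pose specification
#'
#' Defaults follow the published random test-set protocol: x, z translation
#' in \[-5, 5\] A, halogen height y in \[1.5, 5\] A, rotation about the C-X
#' axis in \[0, 360) degrees and C-X tilt angle alpha in \[0, 60\] degrees.
#' The azimuthal direction of the tilt is not stated there; it is sampled
#' uniformly in \[0, 360) degrees and recorded (`psi`).
#'
#' @param n Number of poses.
#' @param x_range,z_range,y_range Numeric length-2 ranges (A).
#' @param y_rot_range,alpha_range Degree ranges.
#' @param seed RNG seed.
#' @return Object of class `xb_random_spec`.
#' @export
random_spec <- function(n = 10000, x_range = c(-5, 5), z_range = c(-5, 5),
                        y_range = c(1.5, 5.0), y_rot_range = c(0, 360),
                        alpha_range = c(0, 60), seed = 1) {
  if (n <= 0) stop("n must be positive")
  structure(list(n = as.integer(n), x_range = x_range, z_range = z_range,
                 y_range = y_range, y_rot_range = y_rot_range,
                 alpha_range = alpha_range, seed = as.integer(seed)),
            class = "xb_random_spec")
}

#' Enumerate the systematic pose grid
#'
#' Emits the full Cartesian product of the grid parameters as a pose table
#' (one row per geometry). Poses are materialized on demand with
#' [build_pose()]; the table form keeps the half-million-row default grid
#' cheap. Pose construction: the donor starts in its canonical sigma-hole
#' frame (C-X axis along -y, halogen nearest the plane), is rotated by
#' `y_rot` about its own C-X axis, tilted by `tilt_dev` about the named
#' in-plane axis through the halogen, then translated so the halogen sits at
#' (x, d, z).
#'
#' @param spec [grid_spec()].
#' @param halogen `"Cl"`, `"Br"` or `"I"`.
#' @return `data.table` with columns halogen, x, z, d, y_rot, tilt_axis,
#'   tilt_dev; attribute `kind = "grid"`.
#' @export
enumerate_systematic <- function(spec = grid_spec(), halogen = "I") {
  stopifnot(inherits(spec, "xb_grid_spec"))
  if (!halogen %in% names(.geom_defaults$cx)) stop("unknown halogen: ", halogen)
  tab <- data.table::CJ(x = spec$x, z = spec$z, d = spec$distances,
                        y_rot = spec$y_rotations, tilt_axis = spec$tilt_axes,
                        tilt_dev = spec$tilt_deviations, sorted = FALSE)
  if (isTRUE(spec$dedupe))
    tab <- tab[tab$tilt_dev != 0 | tab$tilt_axis == spec$tilt_axes[1L], ]
  tab <- cbind(data.table::data.table(halogen = halogen), tab)
  data.table::setattr(tab, "kind", "grid")
  tab[]
}

#' Sample random poses
#'
#' Draws `n` unique parameter tuples (x, z, y, y_rot, alpha, psi) uniformly
#' within the spec ranges, reproducibly under the spec seed. Two tuples are
#' duplicates if all six parameters agree within 1e-6; duplicates are
#' resampled, and failure to reach `n` unique tuples within `max_attempts`
#' draws is an error.
#'
#' @param spec [random_spec()].
#' @param halogen `"Cl"`, `"Br"` or `"I"`.
#' @param max_attempts Total draw budget (default `50 * n`).
#' @return `data.table` with columns halogen, x, z, y, y_rot, alpha, psi;
#'   attribute `kind = "random"`.
#' @export
generate_random <- function(spec = random_spec(), halogen = "I",
                            max_attempts = 50L * spec$n) {
  stopifnot(inherits(spec, "xb_random_spec"))
  if (!halogen %in% names(.geom_defaults$cx)) stop("unknown halogen: ", halogen)
  draw <- function(k) {
    cbind(x = stats::runif(k, spec$x_range[1], spec$x_range[2]),
          z = stats::runif(k, spec$z_range[1], spec$z_range[2]),
          y = stats::runif(k, spec$y_range[1], spec$y_range[2]),
          y_rot = stats::runif(k, spec$y_rot_range[1], spec$y_rot_range[2]),
          alpha = stats::runif(k, spec$alpha_range[1], spec$alpha_range[2]),
          psi = stats::runif(k, 0, 360))
  }
  old <- .Random.seed.exists()
  set.seed(spec$seed)
  kept <- matrix(numeric(0), 0, 6)
  attempts <- 0L
  while (nrow(kept) < spec$n) {
    need <- spec$n - nrow(kept)
    if (attempts + need > max_attempts)
      stop("could not reach ", spec$n, " unique pose tuples within ",
           max_attempts, " attempts")
    batch <- draw(need)
    attempts <- attempts + need
    all_rows <- rbind(kept, batch)
    dup <- duplicated(pose_tuple_key(all_rows))
    kept <- all_rows[!dup, , drop = FALSE]
  }
  .Random.seed.restore(old)
  tab <- data.table::as.data.table(kept)
  data.table::setnames(tab, c("x", "z", "y", "y_rot", "alpha", "psi"))
  tab <- cbind(data.table::data.table(halogen = halogen), tab)
  data.table::setattr(tab, "kind", "random")
  tab[]
}

# uniqueness key: tuples agreeing within ~1e-6 in every parameter collide
pose_tuple_key <- function(m) {
  apply(round(m, 6), 1, paste, collapse = "|")
}

.Random.seed.exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# orientation matrix for one pose row (list or single-row data.frame)
pose_rotation <- function(p) {
  Ry <- rotation_about(c(0, 1, 0), p$y_rot)
  if (!is.null(p$tilt_axis)) {
    Rt <- rotation_about(.tilt_axes[[p$tilt_axis]], p$tilt_dev)
  } else {
    Rt <- rotation_about(c(cos(p$psi * pi / 180), 0, sin(p$psi * pi / 180)),
                         p$alpha)
  }
  Rt %*% Ry
}

pose_translation <- function(p) {
  c(p$x, if (!is.null(p$d)) p$d else p$y, p$z)
}

#' Materialize one pose as a donor-acceptor complex
#'
#' @param p One pose-table row (as list, or single-row data.frame from
#'   [enumerate_systematic()] / [generate_random()]).
#' @param acceptor Acceptor benzene (canonical by default).
#' @return Object of class `xb_complex` with `donor`, `acceptor`, `meta`.
#' @export
build_pose <- function(p, acceptor = build_benzene()) {
  p <- as.list(p)
  donor <- build_halobenzene(p$halogen)
  donor <- apply_transform(donor, rigid_transform(pose_rotation(p),
                                                  pose_translation(p)))
  structure(list(donor = donor, acceptor = acceptor, meta = p),
            class = "xb_complex")
}

#' @export
print.xb_complex <- function(x, ...) {
  cat(sprintf("<xb_complex: %s donor, %d + %d atoms>\n",
              x$donor$elements[x$donor$roles == "halogen"],
              n_atoms(x$donor), n_atoms(x$acceptor)))
  invisible(x)
}

# shared measurement core; normal must already point toward the donor side
pose_measures_core <- function(x_pos, c_pos, normal, centroid) {
  rel <- x_pos - centroid
  d_plane <- sum(rel * normal)
  foot <- rel - d_plane * normal
  list(d_plane = d_plane,
       alpha = vec_angle(c_pos - x_pos, normal),
       r_off = sqrt(sum(foot^2)))
}

#' Measure the sigma-hole pose parameters of a complex
#'
#' Returns the perpendicular halogen-to-plane distance `d_plane` (A), the
#' deviation angle `alpha` between the X->C(ipso) direction and the ring
#' normal oriented toward the donor (degrees; 0 = ideal sigma-hole
#' alignment, i.e. the C-X bond points straight at the plane), and the
#' in-plane offset `r_off` of the halogen's foot point from the ring
#' centroid (A).
#'
#' @param cx `xb_complex`.
#' @return List `d_plane`, `alpha`, `r_off`.
#' @export
measure_pose <- function(cx) {
  stopifnot(inherits(cx, "xb_complex"))
  xi <- role_index(cx$donor, "halogen")
  ci <- role_index(cx$donor, "ipso_carbon")
  if (length(xi) != 1L || length(ci) != 1L)
    stop("donor must tag exactly one halogen and one ipso carbon")
  x_pos <- cx$donor$coords[xi, ]
  pl <- plane_and_centroid(cx$acceptor, toward = x_pos)
  pose_measures_core(x_pos, cx$donor$coords[ci, ], pl$normal, pl$centroid)
}

#' Write a pose set as multi-frame XYZ plus a parameter sidecar table
#'
#' @param poses Pose table from [enumerate_systematic()]/[generate_random()].
#' @param prefix Output path prefix; writes `<prefix>.xyz` and
#'   `<prefix>_meta.csv`.
#' @param max_frames Cap on the number of XYZ frames written (the sidecar
#'   always covers every row).
#' @export
write_pose_set <- function(poses, prefix, max_frames = 1000L) {
  data.table::fwrite(poses, paste0(prefix, "_meta.csv"))
  k <- min(nrow(poses), max_frames)
  mols <- lapply(seq_len(k), function(i) {
    cx <- build_pose(poses[i, ])
    molecule(c(cx$donor$elements, cx$acceptor$elements),
             rbind(cx$donor$coords, cx$acceptor$coords))
  })
  write_xyz(mols, paste0(prefix, ".xyz"),
            comments = sprintf("pose %d", seq_len(k)))
  invisible(prefix)
}
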