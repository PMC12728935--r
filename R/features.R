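# 30-component geometric descriptor.
#
# 24 atom-pair distances (halogen, ipso carbon and the two ortho carbons,
# each to the six acceptor ring carbons), three further distances
# (halogen->ring centroid, ipso->ring centroid, perpendicular
# halogen-to-plane distance) and three angles (C-X...ring centre,
# C-X...plane normal, ortho->ortho vector...plane normal). The permutation
# that sorts the six halogen->carbon distances ascending is applied to every
# per-carbon block, which makes the descriptor invariant to relabelling of
# the benzene carbons (60-degree self-rotations).

FEATURE_SCHEMA_ID <- "xb30-v1"

#' Feature names of the `xb30-v1` descriptor schema
#' @return Character vector of length 30.
#' @export
feature_names <- function() {
  c(sprintf("d_x_b%d", 1:6), sprintf("d_ci_b%d", 1:6),
    sprintf("d_co1_b%d", 1:6), sprintf("d_co2_b%d", 1:6),
    "d_x_com", "d_ci_com", "d_x_plane",
    "a_cx_com", "a_cx_normal", "a_oo_normal")
}

# Ring-carbon ordering: ascending halogen distance, with ties (symmetric
# poses) broken lexicographically by the ipso and ortho distances. Keys are
# rounded so that floating-point jitter from rigid motions cannot flip the
# order of genuinely tied columns.
rank_ring_carbons <- function(dx, dci, dco1, dco2) {
  order(round(dx, 9), round(dci, 9), round(dco1, 9), round(dco2, 9))
}

# Core descriptor from raw coordinates. `normal` must point toward the donor.
feature_vector_core <- function(x_pos, ci_pos, co1_pos, co2_pos,
                                ring, normal, centroid) {
  dmat <- function(p) sqrt(colSums((t(ring) - p)^2))
  dx <- dmat(x_pos); dci <- dmat(ci_pos)
  dco1 <- dmat(co1_pos); dco2 <- dmat(co2_pos)
  o <- rank_ring_carbons(dx, dci, dco1, dco2)
  v <- c(dx[o], dci[o], dco1[o], dco2[o],
         sqrt(sum((x_pos - centroid)^2)),
         sqrt(sum((ci_pos - centroid)^2)),
         sum((x_pos - centroid) * normal),
         vec_angle(ci_pos - x_pos, centroid - x_pos),
         vec_angle(ci_pos - x_pos, normal),
         vec_angle(co2_pos - co1_pos, normal))
  names(v) <- feature_names()
  v
}

#' Extract the 30-component descriptor from a complex
#'
#' @param cx `xb_complex` whose donor tags a halogen, an ipso carbon and two
#'   ortho carbons, and whose acceptor is a six-membered ring.
#' @return Named numeric vector of length 30 (distances in A, angles in
#'   degrees), attribute `schema_id`.
#' @export
extract_features <- function(cx) {
  stopifnot(inherits(cx, "xb_complex"))
  xi <- role_index(cx$donor, "halogen")
  ci <- role_index(cx$donor, "ipso_carbon")
  co <- role_index(cx$donor, "ortho_carbon")
  if (length(xi) != 1L || length(ci) != 1L || length(co) != 2L)
    stop("donor must tag one halogen, one ipso carbon and two ortho carbons")
  ring <- ring_coords(cx$acceptor)
  if (nrow(ring) != 6L) stop("acceptor must expose a six-membered carbon ring")
  x_pos <- cx$donor$coords[xi, ]
  pl <- plane_and_centroid(cx$acceptor, toward = x_pos)
  v <- feature_vector_core(x_pos, cx$donor$coords[ci, ],
                           cx$donor$coords[co[1], ], cx$donor$coords[co[2], ],
                           ring, pl$normal, pl$centroid)
  attr(v, "schema_id") <- FEATURE_SCHEMA_ID
  v
}

#' Fit a per-feature min-max scaler
#'
#' @param x Numeric matrix or data.frame of feature rows (fit only on the
#'   training partition).
#' @return Object of class `xb_scaler` holding per-feature `min` and `max`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to fit a scaler")
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max),
                 names = colnames(x), schema_id = FEATURE_SCHEMA_ID),
            class = "xb_scaler")
}

#' Apply (or invert) a fitted min-max scaler
#'
#' Maps each feature through (x - min) / (max - min). Values outside the fit
#' range map outside \[0, 1\] deliberately: flagging such inputs is the
#' applicability-domain module's job, not the scaler's. Features constant in
#' the fit set (max == min) map to 0.
#'
#' @param x Feature matrix/vector (raw units, or scaled if `invert = TRUE`).
#' @param s `xb_scaler`.
#' @param invert Undo the scaling instead.
#' @return Matrix of the same shape.
#' @export
apply_scaler <- function(x, s, invert = FALSE) {
  stopifnot(inherits(s, "xb_scaler"))
  one_row <- is.null(dim(x))
  x <- if (one_row) matrix(x, 1, dimnames = list(NULL, names(x))) else as.matrix(x)
  if (ncol(x) != length(s$min))
    stop("feature width ", ncol(x), " does not match scaler width ", length(s$min))
  if (!is.null(colnames(x)) && !is.null(s$names) &&
      !identical(colnames(x), s$names))
    stop("feature schema mismatch: column names differ from the fitted scaler")
  rng <- s$max - s$min
  # features constant up to floating-point jitter map to 0 (not 1/range,
  # which would amplify rounding noise by ~1e14)
  const <- rng <= 1e-9 * pmax(abs(s$max), abs(s$min), 1)
  rng[const] <- 1
  if (invert) {
    out <- sweep(sweep(x, 2, rng, "*"), 2, s$min, "+")
  } else {
    out <- sweep(sweep(x, 2, s$min), 2, rng, "/")
    out[, const] <- 0
  }
  if (one_row) out[1, ] else out
}
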