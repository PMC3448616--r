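# Shape and electrostatic-field similarity of poses against a reference
# inhibitor pose.
#
# Shape uses the analytic first-order Gaussian-overlap formulation:
# each heavy atom is a spherical Gaussian of amplitude p = 2.7 whose
# integral reproduces its hard-sphere van der Waals volume; the shape
# Tanimoto is V_AB / (V_AA + V_BB - V_AB). The electrostatic field is a
# Coulomb potential with a distance-dependent dielectric (eps = 4r by
# default) sampled on a regular grid; the electrostatic Tanimoto is the
# Tanimoto ratio of field inner products, 1 for identical potentials and
# negative when positive and negative regions overlap.

.gauss_p <- 2.7

gauss_alpha <- function(radii) pi * (3 * .gauss_p / (4 * pi * radii^3))^(2 / 3)

heavy_coords_radii <- function(pose) {
  mol <- pose_mol(pose)
  keep <- mol$elements != "H"
  if (!any(keep)) stop("pose has no heavy atoms")
  list(xyz = pose_coords(pose)[keep, , drop = FALSE],
       r = vdw_radius(mol$elements[keep]))
}

check_frames <- function(a, b) {
  if (!identical(a$frame_tag, b$frame_tag))
    stop(sprintf("frame mismatch: '%s' vs '%s'", a$frame_tag, b$frame_tag))
}

gauss_overlap_xyz <- function(xa, ra, xb, rb) {
  aa <- gauss_alpha(ra)
  ab <- gauss_alpha(rb)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * (xa %*% t(xb))
  d2[d2 < 0] <- 0
  asum <- outer(aa, ab, "+")
  sum(.gauss_p^2 * (pi / asum)^1.5 * exp(-outer(aa, ab) / asum * d2))
}

#' Analytic Gaussian overlap volume of two poses
#'
#' First-order pairwise overlap of atom-centred Gaussians
#' (heavy atoms only), parameterized to reproduce hard-sphere van der
#' Waals volumes. Symmetric and positive.
#'
#' @param a,b `phyto_pose` objects sharing a frame.
#' @return overlap volume in cubic angstrom.
#' @export
gaussian_overlap_volume <- function(a, b) {
  check_frames(a, b)
  A <- heavy_coords_radii(a)
  B <- heavy_coords_radii(b)
  gauss_overlap_xyz(A$xyz, A$r, B$xyz, B$r)
}

#' Shape Tanimoto of two poses
#'
#' `V_AB / (V_AA + V_BB - V_AB)`; 1 corresponds to a perfect overlap
#' (the same shape), values near 0 to disjoint shapes.
#'
#' @param a,b `phyto_pose` objects sharing a frame.
#' @return shape Tanimoto score (dimensionless).
#' @export
shape_tanimoto <- function(a, b) {
  check_frames(a, b)
  A <- heavy_coords_radii(a)
  B <- heavy_coords_radii(b)
  vab <- gauss_overlap_xyz(A$xyz, A$r, B$xyz, B$r)
  vaa <- gauss_overlap_xyz(A$xyz, A$r, A$xyz, A$r)
  vbb <- gauss_overlap_xyz(B$xyz, B$r, B$xyz, B$r)
  vab / (vaa + vbb - vab)
}

#' Scalar-field grid
#' @param origin 3D coordinate of the first voxel centre.
#' @param spacing voxel edge in angstrom (> 0).
#' @param dims integer vector of three grid dimensions.
#' @param values numeric array of voxel values (`prod(dims)` entries).
#' @param mask optional logical array; `FALSE` voxels are excluded from
#'   field comparisons (used to blank the singular molecular core).
#' @return object of class `field_grid`.
#' @export
field_grid <- function(origin, spacing, dims, values, mask = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, spacing > 0, length(dims) == 3L,
            length(values) == prod(dims))
  values <- array(values, dim = dims)
  if (!is.null(mask)) {
    stopifnot(length(mask) == prod(dims))
    mask <- array(as.logical(mask), dim = dims)
  }
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dims, values = values, mask = mask),
            class = "field_grid")
}

grid_points <- function(g) {
  ax <- lapply(1:3, function(k) g$origin[k] + (seq_len(g$dims[k]) - 1L) * g$spacing)
  as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))  # column-major like array
}

#' Electrostatic potential of a pose on a grid
#'
#' Coulomb sum `V(x) = sum_i q_i / (eps(r_i) r_i)` over all atoms
#' (hydrogens included), with `eps(r) = 4r` for the default
#' distance-dependent dielectric and distances clamped below
#' `r_clamp` to avoid the nuclear singularity. Units are arbitrary but
#' consistent, which is all a Tanimoto comparison needs.
#'
#' @param pose a `phyto_pose` with partial charges assigned.
#' @param origin,spacing,dims grid geometry (see [field_grid()]).
#' @param dielectric `"distance"` for eps(r) = 4r, `"constant"` for
#'   vacuum-like eps = 1.
#' @param r_clamp minimum distance (angstrom) entering the denominator.
#' @return a [field_grid()].
#' @export
potential_grid <- function(pose, origin, spacing, dims,
                           dielectric = c("distance", "constant"),
                           r_clamp = 1.0) {
  dielectric <- match.arg(dielectric)
  mol <- pose_mol(pose)
  if (is.null(mol$pcharge)) stop("pose has no partial charges assigned")
  pts <- grid_points(field_grid(origin, spacing, dims, numeric(prod(dims))))
  xyz <- pose_coords(pose)
  v <- numeric(nrow(pts))
  for (i in seq_len(nrow(xyz))) {
    r <- sqrt(rowSums(sweep(pts, 2, xyz[i, ])^2))
    r <- pmax(r, r_clamp)
    v <- v + if (dielectric == "distance") mol$pcharge[i] / (4 * r^2) else
      mol$pcharge[i] / r
  }
  field_grid(origin, spacing, dims, v)
}

#' Electrostatic Tanimoto of two field grids
#'
#' `O_AB / (O_AA + O_BB - O_AB)` with `O_XY` the voxel-wise inner
#' product over unmasked voxels. Equals 1 for identical fields and turns
#' negative when opposed charges overlap (`O_AB < 0`).
#'
#' @param a,b [field_grid()] objects with identical geometry.
#' @return electrostatic Tanimoto score.
#' @export
electrostatic_tanimoto <- function(a, b) {
  stopifnot(inherits(a, "field_grid"), inherits(b, "field_grid"))
  if (max(abs(a$origin - b$origin)) > 1e-9 ||
      abs(a$spacing - b$spacing) > 1e-9 || !identical(a$dims, b$dims))
    stop("grid geometry mismatch")
  w <- rep(TRUE, prod(a$dims))
  if (!is.null(a$mask)) w <- w & as.vector(a$mask)
  if (!is.null(b$mask)) w <- w & as.vector(b$mask)
  va <- as.vector(a$values)[w]
  vb <- as.vector(b$values)[w]
  oaa <- sum(va * va); obb <- sum(vb * vb); oab <- sum(va * vb)
  if (oaa == 0 && obb == 0) stop("both fields are identically zero")
  oab / (oaa + obb - oab)
}

#' Shape and electrostatic scores of a pose against a reference
#'
#' Both molecules are placed on a common grid (union bounding box plus
#' padding); voxels inside either molecular core (closer than
#' `core_radius` to any nucleus) are masked from the electrostatic sum.
#' `et_combo` is the sum of the shape and electrostatic Tanimotos.
#'
#' @param pose,reference `phyto_pose` objects with charges, same frame.
#' @param grid_spec list with `spacing`, `padding`, `core_radius`,
#'   `dielectric` overrides (defaults 0.5 A, 4 A, 1.2 A, "distance").
#' @return object of class `field_scores`: `st`, `et_pb`, `et_combo`.
#' @export
score_pose <- function(pose, reference, grid_spec = list()) {
  check_frames(pose, reference)
  spec <- modifyList(list(spacing = 0.5, padding = 4.0, core_radius = 1.2,
                          dielectric = "distance"), grid_spec)
  xa <- pose_coords(pose)
  xb <- pose_coords(reference)
  lo <- pmin(apply(xa, 2, min), apply(xb, 2, min)) - spec$padding
  hi <- pmax(apply(xa, 2, max), apply(xb, 2, max)) + spec$padding
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spec$spacing)) + 1L)
  ga <- potential_grid(pose, lo, spec$spacing, dims, spec$dielectric)
  gb <- potential_grid(reference, lo, spec$spacing, dims, spec$dielectric)
  pts <- grid_points(ga)
  near <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(xa))) {
    near <- near | rowSums(sweep(pts, 2, xa[i, ])^2) < spec$core_radius^2
  }
  for (i in seq_len(nrow(xb))) {
    near <- near | rowSums(sweep(pts, 2, xb[i, ])^2) < spec$core_radius^2
  }
  mask <- array(!near, dim = dims)
  ga$mask <- mask
  gb$mask <- mask
  st <- shape_tanimoto(pose, reference)
  et <- electrostatic_tanimoto(ga, gb)
  structure(list(st = st, et_pb = et, et_combo = st + et),
            class = "field_scores")
}

#' @export
print.field_scores <- function(x, ...) {
  cat(sprintf("<field_scores> ST %.3f  ET_pb %.3f  ET_combo %.3f\n",
              x$st, x$et_pb, x$et_combo))
  invisible(x)
}

#' Acceptance thresholds for the field-similarity filter
#'
#' The shipped defaults are the published operating point of the DPP-IV
#' screen (`ET_pb >= 0.468` and `ST >= 0.237`); [calibrate_thresholds()]
#' re-derives thresholds from a reference panel under this package's
#' field model.
#'
#' @param et_pb_min minimum electrostatic Tanimoto.
#' @param st_min minimum shape Tanimoto.
#' @return object of class `field_thresholds`.
#' @export
field_thresholds <- function(et_pb_min = 0.468, st_min = 0.237) {
  stopifnot(et_pb_min <= 1, st_min <= 1)
  structure(list(et_pb_min = et_pb_min, st_min = st_min),
            class = "field_thresholds")
}

#' Calibrate thresholds from a panel of known-inhibitor poses
#'
#' Scores every panel pose against the reference and returns the panel
#' minima of the electrostatic and shape Tanimotos, the most permissive
#' operating point that still accepts every known inhibitor pose.
#'
#' @param reference reference `phyto_pose` (charges assigned).
#' @param panel non-empty list of `phyto_pose` (charges assigned).
#' @param grid_spec grid overrides passed to [score_pose()].
#' @return a [field_thresholds()] with attribute `panel_scores`.
#' @export
calibrate_thresholds <- function(reference, panel, grid_spec = list()) {
  if (!length(panel)) stop("calibration panel is empty")
  scores <- lapply(panel, score_pose, reference = reference,
                   grid_spec = grid_spec)
  th <- field_thresholds(
    et_pb_min = min(vapply(scores, `[[`, 0, "et_pb")),
    st_min = min(vapply(scores, `[[`, 0, "st")))
  attr(th, "panel_scores") <- scores
  th
}
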