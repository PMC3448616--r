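test_that("analytic Gaussian overlaps match 3D quadrature within 1%", {
  c1 <- make_test_pose("c1", "C", rbind(c(0, 0, 0)))
  c2 <- make_test_pose("c2", "C", rbind(c(1, 0, 0)))
  v <- gaussian_overlap_volume(c1, c2)
  q <- quadrature_overlap("C", rbind(c(0, 0, 0)), "C", rbind(c(1, 0, 0)))
  expect_lt(abs(v - q) / q, 0.01)
  # mixed-element multi-atom system
  ea <- c("C", "N", "O")
  xa <- rbind(c(0, 0, 0), c(1.4, 0.3, 0), c(0.4, 1.2, 0.5))
  eb <- c("C", "C")
  xb <- rbind(c(0.5, 0.5, 0.2), c(1.8, 1.0, -0.3))
  pa <- make_test_pose("pa", ea, xa)
  pb <- make_test_pose("pb", eb, xb)
  v2 <- gaussian_overlap_volume(pa, pb)
  q2 <- quadrature_overlap(ea, xa, eb, xb)
  expect_lt(abs(v2 - q2) / q2, 0.01)
  st <- shape_tanimoto(pa, pb)
  qaa <- quadrature_overlap(ea, xa, ea, xa)
  qbb <- quadrature_overlap(eb, xb, eb, xb)
  expect_equal(st, q2 / (qaa + qbb - q2), tolerance = 0.01)
})

test_that("shape Tanimoto identities: self is 1, far pairs vanish, symmetric", {
  a <- fragment_pose("a")
  expect_equal(shape_tanimoto(a, a), 1, tolerance = 1e-9)
  far <- fragment_pose("far", shift = c(50, 0, 0))
  expect_lt(gaussian_overlap_volume(a, far), 1e-9)
  expect_lt(shape_tanimoto(a, far), 1e-9)
  b <- make_test_pose("b", c("C", "O"), rbind(c(0.4, 0.2, 0), c(1.6, 0.7, 0.2)))
  expect_equal(shape_tanimoto(a, b), shape_tanimoto(b, a), tolerance = 1e-12)
  expect_error(shape_tanimoto(a, fragment_pose("x", frame = "other")),
               "frame mismatch")
})

test_that("potential grids obey symmetry and match hand-computed Coulomb sums", {
  mono <- make_test_pose("q", "N", rbind(c(0, 0, 0)), pcharge = 1)
  g <- potential_grid(mono, origin = c(-2, -2, -2), spacing = 1, dims = c(5, 5, 5))
  expect_equal(g$values, g$values[5:1, , ], tolerance = 1e-12)  # mirror symmetry
  dip <- make_test_pose("d", c("N", "N"), rbind(c(-1, 0, 0), c(1, 0, 0)),
                        pcharge = c(1, -1))
  gd <- potential_grid(dip, origin = c(0, -2, -2), spacing = 1, dims = c(1, 5, 5))
  expect_lt(max(abs(gd$values)), 1e-9)  # midplane of a symmetric dipole
  # direct evaluation oracle at sampled voxels, eps(r) = 4r
  two <- make_test_pose("t", c("C", "O"), rbind(c(0, 0, 0), c(2, 0, 0)),
                        pcharge = c(0.4, -0.6))
  gt <- potential_grid(two, origin = c(-1, -1, -1), spacing = 1, dims = c(4, 3, 3))
  pts <- rbind(c(-1, -1, -1), c(0, 0, 0), c(2, 1, 1), c(1, 0, -1), c(2, -1, 1))
  for (p in seq_len(nrow(pts))) {
    r1 <- max(sqrt(sum((pts[p, ] - c(0, 0, 0))^2)), 1.0)
    r2 <- max(sqrt(sum((pts[p, ] - c(2, 0, 0))^2)), 1.0)
    manual <- 0.4 / (4 * r1^2) - 0.6 / (4 * r2^2)
    idx <- pts[p, ] - c(-1, -1, -1) + 1
    expect_equal(gt$values[idx[1], idx[2], idx[3]], manual, tolerance = 1e-12)
  }
  uncharged <- make_test_pose("u", "C", rbind(c(0, 0, 0)))
  expect_error(potential_grid(uncharged, c(0, 0, 0), 1, c(2, 2, 2)),
               "no partial charges")
})

test_that("electrostatic Tanimoto matches direct inner products on tiny grids", {
  va <- c(1, 2, -1, 0.5, 0, 3, -2, 1)
  vb <- c(0.5, 1, 1, -0.5, 2, 0, 1, -1)
  a <- field_grid(c(0, 0, 0), 1, c(2, 2, 2), va)
  b <- field_grid(c(0, 0, 0), 1, c(2, 2, 2), vb)
  oaa <- sum(va^2); obb <- sum(vb^2); oab <- sum(va * vb)
  expect_equal(electrostatic_tanimoto(a, b), oab / (oaa + obb - oab),
               tolerance = 1e-12)
  expect_equal(electrostatic_tanimoto(a, a), 1, tolerance = 1e-12)
  neg <- field_grid(c(0, 0, 0), 1, c(2, 2, 2), -va)
  expect_lt(electrostatic_tanimoto(a, neg), 0)
  # scale invariance under a common positive factor
  expect_equal(electrostatic_tanimoto(field_grid(c(0, 0, 0), 1, c(2, 2, 2), 7 * va),
                                      field_grid(c(0, 0, 0), 1, c(2, 2, 2), 7 * vb)),
               electrostatic_tanimoto(a, b), tolerance = 1e-12)
  off <- field_grid(c(1, 0, 0), 1, c(2, 2, 2), vb)
  expect_error(electrostatic_tanimoto(a, off), "geometry mismatch")
  zero <- field_grid(c(0, 0, 0), 1, c(2, 2, 2), numeric(8))
  expect_error(electrostatic_tanimoto(zero, zero), "identically zero")
})

test_that("pose scoring decomposes into st + et_pb and honours identities", {
  ref <- fragment_pose("ref")
  s <- score_pose(ref, ref)
  expect_equal(s$st, 1, tolerance = 1e-9)
  expect_equal(s$et_pb, 1, tolerance = 1e-9)
  expect_equal(s$et_combo, 2, tolerance = 1e-9)
  for (shift in list(c(1, 0.5, 0), c(-2, 1, 1))) {
    other <- fragment_pose("o", shift = shift)
    sc <- score_pose(other, ref)
    expect_equal(sc$et_combo - sc$st - sc$et_pb, 0, tolerance = 1e-12)
  }
  far <- fragment_pose("far", shift = c(20, 0, 0))
  expect_lt(score_pose(far, ref)$st, 1e-6)
})

test_that("shape Tanimoto is invariant under a common rigid motion", {
  ref <- fragment_pose("ref")
  other <- fragment_pose("o", shift = c(1.2, -0.4, 0.7))
  st0 <- shape_tanimoto(other, ref)
  for (seed in c(2, 9)) {
    tr <- phytophore:::random_rigid_transform(seed)
    move <- function(p) {
      p$conformer$coords <- phytophore:::apply_rigid(pose_coords(p), tr$R, tr$t)
      p$conformer$mol$coords <- p$conformer$coords
      p
    }
    expect_equal(shape_tanimoto(move(other), move(ref)), st0,
                 tolerance = 1e-6)
  }
})

test_that("threshold calibration takes panel minima", {
  ref <- fragment_pose("ref")
  solo <- calibrate_thresholds(ref, list(ref))
  expect_equal(solo$et_pb_min, 1, tolerance = 1e-9)
  expect_equal(solo$st_min, 1, tolerance = 1e-9)
  panel <- list(fragment_pose("p1", shift = c(0.6, 0, 0)),
                fragment_pose("p2", shift = c(1.5, 0.8, 0)))
  th <- calibrate_thresholds(ref, panel)
  sc <- lapply(panel, score_pose, reference = ref)
  expect_equal(th$et_pb_min, min(vapply(sc, `[[`, 0, "et_pb")))
  expect_equal(th$st_min, min(vapply(sc, `[[`, 0, "st")))
  expect_error(calibrate_thresholds(ref, list()), "empty")
  # shipped defaults are the published operating point
  expect_equal(field_thresholds()$et_pb_min, 0.468)
  expect_equal(field_thresholds()$st_min, 0.237)
})
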