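test_that("pharmacophore definition files load with validated structure", {
  path <- withr::local_tempfile(fileext = ".phore")
  model <- make_toy_pharmacophore(1)
  write_pharmacophore(model, path)
  back <- load_pharmacophore(path)
  expect_length(back$features, 7L)
  expect_identical(vapply(back$features, `[[`, TRUE, "mandatory"),
                   vapply(model$features, `[[`, TRUE, "mandatory"))
  expect_length(back$excluded, 3L)
  one <- withr::local_tempfile(fileext = ".phore")
  writeLines(c("FRAME f", "FEATURE acceptor 0 0 0 1.5 mandatory"), one)
  expect_length(load_pharmacophore(one)$features, 1L)
  bad <- withr::local_tempfile(fileext = ".phore")
  writeLines(c("FRAME f", "FEATURE acceptor 0 0 0 1.5 optional"), bad)
  expect_error(load_pharmacophore(bad), "mandatory")
})

test_that("the shipped DPP-IV style definition has 2 mandatory and 5 optional sites", {
  model <- load_pharmacophore(system.file(
    "extdata", "dppiv_pharmacophore_synthetic.phore", package = "phytophore"))
  mand <- vapply(model$features, `[[`, TRUE, "mandatory")
  expect_identical(sum(mand), 2L)
  expect_identical(sum(!mand), 5L)
  kinds <- vapply(model$features, `[[`, "", "kind")
  expect_setequal(kinds[mand], c("positive_or_donor", "hydrophobic_or_aromatic"))
  expect_identical(sum(kinds == "acceptor"), 2L)
  expect_gte(length(model$excluded), 3L)
})

test_that("feature perception finds ring centroids, donors and acceptors", {
  benz <- smiles_to_mol("c1ccccc1", "benzene")
  benz$coords <- build_base_coords(benz)
  f <- perceive_features(benz)
  expect_identical(nrow(f), 1L)
  expect_identical(f$kind, "hydrophobic_or_aromatic")
  expect_lt(max(abs(as.numeric(f[1, c("x", "y", "z")]) -
                      colMeans(benz$coords))), 1e-9)
  ba <- protonate_ph7(smiles_to_mol("NCc1ccccc1", "benzylamine"))
  ba$coords <- build_base_coords(ba)
  fb <- perceive_features(ba)
  expect_gte(sum(fb$kind == "positive_or_donor"), 1L)
  expect_identical(sum(fb$kind == "hydrophobic_or_aromatic"), 1L)
  meth <- smiles_to_mol("C", "methane")
  meth$coords <- build_base_coords(meth)
  expect_identical(nrow(perceive_features(meth)), 0L)
})

test_that("reorienting matcher recovers rigidly displaced ligands exactly", {
  model <- make_toy_pharmacophore(3)
  fix <- make_funnel_library(fixture_spec(3, 1, 0, 0, 0), model)
  mol <- fix$molecules[[1]]
  for (seed in c(11, 12, 13)) {
    tr <- phytophore:::random_rigid_transform(seed)
    moved <- mol
    moved$coords <- phytophore:::apply_rigid(mol$coords, tr$R, tr$t)
    res <- match_with_reorientation(new_conformer(moved, moved$coords), model)
    expect_true(res$matched)
    ref <- match_with_reorientation(new_conformer(mol, mol$coords), model)
    expect_identical(res$n_matched, ref$n_matched)
    expect_lt(abs(res$rmsd - ref$rmsd), 1e-6)
  }
})

test_that("a ligand matching only the two mandatory sites is rejected", {
  model <- make_toy_pharmacophore(1)
  fix <- make_funnel_library(fixture_spec(1, 0, 1, 0, 0), model)
  res <- match_with_reorientation(
    new_conformer(fix$molecules[[1]], fix$molecules[[1]]$coords), model)
  expect_false(res$matched)
})

test_that("excluded-volume clashes force rejection and are reported", {
  model <- make_toy_pharmacophore(1)
  fix <- make_funnel_library(fixture_spec(1, 1, 0, 0, 0), model)
  mol <- fix$molecules[[1]]
  res0 <- match_with_reorientation(new_conformer(mol, mol$coords), model)
  expect_true(res0$matched)
  # plant a sphere right on a ligand heavy atom
  clashed <- pharmacophore_model(
    model$features, c(model$excluded,
                      list(excluded_volume(mol$coords[3, ], 1.5))),
    model$frame_tag)
  res <- match_with_reorientation(new_conformer(mol, mol$coords), clashed)
  expect_false(res$matched)
  expect_true(res$clash)
})

test_that("static matching uses the pose as docked and checks frames", {
  model <- make_toy_pharmacophore(1)
  fix <- make_funnel_library(fixture_spec(1, 1, 0, 0, 0), model)
  pose <- fix$poses[[fix$molecules[[1]]$id]][[1]]
  expect_true(match_pose_static(pose, model)$matched)
  shifted <- pose
  shifted$conformer$coords <- pose_coords(pose) + 10
  shifted$conformer$mol$coords <- shifted$conformer$coords
  expect_false(match_pose_static(shifted, model)$matched)
  expect_true(match_with_reorientation(shifted$conformer, model)$matched)
  wrong <- pose
  wrong$frame_tag <- "another-frame"
  expect_error(match_pose_static(wrong, model), "frame mismatch")
})

test_that("static success implies reorienting success on the fixture suite", {
  model <- make_toy_pharmacophore(5)
  fix <- make_funnel_library(fixture_spec(5, 3, 2, 2, 1), model)
  for (id in names(fix$poses)) {
    for (pose in fix$poses[[id]]) {
      if (match_pose_static(pose, model)$matched) {
        expect_true(match_with_reorientation(pose$conformer, model)$matched,
                    label = sprintf("reorientation succeeds for %s", id))
      }
    }
  }
})

test_that("acceptance is monotone when feature tolerances grow", {
  model <- make_toy_pharmacophore(2)
  fix <- make_funnel_library(fixture_spec(2, 2, 2, 1, 1), model)
  grow <- function(model, f) {
    pharmacophore_model(lapply(model$features, function(ft) {
      ft$tolerance <- ft$tolerance * f
      ft
    }), model$excluded, model$frame_tag)
  }
  big <- grow(model, 2.5)
  for (m in fix$molecules) {
    r1 <- match_with_reorientation(new_conformer(m, m$coords), model)
    if (r1$matched) {
      expect_true(match_with_reorientation(new_conformer(m, m$coords),
                                           big)$matched)
    }
  }
})

test_that("derived excluded volumes equal a brute-force distance scan", {
  pdb_path <- withr::local_tempfile(fileext = ".pdb")
  set.seed(42)
  rec <- matrix(runif(30, -6, 6), 10, 3)
  lines <- vapply(seq_len(10), function(i)
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, i, rec[i, 1], rec[i, 2], rec[i, 3]), "")
  writeLines(c(lines, "END"), pdb_path)
  lig <- fragment_pose("lig")
  for (shell in c(4, 5)) {
    vols <- suppressWarnings(derive_excluded_volumes(pdb_path, lig, shell))
    expected <- sum(apply(rec, 1, function(a)
      min(sqrt(rowSums(sweep(pose_coords(lig), 2, a)^2))) <= shell))
    expect_length(vols, expected)
  }
  expect_warning(v0 <- derive_excluded_volumes(pdb_path, lig, shell = 0),
                 "empty pocket")
  expect_length(v0, 0L)
})
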