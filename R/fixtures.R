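# Deterministic synthetic fixtures: a toy pharmacophore mirroring the
# 2-mandatory / 5-optional DPP-IV topology, screening libraries with
# planted stage-by-stage funnel outcomes, and molecule collections with
# planted scaffold families. Every generator is a pure function of its
# spec and seed.

#' Specification of a planted funnel fixture
#'
#' @param seed integer seed (drives the small geometric jitter).
#' @param n_pass_all molecules passing every funnel stage.
#' @param n_fail_pharmacophore molecules matching only the two
#'   mandatory sites (rejected at stage 1: no optional site).
#' @param n_fail_static molecules whose docked pose is displaced from
#'   the productive orientation (pass stage 1, fail the static
#'   re-filter).
#' @param n_fail_thresholds molecules with opposed electrostatics
#'   (pass the static re-filter, fail the ET_pb threshold; shape is
#'   left untouched so the two threshold conditions stay independent).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_pass_all = 4L, n_fail_pharmacophore = 3L,
                         n_fail_static = 2L, n_fail_thresholds = 1L) {
  counts <- c(n_pass_all, n_fail_pharmacophore, n_fail_static,
              n_fail_thresholds)
  stopifnot(all(counts >= 0L), sum(counts) >= 1L)
  structure(list(seed = as.integer(seed), n_pass_all = n_pass_all,
                 n_fail_pharmacophore = n_fail_pharmacophore,
                 n_fail_static = n_fail_static,
                 n_fail_thresholds = n_fail_thresholds),
            class = "fixture_spec")
}

#' Toy pharmacophore model with the DPP-IV screen's topology
#'
#' Two mandatory features (one positive/donor, one hydrophobic/aromatic
#' ring) and five optional features (two acceptors, three rings), plus
#' three excluded-volume spheres placed away from the ligand region.
#' The topology is fixed; the seed jitters the geometry reproducibly.
#'
#' @param seed integer seed.
#' @param tolerance per-feature matching radius in angstrom.
#' @return a [pharmacophore_model()].
#' @export
make_toy_pharmacophore <- function(seed = 1L, tolerance = 2.0) {
  base <- rbind(
    c(0, 0, 0),        # mandatory positive/donor
    c(4.5, 0, 0),      # mandatory ring
    c(2.0, 3.0, 0.5),  # optional acceptor
    c(-2.5, 2.0, -0.5),# optional acceptor
    c(7.5, 2.5, 0),    # optional ring
    c(2.0, -3.5, 1.0), # optional ring
    c(-1.5, 4.5, -1.5))# optional ring
  kinds <- c("positive_or_donor", "hydrophobic_or_aromatic", "acceptor",
             "acceptor", rep("hydrophobic_or_aromatic", 3))
  mand <- c(TRUE, TRUE, rep(FALSE, 5))
  jit <- with_preserved_rng({
    set.seed(seed)
    matrix(runif(21, -0.3, 0.3), 7, 3)
  })
  feats <- lapply(seq_len(7), function(k)
    phore_feature(kinds[k], base[k, ] + jit[k, ], tolerance, mand[k]))
  excl <- list(excluded_volume(c(0, -3.0, -3.0), 1.5),
               excluded_volume(c(5.0, 3.5, -3.0), 1.5),
               excluded_volume(c(-3.5, -2.5, 2.0), 1.5))
  pharmacophore_model(feats, excl, frame_tag = "toy-receptor-frame")
}

# template ligand built directly in the model frame: an aromatic
# hexagon on the mandatory ring feature, an amine nitrogen on the
# mandatory donor feature and a carbonyl oxygen on the first optional
# acceptor. `charged_n` FALSE keeps a neutral N-H donor so electrostatic
# failures can be planted without touching the pharmacophore.
build_template_mol <- function(id, model, jitter = NULL, charged_n = TRUE,
                               negate_charges = FALSE) {
  kinds <- vapply(model$features, `[[`, "", "kind")
  mand <- vapply(model$features, `[[`, TRUE, "mandatory")
  donor_c <- model$features[[which(mand & kinds == "positive_or_donor")[1]]]$center
  ring_c <- model$features[[which(mand & kinds == "hydrophobic_or_aromatic")[1]]]$center
  acc_i <- which(!mand & kinds == "acceptor")
  if (!length(acc_i))
    stop("infeasible fixture: model has no optional acceptor feature")
  acc_c <- model$features[[acc_i[1]]]$center
  u <- unitv(donor_c - ring_c)
  w <- perp_vector(u)
  v <- unitv(cross3(u, w))
  hex <- t(vapply(0:5, function(k) {
    ang <- k * pi / 3
    ring_c + 1.40 * (cos(ang) * u + sin(ang) * w)
  }, numeric(3)))
  c1 <- hex[1, ]                       # ring vertex facing the donor
  c7 <- c1 + 1.50 * unitv(donor_c - c1)
  n8 <- donor_c
  c9 <- acc_c + 1.23 * unitv(c7 - acc_c)
  o10 <- acc_c
  coords <- rbind(hex, c7, n8, c9, o10)
  if (!is.null(jitter)) coords <- coords + jitter
  bonds <- data.frame(
    i = c(1, 2, 3, 4, 5, 6, 1, 7, 7, 9),
    j = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10),
    order = c(2, 1, 2, 1, 2, 1, 1, 1, 1, 2))
  fcharge <- c(rep(0L, 7), if (charged_n) 1L else 0L, 0L, 0L)
  q <- c(rep(-0.03, 6), 0.25, if (charged_n) 0.9 else 0.55, 0.38, -0.35)
  q <- q + (sum(fcharge) - sum(q)) / length(q)
  if (negate_charges) q <- -q + (sum(fcharge) - sum(-q)) / length(q)
  phyto_mol(id, elements = c(rep("C", 6), "C", "N", "C", "O"),
            fcharge = fcharge, bonds = bonds, coords = coords, pcharge = q)
}

#' Planted-outcome screening library
#'
#' Builds molecules and in-frame poses whose funnel fate is known by
#' construction: full passers sit on the feature centers with
#' reference-like charges; stage-1 failures present only the two
#' mandatory sites; static failures are rigidly displaced docked poses
#' of otherwise-passing molecules; threshold failures have their charge
#' pattern negated (shape untouched). Deterministic for a fixed spec.
#'
#' @param spec a [fixture_spec()].
#' @param model a [make_toy_pharmacophore()]-style model.
#' @return list: `molecules`, `poses` (named list of pose lists),
#'   `labels` (named vector: pass / fail_pharmacophore / fail_static /
#'   fail_thresholds), `reference` (a charged `phyto_pose`), `model`.
#' @export
make_funnel_library <- function(spec, model = make_toy_pharmacophore()) {
  stopifnot(inherits(spec, "fixture_spec"))
  frame <- model$frame_tag
  jitters <- with_preserved_rng({
    set.seed(spec$seed)
    total <- spec$n_pass_all + spec$n_fail_pharmacophore +
      spec$n_fail_static + spec$n_fail_thresholds
    lapply(seq_len(total), function(k) matrix(runif(30, -0.12, 0.12), 10, 3))
  })
  mols <- list(); poses <- list(); labels <- character()
  ji <- 0L
  nxt <- function() { ji <<- ji + 1L; jitters[[ji]] }
  add <- function(m, pose_coords, label) {
    mols[[length(mols) + 1L]] <<- m
    pm <- m; pm$coords <- pose_coords
    poses[[m$id]] <<- list(as_pose(pm, frame))
    labels[m$id] <<- label
  }
  for (k in seq_len(spec$n_pass_all)) {
    m <- build_template_mol(sprintf("PASS_%02d", k), model, jitter = nxt())
    add(m, m$coords, "pass")
  }
  for (k in seq_len(spec$n_fail_pharmacophore)) {
    full <- build_template_mol(sprintf("NOPH_%02d", k), model, jitter = nxt())
    # keep only ring + linker + amine: both mandatory sites, no optional
    keep <- 1:8
    m <- phyto_mol(full$id, full$elements[keep], full$fcharge[keep],
                   full$bonds[full$bonds$i %in% keep & full$bonds$j %in% keep, ],
                   coords = full$coords[keep, ],
                   pcharge = {
                     q <- full$pcharge[keep]
                     q + (sum(full$fcharge[keep]) - sum(q)) / length(q)
                   })
    add(m, m$coords, "fail_pharmacophore")
  }
  displace <- random_rigid_transform(spec$seed + 1000L)
  for (k in seq_len(spec$n_fail_static)) {
    m <- build_template_mol(sprintf("NOST_%02d", k), model, jitter = nxt())
    moved <- apply_rigid(m$coords, displace$R, displace$t)
    m$coords <- moved
    add(m, moved, "fail_static")
  }
  for (k in seq_len(spec$n_fail_thresholds)) {
    m <- build_template_mol(sprintf("NOTH_%02d", k), model, jitter = nxt(),
                            charged_n = FALSE, negate_charges = TRUE)
    add(m, m$coords, "fail_thresholds")
  }
  ref <- build_template_mol("REFERENCE", model)
  list(molecules = mols, poses = poses, labels = labels,
       reference = as_pose(ref, frame), model = model)
}

#' Write a funnel fixture to SDF files
#'
#' Byte-identical output for identical spec and seed.
#'
#' @param fixture result of [make_funnel_library()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_funnel_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_molecules(fixture$molecules, file.path(dir, "library.sdf"))
  write_poses(unlist(fixture$poses, recursive = FALSE),
              file.path(dir, "poses.sdf"))
  write_poses(list(fixture$reference), file.path(dir, "reference.sdf"))
  invisible(dir)
}

# Tricyclic cores from well-separated chemotype classes. Members attach
# a single varying head atom through a constant ethylene linker, so
# every within-family pair differs by a constant-size environment set:
# the first two (aza-aromatic) cores give exactly equal within-family
# spreads, which keeps Kelley level selection stable even for
# two-family collections; the aliphatic N/O/S cores fill out larger
# collections.
.scaffold_cores <- c("c1ccc2ncc3ccncc3c2n1", "c1ccc2ncc3ccccc3c2c1",
                     "C1CCC2NCC3CCNCC3C2N1", "C1CCC2OCC3CCOCC3C2O1",
                     "C1CCC2SCC3CCSCC3C2S1")
# single-heteroatom heads on an ethylene linker: uniform perturbation
.scaffold_subs <- c("CCC", "NCC", "OCC", "FCC", "SCC", "ClCC", "BrCC",
                    "ICC")

#' Molecule collection with planted scaffold families
#'
#' Each family decorates one core SMILES with distinct small
#' substituents; the generator asserts that within-family Tanimoto
#' similarity exceeds every between-family similarity and errors out
#' when the requested cores are not separable.
#'
#' @param families data.frame with columns `core` (SMILES) and `n`
#'   (member count), or an integer number of families drawn from the
#'   built-in core list.
#' @param seed integer seed (substituent selection).
#' @param members_per_family member count used when `families` is given
#'   as an integer.
#' @return list: `smiles`, `ids`, `family` (integer labels),
#'   `molecules`, `fingerprints`.
#' @export
make_scaffold_collection <- function(families = 2L, seed = 1L,
                                     members_per_family = 5L) {
  if (is.numeric(families) && length(families) == 1L) {
    stopifnot(families >= 2L, families <= length(.scaffold_cores))
    families <- data.frame(core = .scaffold_cores[seq_len(families)],
                           n = members_per_family)
  }
  stopifnot(nrow(families) >= 2L, all(families$n >= 1L))
  core_fps <- lapply(seq_len(nrow(families)), function(f)
    molprint2d(smiles_to_mol(families$core[f], sprintf("CORE%d", f))))
  for (i in seq_len(length(core_fps) - 1L)) {
    for (j in (i + 1L):length(core_fps)) {
      if (fp_tanimoto(core_fps[[i]], core_fps[[j]]) >= 0.8)
        stop("family cores are not separable (Tanimoto >= 0.8)")
    }
  }
  smiles <- character(); ids <- character(); family <- integer()
  for (f in seq_len(nrow(families))) {
    n <- families$n[f]
    if (n > length(.scaffold_subs))
      stop("at most ", length(.scaffold_subs), " members per family")
    subs <- with_preserved_rng({
      set.seed(seed + f)
      sample(.scaffold_subs, n)
    })
    fam_smi <- paste0(subs, families$core[f])
    smiles <- c(smiles, fam_smi)
    ids <- c(ids, sprintf("F%d_M%02d", f, seq_len(n)))
    family <- c(family, rep(f, n))
  }
  molecules <- Map(smiles_to_mol, smiles, ids)
  names(molecules) <- ids
  fps <- lapply(molecules, molprint2d)
  # separability assertion on the realized members
  n <- length(fps)
  if (n >= 2L && any(vapply(unique(family), function(f) sum(family == f), 0L) >= 2L)) {
    wmin <- Inf; bmax <- -Inf
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        t <- fp_tanimoto(fps[[i]], fps[[j]])
        if (family[i] == family[j]) wmin <- min(wmin, t) else bmax <- max(bmax, t)
      }
    }
    if (is.finite(wmin) && wmin <= bmax)
      stop(sprintf("families not separable: min within %.3f <= max between %.3f",
                   wmin, bmax))
  }
  list(smiles = smiles, ids = ids, family = family,
       molecules = molecules, fingerprints = fps)
}
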