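# Structure-based pharmacophore model: typed feature points with
# per-feature matching tolerances, mandatory/optional flags, and
# receptor-derived excluded-volume spheres. The matcher accepts a
# conformer when every mandatory feature and at least one optional
# feature can be superposed within tolerance without planting any heavy
# atom inside an excluded sphere.

.feature_kinds <- c("positive_or_donor", "acceptor", "hydrophobic_or_aromatic")

#' Pharmacophore feature point
#' @param kind one of `"positive_or_donor"`, `"acceptor"`,
#'   `"hydrophobic_or_aromatic"`.
#' @param center 3D coordinate (angstrom, model frame).
#' @param tolerance matching radius in angstrom (> 0).
#' @param mandatory logical flag.
#' @return object of class `phore_feature`.
#' @export
phore_feature <- function(kind, center, tolerance = 2.0, mandatory = FALSE) {
  kind <- match.arg(kind, .feature_kinds)
  center <- as.numeric(center)
  stopifnot(length(center) == 3L, all(is.finite(center)), tolerance > 0)
  structure(list(kind = kind, center = center, tolerance = tolerance,
                 mandatory = isTRUE(mandatory)), class = "phore_feature")
}

#' Excluded-volume sphere
#' @param center 3D coordinate (angstrom, model frame).
#' @param radius sphere radius in angstrom (> 0).
#' @return object of class `phore_exclusion`.
#' @export
excluded_volume <- function(center, radius = 1.5) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3L, all(is.finite(center)), radius > 0)
  structure(list(center = center, radius = radius), class = "phore_exclusion")
}

#' Pharmacophore model
#' @param features list of [phore_feature()] (at least one mandatory).
#' @param excluded list of [excluded_volume()].
#' @param frame_tag receptor frame identifier.
#' @return object of class `phore_model`.
#' @export
pharmacophore_model <- function(features, excluded = list(), frame_tag = "model") {
  stopifnot(length(features) >= 1L,
            all(vapply(features, inherits, TRUE, "phore_feature")),
            all(vapply(excluded, inherits, TRUE, "phore_exclusion")))
  if (!any(vapply(features, function(f) f$mandatory, TRUE)))
    stop("a pharmacophore model needs at least one mandatory feature")
  structure(list(features = features, excluded = excluded,
                 frame_tag = frame_tag), class = "phore_model")
}

#' @export
print.phore_model <- function(x, ...) {
  nm <- sum(vapply(x$features, function(f) f$mandatory, TRUE))
  cat(sprintf("<phore_model> %d features (%d mandatory, %d optional), %d excluded spheres, frame '%s'\n",
              length(x$features), nm, length(x$features) - nm,
              length(x$excluded), x$frame_tag))
  invisible(x)
}

#' Load a pharmacophore definition file
#'
#' Plain-text format, one directive per line (comments with `#`):
#' \preformatted{
#' FRAME   <tag>
#' FEATURE <kind> <x> <y> <z> <tolerance> <mandatory|optional>
#' EXCLUDE <x> <y> <z> <radius>
#' }
#'
#' @param path definition file.
#' @return a [pharmacophore_model()].
#' @export
load_pharmacophore <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  features <- list()
  excluded <- list()
  frame_tag <- "model"
  for (ln in lines) {
    f <- strsplit(ln, "\\s+")[[1]]
    if (f[1] == "FRAME") {
      frame_tag <- f[2]
    } else if (f[1] == "FEATURE") {
      if (length(f) != 7L) stop("malformed FEATURE line: ", ln)
      features[[length(features) + 1L]] <- phore_feature(
        f[2], as.numeric(f[3:5]), as.numeric(f[6]),
        mandatory = identical(f[7], "mandatory"))
    } else if (f[1] == "EXCLUDE") {
      if (length(f) != 5L) stop("malformed EXCLUDE line: ", ln)
      excluded[[length(excluded) + 1L]] <- excluded_volume(
        as.numeric(f[2:4]), as.numeric(f[5]))
    } else stop("unknown directive in pharmacophore file: ", f[1])
  }
  pharmacophore_model(features, excluded, frame_tag)
}

#' Write a pharmacophore definition file
#' @param model a [pharmacophore_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pharmacophore <- function(model, path) {
  out <- c(paste("FRAME", model$frame_tag),
           vapply(model$features, function(f)
             sprintf("FEATURE %s %.4f %.4f %.4f %.3f %s", f$kind,
                     f$center[1], f$center[2], f$center[3], f$tolerance,
                     if (f$mandatory) "mandatory" else "optional"), ""),
           vapply(model$excluded, function(e)
             sprintf("EXCLUDE %.4f %.4f %.4f %.3f",
                     e$center[1], e$center[2], e$center[3], e$radius), ""))
  writeLines(out, path)
  invisible(path)
}

#' Perceive pharmacophore feature points on a conformer
#'
#' Every aromatic ring yields one `hydrophobic_or_aromatic` feature at
#' its centroid; positively charged or H-bearing N/O atoms yield
#' `positive_or_donor`; N/O atoms that are not positively charged (and
#' are not ring N-H donating their lone pair into an aromatic system)
#' yield `acceptor`. Output order is deterministic (kind, then atom
#' index).
#'
#' @param x a `phyto_conformer`, `phyto_pose`, or `phyto_mol` with
#'   coordinates.
#' @return data.frame with columns `kind`, `x`, `y`, `z` and a list
#'   column `atom_ids`.
#' @export
perceive_features <- function(x) {
  if (inherits(x, "phyto_pose")) x <- x$conformer
  if (inherits(x, "phyto_conformer")) {
    mol <- x$mol
    mol$coords <- x$coords
  } else mol <- x
  if (is.null(mol$coords)) stop("feature perception needs 3D coordinates")
  arom <- aromatic_atoms(mol)
  hc <- implicit_h_counts(mol)
  adj <- mol_adjacency(mol)
  expl_h <- vapply(seq_len(n_atoms(mol)), function(a) {
    nb <- adj[[a]]
    if (is.null(nb)) 0L else sum(mol$elements[nb[, 1]] == "H")
  }, 0L)
  nH <- hc + expl_h
  feats <- list()
  push <- function(kind, pos, atoms) {
    feats[[length(feats) + 1L]] <<- list(kind = kind, pos = pos, atoms = atoms)
  }
  for (ring in aromatic_rings(mol)) {
    push("hydrophobic_or_aromatic",
         colMeans(mol$coords[ring, , drop = FALSE]), sort(ring))
  }
  for (a in seq_len(n_atoms(mol))) {
    el <- mol$elements[a]
    if (!(el %in% c("N", "O"))) next
    if (mol$fcharge[a] > 0L || nH[a] >= 1L)
      push("positive_or_donor", mol$coords[a, ], a)
    if (mol$fcharge[a] <= 0L && !(arom[a] && nH[a] >= 1L))
      push("acceptor", mol$coords[a, ], a)
  }
  if (!length(feats)) {
    return(data.frame(kind = character(), x = numeric(), y = numeric(),
                      z = numeric(), atom_ids = I(list())))
  }
  kinds <- vapply(feats, `[[`, "", "kind")
  amin <- vapply(feats, function(f) min(f$atoms), 1L)
  ord <- order(match(kinds, .feature_kinds), amin)
  feats <- feats[ord]
  data.frame(kind = vapply(feats, `[[`, "", "kind"),
             x = vapply(feats, function(f) f$pos[1], 0),
             y = vapply(feats, function(f) f$pos[2], 0),
             z = vapply(feats, function(f) f$pos[3], 0),
             atom_ids = I(lapply(feats, `[[`, "atoms")))
}

feature_positions <- function(feats) as.matrix(feats[, c("x", "y", "z")])

# heavy-atom clash test against the model's excluded spheres
has_excluded_clash <- function(model, heavy_xyz) {
  for (e in model$excluded) {
    d2 <- rowSums(sweep(heavy_xyz, 2, e$center)^2)
    if (any(d2 < e$radius^2 - 1e-12)) return(TRUE)
  }
  FALSE
}

# exhaustive correspondence search shared by both matching modes.
# reorient = TRUE solves a least-squares rigid superposition per
# correspondence; FALSE keeps the identity transform.
match_engine <- function(mol, coords, feats, model, reorient) {
  nM <- length(model$features)
  mand <- which(vapply(model$features, function(f) f$mandatory, TRUE))
  kindsM <- vapply(model$features, `[[`, "", "kind")
  tolM <- vapply(model$features, `[[`, 0, "tolerance")
  ctrM <- t(vapply(model$features, `[[`, numeric(3), "center"))
  nL <- nrow(feats)
  posL <- if (nL) feature_positions(feats) else matrix(0, 0, 3)
  heavy_xyz <- coords[mol$elements != "H", , drop = FALSE]
  unmatched <- list(matched = FALSE, correspondence = NULL,
                    transform = list(R = diag(3), t = c(0, 0, 0)),
                    rmsd = NA_real_, clash = FALSE, n_matched = 0L)
  if (nL == 0L) return(structure(unmatched, class = "phore_match"))
  cand <- lapply(seq_len(nM), function(m) which(feats$kind == kindsM[m]))
  if (any(vapply(mand, function(m) length(cand[[m]]) == 0L, TRUE)))
    return(structure(unmatched, class = "phore_match"))
  dM <- as.matrix(dist(ctrM))
  dL <- as.matrix(dist(posL))
  best <- NULL
  clash_seen <- FALSE
  consider <- function(assign_idx) {
    mi <- which(!is.na(assign_idx))
    li <- assign_idx[mi]
    n_opt <- sum(!(mi %in% mand))
    if (n_opt < 1L) return()
    mob <- posL[li, , drop = FALSE]
    tgt <- ctrM[mi, , drop = FALSE]
    if (reorient) {
      fit <- kabsch_fit(mob, tgt)
    } else {
      fit <- list(R = diag(3), t = c(0, 0, 0))
    }
    moved <- apply_rigid(mob, fit$R, fit$t)
    dev <- sqrt(rowSums((moved - tgt)^2))
    if (any(dev > tolM[mi] + 1e-9)) return()
    hx <- apply_rigid(heavy_xyz, fit$R, fit$t)
    if (has_excluded_clash(model, hx)) {
      clash_seen <<- TRUE
      return()
    }
    rmsd <- sqrt(mean(dev^2))
    cor <- cbind(model = mi, ligand = li)
    key <- paste(assign_idx, collapse = ",")
    better <- is.null(best) ||
      length(mi) > best$n_matched ||
      (length(mi) == best$n_matched && rmsd < best$rmsd - 1e-12) ||
      (length(mi) == best$n_matched && abs(rmsd - best$rmsd) <= 1e-12 &&
         key < best$key)
    if (better) {
      best <<- list(matched = TRUE, correspondence = cor, transform = fit,
                    rmsd = rmsd, clash = FALSE, n_matched = length(mi),
                    key = key)
    }
  }
  assign_idx <- rep(NA_integer_, nM)
  recurse <- function(m) {
    if (m > nM) { consider(assign_idx); return() }
    choices <- setdiff(cand[[m]], assign_idx[!is.na(assign_idx)])
    for (l in choices) {
      ok <- TRUE
      for (m2 in which(!is.na(assign_idx))) {
        # pairwise-distance compatibility prune; exact for the static
        # mode and admissible for the reorienting mode
        lim <- tolM[m] + tolM[m2]
        if (abs(dM[m, m2] - dL[l, assign_idx[m2]]) > lim + 1e-9) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign_idx[m] <<- l
      recurse(m + 1L)
      assign_idx[m] <<- NA_integer_
    }
    if (!(m %in% mand)) recurse(m + 1L)  # optional feature may stay unmatched
  }
  recurse(1L)
  if (is.null(best)) {
    unmatched$clash <- clash_seen
    return(structure(unmatched, class = "phore_match"))
  }
  best$key <- NULL
  structure(best, class = "phore_match")
}

#' @export
print.phore_match <- function(x, ...) {
  if (x$matched)
    cat(sprintf("<phore_match> matched %d features, rmsd %.3f A\n",
                x$n_matched, x$rmsd))
  else
    cat(sprintf("<phore_match> no match%s\n",
                if (x$clash) " (excluded-volume clash)" else ""))
  invisible(x)
}

#' Match a conformer against a pharmacophore with reorientation
#'
#' Searches kind-compatible feature correspondences (all mandatory
#' features plus at least one optional), solves the least-squares rigid
#' superposition for each, and accepts when every matched pair lies
#' within its feature tolerance and no ligand heavy atom falls inside an
#' excluded volume after the transform. The best accepted correspondence
#' (most features, then lowest rmsd) is returned.
#'
#' @param conformer a `phyto_conformer` (or `phyto_mol` with coords).
#' @param model a [pharmacophore_model()].
#' @return a `phore_match` with elements `matched`, `correspondence`,
#'   `transform` (`R`, `t`), `rmsd`, `clash`, `n_matched`.
#' @export
match_with_reorientation <- function(conformer, model) {
  if (inherits(conformer, "phyto_pose")) conformer <- conformer$conformer
  if (inherits(conformer, "phyto_conformer")) {
    mol <- conformer$mol; coords <- conformer$coords
  } else { mol <- conformer; coords <- conformer$coords }
  if (is.null(coords)) stop("matching needs 3D coordinates")
  feats <- perceive_features(mol)
  match_engine(mol, coords, feats, model, reorient = TRUE)
}

#' Match a docked pose against a pharmacophore without reorientation
#'
#' Same acceptance rule as [match_with_reorientation()] but the pose is
#' evaluated exactly where it was docked (identity transform). The pose
#' and the model must share the same receptor frame.
#'
#' @param pose a `phyto_pose`.
#' @param model a [pharmacophore_model()].
#' @return a `phore_match`.
#' @export
match_pose_static <- function(pose, model) {
  stopifnot(inherits(pose, "phyto_pose"))
  if (!identical(pose$frame_tag, model$frame_tag))
    stop(sprintf("frame mismatch: pose '%s' vs model '%s'",
                 pose$frame_tag, model$frame_tag))
  mol <- pose_mol(pose)
  coords <- pose_coords(pose)
  feats <- perceive_features(mol)
  match_engine(mol, coords, feats, model, reorient = FALSE)
}

#' Receptor-derived excluded volumes around a bound ligand
#'
#' One sphere is placed on every receptor heavy atom within `shell`
#' angstrom of any ligand atom.
#'
#' @param receptor path to a PDB file or a `bio3d` pdb object.
#' @param ligand_pose a `phyto_pose` in the receptor frame.
#' @param shell pocket selection distance in angstrom.
#' @param radius sphere radius assigned to each excluded volume.
#' @return list of [excluded_volume()] (possibly empty, with a warning).
#' @export
derive_excluded_volumes <- function(receptor, ligand_pose, shell = 5.0,
                                    radius = 1.5) {
  pdb <- if (is.character(receptor)) bio3d::read.pdb(receptor) else receptor
  at <- pdb$atom
  heavy <- is.na(at$elesy) | toupper(trimws(at$elesy)) != "H"
  rx <- cbind(at$x, at$y, at$z)[heavy, , drop = FALSE]
  lig <- pose_coords(ligand_pose)
  out <- list()
  if (shell > 0 && nrow(rx)) {
    for (k in seq_len(nrow(rx))) {
      d2 <- min(rowSums(sweep(lig, 2, rx[k, ])^2))
      if (d2 <= shell^2) out[[length(out) + 1L]] <- excluded_volume(rx[k, ], radius)
    }
  }
  if (!length(out)) warning("empty pocket selection: no excluded volumes derived")
  out
}
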