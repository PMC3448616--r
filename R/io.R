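#' Read molecules from SMILES or SDF
#'
#' Invalid records are skipped with a warning and counted in the
#' `"skipped"` attribute of the result; a file with zero valid records
#' is an error.
#'
#' @param path input file.
#' @param format `"smiles"` (one molecule per line, optional whitespace-
#'   separated name) or `"sdf"` (multi-record V2000).
#' @return list of [phyto_mol()] objects with attribute `skipped`.
#' @export
read_molecules <- function(path, format = c("sdf", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  mols <- list()
  skipped <- 0L
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (k in seq_along(lines)) {
      parts <- strsplit(trimws(lines[k]), "[\t ]+")[[1]]
      id <- if (length(parts) >= 2L) parts[2] else sprintf("MOL%04d", k)
      m <- tryCatch(smiles_to_mol(parts[1], id = id), error = function(e) NULL)
      if (is.null(m)) skipped <- skipped + 1L else mols[[length(mols) + 1L]] <- m
    }
  } else {
    for (rec in split_sdf_records(path)) {
      m <- tryCatch(ctab_to_mol(rec, default_id = sprintf("MOL%04d", length(mols) + 1L)),
                    error = function(e) NULL)
      if (is.null(m)) skipped <- skipped + 1L else mols[[length(mols) + 1L]] <- m
    }
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d unreadable record(s) in %s", skipped, path))
  if (!length(mols)) stop("no valid records in ", path)
  attr(mols, "skipped") <- skipped
  mols
}

split_sdf_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines) + 1L
  recs <- list()
  start <- 1L
  for (e in ends) {
    if (e > start) recs[[length(recs) + 1L]] <- lines[start:(e - 1L)]
    start <- e + 1L
  }
  recs
}

#' Write molecules to SDF or SMILES
#'
#' @param mols list of [phyto_mol()].
#' @param path output file.
#' @param format output format.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(mols, path, format = c("sdf", "smiles")) {
  format <- match.arg(format)
  if (inherits(mols, "phyto_mol")) mols <- list(mols)
  if (format == "sdf") {
    out <- unlist(lapply(mols, mol_to_ctab))
  } else {
    out <- vapply(mols, function(m) {
      smi <- if (!is.na(m$smiles)) m$smiles else canonical_smiles(m)
      paste0(smi, "\t", m$id)
    }, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Conformer of a molecule
#'
#' @param mol parent `phyto_mol`.
#' @param coords n x 3 coordinate matrix (angstrom), one row per atom.
#' @param energy_rank non-negative integer rank (0 = lowest energy).
#' @return object of class `phyto_conformer`.
#' @export
new_conformer <- function(mol, coords, energy_rank = 0L) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n_atoms(mol), ncol(coords) == 3L,
            all(is.finite(coords)), energy_rank >= 0L)
  dimnames(coords) <- NULL
  structure(list(molecule_id = mol$id, mol = mol, coords = coords,
                 energy_rank = as.integer(energy_rank)),
            class = "phyto_conformer")
}

#' Pose: a conformer anchored in a named receptor frame
#'
#' Field similarity and no-reorientation pharmacophore matching require
#' both operands to share the same `frame_tag`.
#'
#' @param conformer a `phyto_conformer`.
#' @param frame_tag identifier of the receptor coordinate frame.
#' @return object of class `phyto_pose`.
#' @export
new_pose <- function(conformer, frame_tag) {
  stopifnot(inherits(conformer, "phyto_conformer"),
            is.character(frame_tag), length(frame_tag) == 1L)
  structure(list(conformer = conformer, frame_tag = frame_tag),
            class = "phyto_pose")
}

#' Wrap a molecule with stored coordinates as a pose
#' @param mol `phyto_mol` with coordinates.
#' @param frame_tag receptor frame identifier.
#' @return a `phyto_pose`.
#' @export
as_pose <- function(mol, frame_tag) {
  if (is.null(mol$coords)) stop("molecule has no coordinates")
  new_pose(new_conformer(mol, mol$coords), frame_tag)
}

#' Pose accessors
#'
#' @param p a `phyto_pose`.
#' @return the underlying molecule, its coordinate matrix, or its
#'   molecule id.
#' @export
pose_mol <- function(p) p$conformer$mol

#' @rdname pose_mol
#' @export
pose_coords <- function(p) p$conformer$coords

#' @rdname pose_mol
#' @export
pose_id <- function(p) p$conformer$molecule_id

#' Read docked poses from an SDF file
#'
#' Records without 3D information (all-zero z column) are skipped with a
#' warning. Coordinates are preserved exactly as parsed.
#'
#' @param path SDF file of docked poses.
#' @param frame_tag receptor frame the coordinates live in.
#' @return list of `phyto_pose` objects.
#' @export
read_poses <- function(path, frame_tag) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  poses <- list()
  skipped <- 0L
  for (rec in split_sdf_records(path)) {
    m <- tryCatch(ctab_to_mol(rec, default_id = sprintf("POSE%04d", length(poses) + 1L)),
                  error = function(e) NULL)
    if (is.null(m) || is.null(m$coords) || all(abs(m$coords[, 3]) < 1e-12)) {
      skipped <- skipped + 1L
      next
    }
    poses[[length(poses) + 1L]] <- as_pose(m, frame_tag)
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d record(s) without 3D coordinates in %s",
                    skipped, path))
  attr(poses, "skipped") <- skipped
  poses
}

#' Write poses to SDF
#' @param poses list of `phyto_pose`.
#' @param path output SDF file.
#' @return `path`, invisibly.
#' @export
write_poses <- function(poses, path) {
  if (inherits(poses, "phyto_pose")) poses <- list(poses)
  mols <- lapply(poses, function(p) {
    m <- pose_mol(p)
    m$coords <- pose_coords(p)
    m
  })
  write_molecules(mols, path, format = "sdf")
}
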