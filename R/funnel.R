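# Sequential virtual-screening funnel: pharmacophore screen with
# reorientation -> pose acquisition (pluggable docking interface) ->
# static pharmacophore re-filter -> shape/electrostatic rescoring
# against a reference pose. Each stage consumes the survivors of the
# previous one; the report keeps nested survivor id sets and the best
# field scores per molecule.

#' Inclusive threshold filter on field scores
#'
#' `TRUE` iff `et_pb >= et_pb_min` and `st >= st_min` (closed
#' comparisons, matching the published ">=" conditions).
#'
#' @param scores a `field_scores`.
#' @param thresholds a [field_thresholds()].
#' @return logical scalar.
#' @export
boundary_filter <- function(scores, thresholds) {
  scores$et_pb >= thresholds$et_pb_min && scores$st >= thresholds$st_min
}

#' Pose provider backed by a pre-docked SDF file
#'
#' Poses are grouped by molecule id (record title) preserving file
#' order; the returned function maps a molecule id to its pose list
#' (empty when the id is absent, in which case the funnel drops the
#' molecule with a logged reason).
#'
#' @param sdf_path SDF of docked poses.
#' @param frame_tag receptor frame of the poses.
#' @return function(id) -> list of `phyto_pose`.
#' @export
external_pose_provider <- function(sdf_path, frame_tag) {
  if (!file.exists(sdf_path)) stop("cannot read pose file: ", sdf_path)
  poses <- read_poses(sdf_path, frame_tag)
  ids <- vapply(poses, pose_id, "")
  function(molecule_id) poses[ids == molecule_id]
}

#' Pose provider from an in-memory named list
#' @param pose_list named list: molecule id -> list of `phyto_pose`.
#' @return function(id) -> list of `phyto_pose`.
#' @export
memory_pose_provider <- function(pose_list) {
  function(molecule_id) {
    p <- pose_list[[molecule_id]]
    if (is.null(p)) list() else if (inherits(p, "phyto_pose")) list(p) else p
  }
}

#' Funnel configuration
#' @param max_confs conformer cap per molecule when embedding is needed
#'   (200, the raised cap used in the original screen).
#' @param seed seed for conformer embedding.
#' @param grid_spec field-grid overrides for [score_pose()].
#' @param docking_box_side passthrough note for external docking tools
#'   (the original workflow enlarged the cubic docking box from 10 to
#'   15 angstrom); not used by the package itself.
#' @return list of class `funnel_config`.
#' @export
funnel_config <- function(max_confs = 200L, seed = 1L, grid_spec = list(),
                          docking_box_side = 15) {
  structure(list(max_confs = max_confs, seed = seed, grid_spec = grid_spec,
                 docking_box_side = docking_box_side),
            class = "funnel_config")
}

#' Run the sequential virtual-screening funnel
#'
#' Stage 1 keeps molecules with at least one conformer matching the
#' pharmacophore with reorientation allowed; stage 2 obtains docked
#' poses for the survivors from `pose_provider`; stage 3 keeps molecules
#' with at least one pose matching without reorientation; stage 4 keeps
#' molecules with at least one pose meeting both field-score thresholds
#' against the reference. Molecules whose coordinates are present are
#' screened as given; others are embedded deterministically.
#'
#' @param library list of `phyto_mol` (non-empty).
#' @param model a [pharmacophore_model()].
#' @param pose_provider function(id) -> list of `phyto_pose` in the
#'   model/reference frame (see [external_pose_provider()]).
#' @param reference reference `phyto_pose` with charges assigned.
#' @param thresholds a [field_thresholds()].
#' @param config a [funnel_config()].
#' @return object of class `funnel_report`: `stage_names`,
#'   `survivor_counts`, `survivor_ids`, `scores` (best per molecule),
#'   `drops` (per-molecule drop log).
#' @export
run_funnel <- function(library, model, pose_provider, reference,
                       thresholds = field_thresholds(),
                       config = funnel_config()) {
  stopifnot(length(library) >= 1L)
  ids <- vapply(library, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate molecule ids in library")
  drops <- character()
  log_drop <- function(id, stage, why) {
    drops[length(drops) + 1L] <<- sprintf("%s\t%s\t%s", id, stage, why)
  }

  s1 <- character()
  for (m in library) {
    confs <- if (!is.null(m$coords)) {
      list(new_conformer(m, m$coords))
    } else {
      tryCatch(embed_conformers(m, config$max_confs, config$seed),
               error = function(e) NULL)
    }
    if (is.null(confs)) {
      log_drop(m$id, "pharmacophore", paste("embedding failed"))
      next
    }
    hit <- FALSE
    for (cf in confs) {
      if (match_with_reorientation(cf, model)$matched) { hit <- TRUE; break }
    }
    if (hit) s1 <- c(s1, m$id) else log_drop(m$id, "pharmacophore", "no matching conformer")
  }

  pose_sets <- list()
  s2 <- character()
  if (length(s1)) {
    for (id in s1) {
      p <- tryCatch(pose_provider(id), error = function(e) e)
      if (inherits(p, "error")) {
        log_drop(id, "docking", paste("pose provider failure:",
                                      conditionMessage(p)))
        next
      }
      if (!length(p)) {
        log_drop(id, "docking", "no docked poses")
        next
      }
      bad <- vapply(p, function(q) !identical(q$frame_tag, model$frame_tag), TRUE)
      if (all(bad)) {
        log_drop(id, "docking", "poses not in model frame")
        next
      }
      pose_sets[[id]] <- p[!bad]
      s2 <- c(s2, id)
    }
  }

  s3 <- character()
  static_pass <- list()
  for (id in s2) {
    keep <- Filter(function(p) match_pose_static(p, model)$matched,
                   pose_sets[[id]])
    if (length(keep)) {
      static_pass[[id]] <- keep
      s3 <- c(s3, id)
    } else log_drop(id, "pharmacophore_static", "no pose matches without reorientation")
  }

  # poses arriving from external docking usually carry no partial
  # charges; assign them on the fly before field rescoring
  ensure_charges <- function(p) {
    if (!is.null(pose_mol(p)$pcharge)) return(p)
    as_pose(assign_partial_charges(pose_mol(p)), p$frame_tag)
  }

  s4 <- character()
  score_rows <- list()
  for (id in s3) {
    scored <- lapply(lapply(static_pass[[id]], ensure_charges), score_pose,
                     reference = reference, grid_spec = config$grid_spec)
    best <- scored[[which.max(vapply(scored, `[[`, 0, "et_combo"))]]
    score_rows[[id]] <- data.frame(molecule_id = id, st = best$st,
                                   et_pb = best$et_pb, et_combo = best$et_combo)
    if (any(vapply(scored, boundary_filter, TRUE, thresholds = thresholds))) {
      s4 <- c(s4, id)
    } else log_drop(id, "field_rescoring", "below ST/ET_pb thresholds")
  }

  report <- structure(list(
    stage_names = c("input", "pharmacophore", "docking",
                    "pharmacophore_static", "field_rescoring"),
    survivor_counts = c(length(ids), length(s1), length(s2), length(s3),
                        length(s4)),
    survivor_ids = list(input = ids, pharmacophore = s1, docking = s2,
                        pharmacophore_static = s3, field_rescoring = s4),
    scores = if (length(score_rows)) do.call(rbind, unname(score_rows)) else
      data.frame(molecule_id = character(), st = numeric(),
                 et_pb = numeric(), et_combo = numeric()),
    drops = drops), class = "funnel_report")
  report
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  for (k in seq_along(x$stage_names)) {
    cat(sprintf("  %-22s %d\n", x$stage_names[k], x$survivor_counts[k]))
  }
  invisible(x)
}

#' Write a funnel report to a directory
#'
#' Emits per-stage survivor tables, the field-score table, a JSON-like
#' machine-readable summary and the drop log, all as plain text.
#'
#' @param report a `funnel_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_funnel_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (st in names(report$survivor_ids)) {
    writeLines(report$survivor_ids[[st]],
               file.path(dir, paste0("survivors_", st, ".txt")))
  }
  write.table(report$scores, file.path(dir, "field_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(report$drops, file.path(dir, "drop_log.tsv"))
  counts <- paste(sprintf("  \"%s\": %d", report$stage_names,
                          report$survivor_counts), collapse = ",\n")
  writeLines(c("{", counts, "}"), file.path(dir, "funnel_summary.json"))
  invisible(dir)
}
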