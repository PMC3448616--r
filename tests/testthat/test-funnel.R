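test_that("the funnel recovers planted stage labels exactly", {
  spec <- fixture_spec(1, 4, 3, 2, 1)
  fix <- make_funnel_library(spec)
  rep <- run_funnel(fix$molecules, fix$model,
                    memory_pose_provider(fix$poses), fix$reference)
  expect_identical(rep$survivor_counts, c(10L, 7L, 7L, 5L, 4L))
  lab <- fix$labels
  expect_setequal(rep$survivor_ids$pharmacophore,
                  names(lab)[lab != "fail_pharmacophore"])
  expect_setequal(rep$survivor_ids$pharmacophore_static,
                  names(lab)[lab %in% c("pass", "fail_thresholds")])
  expect_setequal(rep$survivor_ids$field_rescoring,
                  names(lab)[lab == "pass"])
})

test_that("survivor sets are nested and counts non-increasing", {
  for (seed in 1:3) {
    fix <- make_funnel_library(fixture_spec(seed, 3, 2, 2, 2))
    rep <- run_funnel(fix$molecules, fix$model,
                      memory_pose_provider(fix$poses), fix$reference)
    expect_true(all(diff(rep$survivor_counts) <= 0))
    ids <- rep$survivor_ids
    for (k in 2:length(ids)) {
      expect_true(all(ids[[k]] %in% ids[[k - 1]]))
      expect_identical(length(ids[[k]]), rep$survivor_counts[k])
    }
  }
})

test_that("rerunning the funnel on final survivors keeps all of them", {
  fix <- make_funnel_library(fixture_spec(2, 3, 2, 1, 1))
  rep <- run_funnel(fix$molecules, fix$model,
                    memory_pose_provider(fix$poses), fix$reference)
  keep <- rep$survivor_ids$field_rescoring
  again <- run_funnel(fix$molecules[vapply(fix$molecules, `[[`, "", "id") %in% keep],
                      fix$model, memory_pose_provider(fix$poses),
                      fix$reference)
  expect_setequal(again$survivor_ids$field_rescoring, keep)
  expect_identical(again$survivor_counts,
                   rep(length(keep), 5L) |> as.integer())
})

test_that("vacuous thresholds make stage 4 equal stage 3; funnel is deterministic", {
  fix <- make_funnel_library(fixture_spec(4, 2, 1, 1, 2))
  open_th <- field_thresholds(et_pb_min = -Inf, st_min = -Inf)
  rep <- run_funnel(fix$molecules, fix$model,
                    memory_pose_provider(fix$poses), fix$reference, open_th)
  expect_identical(rep$survivor_ids$field_rescoring,
                   rep$survivor_ids$pharmacophore_static)
  rep2 <- run_funnel(fix$molecules, fix$model,
                     memory_pose_provider(fix$poses), fix$reference, open_th)
  expect_identical(rep, rep2)
})

test_that("molecules without poses are dropped with a logged reason", {
  fix <- make_funnel_library(fixture_spec(3, 2, 1, 0, 0))
  starved <- fix$poses
  gone <- names(starved)[1]
  starved[[gone]] <- list()
  rep <- run_funnel(fix$molecules, fix$model,
                    memory_pose_provider(starved), fix$reference)
  expect_false(gone %in% rep$survivor_ids$docking)
  expect_true(any(grepl(gone, rep$drops) & grepl("no docked poses", rep$drops)))
})

test_that("an empty stage-1 survivor set short-circuits the rest", {
  fix <- make_funnel_library(fixture_spec(1, 0, 3, 0, 0))
  calls <- 0L
  counting_provider <- function(id) { calls <<- calls + 1L; list() }
  rep <- run_funnel(fix$molecules, fix$model, counting_provider,
                    fix$reference)
  expect_identical(rep$survivor_counts[-1], rep(0L, 4L))
  expect_identical(calls, 0L)
})

test_that("boundary filter is inclusive exactly at the published operating point", {
  th <- field_thresholds()  # ET_pb >= 0.468, ST >= 0.237
  fs <- function(st, et) structure(list(st = st, et_pb = et,
                                        et_combo = st + et),
                                   class = "field_scores")
  expect_true(boundary_filter(fs(0.237, 0.468), th))
  expect_false(boundary_filter(fs(0.236, 0.468), th))
  expect_false(boundary_filter(fs(0.237, 0.467), th))
  expect_true(boundary_filter(fs(1, 1), th))
})

test_that("the SDF pose provider groups poses by id preserving order", {
  fix <- make_funnel_library(fixture_spec(6, 2, 0, 1, 0))
  dir <- withr::local_tempdir()
  write_funnel_fixture(fix, dir)
  prov <- suppressWarnings(external_pose_provider(
    file.path(dir, "poses.sdf"), frame_tag = fix$model$frame_tag))
  id1 <- fix$molecules[[1]]$id
  got <- prov(id1)
  expect_length(got, length(fix$poses[[id1]]))
  expect_lt(max(abs(pose_coords(got[[1]]) -
                      round(pose_coords(fix$poses[[id1]][[1]]), 4))), 1e-9)
  expect_length(prov("ABSENT_ID"), 0L)
  expect_error(external_pose_provider("/no/such.sdf", "f"), "cannot read")
})

test_that("funnel reports serialize to plain-text outputs", {
  fix <- make_funnel_library(fixture_spec(1, 1, 1, 0, 0))
  rep <- run_funnel(fix$molecules, fix$model,
                    memory_pose_provider(fix$poses), fix$reference)
  dir <- withr::local_tempdir()
  write_funnel_report(rep, dir)
  expect_true(file.exists(file.path(dir, "funnel_summary.json")))
  surv <- readLines(file.path(dir, "survivors_field_rescoring.txt"))
  expect_setequal(surv[nzchar(surv)], rep$survivor_ids$field_rescoring)
})
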