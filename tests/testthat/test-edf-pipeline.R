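small_scenario <- function(seed = 1) {
  sim_scenario(duration_s = 300, n_rows = 4, n_cols = 4, fs_hz = 20,
               ap_width_s = 0.5,
               contraction_schedule = rbind(c(40, 40), c(170, 45)),
               true_cv_cm_s = c(7, 9), true_angle_rad = c(0.3, -0.8),
               snr_db = 12, rng_seed = seed)
}

test_that("EDF round trip preserves signals to quantization accuracy", {
  rec <- generate_grid_recording(small_scenario())
  path <- file.path(tempdir(), "roundtrip.edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(dim(back$grid), dim(rec$grid))
  expect_equal(back$fs_hz, rec$fs_hz)
  expect_equal(back$electrode_spacing_cm, rec$electrode_spacing_cm)
  q <- (max(rec$grid) - min(rec$grid)) / 65535
  expect_lt(max(abs(back$grid - rec$grid)), 1.01 * q)
  expect_lt(max(abs(back$bipolar - rec$bipolar)),
            1.01 * (max(rec$bipolar) - min(rec$bipolar)) / 65535)
  # sidecar restored the annotations
  expect_equal(back$toco_marks, rec$toco_marks)
  expect_equal(back$perception_marks, rec$perception_marks)
  unlink(c(path, paste0(path, ".json")))
})

test_that("annotation sidecars round trip through JSON", {
  rec <- generate_grid_recording(small_scenario(3))
  path <- file.path(tempdir(), "ann.json")
  write_annotations(rec, path)
  ann <- read_annotations(path)
  expect_equal(ann$toco_marks, unname(rec$toco_marks))
  expect_equal(ann$perception_marks, rec$perception_marks)
  expect_equal(ann$electrode_spacing_cm, 0.5)
  expect_equal(ann$ground_truth$true_cv_cm_s, c(7, 9))
  unlink(path)
})

test_that("fixture presets honor their contracts", {
  rec <- make_fixture("noiseless-unit", 0)
  # channel (2,1) is an exact 0.05 s shifted copy of (1,1)
  x1 <- rec$grid[1, 1, ]; x2 <- rec$grid[2, 1, ]
  expect_lt(max(abs(x2[-(1:10)] - x1[seq_len(length(x1) - 10)])), 1e-8)
  expect_identical(make_fixture("labor-like", 1)$grid,
                   make_fixture("labor-like", 1)$grid)
  expect_error(make_fixture("unheard-of", 1), class = "ehgcv_invalid_argument")
})

test_that("invalid pipeline configurations are rejected before any work", {
  recs <- list(list(scenario = small_scenario(), hours_to_delivery = 6))
  expect_error(pipeline_config(recs, cv = list(window_length_s = 5, overlap_s = 5)),
               class = "ehgcv_invalid_argument")
  expect_error(pipeline_config(recs, detect = list(bogus_key = 1)),
               class = "ehgcv_invalid_argument")
  expect_error(pipeline_config(list()), class = "ehgcv_invalid_argument")
  expect_error(pipeline_config(list(list(patient_id = "x"))),
               class = "ehgcv_invalid_argument")
})

test_that("the pipeline runs end to end and is deterministic under a seed", {
  cfg <- pipeline_config(
    recordings = list(list(scenario = small_scenario(5), patient_id = "P01",
                           hours_to_delivery = 6)),
    rng_seed = 42, out_dir = file.path(tempdir(), "run1"))
  rep1 <- run_pipeline(cfg)
  expect_equal(rep1$counts$P01$detected, 2)
  expect_equal(rep1$counts$P01$confirmed, 2)
  expect_gt(nrow(rep1$window_cvs), 0)
  expect_true(all(rep1$window_cvs$contraction_id %in% 1:2))
  expect_equal(rep1$patients$group, "labor")
  # all window estimates near the scheduled truth, none wildly off
  ok <- rep1$window_cvs[!rep1$window_cvs$excluded, ]
  expect_true(all(ok$cv_cm_s > 2 & ok$cv_cm_s < 30))

  cfg2 <- cfg
  cfg2$out_dir <- file.path(tempdir(), "run2")
  rep2 <- run_pipeline(cfg2)
  expect_identical(unname(tools::md5sum(rep1$outputs$cv_windows)),
                   unname(tools::md5sum(rep2$outputs$cv_windows)))
  expect_equal(rep1$provenance$config_md5, rep2$provenance$config_md5)
  unlink(c(cfg$out_dir, cfg2$out_dir), recursive = TRUE)
})

test_that("stage failures carry the failing stage", {
  cfg <- pipeline_config(
    recordings = list(list(path = file.path(tempdir(), "missing.edf"),
                           patient_id = "PX")),
    rng_seed = 1)
  err <- tryCatch(run_pipeline(cfg), error = function(e) e)
  expect_s3_class(err, "ehgcv_stage_error")
  expect_equal(err$stage, "simulate/load")
})
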