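test_that("a small paired study runs end to end with the expected schema", {
  cfg <- run_config(seed = 5, n_subjects = 2,
                    grid = voxel_grid(c(24, 24, 10), spacing = 6),
                    n_beams = 5, beamlet_size_mm = 14,
                    out_dir = file.path(tempdir(), "wishplan-study-test"))
  res <- suppressWarnings(run_study(cfg))
  expect_s3_class(res, "study_result")
  expect_length(res$subjects, 2)

  # Table-2-style rows are all present
  need <- c("PTV V_95pct_pct", "PTV HI", "PTV CI", "KidneyL D_50pct_Gy",
            "KidneyR D_50pct_Gy", "Liver-PTV V_30Gy_pct",
            "SpinalCord D_max_Gy", "Body D_mean_Gy", "Body V_5Gy_pct",
            "KidneyL NTCP_pct")
  expect_true(all(need %in% res$pairs$metric))
  expect_true(all(need %in% res$report$metric))

  # both plans of every subject are normalized to the prescription
  for (sub in res$subjects) {
    for (pl in list(sub$prioritized, sub$baseline)) {
      d <- structure_dose(pl, sub$structures, "PTV")
      expect_equal(dose_at_volume(compute_dvh(d), 50), 45,
                   tolerance = 1e-9)
    }
  }

  # the kidney-blind template loses on kidney dose: positive paired
  # difference favours the prioritized plans
  kidL <- res$report[res$report$metric == "KidneyL D_50pct_Gy", ]
  kidR <- res$report[res$report$metric == "KidneyR D_50pct_Gy", ]
  expect_gt(kidL$diff_mean, 0)
  expect_gt(kidR$diff_mean, 0)

  # artifacts on disk with the manifest recording seeds and config hash
  expect_true(file.exists(file.path(cfg$out_dir, "comparison_report.csv")))
  expect_true(file.exists(file.path(cfg$out_dir, "paired_metrics.csv")))
  man <- jsonlite::read_json(file.path(cfg$out_dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 5)
  expect_equal(man$subject_seeds, c(5001, 5002))
  expect_match(man$config_hash, "^[0-9a-f]{32}$")
})

test_that("study outputs are reproducible for a fixed configuration", {
  cfg <- run_config(seed = 9, n_subjects = 1,
                    grid = voxel_grid(c(18, 18, 8), spacing = 8),
                    n_beams = 5, beamlet_size_mm = 14)
  r1 <- suppressWarnings(run_study(cfg))
  r2 <- suppressWarnings(run_study(cfg))
  expect_identical(r1$pairs$prioritized, r2$pairs$prioritized)
  expect_identical(r1$pairs$baseline, r2$pairs$baseline)
})

test_that("a failing subject is skipped and recorded, not fatal", {
  cfg <- run_config(seed = 5, n_subjects = 1,
                    grid = voxel_grid(c(24, 24, 10), spacing = 6),
                    n_beams = 5, beamlet_size_mm = 14)
  # sabotage: a wish-list naming a structure the phantom lacks is a
  # validation error per subject
  tf <- tempfile(fileext = ".yaml")
  wl <- yaml::read_yaml(cfg$wishlist_path)
  wl$objectives[[1]]$volume <- "Duodenum"
  yaml::write_yaml(wl, tf)
  cfg$wishlist_path <- tf
  expect_warning(expect_error(run_study(cfg), "no subject completed"),
                 "skipped")
})
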