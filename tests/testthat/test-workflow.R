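test_that("kinetics workflow runs a preset end to end", {
  out <- withr::local_tempdir()
  res <- run_kinetics_workflow(list(preset = "pgs_15um", out_dir = out,
                                    seed = 3, verbosity = 0))
  expect_identical(res$verdict$mode, "allosteric-4OH-favoring")
  expect_true(res$converged)
  expect_true(file.exists(file.path(out, "som_curve.csv")))
  report <- jsonlite::read_json(file.path(out, "fit_report.json"))
  expect_identical(report$verdict$mode, "allosteric-4OH-favoring")
  expect_identical(report$seed, 3L)
  # baseline fit in the report recovers the generating constants
  expect_equal(report$baseline_fit$estimates$kd_prod_s, 5.1,
               tolerance = 1e-3)
  # SOM curve file carries the provenance header and parses back
  curve_lines <- readLines(file.path(out, "som_curve.csv"))
  expect_match(curve_lines[1], "^# cypsom")
  expect_match(curve_lines[2], "^# config_hash: ")
  expect_match(curve_lines[3], "^# seed: 3")
})

test_that("kinetics workflow reruns are byte-identical", {
  out_a <- withr::local_tempdir()
  out_b <- withr::local_tempdir()
  run_kinetics_workflow(list(preset = "schisandrin_weak", out_dir = out_a,
                             seed = 5, verbosity = 0))
  run_kinetics_workflow(list(preset = "schisandrin_weak", out_dir = out_b,
                             seed = 5, verbosity = 0))
  for (f in c("som_curve.csv", "fit_report.json")) {
    expect_identical(readLines(file.path(out_a, f)),
                     readLines(file.path(out_b, f)))
  }
})

test_that("kinetics workflow distinguishes input errors from fit failures", {
  out <- withr::local_tempdir()
  empty <- file.path(out, "empty.csv")
  writeLines(character(0), empty)
  expect_error(run_kinetics_workflow(list(rates = empty, out_dir = out,
                                          verbosity = 0)),
               class = "cypsom_input_error")
  expect_error(run_kinetics_workflow(list(out_dir = out, verbosity = 0)),
               class = "cypsom_config_error")
  # data without effector-free rows cannot anchor a baseline
  d <- generate_rate_dataset(mdz_params(kd_allo_x = 5),
                             rate_design(x_levels = 15))
  path <- file.path(out, "nox.csv")
  write_rate_csv(d, path)
  expect_error(run_kinetics_workflow(list(rates = path, out_dir = out,
                                          verbosity = 0)),
               class = "cypsom_input_error")
})

test_that("trajectory workflow compares two conditions against truth", {
  out <- withr::local_tempdir()
  preset <- scenario_presets("pgs_trajectory_pair")
  g1 <- generate_toy_trajectory(preset$conditions$no_pgs)
  g2 <- generate_toy_trajectory(preset$conditions$with_pgs)
  res <- run_trajectory_workflow(list(
    conditions = list(list(label = "no_pgs", traj = g1$traj),
                      list(label = "with_pgs", traj = g2$traj)),
    out_dir = out, verbosity = 0))

  # summary matches the generators' own labels
  expect_equal(res$summary$n_productive[1], sum(g1$labels$productive))
  expect_equal(res$summary$n_selective[2],
               sum(g2$labels$selective %in% TRUE))
  # effector condition shows the higher non-selective fraction
  expect_gt(res$summary$nonselective_fraction[2],
            res$summary$nonselective_fraction[1])

  # differential flags exactly the residues whose generating contact
  # probabilities changed by >= 50%
  pa <- preset$conditions$no_pgs$contact_probs
  pb <- preset$conditions$with_pgs$contact_probs
  truth_flag <- (pb - pa) / pa <= -0.5
  d <- res$differential
  expect_identical(d$flag_major_loss[match(names(pa), d$residue)],
                   unname(truth_flag))
  for (f in c("frames_no_pgs.csv", "hist_c4_with_pgs.csv",
              "contacts_no_pgs.csv", "contact_differential.csv",
              "condition_summary.csv"))
    expect_true(file.exists(file.path(out, f)))
})

test_that("trajectory workflow handles one condition and honours stride", {
  out <- withr::local_tempdir()
  gen <- generate_toy_trajectory(trajectory_spec(n_frames = 60, seed = 33))
  res <- run_trajectory_workflow(list(
    conditions = list(list(label = "solo", traj = gen$traj)),
    out_dir = out, stride = 3, verbosity = 0))
  expect_null(res$differential)
  frames <- utils::read.csv(file.path(out, "frames_solo.csv"),
                            comment.char = "#")
  expect_identical(nrow(frames), 20L)
  expect_identical(frames$frame, seq(0L, 59L, by = 3L))
})

test_that("make_synthetic materialises presets with a faithful manifest", {
  out <- withr::local_tempdir()
  man <- make_synthetic(list(preset = "steroid_20_50um", out_dir = out,
                             seed = 9, verbosity = 0))
  expect_identical(man$seed, 9L)
  d <- read_rate_csv(man$paths$rates)
  expect_identical(sort(unique(d$x_um)), c(0, 20, 50))
  manifest <- read_config(file.path(out, "manifest.yaml"))
  expect_identical(manifest$seed, 9L)
  expect_identical(manifest$preset, "steroid_20_50um")
  truth <- config_to_params(manifest$truth)
  expect_equal(truth$kd_allo_x, 20)

  man2 <- make_synthetic(list(preset = "medroxyprogesterone_2_8um",
                              out_dir = withr::local_tempdir(),
                              verbosity = 0))
  d2 <- read_rate_csv(man2$paths$rates)
  expect_identical(sort(unique(d2$x_um)), c(0, 2, 8))

  expect_error(make_synthetic(list(preset = "nope", out_dir = out)),
               class = "cypsom_lookup_error")
})
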