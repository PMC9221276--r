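test_that("generators are bit-reproducible under a fixed seed", {
  truth <- mdz_params(kd_allo_x = 5)
  design <- rate_design(x_levels = c(0, 15), noise = "proportional",
                        cv = 0.05, seed = 9)
  d1 <- generate_rate_dataset(truth, design)
  d2 <- generate_rate_dataset(truth, design)
  expect_identical(d1, d2)
  design3 <- rate_design(x_levels = c(0, 15), noise = "proportional",
                         cv = 0.05, seed = 10)
  expect_false(isTRUE(all.equal(d1$v1oh,
                                generate_rate_dataset(truth, design3)$v1oh)))

  t1 <- generate_titration(10, 0.7, c(1, 5, 20, 80), noise_sd = 0.02, seed = 4)
  t2 <- generate_titration(10, 0.7, c(1, 5, 20, 80), noise_sd = 0.02, seed = 4)
  expect_identical(t1, t2)

  spec <- trajectory_spec(n_frames = 50, seed = 12)
  g1 <- generate_toy_trajectory(spec)
  g2 <- generate_toy_trajectory(spec)
  expect_identical(g1$traj$xyz, g2$traj$xyz)
  spec2 <- trajectory_spec(n_frames = 50, seed = 13)
  expect_false(identical(g1$traj$xyz, generate_toy_trajectory(spec2)$traj$xyz))
})

test_that("noiseless rate data pass the model predictions through", {
  truth <- mdz_params(kd_allo_x = 5)
  d <- generate_rate_dataset(truth, rate_design(x_levels = c(0, 15)))
  pred <- predict_rates(truth, d$s_um, d$x_um)
  expect_identical(d$v1oh, pred$v_1oh)
  expect_identical(d$v4oh, pred$v_4oh)
})

test_that("proportional noise realises the requested coefficient of variation", {
  truth <- mdz_params()
  design <- rate_design(s_grid = rep(10, 4), x_levels = 0,
                        noise = "proportional", cv = 0.05,
                        replicates = 250, seed = 14)
  d <- generate_rate_dataset(truth, design)
  cv_hat <- sd(d$v1oh) / mean(d$v1oh)
  expect_lt(abs(cv_hat - 0.05) / 0.05, 0.10)
})

test_that("titration generator honours exact points and clipping", {
  tc <- generate_titration(ks = 10, bmax = 0.7, grid = c(0, 5, 10, 50))
  expect_equal(tc$response[tc$ligand_um == 10], 0.35)
  expect_equal(tc$response[tc$ligand_um == 0], 0)
  noisy <- generate_titration(ks = 10, bmax = 0.9, grid = rep(c(1, 100), 50),
                              noise_sd = 0.6, seed = 15)
  expect_true(all(noisy$response >= 0 & noisy$response <= 1))
  expect_error(generate_titration(10, 0.7, c(-1, 5)),
               class = "cypsom_input_error")
})

test_that("generated label frequencies converge to the spec probabilities", {
  spec <- trajectory_spec(n_frames = 10000, productive_probability = 0.52,
                          selective_probability = 0.8,
                          contact_probs = c("106" = 0.6, "215" = 0.25),
                          seed = 16)
  gen <- generate_toy_trajectory(spec)
  ci <- function(p, n) qnorm(0.995) * sqrt(p * (1 - p) / n)
  p_hat <- mean(gen$labels$productive)
  expect_lt(abs(p_hat - 0.52), ci(0.52, 10000))
  sel <- gen$labels$selective[gen$labels$productive]
  expect_lt(abs(mean(sel) - 0.8), ci(0.8, length(sel)))
  expect_lt(abs(mean(gen$labels$contact_106) - 0.6), ci(0.6, 10000))
  expect_lt(abs(mean(gen$labels$contact_215) - 0.25), ci(0.25, 10000))
})

test_that("a zero contact probability yields zero contacts", {
  spec <- trajectory_spec(n_frames = 300,
                          contact_probs = c("106" = 0, "215" = 0.5),
                          seed = 18)
  gen <- generate_toy_trajectory(spec)
  ct <- contact_counts(gen$traj, "resname MDZ", c(106L, 215L),
                       mask = rep(TRUE, 300))
  expect_identical(ct$counts[["106"]], 0L)
  expect_gt(ct$counts[["215"]], 0L)
})

test_that("written fixture files reproduce the in-memory trajectory", {
  spec <- trajectory_spec(n_frames = 40, seed = 22)
  dir <- withr::local_tempdir()
  gen <- generate_toy_trajectory(spec, dir = dir, prefix = "fix")
  expect_true(file.exists(gen$topology))
  expect_true(file.exists(gen$trajectory))
  reread <- read_trajectory(gen$topology, gen$trajectory)
  scan_mem <- scan_trajectory(gen$traj, gen$selections)
  scan_file <- scan_trajectory(reread, gen$selections)
  # PDB coordinates carry 3 decimals; labels must survive exactly
  expect_identical(scan_file$frames$productive, scan_mem$frames$productive)
  expect_identical(scan_file$frames$selective, scan_mem$frames$selective)
  expect_lt(max(abs(scan_file$frames$d_c1_o - scan_mem$frames$d_c1_o)), 5e-3)
  labels <- utils::read.csv(gen$labels_path)
  expect_identical(as.logical(labels$productive), gen$labels$productive)
})

test_that("scenario presets encode the published designs", {
  presets <- scenario_presets()
  expect_identical(setdiff(presets$pgs_15um$design$x_levels, 0), 15)
  expect_identical(setdiff(presets$steroid_20_50um$design$x_levels, 0),
                   c(20, 50))
  expect_identical(
    setdiff(presets$medroxyprogesterone_2_8um$design$x_levels, 0), c(2, 8))
  expect_lt(presets$anf_gefitinib_opposite$true_params$f4oh_sx,
            presets$anf_gefitinib_opposite$true_params$f4oh_ss)
  expect_identical(presets$pgs_trajectory_pair$kind, "trajectory")
  expect_error(scenario_presets("nonexistent"), class = "cypsom_lookup_error")
})

test_that("presets survive a config serialisation round trip", {
  dir <- withr::local_tempdir()
  for (nm in names(scenario_presets())) {
    preset <- scenario_presets(nm)
    path <- file.path(dir, paste0(nm, ".yaml"))
    write_config(preset_to_config(preset), path)
    back <- config_to_preset(read_config(path))
    expect_equal(back, preset, tolerance = 1e-9)
  }
})
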