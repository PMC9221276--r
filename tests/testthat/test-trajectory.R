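test_that("virtual oxygen sits on the distal heme normal", {
  o <- build_virtual_oxygen(ideal_heme())
  expect_equal(o, c(0, 0, 1.65), tolerance = 1e-12)
  # custom ferryl bond length
  o2 <- build_virtual_oxygen(ideal_heme(), fe_o_distance = 2)
  expect_equal(o2, c(0, 0, 2), tolerance = 1e-12)
})

test_that("virtual oxygen construction is rigid-motion equivariant", {
  set.seed(21)
  h <- ideal_heme()
  # perturb the nitrogens slightly off-plane so the plane fit is non-trivial
  h$pyrrole_n <- h$pyrrole_n + matrix(rnorm(12, 0, 0.05), 4, 3)
  h <- heme_geometry(h$fe, h$pyrrole_n, h$axial_s)
  o_ref <- build_virtual_oxygen(h)
  for (i in 1:50) {
    rot <- random_rotation()
    shift <- rnorm(3, 0, 10)
    ht <- heme_geometry(fe = as.numeric(rot %*% h$fe + shift),
                        pyrrole_n = t(apply(h$pyrrole_n, 1,
                                            function(p) rot %*% p + shift)),
                        axial_s = as.numeric(rot %*% h$axial_s + shift))
    o_t <- build_virtual_oxygen(ht)
    expect_lt(sqrt(sum((o_t - (rot %*% o_ref + shift))^2)), 1e-9)
  }
})

test_that("degenerate heme geometries are rejected", {
  # collinear nitrogens: no unique plane
  expect_error(
    heme_geometry(fe = c(0, 0, 0),
                  pyrrole_n = rbind(c(1, 0, 0), c(2, 0, 0),
                                    c(3, 0, 0), c(4, 0, 0)),
                  axial_s = c(0, 0, -2.3)),
    class = "cypsom_geometry_error")
  # axial sulfur in the pyrrole plane: distal side undefined
  expect_error(
    heme_geometry(fe = c(0, 0, 0),
                  pyrrole_n = rbind(c(2, 0, 0), c(-2, 0, 0),
                                    c(0, 2, 0), c(0, -2, 0)),
                  axial_s = c(2.5, 2.5, 0)),
    class = "cypsom_orientation_error")
  # badly non-planar nitrogens (two raised on the same side: no plane
  # within the 0.5 Angstrom tolerance)
  expect_error(
    heme_geometry(fe = c(0, 0, 0),
                  pyrrole_n = rbind(c(2, 0, 0), c(-2, 0, 0),
                                    c(0, 2, 1.5), c(0, -2, 1.5)),
                  axial_s = c(0, 0, -2.3)),
    class = "cypsom_geometry_error")
})

test_that("frame classification honours the boundary conventions", {
  o <- c(0, 0, 0)
  th <- classification_thresholds()
  at <- function(d) c(d, 0, 0)
  # productive boundary is inclusive ("within 4.5 A")
  expect_true(classify_frame(at(4.4), at(10), o, th)$productive)
  expect_true(classify_frame(at(4.5), at(10), o, th)$productive)
  expect_false(classify_frame(at(4.6), at(10), o, th)$productive)
  expect_true(is.na(classify_frame(at(4.6), at(10), o, th)$selective))
  # selective boundary is strict ("more than 5.5 A")
  expect_true(classify_frame(at(4.0), at(5.6), o, th)$selective)
  expect_false(classify_frame(at(4.0), at(5.5), o, th)$selective)
  expect_false(classify_frame(at(4.0), at(5.4), o, th)$selective)
  expect_error(classify_frame(c(0, 0, NA), at(1), o, th),
               class = "cypsom_input_error")
})

test_that("classifier agrees with brute-force distances on random frames", {
  set.seed(31)
  th <- classification_thresholds()
  o <- rnorm(3)
  for (i in 1:2000) {
    c1 <- rnorm(3, 0, 4)
    c4 <- rnorm(3, 0, 4)
    got <- classify_frame(c1, c4, o, th)
    d1 <- sqrt((c1[1] - o[1])^2 + (c1[2] - o[2])^2 + (c1[3] - o[3])^2)
    d4 <- sqrt((c4[1] - o[1])^2 + (c4[2] - o[2])^2 + (c4[3] - o[3])^2)
    expect_identical(got$productive, d1 <= 4.5)
    expect_identical(got$selective,
                     if (d1 <= 4.5) d4 > 5.5 else NA)
  }
})

test_that("scan_trajectory recovers generator labels exactly", {
  spec <- trajectory_spec(n_frames = 1000, productive_probability = 0.5,
                          selective_probability = 0.7, seed = 17)
  gen <- generate_toy_trajectory(spec)
  scan <- scan_trajectory(gen$traj, gen$selections)
  expect_identical(scan$frames$productive, gen$labels$productive)
  expect_identical(scan$frames$selective, gen$labels$selective)
  # summary counts agree with the per-frame list
  expect_identical(scan$summary$n_total, nrow(scan$frames))
  expect_identical(scan$summary$n_productive, sum(scan$frames$productive))
  expect_identical(scan$summary$n_selective,
                   sum(scan$frames$selective %in% TRUE))
  expect_identical(scan$summary$n_nonselective,
                   sum(scan$frames$selective %in% FALSE))
})

test_that("stride subsamples frames after reading", {
  spec <- trajectory_spec(n_frames = 100, seed = 19)
  gen <- generate_toy_trajectory(spec)
  full <- scan_trajectory(gen$traj, gen$selections)
  half <- scan_trajectory(gen$traj, gen$selections, stride = 2)
  expect_identical(half$frames$frame, seq(0L, 99L, by = 2L))
  expect_identical(half$frames$productive,
                   full$frames$productive[seq(1, 100, by = 2)])
})

test_that("constant trajectories classify all frames identically", {
  spec <- trajectory_spec(n_frames = 1, seed = 23)
  gen <- generate_toy_trajectory(spec)
  xyz <- gen$traj$xyz[rep(1, 20), , drop = FALSE]
  traj <- cyp_trajectory(gen$traj$atoms, xyz)
  scan <- scan_trajectory(traj, gen$selections)
  expect_true(scan$summary$n_productive %in% c(0L, 20L))
})

test_that("selection failures name the offending selection", {
  spec <- trajectory_spec(n_frames = 5, seed = 29)
  gen <- generate_toy_trajectory(spec)
  sels <- gen$selections
  sels$c1 <- "resname MDZ and name C9"
  err <- tryCatch(scan_trajectory(gen$traj, sels), error = function(e) e)
  expect_s3_class(err, "cypsom_selection_error")
  expect_match(conditionMessage(err), "c1")
})

test_that("distance histograms match a brute-force tally", {
  spec <- trajectory_spec(n_frames = 300, seed = 37)
  gen <- generate_toy_trajectory(spec)
  scan <- scan_trajectory(gen$traj, gen$selections)
  edges <- seq(0, 14, by = 0.5)
  for (po in c(FALSE, TRUE)) {
    h <- distance_histogram(scan, "c4", edges, productive_only = po)
    rows <- if (po) scan$frames[scan$frames$productive, ] else scan$frames
    expect_equal(sum(h$count), nrow(rows))
    for (b in seq_len(nrow(h))) {
      lo <- h$bin_lo[b]; hi <- h$bin_hi[b]
      manual <- sum(if (b == 1) rows$d_c4_o >= lo & rows$d_c4_o <= hi
                    else rows$d_c4_o > lo & rows$d_c4_o <= hi)
      expect_identical(h$count[b], as.integer(manual))
    }
  }
  # single spanning bin holds everything
  h1 <- distance_histogram(scan, "c1", c(0, 50))
  expect_identical(h1$count, nrow(scan$frames))
  expect_error(distance_histogram(scan, "c1", c(1, 1, 2)),
               class = "cypsom_input_error")
  expect_warning(
    distance_histogram(scan$frames[0, ], "c1", edges),
    "empty|no frames")
})

test_that("contact counts match hand enumeration on a toy system", {
  # 2 ligand atoms, 3 single-atom residues, 4 frames with hand distances
  atoms <- data.frame(
    name = c("C1", "C4", "CA", "CA", "CA"),
    resname = c("MDZ", "MDZ", "ALA", "ALA", "ALA"),
    resid = c(601L, 601L, 10L, 20L, 30L),
    chain = "A", element = "C", stringsAsFactors = FALSE)
  # frame layout: ligand at origin/x=2; residues at controlled distances
  place <- function(d10, d20, d30) {
    as.numeric(t(rbind(c(0, 0, 0), c(2, 0, 0),
                       c(d10, 0, 0), c(0, d20, 0), c(0, 0, d30))))
  }
  xyz <- rbind(place(3, 5, 10),    # res10 in contact
               place(4.0, 3.9, 10),  # res10 at cutoff (counts), res20 in
               place(7, 8, 3),     # res30 in contact
               place(9, 9, 9))     # none
  traj <- cyp_trajectory(atoms, xyz)
  ct <- contact_counts(traj, "resname MDZ", c(10L, 20L, 30L),
                       mask = rep(TRUE, 4), contact_cutoff = 4.0)
  expect_identical(unname(ct$counts), c(2L, 1L, 1L))
  # masking drops frames from the tally
  ct2 <- contact_counts(traj, "resname MDZ", c(10L, 20L, 30L),
                        mask = c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(unname(ct2$counts), c(1L, 0L, 1L))
  expect_identical(ct2$n_frames, 2L)
  # a vanishing cutoff removes all contacts
  ct0 <- contact_counts(traj, "resname MDZ", c(10L, 20L, 30L),
                        mask = rep(TRUE, 4), contact_cutoff = 1e-9)
  expect_true(all(ct0$counts == 0))
  expect_error(contact_counts(traj, "resname MDZ", c(10L, 99L),
                              mask = rep(TRUE, 4)),
               class = "cypsom_input_error")
  expect_error(contact_counts(traj, "resname MDZ", 10L, mask = TRUE),
               class = "cypsom_input_error")
})

test_that("contact counts are monotone in the cutoff", {
  spec <- trajectory_spec(n_frames = 200, seed = 41)
  gen <- generate_toy_trajectory(spec)
  rids <- as.integer(gsub("contact_", "",
                          grep("contact_", names(gen$labels), value = TRUE)))
  mask <- rep(TRUE, 200)
  prev <- rep(0L, length(rids))
  for (cutoff in c(1, 2.5, 4, 6, 9)) {
    ct <- contact_counts(gen$traj, "resname MDZ", rids, mask,
                         contact_cutoff = cutoff)
    expect_true(all(ct$counts >= prev))
    prev <- ct$counts
  }
})

test_that("sampled contact frequencies sit inside the binomial interval", {
  p_true <- 0.3
  spec <- trajectory_spec(n_frames = 10000,
                          contact_probs = c("106" = p_true), seed = 43)
  gen <- generate_toy_trajectory(spec)
  ct <- contact_counts(gen$traj, "resname MDZ", 106L,
                       mask = rep(TRUE, 10000))
  # 99% binomial interval around the generating probability
  half <- qnorm(0.995) * sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(ct$counts[["106"]] / 10000 - p_true), half)
  # and the count matches the generator's own labels exactly
  expect_identical(unname(ct$counts), sum(gen$labels$contact_106))
})

test_that("contact differentials flag major changes and stay antisymmetric", {
  mk <- function(counts, n, label) {
    structure(list(condition = label, n_frames = n,
                   counts = stats::setNames(as.integer(counts),
                                            c("106", "108", "215")),
                   residue_ids = c(106L, 108L, 215L),
                   contact_cutoff = 4.0),
              class = "contact_table")
  }
  a <- mk(c(100, 50, 0), 1000, "apo")
  b <- mk(c(40, 60, 30), 1000, "pgs")

  # identical tables: all zero, no flags
  d0 <- contact_differential(a, a)
  expect_true(all(d0$rel_change == 0))
  expect_false(any(d0$flag_major_loss | d0$flag_major_gain))

  d <- contact_differential(a, b)
  expect_equal(d$rel_change[d$residue == 106], -0.6)
  expect_true(d$flag_major_loss[d$residue == 106])
  expect_equal(d$rel_change[d$residue == 108], 0.2)
  expect_false(d$flag_major_loss[d$residue == 108] ||
                 d$flag_major_gain[d$residue == 108])
  # zero baseline becomes a new-contact category, not a division by zero
  expect_identical(d$category[d$residue == 215], "new-contact")
  expect_true(d$flag_major_gain[d$residue == 215])

  # swapping conditions negates finite changes
  rev <- contact_differential(b, a)
  expect_equal(rev$rel_change[rev$residue == 106],
               -d$rel_change[d$residue == 106] /
                 (1 + d$rel_change[d$residue == 106]))
  expect_true(rev$flag_major_gain[rev$residue == 106])

  # comparability guards
  c_other <- mk(c(1, 2, 3), 1000, "other")
  c_other$residue_ids <- c(106L, 108L, 999L)
  names(c_other$counts) <- c("106", "108", "999")
  expect_error(contact_differential(a, c_other),
               class = "cypsom_comparability_error")
  b_cut <- b
  b_cut$contact_cutoff <- 5
  expect_error(contact_differential(a, b_cut),
               class = "cypsom_comparability_error")
})
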