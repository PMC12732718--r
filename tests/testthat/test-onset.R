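topo <- default_topology()

test_that("upper-leaflet height averages POPC PO4 beads only", {
  # two 4-bead sheets plus one LND bead above: upper = sheet facing the LND
  heads <- NULL
  fr <- tiny_membrane_frame(n_side = 2, box = c(8, 8, 16), lnd_z = 12)
  fr$xyz[1:4, 3] <- c(10.0, 10.0, 10.2, 10.2)   # upper PO4 beads
  fr$xyz[5:8, 3] <- c(6.0, 6.0, 5.8, 5.8)       # mirror sheet keeps the centre at 8
  fr <- with_origins(fr, topo)
  expect_equal(upper_leaflet_height(fr, topo), 10.1, tolerance = 1e-9)
  # membrane whose LND-facing leaflet has no POPC -> error
  fr2 <- fr
  fr2$atoms$molecule_name[1:4] <- "DOPE"
  expect_error(upper_leaflet_height(fr2, topo), "POPC")
})

test_that("delta-z series is constant for a static elevated droplet", {
  fr <- tiny_membrane_frame(n_side = 3, box = c(8, 8, 16), lnd_z = 13)
  traj <- frame_to_traj(fr, times_ps = seq(0, 800, by = 200))
  traj <- with_origins(traj, topo)
  ser <- delta_z_series(traj, topo)
  expect_equal(ser$delta_z, rep(3, 5), tolerance = 1e-9)
  expect_true(all(ser$argmin_molecule_name == "ALCP"))
  expect_true(is.na(detect_onset(ser)$onset_time_ps))
})

test_that("planted linear descent and deepest molecule are recovered per frame", {
  run <- small_run(seed = 31, frames = 80, onset_ps = 8000)
  gt <- run$ground_truth
  ser <- delta_z_series(run$trajectory, run$topology)
  pre <- seq_len(gt$onset_frame - 1L)
  expect_equal(ser$delta_z[pre], gt$dz_plan[pre], tolerance = 1e-9)
  expect_equal(diff(ser$delta_z[pre]), rep(-1 * 200 / 8000, length(pre) - 1L),
               tolerance = 1e-9)
  expect_true(all(ser$argmin_molecule_id[seq_len(gt$onset_frame)] ==
                    gt$deepest_molecule_id))
})

test_that("onset rule: strict sign, persistence, blip rejection, censoring", {
  mkser <- function(dz, spacing = 200) {
    structure(data.frame(frame = seq_along(dz), time_ps = (seq_along(dz) - 1) * spacing,
                         h_u = 0, h_L = dz, delta_z = dz,
                         argmin_molecule_id = 1L, argmin_molecule_name = "ALCP"),
              class = c("delta_z_series", "data.frame"))
  }
  # sub-persistence blip at frame 20 rejected, real crossing at frame 37 found
  dz <- rep(1, 60)
  dz[20:21] <- -0.2
  dz[37:60] <- -0.5
  r <- detect_onset(mkser(dz))
  expect_equal(r$onset_frame, 37L)
  expect_equal(r$onset_frame, oracle_onset(dz, (0:59) * 200))
  # exact zero does not trigger
  dz0 <- dz; dz0[37] <- 0
  expect_equal(detect_onset(mkser(dz0))$onset_frame, 38L)
  # negative run truncated by trajectory end -> absent, censored
  dzc <- rep(1, 60); dzc[58:60] <- -0.5
  rc <- detect_onset(mkser(dzc))
  expect_true(is.na(rc$onset_time_ps))
  expect_true(rc$censored)
  # randomized series agree with the plain scan oracle
  set.seed(42)
  for (k in 1:25) {
    dzr <- ifelse(runif(80) < 0.4, -runif(80), runif(80))
    expect_equal(detect_onset(mkser(dzr))$onset_frame, oracle_onset(dzr, (0:79) * 200),
                 info = paste("series", k))
  }
})

test_that("detection is invariant to time translation and xy translation", {
  run <- small_run(seed = 8, frames = 60, onset_ps = 4000)
  ser <- delta_z_series(run$trajectory, run$topology)
  base <- detect_onset(ser)
  t2 <- run$trajectory
  t2$times_ps <- t2$times_ps + 5e5
  ser2 <- delta_z_series(t2, run$topology)
  expect_equal(detect_onset(ser2)$onset_time_ps, base$onset_time_ps + 5e5)
  t3 <- run$trajectory
  t3$coords[, 1, ] <- t3$coords[, 1, ] + 3.3
  t3$coords[, 2, ] <- t3$coords[, 2, ] - 1.7
  ser3 <- delta_z_series(t3, run$topology)
  expect_equal(ser3$delta_z, ser$delta_z, tolerance = 1e-9)
  # and to whole-box periodic z shifts
  t4 <- run$trajectory
  t4$coords[, 3, ] <- (t4$coords[, 3, ] + 7) %% t4$boxes[1, 3]
  ser4 <- delta_z_series(t4, run$topology)
  expect_equal(ser4$delta_z, ser$delta_z, tolerance = 1e-9)
})

test_that("entry ranking identifies the best-placed ionizable lipid", {
  run <- small_run(seed = 6, frames = 40, onset_ps = 2000)
  res <- fusion_onset(run$trajectory, run$topology)
  expect_equal(res$onset_time_ps, run$ground_truth$onset_ps)
  expect_equal(res$il_rank, 1L)
  expect_equal(res$ranking$molecule_id[1], run$ground_truth$deepest_molecule_id)
  # cholesterol planted deeper than every ionizable lipid -> rank 2
  run2 <- small_run(seed = 16, frames = 40, onset_ps = 2000,
                    deepest_species = "CHOL", second_species = "IL")
  res2 <- fusion_onset(run2$trajectory, run2$topology)
  expect_equal(res2$first_entrant, "CHOL")
  expect_equal(res2$il_rank, 2L)
  # a single-molecule droplet (one ionizable lipid) trivially ranks first
  run3 <- small_run(seed = 26, frames = 40, onset_ps = 2000,
                    protonated_percent = 100,
                    lnd_composition = c(IL = 1, CHOL = 0, DSPC = 0),
                    retained = c(protonated = 1, deprotonated = 0, other = 0))
  res3 <- fusion_onset(run3$trajectory, run3$topology)
  expect_equal(res3$il_rank, 1L)
  expect_equal(nrow(res3$ranking), 1L)
})
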