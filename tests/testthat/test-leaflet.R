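topo <- default_topology()

test_that("leaflet reference splits POPC sheets and tracks orientation", {
  run <- small_run(seed = 12, frames = 6, onset_ps = 400)
  ref <- build_leaflet_reference(run$trajectory, run$topology)
  expect_length(ref$inner_po4_idx, 96)   # EEM: 192 POPC split over two sheets
  expect_length(ref$outer_po4_idx, 96)
  expect_length(intersect(ref$inner_molecules, ref$outer_molecules), 0)
  led <- run$ground_truth$membrane_ledger
  expect_setequal(ref$inner_molecules,
                  led$molecule_id[led$molecule_name == "POPC" & led$leaflet == "upper"])
  # reflecting the system in z puts the droplet below: labels must swap
  t2 <- run$trajectory
  t2$coords[, 3, ] <- t2$boxes[1, 3] - t2$coords[, 3, ]
  ref2 <- build_leaflet_reference(t2, run$topology)
  expect_setequal(ref2$inner_molecules, ref$inner_molecules)
  # monolayer input is rejected
  fr <- tiny_membrane_frame(n_side = 3, box = c(8, 8, 16), lnd_z = 12)
  fr$xyz[10:18, 3] <- 10          # collapse the lower sheet onto the upper
  expect_error(build_leaflet_reference(frame_to_traj(fr), topo), "both sides")
})

test_that("head-bead classification follows the dual-cutoff rule exactly", {
  fr <- tiny_membrane_frame(n_side = 4, box = c(8, 8, 16),
                            il_heads = rbind(c(1, 1, 6),      # on an outer PO4 bead
                                             c(4, 4, 8),      # equidistant midplane
                                             c(3, 3, 9.6)),   # near the inner sheet
                            lnd_z = 13)   # droplet marker: the upper sheet is inner
  traj <- frame_to_traj(fr)
  ref <- build_leaflet_reference(traj, topo)
  cl <- classify_head_beads(get_frame(traj, 1), ref, topo)
  expect_equal(cl$class, c("OUTER", "MIDPLANE", "INNER"))
  expect_equal(cl$d_outer[1], 0)
  # 500 random head placements against the brute-force oracle
  set.seed(99)
  heads <- cbind(runif(500) * 8, runif(500) * 8, runif(500, 4, 12))
  fr2 <- tiny_membrane_frame(n_side = 4, box = c(8, 8, 16), il_heads = heads)
  traj2 <- frame_to_traj(fr2)
  ref2 <- build_leaflet_reference(traj2, topo)
  got <- classify_head_beads(get_frame(traj2, 1), ref2, topo)$class
  inner <- fr2$xyz[ref2$inner_po4_idx, , drop = FALSE]
  outer <- fr2$xyz[ref2$outer_po4_idx, , drop = FALSE]
  expect_identical(got, oracle_classify(heads, inner, outer, fr2$box, 1.2))
})

test_that("midplane frequency is monotone in the cutoff with the right limits", {
  set.seed(5)
  heads <- cbind(runif(200) * 8, runif(200) * 8, runif(200, 3, 13))
  fr <- tiny_membrane_frame(n_side = 4, box = c(8, 8, 16), il_heads = heads)
  traj <- frame_to_traj(fr)
  mids <- vapply(c(0.05, 0.6, 1.2, 2.5, 12), function(co) {
    ref <- build_leaflet_reference(traj, topo, cutoff = co)
    mean(classify_head_beads(get_frame(traj, 1), ref, topo)$class == "MIDPLANE")
  }, 0)
  expect_true(all(diff(mids) <= 0))
  expect_equal(mids[1], 1)      # cutoff -> 0: everything midplane
  expect_equal(mids[5], 0)      # cutoff beyond the box: nothing midplane
})

test_that("migration fractions recover planted occupancy and sum to one", {
  probs <- list(IL_PROTONATED = c(inner = 0.20, outer = 0.44, midplane = 0.36),
                IL_DEPROTONATED = c(inner = 0.02, outer = 0.04, midplane = 0.94))
  run <- small_run(seed = 77, frames = 60, onset_ps = 1000, class_probs = probs)
  ref <- build_leaflet_reference(run$trajectory, run$topology)
  mf <- migration_fractions(run$trajectory, ref, run$topology,
                            window_ps = c(2000, 11800), stride_ps = 200)
  sums <- mf$fraction_inner + mf$fraction_outer + mf$fraction_midplane
  expect_equal(sums, c(1, 1), tolerance = 1e-12)
  # per-molecule occupancy makes the species molecule count the binomial n
  gt <- run$ground_truth$classes
  for (s in mf$species) {
    g <- if (s == "IL_PROTONATED") "protonated" else "deprotonated"
    n <- sum(gt$group == g)
    for (k in c("outer", "midplane")) {
      p <- probs[[s]][[k]]
      est <- mf[[paste0("fraction_", k)]][mf$species == s]
      expect_lte(abs(est - p), 3 * sqrt(p * (1 - p) / n) + 1e-9,
                 label = paste(s, k))
    }
  }
  # heads pinned to the inner sheet
  run2 <- small_run(seed = 78, frames = 20, onset_ps = 600,
                    class_probs = list(
                      IL_PROTONATED = c(inner = 1, outer = 0, midplane = 0),
                      IL_DEPROTONATED = c(inner = 1, outer = 0, midplane = 0)))
  ref2 <- build_leaflet_reference(run2$trajectory, run2$topology)
  mf2 <- migration_fractions(run2$trajectory, ref2, run2$topology,
                             window_ps = c(1000, 3800), stride_ps = 200)
  expect_equal(mf2$fraction_inner, c(1, 1))
  expect_equal(mf2$fraction_outer + mf2$fraction_midplane, c(0, 0))
})

test_that("a species absent at the protonation extremes reports NA", {
  run <- small_run(seed = 41, frames = 20, onset_ps = 600, protonated_percent = 0,
                   retained = c(protonated = 0, deprotonated = 20, other = 10))
  ref <- build_leaflet_reference(run$trajectory, run$topology)
  mf <- migration_fractions(run$trajectory, ref, run$topology,
                            window_ps = c(1000, 3800), stride_ps = 200)
  expect_true(is.na(mf$fraction_outer[mf$species == "IL_PROTONATED"]))
  expect_false(is.na(mf$fraction_outer[mf$species == "IL_DEPROTONATED"]))
})

test_that("replica aggregation uses mean and sample SD", {
  mk <- function(v) data.frame(species = c("IL_PROTONATED", "IL_DEPROTONATED"),
                               fraction_inner = 1 - v, fraction_outer = v,
                               fraction_midplane = 0)
  same <- replica_mean_sd(list(mk(0.4), mk(0.4), mk(0.4)))
  expect_equal(same$sd[same$class == "OUTER"], c(0, 0))
  spread <- replica_mean_sd(list(mk(0.2), mk(0.4), mk(0.6)))
  out_p <- spread[spread$species == "IL_PROTONATED" & spread$class == "OUTER", ]
  expect_equal(out_p$mean, 0.4)
  expect_equal(out_p$sd, 0.2)   # closed-form sample SD of (0.2, 0.4, 0.6)
  single <- replica_mean_sd(list(mk(0.3)))
  expect_true(attr(single, "single_replica"))
  expect_equal(single$sd, rep(0, 6))
})
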