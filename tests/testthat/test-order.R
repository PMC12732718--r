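test_that("P2 hits its analytic limits and isotropic null", {
  expect_identical(p2_of_vectors(rbind(c(0, 0, 1), c(0, 0, -3))), 1)
  expect_identical(p2_of_vectors(rbind(c(1, 0, 0), c(0, 2, 0), c(1, -1, 0))), -0.5)
  set.seed(2)
  iso <- lndfusion:::.unit_sphere(1e5)
  expect_lt(abs(p2_of_vectors(iso)), 0.01)
  expect_error(p2_of_vectors(rbind(c(0, 0, 1), c(0, 0, 0))), "zero-length")
})

test_that("P2 is invariant to sign flips and rotations about the normal", {
  set.seed(4)
  v <- lndfusion:::.unit_sphere(500) * runif(500, 0.5, 2)
  base <- p2_of_vectors(v)
  expect_equal(p2_of_vectors(-v), base, tolerance = 1e-12)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(p2_of_vectors(v %*% rot), base, tolerance = 1e-12)
})

test_that("segmental profile recovers the planted aligned weights", {
  w <- c(il_protonated = 0.30, il_deprotonated = 0.05, popc = 0.60,
         membrane_other = 0.50, dspc = 0.30)
  run <- small_run(seed = 71, frames = 80, onset_ps = 1000, order_w = w)
  op <- segmental_order_profile(run$trajectory, run$topology,
                                window_ps = c(2000, 15800), stride_ps = 200)
  il_names <- c(il_protonated = "ALCP", il_deprotonated = "ALCD", popc = "POPC")
  for (k in names(il_names)) {
    rows <- op[op$species == il_names[[k]], ]
    expect_gt(nrow(rows), 0)
    # pooled vectors: n per segment ~ molecules x snapshots
    se <- sqrt(0.35 / min(rows$n_vectors))
    expect_true(all(abs(rows$p2 - w[[k]]) < 3 * se + 0.01),
                label = paste("species", il_names[[k]]))
    # chemically equivalent chains give matching per-chain profiles
    m <- tapply(rows$p2, rows$chain, mean)
    expect_equal(unname(m[1]), unname(m[2]), tolerance = 0.05)
    # consecutive bonds and non-consecutive vectors carry the same order
    byk <- tapply(rows$p2, rows$kind, mean)
    expect_equal(unname(byk["CONSECUTIVE_BOND"]), unname(byk["NONCONSECUTIVE"]),
                 tolerance = 0.05)
  }
})

test_that("rigid all-parallel tails give P2 = 1 on every segment", {
  w <- c(il_protonated = 1, il_deprotonated = 1, popc = 1,
         membrane_other = 1, dspc = 1)
  run <- small_run(seed = 72, frames = 12, onset_ps = 600, order_w = w)
  op <- segmental_order_profile(run$trajectory, run$topology,
                                window_ps = c(1000, 2200), stride_ps = 200)
  expect_equal(op$p2, rep(1, nrow(op)), tolerance = 1e-9)
})

test_that("species filtering and absent species behave", {
  run <- small_run(seed = 73, frames = 10, onset_ps = 400, protonated_percent = 100,
                   retained = c(protonated = 10, deprotonated = 0, other = 10))
  op <- segmental_order_profile(run$trajectory, run$topology, species = "ALCP",
                                window_ps = c(800, 1800), stride_ps = 200)
  expect_setequal(unique(op$species), "ALCP")
  none <- segmental_order_profile(run$trajectory, run$topology, species = "MC3P",
                                  window_ps = c(800, 1800), stride_ps = 200)
  expect_equal(nrow(none), 0L)
})
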