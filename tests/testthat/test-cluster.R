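test_that("single-linkage components match planted blob structure", {
  box <- c(20, 20, 20)
  blob <- function(n, centre, first_id) {
    g <- expand.grid(x = 1:4, y = 1:4, z = 1:4)[seq_len(n), ] * 0.5
    xyz <- sweep(as.matrix(g), 2L, centre, "+")
    data.frame(molecule_id = first_id - 1L + seq_len(n), molecule_name = "CHOL",
               bead_name = "ROH", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  df <- rbind(blob(30, c(2, 2, 2), 1L), blob(20, c(12, 12, 12), 31L))
  fr <- cg_frame(df[1:3], as.matrix(df[4:6]), box)
  comps <- cluster_components(fr, df$molecule_id, cutoff = 1.2)
  expect_equal(vapply(comps, length, 0L), c(30L, 20L))
  expect_setequal(comps[[1]], 1:30)
  # single molecule: one component of size one
  fr1 <- cg_frame(df[1, 1:3], as.matrix(df[1, 4:6, drop = FALSE]), box)
  expect_equal(cluster_components(fr1, 1L), list(1L))
  # partition invariants + relabeling invariance
  all_ids <- unlist(comps)
  expect_setequal(all_ids, df$molecule_id)
  expect_equal(anyDuplicated(all_ids), 0L)
  perm <- sample(nrow(df))
  fr_p <- cg_frame(df[perm, 1:3], as.matrix(df[perm, 4:6]), box)
  expect_equal(canon_components(cluster_components(fr_p, df$molecule_id, 1.2)),
               canon_components(comps))
})

test_that("components agree with a brute-force union-find oracle", {
  set.seed(123)
  for (k in 1:12) {
    box <- c(6, 6, 6)
    fr <- random_molecule_frame(n_mol = 30, box = box)
    for (cutoff in c(0.8, 1.2)) {
      got <- cluster_components(fr, unique(fr$atoms$molecule_id), cutoff)
      want <- oracle_components(fr, fr$atoms$molecule_id, cutoff)
      expect_equal(canon_components(got), canon_components(want),
                   info = paste("frame", k, "cutoff", cutoff))
    }
  }
})

test_that("component structure is monotone in the linkage cutoff", {
  set.seed(17)
  fr <- random_molecule_frame(n_mol = 40, box = c(7, 7, 7))
  ids <- unique(fr$atoms$molecule_id)
  cuts <- c(0.3, 0.6, 1.0, 1.5, 2.5)
  sizes <- vapply(cuts, function(co) max(vapply(
    cluster_components(fr, ids, co), length, 0L)), 0L)
  expect_true(all(diff(sizes) >= 0))
  # edges only appear as the cutoff grows: partitions refine downward
  comp_small <- cluster_components(fr, ids, 0.6)
  comp_big <- cluster_components(fr, ids, 1.5)
  for (cs in comp_small) {
    hosts <- vapply(comp_big, function(cb) all(cs %in% cb), TRUE)
    expect_equal(sum(hosts), 1L)
  }
})

test_that("max-cluster series tracks the droplet then the planted retention", {
  run <- small_run(seed = 55, frames = 40, onset_ps = 4000, protonated_percent = 90,
                   membrane = "LEM",
                   retained = c(protonated = 5, deprotonated = 0, other = 10))
  # before fusion, the intact 100-lipid droplet is one cluster
  ct_pre <- max_cluster_timeseries(run$trajectory, run$topology,
                                   window_ps = c(0, 2000), stride_ps = 1000)
  expect_true(all(ct_pre$max_cluster_size == 100))
  # after fusion, the planted retained counts survive in the max cluster
  ct_post <- max_cluster_timeseries(run$trajectory, run$topology,
                                    window_ps = c(5000, 7800), stride_ps = 1000)
  expect_true(all(ct_post$max_cluster_size == 15))
  expect_true(all(ct_post$n_protonated == 5))
  expect_true(all(ct_post$n_deprotonated == 0))
  expect_error(max_cluster_timeseries(run$trajectory, run$topology,
                                      window_ps = c(9000, 9500)), "window")
})
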