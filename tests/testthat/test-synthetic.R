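test_that("same seed reproduces the run bit for bit; seeds differ otherwise", {
  p <- synthetic_params(seed = 33, frames = 20, onset_ps = 1000)
  a <- generate_fusion_trajectory(p)
  b <- generate_fusion_trajectory(p)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_fusion_trajectory(synthetic_params(seed = 34, frames = 20,
                                                   onset_ps = 1000))
  expect_false(identical(a$trajectory$coords, c$trajectory$coords))
  # different seeds: same ledger structure (sizes, species counts, bead roll)
  expect_identical(dim(a$trajectory$coords), dim(c$trajectory$coords))
  expect_identical(table(a$trajectory$atoms$molecule_name),
                   table(c$trajectory$atoms$molecule_name))
  expect_identical(sort(unique(a$trajectory$atoms$molecule_id)),
                   sort(unique(c$trajectory$atoms$molecule_id)))
})

test_that("membrane compositions match the study recipes", {
  m <- make_membrane(synthetic_params(seed = 2))
  tab <- table(m$ledger$molecule_name)
  expect_equal(sum(tab), 448L)   # early endosomal membrane
  expect_equal(as.integer(tab[c("POPC", "DOPE", "CHOL")]), c(192L, 94L, 162L))
  comp <- prop.table(tab)[c("POPC", "DOPE", "CHOL")]
  expect_equal(as.integer(round(100 * comp)), c(43L, 21L, 36L))   # 43/21/36 mol%
  s <- make_membrane(synthetic_params(seed = 2, membrane = "SLB"))
  expect_equal(as.integer(table(s$ledger$molecule_name)[c("POPC", "POPS")]),
               c(360L, 90L))
  # leaflet ledger agrees with the geometric side for every lipid
  mid <- 12.5
  po4 <- s$frame$atoms$bead_name %in% c("PO4", "ROH")
  z1 <- tapply(s$frame$xyz[po4, 3], s$frame$atoms$molecule_id[po4], mean)
  expect_identical(as.vector(z1[as.character(s$ledger$molecule_id)] > mid),
                   s$ledger$leaflet == "upper")
})

test_that("zero jitter puts every PO4 bead exactly on its sheet plane", {
  m <- make_membrane(synthetic_params(seed = 3, jitter = 0))
  po4 <- which(m$frame$atoms$bead_name == "PO4")
  up <- m$ledger$molecule_id[m$ledger$leaflet == "upper"]
  z <- m$frame$xyz[po4, 3]
  is_up <- m$frame$atoms$molecule_id[po4] %in% up
  expect_true(all(z[is_up] == m$planes[["upper"]]))
  expect_true(all(z[!is_up] == m$planes[["lower"]]))
})

test_that("upper-leaflet height estimate matches the built sheet closely", {
  p <- synthetic_params(seed = 19, membrane_counts = c(POPC = 400), frames = 5)
  m <- make_membrane(p)
  # one droplet bead above the bilayer marks which leaflet is "upper"
  atoms <- rbind(m$frame$atoms,
                 data.frame(molecule_id = 9999L, molecule_name = "ALCP",
                            bead_name = "NC3", stringsAsFactors = FALSE))
  xyz <- rbind(m$frame$xyz, c(5, 5, m$planes[["upper"]] + 3))
  fr <- with_origins(cg_frame(atoms, xyz, p$box), default_topology())
  expect_equal(upper_leaflet_height(fr, default_topology()), m$planes[["upper"]],
               tolerance = 0.015)   # 200 upper lipids, jitter SD 0.05
})

test_that("droplet composition, protonation split and connectivity are planted", {
  l <- make_lnd(synthetic_params(seed = 8, protonated_percent = 50))
  tab <- table(l$ledger$molecule_name)
  expect_equal(as.integer(tab[c("ALCP", "ALCD", "CHOL", "DSPC")]),
               c(25L, 25L, 40L, 10L))
  comps <- cluster_components(l$frame, l$ledger$molecule_id, cutoff = 1.2)
  expect_length(comps, 1L)
  expect_equal(length(comps[[1]]), 100L)
  l0 <- make_lnd(synthetic_params(seed = 8, protonated_percent = 0))
  expect_false("ALCP" %in% l0$ledger$molecule_name)
  expect_equal(sum(l0$ledger$molecule_name == "ALCD"), 50L)
  # the planted deepest bead sits at the droplet bottom
  deep_rows <- l$frame$atoms$molecule_id == l$deepest_molecule_id
  expect_equal(min(l$frame$xyz[deep_rows, 3]), min(l$frame$xyz[, 3]))
})

test_that("inconsistent plans are rejected", {
  expect_error(synthetic_params(retained = c(protonated = 30, deprotonated = 0,
                                             other = 0)),
               "exceed")
  expect_error(synthetic_params(protonated_percent = 55), "10% grid")
  expect_error(synthetic_params(blip = list(at_frac = 0.5, n_frames = 10)),
               "persistence")
  # dispersal overflow: tiny box cannot isolate the dispersed lipids
  p <- synthetic_params(seed = 1, frames = 6, onset_ps = 400,
                        box = c(6, 6, 25),
                        membrane_counts = c(POPC = 120, DOPE = 20, CHOL = 20),
                        retained = c(protonated = 0, deprotonated = 0, other = 0))
  expect_error(generate_fusion_trajectory(p), "overflow")
})

test_that("generated files are valid reader inputs end to end", {
  run <- small_run(seed = 14, frames = 5, onset_ps = 400)
  d <- withr::local_tempdir()
  paths <- write_synthetic_run(run, d, "cgtraj")
  topo <- read_topology(paths[["topology"]])
  tr <- read_trajectory(paths[["gro"]], paths[["traj"]], topo)
  expect_equal(n_frames(tr), 5L)
  expect_equal(sort(unique(tr$atoms$molecule_id[tr$atoms$origin == "LND"])),
               sort(run$ground_truth$lnd_molecule_ids))
  gt <- jsonlite::read_json(paths[["ground_truth"]], simplifyVector = TRUE)
  expect_equal(gt$onset_ps, run$ground_truth$onset_ps)
  expect_equal(gt$seed, run$params$seed)
})
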