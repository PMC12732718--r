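pct1 <- function(f) round(100 * f, 1)

test_that("Henderson-Hasselbalch fractions reproduce the published endpoints", {
  # ALC-0315 (pKa 6.09)
  expect_equal(pct1(protonated_fraction(6.8, 6.09)), 16.3)
  expect_equal(pct1(protonated_fraction(5.0, 6.09)), 92.5)
  # MC3 (pKa 6.44)
  expect_equal(pct1(protonated_fraction(6.8, 6.44)), 30.4)
  expect_equal(pct1(protonated_fraction(5.9, 6.44)), 77.6)
  expect_equal(pct1(protonated_fraction(5.5, 6.44)), 89.7)
  expect_equal(pct1(protonated_fraction(5.0, 6.44)), 96.5)
  # the symmetry point is exact
  expect_identical(protonated_fraction(6.09, 6.09), 0.5)
})

test_that("inverse relation reproduces the design-table pH values", {
  expect_equal(round(ph_for_fraction(0.10, 6.09), 2), 7.04)
  expect_equal(round(ph_for_fraction(0.80, 6.09), 2), 5.49)
  expect_equal(round(ph_for_fraction(0.90, 6.44), 2), 5.49)
  expect_equal(round(ph_for_fraction(0.80, 6.44), 2), 5.84)
  expect_identical(ph_for_fraction(0.50, 6.44), 6.44)
  expect_true(is.na(ph_for_fraction(0, 6.09)))
  expect_true(is.na(ph_for_fraction(1, 6.09)))
})

test_that("fraction and pH maps are mutual inverses and monotone", {
  f <- seq(0.01, 0.99, by = 0.01)
  for (pKa in c(6.09, 6.44)) {
    expect_equal(protonated_fraction(ph_for_fraction(f, pKa), pKa), f,
                 tolerance = 1e-12)
  }
  pH <- seq(3, 10, by = 0.25)
  expect_true(all(diff(protonated_fraction(pH, 6.09)) < 0))   # decreasing in pH
  pKa <- seq(4, 9, by = 0.25)
  expect_true(all(diff(protonated_fraction(6.0, pKa)) > 0))   # increasing in pKa
})

test_that("compartment fraction ranges match the reported percent windows", {
  sp <- il_species()
  comp <- endosome_compartments()
  alc <- sp[sp$name == "ALC-0315", ]
  mc3 <- sp[sp$name == "MC3", ]
  lem <- comp[comp$name == "LEM", ]
  eem <- comp[comp$name == "EEM", ]
  r <- compartment_fraction_range(alc, lem)
  expect_equal(unname(r["f_max"]), 92.5)
  expect_true(r["f_min"] %in% c(79.5, 79.6))  # formula gives 79.55; printed 79.5
  expect_equal(unname(compartment_fraction_range(mc3, eem)), c(30.4, 77.6))
  # degenerate compartment pinned at the pKa
  deg <- data.frame(name = "X", pH_low = 6.44, pH_high = 6.44)
  expect_equal(unname(compartment_fraction_range(mc3, deg)), c(50, 50))
  expect_null(compartment_fraction_range(alc, comp[comp$name == "SLB", ]))
})

test_that("design matrix reproduces the 45-complex / 135-run layout", {
  d <- build_design_matrix()
  expect_equal(attr(d, "n_complexes"), 45L)
  expect_equal(attr(d, "n_runs"), 135L)
  tab <- table(d$il, d$membrane)
  expect_equal(sum(tab["ALC-0315", c("EEM", "LEM")]), 12)
  expect_equal(sum(tab["MC3", c("EEM", "LEM")]), 11)
  expect_equal(sum(tab[, "SLB"]), 22)
  # the ambiguous ALC 70% case pairs with both endosomal membranes
  a70 <- d[d$il == "ALC-0315" & d$percent == 70 & d$membrane != "SLB", ]
  expect_setequal(a70$membrane, c("EEM", "LEM"))
  expect_true(all(a70$assignment == "gap_both"))
  # MC3 80% is clearly nearer the early-endosome range
  m80 <- d[d$il == "MC3" & d$percent == 80 & d$membrane != "SLB", ]
  expect_equal(m80$membrane, "EEM")
  expect_equal(m80$assignment, "gap_nearer")
})

test_that("design matrix invariants: ordering, pH consistency, flags", {
  d1 <- build_design_matrix()
  d2 <- build_design_matrix(species = il_species()[2:1, ])
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(attr(d2, "n_complexes"), 45L)
  # every defined pH sits in its compartment's range, or the row is flagged
  comp <- endosome_compartments()
  for (i in seq_len(nrow(d1))) {
    if (is.na(d1$pH[i]) || d1$membrane[i] == "SLB") next
    r <- comp[comp$name == d1$membrane[i], ]
    in_range <- d1$pH[i] >= r$pH_low - 0.005 && d1$pH[i] <= r$pH_high + 0.005
    expect_true(in_range || d1$assignment[i] %in%
                  c("below_range", "above_range", "gap_nearer", "gap_both"),
                info = paste("row", i))
    if (d1$assignment[i] == "in_range") expect_true(in_range, info = paste("row", i))
  }
  # overlapping ranges are impossible with sane constants but must error
  bad <- data.frame(name = c("EEM", "LEM"), pH_low = c(5.0, 5.9),
                    pH_high = c(5.5, 6.8))
  expect_error(build_design_matrix(compartments = rbind(bad,
    data.frame(name = "SLB", pH_low = NA, pH_high = NA))), "overlapping")
})
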