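#' Ionizable-lipid species and endosomal compartments
#'
#' The two ionizable lipids carried by default are ALC-0315 (apparent pKa
#' 6.09) and D-Lin-MC3-DMA ("MC3", apparent pKa 6.44). The compartments are
#' the early endosomal membrane (EEM, lumen pH 6.8 down to 5.9), the late
#' endosomal membrane (LEM, pH 5.5 down to 5.0) and the simplified anionic
#' bilayer (SLB, no pH constraint).
#'
#' @return `il_species()`: data.frame with `name`, `apparent_pKa`;
#'   `endosome_compartments()`: data.frame with `name`, `pH_low`, `pH_high`.
#' @export
il_species <- function() {
  data.frame(name = c("ALC-0315", "MC3"), apparent_pKa = c(6.09, 6.44),
             stringsAsFactors = FALSE)
}

#' @rdname il_species
#' @export
endosome_compartments <- function() {
  data.frame(name = c("EEM", "LEM", "SLB"),
             pH_low = c(5.9, 5.0, NA), pH_high = c(6.8, 5.5, NA),
             stringsAsFactors = FALSE)
}

#' Protonated fraction of an ionizable lipid at a given pH
#'
#' Henderson-Hasselbalch: the acid HA is the protonated lipid, the conjugate
#' base A- the deprotonated one, so
#' `f = [HA] / ([HA] + [A-]) = 1 / (1 + 10^(pH - pKa))`.
#'
#' @param pH solution pH (vectorised).
#' @param pKa apparent pKa of the lipid.
#' @return protonated fraction in `[0, 1]`.
#' @examples
#' protonated_fraction(6.8, 6.09)  # 0.163
#' @export
protonated_fraction <- function(pH, pKa) {
  stopifnot(is.numeric(pH), is.numeric(pKa))
  1 / (1 + 10^(pH - pKa))
}

#' pH at which an ionizable lipid has a given protonated fraction
#'
#' Inverse of [protonated_fraction()]: `pH = pKa + log10((1 - f) / f)`.
#' Fractions of exactly 0 or 1 have no finite pH; `NA` is returned for them
#' (design tables print a dash for the 0% and 100% cases).
#'
#' @param f protonated fraction, strictly inside `(0, 1)` for a finite pH.
#' @param pKa apparent pKa.
#' @return pH (NA where `f` is 0 or 1).
#' @examples
#' ph_for_fraction(0.10, 6.09)  # 7.04
#' @export
ph_for_fraction <- function(f, pKa) {
  stopifnot(is.numeric(f), all(f >= 0 & f <= 1, na.rm = TRUE))
  out <- pKa + log10((1 - f) / f)
  out[f %in% c(0, 1)] <- NA_real_
  out
}

# round half away from zero at `digits` decimals (matches the printed tables)
round_half_away <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Protonated-fraction range of an ionizable lipid in a compartment
#'
#' Evaluates the Henderson-Hasselbalch fraction at the compartment's two pH
#' endpoints. Because the fraction decreases with pH, the compartment's high
#' pH gives the minimum fraction and its low pH the maximum. Fractions are
#' reported as percents rounded to one decimal (half away from zero), the
#' convention of the printed design values.
#'
#' @param il row of [il_species()] (or a list with `name`, `apparent_pKa`).
#' @param compartment row of [endosome_compartments()].
#' @return named numeric `c(f_min, f_max)` in percent, or `NULL` for a
#'   compartment without a pH range (SLB).
#' @export
compartment_fraction_range <- function(il, compartment) {
  if (is.na(compartment$pH_low) || is.na(compartment$pH_high)) return(NULL)
  f <- protonated_fraction(c(compartment$pH_high, compartment$pH_low),
                           il$apparent_pKa)
  c(f_min = round_half_away(100 * f[1], 1L), f_max = round_half_away(100 * f[2], 1L))
}

#' Build the LND-membrane complex design matrix
#'
#' For each ionizable lipid, protonation cases run over a percent grid
#' (default 0-100% in steps of 10). Each case is paired with the endosomal
#' compartment whose Henderson-Hasselbalch fraction range contains it: cases
#' at or below the EEM range go to EEM, cases at or above the LEM range go
#' to LEM. A case falling in the gap between the two ranges goes to the
#' nearer range endpoint, or to both compartments when its distances to the
#' two endpoints differ by at most `gap_tol` percentage points (this
#' reproduces the ambiguous 70% ALC-0315 case being paired with both, while
#' 80% MC3 pairs with EEM only). Every case is additionally paired with the
#' simplified bilayer (SLB). Cases strictly between 0 and 100% carry the pH
#' implied by the inverse Henderson-Hasselbalch relation; 0% and 100% have
#' no finite pH.
#'
#' @param species data.frame like [il_species()].
#' @param compartments data.frame like [endosome_compartments()]; must
#'   contain EEM, LEM and (optionally) SLB rows.
#' @param grid_step protonation grid step in percent; must divide 100.
#' @param replicas replicate simulations per complex.
#' @param gap_tol dual-assignment tolerance in percentage points.
#' @return data.frame of class `lnd_design` with columns `il`, `percent`,
#'   `membrane`, `pH`, `replicas`, `assignment`; attributes `n_complexes`
#'   and `n_runs`.
#' @examples
#' d <- build_design_matrix()
#' attr(d, "n_complexes")  # 45
#' attr(d, "n_runs")       # 135
#' @export
build_design_matrix <- function(species = il_species(),
                                compartments = endosome_compartments(),
                                grid_step = 10L, replicas = 3L, gap_tol = 1.5) {
  stopifnot(100L %% grid_step == 0L, replicas >= 1L)
  grid <- seq(0L, 100L, by = grid_step)
  comp <- function(nm) {
    r <- compartments[compartments$name == nm, , drop = FALSE]
    if (nrow(r) != 1L) NULL else r
  }
  eem <- comp("EEM"); lem <- comp("LEM"); slb <- comp("SLB")
  rows <- list()
  add <- function(il, p, membrane, assignment) {
    pH <- if (p %in% c(0L, 100L)) NA_real_ else ph_for_fraction(p / 100, il$apparent_pKa)
    rows[[length(rows) + 1L]] <<- data.frame(
      il = il$name, percent = p, membrane = membrane,
      pH = if (is.na(pH)) NA_real_ else round_half_away(pH, 2L),
      replicas = replicas, assignment = assignment, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(species))) {
    il <- species[i, , drop = FALSE]
    re <- compartment_fraction_range(il, eem)
    rl <- compartment_fraction_range(il, lem)
    if (is.null(re) || is.null(rl)) {
      stop("EEM and LEM compartments must both have pH ranges", call. = FALSE)
    }
    if (rl["f_min"] <= re["f_max"]) {
      stop("overlapping compartment fraction ranges for ", il$name, call. = FALSE)
    }
    for (p in grid) {
      if (p <= re["f_max"]) {
        add(il, p, "EEM", if (p < re["f_min"]) "below_range" else "in_range")
      } else if (p >= rl["f_min"]) {
        add(il, p, "LEM", if (p > rl["f_max"]) "above_range" else "in_range")
      } else {
        d_eem <- p - re["f_max"]
        d_lem <- rl["f_min"] - p
        if (abs(d_eem - d_lem) <= gap_tol) {
          add(il, p, "EEM", "gap_both")
          add(il, p, "LEM", "gap_both")
        } else {
          add(il, p, if (d_eem < d_lem) "EEM" else "LEM", "gap_nearer")
        }
      }
      if (!is.null(slb)) add(il, p, "SLB", "slb")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_complexes = nrow(out), n_runs = nrow(out) * replicas,
            class = c("lnd_design", "data.frame"))
}

#' @export
print.lnd_design <- function(x, ...) {
  cat("LND-membrane design matrix:", attr(x, "n_complexes"), "complexes,",
      attr(x, "n_runs"), "runs\n")
  tab <- table(x$il, x$membrane)
  print(tab)
  NextMethod()
}
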