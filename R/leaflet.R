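#' Build the leaflet reference from the first frame
#'
#' Splits membrane POPC PO4 beads by the sign of z minus the membrane PO4
#' median in the (recentred) reference frame; the side facing the LND
#' centroid is labelled INNER. Leaflet labels are carried per POPC molecule:
#' at analysis time the reference sheets are rebuilt from the current
#' positions of the molecules assigned to each leaflet in frame 0, so sheet
#' geometry follows the trajectory while labels do not churn if a POPC
#' itself flips.
#'
#' @param traj a [cg_trajectory] (frame 1 is the reference frame).
#' @param topology a [cg_topology].
#' @param cutoff leaflet assignment cutoff in nm (default 1.2).
#' @return list of class `leaflet_reference`: `inner_molecules`,
#'   `outer_molecules` (POPC molecule ids), `inner_po4_idx`,
#'   `outer_po4_idx` (bead indices), `cutoff`.
#' @export
build_leaflet_reference <- function(traj, topology, cutoff = 1.2) {
  stopifnot(cutoff > 0)
  ctx <- membrane_context(traj, topology)
  if (!length(ctx$upper_popc_po4) || !length(ctx$lower_popc_po4)) {
    stop("leaflet reference needs POPC PO4 beads on both sides of the ",
         "membrane midplane (monolayer or missing-POPC input?)", call. = FALSE)
  }
  ref <- list(inner_molecules = ctx$upper_popc_molecules,
              outer_molecules = ctx$lower_popc_molecules,
              inner_po4_idx = ctx$upper_popc_po4,
              outer_po4_idx = ctx$lower_popc_po4,
              mem_po4 = ctx$mem_po4,
              cutoff = cutoff)
  class(ref) <- "leaflet_reference"
  ref
}

#' @export
print.leaflet_reference <- function(x, ...) {
  cat(sprintf("<leaflet_reference> inner %d / outer %d POPC molecules, cutoff %.2f nm\n",
              length(x$inner_molecules), length(x$outer_molecules), x$cutoff))
  invisible(x)
}

#' Classify ionizable-lipid head beads as inner / outer / midplane
#'
#' A head-terminal bead belongs to a leaflet if its minimum-image distance
#' to any POPC PO4 bead of that leaflet's sheet is at most the cutoff
#' (1.2 nm). If it is within the cutoff of both sheets the nearer sheet
#' wins; an exact tie is MIDPLANE. Beads within neither cutoff are MIDPLANE
#' (this includes heads that have detached into solvent; they are counted
#' separately as a diagnostic downstream).
#'
#' @param frame a [cg_frame] (coordinates may be raw; they are recentred
#'   internally against the reference membrane PO4 beads).
#' @param reference a [build_leaflet_reference()] result.
#' @param topology a [cg_topology].
#' @return data.frame with one row per ionizable-lipid molecule:
#'   `molecule_id`, `molecule_name`, `species_class`, `class`
#'   (INNER/OUTER/MIDPLANE), `d_inner`, `d_outer`.
#' @export
classify_head_beads <- function(frame, reference, topology) {
  a <- frame$atoms
  if (!"origin" %in% names(a)) {
    a$origin <- assign_origins(a, topology)
  }
  cls <- species_class(topology, a$molecule_name)
  is_il <- cls %in% c("IL_PROTONATED", "IL_DEPROTONATED")
  head_bead <- head_terminal_bead(topology, a$molecule_name)
  hi <- which(is_il & a$bead_name == head_bead)
  if (!length(hi)) {
    return(data.frame(molecule_id = integer(), molecule_name = character(),
                      species_class = character(), class = character(),
                      d_inner = numeric(), d_outer = numeric(),
                      stringsAsFactors = FALSE))
  }
  xyz <- recenter_z(frame$xyz, frame$box, reference$mem_po4)
  d_in <- min_dist_to_set(xyz[hi, , drop = FALSE],
                          xyz[reference$inner_po4_idx, , drop = FALSE], frame$box)
  d_out <- min_dist_to_set(xyz[hi, , drop = FALSE],
                           xyz[reference$outer_po4_idx, , drop = FALSE], frame$box)
  co <- reference$cutoff
  class <- rep("MIDPLANE", length(hi))
  class[d_in <= co & (d_out > co | d_in < d_out)] <- "INNER"
  class[d_out <= co & (d_in > co | d_out < d_in)] <- "OUTER"
  # exact tie within both cutoffs stays MIDPLANE by construction
  data.frame(molecule_id = a$molecule_id[hi], molecule_name = a$molecule_name[hi],
             species_class = cls[hi], class = class,
             d_inner = d_in, d_outer = d_out, stringsAsFactors = FALSE)
}

#' Window snapshot indices at a given stride
#' @keywords internal
window_frames <- function(traj, window_ps, stride_ps) {
  t <- traj$times_ps
  if (window_ps[1] < t[1] - 1e-6 || window_ps[2] > t[length(t)] + 1e-6) {
    stop(sprintf("analysis window %g-%g ps lies outside the trajectory span %g-%g ps",
                 window_ps[1], window_ps[2], t[1], t[length(t)]), call. = FALSE)
  }
  idx <- which(t >= window_ps[1] - 1e-6 & t <= window_ps[2] + 1e-6)
  if (!length(idx)) stop("no stored frames in the analysis window", call. = FALSE)
  sp <- frame_spacing_ps(traj)
  if (!is.na(sp) && !is.na(stride_ps) && stride_ps > sp) {
    k <- max(1L, round(stride_ps / sp))
    idx <- idx[seq(1L, length(idx), by = k)]
  }
  idx
}

#' Leaflet occupancy (flip-flop) fractions over the post-fusion window
#'
#' For every snapshot in the window (default the 1500-2000 ns range at
#' 200 ps stride), classifies all ionizable-lipid head beads and averages
#' the per-class fractions over snapshots, separately for the protonated
#' and the deprotonated species. Denominators are the molecule counts of
#' the species in the whole system, so the three fractions sum to one
#' exactly in every snapshot. A species absent from the system (0% or 100%
#' protonated cases) is reported as `NA`.
#'
#' @param traj a [cg_trajectory].
#' @param reference a [build_leaflet_reference()] result.
#' @param topology a [cg_topology].
#' @param window_ps length-2 window in ps (default `c(1.5e6, 2e6)`).
#' @param stride_ps snapshot stride in ps (default 200).
#' @return data.frame of class `migration_fractions`: one row per species
#'   class with `fraction_inner`, `fraction_outer`, `fraction_midplane`,
#'   `n_molecules`, `n_snapshots` and the diagnostic `mean_detached`
#'   (average number of heads farther than twice the cutoff from both
#'   sheets, classified MIDPLANE by the rule).
#' @export
migration_fractions <- function(traj, reference, topology,
                                window_ps = c(1.5e6, 2e6), stride_ps = 200) {
  idx <- window_frames(traj, window_ps, stride_ps)
  species <- c("IL_PROTONATED", "IL_DEPROTONATED")
  acc <- matrix(0, 2L, 3L, dimnames = list(species, c("INNER", "OUTER", "MIDPLANE")))
  detach <- c(0, 0)
  nmol <- c(NA_integer_, NA_integer_)
  for (f in idx) {
    cl <- classify_head_beads(get_frame(traj, f), reference, topology)
    for (s in 1:2) {
      rows <- cl[cl$species_class == species[s], , drop = FALSE]
      nmol[s] <- nrow(rows)
      if (nrow(rows)) {
        acc[s, ] <- acc[s, ] + c(sum(rows$class == "INNER"),
                                 sum(rows$class == "OUTER"),
                                 sum(rows$class == "MIDPLANE")) / nrow(rows)
        detach[s] <- detach[s] +
          sum(rows$d_inner > 2 * reference$cutoff & rows$d_outer > 2 * reference$cutoff)
      }
    }
  }
  ns <- length(idx)
  out <- data.frame(
    species = species,
    fraction_inner = ifelse(nmol > 0, acc[, "INNER"] / ns, NA_real_),
    fraction_outer = ifelse(nmol > 0, acc[, "OUTER"] / ns, NA_real_),
    fraction_midplane = ifelse(nmol > 0, acc[, "MIDPLANE"] / ns, NA_real_),
    n_molecules = nmol, n_snapshots = ns,
    mean_detached = ifelse(nmol > 0, detach / ns, NA_real_),
    stringsAsFactors = FALSE
  )
  class(out) <- c("migration_fractions", "data.frame")
  out
}

#' Replica mean and standard deviation of migration fractions
#'
#' Aggregates per-replica occupancy fractions into the reporting form of
#' the migration tables: per species and class, the arithmetic mean and
#' the sample standard deviation (n - 1) over replicas. A single replica
#' yields SD 0 and is flagged.
#'
#' @param replicas list of [migration_fractions()] results.
#' @return data.frame of class `migration_summary`: `species`, `class`,
#'   `mean`, `sd`, `n_replicas`; attribute `single_replica`.
#' @export
replica_mean_sd <- function(replicas) {
  stopifnot(length(replicas) >= 1L)
  cols <- c(INNER = "fraction_inner", OUTER = "fraction_outer",
            MIDPLANE = "fraction_midplane")
  species <- replicas[[1]]$species
  rows <- list()
  for (s in species) {
    for (k in names(cols)) {
      v <- vapply(replicas, function(r) r[[cols[k]]][r$species == s], 0)
      m <- mean(v)
      sdev <- if (length(v) > 1L) stats::sd(v) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        species = s, class = k, mean = m, sd = if (all(is.na(v))) NA_real_ else sdev,
        n_replicas = length(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "single_replica") <- length(replicas) == 1L
  class(out) <- c("migration_summary", "data.frame")
  out
}

#' @export
print.migration_summary <- function(x, ...) {
  cat("Migration (flip-flop) summary over", x$n_replicas[1], "replica(s)",
      if (isTRUE(attr(x, "single_replica"))) "[single replica]" else "", "\n")
  y <- x
  y$value <- sprintf("%.2f +/- %.2f", y$mean, y$sd)
  print(as.data.frame(y[, c("species", "class", "value")]), row.names = FALSE)
  invisible(x)
}
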