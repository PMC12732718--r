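#' Indices used by membrane-referenced analyses
#'
#' Internal helper resolving the bead sets the onset and leaflet analyses
#' need: all membrane PO4 beads (for recentring and the leaflet split),
#' membrane POPC PO4 beads, and all LND-origin beads. The "upper" leaflet is
#' the one whose mean PO4 z (after recentring frame `ref_frame`) is nearer
#' the LND centroid; leaflet membership is assigned in that frame by the
#' sign of z minus the membrane PO4 median and held fixed per molecule
#' thereafter.
#'
#' @keywords internal
membrane_context <- function(traj, topology, ref_frame = 1L,
                             popc_name = "POPC", po4_bead = "PO4") {
  if (!"origin" %in% names(traj$atoms)) traj <- with_origins(traj, topology)
  a <- traj$atoms
  mem_po4 <- select_beads(traj, origin = "MEMBRANE", bead_name = po4_bead)
  if (!length(mem_po4)) stop("no membrane PO4 beads found", call. = FALSE)
  lnd <- select_beads(traj, origin = "LND")
  if (!length(lnd)) stop("no LND-origin beads found", call. = FALSE)
  xyz0 <- recenter_z(traj$coords[, , ref_frame, drop = TRUE],
                     traj$boxes[ref_frame, ], mem_po4)
  zmed <- stats::median(xyz0[mem_po4, 3])
  upper_side <- xyz0[mem_po4, 3] > zmed
  lnd_z <- mean(xyz0[lnd, 3])
  # the leaflet facing the LND is "upper" (inner); flip if the LND sits below
  if (lnd_z < zmed) upper_side <- !upper_side
  popc_po4 <- mem_po4[a$molecule_name[mem_po4] == popc_name]
  upper_popc_po4 <- intersect(mem_po4[upper_side], popc_po4)
  lower_popc_po4 <- intersect(mem_po4[!upper_side], popc_po4)
  list(traj = traj, mem_po4 = mem_po4, lnd = lnd,
       upper_popc_po4 = upper_popc_po4, lower_popc_po4 = lower_popc_po4,
       upper_popc_molecules = unique(a$molecule_id[upper_popc_po4]),
       lower_popc_molecules = unique(a$molecule_id[lower_popc_po4]))
}

#' Mean height of the upper-leaflet POPC phosphate beads
#'
#' The upper leaflet is the one facing the nanodroplet. Only POPC PO4 beads
#' enter the average; DOPE/POPS phosphates are excluded. The frame is
#' recentred (membrane PO4 centre to box-z/2) before averaging.
#'
#' @param frame a [cg_frame] with origins (see [with_origins()]).
#' @param topology a [cg_topology].
#' @return mean z in nm (in recentred coordinates).
#' @export
upper_leaflet_height <- function(frame, topology) {
  traj <- cg_trajectory(frame$atoms, array(frame$xyz, c(nrow(frame$xyz), 3L, 1L)),
                        frame$time_ps, frame$box)
  ctx <- membrane_context(traj, topology)
  if (!length(ctx$upper_popc_po4)) {
    stop("no POPC PO4 beads in the upper leaflet", call. = FALSE)
  }
  xyz <- recenter_z(frame$xyz, frame$box, ctx$mem_po4)
  mean(xyz[ctx$upper_popc_po4, 3])
}

#' Per-frame fusion-depth series (delta-Z)
#'
#' For every frame, computes `h_u` (mean z of upper-leaflet POPC PO4 beads),
#' `h_L` (minimum z over all LND-origin beads of every residue type) and
#' their difference `delta_z = h_L - h_u`, together with the LND molecule
#' attaining the minimum. Each frame is recentred so the membrane PO4 centre
#' of geometry sits at box-z/2, which makes the series invariant to
#' periodic z-wrapping and barostat drift.
#'
#' @param traj a [cg_trajectory].
#' @param topology a [cg_topology].
#' @return data.frame of class `delta_z_series` with columns `frame`,
#'   `time_ps`, `h_u`, `h_L`, `delta_z`, `argmin_molecule_id`,
#'   `argmin_molecule_name`.
#' @export
delta_z_series <- function(traj, topology) {
  ctx <- membrane_context(traj, topology)
  traj <- ctx$traj
  if (!length(ctx$upper_popc_po4)) {
    stop("no POPC PO4 beads in the upper leaflet", call. = FALSE)
  }
  nf <- n_frames(traj)
  h_u <- h_l <- numeric(nf)
  amin <- integer(nf)
  for (f in seq_len(nf)) {
    xyz <- recenter_z(traj$coords[, , f, drop = TRUE], traj$boxes[f, ], ctx$mem_po4)
    h_u[f] <- mean(xyz[ctx$upper_popc_po4, 3])
    zl <- xyz[ctx$lnd, 3]
    k <- which.min(zl)
    h_l[f] <- zl[k]
    amin[f] <- ctx$lnd[k]
  }
  out <- data.frame(frame = seq_len(nf), time_ps = traj$times_ps,
                    h_u = h_u, h_L = h_l, delta_z = h_l - h_u,
                    argmin_molecule_id = traj$atoms$molecule_id[amin],
                    argmin_molecule_name = traj$atoms$molecule_name[amin],
                    stringsAsFactors = FALSE)
  class(out) <- c("delta_z_series", "data.frame")
  out
}

#' @export
plot.delta_z_series <- function(x, ...) {
  graphics::plot(x$time_ps / 1000, x$delta_z, type = "l",
                 xlab = "time (ns)", ylab = expression(Delta * Z ~ "(nm)"), ...)
  graphics::abline(h = 0, lty = 2, col = "red")
  invisible(x)
}

#' Detect the onset of fusion from a delta-Z series
#'
#' Fusion starts at the earliest stored frame where `delta_z` is strictly
#' negative and stays negative at every stored frame for at least
#' `persistence_ns` thereafter. The persistence check uses stored frames
#' only (no interpolation) and requires the window to be fully covered by
#' data: a candidate whose window runs past the end of the trajectory does
#' not qualify, and if no candidate's window is covered the result is absent
#' with `censored = TRUE`. `delta_z == 0` exactly does not trigger.
#'
#' @param series a [delta_z_series()] result.
#' @param persistence_ns persistence requirement in nanoseconds.
#' @return list of class `onset_result`: `onset_time_ps` (NA if absent),
#'   `onset_frame`, `first_entrant` (residue name of the molecule attaining
#'   the minimum at onset), `censored`.
#' @export
detect_onset <- function(series, persistence_ns = 1.0) {
  stopifnot(nrow(series) > 0)
  pers_ps <- persistence_ns * 1000
  neg <- series$delta_z < 0
  t <- series$time_ps
  t_end <- t[length(t)]
  onset <- NA_integer_
  censored <- FALSE
  for (i in which(neg)) {
    covered <- t_end >= t[i] + pers_ps
    win <- t >= t[i] & t <= t[i] + pers_ps
    if (all(neg[win])) {
      if (covered) { onset <- i; break }
      censored <- TRUE   # sustained sign change, but window runs off the data
    }
  }
  res <- list(
    onset_time_ps = if (is.na(onset)) NA_real_ else t[onset],
    onset_frame = onset,
    first_entrant = if (is.na(onset)) NA_character_ else
      series$argmin_molecule_name[onset],
    censored = censored
  )
  class(res) <- "onset_result"
  res
}

#' @export
print.onset_result <- function(x, ...) {
  if (is.na(x$onset_time_ps)) {
    cat("Fusion onset: not detected",
        if (x$censored) "(censored: negative run truncated by trajectory end)" else "",
        "\n")
  } else {
    cat(sprintf("Fusion onset at %g ps (frame %d); first-entering residue: %s\n",
                x$onset_time_ps, x$onset_frame, x$first_entrant))
    if (!is.null(x$il_rank)) cat("  rank of best-placed ionizable lipid:", x$il_rank, "\n")
  }
  invisible(x)
}

#' Rank LND molecules by depth at the onset frame
#'
#' Orders LND molecules by their per-molecule minimum z minus `h_u` at the
#' onset frame (ascending: deepest first) and reports the 1-based rank of
#' the best-placed ionizable lipid. Ties break by molecule id.
#'
#' @param traj a [cg_trajectory].
#' @param topology a [cg_topology].
#' @param onset_frame frame index (e.g. from [detect_onset()]).
#' @return list with `ranking` (data.frame `molecule_id`, `molecule_name`,
#'   `species_class`, `delta_z`) and `il_rank`.
#' @export
entry_ranking <- function(traj, topology, onset_frame) {
  ctx <- membrane_context(traj, topology)
  traj <- ctx$traj
  stopifnot(onset_frame >= 1L, onset_frame <= n_frames(traj))
  xyz <- recenter_z(traj$coords[, , onset_frame, drop = TRUE],
                    traj$boxes[onset_frame, ], ctx$mem_po4)
  h_u <- mean(xyz[ctx$upper_popc_po4, 3])
  mol <- traj$atoms$molecule_id[ctx$lnd]
  zmin <- tapply(xyz[ctx$lnd, 3], mol, min)
  ids <- as.integer(names(zmin))
  nm <- traj$atoms$molecule_name[match(ids, traj$atoms$molecule_id)]
  ord <- order(zmin, ids)
  rk <- data.frame(molecule_id = ids[ord], molecule_name = nm[ord],
                   species_class = species_class(topology, nm[ord]),
                   delta_z = as.numeric(zmin)[ord] - h_u,
                   stringsAsFactors = FALSE)
  il_rank <- which(rk$species_class %in% c("IL_PROTONATED", "IL_DEPROTONATED"))[1]
  list(ranking = rk, il_rank = if (is.na(il_rank)) NA_integer_ else il_rank)
}

#' Full fusion-onset analysis of a trajectory
#'
#' Convenience wrapper: [delta_z_series()], [detect_onset()] and, when an
#' onset is found, [entry_ranking()].
#'
#' @inheritParams delta_z_series
#' @param persistence_ns persistence requirement in nanoseconds.
#' @return an `onset_result` with `series`, `il_rank` and `ranking` attached.
#' @export
fusion_onset <- function(traj, topology, persistence_ns = 1.0) {
  ser <- delta_z_series(traj, topology)
  res <- detect_onset(ser, persistence_ns)
  res$series <- ser
  if (!is.na(res$onset_frame)) {
    er <- entry_ranking(traj, topology, res$onset_frame)
    res$il_rank <- er$il_rank
    res$ranking <- er$ranking
  }
  res
}
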