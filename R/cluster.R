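#' Molecule adjacency under a minimum inter-bead distance cutoff
#'
#' Two molecules are adjacent when the minimum-image distance between any
#' bead of one and any bead of the other (ALL beads, head and tails) is at
#' most the cutoff.
#'
#' @param frame a [cg_frame].
#' @param molecule_ids molecules to consider.
#' @param cutoff linkage distance in nm.
#' @return two-column matrix of adjacent molecule-id pairs.
#' @keywords internal
molecule_adjacency <- function(frame, molecule_ids, cutoff) {
  keep <- frame$atoms$molecule_id %in% molecule_ids
  mol <- frame$atoms$molecule_id[keep]
  xyz <- frame$xyz[keep, , drop = FALSE]
  d2 <- pair_distance_matrix(xyz, xyz, frame$box, squared = TRUE)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  pairs <- cbind(mol[hit[, 1]], mol[hit[, 2]])
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  unique(pairs)
}

#' Single-linkage cluster components of a molecule set
#'
#' Connected components of the graph whose edges join molecule pairs with
#' minimum inter-bead minimum-image distance at most `cutoff` (1.2 nm by
#' default, the linkage criterion used throughout).
#'
#' @param frame a [cg_frame].
#' @param molecule_ids molecule ids to cluster (nonempty).
#' @param cutoff linkage distance in nm.
#' @return list of integer vectors of molecule ids (one per component),
#'   ordered by decreasing size then by smallest member id.
#' @export
cluster_components <- function(frame, molecule_ids, cutoff = 1.2) {
  molecule_ids <- unique(as.integer(molecule_ids))
  if (!length(molecule_ids)) stop("empty molecule set", call. = FALSE)
  stopifnot(cutoff > 0)
  adj <- molecule_adjacency(frame, molecule_ids, cutoff)
  ids <- as.character(molecule_ids)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(adj[, 1]), to = as.character(adj[, 2])),
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  parts <- split(molecule_ids, comp$membership[ids])
  parts <- lapply(parts, sort)
  ord <- order(-vapply(parts, length, 0L), vapply(parts, min, 0L))
  unname(parts[ord])
}

#' Largest-cluster time series over the nanodroplet molecules
#'
#' For each snapshot (at the given stride), computes the single-linkage
#' components over all LND-origin molecules (ionizable lipids, cholesterol,
#' DSPC) and records the size of the largest component and how many
#' protonated and deprotonated ionizable lipids it contains. When several
#' components tie for the maximum, the one containing the smallest molecule
#' id is reported (deterministic).
#'
#' @param traj a [cg_trajectory].
#' @param topology a [cg_topology].
#' @param window_ps optional length-2 analysis window (ps); default spans
#'   the whole trajectory.
#' @param stride_ps snapshot stride in ps (default 200).
#' @param cutoff linkage distance in nm (default 1.2).
#' @return data.frame of class `cluster_timeseries`: `time_ps`,
#'   `max_cluster_size`, `n_protonated`, `n_deprotonated`.
#' @export
max_cluster_timeseries <- function(traj, topology, window_ps = NULL,
                                   stride_ps = 200, cutoff = 1.2) {
  if (!"origin" %in% names(traj$atoms)) traj <- with_origins(traj, topology)
  lnd_idx <- select_beads(traj, origin = "LND")
  if (!length(lnd_idx)) stop("no LND-origin molecules identifiable", call. = FALSE)
  lnd_mols <- unique(traj$atoms$molecule_id[lnd_idx])
  if (is.null(window_ps)) {
    window_ps <- c(traj$times_ps[1], traj$times_ps[n_frames(traj)])
  }
  idx <- window_frames(traj, window_ps, stride_ps)
  a1 <- traj$atoms[match(lnd_mols, traj$atoms$molecule_id), ]
  spc <- species_class(topology, a1$molecule_name)
  prot_ids <- lnd_mols[spc == "IL_PROTONATED"]
  deprot_ids <- lnd_mols[spc == "IL_DEPROTONATED"]
  out <- data.frame(time_ps = traj$times_ps[idx], max_cluster_size = NA_integer_,
                    n_protonated = NA_integer_, n_deprotonated = NA_integer_)
  for (j in seq_along(idx)) {
    comps <- cluster_components(get_frame(traj, idx[j]), lnd_mols, cutoff)
    big <- comps[[1]]   # ordering puts the largest (smallest-min-id on ties) first
    out$max_cluster_size[j] <- length(big)
    out$n_protonated[j] <- sum(big %in% prot_ids)
    out$n_deprotonated[j] <- sum(big %in% deprot_ids)
  }
  class(out) <- c("cluster_timeseries", "data.frame")
  out
}

#' @export
plot.cluster_timeseries <- function(x, ...) {
  graphics::plot(x$time_ps / 1000, x$max_cluster_size, type = "l", col = "darkorange",
                 ylim = c(0, max(x$max_cluster_size)), xlab = "time (ns)",
                 ylab = "molecules in max cluster", ...)
  graphics::lines(x$time_ps / 1000, x$n_deprotonated, col = "darkgreen")
  graphics::lines(x$time_ps / 1000, x$n_protonated, col = "red")
  graphics::legend("topright", c("max cluster", "deprotonated IL", "protonated IL"),
                   col = c("darkorange", "darkgreen", "red"), lty = 1, bty = "n")
  invisible(x)
}
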