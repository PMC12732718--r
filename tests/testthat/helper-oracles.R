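# Independent brute-force oracles used to validate the package's geometry,
# classification and clustering routes.

# all 27 periodic images, enumerated explicitly
.shifts27 <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))

oracle_min_image <- function(a, b, box) {
  imgs <- sweep(.shifts27, 2L, box, "*")
  d <- sweep(imgs, 2L, b - a, "+")
  sqrt(min(rowSums(d * d)))
}

oracle_min_dist_sets <- function(x, y, box) {
  vapply(seq_len(nrow(x)), function(i) {
    min(vapply(seq_len(nrow(y)), function(j) oracle_min_image(x[i, ], y[j, ], box), 0))
  }, 0)
}

# leaflet classification, re-derived from the rule text
oracle_classify <- function(heads, inner, outer, box, cutoff) {
  d_in <- oracle_min_dist_sets(heads, inner, box)
  d_out <- oracle_min_dist_sets(heads, outer, box)
  out <- rep("MIDPLANE", nrow(heads))
  for (i in seq_along(d_in)) {
    if (d_in[i] <= cutoff && d_out[i] <= cutoff) {
      if (d_in[i] < d_out[i]) out[i] <- "INNER"
      if (d_out[i] < d_in[i]) out[i] <- "OUTER"
    } else if (d_in[i] <= cutoff) {
      out[i] <- "INNER"
    } else if (d_out[i] <= cutoff) {
      out[i] <- "OUTER"
    }
  }
  out
}

# hand-rolled union-find single-linkage clustering over molecules
oracle_components <- function(frame, molecule_ids, cutoff) {
  ids <- sort(unique(molecule_ids))
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  beads <- lapply(ids, function(m) frame$xyz[frame$atoms$molecule_id == m, , drop = FALSE])
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      dmin <- Inf
      for (a in seq_len(nrow(beads[[i]]))) {
        for (bb in seq_len(nrow(beads[[j]]))) {
          dmin <- min(dmin, oracle_min_image(beads[[i]][a, ], beads[[j]][bb, ], frame$box))
        }
      }
      if (dmin <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(ids), find, 0L)
  unname(lapply(split(ids, roots), sort))
}

# canonical form for comparing component partitions
canon_components <- function(comps) {
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, min, 0))]
}

# plain scan re-derivation of the onset rule
oracle_onset <- function(dz, times, persistence_ps = 1000) {
  t_end <- times[length(times)]
  for (i in seq_along(dz)) {
    if (dz[i] < 0) {
      win <- times >= times[i] & times <= times[i] + persistence_ps
      if (all(dz[win] < 0) && t_end >= times[i] + persistence_ps) return(i)
    }
  }
  NA_integer_
}

# small random frame of compact multi-bead molecules for oracle comparisons
random_molecule_frame <- function(n_mol, box, beads_per_mol = 3L, spread = 0.3) {
  ctr <- cbind(runif(n_mol, 0, box[1]), runif(n_mol, 0, box[2]), runif(n_mol, 0, box[3]))
  xyz <- ctr[rep(seq_len(n_mol), each = beads_per_mol), ] +
    matrix(runif(n_mol * beads_per_mol * 3, -spread, spread), ncol = 3)
  atoms <- data.frame(molecule_id = rep(seq_len(n_mol), each = beads_per_mol),
                      molecule_name = "MOL",
                      bead_name = rep(paste0("B", seq_len(beads_per_mol)), n_mol),
                      stringsAsFactors = FALSE)
  cg_frame(atoms, xyz, box)
}

# minimal planar membrane + ionizable-lipid head fixture built by hand
tiny_membrane_frame <- function(n_side = 4, box = c(8, 8, 16), il_heads = NULL,
                                lnd_z = NULL) {
  mid <- box[3] / 2
  xy <- expand.grid(x = (seq_len(n_side) - 0.5) * box[1] / n_side,
                    y = (seq_len(n_side) - 0.5) * box[2] / n_side)
  n <- nrow(xy)
  atoms <- data.frame(
    molecule_id = c(seq_len(2 * n), 2 * n + seq_len(NROW(il_heads))),
    molecule_name = c(rep("POPC", 2 * n), rep("ALCP", NROW(il_heads))),
    bead_name = c(rep("PO4", 2 * n), rep("OH", NROW(il_heads))),
    stringsAsFactors = FALSE)
  xyz <- rbind(cbind(xy$x, xy$y, mid + 2), cbind(xy$x, xy$y, mid - 2),
               il_heads)
  if (!is.null(lnd_z)) {
    atoms <- rbind(atoms, data.frame(molecule_id = max(atoms$molecule_id) + 1L,
                                     molecule_name = "ALCP", bead_name = "NC3",
                                     stringsAsFactors = FALSE))
    xyz <- rbind(xyz, c(box[1] / 2, box[2] / 2, lnd_z))
  }
  cg_frame(atoms, xyz, box)
}

frame_to_traj <- function(frame, times_ps = 0) {
  n <- nrow(frame$atoms)
  coords <- array(rep(frame$xyz, length(times_ps)), c(n, 3L, length(times_ps)))
  cg_trajectory(frame$atoms, coords, times_ps, frame$box)
}

# fast small synthetic run shared across tests
small_run <- function(seed = 1, frames = 60, onset_ps = 2000, ...) {
  generate_fusion_trajectory(synthetic_params(seed = seed, frames = frames,
                                              onset_ps = onset_ps, ...))
}
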