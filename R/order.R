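#' Second-rank order parameter of a set of vectors
#'
#' `P2 = < (3 cos^2 theta - 1) / 2 >` where theta is the angle between each
#' vector and the reference normal (the laboratory z-axis by default; the
#' membranes analysed here are planar and xy-periodic, so no per-frame
#' normal is fitted). The sign of a vector is irrelevant (cos^2 symmetry).
#' P2 = 1 for vectors parallel to the normal, -0.5 for vectors in the
#' plane, 0 for an isotropic distribution.
#'
#' @param vectors n x 3 matrix of segment vectors (any nonzero length).
#' @param normal reference direction (default `c(0, 0, 1)`).
#' @return scalar P2 in `[-0.5, 1]`.
#' @examples
#' p2_of_vectors(rbind(c(0, 0, 2)))   # 1
#' p2_of_vectors(rbind(c(1, 1, 0)))   # -0.5
#' @export
p2_of_vectors <- function(vectors, normal = c(0, 0, 1)) {
  v <- as.matrix(vectors)
  stopifnot(ncol(v) == 3L)
  n2 <- rowSums(v * v)
  if (any(n2 == 0)) {
    stop("zero-length segment vector at row ", which(n2 == 0)[1], call. = FALSE)
  }
  nu <- normal / sqrt(sum(normal^2))
  cth2 <- (v %*% nu)^2 / n2
  mean((3 * cth2 - 1) / 2)
}

#' Segmental P2 order profile for tail segments
#'
#' For every species with segment definitions in the topology (ionizable
#' lipids and POPC by default), computes P2 per defined segment: the vector
#' from `bead_a` to `bead_b` within each molecule (minimum-image per
#' dimension), pooled over all molecules of the species and all window
#' snapshots, against the bilayer normal (laboratory z). Protonated and
#' deprotonated ionizable-lipid species are reported separately, as are the
#' POPC sn1/sn2 chains. Molecules are included regardless of their leaflet
#' or midplane location.
#'
#' @param traj a [cg_trajectory].
#' @param topology a [cg_topology] with a segments table.
#' @param window_ps optional length-2 analysis window (ps); default the
#'   whole trajectory.
#' @param stride_ps snapshot stride in ps (default 200).
#' @param species optional character vector of residue names to restrict to.
#' @return data.frame of class `order_profile`: `species`, `chain`,
#'   `segment`, `kind`, `p2`, `n_vectors`.
#' @export
segmental_order_profile <- function(traj, topology, window_ps = NULL,
                                    stride_ps = 200, species = NULL) {
  seg <- topology$segments
  if (is.null(seg)) stop("topology has no tail segment definitions", call. = FALSE)
  if (!is.null(species)) seg <- seg[seg$molecule_name %in% species, , drop = FALSE]
  present <- unique(traj$atoms$molecule_name)
  seg <- seg[seg$molecule_name %in% present, , drop = FALSE]
  if (!nrow(seg)) {
    out <- data.frame(species = character(), chain = character(),
                      segment = character(), kind = character(),
                      p2 = numeric(), n_vectors = integer())
    class(out) <- c("order_profile", "data.frame")
    return(out)
  }
  if (is.null(window_ps)) {
    window_ps <- c(traj$times_ps[1], traj$times_ps[n_frames(traj)])
  }
  idx <- window_frames(traj, window_ps, stride_ps)
  a <- traj$atoms
  out <- seg[, c("molecule_name", "chain", "label", "kind")]
  names(out) <- c("species", "chain", "segment", "kind")
  out$p2 <- NA_real_
  out$n_vectors <- 0L
  for (i in seq_len(nrow(seg))) {
    sp <- seg$molecule_name[i]
    ia <- which(a$molecule_name == sp & a$bead_name == seg$bead_a[i])
    ib <- which(a$molecule_name == sp & a$bead_name == seg$bead_b[i])
    if (!length(ia) || length(ia) != length(ib)) {
      stop("segment ", seg$label[i], " of ", sp,
           ": beads missing or mismatched in the trajectory", call. = FALSE)
    }
    # align by molecule id so the vector is intramolecular
    ia <- ia[order(a$molecule_id[ia])]
    ib <- ib[order(a$molecule_id[ib])]
    if (any(a$molecule_id[ia] != a$molecule_id[ib])) {
      stop("segment ", seg$label[i], " of ", sp,
           ": bead_a/bead_b not paired within molecules", call. = FALSE)
    }
    s2 <- 0
    ntot <- 0L
    for (f in idx) {
      box <- traj$boxes[f, ]
      dv <- traj$coords[ib, , f, drop = FALSE] - traj$coords[ia, , f, drop = FALSE]
      dim(dv) <- c(length(ia), 3L)
      for (k in 1:3) dv[, k] <- min_image_delta(dv[, k], box[k])
      n2 <- rowSums(dv * dv)
      if (any(n2 == 0)) {
        stop("zero-length segment ", seg$label[i], " of ", sp, " (molecule ",
             a$molecule_id[ia[which(n2 == 0)[1]]], ", frame ", f, ")", call. = FALSE)
      }
      s2 <- s2 + sum((3 * dv[, 3]^2 / n2 - 1) / 2)
      ntot <- ntot + length(n2)
    }
    out$p2[i] <- s2 / ntot
    out$n_vectors[i] <- ntot
  }
  rownames(out) <- NULL
  class(out) <- c("order_profile", "data.frame")
  out
}

#' @export
plot.order_profile <- function(x, ...) {
  sp <- paste(x$species, x$chain, sep = "/")
  cols <- as.integer(factor(sp))
  graphics::plot(seq_len(nrow(x)), x$p2, pch = 19, col = cols, xaxt = "n",
                 xlab = "", ylab = expression(P[2]), ylim = range(c(0, x$p2)), ...)
  graphics::axis(1, at = seq_len(nrow(x)), labels = x$segment, las = 2, cex.axis = 0.7)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", legend = unique(sp), col = unique(cols),
                   pch = 19, bty = "n", cex = 0.8)
  invisible(x)
}
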