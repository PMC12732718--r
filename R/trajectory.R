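#' Construct a single coordinate frame
#'
#' @param atoms data.frame with columns `molecule_id`, `molecule_name`,
#'   `bead_name` and optionally `origin`; one row per bead.
#' @param xyz n x 3 numeric matrix of positions (nm).
#' @param box length-3 numeric box edge lengths (nm).
#' @param time_ps frame time in picoseconds.
#' @return object of class `cg_frame`.
#' @export
cg_frame <- function(atoms, xyz, box, time_ps = 0) {
  check_box(box)
  xyz <- as.matrix(xyz)
  dimnames(xyz) <- NULL
  stopifnot(is.data.frame(atoms), ncol(xyz) == 3L, nrow(xyz) == nrow(atoms))
  if (any(!nzchar(atoms$bead_name))) stop("bead_name must be nonempty", call. = FALSE)
  structure(list(atoms = atoms, xyz = xyz, box = as.numeric(box),
                 time_ps = as.numeric(time_ps)),
            class = "cg_frame")
}

#' @export
print.cg_frame <- function(x, ...) {
  cat(sprintf("<cg_frame> %d beads, %d molecules, t = %g ps, box %s nm\n",
              nrow(x$atoms), length(unique(x$atoms$molecule_id)), x$time_ps,
              paste(signif(x$box, 4), collapse = " x ")))
  invisible(x)
}

#' Construct a trajectory
#'
#' A trajectory holds one immutable atoms table (bead count and ordering are
#' identical across frames) together with a 3-D coordinate array, per-frame
#' times and per-frame boxes. Times must be strictly increasing; a
#' non-constant frame spacing is accepted with a warning.
#'
#' @param atoms data.frame as in [cg_frame()].
#' @param coords numeric array of dim `c(n_beads, 3, n_frames)` (nm).
#' @param times_ps numeric vector of frame times (ps), strictly increasing.
#' @param boxes `n_frames x 3` matrix of box edges (nm), or a single length-3
#'   box recycled over frames.
#' @return object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(atoms, coords, times_ps, boxes) {
  stopifnot(is.data.frame(atoms), length(dim(coords)) == 3L)
  nf <- dim(coords)[3]
  if (nf == 0L) stop("trajectory has zero frames", call. = FALSE)
  if (dim(coords)[1] != nrow(atoms) || dim(coords)[2] != 3L) {
    stop("coords must have dim c(n_beads, 3, n_frames)", call. = FALSE)
  }
  if (length(times_ps) != nf) stop("times_ps length must equal frame count", call. = FALSE)
  if (nf > 1L && any(diff(times_ps) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  if (is.null(dim(boxes))) boxes <- matrix(boxes, nf, 3, byrow = TRUE)
  apply(boxes, 1L, check_box)
  if (nf > 2L) {
    sp <- diff(times_ps)
    if (max(sp) - min(sp) > 1e-6 * max(sp)) {
      warning("frame spacing is not constant (", signif(min(sp), 4), " to ",
              signif(max(sp), 4), " ps)", call. = FALSE)
    }
  }
  structure(list(atoms = atoms, coords = coords,
                 times_ps = as.numeric(times_ps), boxes = boxes),
            class = "cg_trajectory")
}

#' Number of frames in a trajectory
#' @param traj a [cg_trajectory].
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Frame spacing of a trajectory in picoseconds
#'
#' @param traj a [cg_trajectory].
#' @return median spacing in ps, or `NA` for a single-frame trajectory.
#' @export
frame_spacing_ps <- function(traj) {
  if (n_frames(traj) < 2L) return(NA_real_)
  stats::median(diff(traj$times_ps))
}

#' Extract one frame of a trajectory
#' @param traj a [cg_trajectory].
#' @param i frame index (1-based).
#' @return a [cg_frame].
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  cg_frame(traj$atoms, traj$coords[, , i, drop = TRUE], traj$boxes[i, ],
           traj$times_ps[i])
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> %d beads x %d frames, t = %g..%g ps (spacing %s ps)\n",
              nrow(x$atoms), n_frames(x), x$times_ps[1],
              x$times_ps[n_frames(x)],
              format(frame_spacing_ps(x))))
  invisible(x)
}

#' @export
summary.cg_trajectory <- function(object, ...) {
  counts <- table(object$atoms$molecule_name)
  cat(sprintf("Trajectory: %d beads, %d molecules, %d frames\n",
              nrow(object$atoms), length(unique(object$atoms$molecule_id)),
              n_frames(object)))
  cat("Beads per residue name:\n")
  print(counts)
  if ("origin" %in% names(object$atoms)) {
    cat("Beads per origin:\n")
    print(table(object$atoms$origin))
  }
  invisible(object)
}

#' Select bead indices by origin, residue name and/or bead name
#'
#' Predicates combine with AND; `NULL` leaves a predicate unconstrained.
#' Selections depend only on the atoms table, hence are identical in every
#' frame of a trajectory.
#'
#' @param x a [cg_frame] or [cg_trajectory] (anything with an `atoms` table).
#' @param origin,molecule_name,bead_name character vectors of admissible
#'   values, or `NULL`.
#' @param molecule_id integer vector of admissible molecule ids, or `NULL`.
#' @return integer vector of bead (row) indices.
#' @export
select_beads <- function(x, origin = NULL, molecule_name = NULL,
                         bead_name = NULL, molecule_id = NULL) {
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(origin)) keep <- keep & a$origin %in% origin
  if (!is.null(molecule_name)) keep <- keep & a$molecule_name %in% molecule_name
  if (!is.null(bead_name)) keep <- keep & a$bead_name %in% bead_name
  if (!is.null(molecule_id)) keep <- keep & a$molecule_id %in% molecule_id
  which(keep)
}

#' Attach per-bead origins to a frame or trajectory
#'
#' Convenience wrapper around [assign_origins()]; errors if any residue name
#' is not covered by the topology.
#'
#' @param x a [cg_frame] or [cg_trajectory].
#' @param topology a [cg_topology].
#' @return `x` with an `origin` column in its atoms table.
#' @export
with_origins <- function(x, topology) {
  x$atoms$origin <- assign_origins(x$atoms, topology)
  x
}
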