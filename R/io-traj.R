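#' Plain-text trajectory dialect
#'
#' A line-oriented, human-inspectable trajectory format used for fixtures
#' and debugging:
#' ```
#' #cgtraj 1
#' frame <time_ps> <lx> <ly> <lz>
#' <molecule_id> <molecule_name> <bead_name> <x> <y> <z>
#' ...
#' frame <time_ps> <lx> <ly> <lz>
#' ...
#' ```
#' Coordinates are in nm, written with five decimals; times in ps. The bead
#' list must be identical (count and order) in every frame.
#'
#' @name cgtraj-dialect
#' @keywords internal
NULL

#' Write a trajectory in the plain-text dialect
#'
#' @param traj a [cg_trajectory].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_cgtraj()]
#' @export
write_cgtraj <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#cgtraj 1", con)
  a <- traj$atoms
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("frame %.6g %.5f %.5f %.5f", traj$times_ps[f],
                       traj$boxes[f, 1], traj$boxes[f, 2], traj$boxes[f, 3]), con)
    writeLines(sprintf("%d %s %s %.5f %.5f %.5f", a$molecule_id, a$molecule_name,
                       a$bead_name, traj$coords[, 1, f], traj$coords[, 2, f],
                       traj$coords[, 3, f]), con)
  }
  invisible(path)
}

#' Read a plain-text dialect trajectory
#'
#' @param path path to a `#cgtraj 1` file.
#' @return a [cg_trajectory] (atoms taken from the first frame block).
#' @export
read_cgtraj <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#cgtraj")) {
    stop("not a cgtraj file (missing '#cgtraj' header): ", path, call. = FALSE)
  }
  lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  hdr <- startsWith(lines, "frame ")
  if (!any(hdr)) stop("cgtraj file has zero frames: ", path, call. = FALSE)
  starts <- which(hdr)
  nf <- length(starts)
  per_frame <- diff(c(starts, length(lines) + 1L)) - 1L
  if (length(unique(per_frame)) != 1L) {
    stop("cgtraj frames differ in bead count: ", paste(unique(per_frame), collapse = ", "),
         call. = FALSE)
  }
  n <- per_frame[1]
  if (n == 0L) stop("cgtraj frame with zero beads: ", path, call. = FALSE)
  hvals <- lapply(strsplit(sub("^frame\\s+", "", lines[starts]), "\\s+"), as.numeric)
  if (any(vapply(hvals, length, 0L) != 4L) || anyNA(unlist(hvals))) {
    stop("malformed frame header line in ", path, call. = FALSE)
  }
  times <- vapply(hvals, `[`, 0, 1L)
  boxes <- t(vapply(hvals, function(v) v[2:4], numeric(3)))
  body <- lines[!hdr]
  toks <- strsplit(trimws(body), "\\s+")
  if (any(vapply(toks, length, 0L) != 6L)) {
    stop("malformed bead line in ", path, call. = FALSE)
  }
  tm <- matrix(unlist(toks), ncol = 6L, byrow = TRUE)
  first <- seq_len(n)
  atoms <- data.frame(molecule_id = as.integer(tm[first, 1]),
                      molecule_name = tm[first, 2], bead_name = tm[first, 3],
                      stringsAsFactors = FALSE)
  xyz <- matrix(as.numeric(tm[, 4:6]), ncol = 3L)
  if (anyNA(xyz)) stop("non-numeric coordinate in ", path, call. = FALSE)
  coords <- array(NA_real_, c(n, 3L, nf))
  for (f in seq_len(nf)) coords[, , f] <- xyz[(f - 1L) * n + first, ]
  cg_trajectory(atoms, coords, times, boxes)
}

# ---- GROMACS TRR (XDR) ---------------------------------------------------

.trr_magic <- 1993L

#' Write a trajectory as a GROMACS TRR file
#'
#' Writes the standard XDR TRR layout (single precision by default):
#' positions in nm, times in ps, diagonal box. Velocities and forces are not
#' written.
#'
#' @param traj a [cg_trajectory].
#' @param path output path.
#' @param double write double-precision reals.
#' @return `path`, invisibly.
#' @export
write_trr <- function(traj, path, double = FALSE) {
  prec <- if (double) 8L else 4L
  n <- nrow(traj$atoms)
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "big")
  wreal <- function(v) writeBin(as.numeric(v), con, size = prec, endian = "big")
  for (f in seq_len(n_frames(traj))) {
    wint(.trr_magic)
    wint(c(13L, 12L))
    writeBin(charToRaw("GMX_trn_file"), con)
    wint(c(0L, 0L,                    # ir_size, e_size
           9L * prec,                 # box_size
           0L, 0L, 0L, 0L,           # vir, pres, top, sym
           3L * n * prec,             # x_size
           0L, 0L,                    # v_size, f_size
           n, f - 1L, 0L))            # natoms, step, nre
    wreal(c(traj$times_ps[f], 0))     # t, lambda
    b <- traj$boxes[f, ]
    wreal(c(b[1], 0, 0, 0, b[2], 0, 0, 0, b[3]))
    wreal(t(traj$coords[, , f]))      # bead-major (x y z per bead)
  }
  invisible(path)
}

#' Read a GROMACS TRR trajectory
#'
#' Supports single- and double-precision files with positions; velocity and
#' force blocks, if present, are skipped. Only diagonal (orthorhombic) boxes
#' are accepted.
#'
#' @param path path to a `.trr` file.
#' @return list with `coords` (array `n x 3 x n_frames`), `times_ps`,
#'   `boxes`, `natoms`.
#' @export
read_trr <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rint <- function(k) readBin(con, "integer", n = k, size = 4L, endian = "big")
  frames <- list()
  repeat {
    magic <- rint(1L)
    if (!length(magic)) break
    if (magic != .trr_magic) stop("bad TRR magic in ", path, call. = FALSE)
    sl <- rint(2L)
    readBin(con, "raw", n = sl[2])   # version string bytes
    h <- rint(13L)
    names(h) <- c("ir", "e", "box", "vir", "pres", "top", "sym",
                  "x", "v", "f", "natoms", "step", "nre")
    natoms <- as.integer(h[["natoms"]])
    prec <- if (h[["x"]] > 0) h[["x"]] / (3L * natoms) else h[["box"]] / 9L
    if (!prec %in% c(4, 8)) stop("cannot infer TRR precision in ", path, call. = FALSE)
    rreal <- function(k) readBin(con, "double", n = k, size = prec, endian = "big")
    tl <- rreal(2L)
    skip <- function(sz) if (sz > 0) readBin(con, "raw", n = sz)
    box <- NULL
    if (h["box"] > 0) {
      bm <- matrix(rreal(9L), 3L, 3L, byrow = TRUE)
      if (any(abs(bm[upper.tri(bm) | lower.tri(bm)]) > 1e-9)) {
        stop("triclinic box in TRR ", path, ": only orthorhombic cells supported",
             call. = FALSE)
      }
      box <- diag(bm)
    }
    skip(h["vir"]); skip(h["pres"])
    if (h["x"] == 0) stop("TRR frame without positions in ", path, call. = FALSE)
    xyz <- matrix(rreal(3L * natoms), ncol = 3L, byrow = TRUE)
    skip(h["v"]); skip(h["f"])
    frames[[length(frames) + 1L]] <- list(t = tl[1], box = box, xyz = xyz, n = natoms)
  }
  if (!length(frames)) stop("TRR file has zero frames: ", path, call. = FALSE)
  n <- frames[[1]]$n
  if (any(vapply(frames, `[[`, 0L, "n") != n)) {
    stop("TRR frames differ in atom count: ", path, call. = FALSE)
  }
  coords <- array(NA_real_, c(n, 3L, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]$xyz
  list(coords = coords,
       times_ps = vapply(frames, `[[`, 0, "t"),
       boxes = t(vapply(frames, `[[`, numeric(3), "box")),
       natoms = as.integer(n))
}

# ---- dispatcher ----------------------------------------------------------

#' Read a trajectory from a coordinate file plus a trajectory file
#'
#' Bead identity (molecule ids/names, bead names) is taken from the GRO
#' coordinate file; per-frame positions, times and boxes from the trajectory
#' file (`.trr` or the plain-text `.cgtraj`/`.traj` dialect). With
#' `traj_path = NULL` the GRO file alone yields a valid single-frame
#' trajectory. XTC is not supported; convert to TRR first
#' (e.g. `gmx trjconv -f run.xtc -o run.trr`).
#'
#' @param coords_path path to a `.gro` file.
#' @param traj_path path to a `.trr` or text-dialect trajectory, or `NULL`.
#' @param topology optional [cg_topology]; when given, origins are attached
#'   and residue-name coverage is checked.
#' @return a [cg_trajectory].
#' @export
read_trajectory <- function(coords_path, traj_path = NULL, topology = NULL) {
  frame0 <- read_gro(coords_path)
  n <- nrow(frame0$atoms)
  if (is.null(traj_path)) {
    traj <- cg_trajectory(frame0$atoms, array(frame0$xyz, c(n, 3L, 1L)),
                          frame0$time_ps, frame0$box)
  } else {
    ext <- tolower(tools::file_ext(traj_path))
    if (ext == "xtc") {
      stop("XTC trajectories are not supported; convert to TRR ",
           "(gmx trjconv -f run.xtc -o run.trr) or use the text dialect",
           call. = FALSE)
    }
    raw <- if (ext == "trr") read_trr(traj_path) else {
      tr <- read_cgtraj(traj_path)
      list(coords = tr$coords, times_ps = tr$times_ps, boxes = tr$boxes,
           natoms = nrow(tr$atoms))
    }
    if (raw$natoms != n) {
      stop("bead count mismatch: coordinate file has ", n,
           " beads but trajectory has ", raw$natoms, call. = FALSE)
    }
    traj <- cg_trajectory(frame0$atoms, raw$coords, raw$times_ps, raw$boxes)
  }
  if (!is.null(topology)) traj <- with_origins(traj, topology)
  traj
}

#' Write a trajectory to file (TRR or text dialect, chosen by extension)
#'
#' @param traj a [cg_trajectory].
#' @param path output path ending in `.trr` or a text-dialect extension.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (tolower(tools::file_ext(path)) == "trr") write_trr(traj, path)
  else write_cgtraj(traj, path)
}
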