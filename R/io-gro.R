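#' Read a GRO coordinate file
#'
#' Parses the fixed-column GRO layout (positions in nm, three decimals) into
#' a single [cg_frame]. Velocities, if present, are ignored. Only
#' orthorhombic boxes are supported; a box line with non-zero off-diagonal
#' components is rejected.
#'
#' Molecule identity is the (residue number, residue name) pair; because the
#' GRO residue field wraps at five digits, residues are re-indexed
#' monotonically so molecule ids are unique even in large systems.
#'
#' @param path path to a `.gro` file.
#' @return a [cg_frame] (without origins; see [with_origins()]).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("GRO file too short: ", path, call. = FALSE)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || natoms < 1L) {
    stop("GRO parse error at line 2: invalid atom count '", trimws(lines[2]), "'",
         call. = FALSE)
  }
  if (length(lines) < 2L + natoms + 1L) {
    stop("GRO file ", path, " missing box line: expected ", 2L + natoms + 1L,
         " lines, found ", length(lines), call. = FALSE)
  }
  al <- lines[3:(2L + natoms)]
  bad <- which(nchar(al) < 44L)
  if (length(bad)) {
    stop("GRO parse error at line ", 2L + bad[1],
         ": atom line shorter than fixed-column layout", call. = FALSE)
  }
  num <- function(s, from, to, what) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    if (anyNA(v)) {
      stop("GRO parse error at line ", 2L + which(is.na(v))[1], ": bad ", what,
           " field", call. = FALSE)
    }
    v
  }
  resid <- as.integer(num(al, 1, 5, "residue number"))
  resname <- trimws(substr(al, 6, 10))
  beadname <- trimws(substr(al, 11, 15))
  x <- num(al, 21, 28, "x coordinate")
  y <- num(al, 29, 36, "y coordinate")
  z <- num(al, 37, 44, "z coordinate")
  # monotone re-indexing across the 5-digit residue-number wrap
  newmol <- c(TRUE, resid[-1] != resid[-natoms] | resname[-1] != resname[-natoms])
  molecule_id <- cumsum(newmol)
  boxvals <- suppressWarnings(as.numeric(strsplit(trimws(lines[2L + natoms + 1L]),
                                                  "\\s+")[[1]]))
  if (length(boxvals) < 3L || anyNA(boxvals)) {
    stop("GRO parse error: malformed box line in ", path, call. = FALSE)
  }
  if (length(boxvals) > 3L && any(abs(boxvals[-(1:3)]) > 1e-9)) {
    stop("triclinic box in ", path, ": only orthorhombic cells are supported",
         call. = FALSE)
  }
  atoms <- data.frame(molecule_id = molecule_id, molecule_name = resname,
                      bead_name = beadname, stringsAsFactors = FALSE)
  cg_frame(atoms, cbind(x, y, z), boxvals[1:3], time_ps = 0)
}

#' Write a frame to a GRO coordinate file
#'
#' Positions are written at GRO precision (three decimals, nm). Residue and
#' atom numbers wrap at the five-digit field width as the format requires.
#'
#' @param frame a [cg_frame].
#' @param path output path.
#' @param title title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path, title = "written by lndfusion") {
  a <- frame$atoms
  n <- nrow(a)
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   a$molecule_id %% 100000L, substr(a$molecule_name, 1, 5),
                   substr(a$bead_name, 1, 5), seq_len(n) %% 100000L,
                   frame$xyz[, 1], frame$xyz[, 2], frame$xyz[, 3])
  writeLines(c(title, sprintf("%5d", n), lines,
               sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3])),
             path)
  invisible(path)
}
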