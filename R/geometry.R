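#' Periodic-box geometry primitives
#'
#' All coordinates in this package are in nanometres and all boxes are
#' orthorhombic (rectangular). Triclinic cells are rejected at read time.
#'
#' @name geometry
#' @keywords internal
NULL

#' Validate an orthorhombic box
#'
#' @param box numeric length-3 vector of box edge lengths (nm).
#' @return the box, invisibly, after validation.
#' @keywords internal
check_box <- function(box) {
  if (!is.numeric(box) || length(box) != 3L || anyNA(box)) {
    stop("box must be a numeric length-3 vector of edge lengths (nm)", call. = FALSE)
  }
  if (any(box <= 0)) {
    stop("box edge lengths must all be > 0, got: ", paste(signif(box, 6), collapse = " "),
         call. = FALSE)
  }
  invisible(box)
}

#' Minimum-image displacement components
#'
#' Wraps per-dimension differences into (-L/2, L/2].
#'
#' @param d numeric vector/matrix of raw coordinate differences (nm).
#' @param len box edge length(s) matching `d` (recycled).
#' @return wrapped differences.
#' @keywords internal
min_image_delta <- function(d, len) {
  d - len * round(d / len)
}

#' Minimum-image distance between two points
#'
#' Euclidean distance under the minimum-image convention in all three
#' dimensions of an orthorhombic periodic cell.
#'
#' @param a,b numeric length-3 positions (nm).
#' @param box numeric length-3 box edge lengths (nm).
#' @return distance in nm.
#' @examples
#' min_image_distance(c(0, 0, 0), c(10, 0, 0), c(10, 10, 10))  # 0
#' @export
min_image_distance <- function(a, b, box) {
  check_box(box)
  d <- min_image_delta(as.numeric(a) - as.numeric(b), box)
  sqrt(sum(d * d))
}

#' Pairwise minimum-image distance matrix between two point sets
#'
#' @param x,y numeric matrices (n x 3 and m x 3) of positions (nm).
#' @param box numeric length-3 box (nm).
#' @param squared return squared distances (skips the sqrt).
#' @return n x m matrix of (squared) distances.
#' @keywords internal
pair_distance_matrix <- function(x, y, box, squared = FALSE) {
  check_box(box)
  n <- nrow(x)
  m <- nrow(y)
  d2 <- matrix(0, n, m)
  for (k in 1:3) {
    dk <- min_image_delta(outer(x[, k], y[, k], "-"), box[k])
    d2 <- d2 + dk * dk
  }
  if (squared) d2 else sqrt(d2)
}

#' Minimum distance from each row of `x` to the point set `y`
#' @keywords internal
min_dist_to_set <- function(x, y, box) {
  d2 <- pair_distance_matrix(x, y, box, squared = TRUE)
  sqrt(apply(d2, 1L, min))
}

#' Circular (wrap-aware) mean of coordinates along one periodic dimension
#'
#' @param z coordinates (nm) along the periodic dimension.
#' @param len box edge length (nm).
#' @return mean position in `[0, len)`.
#' @keywords internal
circular_mean <- function(z, len) {
  th <- 2 * pi * z / len
  m <- atan2(mean(sin(th)), mean(cos(th))) * len / (2 * pi)
  m %% len
}

#' Recenter a frame so a reference bead set sits at box-z/2
#'
#' Shifts all z coordinates so the wrap-aware centre of geometry of the
#' reference beads (typically the membrane PO4 beads) lies at half the box
#' height, then wraps every bead into `[0, Lz)`. After recentring, a bead's
#' z value is its minimum-image position relative to the membrane centre,
#' so absolute z comparisons (heights, leaflet sides) are meaningful even
#' when the raw trajectory wrapped the system across the periodic boundary.
#'
#' @param xyz n x 3 coordinate matrix (nm).
#' @param box length-3 box (nm).
#' @param ref_idx integer indices of the reference beads.
#' @return recentred n x 3 coordinate matrix.
#' @export
recenter_z <- function(xyz, box, ref_idx) {
  check_box(box)
  if (length(ref_idx) == 0L) stop("recenter_z: empty reference bead set", call. = FALSE)
  lz <- box[3]
  zc <- circular_mean(xyz[ref_idx, 3], lz)
  xyz[, 3] <- (xyz[, 3] + (lz / 2 - zc)) %% lz
  xyz
}
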