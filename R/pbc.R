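#' Minimum-image displacement
#'
#' @param d displacements (any numeric array).
#' @param box_length periodic box length.
#' @return Displacements folded into `(-box_length/2, box_length/2]`.
#' @export
min_image <- function(d, box_length) {
  d - box_length * round(d / box_length)
}

#' Wrap coordinates into the periodic box
#'
#' @param x coordinates (vector or matrix with one column per dimension).
#' @param box box lengths (recycled across columns of a matrix).
#' @return Wrapped coordinates in `[0, box)`.
#' @export
wrap_coords <- function(x, box) {
  if (is.matrix(x)) {
    for (j in seq_len(ncol(x))) x[, j] <- x[, j] %% box[j]
    x
  } else {
    x %% box
  }
}

#' Center of mass under periodic boundary conditions
#'
#' One-dimensional periodic center of mass: each coordinate is mapped to an
#' angle on a circle of circumference `box_length`, the mass-weighted mean
#' angle gives a provisional center, and the exact center is the arithmetic
#' mean of the coordinates unwrapped (minimum image) about that provisional
#' value.  The result is invariant (mod box) under rigid translation of all
#' points, and reduces exactly to the arithmetic mean whenever the point
#' cloud spans less than half the box.
#'
#' @param x coordinates along one periodic dimension.
#' @param box_length the box length (> 0).
#' @param weights optional non-negative masses.
#' @return A scalar in `[0, box_length)`.
#' @export
pbc_center_of_mass <- function(x, box_length, weights = NULL) {
  if (length(x) == 0) stop("cannot take the center of mass of an empty set")
  stopifnot(box_length > 0)
  if (is.null(weights)) weights <- rep(1, length(x))
  stopifnot(length(weights) == length(x), all(weights >= 0),
            sum(weights) > 0)
  w <- weights / sum(weights)
  theta <- 2 * pi * x / box_length
  ang <- atan2(sum(w * sin(theta)), sum(w * cos(theta)))
  ref <- box_length * ang / (2 * pi)
  com <- ref + sum(w * min_image(x - ref, box_length))
  com %% box_length
}

#' Periodic center of mass of points in the xy plane
#'
#' @param xy two-column matrix of coordinates.
#' @param box length-2 (or longer) box vector.
#' @param weights optional masses.
#' @return Length-2 vector.
#' @keywords internal
pbc_com_xy <- function(xy, box, weights = NULL) {
  c(pbc_center_of_mass(xy[, 1], box[1], weights),
    pbc_center_of_mass(xy[, 2], box[2], weights))
}
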