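#' A single configuration of a (pseudo-)bilayer system
#'
#' Container for one coordinate frame with the atom annotations every
#' membrane collective variable needs: Cartesian coordinates in nm, an
#' orthorhombic box, per-atom role flags (polar heavy atom, phosphorus,
#' water oxygen) and lipid membership.
#'
#' @param coords numeric matrix, one row per atom, columns x, y, z (nm).
#' @param box length-3 vector of box lengths (nm), all > 0.
#' @param polar_heavy,phosphorus,water_oxygen logical per-atom role flags.
#' @param lipid_id integer per-atom lipid membership, `NA` for non-lipid
#'   atoms.  Every phosphorus atom must belong to exactly one lipid.
#' @param atom_name,res_name,res_id optional per-atom metadata (used by the
#'   GRO reader/writer).
#' @param time frame time in ps.
#' @return An object of class `bilayer_frame`.
#' @export
bilayer_frame <- function(coords, box, polar_heavy, phosphorus, water_oxygen,
                          lipid_id, atom_name = NULL, res_name = NULL,
                          res_id = NULL, time = 0) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)),
            length(box) == 3, all(box > 0),
            length(polar_heavy) == n, length(phosphorus) == n,
            length(water_oxygen) == n, length(lipid_id) == n)
  if (any(phosphorus & is.na(lipid_id)))
    stop("every phosphorus atom must belong to a lipid")
  lip <- lipid_id[phosphorus]
  if (anyDuplicated(lip))
    stop("each lipid must carry exactly one phosphorus atom")
  coords <- wrap_coords(coords, box)
  structure(
    list(coords = coords, box = as.numeric(box),
         polar_heavy = as.logical(polar_heavy),
         phosphorus = as.logical(phosphorus),
         water_oxygen = as.logical(water_oxygen),
         lipid_id = as.integer(lipid_id),
         atom_name = atom_name, res_name = res_name, res_id = res_id,
         time = time),
    class = "bilayer_frame")
}

#' @export
print.bilayer_frame <- function(x, ...) {
  cat("bilayer_frame: ", nrow(x$coords), " atoms, ",
      sum(!is.na(unique(x$lipid_id))), " lipids, box ",
      paste(signif(x$box, 4), collapse = " x "), " nm, t = ", x$time,
      " ps\n", sep = "")
  invisible(x)
}

#' Number of lipids in a frame
#' @param frame a [bilayer_frame()].
#' @return Integer count.
#' @export
n_lipids <- function(frame) {
  length(unique(frame$lipid_id[!is.na(frame$lipid_id)]))
}

#' Bilayer center of mass along z
#'
#' Periodic center of mass of all lipid atoms along the membrane normal.
#' Using the periodic form keeps the reference stable even when the bilayer
#' straddles the z boundary of the box.
#'
#' @param frame a [bilayer_frame()].
#' @return z coordinate in `[0, box_z)`.
#' @export
membrane_zcom <- function(frame) {
  sel <- !is.na(frame$lipid_id)
  if (!any(sel)) stop("frame contains no lipid atoms")
  pbc_center_of_mass(frame$coords[sel, 3], frame$box[3])
}

#' Phosphorus table of a frame
#'
#' One row per lipid: lipid id, phosphorus coordinates, and the z offset
#' from the membrane center of mass (minimum image).
#'
#' @param frame a [bilayer_frame()].
#' @param zcom optional precomputed [membrane_zcom()].
#' @return A data.frame ordered by lipid id.
#' @keywords internal
phosphorus_table <- function(frame, zcom = NULL) {
  if (is.null(zcom)) zcom <- membrane_zcom(frame)
  sel <- which(frame$phosphorus)
  df <- data.frame(lipid_id = frame$lipid_id[sel],
                   x = frame$coords[sel, 1], y = frame$coords[sel, 2],
                   z = frame$coords[sel, 3])
  df$dz <- min_image(df$z - zcom, frame$box[3])
  df[order(df$lipid_id), , drop = FALSE]
}
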