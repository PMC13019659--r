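#' Specification of a synthetic pseudo-bilayer frame
#'
#' Parametric description of a DMPC-like point-lipid bilayer used to
#' unit-test the membrane collective variables: two leaflets of lipids, each
#' lipid a phosphorus head site plus three collinear tail beads, waters as
#' single oxygen sites outside the hydrophobic slab, and optional structural
#' features (local thinning, a polar defect column spanning the membrane,
#' translocated lipids, coherent undulation).  Defaults target a 128-DMPC /
#' 5749-water system in a roughly 6 x 6 x 7 nm box with a ~3.4 nm
#' phosphate-phosphate thickness.
#'
#' @param n_lipids even total lipid count.
#' @param box length-3 box (nm).
#' @param thickness phosphate-phosphate distance of the flat bilayer (nm).
#' @param leaflet_split integer pair (upper, lower) lipid counts; defaults to
#'   a symmetric split shifted by `flipped_lipids`.
#' @param flipped_lipids number of lipids translocated from the upper to the
#'   lower leaflet.
#' @param waters number of water molecules (single oxygen sites).
#' @param thinning `NULL` or `list(center_xy=, depth=, radius=)`: lipids with
#'   head xy within `radius` of `center_xy` have their head pulled `depth` nm
#'   toward the midplane (both leaflets).
#' @param defect_column `NULL` or `list(center_xy=, n_polar_atoms_per_slice=,
#'   n_slices=, slice_thickness=)`: water oxygens placed at the slice centers
#'   of a membrane-spanning column (counts recycled across slices).
#' @param undulation_amplitude amplitude (nm) of a coherent
#'   `sin(2 pi x / Lx)` height modulation applied to both leaflets.
#' @param xy_jitter,z_jitter standard deviations (nm) of positional noise.
#' @param rng_seed integer seed; all randomness in the generator flows
#'   through one generator seeded with it.
#' @return An object of class `bilayer_spec`.
#' @export
bilayer_spec <- function(n_lipids = 128, box = c(6.2, 6.2, 7.0),
                         thickness = 3.4, leaflet_split = NULL,
                         flipped_lipids = 0, waters = 5749, thinning = NULL,
                         defect_column = NULL, undulation_amplitude = 0,
                         xy_jitter = 0.04, z_jitter = 0.04, rng_seed = 1) {
  stopifnot(n_lipids >= 4, n_lipids %% 2 == 0, length(box) == 3,
            all(box > 0), thickness > 0, flipped_lipids >= 0, waters >= 0)
  if (thickness >= box[3])
    stop("box z length must exceed the bilayer thickness")
  if (is.null(leaflet_split))
    leaflet_split <- c(n_lipids / 2 - flipped_lipids,
                       n_lipids / 2 + flipped_lipids)
  stopifnot(length(leaflet_split) == 2, all(leaflet_split >= 1))
  if (sum(leaflet_split) != n_lipids)
    stop("leaflet_split must sum to n_lipids")
  if (leaflet_split[1] != n_lipids / 2 - flipped_lipids)
    stop("leaflet_split inconsistent with flipped_lipids: expected (",
         n_lipids / 2 - flipped_lipids, ", ", n_lipids / 2 + flipped_lipids,
         ")")
  if (!is.null(thinning)) {
    stopifnot(is.list(thinning),
              all(c("center_xy", "depth", "radius") %in% names(thinning)))
    if (thinning$radius > min(box[1:2]) / 2)
      stop("thinning radius exceeds half the box; infeasible specification")
    if (thinning$depth < 0 || thinning$depth > thickness / 2)
      stop("thinning depth must lie in [0, thickness/2]")
  }
  if (!is.null(defect_column)) {
    stopifnot(is.list(defect_column),
              "n_polar_atoms_per_slice" %in% names(defect_column))
    if (is.null(defect_column$center_xy))
      defect_column$center_xy <- box[1:2] / 2
    if (is.null(defect_column$n_slices)) defect_column$n_slices <- 26L
    if (is.null(defect_column$slice_thickness))
      defect_column$slice_thickness <- 0.1
    if (defect_column$n_slices * defect_column$slice_thickness > box[3])
      stop("defect column longer than the box; infeasible specification")
  }
  structure(
    list(n_lipids = n_lipids, box = as.numeric(box), thickness = thickness,
         leaflet_split = as.integer(leaflet_split),
         flipped_lipids = as.integer(flipped_lipids),
         waters = as.integer(waters), thinning = thinning,
         defect_column = defect_column,
         undulation_amplitude = undulation_amplitude,
         xy_jitter = xy_jitter, z_jitter = z_jitter,
         rng_seed = as.integer(rng_seed)),
    class = "bilayer_spec")
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# grid positions for one leaflet, jittered, wrapped
leaflet_xy <- function(n, box, jitter) {
  nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  gx <- (seq_len(nx) - 0.5) * box[1] / nx
  gy <- (seq_len(ny) - 0.5) * box[2] / ny
  g <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  g$x <- (g$x + stats::rnorm(n, sd = jitter)) %% box[1]
  g$y <- (g$y + stats::rnorm(n, sd = jitter)) %% box[2]
  as.matrix(g)
}

#' Generate a synthetic pseudo-bilayer frame
#'
#' Realises a [bilayer_spec()] as a [bilayer_frame()].  Each lipid carries
#' one phosphorus head site and three collinear tail beads pointing toward
#' the midplane; waters are single oxygen sites placed outside the
#' hydrophobic slab, except those requested inside the defect column.  Polar
#' heavy atoms are the phosphorus and water oxygen sites.  The requested
#' features are recorded in the `"ground_truth"` attribute (flipped lipid
#' ids, thinned lipid ids, column position) so tests can assert them from
#' raw coordinates without going through the CV code.
#'
#' @param spec a [bilayer_spec()].
#' @return A [bilayer_frame()] with attribute `ground_truth`.
#' @export
generate_bilayer_frame <- function(spec) {
  stopifnot(inherits(spec, "bilayer_spec"))
  with_local_seed(spec$rng_seed, {
    box <- spec$box
    zmid <- box[3] / 2
    half <- spec$thickness / 2
    n_up <- spec$leaflet_split[1]
    n_lo <- spec$leaflet_split[2]
    n_lip <- spec$n_lipids

    xy_up <- leaflet_xy(n_up, box, spec$xy_jitter)
    xy_lo <- leaflet_xy(n_lo, box, spec$xy_jitter)
    xy <- rbind(xy_up, xy_lo)
    side <- c(rep(1, n_up), rep(-1, n_lo))   # +1 upper leaflet
    headz <- zmid + side * half + stats::rnorm(n_lip, sd = spec$z_jitter)
    if (spec$undulation_amplitude != 0)
      headz <- headz +
        spec$undulation_amplitude * sin(2 * pi * xy[, 1] / box[1])

    thinned <- integer(0)
    if (!is.null(spec$thinning)) {
      th <- spec$thinning
      dx <- min_image(xy[, 1] - th$center_xy[1], box[1])
      dy <- min_image(xy[, 2] - th$center_xy[2], box[2])
      thinned <- which(sqrt(dx^2 + dy^2) <= th$radius)
      headz[thinned] <- headz[thinned] - side[thinned] * th$depth
    }

    # lipid atoms: head P then three tail beads toward the midplane
    tail_step <- 0.35
    coords <- vector("list", n_lip)
    for (i in seq_len(n_lip)) {
      tz <- headz[i] - side[i] * tail_step * (1:3)
      coords[[i]] <- cbind(rep(xy[i, 1], 4), rep(xy[i, 2], 4),
                           c(headz[i], tz))
    }
    lip_coords <- do.call(rbind, coords)
    n_lip_atoms <- nrow(lip_coords)
    lipid_id <- rep(seq_len(n_lip), each = 4)
    phosphorus <- rep(c(TRUE, FALSE, FALSE, FALSE), n_lip)
    atom_name <- rep(c("P", "C1", "C2", "C3"), n_lip)

    # bulk waters: uniform xy, z outside the slab (with a 0.25 nm margin)
    wat_coords <- NULL
    if (spec$waters > 0) {
      margin <- 0.25
      z_top <- zmid + half + margin
      z_bot <- zmid - half - margin
      room <- box[3] - (z_top - z_bot)
      if (room <= 0) stop("no room for water outside the hydrophobic slab")
      u <- stats::runif(spec$waters, 0, room)
      wz <- (z_top + u) %% box[3]
      wat_coords <- cbind(stats::runif(spec$waters, 0, box[1]),
                          stats::runif(spec$waters, 0, box[2]), wz)
    }

    # defect column: water oxygens at cylinder slice centers
    col_coords <- NULL
    if (!is.null(spec$defect_column)) {
      dc <- spec$defect_column
      ns <- dc$n_slices
      counts <- rep_len(dc$n_polar_atoms_per_slice, ns)
      zs <- zmid + (seq_len(ns) - (ns + 1) / 2) * dc$slice_thickness
      rows <- vector("list", ns)
      for (k in seq_len(ns)) {
        if (counts[k] == 0) next
        ang <- stats::runif(counts[k], 0, 2 * pi)
        rad <- stats::runif(counts[k], 0, 0.05)
        rows[[k]] <- cbind(dc$center_xy[1] + rad * cos(ang),
                           dc$center_xy[2] + rad * sin(ang),
                           rep(zs[k], counts[k]))
      }
      col_coords <- do.call(rbind, rows)
    }

    wat_all <- rbind(wat_coords, col_coords)
    n_wat <- if (is.null(wat_all)) 0L else nrow(wat_all)
    coords_all <- rbind(lip_coords, wat_all)
    frame <- bilayer_frame(
      coords = coords_all, box = box,
      polar_heavy = c(phosphorus, rep(TRUE, n_wat)),
      phosphorus = c(phosphorus, rep(FALSE, n_wat)),
      water_oxygen = c(rep(FALSE, n_lip_atoms), rep(TRUE, n_wat)),
      lipid_id = c(lipid_id, rep(NA_integer_, n_wat)),
      atom_name = c(atom_name, rep("OW", n_wat)),
      res_name = c(rep("DMPC", n_lip_atoms), rep("SOL", n_wat)),
      res_id = c(lipid_id, if (n_wat) n_lip + seq_len(n_wat) else integer(0)))
    flipped <- if (spec$flipped_lipids > 0)
      n_up + n_lo - seq_len(spec$flipped_lipids) + 1L else integer(0)
    attr(frame, "ground_truth") <- list(
      leaflet = side, thinned_lipids = thinned,
      flipped_lipids = as.integer(flipped),
      column_xy = if (!is.null(spec$defect_column))
        spec$defect_column$center_xy else NULL,
      zmid = zmid, head_z = headz)
    frame
  })
}
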