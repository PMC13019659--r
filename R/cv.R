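#' Membrane-spanning cylinder specification
#'
#' Geometry and fill conventions of the chain-coordinate cylinder: a
#' vertical cylinder of given radius divided into z slices centred on the
#' membrane midplane.  Defaults match the standard DMPC parameterisation
#' (radius 0.8 nm, 26 slices of 0.1 nm, so a 2.6 nm extent); the POPC preset
#' uses 30 slices.  A slice holding a single polar heavy atom counts as
#' fractionally occupied (`partial_fill`, default 0.75) and a slice holding
#' two or more atoms as completely filled (exactly 1 by this package's
#' convention).  `xi_p_radius` is the wider radius of the pore-expansion
#' region used by [xi_p()].
#'
#' @param radius cylinder radius (nm).
#' @param n_slices number of z slices.
#' @param slice_thickness slice thickness (nm).
#' @param partial_fill occupancy value of a single-atom slice, in (0, 1].
#' @param xi_p_radius radius (nm) of the expansion region; default 1.5x the
#'   cylinder radius.
#' @param preset `"dmpc"` (default) or `"popc"` (30 slices).
#' @return An object of class `cylinder_spec`.
#' @export
cylinder_spec <- function(radius = 0.8, n_slices = 26, slice_thickness = 0.1,
                          partial_fill = 0.75, xi_p_radius = 1.5 * radius,
                          preset = c("dmpc", "popc")) {
  preset <- match.arg(preset)
  if (preset == "popc" && missing(n_slices)) n_slices <- 30L
  stopifnot(radius > 0, n_slices >= 1, slice_thickness > 0,
            partial_fill > 0, partial_fill <= 1, xi_p_radius >= radius)
  structure(
    list(radius = radius, n_slices = as.integer(n_slices),
         slice_thickness = slice_thickness,
         z_extent = n_slices * slice_thickness,
         partial_fill = partial_fill, xi_p_radius = xi_p_radius),
    class = "cylinder_spec")
}

# polar heavy atoms within the cylinder z extent; returns index, xy, dz
slab_polar_atoms <- function(frame, spec, zcom) {
  sel <- which(frame$polar_heavy)
  dz <- min_image(frame$coords[sel, 3] - zcom, frame$box[3])
  keep <- abs(dz) <= spec$z_extent / 2
  list(idx = sel[keep],
       xy = frame$coords[sel[keep], 1:2, drop = FALSE],
       dz = dz[keep])
}

# slice index (1..n_slices) of z offsets relative to the membrane midplane
slice_index <- function(dz, spec) {
  k <- floor((dz + spec$z_extent / 2) / spec$slice_thickness) + 1
  pmin(pmax(k, 1L), spec$n_slices)
}

# xy distances (minimum image) from a center
xy_dist <- function(xy, center, box) {
  dx <- min_image(xy[, 1] - center[1], box[1])
  dy <- min_image(xy[, 2] - center[2], box[2])
  sqrt(dx^2 + dy^2)
}

slice_counts <- function(slab, center, frame, spec) {
  d <- xy_dist(slab$xy, center, frame$box)
  inside <- d <= spec$radius
  counts <- integer(spec$n_slices)
  if (any(inside)) {
    tab <- table(slice_index(slab$dz[inside], spec))
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  counts
}

xi_ch_from_counts <- function(counts, spec) {
  fill <- ifelse(counts == 0, 0, ifelse(counts == 1, spec$partial_fill, 1))
  mean(fill)
}

#' Self-consistent xy localisation of the chain-coordinate cylinder
#'
#' Finds the fixed point of the cylinder placement rule: polar heavy atoms
#' inside the current cylinder are grouped into z slices, each nonempty
#' slice's periodic xy center of mass is computed, and the new cylinder
#' center is the unweighted average (again periodic) of those slice
#' centers.  Iteration starts from `init` when given (use the previous
#' frame's center along a path for continuity), otherwise from the xy
#' center of mass of the most central polar atoms.  Convergence is declared
#' below 0.01 nm displacement; if the fixed-point iteration still cycles
#' after `max_iter` sweeps the iterate with the largest chain coordinate is
#' returned with `converged = FALSE`.
#'
#' When several separated defect columns coexist the fixed point is not
#' unique and the converged center depends on the initial guess.
#'
#' @param frame a [bilayer_frame()].
#' @param spec a [cylinder_spec()].
#' @param init optional initial xy center.
#' @param tol convergence displacement (nm).
#' @param max_iter iteration cap.
#' @return List with `center` (xy), `converged`, `n_iter`.
#' @export
locate_cylinder <- function(frame, spec = cylinder_spec(), init = NULL,
                            tol = 0.01, max_iter = 50) {
  zcom <- membrane_zcom(frame)
  slab <- slab_polar_atoms(frame, spec, zcom)
  if (length(slab$idx) == 0)
    stop("no polar heavy atoms within the cylinder z extent")
  if (is.null(init)) {
    central <- abs(slab$dz) <= spec$z_extent / 4
    if (!any(central)) central <- rep(TRUE, length(slab$dz))
    init <- pbc_com_xy(slab$xy[central, , drop = FALSE], frame$box)
  }
  center <- init
  centers <- matrix(NA_real_, max_iter, 2)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    d <- xy_dist(slab$xy, center, frame$box)
    inside <- d <= spec$radius
    if (!any(inside)) {
      # empty cylinder: recenter on the nearest polar atom and continue
      j <- which.min(d)
      newc <- slab$xy[j, ]
    } else {
      ks <- slice_index(slab$dz[inside], spec)
      xy_in <- slab$xy[inside, , drop = FALSE]
      uk <- sort(unique(ks))
      layer_centers <- t(vapply(uk, function(k)
        pbc_com_xy(xy_in[ks == k, , drop = FALSE], frame$box),
        numeric(2)))
      newc <- pbc_com_xy(layer_centers, frame$box)
    }
    centers[it, ] <- newc
    disp <- sqrt(sum(min_image(newc - center, frame$box[1:2])^2))
    center <- newc
    if (disp < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    # oscillating fixed point: keep the candidate with the largest xi_ch
    vals <- apply(centers[seq_len(it), , drop = FALSE], 1, function(cc)
      xi_ch_from_counts(slice_counts(slab, cc, frame, spec), spec))
    center <- centers[which.max(vals), ]
    warning("cylinder placement did not converge; returning best candidate")
  }
  list(center = as.numeric(center), converged = converged, n_iter = it)
}

as_center <- function(center) {
  if (is.null(center)) return(NULL)
  if (is.list(center)) center$center else as.numeric(center)
}

#' Chain coordinate
#'
#' Fraction of occupied slices of the membrane-spanning cylinder, counting
#' polar heavy atoms (water oxygens and lipid phosphate sites): an empty
#' slice contributes 0, a single-atom slice `partial_fill` (default 0.75)
#' and a slice with two or more atoms 1.  A value of 0.75 therefore means
#' exactly one atom in every slice, and values above 0.75 a continuous
#' polar defect.
#'
#' @param frame a [bilayer_frame()].
#' @param spec a [cylinder_spec()].
#' @param center cylinder xy center (vector, or result of
#'   [locate_cylinder()]); located automatically when `NULL`.
#' @return Value in `[0, 1]`.
#' @export
xi_ch <- function(frame, spec = cylinder_spec(), center = NULL) {
  if (is.null(center)) center <- locate_cylinder(frame, spec)
  center <- as_center(center)
  zcom <- membrane_zcom(frame)
  slab <- slab_polar_atoms(frame, spec, zcom)
  if (length(slab$idx) == 0) return(0)
  xi_ch_from_counts(slice_counts(slab, center, frame, spec), spec)
}

#' Pore-expansion coordinate
#'
#' Extends the chain coordinate beyond 1 once a continuous polar defect has
#' formed.  While any slice of the cylinder is empty, `xi_p` equals
#' [xi_ch()].  Once every slice is occupied the coordinate becomes
#' \deqn{\xi_p = \max\{\xi_{ch},\; 1 + (N - N_{ref}) / N_{ref}\},}
#' where `N` counts the polar heavy atoms within the wider expansion radius
#' (`xi_p_radius`) of the cylinder z extent, and the reference count
#' `N_ref = 2 n_slices` is the occupancy at which every slice is completely
#' filled.  A nascent continuous defect thus sits near 1 and a widening
#' pore grows without bound as polar atoms accumulate.
#'
#' @inheritParams xi_ch
#' @return Non-negative value; > 1 indicates pore expansion.
#' @export
xi_p <- function(frame, spec = cylinder_spec(), center = NULL) {
  if (is.null(center)) center <- locate_cylinder(frame, spec)
  center <- as_center(center)
  zcom <- membrane_zcom(frame)
  slab <- slab_polar_atoms(frame, spec, zcom)
  if (length(slab$idx) == 0) return(0)
  counts <- slice_counts(slab, center, frame, spec)
  xch <- xi_ch_from_counts(counts, spec)
  if (any(counts == 0)) return(xch)
  d <- xy_dist(slab$xy, center, frame$box)
  n_ext <- sum(d <= spec$xi_p_radius)
  n_ref <- 2 * spec$n_slices
  max(xch, 1 + (n_ext - n_ref) / n_ref)
}

#' Local leaflet proximity
#'
#' Mean phosphate z separation of the two leaflets among the `n_llp` lipids
#' whose heads are laterally closest (minimum image) to the cylinder
#' center: lipids are split into upper and lower sets by their z offset
#' from the membrane center of mass, and the difference of the set means is
#' returned.  If the nearest selection leaves one set empty, the selection
#' is extended by the next-nearest lipids until both sets are populated.
#' Small values flag local thinning around the (incipient) defect.
#'
#' @param frame a [bilayer_frame()].
#' @param center cylinder xy center.
#' @param n_llp number of nearest lipids considered (default 12).
#' @return Separation in nm.
#' @export
d_llp <- function(frame, center, n_llp = 12) {
  stopifnot(n_llp >= 2)
  center <- as_center(center)
  pt <- phosphorus_table(frame)
  if (nrow(pt) < 2) stop("d_llp requires at least two lipids")
  d <- xy_dist(as.matrix(pt[, c("x", "y")]), center, frame$box)
  ord <- order(d, pt$lipid_id)
  k <- min(n_llp, nrow(pt))
  repeat {
    sel <- ord[seq_len(k)]
    up <- pt$dz[sel] > 0
    if (any(up) && any(!up)) break
    if (k == nrow(pt))
      stop("all lipids fall on one side of the midplane")
    k <- k + 1
  }
  mean(pt$dz[sel][up]) - mean(pt$dz[sel][!up])
}

# shared machinery for the translocation pair distances
split_leaflet_sets <- function(frame) {
  pt <- phosphorus_table(frame)
  n <- nrow(pt)
  if (n < 4) stop("translocation distances require at least 4 lipids")
  if (n %% 2 != 0)
    stop("translocation distances are defined for even lipid counts")
  ord <- order(-pt$dz, pt$lipid_id)
  upper <- pt[ord[seq_len(n / 2)], , drop = FALSE]
  lower <- pt[ord[(n / 2 + 1):n], , drop = FALSE]
  list(upper = upper, lower = lower)
}

pair_matrix <- function(upper, lower, box, metric) {
  dx <- outer(upper$x, lower$x, function(a, b) min_image(a - b, box[1]))
  dy <- outer(upper$y, lower$y, function(a, b) min_image(a - b, box[2]))
  dzm <- outer(upper$z, lower$z, function(a, b) min_image(a - b, box[3]))
  if (metric == "euclidean") sqrt(dx^2 + dy^2 + dzm^2) else abs(dzm)
}

min_pair <- function(m, upper, lower) {
  # lowest value; ties broken by lowest upper then lower lipid index
  idx <- which(m == min(m), arr.ind = TRUE)
  if (nrow(idx) > 1) {
    key <- order(upper$lipid_id[idx[, 1]], lower$lipid_id[idx[, 2]])
    idx <- idx[key[1], , drop = FALSE]
  }
  c(idx[1, 1], idx[1, 2])
}

trans_pair_distances <- function(frame, metric) {
  s <- split_leaflet_sets(frame)
  m <- pair_matrix(s$upper, s$lower, frame$box, metric)
  p1 <- min_pair(m, s$upper, s$lower)
  d1 <- s$upper$dz[p1[1]] - s$lower$dz[p1[2]]
  u2 <- s$upper[-p1[1], , drop = FALSE]
  l2 <- s$lower[-p1[2], , drop = FALSE]
  if (nrow(u2) == 0 || nrow(l2) == 0) return(c(d1, NA_real_))
  m2 <- pair_matrix(u2, l2, frame$box, metric)
  p2 <- min_pair(m2, u2, l2)
  d2 <- u2$dz[p2[1]] - l2$dz[p2[2]]
  c(d1, d2)
}

#' Lipid translocation distances d1, d2
#'
#' Lipids are z-sorted into an upper and a lower half by their phosphorus
#' position; `d1` is the z separation of the cross-set pair with the
#' smallest three-dimensional (minimum image) distance, and `d2` repeats
#' the search excluding the `d1` pair.  Both are non-negative by the
#' z-sorted split.  `d1` close to the membrane thickness signals an intact
#' symmetric bilayer; `d1 ~ 0` a lipid at the midplane or a completed
#' translocation, and `d1 + d2` distinguishes 0, 1, 2 translocated lipids.
#'
#' @param frame a [bilayer_frame()] with an even number of lipids.
#' @return Named numeric vector `c(d1 =, d2 =)` (nm).
#' @export
d1_d2 <- function(frame) {
  v <- trans_pair_distances(frame, "euclidean")
  c(d1 = v[1], d2 = v[2])
}

#' z-only variants d1*, d2*
#'
#' Identical to [d1_d2()] except that pairs are selected by minimal
#' separation along z alone.  These variants can decrease spuriously during
#' coherent membrane undulations (tilted leaflets bring laterally distant
#' lipids close in z), which is why the Euclidean forms are preferred for
#' new work; both are provided because existing sampling setups use the
#' starred forms in their order parameter.
#'
#' @inheritParams d1_d2
#' @return Named numeric vector `c(d1_star =, d2_star =)` (nm).
#' @export
d1_d2_star <- function(frame) {
  v <- trans_pair_distances(frame, "z")
  c(d1_star = v[1], d2_star = v[2])
}

#' Leaflet count imbalance
#'
#' Absolute difference between half the lipid count and the number of
#' lipids whose phosphorus sits above the bilayer center of mass:
#' `d_CNT = 0, 1, 2` for -0/+0, -1/+1, -2/+2 leaflet imbalances.
#'
#' @param frame a [bilayer_frame()] with an even number of lipids.
#' @return Non-negative integer.
#' @export
d_cnt <- function(frame) {
  pt <- phosphorus_table(frame)
  n <- nrow(pt)
  if (n %% 2 != 0) stop("d_cnt is defined for even lipid counts")
  as.integer(abs(n / 2 - sum(pt$dz > 0)))
}

#' All membrane collective variables of one frame
#'
#' Computes the full CV record: chain coordinate, pore expansion, local
#' leaflet proximity, translocation distances (Euclidean and z-only),
#' leaflet count imbalance and the located cylinder center.
#'
#' @param frame a [bilayer_frame()].
#' @param spec a [cylinder_spec()].
#' @param n_llp nearest-lipid count for [d_llp()].
#' @param center optional initial cylinder center (e.g. the previous
#'   frame's, for continuity along a path).
#' @return A one-row data.frame (class `cv_record`).
#' @export
compute_cvs <- function(frame, spec = cylinder_spec(), n_llp = 12,
                        center = NULL) {
  fit <- locate_cylinder(frame, spec, init = as_center(center))
  d12 <- d1_d2(frame)
  d12s <- d1_d2_star(frame)
  rec <- data.frame(
    frame_time = frame$time,
    xi_ch = xi_ch(frame, spec, fit),
    xi_p = xi_p(frame, spec, fit),
    d_llp = d_llp(frame, fit, n_llp),
    d1 = unname(d12[1]), d2 = unname(d12[2]),
    d1_star = unname(d12s[1]), d2_star = unname(d12s[2]),
    d_cnt = d_cnt(frame),
    cyl_x = fit$center[1], cyl_y = fit$center[2],
    converged = fit$converged)
  class(rec) <- c("cv_record", class(rec))
  rec
}

#' CV records for a sequence of frames
#'
#' Applies [compute_cvs()] to each frame, seeding each cylinder search from
#' the previous frame's center (path continuity).
#'
#' @param frames list of [bilayer_frame()] objects.
#' @inheritParams compute_cvs
#' @return A data.frame with one row per frame.
#' @export
cv_trajectory <- function(frames, spec = cylinder_spec(), n_llp = 12) {
  center <- NULL
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    out[[i]] <- compute_cvs(frames[[i]], spec, n_llp, center = center)
    center <- c(out[[i]]$cyl_x, out[[i]]$cyl_y)
  }
  do.call(rbind, out)
}

#' Conditional order parameter schemes
#'
#' Maps a CV record to the scalar order parameter lambda of a sampling
#' scheme: `"PF"` (pore formation with translocation bookkeeping) uses
#' `lambda = xi_p - (d1* + d2*)`; `"PC"` (pore closing) uses
#' `lambda = -xi_p`, so that progress toward the closed state increases
#' lambda; `"XI_CH"` uses the chain coordinate directly.
#'
#' @param cv_record one-row data.frame from [compute_cvs()] (or any list
#'   with the needed fields).
#' @param scheme one of `"PF"`, `"PC"`, `"XI_CH"`.
#' @return Scalar lambda.
#' @export
conditional_order_parameter <- function(cv_record, scheme) {
  if (!is.character(scheme) || length(scheme) != 1 ||
      !scheme %in% c("PF", "PC", "XI_CH"))
    stop("unknown order-parameter scheme: ",
         paste(format(scheme), collapse = ", "))
  switch(scheme,
         PF = cv_record$xi_p - (cv_record$d1_star + cv_record$d2_star),
         PC = -cv_record$xi_p,
         XI_CH = cv_record$xi_ch)
}
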