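# Kinetics and mechanism analysis of path archives.

weighted_mean <- function(x, w) sum(w * x) / sum(w)

# reconstruct the per-cycle series a set of records represents (each record
# repeated by its integer weight), for autocorrelation-aware errors
expand_series <- function(values, weights) {
  rep(values, times = pmax(1, round(weights)))
}

#' Per-ensemble local crossing probabilities
#'
#' For each `[i+]` ensemble, the weighted fraction of its archived paths
#' whose order-parameter maximum reaches the next interface.  Standard
#' errors come from block averaging of the cycle-expanded indicator series.
#'
#' @param archive `path_archive` from [run_sampler()].
#' @return data.frame with `ensemble`, `lambda_i`, `lambda_next`, `p`,
#'   `se`, `n_paths`, `total_weight`.
#' @export
local_crossing_probabilities <- function(archive) {
  tab <- archive_table(archive)
  lam <- archive$interfaces$lambdas
  n <- length(lam) - 1
  out <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("[%d+]", i - 1)
    rec <- tab[tab$ensemble == id, , drop = FALSE]
    if (nrow(rec) == 0)
      stop("archive holds no paths for ensemble ", id)
    lam_next <- if (i < n) lam[i + 1] else lam[n + 1]
    ind <- as.numeric(rec$lmax >= lam_next)
    p <- weighted_mean(ind, rec$weight)
    se <- tryCatch({
      s <- expand_series(ind, rec$weight)
      if (length(s) >= 16 && stats::sd(s) > 0)
        block_error(s)$se else NA_real_
    }, error = function(e) NA_real_)
    out[[i]] <- data.frame(ensemble = id, lambda_i = lam[i],
                           lambda_next = lam_next, p = p, se = se,
                           n_paths = nrow(rec),
                           total_weight = sum(rec$weight))
  }
  do.call(rbind, out)
}

#' Assemble the full crossing-probability curve
#'
#' Histogram matching of the per-ensemble distributions of path
#' order-parameter maxima: on the segment `[lambda_i, lambda_{i+1})` the
#' curve is the `[i+]` ensemble's weighted survival function of maxima,
#' scaled by the product of the preceding local probabilities.  The
#' telescoping identity `P(lambda_B | lambda_A) = prod_i p_i` holds
#' exactly at the interface positions.
#'
#' @param local data.frame from [local_crossing_probabilities()].
#' @param archive the corresponding `path_archive`.
#' @param n_grid number of grid points across `[lambda_A, lambda_B]`.
#' @return Object of class `crossing_curve`: data.frame `curve`
#'   (`lambda`, `p`), the `local` table and `p_total`.
#' @export
match_crossing_curve <- function(local, archive, n_grid = 200) {
  tab <- archive_table(archive)
  lam <- archive$interfaces$lambdas
  n <- length(lam) - 1
  grid <- seq(lam[1], lam[n + 1], length.out = n_grid)
  p_curve <- numeric(n_grid)
  prefix <- c(1, cumprod(local$p))
  for (g in seq_len(n_grid)) {
    x <- grid[g]
    i <- max(1, min(n, findInterval(x, lam, rightmost.closed = TRUE)))
    id <- sprintf("[%d+]", i - 1)
    rec <- tab[tab$ensemble == id, , drop = FALSE]
    surv <- weighted_mean(as.numeric(rec$lmax >= x), rec$weight)
    p_curve[g] <- prefix[i] * surv
  }
  p_curve <- cummin(pmax(p_curve, 0))   # enforce monotone non-increase
  structure(list(curve = data.frame(lambda = grid, p = p_curve),
                 local = local, p_total = prod(local$p)),
            class = "crossing_curve")
}

#' Initial flux out of state A
#'
#' `f_A = 1 / (<t>_[0-] + <t>_[0+])` with the weighted mean path durations
#' of the two lowest ensembles; the relative error combines block-averaged
#' errors of the two means.
#'
#' @param archive `path_archive` from [run_sampler()].
#' @return List with `flux`, `se`, `mean_t_minus`, `mean_t_plus`.
#' @export
initial_flux <- function(archive) {
  tab <- archive_table(archive)
  m <- tab[tab$ensemble == "[0-]", , drop = FALSE]
  p <- tab[tab$ensemble == "[0+]", , drop = FALSE]
  if (nrow(m) == 0) stop("archive holds no [0-] paths")
  if (nrow(p) == 0) stop("archive holds no [0+] paths")
  tm <- weighted_mean(m$duration, m$weight)
  tp <- weighted_mean(p$duration, p$weight)
  f <- 1 / (tm + tp)
  se_of <- function(rec) {
    tryCatch({
      s <- expand_series(rec$duration, rec$weight)
      if (length(s) >= 16 && stats::sd(s) > 0) block_error(s)$se
      else NA_real_
    }, error = function(e) NA_real_)
  }
  se_sum <- sqrt(sum(c(se_of(m), se_of(p))^2, na.rm = TRUE))
  list(flux = f, se = f^2 * se_sum, mean_t_minus = tm, mean_t_plus = tp)
}

#' Rate constant from flux and crossing probability
#'
#' The central identity `k_AB = f_A P_A(lambda_B | lambda_A)`; relative
#' errors propagate in quadrature.
#'
#' @param flux initial flux (per time unit).
#' @param crossing_probability total crossing probability.
#' @param flux_rel_err,p_rel_err optional relative errors.
#' @return List of class `rate_estimate` with `k_ab`, `flux`,
#'   `crossing_probability`, `rel_err`.
#' @export
rate_constant <- function(flux, crossing_probability, flux_rel_err = 0,
                          p_rel_err = 0) {
  stopifnot(flux >= 0, crossing_probability >= 0)
  structure(list(k_ab = flux * crossing_probability, flux = flux,
                 crossing_probability = crossing_probability,
                 rel_err = sqrt(flux_rel_err^2 + p_rel_err^2)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("rate_estimate: k_AB = ", signif(x$k_ab, 4), " = ",
      signif(x$flux, 4), " x ", signif(x$crossing_probability, 4),
      " (rel err ", signif(x$rel_err, 2), ")\n", sep = "")
  invisible(x)
}

#' End-to-end rate analysis of an archive
#'
#' Convenience wrapper: local probabilities, matched curve, flux and rate.
#'
#' @param archive `path_archive` from [run_sampler()].
#' @return List with `local`, `curve`, `flux`, `rate` (a `rate_estimate`).
#' @export
analyze_rate <- function(archive) {
  local <- local_crossing_probabilities(archive)
  curve <- match_crossing_curve(local, archive)
  fl <- initial_flux(archive)
  p_rel <- sqrt(sum((local$se / local$p)^2, na.rm = TRUE))
  rate <- rate_constant(fl$flux, curve$p_total,
                        flux_rel_err = fl$se / fl$flux, p_rel_err = p_rel)
  list(local = local, curve = curve, flux = fl, rate = rate)
}

#' Transmission coefficient by effective positive flux counting
#'
#' At a dividing surface `lambda = s`, every crossing with positive
#' momentum (the order parameter increases across the surface between
#' consecutive stored frames) enters the denominator with its path weight.
#' The numerator counts, once per path, the first positive crossing of
#' paths that arrive directly from the reactant basin and proceed to the
#' product state (status `AB`).  Paths from a product-originating archive
#' may be included via `backward_archive` with a relative
#' `backward_weight` (the rate ratio `k_AB / k_BA`); their contribution is
#' negligible whenever that ratio is small.
#'
#' @param archive `path_archive` whose records store full `lambdas`
#'   (run with `store_lambdas = TRUE`).
#' @param dividing_surface surface value on the order parameter.
#' @param backward_archive optional product-side archive.
#' @param backward_weight relative weight of backward paths.
#' @return List with `kappa`, `effective`, `total`.
#' @export
transmission_coefficient <- function(archive, dividing_surface,
                                     backward_archive = NULL,
                                     backward_weight = 0) {
  count_one <- function(recs, s, wfac) {
    eff <- 0
    tot <- 0
    for (rec in recs) {
      lam <- rec$lambdas
      if (is.null(lam))
        stop("records carry no lambda series; rerun with store_lambdas")
      nc <- sum(lam[-length(lam)] < s & lam[-1] >= s)
      if (nc == 0) next
      w <- rec$weight * wfac
      tot <- tot + w * nc
      if (rec$status == "AB") eff <- eff + w
    }
    c(eff, tot)
  }
  f <- count_one(archive$records, dividing_surface, 1)
  if (!is.null(backward_archive) && backward_weight > 0)
    f <- f + count_one(backward_archive$records, dividing_surface,
                       backward_weight)
  if (f[2] == 0)
    stop("no positive-momentum crossings of the dividing surface")
  list(kappa = f[1] / f[2], effective = f[1], total = f[2])
}

#' Transition-state-theory rate for the toy potential
#'
#' One-dimensional TST through a dividing surface at `x = s`:
#' `k_TST = sqrt(kT / 2 pi) exp(-V(s)/kT) / integral_A exp(-V(x)/kT) dx`,
#' with the configurational integral over the reactant side (`x < s`); the
#' harmonic y coordinate cancels.  TST ignores recrossings, so this is an
#' upper bound on the true rate: `k_AB = kappa k_TST` with `kappa <= 1`.
#'
#' @param potential a [toy_potential()].
#' @param temperature temperature (energy units).
#' @param surface dividing surface position (default the saddle, `x = 0`).
#' @return Rate in inverse time units.
#' @export
toy_tst_rate <- function(potential, temperature, surface = 0) {
  v <- function(x) {
    u <- (x / potential$a)^2 - 1
    potential$barrier_height * u^2
  }
  za <- stats::integrate(function(x) exp(-v(x) / temperature),
                         lower = -Inf, upper = surface)$value
  sqrt(temperature / (2 * pi)) * exp(-v(surface) / temperature) / za
}

#' Block-averaged relative error of a correlated series
#'
#' Flyvbjerg-Petersen style blocking: the series is cut into blocks of
#' doubling size, and the standard error of the block means is followed
#' until it plateaus (first block size whose error grows by less than 2%
#' upon doubling, requiring at least `min_blocks` blocks).  For an i.i.d.
#' series the plateau is the textbook `sd/sqrt(N)`; for autocorrelated
#' series the plateau absorbs the autocorrelation time.
#'
#' @param x numeric series, or a running estimate when `running = TRUE`
#'   (the raw contributions are recovered by first differences of
#'   `n * running_mean`).
#' @param running is `x` a running (cumulative) estimate?
#' @param min_blocks minimum number of blocks at the plateau.
#' @return List with `relative_error`, `se`, `mean`, `block_size` and the
#'   diagnostic `curve` (data.frame of block size vs SE).
#' @export
block_error <- function(x, running = FALSE, min_blocks = 8) {
  x <- as.numeric(x)
  if (running) {
    n <- seq_along(x)
    x <- c(x[1], diff(n * x))
  }
  n <- length(x)
  if (n < 2 * min_blocks)
    stop("series too short for block averaging (need >= ",
         2 * min_blocks, " points)")
  m <- mean(x)
  if (stats::sd(x) == 0)
    return(list(relative_error = 0, se = 0, mean = m, block_size = 1,
                curve = data.frame(block_size = 1, se = 0)))
  sizes <- 2^(0:floor(log2(n / min_blocks)))
  ses <- vapply(sizes, function(b) {
    nb <- floor(n / b)
    bm <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
    stats::sd(bm) / sqrt(nb)
  }, numeric(1))
  plateau <- length(sizes)
  for (k in seq_len(length(sizes) - 1)) {
    if (ses[k + 1] <= ses[k] * 1.02) {
      plateau <- k
      break
    }
  }
  se <- ses[plateau]
  list(relative_error = if (m != 0) se / abs(m) else Inf, se = se,
       mean = m, block_size = sizes[plateau],
       curve = data.frame(block_size = sizes, se = ses))
}

#' Project free energy and committor onto a collective variable
#'
#' Combines a product-directed (A-originating, "forward") archive and
#' optionally a reactant-directed ("backward": reversed order parameter)
#' archive into a one-dimensional free-energy and average-committor
#' profile.  Within each archive, per-ensemble frame histograms are
#' accumulated over their reliable regions (`[0-]` below `lambda_A`, each
#' `[i+]` at `lambda >= lambda_i`) and matched sequentially on overlapping
#' bins by multiplicative constants fitted on log densities; the two
#' archives are then matched by a single multiplicative constant on their
#' overlap and summed, giving `F = -kT log(density)` up to an additive
#' constant.  The committor per bin is the weighted fraction of
#' contributing frames whose path ends, in physical time, in the product
#' state: status `AB` for forward records; `AA`, `BA` or the `[0-]`
#' interior class for backward records (whose order parameter is
#' reversed).  Empty bins are flagged `NA`, never zero-filled.
#'
#' @param forward_archive `path_archive` run with `store_frames = TRUE`.
#' @param backward_archive optional reversed-direction archive.
#' @param cv function `(frames, record) -> values` mapping frames to the
#'   projection CV; default uses the archived order parameter.
#' @param backward_cv same for the backward archive; default negates its
#'   archived order parameter (the usual reversed-scheme convention).
#' @param breaks bin breaks on the CV.
#' @param kT thermal energy for the free-energy scale.
#' @return Object of class `projected_surface`: data.frame with `bin_mid`,
#'   `free_energy`, `committor`, `count_forward`, `count_backward`.
#' @export
project_surface <- function(forward_archive, backward_archive = NULL,
                            cv = NULL, backward_cv = NULL, breaks,
                            kT = 1) {
  nb <- length(breaks) - 1
  mids <- (breaks[-1] + breaks[-(nb + 1)]) / 2
  if (is.null(cv)) cv <- function(frames, rec) rec$lambdas
  if (is.null(backward_cv))
    backward_cv <- function(frames, rec) -rec$lambdas

  gather <- function(archive, cv_fun, reversed) {
    lamset <- archive$interfaces$lambdas
    n_int <- length(lamset) - 1
    ens_ids <- c("[0-]", sprintf("[%d+]", seq_len(n_int) - 1))
    h <- matrix(0, nb, length(ens_ids), dimnames = list(NULL, ens_ids))
    wtot <- numeric(length(ens_ids))
    pb_num <- numeric(nb)
    pb_den <- numeric(nb)
    lam_min_bin <- rep(Inf, nb)   # lowest lambda seen per CV bin
    for (rec in archive$records) {
      if (is.null(rec$frames))
        stop("records carry no frames; rerun with store_frames = TRUE")
      fr <- if (is.matrix(rec$frames)) rec$frames else
        do.call(rbind, rec$frames)
      vals <- cv_fun(fr, rec)
      lamv <- rec$lambdas
      e <- match(rec$ensemble, ens_ids)
      if (is.na(e)) next
      wtot[e] <- wtot[e] + rec$weight
      nf <- length(lamv)
      # drop terminal-state endpoint frames: the interiors of [0-] and
      # [0+] paths then tile the equilibrium trajectory one-to-one
      interior <- rep(FALSE, nf)
      if (nf > 2) interior[2:(nf - 1)] <- TRUE
      idx_all <- findInterval(vals, breaks, rightmost.closed = TRUE)
      ok_all <- interior & idx_all >= 1 & idx_all <= nb
      if (any(ok_all)) {
        mins <- tapply(lamv[ok_all], idx_all[ok_all], min)
        bb <- as.integer(names(mins))
        lam_min_bin[bb] <- pmin(lam_min_bin[bb], as.numeric(mins))
      }
      keep <- interior & if (e == 1) lamv <= lamset[1] else
        lamv >= lamset[e - 1]
      if (!any(keep)) next
      idx <- findInterval(vals[keep], breaks, rightmost.closed = TRUE)
      ok <- idx >= 1 & idx <= nb
      if (!any(ok)) next
      idx <- idx[ok]
      add <- tabulate(idx, nbins = nb) * rec$weight
      h[, e] <- h[, e] + add
      label <- if (!reversed) as.numeric(rec$status == "AB")
               else as.numeric(rec$status %in% c("AA", "BA", "L0minus"))
      pb_num <- pb_num + add * label
      pb_den <- pb_den + add
    }
    # [0-] and [0+] interiors alternate one path each per crossing cycle:
    # normalising each histogram by its total path weight puts them on a
    # common per-cycle scale with no overlap fit needed
    dens <- numeric(nb)
    if (wtot[1] > 0) dens <- dens + h[, 1] / wtot[1]
    if (length(wtot) >= 2 && wtot[2] > 0)
      dens <- dens + h[, 2] / wtot[2]
    # higher ensembles: sequential overlap matching, then overwrite their
    # own reliable region (better statistics there).  Bins only partially
    # covered by an ensemble's lambda >= lambda_i restriction (the bin also
    # holds frames below lambda_i) are excluded from both the fit and the
    # overwrite, or the truncated straddle bins would skew the constants.
    for (e in seq_len(ncol(h))[-(1:2)]) {
      he <- h[, e]
      if (all(he == 0)) next
      full <- lam_min_bin >= lamset[e - 1]
      ov <- which(dens > 0 & he > 0 & full)
      if (length(ov) == 0) {
        if (all(dens == 0)) dens <- he
        next
      }
      w <- pmin(dens[ov], he[ov])
      cc <- exp(sum(w * log(dens[ov] / he[ov])) / sum(w))
      repl <- he > 0 & full
      dens[repl] <- cc * he[repl]
    }
    list(dens = dens, pb_num = pb_num, pb_den = pb_den)
  }

  fwd <- gather(forward_archive, cv, reversed = FALSE)
  if (!is.null(backward_archive)) {
    bwd <- gather(backward_archive, backward_cv, reversed = TRUE)
    ov <- which(fwd$dens > 0 & bwd$dens > 0)
    if (length(ov) == 0)
      stop("forward and backward densities do not overlap")
    w <- pmin(fwd$dens[ov], bwd$dens[ov])
    cc <- exp(sum(w * log(fwd$dens[ov] / bwd$dens[ov])) / sum(w))
    dens <- fwd$dens + cc * bwd$dens
    pb_num <- fwd$pb_num + bwd$pb_num
    pb_den <- fwd$pb_den + bwd$pb_den
    cb <- bwd$pb_den
  } else {
    dens <- fwd$dens
    pb_num <- fwd$pb_num
    pb_den <- fwd$pb_den
    cb <- numeric(nb)
  }
  fe <- ifelse(dens > 0, -kT * log(dens), NA_real_)
  fe <- fe - min(fe, na.rm = TRUE)
  committor <- ifelse(pb_den > 0, pb_num / pb_den, NA_real_)
  structure(
    list(table = data.frame(bin_mid = mids, free_energy = fe,
                            committor = committor,
                            count_forward = fwd$pb_den,
                            count_backward = cb),
         kT = kT, breaks = breaks),
    class = "projected_surface")
}

#' Classify a lipid-translocation path
#'
#' Maps a path's CV records to the translocation bookkeeping: the change
#' in leaflet imbalance between the first and last frame,
#' `delta = d_CNT(last) - d_CNT(first)`, labels asymmetric translocation
#' of `|delta|` lipids; `delta = 0` with a detected mid-path defect (any
#' interior frame with a continuous polar defect, chain coordinate at or
#' above 0.75, or a lipid at the midplane, `d1 <= 0.2` nm) is the
#' simultaneous exchange ("flip and flop") class; otherwise no event.
#'
#' @param cv_records data.frame of per-frame CV records (see
#'   [cv_trajectory()]), time-ordered.
#' @param xi_ch_defect chain-coordinate threshold for a continuous defect.
#' @param d1_defect midplane-lipid threshold on `d1` (nm).
#' @return List with `delta_d_cnt`, `category`, `end_d_cnt`.
#' @export
classify_translocation <- function(cv_records, xi_ch_defect = 0.75,
                                   d1_defect = 0.2) {
  n <- nrow(cv_records)
  stopifnot(n >= 1)
  delta <- cv_records$d_cnt[n] - cv_records$d_cnt[1]
  defect <- any(cv_records$xi_ch >= xi_ch_defect |
                  cv_records$d1 <= d1_defect)
  category <- if (delta != 0)
    sprintf("asymmetric_translocation_%d", abs(delta))
  else if (defect) "flip_and_flop" else "none"
  list(delta_d_cnt = delta, category = category,
       end_d_cnt = cv_records$d_cnt[n])
}

#' Unwrapped cylinder-center traces
#'
#' Turns per-frame cylinder centers into a minimum-image-continuous xy
#' trace (each step displacement folded below half a box length),
#' normalised by the box lengths, with the net lateral displacement per
#' path.
#'
#' @param cv_records data.frame with `cyl_x`, `cyl_y` columns and
#'   optionally a `path` id column.
#' @param box length-2 (or 3) box vector (nm).
#' @return data.frame with normalised unwrapped coordinates `u_x`, `u_y`
#'   per frame; attribute `displacement` summarises net displacement per
#'   path (in nm).
#' @export
cylinder_track <- function(cv_records, box) {
  ids <- if ("path" %in% names(cv_records)) cv_records$path
         else rep(1L, nrow(cv_records))
  out <- vector("list", length(unique(ids)))
  disp <- numeric(0)
  for (k in seq_along(unique(ids))) {
    id <- unique(ids)[k]
    sub <- cv_records[ids == id, , drop = FALSE]
    ux <- cumsum(c(sub$cyl_x[1],
                   min_image(diff(sub$cyl_x), box[1])))
    uy <- cumsum(c(sub$cyl_y[1],
                   min_image(diff(sub$cyl_y), box[2])))
    out[[k]] <- data.frame(path = id, u_x = ux / box[1],
                           u_y = uy / box[2])
    disp[as.character(id)] <-
      sqrt((ux[length(ux)] - ux[1])^2 + (uy[length(uy)] - uy[1])^2)
  }
  res <- do.call(rbind, out)
  attr(res, "displacement") <- disp
  res
}
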