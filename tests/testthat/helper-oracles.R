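# Independent brute-force oracles, written against raw frame data only
# (no reuse of the package's CV internals beyond the frame container).

oracle_min_image <- function(d, L) d - L * round(d / L)

# phosphorus positions and z offsets from a naive z center of mass
oracle_phos <- function(frame) {
  sel <- which(frame$phosphorus)
  lip <- which(!is.na(frame$lipid_id))
  # center the membrane by unwrapping z about the circular mean
  z <- frame$coords[lip, 3]
  L <- frame$box[3]
  th <- 2 * pi * z / L
  ref <- L * atan2(mean(sin(th)), mean(cos(th))) / (2 * pi)
  zcom <- ref + mean(oracle_min_image(z - ref, L))
  data.frame(lipid_id = frame$lipid_id[sel],
             x = frame$coords[sel, 1], y = frame$coords[sel, 2],
             z = frame$coords[sel, 3],
             dz = oracle_min_image(frame$coords[sel, 3] - zcom, L))
}

# exhaustive pair search for the translocation distances
oracle_pair_distances <- function(frame, metric) {
  pt <- oracle_phos(frame)
  pt <- pt[order(pt$lipid_id), ]
  n <- nrow(pt)
  ord <- order(-pt$dz, pt$lipid_id)
  up <- pt[ord[1:(n / 2)], ]
  lo <- pt[ord[(n / 2 + 1):n], ]
  box <- frame$box
  best <- function(u, l) {
    bd <- Inf
    bi <- bj <- NA
    for (i in seq_len(nrow(u))) for (j in seq_len(nrow(l))) {
      dx <- oracle_min_image(u$x[i] - l$x[j], box[1])
      dy <- oracle_min_image(u$y[i] - l$y[j], box[2])
      dz <- oracle_min_image(u$z[i] - l$z[j], box[3])
      d <- if (metric == "euclidean") sqrt(dx^2 + dy^2 + dz^2) else abs(dz)
      if (d < bd - 1e-12 ||
          (abs(d - bd) <= 1e-12 &&
           (u$lipid_id[i] < u$lipid_id[bi] ||
            (u$lipid_id[i] == u$lipid_id[bi] &&
             l$lipid_id[j] < l$lipid_id[bj])))) {
        bd <- d
        bi <- i
        bj <- j
      }
    }
    c(bi, bj)
  }
  p1 <- best(up, lo)
  d1 <- up$dz[p1[1]] - lo$dz[p1[2]]
  u2 <- up[-p1[1], ]
  l2 <- lo[-p1[2], ]
  p2 <- best(u2, l2)
  d2 <- u2$dz[p2[1]] - l2$dz[p2[2]]
  c(d1, d2)
}

oracle_d_llp <- function(frame, center, n_llp = 12) {
  pt <- oracle_phos(frame)
  box <- frame$box
  dx <- oracle_min_image(pt$x - center[1], box[1])
  dy <- oracle_min_image(pt$y - center[2], box[2])
  ord <- order(sqrt(dx^2 + dy^2), pt$lipid_id)
  k <- n_llp
  repeat {
    sel <- ord[1:k]
    up <- pt$dz[sel] > 0
    if (any(up) && any(!up)) break
    k <- k + 1
  }
  mean(pt$dz[sel][up]) - mean(pt$dz[sel][!up])
}

oracle_d_cnt <- function(frame) {
  pt <- oracle_phos(frame)
  abs(nrow(pt) / 2 - sum(pt$dz > 0))
}

# grid scan maximising xi_ch over an xy mesh (cylinder-placement oracle)
oracle_grid_scan <- function(frame, spec, mesh = 0.1) {
  gx <- seq(0, frame$box[1], by = mesh)
  gy <- seq(0, frame$box[2], by = mesh)
  best <- c(NA, NA)
  bv <- -1
  for (x in gx) for (y in gy) {
    v <- xi_ch(frame, spec, center = c(x, y))
    if (v > bv) {
      bv <- v
      best <- c(x, y)
    }
  }
  list(center = best, xi_ch = bv)
}

# small random pseudo-bilayer for oracle comparisons (few waters: the
# translocation and proximity CVs only read lipid sites)
random_frame <- function(seed, n_lipids = 32) {
  generate_bilayer_frame(bilayer_spec(
    n_lipids = n_lipids, box = c(4.2, 4.2, 7.0), waters = 40,
    xy_jitter = 0.3, z_jitter = 0.25, rng_seed = seed))
}

# toy helpers shared across engine tests
toy_setup <- function(dt = 0.02, friction = 1, temperature = 1) {
  pot <- toy_potential(barrier_height = 5, well_separation = 2,
                       coupling = 1)
  list(pot = pot,
       dyn = toy_dynamics(pot, dt = dt, friction = friction,
                          temperature = temperature))
}

# reversed-order-parameter toy backend (state B as reactant)
toy_backward_dynamics <- function(dt = 0.02, friction = 1,
                                  temperature = 1) {
  s <- toy_setup(dt, friction, temperature)
  dyn <- s$dyn
  pot <- s$pot
  dyn$lambda <- function(frames)
    if (is.matrix(frames)) -frames[, 1] else -frames[1]
  dyn$propagate <- function(phase, stop_low, stop_high, max_steps) {
    out <- poretis:::propagate_toy_cpp(
      as.numeric(phase), dt, friction, temperature,
      pot$barrier_height, pot$a, pot$coupling,
      -stop_high, -stop_low, as.integer(max_steps))
    term <- c(0L, 2L, 1L)[out$terminal + 1L]
    list(frames = out$frames, lambdas = -out$frames[, 1],
         n_steps = out$n_steps, terminal = term)
  }
  dyn
}

# hand-built path with a given lambda series (frames = lambda as 1 column)
lambda_path <- function(lambdas, weight = 1) {
  tis_path(matrix(lambdas, ncol = 1), lambdas, weight = weight)
}

# minimal archive from hand-built records
manual_archive <- function(records, interfaces, timestep = 1) {
  structure(list(records = records, interfaces = interfaces,
                 timestep = timestep),
            class = "path_archive")
}

manual_record <- function(lambdas, ensemble, weight = 1, status = NULL,
                          interfaces = NULL, frames = NULL) {
  if (is.null(status))
    status <- classify_path(lambda_path(lambdas), interfaces)
  list(ensemble = ensemble, cycle = 1, weight = weight,
       lmax = max(lambdas), lmin = min(lambdas),
       n_frames = length(lambdas), duration = length(lambdas) - 1,
       status = status, generation = "load", lambdas = lambdas,
       frames = frames)
}

# brute-force infinite-swap occupancies by permutation enumeration
oracle_infswap <- function(validity) {
  n <- nrow(validity)
  perms <- gtools_permutations(n)
  w <- matrix(0, n, n)
  count <- 0
  for (k in seq_len(nrow(perms))) {
    p <- perms[k, ]
    if (all(validity[cbind(p, seq_len(n))] > 0)) {
      count <- count + 1
      w[cbind(p, seq_len(n))] <- w[cbind(p, seq_len(n))] + 1
    }
  }
  w / count
}

# all permutations of 1..n (tiny n), no external dependency
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, matrix(setdiff(seq_len(n), i)[sub],
                             nrow = nrow(sub)))
    out <- rbind(out, block)
  }
  out
}
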