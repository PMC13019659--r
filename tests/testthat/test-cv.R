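make_column_frame <- function(per_slice = 1, seed = 7, waters = 500) {
  generate_bilayer_frame(bilayer_spec(
    defect_column = list(n_polar_atoms_per_slice = per_slice),
    waters = waters, rng_seed = seed))
}

test_that("chain coordinate hits its defining values", {
  spec <- cylinder_spec()
  fr1 <- make_column_frame(1)
  fit <- locate_cylinder(fr1, spec)
  expect_true(fit$converged)
  expect_equal(xi_ch(fr1, spec, fit), 0.75)

  # empty cylinder
  f0 <- generate_bilayer_frame(bilayer_spec(waters = 300, rng_seed = 3))
  expect_equal(xi_ch(f0, spec, center = c(3.1, 3.1)), 0)

  # two or more atoms per slice fill completely
  fr2 <- make_column_frame(2)
  expect_equal(xi_ch(fr2, spec, locate_cylinder(fr2, spec)), 1)

  # monotonicity: removing atoms never increases xi_ch
  expect_lte(xi_ch(fr1, spec, locate_cylinder(fr1, spec)),
             xi_ch(fr2, spec, locate_cylinder(fr2, spec)))
})

test_that("pore expansion extends the chain coordinate monotonically", {
  spec <- cylinder_spec()
  f0 <- generate_bilayer_frame(bilayer_spec(waters = 300, rng_seed = 3))
  expect_equal(xi_p(f0, spec, center = c(3.1, 3.1)),
               xi_ch(f0, spec, center = c(3.1, 3.1)))
  # adding polar atoms to a full cylinder strictly increases xi_p
  vals <- sapply(c(2, 4, 7), function(k) {
    fr <- make_column_frame(k)
    c(xi_ch(fr, spec, locate_cylinder(fr, spec)),
      xi_p(fr, spec, locate_cylinder(fr, spec)))
  })
  expect_equal(vals[1, ], c(1, 1, 1))
  expect_true(all(diff(vals[2, ]) > 0))
  # wide-open pore convention: xi_p > 2 achievable
  wide <- generate_bilayer_frame(bilayer_spec(
    defect_column = list(n_polar_atoms_per_slice = 13), waters = 300,
    rng_seed = 8))
  expect_gt(xi_p(wide, spec, locate_cylinder(wide, spec)), 2.0)
})

test_that("cylinder localisation finds defect columns and dense regions", {
  spec <- cylinder_spec()
  # a single polar-atom column is its own fixed point
  fr <- generate_bilayer_frame(bilayer_spec(
    defect_column = list(center_xy = c(4.4, 2.2),
                         n_polar_atoms_per_slice = 1),
    waters = 400, rng_seed = 11))
  fit <- locate_cylinder(fr, spec)
  expect_true(fit$converged)
  expect_lt(sqrt(sum(min_image(fit$center - c(4.4, 2.2), fr$box[1:2])^2)),
            0.1)

  # a defect-free frame with no polar atoms near the midplane is the
  # documented error case
  clean <- generate_bilayer_frame(bilayer_spec(waters = 200, z_jitter = 0,
                                               rng_seed = 12))
  expect_error(locate_cylinder(clean, spec), "polar")

  # pore-free frame with a locally thinned patch (polar heads dip into
  # the slab there): converged center within 0.8 nm of the grid-scan
  # maximiser of xi_ch
  f0 <- generate_bilayer_frame(bilayer_spec(
    thinning = list(center_xy = c(2.0, 4.0), depth = 0.6, radius = 1.0),
    waters = 2000, rng_seed = 13))
  fit0 <- locate_cylinder(f0, spec)
  scan <- oracle_grid_scan(f0, spec, mesh = 0.2)
  expect_lte(xi_ch(f0, spec, fit0), scan$xi_ch + 1e-9)
  d <- sqrt(sum(min_image(fit0$center - scan$center, f0$box[1:2])^2))
  expect_lt(d, 0.8)

  # two identical columns: the converged center follows the initial guess
  fr2 <- generate_bilayer_frame(bilayer_spec(
    defect_column = list(center_xy = c(1.5, 1.5),
                         n_polar_atoms_per_slice = 1),
    waters = 0, rng_seed = 14))
  extra <- generate_bilayer_frame(bilayer_spec(
    defect_column = list(center_xy = c(4.6, 4.6),
                         n_polar_atoms_per_slice = 1),
    waters = 0, rng_seed = 14))
  both <- bilayer_frame(
    coords = rbind(fr2$coords, extra$coords[extra$water_oxygen, ]),
    box = fr2$box,
    polar_heavy = c(fr2$polar_heavy,
                    rep(TRUE, sum(extra$water_oxygen))),
    phosphorus = c(fr2$phosphorus,
                   rep(FALSE, sum(extra$water_oxygen))),
    water_oxygen = c(fr2$water_oxygen,
                     rep(TRUE, sum(extra$water_oxygen))),
    lipid_id = c(fr2$lipid_id,
                 rep(NA_integer_, sum(extra$water_oxygen))))
  fitA <- locate_cylinder(both, spec, init = c(1.7, 1.7))
  fitB <- locate_cylinder(both, spec, init = c(4.4, 4.4))
  expect_lt(max(abs(min_image(fitA$center - c(1.5, 1.5), both$box[1:2]))),
            0.2)
  expect_lt(max(abs(min_image(fitB$center - c(4.6, 4.6), both$box[1:2]))),
            0.2)
})

test_that("local leaflet proximity measures thinning and extends sets", {
  # flat bilayer at zero jitter: exactly the head-head distance
  flat <- generate_bilayer_frame(bilayer_spec(waters = 0, xy_jitter = 0,
                                              z_jitter = 0, rng_seed = 1))
  expect_equal(d_llp(flat, c(3.1, 3.1)), 3.4, tolerance = 1e-9)

  # thinning by 1.0 nm on both leaflets: 3.4 - 2.0 = 1.4 when all selected
  # lipids sit inside the patch
  th <- generate_bilayer_frame(bilayer_spec(
    thinning = list(center_xy = c(3.1, 3.1), depth = 1.0, radius = 2.4),
    waters = 0, z_jitter = 0, rng_seed = 2))
  expect_equal(d_llp(th, c(3.1, 3.1)), 1.4, tolerance = 1e-9)

  # all nearest lipids in one leaflet triggers the set extension
  one_side <- generate_bilayer_frame(bilayer_spec(
    n_lipids = 16, box = c(4, 4, 7), leaflet_split = c(8, 8),
    waters = 0, rng_seed = 3))
  # push upper heads to one corner, lower to the other
  sel_up <- which(one_side$phosphorus &
                    one_side$coords[, 3] > one_side$box[3] / 2)
  for (i in sel_up) {
    lip <- one_side$lipid_id[i]
    rows <- which(one_side$lipid_id == lip)
    one_side$coords[rows, 1] <- one_side$coords[rows, 1] * 0.2
    one_side$coords[rows, 2] <- one_side$coords[rows, 2] * 0.2
  }
  got <- d_llp(one_side, c(0.4, 0.4), n_llp = 6)
  expect_equal(got, oracle_d_llp(one_side, c(0.4, 0.4), 6),
               tolerance = 1e-9)
})

test_that("translocation distances match exhaustive pair search", {
  for (seed in 1:8) {
    fr <- random_frame(seed)
    expect_equal(unname(d1_d2(fr)),
                 oracle_pair_distances(fr, "euclidean"),
                 tolerance = 1e-9, label = paste("frame", seed))
    expect_equal(unname(d1_d2_star(fr)),
                 oracle_pair_distances(fr, "z"),
                 tolerance = 1e-9, label = paste("frame*", seed))
    expect_true(all(d1_d2(fr) >= 0))
    expect_true(all(d1_d2_star(fr) >= 0))
  }
})

test_that("d1 behaves at the midplane and under undulations", {
  # symmetric defect-free frame: d1 slightly below mean P-P thickness
  f0 <- generate_bilayer_frame(bilayer_spec(waters = 0, rng_seed = 5))
  d <- unname(d1_d2(f0)[1])
  pt <- oracle_phos(f0)
  thick <- mean(pt$dz[pt$dz > 0]) - mean(pt$dz[pt$dz < 0])
  expect_lt(d, thick)
  expect_gt(d, 0.8 * thick)

  # one lipid moved to the midplane next to an opposing lipid: d1 ~ 0
  fm <- f0
  gt <- attr(f0, "ground_truth")
  lo <- which(fm$phosphorus & fm$coords[, 3] < gt$zmid)[1]
  hi <- which(fm$phosphorus & fm$coords[, 3] > gt$zmid)[1]
  fm$coords[hi, ] <- fm$coords[lo, ] + c(0.05, 0.05, 0.15)
  fm$coords[hi, 3] <- gt$zmid + 0.05
  fm$coords[lo, 3] <- gt$zmid - 0.05
  expect_lte(unname(d1_d2(fm)[1]), 0.2)

  # coherent undulation: the z-only pair distance dips below the
  # Euclidean one (the documented spurious decrease)
  und <- generate_bilayer_frame(bilayer_spec(
    undulation_amplitude = 0.8, waters = 0, z_jitter = 0.01,
    rng_seed = 6))
  expect_lt(unname(d1_d2_star(und)[1]), unname(d1_d2(und)[1]))

  # flat symmetric bilayer: the two variants coincide
  flat <- generate_bilayer_frame(bilayer_spec(waters = 0, xy_jitter = 0,
                                              z_jitter = 0, rng_seed = 1))
  expect_equal(unname(d1_d2_star(flat)[1]), unname(d1_d2(flat)[1]),
               tolerance = 1e-9)
})

test_that("leaflet count imbalance counts splits exactly", {
  for (f in 0:2) {
    fr <- generate_bilayer_frame(bilayer_spec(flipped_lipids = f,
                                              waters = 30,
                                              rng_seed = 3 + f))
    expect_equal(d_cnt(fr), f)
    expect_equal(d_cnt(fr), oracle_d_cnt(fr))
  }
})

test_that("collective variables are invariant under translation and
           relabeling", {
  fr <- make_column_frame(1, seed = 21, waters = 200)
  spec <- cylinder_spec()
  base <- compute_cvs(fr, spec)

  shift <- c(1.3, -2.1)
  fr2 <- fr
  fr2$coords[, 1] <- (fr2$coords[, 1] + shift[1]) %% fr2$box[1]
  fr2$coords[, 2] <- (fr2$coords[, 2] + shift[2]) %% fr2$box[2]
  moved <- compute_cvs(fr2, spec)
  for (col in c("xi_ch", "xi_p", "d_llp", "d1", "d2", "d1_star",
                "d2_star", "d_cnt"))
    expect_equal(moved[[col]], base[[col]], tolerance = 1e-9,
                 label = paste("translated", col))
  expect_lt(abs(min_image(moved$cyl_x - base$cyl_x - shift[1],
                          fr$box[1])), 0.02)

  # atom order permutation (lipid ids preserved)
  set.seed(1)
  perm <- sample(nrow(fr$coords))
  fr3 <- bilayer_frame(fr$coords[perm, ], fr$box, fr$polar_heavy[perm],
                       fr$phosphorus[perm], fr$water_oxygen[perm],
                       fr$lipid_id[perm])
  relab <- compute_cvs(fr3, spec)
  for (col in c("xi_ch", "xi_p", "d_llp", "d1", "d2", "d1_star",
                "d2_star", "d_cnt"))
    expect_equal(relab[[col]], base[[col]], tolerance = 1e-9,
                 label = paste("relabeled", col))
})

test_that("conditional order parameter schemes", {
  rec <- list(xi_p = 0.3, d1_star = 2.4, d2_star = 2.6, xi_ch = 0.4)
  expect_equal(conditional_order_parameter(rec, "PF"), -4.7)
  expect_equal(conditional_order_parameter(rec, "XI_CH"), 0.4)
  # PC is order-reversing: larger pores map to smaller lambda
  big <- list(xi_p = 1.8)
  small <- list(xi_p = 0.2)
  expect_lt(conditional_order_parameter(big, "PC"),
            conditional_order_parameter(small, "PC"))
  expect_error(conditional_order_parameter(rec, "WRONG"), "scheme")
})
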