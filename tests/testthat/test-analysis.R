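ifc3 <- interface_set(c(0.0, 0.3, 0.6, 1.0))

three_ensemble_archive <- function() {
  # hand-built archive over [0+], [1+], [2+] plus flux ensembles
  recs <- list(
    manual_record(c(-0.1, 0.05, -0.1), "[0-]", weight = 2,
                  status = "L0minus"),
    manual_record(c(0.1, 0.05, 0.1), "[0-]", weight = 2,
                  status = "L0minus"),
    manual_record(c(-0.1, 0.45, -0.1), "[0+]", weight = 2,
                  interfaces = ifc3),
    manual_record(c(-0.1, 0.35, -0.1), "[0+]", weight = 1,
                  interfaces = ifc3),
    manual_record(c(-0.1, 0.25, -0.1), "[0+]", weight = 1,
                  interfaces = ifc3),
    manual_record(c(-0.1, 0.45, -0.1), "[1+]", weight = 1,
                  interfaces = ifc3),
    manual_record(c(-0.1, 0.7, -0.1), "[1+]", weight = 1,
                  interfaces = ifc3),
    manual_record(c(-0.1, 0.4, -0.1), "[1+]", weight = 3,
                  interfaces = ifc3),
    manual_record(c(-0.1, 0.65, -0.1), "[2+]", weight = 4,
                  interfaces = ifc3),
    manual_record(c(-0.1, 0.8, 1.1), "[2+]", weight = 1,
                  interfaces = ifc3))
  manual_archive(recs, ifc3)
}

test_that("local crossing probabilities use path weights", {
  arch <- three_ensemble_archive()
  local <- local_crossing_probabilities(arch)
  # [0+]: weights {2,1,1} with maxima {above, above, below} vs 0.3
  expect_equal(local$p[1], 0.75)
  # [1+]: weights {1,1,3}, maxima vs 0.6: {below, above, below} -> 1/5
  expect_equal(local$p[2], 0.2)
  # [2+]: weights {4,1}, maxima vs 1.0 -> 1/5
  expect_equal(local$p[3], 0.2)
  # all paths crossing gives exactly one
  all_cross <- manual_archive(list(
    manual_record(c(-0.1, 1.1), "[0-]", status = "L0minus"),
    manual_record(c(-0.1, 0.5, 1.1), "[0+]", interfaces = ifc3),
    manual_record(c(-0.1, 0.7, 1.1), "[1+]", interfaces = ifc3),
    manual_record(c(-0.1, 0.9, 1.1), "[2+]", interfaces = ifc3)), ifc3)
  expect_equal(local_crossing_probabilities(all_cross)$p, rep(1, 3))
  # a missing ensemble is reported by name
  empty <- manual_archive(list(
    manual_record(c(-0.1, 0.5, -0.1), "[0+]", interfaces = ifc3)), ifc3)
  expect_error(local_crossing_probabilities(empty), "\\[1\\+\\]")
})

test_that("matched crossing curves telescope exactly", {
  arch <- three_ensemble_archive()
  local <- local_crossing_probabilities(arch)
  curve <- match_crossing_curve(local, arch, n_grid = 301)
  expect_equal(curve$p_total, prod(local$p))
  expect_equal(curve$p_total, 0.75 * 0.2 * 0.2)
  # monotone non-increasing, bounded, starts at one
  p <- curve$curve$p
  expect_equal(p[1], 1)
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(p >= 0 & p <= 1))
  # value at interface positions equals the telescoped product
  at <- function(x) p[which.min(abs(curve$curve$lambda - x))]
  expect_equal(at(0.3), 0.75, tolerance = 1e-6)
  expect_equal(at(0.6), 0.15, tolerance = 1e-6)
  # single ensemble: the curve is that ensemble's survival function
  one <- manual_archive(list(
    manual_record(c(-0.1, 0.2, -0.1), "[0-]", status = "L0minus"),
    manual_record(c(-0.1, 0.4, -0.1), "[0+]",
                  interfaces = interface_set(c(0, 1))),
    manual_record(c(-0.1, 0.8, -0.1), "[0+]",
                  interfaces = interface_set(c(0, 1)))),
    interface_set(c(0, 1)))
  loc1 <- local_crossing_probabilities(one)
  cur1 <- match_crossing_curve(loc1, one, n_grid = 101)
  expect_equal(cur1$curve$p[which.min(abs(cur1$curve$lambda - 0.5))],
               0.5)
})

test_that("the product of local probabilities is plain arithmetic", {
  expect_equal(prod(c(0.5, 0.2, 0.1)), 0.01)
})

test_that("initial flux combines the two lowest ensembles' durations", {
  mk <- function(tm, tp) {
    rec_m <- manual_record(rep(0, 2), "[0-]", status = "L0minus")
    rec_m$duration <- tm
    rec_p <- manual_record(rep(0, 2), "[0+]", status = "AA")
    rec_p$duration <- tp
    manual_archive(list(rec_m, rec_p), interface_set(c(0, 1)))
  }
  f <- initial_flux(mk(0.15, 0.0927))
  expect_equal(f$flux, 4.12, tolerance = 0.001)
  expect_equal(initial_flux(mk(1, 1))$flux, 0.5)
  # doubling all durations halves the flux
  expect_equal(initial_flux(mk(0.3, 0.1854))$flux, f$flux / 2)
  expect_error(initial_flux(manual_archive(list(
    manual_record(rep(0, 2), "[0+]", status = "AA")),
    interface_set(c(0, 1)))), "\\[0-\\]")
})

test_that("rate constants multiply flux and crossing probability", {
  r <- rate_constant(4.12, 1.15e-9, flux_rel_err = 0.1, p_rel_err = 0.2)
  expect_equal(r$k_ab, 4.12 * 1.15e-9)
  expect_equal(r$rel_err, sqrt(0.05))
  expect_equal(rate_constant(1, 0)$k_ab, 0)
})

test_that("effective positive flux counting on constructed path sets", {
  ifc <- interface_set(c(0, 1))
  # surface 0.5; path 1 reactive with one upward crossing; path 2
  # unreactive with two upward crossings -> kappa = 1/3
  arch <- manual_archive(list(
    manual_record(c(-0.1, 0.3, 0.7, 1.1), "[0+]", interfaces = ifc),
    manual_record(c(-0.1, 0.7, 0.3, 0.7, 0.3, -0.1), "[0+]",
                  interfaces = ifc)), ifc)
  k <- transmission_coefficient(arch, 0.5)
  expect_equal(k$kappa, 1 / 3)
  # one reactive path with two upward crossings: only its first counts
  arch2 <- manual_archive(list(
    manual_record(c(-0.1, 0.7, 0.3, 0.7, 1.1), "[0+]",
                  interfaces = ifc)), ifc)
  expect_equal(transmission_coefficient(arch2, 0.5)$kappa, 1 / 2)
  # every crossing effective
  arch3 <- manual_archive(list(
    manual_record(c(-0.1, 0.7, 1.1), "[0+]", interfaces = ifc)), ifc)
  expect_equal(transmission_coefficient(arch3, 0.5)$kappa, 1)
  # no crossings at all
  arch4 <- manual_archive(list(
    manual_record(c(-0.1, 0.2, -0.1), "[0+]", interfaces = ifc)), ifc)
  expect_error(transmission_coefficient(arch4, 0.5), "crossings")
  # product-side paths enter with their (small) relative weight
  kb <- transmission_coefficient(arch, 0.5, backward_archive = arch3,
                                 backward_weight = 1e-7)
  expect_equal(kb$kappa, 1 / 3, tolerance = 1e-6)
})

test_that("block errors recover closed-form standard errors", {
  set.seed(1)
  n <- 4096
  x <- rnorm(n, mean = 5, sd = 2)
  be <- block_error(x)
  expect_lt(abs(be$se - 2 / sqrt(n)) / (2 / sqrt(n)), 0.2)
  expect_equal(be$relative_error, be$se / mean(x))
  # AR(1): effective-sample-size formula
  phi <- 0.9
  m <- 2^15
  e <- rnorm(m)
  y <- as.numeric(stats::filter(e, phi, method = "recursive")) + 10
  bey <- block_error(y)
  se_true <- sd(y) * sqrt((1 + phi) / (1 - phi)) / sqrt(m)
  expect_lt(abs(bey$se - se_true) / se_true, 0.25)
  # constant series has zero error; short series raise
  expect_equal(block_error(rep(3, 100))$relative_error, 0)
  expect_error(block_error(rnorm(10)), "short")
  # a running estimate is unwound to its raw contributions
  z <- rnorm(2048)
  run_est <- cumsum(z) / seq_along(z)
  expect_equal(block_error(run_est, running = TRUE)$mean, mean(z))
})

test_that("translocation classification follows the leaflet imbalance", {
  mk <- function(d_cnt, xi_ch = 0.3, d1 = 2.5) {
    data.frame(d_cnt = d_cnt, xi_ch = xi_ch, d1 = d1)
  }
  # start 0 end 1: single-lipid asymmetric translocation
  r <- classify_translocation(mk(c(0, 0, 1)))
  expect_equal(r$delta_d_cnt, 1)
  expect_equal(r$category, "asymmetric_translocation_1")
  # no change, no defect: no event
  r0 <- classify_translocation(mk(c(1, 1, 1)))
  expect_equal(r0$category, "none")
  # simultaneous two-lipid exchange: unchanged counts, mid-path defect
  rf <- classify_translocation(
    data.frame(d_cnt = c(0, 0, 0), xi_ch = c(0.3, 0.9, 0.3),
               d1 = c(2.5, 0.1, 2.4)))
  expect_equal(rf$delta_d_cnt, 0)
  expect_equal(rf$category, "flip_and_flop")
  expect_equal(rf$end_d_cnt, 0)
})

test_that("cylinder traces unwrap across the periodic boundary", {
  box <- c(6, 6, 7)
  # static column
  still <- data.frame(cyl_x = rep(2, 5), cyl_y = rep(3, 5))
  tr <- cylinder_track(still, box)
  expect_equal(attr(tr, "displacement")[[1]], 0)
  # scripted drift crossing the boundary
  drift <- data.frame(cyl_x = c(5.4, 5.8, 0.2, 0.6),
                      cyl_y = c(1, 1, 1, 1))
  td <- cylinder_track(drift, box)
  steps <- diff(td$u_x * box[1])
  expect_true(all(abs(steps) < box[1] / 2))
  expect_equal(attr(td, "displacement")[[1]], 1.2, tolerance = 1e-9)
})
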