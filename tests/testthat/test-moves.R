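lam <- c(-0.7, -0.45, -0.2, 0.05, 0.7)
ifc <- interface_set(lam)
ens <- ensemble_definitions(ifc)

boot <- function(seed, dt = 0.02, friction = 1,
                 init = c(-1, 0, 0, 0)) {
  s <- toy_setup(dt = dt, friction = friction)
  set.seed(seed)
  list(dyn = s$dyn,
       paths = bootstrap_initial_paths(ifc, s$dyn, init))
}

test_that("zero-perturbation shooting with a symmetric integrator
           regenerates the path", {
  # frictionless + no velocity redraw: deterministic retrace whenever the
  # shooting point is not the path's first frame
  b <- boot(1, friction = 0, init = c(-1, 0, 1.8, 0.5))
  set.seed(2)
  p <- b$paths[["[0+]"]]
  n_acc <- 0
  for (k in 1:10) {
    res <- shooting_move(p, ens[[2]], ifc, b$dyn, redraw = FALSE)
    if (res$accepted) {
      n_acc <- n_acc + 1
      expect_equal(res$path$lambdas, p$lambdas, tolerance = 1e-8)
    }
  }
  expect_gte(n_acc, 1)
})

test_that("shooting rejects invalid and overlong proposals", {
  b <- boot(3)
  set.seed(4)
  # a [2+] proposal that never reaches lambda_2 must be rejected
  rejected <- FALSE
  p2 <- b$paths[["[2+]"]]
  for (k in 1:50) {
    res <- shooting_move(p2, ens[[4]], ifc, b$dyn)
    if (!res$accepted && res$reason == "invalid") rejected <- TRUE
    p2 <- res$path
    expect_true(path_valid_in(p2, ens[[4]], ifc))
  }
  expect_true(rejected)
  # pathological frame cap: every proposal overflows
  res <- shooting_move(b$paths[["[0-]"]], ens[[1]], ifc, b$dyn,
                       max_len = 3)
  expect_false(res$accepted)
  expect_equal(res$reason, "max_length")
})

test_that("shooting sampling is stationary (two-halves comparison)", {
  b <- boot(5)
  set.seed(6)
  p <- b$paths[["[0+]"]]
  n <- 3000
  lmax <- numeric(n)
  for (k in seq_len(n)) {
    res <- shooting_move(p, ens[[2]], ifc, b$dyn)
    p <- res$path
    lmax[k] <- path_lmax(p)
  }
  h1 <- lmax[1:(n / 2)]
  h2 <- lmax[(n / 2 + 1):n]
  # thin the heavily autocorrelated chain before distribution comparison
  thin <- seq(1, n / 2, by = 25)
  ks <- suppressWarnings(ks.test(h1[thin], h2[thin]))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(h1) - mean(h2)),
            3 * sqrt(var(h1) / 60 + var(h2) / 60))
})

test_that("wire fencing assembles valid high-acceptance paths", {
  b <- boot(7)
  set.seed(8)
  p <- b$paths[["[1+]"]]
  acc <- 0
  n <- 200
  for (k in seq_len(n)) {
    res <- wire_fencing_move(p, ens[[3]], ifc, b$dyn, cap = lam[4],
                             n_sub = 3)
    if (res$accepted) {
      expect_true(path_valid_in(res$path, ens[[3]], ifc))
      acc <- acc + 1
    }
    p <- res$path
  }
  # high-acceptance contract: the acceptance ratio approaches one
  expect_gt(acc / n, 0.8)
  expect_error(wire_fencing_move(p, ens[[1]], ifc, b$dyn, cap = 0),
               "\\[i\\+\\]")
  expect_error(wire_fencing_move(p, ens[[3]], ifc, b$dyn, cap = -0.5),
               "cap")
})

test_that("wire fencing and shooting estimate the same local probability", {
  b <- boot(9)
  estimate <- function(move_fun, seed, n = 600) {
    set.seed(seed)
    p <- b$paths[["[1+]"]]
    hits <- 0
    w <- 0
    for (k in seq_len(n)) {
      res <- move_fun(p)
      p <- res$path
      hits <- hits + (path_lmax(p) >= lam[3])
      w <- w + 1
    }
    hits / w
  }
  p_sh <- estimate(function(p) shooting_move(p, ens[[3]], ifc, b$dyn), 10)
  p_wf <- estimate(function(p)
    wire_fencing_move(p, ens[[3]], ifc, b$dyn, cap = lam[4], n_sub = 3),
    11)
  se <- sqrt(p_sh * (1 - p_sh) / 60 + p_wf * (1 - p_wf) / 60)
  expect_lt(abs(p_sh - p_wf), 3 * se)
})

test_that("point exchange swaps [0-] and [0+] through the crossing", {
  b <- boot(12)
  set.seed(13)
  res <- point_exchange_move(b$paths[["[0-]"]], b$paths[["[0+]"]], ifc,
                             b$dyn)
  expect_true(res$accepted)
  # the new [0+] path starts below lambda_A; the new [0-] interior stays
  # below lambda_A
  expect_lt(res$path_plus$lambdas[1], ifc$lambda_a)
  lm <- res$path_minus$lambdas
  expect_true(all(lm[2:(length(lm) - 1)] < ifc$lambda_a))
  expect_true(path_valid_in(res$path_minus, ens[[1]], ifc))
  expect_true(path_valid_in(res$path_plus, ens[[2]], ifc))
})

test_that("repeated point exchange preserves the state-A distribution", {
  b <- boot(14)
  set.seed(15)
  pm <- b$paths[["[0-]"]]
  pp <- b$paths[["[0+]"]]
  xs <- c()
  for (k in 1:400) {
    res <- point_exchange_move(pm, pp, ifc, b$dyn)
    pm <- res$path_minus
    pp <- res$path_plus
    r2 <- shooting_move(pm, ens[[1]], ifc, b$dyn)
    pm <- r2$path
    lmv <- pm$lambdas
    xs <- c(xs, pm$frames[lmv < ifc$lambda_a, 1])
  }
  # Boltzmann moments of x restricted to A, by quadrature
  v <- function(x) 5 * (x^2 - 1)^2
  zz <- integrate(function(x) exp(-v(x)), -Inf, -0.7)$value
  m1 <- integrate(function(x) x * exp(-v(x)), -Inf, -0.7)$value / zz
  m2 <- integrate(function(x) x^2 * exp(-v(x)), -Inf, -0.7)$value / zz
  expect_lt(abs(mean(xs) - m1), 0.02)
  expect_lt(abs(var(xs) - (m2 - m1^2)), 0.02)
})
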