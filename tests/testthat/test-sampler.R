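lam <- c(-0.7, -0.45, -0.2, 0.05, 0.7)

test_that("configuration validation accepts production-scale setups and
           rejects inconsistencies", {
  # a 22-ensemble chain-coordinate setup: terminals 0.4 and 0.99 with 20
  # intermediates ([0-] plus [0+]..[20+])
  lam22 <- c(seq(0.4, 0.97, length.out = 21), 0.99)
  cfg <- retis_config(lam22, scheme = "XI_CH", workers = 8)
  expect_equal(length(ensemble_definitions(interface_set(cfg$interfaces))),
               22)
  expect_error(retis_config(c(0.4, 0.4, 0.99)), "increasing")
  expect_error(retis_config(lam, move = "teleport"), "move")
  expect_error(retis_config(lam, n_sub = 0), "n_sub")
  expect_error(retis_config(lam, wf_cap = c(1, 1)), "cap")
  expect_error(retis_config(lam, workers = 0), "workers")
})

test_that("a fixed seed with one worker reproduces the archive exactly", {
  s <- toy_setup()
  set.seed(1)
  paths <- bootstrap_initial_paths(interface_set(lam), s$dyn,
                                   c(-1, 0, 0, 0))
  cfg <- retis_config(lam, n_cycles = 40, seed = 99)
  a <- archive_table(run_sampler(cfg, s$dyn, paths)$archive)
  b <- archive_table(run_sampler(cfg, s$dyn, paths)$archive)
  expect_identical(a, b)
  # a different seed diverges
  cfg2 <- retis_config(lam, n_cycles = 40, seed = 100)
  d <- archive_table(run_sampler(cfg2, s$dyn, paths)$archive)
  expect_false(identical(a, d))
})

test_that("every archived path satisfies the valid-path rule", {
  s <- toy_setup()
  set.seed(2)
  paths <- bootstrap_initial_paths(interface_set(lam), s$dyn,
                                   c(-1, 0, 0, 0))
  run <- run_sampler(retis_config(lam, n_cycles = 120, seed = 3,
                                  store_lambdas = TRUE), s$dyn, paths)
  ifc <- run$interfaces
  ens <- ensemble_definitions(ifc)
  ids <- vapply(ens, `[[`, character(1), "id")
  for (rec in run$archive$records) {
    p <- lambda_path(rec$lambdas)
    e <- ens[[match(rec$ensemble, ids)]]
    expect_true(path_valid_in(p, e, ifc))
  }
  # fractional occupancies: columns sum to one
  expect_true(!is.null(run$ensemble_weights))
  expect_equal(colSums(run$ensemble_weights),
               rep(1, ncol(run$ensemble_weights)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("[0-] frame histogram matches the Boltzmann distribution", {
  s <- toy_setup()
  set.seed(4)
  paths <- bootstrap_initial_paths(interface_set(lam), s$dyn,
                                   c(-1, 0, 0, 0))
  run <- run_sampler(retis_config(lam, n_cycles = 400, seed = 5,
                                  store_lambdas = TRUE,
                                  store_frames = TRUE), s$dyn, paths)
  xs <- c()
  for (rec in run$archive$records) {
    if (rec$ensemble != "[0-]") next
    inside <- rec$lambdas < -0.7
    xs <- c(xs, rep(rec$frames[inside, 1], rec$weight))
  }
  v <- function(x) 5 * (x^2 - 1)^2
  zz <- integrate(function(x) exp(-v(x)), -Inf, -0.7)$value
  m1 <- integrate(function(x) x * exp(-v(x)), -Inf, -0.7)$value / zz
  m2 <- integrate(function(x) x^2 * exp(-v(x)), -Inf, -0.7)$value / zz
  expect_lt(abs(mean(xs) - m1), 0.02)
  expect_lt(abs(var(xs) - (m2 - m1^2)), 0.02)
})

test_that("worker count permutes scheduling without changing estimates", {
  s <- toy_setup()
  set.seed(6)
  paths <- bootstrap_initial_paths(interface_set(lam), s$dyn,
                                   c(-1, 0, 0, 0))
  run1 <- run_sampler(retis_config(lam, n_cycles = 250, seed = 7),
                      s$dyn, paths)
  run8 <- run_sampler(retis_config(lam, n_cycles = 250, seed = 7,
                                   workers = 8), s$dyn, paths)
  p1 <- local_crossing_probabilities(run1$archive)
  p8 <- local_crossing_probabilities(run8$archive)
  se <- sqrt(p1$se^2 + p8$se^2)
  expect_true(all(abs(p1$p - p8$p) < pmax(3 * se, 0.1, na.rm = TRUE)))
})
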