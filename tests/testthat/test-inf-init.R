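test_that("interface readjustment places survival quantiles", {
  ifc <- interface_set(c(0, 1))
  # uniform maxima, target 0.5: successive halving quantiles
  lmax <- seq(0.0005, 0.9995, length.out = 1000)
  new <- readjust_interfaces(lmax, ifc, target_local_p = 0.5)
  inner <- new$lambdas[-c(1, length(new$lambdas))]
  expect_equal(inner[1:3], c(0.5, 0.75, 0.875), tolerance = 0.01)
  # terminals never move
  expect_equal(new$lambda_a, 0)
  expect_equal(new$lambda_b, 1)
  # a single path bounds the interfaces by its maximum (and is itself a
  # degenerate-maxima case)
  expect_warning(one <- readjust_interfaces(0.37, ifc,
                                            target_local_p = 0.3),
                 "degenerate")
  inner1 <- one$lambdas[-c(1, length(one$lambdas))]
  expect_true(all(inner1 <= 0.37))
  # degenerate maxima: single intermediate with a warning
  expect_warning(deg <- readjust_interfaces(rep(0.4, 10), ifc), "degenerate")
  expect_equal(length(deg$lambdas), 3)
  # interfaces strictly increasing always
  expect_true(all(diff(new$lambdas) > 0))
})

test_that("seed pools require state-A configurations", {
  ifc <- interface_set(c(-0.7, 0.7))
  expect_equal(select_seed_pool(c(-1, -0.9, 0.1), ifc), 1:2)
  expect_error(select_seed_pool(c(0.9, 1.2), ifc), "beyond lambda_B")
  expect_error(select_seed_pool(c(0.0, 0.5), ifc), "near or below")
})

test_that("equilibrium seeding yields valid [0-] and [0+] paths", {
  s <- toy_setup()
  set.seed(1)
  eq <- langevin_run(s$pot, c(-1, 0, 0, 0), 3000, 0.02, 1, 1,
                     save_every = 10)
  ifc <- interface_set(c(-0.7, 0.7))
  paths <- seed_from_equilibrium(eq, ifc, s$dyn)
  ens <- ensemble_definitions(ifc)
  expect_true(path_valid_in(paths[["[0-]"]], ens[[1]], ifc))
  expect_true(path_valid_in(paths[["[0+]"]], ens[[2]], ifc))
})

test_that("membrane frames near the reactant boundary seed a pore scheme", {
  # defect-free generator frames evaluated under the pore-formation
  # order parameter lambda = xi_p - (d1* + d2*) land deep in state A
  fr <- generate_bilayer_frame(bilayer_spec(
    defect_column = list(n_polar_atoms_per_slice = 1), waters = 300,
    rng_seed = 4))
  cvs <- compute_cvs(fr)
  lam <- conditional_order_parameter(cvs, "PF")
  ifc <- interface_set(c(-4.0, 2.0))
  expect_equal(select_seed_pool(lam, ifc), 1)
})

test_that("the initialisation protocol finds toy reactive paths reliably", {
  s <- toy_setup()
  hits <- 0
  for (k in 1:10) {
    set.seed(400 + k)
    eq <- langevin_run(s$pot, c(-1, 0, 0, 0), 3000, 0.02, 1, 1,
                       save_every = 10)
    cfg <- inf_init_config(lambda_a = -0.7, lambda_b = 0.7, rounds = 12,
                           cycles_per_round = 25, seed = 500 + k)
    res <- run_inf_init(cfg, s$dyn, eq)
    if (res$success) {
      hits <- hits + 1
      st <- classify_path(res$reactive_path, res$interfaces_final)
      expect_equal(st, "AB")
      # every round uses strictly increasing interfaces
      for (r in res$rounds)
        expect_true(all(diff(r$interfaces_used) > 0))
    }
  }
  expect_gte(hits, 9)
})

test_that("a deterministic downhill mover terminates in round one", {
  dd <- downhill_dynamics(step = 0.1)
  res <- run_inf_init(inf_init_config(-0.7, 0.7, rounds = 3,
                                      cycles_per_round = 5, seed = 1),
                      dd, matrix(-1, 1, 1))
  expect_true(res$success)
  expect_equal(length(res$rounds), 1)
})

test_that("a zero round budget is an immediate structured failure", {
  s <- toy_setup()
  res <- run_inf_init(inf_init_config(-0.7, 0.7, rounds = 0, seed = 1),
                      s$dyn, matrix(c(-1, 0, 0, 0), 1))
  expect_false(res$success)
  expect_match(res$reason, "budget")
  expect_equal(length(res$rounds), 0)
})

test_that("a translocation-distance surrogate driven toward contact
           reproduces the reversed-coordinate setup", {
  # state A at the equilibrium separation (~2.5 nm), state B at contact:
  # lambda_A = 2.0 and lambda_B = 0.2 on a decreasing coordinate map to an
  # increasing internal order parameter via direction = -1
  dyn <- surrogate_cv_dynamics(minimum_a = 2.5, minimum_b = 0.1,
                               barrier_height = 5, dt = 0.002,
                               temperature = 0.6, direction = -1)
  set.seed(11)
  eq <- matrix(2.5 + rnorm(200, sd = 0.1), ncol = 1)
  cfg <- inf_init_config(lambda_a = -2.0, lambda_b = -0.2, rounds = 15,
                         cycles_per_round = 25, seed = 12,
                         max_len = 2e5)
  res <- run_inf_init(cfg, dyn, eq)
  expect_true(res$success)
  # the reactive path ends at d1 below 0.2 nm
  final_d1 <- -res$reactive_path$lambdas[length(res$reactive_path$lambdas)]
  expect_lt(final_d1, 0.2)
})
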