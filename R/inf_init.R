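# Iterative initialisation: grow first reactive paths from equilibrium
# configurations by alternating short sampling rounds with interface
# readjustment.

#' Select equilibrium frames suitable for seeding
#'
#' @param lambdas order-parameter values of the candidate frames.
#' @param interfaces an [interface_set()].
#' @return Integer indices of frames inside state A (`lambda < lambda_A`).
#' @export
select_seed_pool <- function(lambdas, interfaces) {
  if (all(lambdas > interfaces$lambda_b))
    stop("all equilibrium frames lie beyond lambda_B; nothing to seed from")
  idx <- which(lambdas < interfaces$lambda_a)
  if (length(idx) == 0)
    stop("no equilibrium frames near or below lambda_A")
  idx
}

#' Seed paths from an equilibrium configuration pool
#'
#' Builds valid starting paths for every ensemble of `interfaces` using
#' only configuration points of an unbiased equilibrium trajectory:
#' state-A frames are selected, and short paths are generated by shooting
#' from them (ladder over ensembles, as in
#' [bootstrap_initial_paths()]).
#'
#' @param equilibrium_frames matrix of phase points (rows).
#' @param interfaces an [interface_set()].
#' @param dyn dynamics backend.
#' @param max_len frame cap per proposal.
#' @param max_tries shooting attempts per ensemble.
#' @return Named list of [tis_path()] per ensemble id.
#' @export
seed_from_equilibrium <- function(equilibrium_frames, interfaces, dyn,
                                  max_len = 1e5, max_tries = 2000) {
  if (!is.matrix(equilibrium_frames))
    equilibrium_frames <- matrix(equilibrium_frames, nrow = 1)
  lam <- dyn$lambda(equilibrium_frames)
  pool <- select_seed_pool(lam, interfaces)
  start <- equilibrium_frames[pool[which.min(lam[pool])], ]
  bootstrap_initial_paths(interfaces, dyn, start, max_len = max_len,
                          max_tries = max_tries)
}

#' Readjust intermediate interfaces from sampled path maxima
#'
#' Places new intermediate interfaces at empirical quantiles of the path
#' order-parameter maxima so that each local crossing probability is
#' approximately `target_local_p`: interface `k` sits at the weighted
#' quantile where the survival fraction of maxima equals
#' `target_local_p^k`.  The terminal interfaces never move.  If the maxima
#' are degenerate (all equal) a single intermediate interface is returned
#' with a warning.
#'
#' @param lmax numeric vector of path order-parameter maxima.
#' @param interfaces current [interface_set()] (supplies the fixed
#'   terminals).
#' @param target_local_p desired local crossing probability (default 0.3,
#'   inside the customary 0.2-0.4 placement band).
#' @param weights optional path weights.
#' @return A new [interface_set()].
#' @export
readjust_interfaces <- function(lmax, interfaces, target_local_p = 0.3,
                                weights = NULL) {
  stopifnot(length(lmax) >= 1, target_local_p > 0, target_local_p < 1)
  if (is.null(weights)) weights <- rep(1, length(lmax))
  la <- interfaces$lambda_a
  lb <- interfaces$lambda_b
  eps <- 1e-9 * max(1, abs(lb - la))
  if (max(lmax) - min(lmax) < eps) {
    warning("degenerate path maxima; placing a single intermediate")
    mid <- min(max(lmax[1], la + (lb - la) * 1e-3), lb - (lb - la) * 1e-3)
    return(interface_set(c(la, mid, lb)))
  }
  ord <- order(lmax)
  x <- lmax[ord]
  w <- weights[ord] / sum(weights)
  surv <- rev(cumsum(rev(w)))   # P(lmax >= x_i)
  quant_at <- function(p) {
    i <- which(surv <= p)[1]
    if (is.na(i)) x[length(x)] else x[i]
  }
  new_lam <- c()
  k <- 1
  repeat {
    p <- target_local_p^k
    q <- quant_at(p)
    if (q >= lb - eps || q >= max(x) - eps) break
    new_lam <- c(new_lam, q)
    k <- k + 1
    if (k > 100) break
  }
  new_lam <- unique(new_lam[new_lam > la + eps & new_lam < lb - eps])
  if (length(new_lam) == 0) {
    q <- max(x[x < lb - eps], la + (lb - la) / 2)
    new_lam <- min(max(q, la + (lb - la) * 1e-3), lb - (lb - la) * 1e-3)
  }
  interface_set(c(la, sort(new_lam), lb))
}

#' Configuration for the initialisation protocol
#'
#' @param lambda_a,lambda_b fixed terminal interfaces.
#' @param rounds maximum number of rounds.
#' @param cycles_per_round Monte Carlo cycles per round (the round length
#'   is a fixed move budget, for reproducibility).
#' @param target_local_p interface-placement target (see
#'   [readjust_interfaces()]).
#' @param seed integer seed.
#' @param max_len absolute frame cap per proposal.
#' @param n_sub wire-fencing subtrajectory count in rounds.
#' @return List of class `inf_init_config`.
#' @export
inf_init_config <- function(lambda_a, lambda_b, rounds = 10,
                            cycles_per_round = 20, target_local_p = 0.3,
                            seed = NULL, max_len = 1e5, n_sub = 3) {
  stopifnot(lambda_a < lambda_b, rounds >= 0, cycles_per_round >= 1,
            target_local_p > 0, target_local_p < 1)
  structure(list(lambda_a = lambda_a, lambda_b = lambda_b,
                 rounds = as.integer(rounds),
                 cycles_per_round = as.integer(cycles_per_round),
                 target_local_p = target_local_p, seed = seed,
                 max_len = max_len, n_sub = as.integer(n_sub)),
            class = "inf_init_config")
}

#' Grow a first reactive path from equilibrium configurations
#'
#' Alternates short sampling rounds with interface readjustment: round 1
#' runs with the terminal interfaces only, every later round places
#' intermediate interfaces at survival quantiles of the previously
#' observed path maxima (target local crossing probability
#' `target_local_p`, so the ensemble count grows by roughly one interface
#' per decade of `target_local_p` reached).  The iteration stops when a
#' reactive (`AB`) path appears or the round budget is exhausted; the
#' rounds log records interfaces, maxima and acceptance per round.
#'
#' @param config an [inf_init_config()].
#' @param dyn dynamics backend.
#' @param equilibrium_frames matrix of equilibrium phase points (rows),
#'   used only as shooting configurations.
#' @return List of class `inf_init_result`: `success`, `reactive_path`
#'   (a [tis_path()] or `NULL`), `rounds` (list of per-round records),
#'   `paths_final` (seeds for a production run), `interfaces_final`.
#' @export
run_inf_init <- function(config, dyn, equilibrium_frames) {
  stopifnot(inherits(config, "inf_init_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  rounds_log <- list()
  if (config$rounds == 0)
    return(structure(list(success = FALSE, reactive_path = NULL,
                          rounds = rounds_log, paths_final = NULL,
                          interfaces_final = NULL,
                          reason = "round budget exhausted"),
                     class = "inf_init_result"))
  ifc <- interface_set(c(config$lambda_a, config$lambda_b))
  paths <- seed_from_equilibrium(equilibrium_frames, ifc, dyn,
                                 max_len = config$max_len)
  for (r in seq_len(config$rounds)) {
    subcfg <- retis_config(ifc$lambdas, scheme = "inf_init",
                           n_cycles = config$cycles_per_round,
                           n_sub = config$n_sub, max_len = config$max_len,
                           store_lambdas = TRUE, store_frames = TRUE,
                           infswap_log_every = 1000)
    run <- run_sampler(subcfg, dyn, paths)
    tab <- archive_table(run$archive)
    plus <- tab[tab$ensemble != "[0-]", , drop = FALSE]
    rounds_log[[r]] <- list(round_index = r,
                            interfaces_used = ifc$lambdas,
                            max_lambda_reached = max(plus$lmax),
                            reactive_found = any(plus$status == "AB"),
                            n_paths = nrow(plus))
    hit <- which(vapply(run$archive$records, function(rec)
      rec$ensemble != "[0-]" && rec$status == "AB", logical(1)))
    if (length(hit) > 0) {
      rec <- run$archive$records[[hit[1]]]
      reactive <- tis_path(rec$frames, rec$lambdas,
                           timestep = dyn$timestep,
                           generation = rec$generation)
      return(structure(list(success = TRUE, reactive_path = reactive,
                            rounds = rounds_log,
                            paths_final = run$paths_final,
                            interfaces_final = ifc),
                       class = "inf_init_result"))
    }
    if (r == config$rounds) break
    ifc <- readjust_interfaces(plus$lmax, ifc,
                               target_local_p = config$target_local_p,
                               weights = plus$weight)
    paths <- reseed_round_paths(run, ifc, dyn)
  }
  structure(list(success = FALSE, reactive_path = NULL,
                 rounds = rounds_log, paths_final = NULL,
                 interfaces_final = ifc,
                 reason = "round budget exhausted"),
            class = "inf_init_result")
}

# pick, for every ensemble of the new interface set, a stored path that is
# valid there (preferring the shortest-reaching valid one)
reseed_round_paths <- function(run, interfaces, dyn) {
  ens <- ensemble_definitions(interfaces)
  cands <- c(run$paths_final,
             lapply(run$archive$records, function(rec)
               tis_path(rec$frames, rec$lambdas, timestep = dyn$timestep,
                        generation = rec$generation)))
  paths <- list()
  for (e in ens) {
    ok <- which(vapply(cands, path_valid_in, logical(1), e, interfaces))
    if (length(ok) == 0)
      stop("no stored path valid for new ensemble ", e$id)
    lm <- vapply(cands[ok], path_lmax, numeric(1))
    pick <- cands[[ok[which.min(lm)]]]
    pick$weight <- 1
    paths[[e$id]] <- pick
  }
  paths
}

#' @export
print.inf_init_result <- function(x, ...) {
  cat("inf_init_result: ", if (x$success) "reactive path found"
      else paste0("failed (", x$reason, ")"),
      " after ", length(x$rounds), " round(s)\n", sep = "")
  invisible(x)
}
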