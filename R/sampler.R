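#' Sampler run configuration
#'
#' Collects everything a sampling run needs: the interface set, the
#' order-parameter scheme label, move parameters and execution controls.
#' `validate_config()` checks consistency before any dynamics runs.
#'
#' @param interfaces numeric vector of strictly increasing interface values
#'   (first = `lambda_A`, last = `lambda_B`).
#' @param scheme order-parameter scheme label (free-form for toy backends;
#'   `"PF"`, `"PC"`, `"XI_CH"` for membrane CV records).
#' @param n_cycles number of Monte Carlo cycles.
#' @param seed integer seed applied at the start of the run (`NULL` leaves
#'   the RNG state untouched).
#' @param workers worker count for the asynchronous contract; statistics do
#'   not depend on it, and runs are bit-reproducible for `workers = 1`.
#'   With more workers the per-cycle task order is permuted (ensemble
#'   locking: one writer per ensemble per cycle).
#' @param move `"auto"` (standard shooting in `[0-]`/`[0+]`, wire fencing
#'   above), `"shooting"`, or `"wf"`.
#' @param n_sub wire-fencing subtrajectory count (default 3).
#' @param wf_cap optional numeric vector of cap interfaces, one per `[i+]`
#'   ensemble using wire fencing; default places the cap midway between
#'   `lambda_i` and `lambda_B` in interface index (a proxy for
#'   crossing-probability space under roughly equal local probabilities).
#' @param max_len_factor proposals longer than this multiple of the initial
#'   path length are rejected, never truncated.
#' @param max_len optional absolute frame cap overriding `max_len_factor`
#'   (used by the initialisation protocol, whose seed paths are short).
#' @param pexchange_every perform the `[0-]`/`[0+]` point exchange every
#'   this many cycles.
#' @param infswap_every perform the infinite-swap reassignment of `[i+]`
#'   paths every this many cycles.
#' @param infswap_log_every record the fractional occupancy matrix every
#'   this many swaps.
#' @param store_lambdas,store_frames keep full order-parameter series /
#'   frames on archived paths (memory permitting).
#' @return An object of class `retis_config`.
#' @export
retis_config <- function(interfaces, scheme = "toy", n_cycles = 100,
                         seed = NULL, workers = 1, move = "auto",
                         n_sub = 3, wf_cap = NULL, max_len_factor = 50,
                         max_len = NULL, pexchange_every = 1,
                         infswap_every = 1, infswap_log_every = 10,
                         store_lambdas = FALSE, store_frames = FALSE) {
  cfg <- structure(
    list(interfaces = as.numeric(interfaces), scheme = scheme,
         n_cycles = as.integer(n_cycles), seed = seed,
         workers = as.integer(workers), move = move,
         n_sub = as.integer(n_sub), wf_cap = wf_cap,
         max_len_factor = max_len_factor, max_len = max_len,
         pexchange_every = as.integer(pexchange_every),
         infswap_every = as.integer(infswap_every),
         infswap_log_every = as.integer(infswap_log_every),
         store_lambdas = store_lambdas, store_frames = store_frames),
    class = "retis_config")
  validate_config(cfg)
  cfg
}

#' Validate a sampler configuration
#'
#' @param config a [retis_config()] or plain list with the same fields.
#' @return The config, invisibly; errors describe every inconsistency.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  lam <- config$interfaces
  if (length(lam) < 2) problems <- c(problems, "need >= 2 interfaces")
  if (length(lam) >= 2 && any(diff(lam) <= 0))
    problems <- c(problems, "interfaces must be strictly increasing")
  if (!config$move %in% c("auto", "shooting", "wf"))
    problems <- c(problems, "move must be auto, shooting or wf")
  if (config$n_sub < 1) problems <- c(problems, "n_sub must be >= 1")
  if (config$n_cycles < 1) problems <- c(problems, "n_cycles must be >= 1")
  if (config$workers < 1) problems <- c(problems, "workers must be >= 1")
  if (config$max_len_factor <= 1)
    problems <- c(problems, "max_len_factor must exceed 1")
  if (!is.null(config$wf_cap)) {
    n_plus <- length(lam) - 1
    if (length(config$wf_cap) != n_plus)
      problems <- c(problems, "wf_cap needs one value per [i+] ensemble")
    else if (any(config$wf_cap <= lam[seq_len(n_plus)]))
      problems <- c(problems, "each cap must exceed its lambda_i")
  }
  if (length(problems) > 0)
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  invisible(config)
}

# Default cap for [i+] (0-based i): the interface midway (in index, a
# proxy for crossing-probability space) between lambda_i and lambda_B,
# but always at least two interfaces above lambda_i.  A cap that sits
# exactly at lambda_{i+1} would cut subtrajectories at the very interface
# whose crossing probability the ensemble estimates; keeping the cap
# strictly beyond it (or at lambda_B, where the cut coincides with the
# physical path terminus) leaves that estimate undistorted.
default_caps <- function(lambdas) {
  n <- length(lambdas) - 1
  vapply(seq_len(n) - 1L, function(i) {
    j <- min(i + max(2, ceiling((n - i) / 2)), n)
    lambdas[j + 1]
  }, numeric(1))
}

#' Bootstrap initial paths for every ensemble
#'
#' Builds a valid starting path per ensemble from a single equilibrium
#' phase point in state A by a ladder of shooting attempts: each ensemble
#' is seeded by repeated shots from the highest-order-parameter frames of
#' the path accepted for the previous ensemble.
#'
#' @param interfaces an [interface_set()].
#' @param dyn dynamics backend.
#' @param init_phase phase point inside state A.
#' @param max_len frame cap per proposal.
#' @param max_tries shooting attempts allowed per ensemble.
#' @return Named list of [tis_path()], one per ensemble id.
#' @export
bootstrap_initial_paths <- function(interfaces, dyn, init_phase,
                                    max_len = 1e5, max_tries = 2000) {
  ens <- ensemble_definitions(interfaces)
  la <- interfaces$lambda_a
  lb <- interfaces$lambda_b
  paths <- list()
  # [0-]: explore A in both time directions from the equilibrium point
  fwd <- dyn$propagate(init_phase, -Inf, la, max_len)
  bwd <- dyn$propagate(dyn$flip(init_phase), -Inf, la, max_len)
  if (fwd$terminal == 0L || bwd$terminal == 0L)
    stop("could not bootstrap the [0-] ensemble (max_len reached)")
  frames <- join_segments(dyn, bwd$frames, fwd$frames)
  paths[["[0-]"]] <- tis_path(frames, dyn$lambda(frames),
                              timestep = dyn$timestep)
  # [0+]: continue forward from the upward crossing that ends a [0-] path
  # (the point-exchange construction), regenerating [0-] paths as needed
  minus <- paths[["[0-]"]]
  prev <- NULL
  for (try in seq_len(max_tries)) {
    fm <- minus$frames
    nm <- nrow(fm)
    if (nm >= 2) {
      f <- dyn$propagate(fm[nm, ], la, lb, max_len)
      if (f$terminal != 0L) {
        fr <- rbind(matrix(fm[nm - 1, ], nrow = 1), f$frames)
        cand <- tis_path(fr, dyn$lambda(fr), timestep = dyn$timestep)
        if (path_valid_in(cand, ens[[2]], interfaces)) {
          prev <- cand
          break
        }
      }
    }
    res <- shooting_move(minus, ens[[1]], interfaces, dyn,
                         max_len = max_len)
    minus <- res$path
  }
  if (is.null(prev))
    stop("failed to bootstrap ensemble [0+] after ", max_tries,
         " attempts")
  paths[["[0+]"]] <- prev
  # higher [i+]: ladder of shots from the top frames of the previous path
  for (k in seq_along(ens)[-(1:2)]) {
    e <- ens[[k]]
    found <- NULL
    best <- prev
    for (try in seq_len(max_tries)) {
      pf <- best$frames
      lam <- best$lambdas
      thr <- stats::quantile(lam, 0.8)
      sel <- which(lam >= thr & lam >= la & lam <= lb)
      if (length(sel) == 0) sel <- which(lam >= la & lam <= lb)
      pool <- pf[sel, , drop = FALSE]
      phase <- dyn$draw_velocities(pool[sample.int(nrow(pool), 1), ])
      f <- dyn$propagate(phase, la, lb, max_len)
      if (f$terminal == 0L) next
      b <- dyn$propagate(dyn$flip(phase), la, lb, max_len)
      if (b$terminal == 0L) next
      fr <- join_segments(dyn, b$frames, f$frames)
      cand <- tis_path(fr, dyn$lambda(fr), timestep = dyn$timestep)
      if (path_valid_in(cand, e, interfaces)) {
        found <- cand
        break
      }
      # keep climbing: remember the best A-origin attempt so far
      if (cand$lambdas[1] < la && path_lmax(cand) > path_lmax(best))
        best <- cand
    }
    if (is.null(found))
      stop("failed to bootstrap ensemble ", e$id, " after ", max_tries,
           " attempts; consider an initialisation run")
    paths[[e$id]] <- found
    prev <- found
  }
  paths
}

new_archive <- function() {
  env <- new.env(parent = emptyenv())
  env$records <- vector("list", 256)
  env$n <- 0L
  env
}

archive_push <- function(arch, rec) {
  if (arch$n == length(arch$records))
    arch$records <- c(arch$records, vector("list", length(arch$records)))
  arch$n <- arch$n + 1L
  arch$records[[arch$n]] <- rec
}

make_record <- function(path, ensemble_id, cycle, interfaces, config) {
  list(ensemble = ensemble_id, cycle = cycle, weight = path$weight,
       lmax = path_lmax(path), lmin = min(path$lambdas),
       n_frames = path_nframes(path), duration = path_duration(path),
       status = classify_path(path, interfaces),
       generation = path$generation,
       lambdas = if (isTRUE(config$store_lambdas)) path$lambdas else NULL,
       frames = if (isTRUE(config$store_frames)) path$frames else NULL)
}

#' Run the infinite-swap RETIS sampler
#'
#' Executes the move cycle over all ensembles: shooting (or wire-fencing)
#' moves per ensemble, the `[0-]`/`[0+]` point exchange, and the
#' infinite-swap reassignment of `[i+]` paths (a uniformly random valid
#' permutation, the unit-weight infinite-swap limit).  Rejected moves
#' recount the current path, so archived weights are the number of cycles
#' a path represented its ensemble.  Runs are deterministic for a fixed
#' seed and `workers = 1`.
#'
#' @param config a [retis_config()].
#' @param dyn dynamics backend (see [toy_dynamics()]).
#' @param initial_paths named list of valid starting paths, one per
#'   ensemble id (see [bootstrap_initial_paths()] and [run_inf_init()]).
#' @return An object of class `retis_run`: `archive` (list of path
#'   records), `move_log` (data.frame), `ensemble_weights` (last logged
#'   fractional occupancies), `paths_final`, `interfaces`, `config`.
#' @export
run_sampler <- function(config, dyn, initial_paths) {
  validate_config(config)
  interfaces <- interface_set(config$interfaces)
  ens <- ensemble_definitions(interfaces)
  ids <- vapply(ens, function(e) e$id, character(1))
  if (!setequal(names(initial_paths), ids))
    stop("initial_paths must carry exactly the ensemble ids: ",
         paste(ids, collapse = ", "))
  if (!is.null(config$seed)) set.seed(config$seed)
  caps <- if (is.null(config$wf_cap)) default_caps(config$interfaces)
          else config$wf_cap
  n_plus <- length(ens) - 1
  plus_ids <- ids[-1]
  plus_lambda <- vapply(ens[-1], function(e) e$lambda_i, numeric(1))

  paths <- initial_paths[ids]
  for (id in ids) {
    k <- match(id, ids)
    if (!path_valid_in(paths[[id]], ens[[k]], interfaces))
      stop("initial path for ", id, " is not valid in that ensemble")
    paths[[id]]$weight <- 0
  }
  max_lens <- if (!is.null(config$max_len))
    stats::setNames(rep(config$max_len, length(paths)), ids)
  else vapply(paths, function(p)
    ceiling(config$max_len_factor * path_nframes(p)), numeric(1))

  arch <- new_archive()
  log_rows <- vector("list", 2048)
  log_n <- 0L
  add_log <- function(cycle, ensemble, move, accepted, reason) {
    log_n <<- log_n + 1L
    if (log_n > length(log_rows))
      log_rows <<- c(log_rows, vector("list", length(log_rows)))
    log_rows[[log_n]] <<- data.frame(cycle = cycle, ensemble = ensemble,
                                     move = move, accepted = accepted,
                                     reason = reason)
  }
  flush_path <- function(id, cycle) {
    p <- paths[[id]]
    if (p$weight > 0)
      archive_push(arch, make_record(p, id, cycle, interfaces, config))
  }
  last_weights <- NULL
  swap_count <- 0L

  for (cycle in seq_len(config$n_cycles)) {
    order_idx <- if (config$workers > 1) sample(seq_along(ids))
                 else seq_along(ids)
    for (k in order_idx) {
      id <- ids[k]
      e <- ens[[k]]
      use_wf <- (config$move == "wf" && e$type == "plus") ||
        (config$move == "auto" && e$type == "plus" && e$index >= 1)
      res <- if (use_wf)
        wire_fencing_move(paths[[id]], e, interfaces, dyn,
                          cap = caps[e$index + 1], n_sub = config$n_sub,
                          max_len = max_lens[[id]])
      else
        shooting_move(paths[[id]], e, interfaces, dyn,
                      max_len = max_lens[[id]])
      add_log(cycle, id, if (use_wf) "wf" else "shooting", res$accepted,
              res$reason)
      if (res$accepted) {
        flush_path(id, cycle)
        res$path$weight <- 1
        paths[[id]] <- res$path
      } else {
        paths[[id]]$weight <- paths[[id]]$weight + 1
      }
    }
    if (cycle %% config$pexchange_every == 0) {
      res <- point_exchange_move(paths[["[0-]"]], paths[["[0+]"]],
                                 interfaces, dyn,
                                 max_len = max(max_lens))
      add_log(cycle, "[0-]<->[0+]", "point_exchange", res$accepted,
              res$reason)
      if (res$accepted) {
        flush_path("[0-]", cycle)
        flush_path("[0+]", cycle)
        res$path_minus$weight <- 1
        res$path_plus$weight <- 1
        paths[["[0-]"]] <- res$path_minus
        paths[["[0+]"]] <- res$path_plus
      } else {
        # the exchange attempt is a counting event for both ensembles,
        # accepted or not, or exchange-rich paths would be overweighted
        paths[["[0-]"]]$weight <- paths[["[0-]"]]$weight + 1
        paths[["[0+]"]]$weight <- paths[["[0+]"]]$weight + 1
      }
    }
    if (n_plus >= 2 && cycle %% config$infswap_every == 0) {
      lmaxes <- vapply(plus_ids, function(id) path_lmax(paths[[id]]),
                       numeric(1))
      validity <- outer(lmaxes, plus_lambda, ">=")
      dimnames(validity) <- list(plus_ids, plus_ids)
      swap_count <- swap_count + 1L
      if (swap_count %% config$infswap_log_every == 1L ||
          config$infswap_log_every == 1L)
        last_weights <- infinite_swap_weights(validity)
      perm <- sample_valid_permutation(validity,
                                       restrictiveness = plus_lambda)
      # every swap is one counting event for every [i+] ensemble: moved
      # paths start a fresh record at weight 1, unmoved paths recount
      moved <- which(perm != seq_len(n_plus))
      old_paths <- paths
      for (j in seq_len(n_plus)) {
        dest <- plus_ids[j]
        if (j %in% moved) {
          src <- plus_ids[perm[j]]
          flush_path(dest, cycle)
          p <- old_paths[[src]]
          p$weight <- 1
          p$generation <- "infinite_swap"
          paths[[dest]] <- p
        } else {
          paths[[dest]]$weight <- paths[[dest]]$weight + 1
        }
      }
    }
  }
  for (id in ids) flush_path(id, config$n_cycles)
  move_log <- do.call(rbind, log_rows[seq_len(log_n)])
  structure(
    list(archive = structure(list(records = arch$records[seq_len(arch$n)],
                                  interfaces = interfaces,
                                  timestep = dyn$timestep),
                             class = "path_archive"),
         move_log = move_log, ensemble_weights = last_weights,
         paths_final = paths, interfaces = interfaces, config = config),
    class = "retis_run")
}

#' @export
print.retis_run <- function(x, ...) {
  acc <- tapply(x$move_log$accepted, x$move_log$ensemble, mean)
  cat("retis_run: ", length(x$archive$records), " archived paths, ",
      max(x$move_log$cycle), " cycles\n", sep = "")
  cat("acceptance by ensemble:\n")
  print(round(acc, 3))
  invisible(x)
}

#' Tabulate a path archive
#'
#' @param archive `path_archive` from [run_sampler()].
#' @return data.frame with one row per archived path (ensemble, cycle,
#'   weight, lmax, lmin, n_frames, duration, status, generation).
#' @export
archive_table <- function(archive) {
  recs <- archive$records
  data.frame(
    ensemble = vapply(recs, `[[`, character(1), "ensemble"),
    cycle = vapply(recs, `[[`, numeric(1), "cycle"),
    weight = vapply(recs, `[[`, numeric(1), "weight"),
    lmax = vapply(recs, `[[`, numeric(1), "lmax"),
    lmin = vapply(recs, `[[`, numeric(1), "lmin"),
    n_frames = vapply(recs, `[[`, numeric(1), "n_frames"),
    duration = vapply(recs, `[[`, numeric(1), "duration"),
    status = vapply(recs, `[[`, character(1), "status"),
    generation = vapply(recs, `[[`, character(1), "generation"))
}
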