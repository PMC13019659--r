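# Path-generation moves.  All moves return list(path=, accepted=, reason=)
# (point exchange returns both updated paths).  A rejected move leaves the
# input path untouched; the caller recounts it (weight accumulation).

get_frame <- function(frames, i) {
  if (is.matrix(frames)) frames[i, ] else frames[[i]]
}

flip_rows <- function(dyn, m) {
  out <- m
  for (i in seq_len(nrow(m))) out[i, ] <- dyn$flip(m[i, ])
  out
}

# join a backward segment (integrated from the flipped phase) and a forward
# segment sharing the shooting point into one forward-in-time frame matrix
join_segments <- function(dyn, bwd_frames, fwd_frames) {
  rb <- flip_rows(dyn, bwd_frames)
  rb <- rb[rev(seq_len(nrow(rb))), , drop = FALSE]
  rbind(rb, fwd_frames[-1, , drop = FALSE])
}

move_bounds <- function(ensemble, interfaces) {
  if (ensemble$type == "minus")
    c(-Inf, interfaces$lambda_a)
  else
    c(interfaces$lambda_a, interfaces$lambda_b)
}

#' Shooting move
#'
#' Selects a stored frame of the current path uniformly, redraws its
#' velocities from the thermal distribution, and integrates backward and
#' forward in time until a terminal state is reached.  The proposal is
#' rejected if either segment exceeds `max_len`, if the assembled path is
#' not valid for the ensemble, or by the flexible-path-length Metropolis
#' factor `min(1, N_old / N_new)` that compensates for uniform shooting
#' point selection; full velocity redraw makes the kinetic-energy factor
#' cancel, so together these preserve the stationary path distribution.
#'
#' @param path current [tis_path()], valid in `ensemble`.
#' @param ensemble one element of [ensemble_definitions()].
#' @param interfaces an [interface_set()].
#' @param dyn a dynamics backend (e.g. [toy_dynamics()]).
#' @param max_len maximum number of frames of a proposal.
#' @param redraw redraw velocities (set `FALSE` only for the deterministic
#'   identity-proposal limit).
#' @return `list(path=, accepted=, reason=)`.
#' @export
shooting_move <- function(path, ensemble, interfaces, dyn, max_len = 1e5,
                          redraw = TRUE) {
  n_old <- path_nframes(path)
  idx <- sample.int(n_old, 1)
  phase <- get_frame(path$frames, idx)
  if (redraw) phase <- dyn$draw_velocities(phase)
  b <- move_bounds(ensemble, interfaces)
  fwd <- dyn$propagate(phase, b[1], b[2], max_len)
  if (fwd$terminal == 0L)
    return(list(path = path, accepted = FALSE, reason = "max_length"))
  bwd <- dyn$propagate(dyn$flip(phase), b[1], b[2], max_len)
  if (bwd$terminal == 0L)
    return(list(path = path, accepted = FALSE, reason = "max_length"))
  frames <- join_segments(dyn, bwd$frames, fwd$frames)
  n_new <- nrow(frames)
  if (n_new > max_len)
    return(list(path = path, accepted = FALSE, reason = "max_length"))
  new_path <- tis_path(frames, dyn$lambda(frames), timestep = dyn$timestep,
                       generation = "shooting")
  if (!path_valid_in(new_path, ensemble, interfaces))
    return(list(path = path, accepted = FALSE, reason = "invalid"))
  if (stats::runif(1) > min(1, n_old / n_new))
    return(list(path = path, accepted = FALSE, reason = "metropolis"))
  list(path = new_path, accepted = TRUE, reason = "ok")
}

#' Wire-fencing move
#'
#' High-acceptance shooting variant for `[i+]` ensembles.  `n_sub`
#' subtrajectories are generated inside the fence between `lambda_i` and the
#' cap interface: each is shot from a uniformly chosen fence frame of the
#' current subtrajectory with redrawn velocities, integrated in both time
#' directions and cut at the first crossing of either fence boundary, and
#' accepted against the current subtrajectory with the flexible-length
#' factor on fence-frame counts.  The final subtrajectory's endpoints are
#' then extended by free dynamics (no velocity change) to the terminal
#' states, and the assembled path is accepted if it is valid for the
#' ensemble.  With `n_sub = 1` and the cap at `lambda_B` the move reduces to
#' a shooting-like move restricted to frames above `lambda_i`.
#'
#' @inheritParams shooting_move
#' @param cap cap interface value (> `lambda_i` of the ensemble).
#' @param n_sub number of subtrajectories (default 3).
#' @return `list(path=, accepted=, reason=)`.
#' @export
wire_fencing_move <- function(path, ensemble, interfaces, dyn, cap,
                              n_sub = 3, max_len = 1e5) {
  if (ensemble$type != "plus")
    stop("wire fencing is defined for [i+] ensembles")
  fence_low <- ensemble$lambda_i
  if (cap <= fence_low) stop("cap must lie above the ensemble interface")
  in_fence <- function(lam) lam >= fence_low & lam <= cap
  cur_frames <- if (is.matrix(path$frames)) path$frames else
    do.call(rbind, path$frames)
  cur_lam <- path$lambdas
  keep <- which(in_fence(cur_lam))
  if (length(keep) == 0)
    return(list(path = path, accepted = FALSE, reason = "empty_fence"))
  sub_frames <- cur_frames
  sub_fence_idx <- keep
  any_accepted <- FALSE
  for (k in seq_len(n_sub)) {
    j <- sub_fence_idx[sample.int(length(sub_fence_idx), 1)]
    phase <- dyn$draw_velocities(sub_frames[j, ])
    fwd <- dyn$propagate(phase, fence_low, cap, max_len)
    if (fwd$terminal == 0L) next
    bwd <- dyn$propagate(dyn$flip(phase), fence_low, cap, max_len)
    if (bwd$terminal == 0L) next
    cand <- join_segments(dyn, bwd$frames, fwd$frames)
    cand_fence <- which(in_fence(dyn$lambda(cand)))
    if (length(cand_fence) == 0) next
    if (stats::runif(1) <=
        min(1, length(sub_fence_idx) / length(cand_fence))) {
      sub_frames <- cand
      sub_fence_idx <- cand_fence
      any_accepted <- TRUE
    }
  }
  if (!any_accepted)
    return(list(path = path, accepted = FALSE, reason = "no_subtrajectory"))
  # extend both ends to the terminal states with free dynamics
  la <- interfaces$lambda_a
  lb <- interfaces$lambda_b
  first <- sub_frames[1, ]
  last <- sub_frames[nrow(sub_frames), ]
  ext_b <- dyn$propagate(dyn$flip(first), la, lb, max_len)
  if (ext_b$terminal == 0L)
    return(list(path = path, accepted = FALSE, reason = "max_length"))
  ext_f <- dyn$propagate(last, la, lb, max_len)
  if (ext_f$terminal == 0L)
    return(list(path = path, accepted = FALSE, reason = "max_length"))
  head_seg <- flip_rows(dyn, ext_b$frames)
  head_seg <- head_seg[rev(seq_len(nrow(head_seg))), , drop = FALSE]
  frames <- rbind(head_seg[-nrow(head_seg), , drop = FALSE], sub_frames,
                  ext_f$frames[-1, , drop = FALSE])
  if (nrow(frames) > max_len)
    return(list(path = path, accepted = FALSE, reason = "max_length"))
  new_path <- tis_path(frames, dyn$lambda(frames), timestep = dyn$timestep,
                       generation = "wire_fencing")
  if (!path_valid_in(new_path, ensemble, interfaces))
    return(list(path = path, accepted = FALSE, reason = "invalid"))
  list(path = new_path, accepted = TRUE, reason = "ok")
}

#' Point-exchange move between [0-] and [0+]
#'
#' Swaps the state-A interior and first crossing ensembles by deterministic
#' continuation through their shared crossing of `lambda_0`: the new `[0+]`
#' path continues forward from the upward crossing that ends the `[0-]`
#' path, and the new `[0-]` path continues backward (time-reversed) from
#' the A-side start of the `[0+]` path.  No velocities are redrawn.  If
#' either construction exceeds `max_len` the move is rejected and both
#' paths are left unchanged.
#'
#' @param path_minus current `[0-]` path.
#' @param path_plus current `[0+]` path.
#' @inheritParams shooting_move
#' @return `list(path_minus=, path_plus=, accepted=, reason=)`.
#' @export
point_exchange_move <- function(path_minus, path_plus, interfaces, dyn,
                                max_len = 1e5) {
  la <- interfaces$lambda_a
  lb <- interfaces$lambda_b
  fm <- if (is.matrix(path_minus$frames)) path_minus$frames else
    do.call(rbind, path_minus$frames)
  fp <- if (is.matrix(path_plus$frames)) path_plus$frames else
    do.call(rbind, path_plus$frames)
  nm <- nrow(fm)
  if (nm < 2 || nrow(fp) < 2)
    return(list(path_minus = path_minus, path_plus = path_plus,
                accepted = FALSE, reason = "degenerate"))
  # new [0+]: penultimate frame of [0-] (inside A) + its upward-crossing end
  # + forward continuation until a terminal state
  start_in_a <- fm[nm - 1, ]
  crossing <- fm[nm, ]
  fwd <- dyn$propagate(crossing, la, lb, max_len)
  if (fwd$terminal == 0L)
    return(list(path_minus = path_minus, path_plus = path_plus,
                accepted = FALSE, reason = "max_length"))
  plus_frames <- rbind(matrix(start_in_a, nrow = 1), fwd$frames)
  new_plus <- tis_path(plus_frames, dyn$lambda(plus_frames),
                       timestep = dyn$timestep, generation = "point_exchange")
  # new [0-]: backward exploration of A from the first frame of [0+],
  # terminated at the next upward crossing, then the old crossing frame
  f0 <- fp[1, ]
  f1 <- fp[2, ]
  bwd <- dyn$propagate(dyn$flip(f0), -Inf, la, max_len)
  if (bwd$terminal == 0L)
    return(list(path_minus = path_minus, path_plus = path_plus,
                accepted = FALSE, reason = "max_length"))
  head_seg <- flip_rows(dyn, bwd$frames)
  head_seg <- head_seg[rev(seq_len(nrow(head_seg))), , drop = FALSE]
  minus_frames <- rbind(head_seg, matrix(f1, nrow = 1))
  new_minus <- tis_path(minus_frames, dyn$lambda(minus_frames),
                        timestep = dyn$timestep,
                        generation = "point_exchange")
  ens <- ensemble_definitions(interfaces)
  if (!path_valid_in(new_minus, ens[[1]], interfaces) ||
      !path_valid_in(new_plus, ens[[2]], interfaces))
    return(list(path_minus = path_minus, path_plus = path_plus,
                accepted = FALSE, reason = "invalid"))
  list(path_minus = new_minus, path_plus = new_plus, accepted = TRUE,
       reason = "ok")
}
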