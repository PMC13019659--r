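#' Ordered interface set defining states and path ensembles
#'
#' Strictly increasing order-parameter values `lambda_0 = lambda_A < ... <
#' lambda_n = lambda_B`.  A phase point is in state A below `lambda_A` and
#' in state B above `lambda_B`.  The set defines the `[0-]` ensemble (state
#' A interior) and the `[i+]` ensembles for `i = 0 .. n-1`.
#'
#' @param lambdas strictly increasing numeric vector (length >= 2).
#' @param cap optional wire-fencing cap interface values, one per `[i+]`
#'   ensemble (filled in by the sampler configuration when omitted).
#' @return An object of class `interface_set`.
#' @export
interface_set <- function(lambdas, cap = NULL) {
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) < 2) stop("need at least lambda_A and lambda_B")
  if (any(diff(lambdas) <= 0))
    stop("interfaces must be strictly increasing")
  structure(list(lambdas = lambdas, lambda_a = lambdas[1],
                 lambda_b = lambdas[length(lambdas)], cap = cap),
            class = "interface_set")
}

#' @export
print.interface_set <- function(x, ...) {
  cat("interface_set: ", length(x$lambdas), " interfaces, lambda_A = ",
      x$lambda_a, ", lambda_B = ", x$lambda_b, "\n", sep = "")
  invisible(x)
}

#' Ensembles defined by an interface set
#'
#' @param interfaces an [interface_set()].
#' @return A list of ensembles, each `list(id=, type=, index=, lambda_i=)`;
#'   the first is `[0-]`, followed by `[i+]` for `i = 0 .. n-1`.
#' @export
ensemble_definitions <- function(interfaces) {
  n <- length(interfaces$lambdas) - 1
  ens <- vector("list", n + 1)
  ens[[1]] <- list(id = "[0-]", type = "minus", index = -1L,
                   lambda_i = interfaces$lambda_a)
  for (i in seq_len(n))
    ens[[i + 1]] <- list(id = sprintf("[%d+]", i - 1), type = "plus",
                         index = i - 1L,
                         lambda_i = interfaces$lambdas[i])
  ens
}

#' A sampled path
#'
#' Time-ordered sequence of phase points with their order-parameter values.
#' Only the first and last frame may lie inside a terminal state (the
#' valid-path rule); `weight` accumulates the number of Monte Carlo steps
#' the path represents in its ensemble (rejected moves recount the current
#' path).
#'
#' @param frames matrix of phase points (one row per frame) or a list of
#'   frames for configuration-based backends.
#' @param lambdas numeric order-parameter series, one value per frame.
#' @param timestep physical duration of one frame interval.
#' @param weight non-negative sampling weight.
#' @param generation label of the move that produced the path.
#' @return An object of class `tis_path`.
#' @export
tis_path <- function(frames, lambdas, timestep = 1, weight = 1,
                     generation = "load") {
  n <- if (is.matrix(frames)) nrow(frames) else length(frames)
  stopifnot(n >= 1, length(lambdas) == n, weight >= 0)
  structure(list(frames = frames, lambdas = as.numeric(lambdas),
                 timestep = timestep, weight = weight,
                 generation = generation),
            class = "tis_path")
}

path_nframes <- function(path) length(path$lambdas)
path_lmax <- function(path) max(path$lambdas)
path_duration <- function(path) (path_nframes(path) - 1) * path$timestep

#' @export
print.tis_path <- function(x, ...) {
  cat("tis_path: ", path_nframes(x), " frames, lambda in [",
      signif(min(x$lambdas), 4), ", ", signif(path_lmax(x), 4),
      "], weight ", x$weight, ", generation ", x$generation, "\n", sep = "")
  invisible(x)
}

#' Classify a path by its endpoints
#'
#' Endpoint membership (below `lambda_A` is A, above `lambda_B` is B) gives
#' `"AA"`, `"AB"`, `"BA"` or `"BB"`.  A path whose two endpoints both lie at
#' or above `lambda_A` while every interior frame stays below `lambda_A` is
#' the state-A interior class `"L0minus"`.
#'
#' @param path a [tis_path()].
#' @param interfaces an [interface_set()].
#' @return Status string.
#' @export
classify_path <- function(path, interfaces) {
  lam <- path$lambdas
  n <- length(lam)
  if (n < 2) stop("cannot classify a path with fewer than 2 frames")
  la <- interfaces$lambda_a
  lb <- interfaces$lambda_b
  state_of <- function(l) if (l < la) "A" else if (l > lb) "B" else NA
  s1 <- state_of(lam[1])
  s2 <- state_of(lam[n])
  interior <- if (n > 2) lam[2:(n - 1)] else numeric(0)
  if (is.na(s1) && is.na(s2) && lam[1] >= la && lam[n] >= la &&
      all(interior < la))
    return("L0minus")
  if (is.na(s1) || is.na(s2))
    stop("invalid path: an endpoint lies in no terminal state")
  paste0(s1, s2)
}

#' Is a path valid for an ensemble?
#'
#' `[0-]` requires the state-A interior class.  `[i+]` requires an
#' A-originating path (first frame in A), a terminal last frame (A or B),
#' interior frames confined to `[lambda_A, lambda_B]`, and a crossing of
#' `lambda_i`.
#'
#' @param path a [tis_path()].
#' @param ensemble one element of [ensemble_definitions()].
#' @param interfaces an [interface_set()].
#' @return Logical.
#' @export
path_valid_in <- function(path, ensemble, interfaces) {
  lam <- path$lambdas
  n <- length(lam)
  if (n < 2) return(FALSE)
  la <- interfaces$lambda_a
  lb <- interfaces$lambda_b
  interior <- if (n > 2) lam[2:(n - 1)] else numeric(0)
  if (ensemble$type == "minus")
    return(lam[1] >= la && lam[n] >= la && lam[1] <= lb && lam[n] <= lb &&
             all(interior < la))
  lam[1] < la &&
    (lam[n] < la || lam[n] > lb) &&
    all(interior >= la & interior <= lb) &&
    max(lam) >= ensemble$lambda_i
}
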