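#' Infinite-swap fractional occupancies
#'
#' In the infinite-swap limit every valid assignment of replica paths to
#' `[i+]` ensembles (a permutation compatible with the validity matrix) is
#' realised with equal weight (unit path weights).  The fractional occupancy
#' of replica `r` in ensemble `e` is then the fraction of valid permutations
#' that place `r` in `e`,
#' \deqn{W_{re} = M_{re}\,\mathrm{perm}(M_{-r,-e}) / \mathrm{perm}(M),}
#' computed with exact matrix permanents (Ryser's formula).  Every column
#' sums to 1, and a path valid in exactly one ensemble receives weight 1
#' there.
#'
#' @param validity logical or 0/1 matrix, replicas x ensembles, square.
#' @return Numeric matrix of occupancies with columns summing to 1.
#' @export
infinite_swap_weights <- function(validity) {
  m <- matrix(as.numeric(validity), nrow(validity), ncol(validity))
  n <- nrow(m)
  if (n != ncol(m))
    stop("validity matrix must be square (one replica per ensemble)")
  empty <- which(colSums(m) == 0)
  if (length(empty) > 0)
    stop("no valid path for ensemble(s): ",
         paste(empty, collapse = ", "))
  total <- permanent_cpp(m)
  if (total <= 0)
    stop("infeasible assignment: no valid permutation of paths exists")
  w <- matrix(0, n, n, dimnames = dimnames(validity))
  for (r in seq_len(n)) {
    for (e in seq_len(n)) {
      if (m[r, e] == 0) next
      w[r, e] <- if (n == 1) 1 else
        permanent_cpp(m[-r, -e, drop = FALSE]) / total
    }
  }
  w
}

# TRUE when validity sets, ordered by decreasing restrictiveness, are nested
is_nested_validity <- function(m, order_desc) {
  prev <- rep(TRUE, nrow(m))
  for (e in rev(order_desc)) {   # least restrictive last -> walk upward
    cur <- m[, e] > 0
    if (any(cur & !prev)) return(FALSE)
    prev <- cur
  }
  TRUE
}

#' Sample a uniformly random valid permutation
#'
#' Draws one assignment of replicas to ensembles uniformly among all
#' permutations compatible with the validity matrix.  For the nested
#' validity structure of interface ensembles (a path crossing `lambda_i`
#' is valid in every lower ensemble) a greedy most-restrictive-first pass
#' with uniform choices is exactly uniform; otherwise sequential sampling
#' weighted by permanents of the remaining submatrix is used.
#'
#' @param validity square logical/0-1 matrix (replicas x ensembles).
#' @param restrictiveness numeric, one value per ensemble; higher means
#'   fewer valid paths (defaults to `-colSums(validity)`).
#' @return Integer vector `perm` with `perm[e]` the replica assigned to
#'   ensemble `e`.
#' @export
sample_valid_permutation <- function(validity,
                                     restrictiveness = NULL) {
  m <- matrix(as.numeric(validity), nrow(validity), ncol(validity))
  n <- nrow(m)
  if (is.null(restrictiveness)) restrictiveness <- -colSums(m)
  ord <- order(-restrictiveness)   # most restrictive first
  perm <- integer(n)
  if (is_nested_validity(m, ord)) {
    avail <- rep(TRUE, n)
    for (e in ord) {
      cand <- which(avail & m[, e] > 0)
      if (length(cand) == 0)
        stop("infeasible assignment for ensemble ", e)
      perm[e] <- if (length(cand) == 1) cand else
        cand[sample.int(length(cand), 1)]
      avail[perm[e]] <- FALSE
    }
    return(perm)
  }
  rows <- seq_len(n)
  cols <- ord
  for (k in seq_along(cols)) {
    e <- cols[k]
    rest_cols <- cols[-seq_len(k)]
    cand <- rows[m[rows, e] > 0]
    if (length(cand) == 0) stop("infeasible assignment for ensemble ", e)
    wts <- vapply(cand, function(r) {
      rr <- setdiff(rows, r)
      if (length(rest_cols) == 0) 1
      else permanent_cpp(m[rr, rest_cols, drop = FALSE])
    }, numeric(1))
    if (sum(wts) <= 0) stop("infeasible assignment for ensemble ", e)
    perm[e] <- if (length(cand) == 1) cand else
      sample(cand, 1, prob = wts)
    rows <- setdiff(rows, perm[e])
  }
  perm
}
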