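#' Naive quadratic per-suffix computation (reference oracle)
#'
#' Evaluates the k-mismatch extension of every suffix of \code{x} against
#' every position of \code{y} directly: \code{values[i]} is the maximum of
#' \code{lcp_k(x, i, y, j, k)} over all \code{j}.  O(k n m) time.  This is
#' the ground truth the filtered algorithm is tested against.
#'
#' @param x,y \code{mm_seq} objects
#' @param k mismatch budget
#' @return an \code{mm_maxcor} with \code{mode = "naive"}; all \code{n*m}
#'   pairs count as examined
#' @export
naive_maxcor <- function(x, y, k) {
  xc <- .codes(x); yc <- .codes(y)
  res <- naive_maxcor_cpp(xc, yc, as.integer(k))
  nm <- as.double(length(xc)) * as.double(length(yc))
  .new_maxcor(res$values, res$best_j, k, "naive", x, y,
              pairs_examined = nm, accepted = NA_real_)
}

#' Greedy per-suffix baseline (kmacs-style)
#'
#' For each suffix of \code{x}, find the longest exact match length over
#' all positions of \code{y} and the set Z of positions attaining it, then
#' report the best k-mismatch extension seeded at a member of Z.  A lower
#' bound on the true per-suffix optimum: the longest exact match need not
#' seed the longest k-mismatch match.
#'
#' @inheritParams naive_maxcor
#' @return an \code{mm_maxcor} with \code{mode = "greedy"}
#' @export
greedy_maxcor <- function(x, y, k) {
  res <- greedy_maxcor_cpp(.codes(x), .codes(y), as.integer(k))
  .new_maxcor(res$values, res$best_j, k, "greedy", x, y,
              pairs_examined = NA_real_, accepted = NA_real_)
}
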