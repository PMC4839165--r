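#' Exact longest common extension
#'
#' Length of the longest common prefix of suffixes \code{x[i..]} and
#' \code{y[j..]} under strict match semantics: two codes match iff they are
#' equal and neither is the sentinel.  One-past-end positions are allowed
#' and give 0; extension simply stops at a sequence end (running out of
#' characters is not a mismatch).
#'
#' @param x,y \code{mm_seq} objects (or raw integer code vectors)
#' @param i,j 1-based start positions, \code{1 <= i <= n+1}
#' @return integer match length
#' @examples
#' x <- encode_sequence("ACGT"); y <- encode_sequence("ACGA")
#' lcp0(x, 1, y, 1)   # 3
#' @export
lcp0 <- function(x, i, y, j) {
  lcp0_cpp(.codes(x), as.integer(i), .codes(y), as.integer(j))
}

#' k-mismatch longest common extension (jump-extension)
#'
#' The largest \code{l} such that \code{x[i..i+l-1]} and \code{y[j..j+l-1]}
#' disagree in at most \code{k} positions: computed as up to \code{k+1}
#' chained exact extensions, each skipping over one mismatch.  Character
#' comparison is direct (no index structures); sentinels always mismatch.
#'
#' @inheritParams lcp0
#' @param k mismatch budget, \code{k >= 0}
#' @return integer match length
#' @examples
#' x <- encode_sequence("ACGTACGT"); y <- encode_sequence("ACGGACGT")
#' lcp_k(x, 1, y, 1, k = 1)   # 8
#' @export
lcp_k <- function(x, i, y, j, k) {
  lcpk_cpp(.codes(x), as.integer(i), .codes(y), as.integer(j),
           as.integer(k))
}

#' Sweep one suffix of x against every position of y
#'
#' Evaluates \code{lcp_k(x, i, y, j, k)} for all \code{j} and returns the
#' maximum together with the complete ascending list of positions attaining
#' it.  This is the direct \eqn{O(km)} computation used for the first
#' suffix (and as the fallback when the carry degenerates).
#'
#' @inheritParams lcp_k
#' @return list with \code{best} (integer) and \code{ties} (integer vector,
#'   ascending, non-empty)
#' @export
full_sweep <- function(x, i, y, k) {
  full_sweep_cpp(.codes(x), as.integer(i), .codes(y), as.integer(k))
}
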