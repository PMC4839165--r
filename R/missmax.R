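#' Step state of the filtered per-suffix computation
#'
#' The algorithm walks the suffixes of \code{x} carrying, from step
#' \code{i} to \code{i+1}, the current optimum \code{L = MaxCor_k(i)} and
#' the list of y-positions attaining it.  In exact mode the tie list is
#' complete; in relaxed mode it may be a subset (ties at length
#' \code{L - 1} are not recovered), which is what trades exactness for
#' speed.
#'
#' @param i suffix index in x (1-based)
#' @param L current optimum \code{MaxCor_k(i)}
#' @param ties ascending integer vector of y-positions attaining \code{L}
#' @return an object of class \code{mm_step_state}
#' @export
step_state <- function(i, L, ties) {
  structure(list(i = as.integer(i), L = as.integer(L),
                 ties = as.integer(ties)),
            class = "mm_step_state")
}

#' Initial state: full sweep of the first suffix
#'
#' @param x,y \code{mm_seq} objects
#' @param k mismatch budget
#' @return an \code{mm_step_state} for \code{i = 1}
#' @export
initial_state <- function(x, y, k) {
  sw <- full_sweep(x, 1L, y, k)
  step_state(1L, sw$best, sw$ties)
}

#' Carry the step-i optimum over to step i+1
#'
#' Each step-i tie position \code{j} yields a candidate for suffix
#' \code{i+1} at position \code{j+1}: \code{L - 1} when \code{x_i} matches
#' \code{y_j} (the k mismatches all lie strictly inside the old window), or
#' \code{L + lcp0} past the old window's final mismatch when it does not.
#' If the step-i alignment touched a sequence end the final mismatch the
#' formulas presuppose does not exist, and the candidate is recomputed
#' directly with \code{\link{lcp_k}}.  Ties at \code{j == m} have no image
#' and are dropped; if none survive, \code{ok} is \code{FALSE} and the
#' caller falls back to a full sweep.
#'
#' @param state an \code{mm_step_state} for step \code{i}
#' @param x,y \code{mm_seq} objects
#' @param k mismatch budget
#' @return list with \code{ok}, \code{L_max}, \code{ties} (positions
#'   \code{j+1} attaining \code{L_max}) and \code{pairs_examined} (number
#'   of candidates that required an extension)
#' @export
carry_over <- function(state, x, y, k) {
  stopifnot(inherits(state, "mm_step_state"))
  carry_over_cpp(.codes(x), .codes(y), as.integer(k),
                 state$i, state$L, state$ties)
}

#' Candidate y-positions for a longer match at the next step
#'
#' Applies the two per-symbol mask filters for step \code{i+1} built from
#' the step-i optimum \code{L}: (a) keep \code{r} only if \code{y_r} does
#' NOT match \code{x_i} (a matching predecessor caps the pair at
#' \code{L - 2} or less); (b) keep \code{r} only if \code{y_{r+L}} matches
#' the anchor \code{x_{i+L}} (any match of length \code{>= L} at
#' \code{(i+1, r+1)} must run exactly through that offset).  Filter (b) is
#' skipped when no anchor exists (\code{i + L > n}); a sentinel anchor
#' matches nothing and empties the candidate set.  Each surviving \code{r}
#' denotes the candidate pair \code{(i+1, r+1)}.
#'
#' @param x \code{mm_seq} (the query)
#' @param i current suffix index (step \code{i+1} is being built)
#' @param L optimum at step i
#' @param index_y an \code{\link{build_symbol_index}} over \code{y}
#' @return ascending integer vector of surviving positions \code{r}
#' @export
candidate_mask <- function(x, i, L, index_y) {
  stopifnot(inherits(index_y, "mm_symbol_index"))
  xc <- .codes(x)
  n <- length(xc)
  m <- nrow(index_y)
  stopifnot(i >= 1L, i <= n - 1L)
  xi <- xc[i]
  keep_a <- if (xi == 0L) rep(TRUE, m) else !index_y[, xi]
  if (i + L > n) return(which(keep_a))           # no anchor: filter (a) only
  anchor <- xc[i + L]
  if (anchor == 0L) return(integer(0))           # sentinel anchor
  keep_b <- rep(FALSE, m)
  if (L < m) {
    # shift the anchor mask left by L: r survives iff y_{r+L} == anchor
    keep_b[seq_len(m - L)] <- index_y[(L + 1L):m, anchor]
  }
  which(keep_a & keep_b)
}

#' Verify one filtered candidate
#'
#' For candidate pair \code{(i+1, r+1)} the optimistic length is
#' \code{c = L + lcp0(x, i+L+1, y, r+L+1)} (terms past either end
#' contribute 0): the length the pair attains if no mismatch hides between
#' its own final mismatch and offset \code{L}.  If \code{c < L_max} the
#' candidate is rejected without any extension.  Otherwise the true length
#' \code{L_true = lcp_k(x, i+1, y, r+1, k)} is computed and the candidate
#' is accepted iff \code{L_true == c}: as \code{new_best} when
#' \code{c > L_max}, as \code{tie} when \code{c == L_max}.
#'
#' @param x,y \code{mm_seq} objects
#' @param k mismatch budget
#' @param i step being built (pair is \code{(i+1, r+1)})
#' @param r filtered y-position
#' @param L step-i optimum
#' @param L_max current best for step i+1
#' @return list with \code{verdict} ("new_best", "tie" or "reject"),
#'   \code{c}, \code{L_true} (NA when short-circuited) and
#'   \code{pairs_examined} (1 if an extension ran, else 0)
#' @export
verify_candidate <- function(x, y, k, i, r, L, L_max) {
  xc <- .codes(x); yc <- .codes(y)
  n <- length(xc); m <- length(yc)
  cc <- L
  if (i + L + 1L <= n + 1L && r + L + 1L <= m + 1L)
    cc <- L + lcp0_cpp(xc, i + L + 1L, yc, r + L + 1L)
  if (cc < L_max)
    return(list(verdict = "reject", c = cc, L_true = NA_integer_,
                pairs_examined = 0))
  L_true <- lcpk_cpp(xc, i + 1L, yc, r + 1L, as.integer(k))
  verdict <- if (L_true != cc) "reject"
             else if (cc > L_max) "new_best"
             else "tie"
  list(verdict = verdict, c = cc, L_true = L_true, pairs_examined = 1)
}

.step <- function(state, x, y, k, exact, segment_filter = FALSE) {
  stopifnot(inherits(state, "mm_step_state"))
  nsym <- length(.alphabet_of(x)$symbols)
  res <- step_cpp(.codes(x), .codes(y), as.integer(k),
                  state$i, state$L, state$ties,
                  exact, segment_filter, nsym)
  out <- step_state(res$i, res$L, res$ties)
  attr(out, "pairs_examined") <- res$pairs_examined
  attr(out, "accepted") <- res$accepted
  out
}

#' Advance one suffix in exact mode
#'
#' Exact stepping: carry-over (full-sweep fallback if degenerate), direct
#' evaluation of y-position 1 (the carry shift cannot propose it), the
#' filtered candidate scan in ascending position order with dynamic
#' \code{L_max}, and -- only when the step ends at \code{L_max == L - 1} --
#' the tie-completion pass that re-examines every position the second
#' filter may have wrongly discarded.  The returned optimum equals the
#' naive \code{MaxCor_k(i+1)} and the tie list is complete.
#'
#' @inheritParams carry_over
#' @param segment_filter also require the whole segment
#'   \code{x[i+L .. i+L_max-1]} to match before verifying (an optional
#'   pre-filter; never changes results)
#' @return the \code{mm_step_state} for \code{i + 1}; counters in
#'   attributes \code{pairs_examined} and \code{accepted}
#' @export
step_exact <- function(state, x, y, k, segment_filter = FALSE) {
  .step(state, x, y, k, exact = TRUE, segment_filter = segment_filter)
}

#' Advance one suffix in relaxed mode
#'
#' Identical to \code{\link{step_exact}} except that the \code{L - 1}
#' tie-completion pass is skipped.  The tie list may be incomplete, so
#' later optima can fall below the true value; in practice the error on
#' the averaged statistic is a fraction of a percent.
#'
#' @inheritParams step_exact
#' @return the \code{mm_step_state} for \code{i + 1}
#' @export
step_relaxed <- function(state, x, y, k, segment_filter = FALSE) {
  .step(state, x, y, k, exact = FALSE, segment_filter = segment_filter)
}

.new_maxcor <- function(values, best_j, k, mode, x, y,
                        pairs_examined, accepted) {
  n <- length(values)
  m <- if (inherits(y, "mm_seq")) y$n else length(y)
  pairs_total <- as.double(n) * as.double(m)
  structure(list(
    values = as.integer(values),
    best_j = as.integer(best_j),
    k = as.integer(k),
    mode = mode,
    x_id = if (inherits(x, "mm_seq")) x$id else "x",
    y_id = if (inherits(y, "mm_seq")) y$id else "y",
    n = n, m = m,
    stats = list(pairs_total = pairs_total,
                 pairs_examined = pairs_examined,
                 verifications_accepted = accepted,
                 percentage = if (is.na(pairs_examined)) NA_real_
                              else 100 * pairs_examined / pairs_total)
  ), class = "mm_maxcor")
}

#' Per-suffix longest common substring with k mismatches
#'
#' Computes the full vector \code{MaxCor_k(i)}, \code{i = 1..n}: the length
#' of the longest common prefix with at most \code{k} mismatches between
#' suffix \code{x[i..]} and any position of \code{y}.  The first suffix is
#' solved by a full sweep; every later suffix is derived from its
#' predecessor by carry-over plus mask-filtered verification.  Exact mode
#' maintains the complete tie list (output provably equals the naive
#' quadratic computation); relaxed mode skips the expensive \code{L - 1}
#' tie recovery and may slightly underestimate.
#'
#' @param x,y \code{mm_seq} objects (query and subject)
#' @param k mismatch budget, \code{k >= 0}
#' @param mode \code{"exact"} or \code{"relaxed"}
#' @param segment_filter enable the optional whole-segment pre-filter
#'   (never changes results)
#' @return an object of class \code{mm_maxcor}: integer \code{values} and
#'   \code{best_j} (smallest optimal y-position per suffix), plus a
#'   \code{stats} list with \code{pairs_total = n*m},
#'   \code{pairs_examined} (pairs on which an extension was evaluated),
#'   \code{verifications_accepted} and the filtering \code{percentage}
#' @examples
#' x <- encode_sequence("ACGT"); y <- encode_sequence("TACG")
#' maxcor_vector(x, y, k = 0)$values   # 3 2 1 1
#' @export
maxcor_vector <- function(x, y, k, mode = c("exact", "relaxed"),
                          segment_filter = FALSE) {
  mode <- match.arg(mode)
  xc <- .codes(x); yc <- .codes(y)
  if (length(xc) < 1L || length(yc) < 1L)
    stop("sequences entering comparison must be non-empty")
  nsym <- length(.alphabet_of(x)$symbols)
  res <- maxcor_cpp(xc, yc, as.integer(k), mode == "exact",
                    segment_filter, nsym)
  .new_maxcor(res$values, res$best_j, k, mode, x, y,
              res$pairs_examined, res$accepted)
}

#' @export
print.mm_maxcor <- function(x, ...) {
  cat("<mm_maxcor> ", x$x_id, " vs ", x$y_id,
      "  (n=", x$n, ", m=", x$m, ", k=", x$k, ", mode=", x$mode, ")\n",
      sep = "")
  cat("  MaxCor_k = ", max(x$values),
      ";  kACS = ", format(mean(x$values), digits = 6), "\n", sep = "")
  if (!is.na(x$stats$percentage))
    cat("  pairs examined: ", format(x$stats$pairs_examined, big.mark = ","),
        " / ", format(x$stats$pairs_total, big.mark = ","),
        " (", sprintf("%.2f", x$stats$percentage), "%)\n", sep = "")
  invisible(x)
}
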