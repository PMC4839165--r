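#' Summary statistics of one per-suffix comparison
#'
#' Reduces a per-suffix vector to the two similarity statistics it carries
#' at no extra cost: the global maximum \code{MaxCor_k} (the longest common
#' substring with k mismatches, a.k.a. the k-mismatch longest common
#' factor) and the mean \code{kACS} (the k-mismatch average common
#' substring), plus the filtering percentage.
#'
#' @param vector an \code{mm_maxcor}
#' @return an object of class \code{mm_summary} with fields
#'   \code{maxcor_global}, \code{kacs_raw}, \code{filter_percentage},
#'   \code{mode}, \code{k}
#' @examples
#' x <- encode_sequence("ACGT"); y <- encode_sequence("TACG")
#' summarize_comparison(maxcor_vector(x, y, 0))  # MaxCor 3, kACS 1.75
#' @export
summarize_comparison <- function(vector) {
  stopifnot(inherits(vector, "mm_maxcor"), length(vector$values) >= 1L)
  structure(list(
    maxcor_global = max(vector$values),
    kacs_raw = sum(vector$values) / length(vector$values),
    filter_percentage = vector$stats$percentage,
    mode = vector$mode,
    k = vector$k,
    x_id = vector$x_id, y_id = vector$y_id,
    n = vector$n, m = vector$m
  ), class = "mm_summary")
}

#' @export
print.mm_summary <- function(x, ...) {
  cat("<mm_summary> ", x$x_id, " vs ", x$y_id,
      " (k=", x$k, ", mode=", x$mode, ")\n", sep = "")
  cat("  MaxCor_k (longest match):", x$maxcor_global, "residues\n")
  cat("  kACS (mean match):       ",
      format(x$kacs_raw, digits = 6), "residues\n")
  if (!is.na(x$filter_percentage))
    cat("  pairs examined:          ",
        sprintf("%.2f%%", x$filter_percentage), "\n")
  invisible(x)
}

# Upper cap used when a direction has kACS == 0 (no in-alphabet residue
# shared at all); keeps the matrix finite for tree building.
.MM_DIST_CAP <- 1000

.maxcor_by_mode <- function(x, y, k, mode) {
  switch(mode,
         exact   = maxcor_vector(x, y, k, "exact"),
         relaxed = maxcor_vector(x, y, k, "relaxed"),
         naive   = naive_maxcor(x, y, k),
         greedy  = greedy_maxcor(x, y, k),
         stop("unknown mode: ", mode))
}

#' ACS-style normalized distance between two sequences
#'
#' The average common substring normalization applied to the k-mismatch
#' statistic: for each direction,
#' \code{d'(x -> y) = log(m) / kACS(x -> y) - 2 log(n) / n}
#' (natural logarithm; the subtracted term removes the self-match
#' expectation so that \code{d(x, x) = 0}), then symmetrized by averaging
#' the two directions.  Small negative values arising on near-identical
#' short sequences are clamped to 0.
#'
#' @param x,y \code{mm_seq} objects with \code{n, m >= 2}
#' @param k mismatch budget
#' @param mode "exact", "relaxed", "naive" or "greedy"
#' @return a non-negative scalar distance
#' @export
acs_distance <- function(x, y, k, mode = "exact") {
  stopifnot(inherits(x, "mm_seq"), inherits(y, "mm_seq"),
            x$n >= 2L, y$n >= 2L)
  kxy <- summarize_comparison(.maxcor_by_mode(x, y, k, mode))$kacs_raw
  kyx <- summarize_comparison(.maxcor_by_mode(y, x, k, mode))$kacs_raw
  if (kxy == 0 || kyx == 0)
    warning("kACS is zero (no shared in-alphabet residue); ",
            "distance capped at ", .MM_DIST_CAP)
  dprime <- function(kacs, n, m) {
    if (kacs == 0) .MM_DIST_CAP
    else log(m) / kacs - 2 * log(n) / n
  }
  d <- (dprime(kxy, x$n, y$n) + dprime(kyx, y$n, x$n)) / 2
  max(d, 0)
}

#' Pairwise ACS-style distance matrix
#'
#' Computes \code{\link{acs_distance}} for every unordered pair.  Pairs are
#' independent, so with \code{threads > 1} they are evaluated in parallel
#' (forked workers); the result is identical regardless of scheduling.
#'
#' @param seqs list of at least two \code{mm_seq} with unique ids
#' @param k mismatch budget
#' @param mode comparison mode (see \code{\link{acs_distance}})
#' @param threads worker count for pair-level parallelism
#' @return an \code{mm_distance_matrix}: list with \code{labels} and the
#'   symmetric zero-diagonal \code{values} matrix
#' @export
distance_matrix <- function(seqs, k, mode = "exact", threads = 1L) {
  stopifnot(is.list(seqs), length(seqs) >= 2L)
  labels <- vapply(seqs, function(s) s$id, character(1L))
  if (anyDuplicated(labels))
    stop("duplicate sequence ids: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  p <- length(seqs)
  pairs <- utils::combn(p, 2L)
  one <- function(c) acs_distance(seqs[[pairs[1L, c]]], seqs[[pairs[2L, c]]],
                                  k, mode)
  vals <- if (threads > 1L && .Platform$OS.type == "unix") {
    unlist(parallel::mclapply(seq_len(ncol(pairs)), one,
                              mc.cores = as.integer(threads)))
  } else {
    vapply(seq_len(ncol(pairs)), one, numeric(1L))
  }
  mat <- matrix(0, p, p, dimnames = list(labels, labels))
  for (c in seq_len(ncol(pairs))) {
    mat[pairs[1L, c], pairs[2L, c]] <- vals[c]
    mat[pairs[2L, c], pairs[1L, c]] <- vals[c]
  }
  structure(list(labels = labels, values = mat),
            class = "mm_distance_matrix")
}

#' @export
print.mm_distance_matrix <- function(x, ...) {
  cat("<mm_distance_matrix> ", length(x$labels), " taxa\n", sep = "")
  print(round(x$values, 6))
  invisible(x)
}

#' Write a distance matrix in square PHYLIP format
#'
#' First line: taxon count; then one row per taxon, name padded to 10
#' characters, distances with 6 decimals.
#'
#' @param matrix an \code{mm_distance_matrix}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_phylip <- function(matrix, path) {
  stopifnot(inherits(matrix, "mm_distance_matrix"))
  p <- length(matrix$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", p), con)
  for (r in seq_len(p)) {
    name <- gsub("[ \t]", "_", matrix$labels[r])
    writeLines(paste0(formatC(name, width = -10),
                      paste(sprintf("%.6f", matrix$values[r, ]),
                            collapse = "  ")), con)
  }
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path file written by \code{\link{write_phylip}} (or any square
#'   whitespace-separated PHYLIP matrix)
#' @return an \code{mm_distance_matrix}
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  p <- as.integer(trimws(lines[1L]))
  if (is.na(p) || length(lines) != p + 1L)
    stop("not a square PHYLIP distance matrix: ", path)
  labels <- character(p)
  mat <- matrix(0, p, p)
  for (r in seq_len(p)) {
    tok <- strsplit(trimws(lines[r + 1L]), "[ \t]+")[[1L]]
    labels[r] <- tok[1L]
    mat[r, ] <- as.numeric(tok[-1L])
  }
  dimnames(mat) <- list(labels, labels)
  structure(list(labels = labels, values = mat),
            class = "mm_distance_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Delegates to the standard neighbor-joining implementation and returns
#' the tree serialized as Newick text (2-taxon matrices, which NJ proper
#' cannot handle, become a trivial 2-leaf tree).
#'
#' @param matrix an \code{mm_distance_matrix}
#' @return single Newick string
#' @export
nj_tree <- function(matrix) {
  stopifnot(inherits(matrix, "mm_distance_matrix"))
  p <- length(matrix$labels)
  if (p < 2L) stop("need at least 2 taxa")
  if (p == 2L) {
    h <- matrix$values[1L, 2L] / 2
    return(sprintf("(%s:%.6f,%s:%.6f);",
                   matrix$labels[1L], h, matrix$labels[2L], h))
  }
  tr <- ape::nj(matrix$values)
  ape::write.tree(tr)
}
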