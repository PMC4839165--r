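# Independent pure-R oracles and fixture builders.  The oracle scans
# prefixes character by character and never touches the package's compiled
# extension/stepping code paths.

# largest l such that x[i..i+l-1] and y[j..j+l-1] disagree in <= k positions
# (sentinel code 0 never matches anything)
oracle_lcpk <- function(xc, i, yc, j, k) {
  n <- length(xc); m <- length(yc)
  cap <- min(n - i + 1L, m - j + 1L)
  if (cap <= 0L) return(0L)
  a <- xc[i:(i + cap - 1L)]
  b <- yc[j:(j + cap - 1L)]
  mis <- cumsum(!(a == b & a != 0L))
  over <- which(mis > k)
  if (length(over) == 0L) cap else over[1L] - 1L
}

oracle_sweep <- function(xc, i, yc, k) {
  vals <- vapply(seq_along(yc), function(j) oracle_lcpk(xc, i, yc, j, k),
                 integer(1L))
  list(best = max(vals), ties = which(vals == max(vals)))
}

oracle_maxcor <- function(xc, yc, k) {
  vapply(seq_along(xc), function(i) oracle_sweep(xc, i, yc, k)$best,
         integer(1L))
}

# quick mm_seq builders
seq_dna <- function(s, id = "s") encode_sequence(s, id)

rand_mm_seq <- function(n, nsym = 4L, p_sentinel = 0, id = "r") {
  codes <- sample.int(nsym, n, replace = TRUE)
  if (p_sentinel > 0) codes[runif(n) < p_sentinel] <- 0L
  structure(list(id = id, codes = as.integer(codes), n = as.integer(n),
                 alphabet = mm_alphabet(LETTERS[seq_len(nsym)])),
            class = "mm_seq")
}

write_tmp_fasta <- function(records, width = 0L) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (id in names(records)) {
    writeLines(paste0(">", id), con)
    s <- records[[id]]
    if (width > 0L) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else writeLines(s, con)
  }
  close(con)
  path
}
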