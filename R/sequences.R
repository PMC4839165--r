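#' Residue alphabet
#'
#' An ordered set of residue symbols plus a sentinel code for everything
#' else.  Characters outside the alphabet (ambiguity codes such as N, IUPAC
#' degeneracies, gaps) are encoded as the sentinel, which never matches any
#' code -- including another sentinel -- so undefined regions always consume
#' mismatch budget and can never seed a spurious match.
#'
#' @param symbols character vector of single-character residue symbols
#'   (default DNA: A, C, G, T).  Upper-cased; must be unique.
#' @return an object of class \code{mm_alphabet}
#' @examples
#' mm_alphabet()                 # DNA
#' mm_alphabet(c("0", "1"))      # binary
#' @export
mm_alphabet <- function(symbols = c("A", "C", "G", "T")) {
  symbols <- toupper(as.character(symbols))
  if (length(symbols) < 1L) stop("alphabet needs at least one symbol")
  if (any(nchar(symbols) != 1L)) stop("alphabet symbols must be single characters")
  if (anyDuplicated(symbols)) stop("alphabet symbols must be unique")
  structure(list(symbols = symbols, sentinel = 0L), class = "mm_alphabet")
}

#' @export
print.mm_alphabet <- function(x, ...) {
  cat("<mm_alphabet> ", paste(x$symbols, collapse = ""),
      " (+ sentinel for out-of-alphabet)\n", sep = "")
  invisible(x)
}

.codes <- function(s) {
  if (inherits(s, "mm_seq")) s$codes else as.integer(s)
}

.alphabet_of <- function(s, default = mm_alphabet()) {
  if (inherits(s, "mm_seq")) s$alphabet else default
}

#' Encode a character sequence
#'
#' Upper-cases the input and maps each character to its integer code
#' (1-based index into the alphabet); characters outside the alphabet get
#' the sentinel code 0.
#'
#' @param seq a single string, or a character vector of single residues
#' @param id text label for the sequence
#' @param alphabet an \code{\link{mm_alphabet}}
#' @return an object of class \code{mm_seq} with fields \code{id},
#'   \code{codes}, \code{n} and \code{alphabet}
#' @examples
#' s <- encode_sequence("acgtn", "toy")
#' s$codes   # 1 2 3 4 0
#' @export
encode_sequence <- function(seq, id = "seq", alphabet = mm_alphabet()) {
  chars <- if (length(seq) == 1L)
    strsplit(seq, "", fixed = TRUE)[[1L]] else as.character(seq)
  chars <- toupper(chars)
  if (length(chars) < 1L)
    stop("sequence '", id, "' is empty")
  codes <- match(chars, alphabet$symbols)
  codes[is.na(codes)] <- alphabet$sentinel
  structure(list(id = id, codes = as.integer(codes), n = length(codes),
                 alphabet = alphabet),
            class = "mm_seq")
}

#' Decode an encoded sequence back to text
#'
#' Sentinel codes decode to \code{"N"} (or \code{"?"} if the alphabet
#' already contains N).
#'
#' @param x an \code{mm_seq}
#' @return a single string
#' @export
decode_sequence <- function(x) {
  stopifnot(inherits(x, "mm_seq"))
  unk <- if ("N" %in% x$alphabet$symbols) "?" else "N"
  chars <- c(unk, x$alphabet$symbols)[x$codes + 1L]
  paste(chars, collapse = "")
}

#' @export
print.mm_seq <- function(x, ...) {
  head <- decode_sequence(list_head(x, 60L))
  cat("<mm_seq> ", x$id, " (", x$n, " residues): ", head,
      if (x$n > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

list_head <- function(x, k) {
  structure(list(id = x$id, codes = utils::head(x$codes, k),
                 n = min(x$n, k), alphabet = x$alphabet), class = "mm_seq")
}

#' Read sequences from a FASTA file
#'
#' Multi-record and line-wrapped files are supported; record order is
#' preserved.  Characters are upper-cased before encoding and anything
#' outside the alphabet is encoded as the never-matching sentinel.
#'
#' @param path FASTA file path
#' @param alphabet an \code{\link{mm_alphabet}}
#' @return a list of \code{mm_seq}
#' @export
read_fasta <- function(path, alphabet = mm_alphabet()) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records found in ", path)
  ids <- names(set)
  # first whitespace-delimited token, as aligners do
  ids <- vapply(strsplit(ids, "[ \t]+"), `[`, character(1L), 1L)
  out <- vector("list", length(set))
  for (r in seq_along(set)) {
    txt <- as.character(set[[r]])
    if (nchar(txt) == 0L)
      stop("FASTA record '", ids[r], "' has an empty sequence")
    out[[r]] <- encode_sequence(txt, id = ids[r], alphabet = alphabet)
  }
  out
}

#' Generate i.i.d. uniform random sequences
#'
#' Emulates unrelated genomic background: every residue is drawn uniformly
#' and independently from the alphabet.  Identical
#' \code{(count, length, seed, alphabet)} reproduce identical sequences.
#' The caller's RNG state is left untouched.
#'
#' @param count number of sequences (>= 1)
#' @param length residues per sequence (>= 1)
#' @param seed integer seed
#' @param alphabet an \code{\link{mm_alphabet}}
#' @return a list of \code{mm_seq} with ids \code{random_01}, ...
#' @export
random_sequences <- function(count, length, seed,
                             alphabet = mm_alphabet()) {
  if (!is.numeric(count) || count < 1) stop("count must be >= 1")
  if (!is.numeric(length) || length < 1) stop("length must be >= 1")
  count <- as.integer(count); length <- as.integer(length)
  nsym <- base::length(alphabet$symbols)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(count), function(r) {
      structure(list(id = sprintf("random_%02d", r),
                     codes = sample.int(nsym, length, replace = TRUE),
                     n = length, alphabet = alphabet),
                class = "mm_seq")
    })
  })
}

#' Per-symbol occurrence masks over a subject sequence
#'
#' For every alphabet symbol \code{s}, a logical mask over positions of
#' \code{y} with \code{TRUE} exactly where \code{y_r == s}.  Sentinel
#' positions are \code{FALSE} in every mask, so the masks plus the sentinel
#' positions partition \code{1..m}.  These masks drive the candidate
#' filtering of the stepping algorithm.
#'
#' @param y an \code{mm_seq}
#' @return an \code{mm_symbol_index}: logical matrix (m rows, one column
#'   per symbol) with the alphabet attached
#' @export
build_symbol_index <- function(y) {
  stopifnot(inherits(y, "mm_seq"))
  nsym <- length(y$alphabet$symbols)
  masks <- matrix(FALSE, nrow = y$n, ncol = nsym,
                  dimnames = list(NULL, y$alphabet$symbols))
  for (s in seq_len(nsym)) masks[, s] <- y$codes == s
  structure(masks, class = c("mm_symbol_index", class(masks)),
            alphabet = y$alphabet)
}
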