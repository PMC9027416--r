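#' Circular (or linear) nucleotide sequence
#'
#' Lightweight container for a single contig: an uppercase nucleotide
#' string over `{A,C,G,T,N}`, a topology flag, and optional pass-through
#' coverage metadata (x-fold depth reported by the assembler; it is never
#' computed here).
#'
#' Mitochondrial chromosomes are circular, so most benchmarking inputs
#' carry `topology = "circular"`; linear contigs are accepted and handled
#' gracefully downstream (no rotation is attempted).
#'
#' @param seq Single nucleotide string. Lowercase is uppercased, `U` is
#'   mapped to `T`, and IUPAC ambiguity codes other than `N` are mapped
#'   to `N`. Any character outside the IUPAC nucleotide alphabet is an
#'   error naming the character and its position.
#' @param id Sequence label.
#' @param topology `"circular"` or `"linear"`.
#' @param coverage Optional positive number: x-fold coverage metadata.
#' @return An object of class `circ_seq`.
#' @examples
#' circ_seq("ACGT", id = "m", topology = "circular")
#' @export
circ_seq <- function(seq, id = "seq", topology = c("circular", "linear"),
                     coverage = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L, is.character(id),
            length(id) == 1L)
  topology <- match.arg(topology)
  seq <- normalize_nt(seq, id = id)
  if (nchar(seq) == 0L)
    stop("sequence '", id, "' is empty")
  if (!is.null(coverage)) {
    coverage <- as.numeric(coverage)
    if (!is.finite(coverage) || coverage <= 0)
      stop("coverage metadata for '", id, "' must be a positive number")
  }
  structure(list(id = id, seq = seq, topology = topology,
                 coverage = coverage),
            class = "circ_seq")
}

# Uppercase, RNA->DNA, ambiguity->N; reject non-IUPAC characters with
# the offending character and 1-based position in the message.
normalize_nt <- function(seq, id = "seq") {
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTUNRYSWKMBDHV]", seq)
  if (bad != -1L)
    stop("sequence '", id, "' contains non-nucleotide character '",
         substr(seq, bad, bad), "' at position ", bad)
  seq <- chartr("U", "T", seq)
  if (grepl("[RYSWKMBDHV]", seq))
    seq <- gsub("[RYSWKMBDHV]", "N", seq)
  seq
}

#' @export
print.circ_seq <- function(x, ...) {
  cov <- if (is.null(x$coverage)) "" else sprintf(", coverage %gx", x$coverage)
  head <- substr(x$seq, 1L, 60L)
  if (nchar(x$seq) > 60L) head <- paste0(head, "...")
  cat(sprintf("<circ_seq> %s: %d bp, %s%s\n  %s\n",
              x$id, nchar(x$seq), x$topology, cov, head))
  invisible(x)
}

#' @export
as.character.circ_seq <- function(x, ...) x$seq

#' Sequence length in bases
#' @param x A `circ_seq`.
#' @return Integer length.
#' @export
seq_length <- function(x) {
  stopifnot(inherits(x, "circ_seq"))
  nchar(x$seq)
}

#' Left-rotate a plain nucleotide string
#' @param seq Nucleotide string.
#' @param offset Rotation in bases, interpreted modulo the length.
#' @return The rotated string.
#' @export
rotate_string <- function(seq, offset) {
  n <- nchar(seq)
  offset <- offset %% n
  if (offset == 0L) return(seq)
  paste0(substr(seq, offset + 1L, n), substr(seq, 1L, offset))
}

#' Rotate a circular sequence
#'
#' Moves the origin of a circular sequence left by `offset` bases, so the
#' base at 0-based position `offset` becomes position 0.
#'
#' @param x A `circ_seq`.
#' @param offset Integer rotation, interpreted modulo the length.
#' @return A rotated `circ_seq`.
#' @export
rotate_seq <- function(x, offset) {
  stopifnot(inherits(x, "circ_seq"))
  x$seq <- rotate_string(x$seq, offset)
  x
}

#' Reverse complement of a plain nucleotide string
#' @param seq Nucleotide string over `{A,C,G,T,N}` (N self-complements).
#' @return The reverse-complemented string.
#' @export
revcomp_string <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

#' Reverse complement
#' @param x A `circ_seq`.
#' @return The reverse-complemented `circ_seq` (same id, topology, coverage).
#' @export
reverse_complement <- function(x) {
  stopifnot(inherits(x, "circ_seq"))
  x$seq <- revcomp_string(x$seq)
  x
}
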