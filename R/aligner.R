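#' Alignment scoring scheme
#'
#' Affine-gap scoring for the global assembly-vs-reference alignment.
#' A gap run of length L costs `gap_open + (L - 1) * gap_extend`. The
#' defaults (+2 / -3 / -5 / -2) favor one contiguous indel over several
#' scattered mismatches, which matches the expected discordance
#' structure at ~99.9% identity: nanopore consensus errors are mostly
#' short indels at homopolymer runs, not substitution clusters.
#'
#' @param match Positive match score.
#' @param mismatch Negative mismatch score.
#' @param gap_open Negative cost of the first column of a gap run.
#' @param gap_extend Negative cost of each further gap column.
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = -5,
                           gap_extend = -2) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Optimal global alignment with affine gaps
#'
#' End-to-end (Needleman-Wunsch/Gotoh) alignment of a normalized
#' assembly against the reference. Terminal gaps are charged like
#' internal ones: after circular rotation there is no privileged end.
#' Deterministic for fixed inputs and scoring (tie-breaking in the
#' dynamic program is fixed); gap placement is made canonical separately
#' by [normalize_gaps()].
#'
#' @param reference,assembly `circ_seq` objects (assembly already
#'   normalized — see [normalize_assembly()]).
#' @param scoring A [scoring_scheme()].
#' @param max_cells Guard on the dynamic-programming size
#'   `(m+1) * (n+1)`; the default `1e9` comfortably admits ~16.7 kb
#'   mitogenomes and refuses accidental genome-scale inputs.
#' @return An `aligned_pair`: `ref_row`, `asm_row` (equal-length gapped
#'   strings) and `score`.
#' @examples
#' p <- global_align(circ_seq("ACGT"), circ_seq("ACGT"))
#' p$score  # 8 under default scoring
#' @export
global_align <- function(reference, assembly, scoring = scoring_scheme(),
                         max_cells = 1e9) {
  stopifnot(inherits(reference, "circ_seq"), inherits(assembly, "circ_seq"),
            inherits(scoring, "scoring_scheme"))
  res <- affine_global_align_cpp(reference$seq, assembly$seq,
                                 scoring$match, scoring$mismatch,
                                 scoring$gap_open, scoring$gap_extend,
                                 max_cells)
  aligned_pair(res$ref_row, res$asm_row, res$score)
}

#' Construct an aligned pair
#'
#' Validates the aligned-pair invariants: equal row lengths and no
#' column gapped in both rows.
#'
#' @param ref_row,asm_row Equal-length gapped strings (`-` for gaps).
#' @param score Alignment score.
#' @return An `aligned_pair` object.
#' @export
aligned_pair <- function(ref_row, asm_row, score = NA_real_) {
  stopifnot(is.character(ref_row), is.character(asm_row),
            nchar(ref_row) == nchar(asm_row), nchar(ref_row) > 0L)
  r <- strsplit(ref_row, "", fixed = TRUE)[[1L]]
  a <- strsplit(asm_row, "", fixed = TRUE)[[1L]]
  if (any(r == "-" & a == "-"))
    stop("aligned pair has a column with gaps in both rows")
  structure(list(ref_row = ref_row, asm_row = asm_row,
                 score = as.numeric(score)),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("<aligned_pair> %d columns, score %g\n", nchar(x$ref_row),
              x$score))
  w <- min(60L, nchar(x$ref_row))
  cat("  ref ", substr(x$ref_row, 1L, w), "\n  asm ",
      substr(x$asm_row, 1L, w), "\n", sep = "")
  invisible(x)
}

# Split an aligned pair into its two character vectors.
pair_chars <- function(pair) {
  list(r = strsplit(pair$ref_row, "", fixed = TRUE)[[1L]],
       a = strsplit(pair$asm_row, "", fixed = TRUE)[[1L]])
}

#' Canonicalize gap placement (left normalization)
#'
#' Shifts every gap run as far left as possible among score-equivalent
#' placements: a run moves one column left whenever the base preceding
#' it (in the ungapped row) equals the last base spanned by the run,
#' so swapping preserves both sequences and every column's match
#' status. The position of an indel inside a homopolymer run is
#' otherwise arbitrary, and downstream error classification reads
#' homopolymer context from the canonical form; this makes per-category
#' counts reproducible across aligners and tie-breaks. Idempotent;
#' ungapped columns are never altered.
#'
#' @param pair An `aligned_pair`.
#' @return The gap-normalized `aligned_pair` (same score).
#' @export
normalize_gaps <- function(pair) {
  stopifnot(inherits(pair, "aligned_pair"))
  pc <- pair_chars(pair)
  r <- pc$r
  a <- pc$a
  # insertion runs (gaps in the reference row) shift against the
  # assembly row's content and vice versa; iterate to a fixpoint since
  # a shift in one row can expose a legal shift in the other
  for (iter in 1:10) {
    r2 <- shift_runs_left(gapped = r, solid = a)
    a2 <- shift_runs_left(gapped = a, solid = r2)
    done <- identical(r2, r) && identical(a2, a)
    r <- r2
    a <- a2
    if (done) break
  }
  aligned_pair(paste(r, collapse = ""), paste(a, collapse = ""),
               pair$score)
}

# Left-shift all maximal gap runs of `gapped`; `solid` is the other row
# (read-only: moving a gap run only rearranges the gapped row's
# characters). Shifting run [i..j] left by one is legal iff column i-1
# is ungapped in both rows and solid[i-1] == solid[j]: the base that
# leaves the aligned column equals the one that enters it, so both
# sequences and every column's match status are preserved.
shift_runs_left <- function(gapped, solid) {
  n <- length(gapped)
  i <- 1L
  while (i <= n) {
    if (gapped[i] != "-") { i <- i + 1L; next }
    j <- i
    while (j < n && gapped[j + 1L] == "-") j <- j + 1L
    # shift run [i..j] while legal
    while (i > 1L && gapped[i - 1L] != "-" && solid[i - 1L] != "-" &&
           solid[i - 1L] == solid[j]) {
      gapped[j] <- gapped[i - 1L]
      gapped[i - 1L] <- "-"
      i <- i - 1L
      j <- j - 1L
    }
    i <- j + 1L
  }
  gapped
}
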