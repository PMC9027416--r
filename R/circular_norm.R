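#' Detect assembly strand relative to a reference
#'
#' Decides whether a candidate assembly is on the same strand as the
#' reference or reverse-complemented, by comparing circular k-mer
#' multisets: the strand whose k-mer multiset shares more elements with
#' the reference's wins. K-mers are taken across the circular origin
#' (from the doubled string), so the decision is rotation-invariant.
#'
#' @param assembly,reference `circ_seq` objects, both at least `k` long.
#' @param k Word size (default 15; mitogenome-scale sequences make
#'   opposite-strand sharing negligible at this size).
#' @return `"forward"` or `"reverse_complement"`.
#' @details A tie in shared-k-mer counts raises a condition of class
#'   `mitobench_orientation_tie`; retrying with a smaller `k` can break
#'   genuine near-palindromic ties.
#' @export
detect_orientation <- function(assembly, reference, k = 15L) {
  stopifnot(inherits(assembly, "circ_seq"), inherits(reference, "circ_seq"))
  if (seq_length(assembly) < k || seq_length(reference) < k)
    stop("both sequences must be at least k = ", k, " bases long")
  ref_k <- circular_kmers(reference$seq, k)
  fwd <- shared_multiset(circular_kmers(assembly$seq, k), ref_k)
  rev <- shared_multiset(circular_kmers(revcomp_string(assembly$seq), k),
                         ref_k)
  if (fwd == rev)
    stop(errorCondition(
      paste0("orientation undecidable for '", assembly$id,
             "': forward and reverse strands share ", fwd,
             " k-mers each with the reference (k = ", k,
             "); retry with a smaller k"),
      class = "mitobench_orientation_tie"))
  if (fwd > rev) "forward" else "reverse_complement"
}

# All n k-mers of a circular sequence (across the origin).
circular_kmers <- function(seq, k) {
  n <- nchar(seq)
  doubled <- paste0(seq, substr(seq, 1L, k - 1L))
  substring(doubled, seq_len(n), seq_len(n) + k - 1L)
}

# Size of the multiset intersection of two character vectors.
shared_multiset <- function(a, b) {
  ta <- table(a)
  tb <- table(b)
  common <- intersect(names(ta), names(tb))
  if (!length(common)) return(0L)
  sum(pmin(as.integer(ta[common]), as.integer(tb[common])))
}

#' Rotate an assembly into the reference frame
#'
#' Finds the rotation of a (forward-oriented) circular assembly that
#' places at position 0 the locus best matching the reference's leading
#' `anchor_len` bases. The search scans the anchor against the doubled
#' assembly string (exact-match score per offset); because a sequencing
#' error inside the anchor window can make the raw exact-match maximum
#' ambiguous by a base or two, near-tied candidate offsets are re-scored
#' by globally aligning the leading `refine_len` bases of each candidate
#' rotation against the reference's leading window. Ties break to the
#' smallest offset.
#'
#' Linear-topology assemblies are returned unrotated (offset 0) with a
#' warning: rotation across an origin is only meaningful for circles.
#'
#' @param assembly Forward-oriented `circ_seq`.
#' @param reference Reference `circ_seq`.
#' @param anchor_len Anchor length for the exact-match scan (default 31).
#' @param refine_len Window length for alignment re-scoring of near-tied
#'   offsets (default 300, truncated to the sequence length).
#' @param scoring [scoring_scheme()] used for the refinement window.
#' @return A `normalization` object: `sequence` (rotated `circ_seq`),
#'   `orientation` (`"forward"`; [normalize_assembly()] fills in the
#'   detected strand), `rotation_offset`.
#' @export
rotate_to_reference <- function(assembly, reference, anchor_len = 31L,
                                refine_len = 300L,
                                scoring = scoring_scheme()) {
  stopifnot(inherits(assembly, "circ_seq"), inherits(reference, "circ_seq"))
  n <- seq_length(assembly)
  m <- seq_length(reference)
  if (n < anchor_len || m < anchor_len)
    stop("sequences must be at least anchor_len = ", anchor_len, " bp")
  if (n < m / 2 || n > m * 3 / 2)
    stop("assembly length ", n, " is not within 50% of reference length ",
         m, "; refusing to rotate (wrong organism or failed assembly?)")
  if (assembly$topology == "linear") {
    warning("assembly '", assembly$id,
            "' is linear; skipping rotation (offset 0)")
    return(structure(list(sequence = assembly, orientation = "forward",
                          rotation_offset = 0L),
                     class = "normalization"))
  }
  anchor <- substr(reference$seq, 1L, anchor_len)
  doubled <- paste0(assembly$seq, substr(assembly$seq, 1L, anchor_len - 1L))
  scores <- anchor_match_scores_cpp(doubled, anchor, n)
  best <- max(scores)
  if (best < anchor_len / 2)
    stop("no rotation of '", assembly$id, "' matches the reference anchor",
         " (best ", best, "/", anchor_len,
         " bases); likely wrong organism or failed assembly")
  # An indel inside the anchor window displaces the apparent origin by
  # its length, and the true offset can then score far below the
  # displaced one on exact matches alone. Candidates are therefore the
  # near-maximal anchor offsets plus a +/-8 bp neighbourhood (no
  # taxonomy indel is longer), adjudicated by globally aligning each
  # candidate's leading window against the reference's.
  cands <- which(scores >= best - 8L) - 1L
  if (length(cands) > 8L)
    cands <- cands[order(-scores[cands + 1L], cands)][1:8]
  cands <- sort(unique(as.vector(outer(cands, -8:8, "+")) %% n))
  w <- min(refine_len, n, m)
  slack <- min(16L, n - w)  # room for net indels inside the window
  rev_str <- function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  ref_head <- substr(reference$seq, 1L, w)
  ref_tail <- rev_str(substr(reference$seq, m - w + 1L, m))
  dbl <- paste0(assembly$seq, assembly$seq)
  aln_scores <- vapply(cands, function(off) {
    head_win <- substr(dbl, off + 1L, off + w + slack)
    # the candidate rotation's trailing window, reversed so the
    # alignment is anchored at the sequence end and free inward
    tail_win <- rev_str(substr(dbl, off + n - w - slack + 1L, off + n))
    prefix_align_score_cpp(ref_head, head_win, scoring$match,
                           scoring$mismatch, scoring$gap_open,
                           scoring$gap_extend) +
      prefix_align_score_cpp(ref_tail, tail_win, scoring$match,
                             scoring$mismatch, scoring$gap_open,
                             scoring$gap_extend)
  }, numeric(1L))
  off <- cands[order(-aln_scores, cands)][1L]
  structure(list(sequence = rotate_seq(assembly, off),
                 orientation = "forward",
                 rotation_offset = as.integer(off)),
            class = "normalization")
}

#' @export
print.normalization <- function(x, ...) {
  cat(sprintf("<normalization> %s: orientation %s, rotation offset %d\n",
              x$sequence$id, x$orientation, x$rotation_offset))
  invisible(x)
}

#' Normalize a candidate assembly against the reference
#'
#' Full circular normalization: strand detection ([detect_orientation()]),
#' reverse complementation when needed, then rotation into the
#' reference's frame ([rotate_to_reference()]). The result's invariant:
#' rotating the (possibly reverse-complemented) input left by
#' `rotation_offset` reproduces `sequence$seq` exactly.
#'
#' @inheritParams rotate_to_reference
#' @param k Word size for orientation detection.
#' @return A `normalization` object with `orientation` set to the
#'   detected strand.
#' @export
normalize_assembly <- function(assembly, reference, k = 15L,
                               anchor_len = 31L, refine_len = 300L,
                               scoring = scoring_scheme()) {
  orientation <- detect_orientation(assembly, reference, k = k)
  oriented <- if (orientation == "reverse_complement")
    reverse_complement(assembly) else assembly
  norm <- rotate_to_reference(oriented, reference, anchor_len = anchor_len,
                              refine_len = refine_len, scoring = scoring)
  norm$orientation <- orientation
  norm
}
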