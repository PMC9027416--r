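#' Stop codons of the vertebrate mitochondrial genetic code
#'
#' NCBI translation table 2: `TAA`, `TAG`, `AGA`, `AGG`. Hard-coded;
#' the test suite cross-checks the set against the Biostrings genetic
#' code tables.
#'
#' @return Character vector of the four stop triplets.
#' @export
vertebrate_mito_stops <- function() c("TAA", "TAG", "AGA", "AGG")

#' Project reference gene coordinates onto an assembly
#'
#' Maps each reference annotation interval through the alignment columns
#' into assembly coordinates (0-based half-open). Insertions internal to
#' a gene extend its projection, deletions shrink it, and a gene whose
#' reference bases are entirely deleted maps to an empty interval.
#' Insertions immediately outside a gene's first or last reference base
#' are not part of it.
#'
#' @param pair The `aligned_pair` of reference vs normalized assembly.
#' @param annotations Annotation `data.frame` (see
#'   [read_annotations()]), valid against the reference row.
#' @return A `data.frame`: `gene`, `kind`, `strand`, `ref_start`,
#'   `ref_end`, `asm_start`, `asm_end`.
#' @export
project_annotations <- function(pair, annotations) {
  stopifnot(inherits(pair, "aligned_pair"), is.data.frame(annotations))
  pc <- pair_chars(pair)
  r <- pc$r
  a <- pc$a
  ref_len <- sum(r != "-")
  if (any(annotations$end > ref_len))
    stop("annotation extends beyond the aligned reference length ",
         ref_len)
  # column index of each reference base (1-based), and cumulative
  # assembly bases up to and including each column
  ref_cols <- which(r != "-")
  asm_cum <- cumsum(a != "-")
  n <- nrow(annotations)
  asm_start <- integer(n)
  asm_end <- integer(n)
  for (i in seq_len(n)) {
    colS <- ref_cols[annotations$start[i] + 1L]  # first gene base
    colE <- ref_cols[annotations$end[i]]         # last gene base
    asm_start[i] <- asm_cum[colS] - (a[colS] != "-")
    asm_end[i] <- asm_cum[colE]
  }
  data.frame(gene = annotations$gene, kind = annotations$kind,
             strand = annotations$strand,
             ref_start = annotations$start, ref_end = annotations$end,
             asm_start = asm_start, asm_end = pmax(asm_end, asm_start),
             stringsAsFactors = FALSE)
}

#' Audit protein-coding genes for ORF disruption
#'
#' For every projected protein-coding gene, extracts the assembly
#' subsequence (reverse-complemented for minus-strand genes), reads it
#' in frame 0, and counts stop codons of the vertebrate mitochondrial
#' code ([vertebrate_mito_stops()]) strictly before the final complete
#' codon; an incomplete terminal codon is ignored. A gene is `disrupted`
#' when it has an internal stop or a net frameshift (projected length
#' minus reference length not divisible by 3) - the annotation-level
#' proxy for assembly error: a frameshifting indel typically surfaces as
#' premature stops downstream.
#'
#' `detected` emulates annotation tools missing a gene: it is `FALSE`
#' when the projection is empty or shorter than `min_detect_frac` of the
#' reference gene (or shorter than one codon).
#'
#' @param assembly The normalized assembly `circ_seq` underlying the
#'   projections.
#' @param projections Output of [project_annotations()].
#' @param min_detect_frac Fraction of the reference gene length below
#'   which a projection counts as not detected (default 0.5).
#' @return A `data.frame` with one row per PCG: `gene`, `strand`,
#'   `asm_start`, `asm_end`, `detected`, `frame_shift`,
#'   `internal_stops`, `disrupted`.
#' @export
audit_orfs <- function(assembly, projections, min_detect_frac = 0.5) {
  stopifnot(inherits(assembly, "circ_seq"), is.data.frame(projections))
  pcg <- projections[projections$kind == "PCG", , drop = FALSE]
  n <- nrow(pcg)
  detected <- logical(n)
  frame_shift <- integer(n)
  stops <- integer(n)
  stop_set <- vertebrate_mito_stops()
  for (i in seq_len(n)) {
    ref_len <- pcg$ref_end[i] - pcg$ref_start[i]
    len <- pcg$asm_end[i] - pcg$asm_start[i]
    frame_shift[i] <- len - ref_len
    detected[i] <- len >= 3L && len >= ceiling(min_detect_frac * ref_len)
    if (len < 3L) next
    cds <- substr(assembly$seq, pcg$asm_start[i] + 1L, pcg$asm_end[i])
    if (pcg$strand[i] == "-") cds <- revcomp_string(cds)
    ncod <- len %/% 3L
    if (ncod < 2L) next
    starts <- seq.int(1L, by = 3L, length.out = ncod - 1L)  # exclude final
    codons <- substring(cds, starts, starts + 2L)
    stops[i] <- sum(codons %in% stop_set)
  }
  data.frame(gene = pcg$gene, strand = pcg$strand,
             asm_start = pcg$asm_start, asm_end = pcg$asm_end,
             detected = detected, frame_shift = frame_shift,
             internal_stops = stops,
             disrupted = stops > 0L | frame_shift %% 3L != 0L,
             stringsAsFactors = FALSE)
}
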