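# Independent oracles and small fixture builders used across the suite.
# Every oracle here is deliberately implemented on a different path from
# the package code it checks.

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# --- exhaustive alignment oracle -------------------------------------
# Memoized recursion over (ref index, query index, previous move); a gap
# column costs gap_open after a non-gap (or opposite-gap) move and
# gap_extend after a same-direction gap. Checks the Gotoh implementation
# on tiny strings by construction rather than by shared code.
brute_force_score <- function(ref, qry, scoring = scoring_scheme()) {
  r <- strsplit(ref, "", fixed = TRUE)[[1L]]
  q <- strsplit(qry, "", fixed = TRUE)[[1L]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    if (i == 0L && j == 0L) return(0)
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (r[i] == q[j]) scoring$match else scoring$mismatch
      best <- max(best, rec(i - 1L, j - 1L, "M") + s)
    }
    if (i > 0L) {
      g <- if (prev == "X") scoring$gap_extend else scoring$gap_open
      best <- max(best, rec(i - 1L, j, "X") + g)
    }
    if (j > 0L) {
      g <- if (prev == "Y") scoring$gap_extend else scoring$gap_open
      best <- max(best, rec(i, j - 1L, "Y") + g)
    }
    memo[[key]] <- best
    best
  }
  rec(length(r), length(q), "none")
}

# Biostrings cross-check with the equivalent penalty parameterization:
# its gap of length L costs gapOpening + L * gapExtension.
biostrings_score <- function(ref, qry, scoring = scoring_scheme()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref), Biostrings::DNAString(qry),
    substitutionMatrix = mat,
    gapOpening = -(scoring$gap_open - scoring$gap_extend),
    gapExtension = -scoring$gap_extend, type = "global"))
}

# --- p-distance column-scan oracle -----------------------------------
column_scan_pdist <- function(ref_row, asm_row) {
  r <- strsplit(ref_row, "", fixed = TRUE)[[1L]]
  a <- strsplit(asm_row, "", fixed = TRUE)[[1L]]
  comp <- 0L
  diff <- 0L
  for (i in seq_along(r)) {
    if (r[i] != "-" && a[i] != "-" && r[i] != "N" && a[i] != "N") {
      comp <- comp + 1L
      if (r[i] != a[i]) diff <- diff + 1L
    }
  }
  diff / comp
}

# --- exhaustive rotation oracle --------------------------------------
# Tries every rotation, minimizing the edit distance between the leading
# `w` bases of the rotated assembly and of the reference. An indel near
# the window regularly ties neighbouring offsets, so ties are resolved
# by full-length edit distance (which separates them: a displaced
# origin pays at both sequence ends), then by the smallest offset.
rotation_oracle <- function(asm_seq, ref_seq, w = 200L) {
  n <- nchar(asm_seq)
  w <- min(w, n, nchar(ref_seq))
  dbl <- paste0(asm_seq, asm_seq)
  windows <- substring(dbl, seq_len(n), seq_len(n) + w - 1L)
  d <- utils::adist(substr(ref_seq, 1L, w), windows)[1L, ]
  cand <- which(d == min(d)) - 1L
  if (length(cand) > 1L) {
    full <- vapply(cand, function(off)
      as.numeric(utils::adist(substr(dbl, off + 1L, off + n),
                              ref_seq)[1L, 1L]),
      numeric(1L))
    cand <- cand[full == min(full)]
  }
  cand[1L]
}

# --- homopolymer run-length scanner ----------------------------------
# Regex-based: fraction of bases inside runs of length >= 2.
regex_hp_fraction <- function(seq) {
  m <- gregexpr("(.)\\1+", seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(0)
  sum(attr(m, "match.length")) / nchar(seq)
}

# --- projection column-walk oracle -----------------------------------
# Walks alignment columns one at a time, tracking both coordinates.
column_walk_projection <- function(ref_row, asm_row, start, end) {
  r <- strsplit(ref_row, "", fixed = TRUE)[[1L]]
  a <- strsplit(asm_row, "", fixed = TRUE)[[1L]]
  ref_i <- 0L
  asm_i <- 0L
  asm_start <- NA_integer_
  asm_end <- NA_integer_
  for (col in seq_along(r)) {
    in_gene <- r[col] != "-" && ref_i >= start && ref_i < end
    if (in_gene && is.na(asm_start)) asm_start <- asm_i
    if (r[col] != "-") ref_i <- ref_i + 1L
    if (a[col] != "-") asm_i <- asm_i + 1L
    if (r[col] != "-" && ref_i == end) { asm_end <- asm_i; break }
  }
  if (is.na(asm_start)) asm_start <- asm_end
  c(start = asm_start, end = max(asm_end, asm_start))
}

# --- translation oracle ----------------------------------------------
# Counts internal stops via Biostrings translation under the vertebrate
# mitochondrial code (table 2), excluding the final complete codon.
translation_stop_oracle <- function(cds) {
  ncod <- nchar(cds) %/% 3L
  if (ncod < 2L) return(0L)
  trimmed <- substr(cds, 1L, 3L * ncod)
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(trimmed),
    genetic.code = Biostrings::getGeneticCode("2"))))
  sum(strsplit(substr(aa, 1L, ncod - 1L), "", fixed = TRUE)[[1L]] == "*")
}

# --- gap-placement shuffler ------------------------------------------
# Applies random legal right-shifts to gap runs of a normalized pair,
# producing score-equivalent alternative placements.
shuffle_gaps_right <- function(pair, n_shifts = 20L) {
  r <- strsplit(pair$ref_row, "", fixed = TRUE)[[1L]]
  a <- strsplit(pair$asm_row, "", fixed = TRUE)[[1L]]
  n <- length(r)
  for (s in seq_len(n_shifts)) {
    gapped <- if (s %% 2L == 0L) "r" else "a"
    g <- if (gapped == "r") r else a
    solid <- if (gapped == "r") a else r
    runs <- rle(g == "-")
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    idx <- which(runs$values)
    if (!length(idx)) next
    pick <- sample(idx, 1L)
    i <- starts[pick]
    j <- ends[pick]
    # right-shift legal iff next column ungapped in both rows and the
    # entering base equals the one leaving the aligned column
    if (j < n && g[j + 1L] != "-" && solid[j + 1L] != "-" &&
        solid[j + 1L] == solid[i]) {
      g[i] <- g[j + 1L]
      g[j + 1L] <- "-"
      if (gapped == "r") r <- g else a <- g
    }
  }
  aligned_pair(paste(r, collapse = ""), paste(a, collapse = ""),
               pair$score)
}

# --- small synthetic comparison --------------------------------------
# A compact genome + injected errors for module-level round trips.
small_benchmark <- function(genome_seed, error_seed,
                            counts = c(HP_INS_1 = 6, HP_DEL_1 = 3,
                                       SUBSTITUTION = 2, INS_1 = 2,
                                       DEL_1 = 2),
                            length = 3000L, rotate_by = 0L,
                            revcomp = FALSE) {
  gs <- genome_spec(length = length, n_pcg = 2L, n_trna = 4L, n_rrna = 1L,
                    seed = genome_seed)
  gen <- generate_reference(gs)
  inj <- inject_errors(gen$reference, error_spec(counts, seed = error_seed),
                       rotate_by = rotate_by, revcomp = revcomp)
  list(gen = gen, inj = inj)
}
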