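#' Specification of a synthetic mitogenome-like reference
#'
#' Describes the circular reference the simulator builds: a
#' vertebrate-mitogenome-like sequence (~16.7 kb, GC ~0.38) carrying 13
#' protein-coding genes, 22 tRNAs, 2 rRNAs and a control region, with a
#' controllable fraction of bases inside homopolymer runs of length
#' >= 2 - the substrate on which nanopore-like indel errors are placed.
#'
#' @param length Genome length in bp.
#' @param hp_fraction Target fraction of bases inside runs >= 2.
#' @param gc GC content in (0, 1).
#' @param n_pcg,n_trna,n_rrna Gene counts.
#' @param seed Integer seed (required; all simulator randomness is
#'   explicitly seeded).
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(length = 16705L, hp_fraction = 0.45, gc = 0.38,
                        n_pcg = 13L, n_trna = 22L, n_rrna = 2L, seed) {
  if (missing(seed)) stop("genome_spec requires an explicit seed")
  stopifnot(length >= 1000L, hp_fraction > 0, hp_fraction < 1,
            gc > 0, gc < 1, n_pcg >= 1L, n_trna >= 0L, n_rrna >= 0L)
  structure(list(length = as.integer(length), hp_fraction = hp_fraction,
                 gc = gc, n_pcg = as.integer(n_pcg),
                 n_trna = as.integer(n_trna), n_rrna = as.integer(n_rrna),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# canonical vertebrate mitochondrial gene complement used at the
# default counts: 13 PCGs (nad6 on the minus strand), 22 tRNAs, 2 rRNAs
default_pcg_lengths <- c(nad1 = 975L, nad2 = 1044L, cox1 = 1551L,
                         cox2 = 690L, atp8 = 168L, atp6 = 684L,
                         cox3 = 786L, nad3 = 348L, nad4l = 297L,
                         nad4 = 1380L, nad5 = 1836L, nad6 = 522L,
                         cob = 1140L)
default_minus_pcg <- "nad6"

non_stop_codons <- function() {
  all_codons <- as.vector(outer(outer(c("T", "C", "A", "G"),
                                      c("T", "C", "A", "G"), paste0),
                                c("T", "C", "A", "G"), paste0))
  setdiff(all_codons, vertebrate_mito_stops())
}

#' Generate a synthetic reference genome and gene track
#'
#' Builds a circular reference deterministically from a [genome_spec()]:
#' intergenic and structural-RNA sequence comes from a run-length
#' process tuned so the genome-wide fraction of bases inside
#' homopolymer runs >= 2 lands within +/-0.05 of the target;
#' protein-coding genes are overwritten with in-frame stop-free codons
#' (starting ATG, ending TAA; minus-strand genes are written as the
#' reverse complement of such a frame). No gene spans the circular
#' origin; the control region sits last and absorbs the residual
#' length.
#'
#' @param spec A [genome_spec()].
#' @return A list: `reference` (`circ_seq`, circular) and `annotations`
#'   (`data.frame` as from [read_annotations()]).
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  layout <- build_gene_layout(spec)
  target <- spec$hp_fraction
  f_bg <- target
  seq <- NULL
  realized <- NA_real_
  for (iter in 1:8) {
    cand <- render_genome(spec, layout, f_bg)
    realized <- hp_fraction_of(cand)
    if (abs(realized - target) <= 0.03) { seq <- cand; break }
    f_bg <- min(0.98, max(0.02, f_bg + (target - realized)))
  }
  if (is.null(seq)) {
    if (abs(realized - target) <= 0.05) {
      seq <- cand
    } else {
      stop("could not reach hp_fraction ", target, " (realized ",
           round(realized, 3), "); the protein-coding fraction bounds",
           " the achievable homopolymer content")
    }
  }
  ann <- data.frame(gene = layout$gene, start = layout$start,
                    end = layout$end, strand = layout$strand,
                    kind = layout$kind, stringsAsFactors = FALSE)
  ann <- ann[order(ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  ref <- circ_seq(seq, id = sprintf("synthetic_ref_seed%d", spec$seed),
                  topology = "circular")
  list(reference = ref, annotations = ann)
}

# Fraction of bases inside maximal runs of length >= 2.
hp_fraction_of <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1L]])
  sum(r$lengths[r$lengths >= 2L]) / sum(r$lengths)
}

# Gene order, lengths and strands; CR last, absorbing the remainder.
build_gene_layout <- function(spec) {
  if (spec$n_pcg == 13L && spec$n_trna == 22L && spec$n_rrna == 2L) {
    order_ <- c("trnF", "rrnS", "trnV", "rrnL", "trnL2", "nad1", "trnI",
                "trnQ", "trnM", "nad2", "trnW", "trnA", "trnN", "trnC",
                "trnY", "cox1", "trnS2", "trnD", "cox2", "trnK", "atp8",
                "atp6", "cox3", "trnG", "nad3", "trnR", "nad4l", "nad4",
                "trnH", "trnS1", "trnL1", "nad5", "nad6", "trnE", "cob",
                "trnT", "trnP")
    kind <- ifelse(order_ %in% names(default_pcg_lengths), "PCG",
                   ifelse(order_ %in% c("rrnS", "rrnL"), "rRNA", "tRNA"))
    minus <- c("trnQ", "trnA", "trnN", "trnC", "trnY", "trnS2", "nad6",
               "trnE", "trnP")
    strand <- ifelse(order_ %in% minus, "-", "+")
    len <- integer(length(order_))
    len[kind == "PCG"] <- default_pcg_lengths[order_[kind == "PCG"]]
    len[kind == "tRNA"] <- sample(66:74, sum(kind == "tRNA"),
                                  replace = TRUE)
    len[order_ == "rrnS"] <- 950L
    len[order_ == "rrnL"] <- 1560L
  } else {
    # generic complement for non-default counts: sized to the budget so
    # any sensible spec packs
    trna_len <- sample(66:74, spec$n_trna, replace = TRUE)
    rrna_len <- if (spec$n_rrna > 0L)
      pmin(sample(900:1600, spec$n_rrna, replace = TRUE),
           max(300L, (spec$length %/% 4L) %/% spec$n_rrna))
    else integer(0L)
    budget <- spec$length - 300L - sum(trna_len) - sum(rrna_len)
    per_pcg <- (budget * 85L) %/% (100L * spec$n_pcg)
    if (per_pcg < 90L)
      stop("genes cannot be packed into ", spec$length, " bp")
    pcg_len <- 3L * pmax(30L, floor(stats::runif(spec$n_pcg, 0.6, 1) *
                                      per_pcg / 3))
    order_ <- character(0L); kind <- character(0L); len <- integer(0L)
    pools <- list(PCG = as.integer(pcg_len),
                  tRNA = trna_len,
                  rRNA = rrna_len)
    counts <- c(PCG = spec$n_pcg, tRNA = spec$n_trna, rRNA = spec$n_rrna)
    idx <- c(PCG = 0L, tRNA = 0L, rRNA = 0L)
    while (any(idx < counts)) {
      for (k in c("tRNA", "rRNA", "PCG")) {
        if (idx[[k]] < counts[[k]]) {
          idx[[k]] <- idx[[k]] + 1L
          order_ <- c(order_, paste0(tolower(k), idx[[k]]))
          kind <- c(kind, k)
          len <- c(len, pools[[k]][idx[[k]]])
        }
      }
    }
    strand <- rep("+", length(order_))
    if (spec$n_pcg > 1L) strand[which(kind == "PCG")[spec$n_pcg]] <- "-"
  }
  spacers <- sample(0:3, length(order_), replace = TRUE)
  used <- sum(len) + sum(spacers)
  cr_len <- spec$length - used
  if (cr_len < 100L)
    stop("genes cannot be packed into ", spec$length,
         " bp (need >= ", used + 100L, ")")
  starts <- cumsum(c(0L, (len + spacers)[-length(len)])) + spacers
  # leading spacer before first gene comes out of the control region
  data.frame(gene = c(order_, "CR"),
             kind = c(kind, "CR"),
             strand = c(strand, "+"),
             start = c(starts, starts[length(starts)] +
                         len[length(len)]),
             end = c(starts + len, spec$length),
             stringsAsFactors = FALSE)
}

# Realize the genome: run-length background + stop-free PCG frames.
render_genome <- function(spec, layout, f_bg) {
  chars <- background_run_sequence(spec$length, f_bg, spec$gc)
  codons <- non_stop_codons()
  pcg <- layout[layout$kind == "PCG", , drop = FALSE]
  for (i in seq_len(nrow(pcg))) {
    len <- pcg$end[i] - pcg$start[i]
    ncod <- len %/% 3L
    body <- sample(codons, ncod - 2L, replace = TRUE)
    cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
    extra <- len - 3L * ncod  # lengths are multiples of 3 by construction
    if (extra > 0L)
      cds <- paste0(cds, paste(sample(c("A", "C", "G", "T"), extra,
                                      replace = TRUE), collapse = ""))
    if (pcg$strand[i] == "-") cds <- revcomp_string(cds)
    chars[(pcg$start[i] + 1L):pcg$end[i]] <-
      strsplit(cds, "", fixed = TRUE)[[1L]]
  }
  paste(chars, collapse = "")
}

# Run-length process: runs of length 1 with probability q, otherwise
# 2 + geometric; q solved so the expected fraction of bases inside
# runs >= 2 equals f. Run nucleotides avoid repeating their neighbour
# so runs stay maximal.
background_run_sequence <- function(n, f, gc) {
  p_geo <- 0.55
  mL <- 2 + (1 - p_geo) / p_geo
  q <- mL * (1 - f) / (f + mL * (1 - f))
  n_runs <- ceiling(n / (q + (1 - q) * mL)) + 200L
  lens <- ifelse(stats::runif(n_runs) < q, 1L,
                 2L + stats::rgeom(n_runs, p_geo))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  nts <- sample(names(probs), n_runs, replace = TRUE, prob = probs)
  # resample any run matching its left neighbour until none do
  repeat {
    clash <- which(nts[-1L] == nts[-n_runs]) + 1L
    if (!length(clash)) break
    nts[clash] <- sample(names(probs), length(clash), replace = TRUE,
                         prob = probs)
  }
  chars <- rep(nts, times = lens)
  while (length(chars) < n) {  # safety top-up
    extra <- background_run_sequence(1000L, f, gc)
    chars <- c(chars, extra)
  }
  chars[seq_len(n)]
}

#' Specification of errors to inject
#'
#' Requested per-category counts for [inject_errors()], e.g.
#' `error_spec(counts = c(HP_INS_1 = 40, HP_DEL_1 = 14), seed = 1)`.
#' Count-based injection keeps the ground truth exact; `min_spacing`
#' keeps events far enough apart that alignment cannot merge them - a
#' deliberate idealization relative to real nanopore error tracts.
#'
#' @param counts Named nonnegative integer vector over
#'   [error_categories()] names.
#' @param seed Integer seed (required).
#' @param min_spacing Minimum distance in bp between injected events.
#' @return An `error_spec` list.
#' @export
error_spec <- function(counts, seed, min_spacing = 10L) {
  if (missing(seed)) stop("error_spec requires an explicit seed")
  counts <- counts[counts > 0]
  if (length(counts)) {
    stopifnot(!is.null(names(counts)),
              all(names(counts) %in% error_categories()),
              all(counts == as.integer(counts)), all(counts >= 0))
  }
  structure(list(counts = if (length(counts))
    structure(as.integer(counts), names = names(counts)) else integer(0L),
    seed = as.integer(seed), min_spacing = as.integer(min_spacing)),
    class = "error_spec")
}

#' Inject classified errors into a reference genome
#'
#' Places each requested event at a sampled locus satisfying its
#' category's sequence context - homopolymer indels go to reference
#' runs >= 2 (drawn length-weighted, mirroring the empirical
#' concentration of nanopore errors at longer runs), single
#' non-homopolymer indels to isolated bases, substitutions anywhere -
#' subject to the spacing constraint and at most one event per
#' homopolymer run (two indels in one run would merge into a single
#' alignment event and make exact recovery ill-posed). Events are
#' recorded in reference coordinates as a replayable truth set, the
#' edits are applied, and the mutated sequence is finally rotated by
#' `rotate_by` and/or reverse-complemented, emulating an assembler's
#' arbitrary origin and strand choice.
#'
#' @param reference Reference `circ_seq`.
#' @param spec An [error_spec()].
#' @param rotate_by Left rotation applied to the mutated sequence.
#' @param revcomp Reverse-complement the (rotated) mutated sequence.
#' @param id Identifier for the output assembly.
#' @return A list: `assembly` (`circ_seq`), `truth` (`data.frame`:
#'   `category`, `type`, `ref_pos`, `length`, `bases`, in reference
#'   coordinates, pre-rotation), `rotate_by`, `revcomp`.
#' @export
inject_errors <- function(reference, spec, rotate_by = 0L,
                          revcomp = FALSE,
                          id = paste0(reference$id, "_mut")) {
  stopifnot(inherits(reference, "circ_seq"), inherits(spec, "error_spec"))
  L <- seq_length(reference)
  n_events <- sum(spec$counts)
  if (n_events * spec$min_spacing >= L)
    stop("requested ", n_events, " events at spacing ", spec$min_spacing,
         " exceed the reference length ", L)
  set.seed(spec$seed)
  refc <- strsplit(reference$seq, "", fixed = TRUE)[[1L]]
  rl <- rle(refc)
  run_end <- cumsum(rl$lengths)
  runs <- data.frame(start = run_end - rl$lengths,  # 0-based
                     len = rl$lengths, nt = rl$values,
                     stringsAsFactors = FALSE)
  st <- new.env(parent = emptyenv())
  st$spans <- matrix(numeric(0L), ncol = 2L)   # occupied [start,end] 0-based
  st$used_runs <- logical(nrow(runs))
  events <- list()
  cats <- intersect(error_categories(), names(spec$counts))
  for (cat in cats) {
    for (rep_i in seq_len(spec$counts[[cat]])) {
      ev <- place_event(cat, refc, runs, st, L, spec$min_spacing)
      events[[length(events) + 1L]] <- ev
    }
  }
  truth <- if (length(events)) {
    df <- do.call(rbind, events)
    df <- df[order(df$ref_pos), , drop = FALSE]
    rownames(df) <- NULL
    df
  } else {
    data.frame(category = character(), type = character(),
               ref_pos = integer(), length = integer(),
               bases = character(), stringsAsFactors = FALSE)
  }
  mutated <- apply_truth_events(reference$seq, truth)
  out <- rotate_string(mutated, rotate_by)
  if (revcomp) out <- revcomp_string(out)
  list(assembly = circ_seq(out, id = id, topology = "circular"),
       truth = truth, rotate_by = as.integer(rotate_by %% L),
       revcomp = revcomp)
}

# Sample one event of the given category; updates occupancy state.
place_event <- function(cat, refc, runs, st, L, min_spacing,
                        max_draws = 500L) {
  nts <- c("A", "C", "G", "T")
  parse_hp <- regmatches(cat, regexec("^HP_(INS|DEL)_(\\d+|GT7)$", cat))[[1L]]
  for (draw in seq_len(max_draws)) {
    if (length(parse_hp)) {
      k <- if (parse_hp[3L] == "GT7") 8L else as.integer(parse_hp[3L])
      need <- if (parse_hp[2L] == "DEL") k + 1L else 2L
      ok <- which(!st$used_runs & runs$len >= max(2L, need) &
                    runs$start > 0L & (runs$start + runs$len) < L)
      if (!length(ok))
        stop("no qualifying homopolymer run for ", cat,
             "; regenerate the reference or lower the request")
      ridx <- ok[sample.int(length(ok), 1L,
                            prob = runs$len[ok])]  # length-weighted
      pos <- runs$start[ridx]
      span <- c(runs$start[ridx] - 1L, runs$start[ridx] + runs$len[ridx])
      if (!spacing_ok(st$spans, span, min_spacing)) next
      st$used_runs[ridx] <- TRUE
      st$spans <- rbind(st$spans, span)
      type <- if (parse_hp[2L] == "INS") "insertion" else "deletion"
      return(data.frame(category = cat, type = type, ref_pos = pos,
                        length = k, bases = strrep(runs$nt[ridx], k),
                        stringsAsFactors = FALSE))
    }
    if (cat == "SUBSTITUTION") {
      pos <- sample.int(L - 2L, 1L)  # 0-based in [1, L-2]
      span <- c(pos - 1L, pos + 1L)
      if (!spacing_ok(st$spans, span, min_spacing)) next
      ridx <- run_at(runs, pos)
      if (st$used_runs[ridx]) next
      st$used_runs[ridx] <- TRUE
      st$spans <- rbind(st$spans, span)
      y <- sample(setdiff(nts, refc[pos + 1L]), 1L)
      return(data.frame(category = cat, type = "substitution",
                        ref_pos = pos, length = 1L, bases = y,
                        stringsAsFactors = FALSE))
    }
    if (cat == "INS_1") {
      pos <- sample.int(L - 2L, 1L)  # insertion point, 0-based
      cand <- setdiff(nts, c(refc[pos], refc[pos + 1L]))
      if (!length(cand)) next
      span <- c(pos - 1L, pos + 1L)
      if (!spacing_ok(st$spans, span, min_spacing)) next
      st$spans <- rbind(st$spans, span)
      return(data.frame(category = cat, type = "insertion", ref_pos = pos,
                        length = 1L, bases = sample(cand, 1L),
                        stringsAsFactors = FALSE))
    }
    if (cat == "DEL_1") {
      ok <- which(!st$used_runs & runs$len == 1L & runs$start > 0L &
                    (runs$start + 1L) < L)
      if (!length(ok))
        stop("no isolated base available for DEL_1")
      ridx <- ok[sample.int(length(ok), 1L)]
      pos <- runs$start[ridx]
      span <- c(pos - 1L, pos + 1L)
      if (!spacing_ok(st$spans, span, min_spacing)) next
      st$used_runs[ridx] <- TRUE
      st$spans <- rbind(st$spans, span)
      return(data.frame(category = cat, type = "deletion", ref_pos = pos,
                        length = 1L, bases = refc[pos + 1L],
                        stringsAsFactors = FALSE))
    }
    # short / long non-homopolymer indels
    k <- switch(cat, INS_SHORT = , DEL_SHORT = sample(2:4, 1L),
                INS_LONG = , DEL_LONG = sample(5:7, 1L),
                stop("unknown category: ", cat))
    if (cat %in% c("INS_SHORT", "INS_LONG")) {
      pos <- sample.int(L - 2L, 1L)
      s <- sample(nts, k, replace = TRUE)
      if (length(unique(s)) < 2L) next        # must not be mono
      if (s[k] == refc[pos]) next             # forbid left-shifting
      if (s[1L] == refc[pos + 1L]) next       # keep placement unambiguous
      span <- c(pos - 1L, pos + 1L)
      if (!spacing_ok(st$spans, span, min_spacing)) next
      st$spans <- rbind(st$spans, span)
      return(data.frame(category = cat, type = "insertion", ref_pos = pos,
                        length = k, bases = paste(s, collapse = ""),
                        stringsAsFactors = FALSE))
    }
    pos <- sample.int(L - k - 2L, 1L)  # deletion window [pos, pos+k)
    win <- refc[(pos + 1L):(pos + k)]
    if (length(unique(win)) < 2L) next
    if (refc[pos] == win[k]) next             # forbid left-shifting
    if (pos + k < L && refc[pos + k + 1L] == win[1L]) next
    span <- c(pos - 1L, pos + k)
    if (!spacing_ok(st$spans, span, min_spacing)) next
    touched <- which(runs$start < (pos + k) &
                       (runs$start + runs$len) > pos)
    if (any(st$used_runs[touched])) next
    st$used_runs[touched] <- TRUE
    st$spans <- rbind(st$spans, span)
    return(data.frame(category = cat, type = "deletion", ref_pos = pos,
                      length = k, bases = paste(win, collapse = ""),
                      stringsAsFactors = FALSE))
  }
  stop("could not place a ", cat, " event after ", max_draws,
       " draws; the genome lacks the required context - regenerate the",
       " reference or relax the spec")
}

run_at <- function(runs, pos) {
  findInterval(pos, runs$start)
}

spacing_ok <- function(spans, span, min_spacing) {
  if (!nrow(spans)) return(TRUE)
  all(span[1L] - spans[, 2L] >= min_spacing |
        spans[, 1L] - span[2L] >= min_spacing)
}

#' Replay a truth set against a reference sequence
#'
#' Applies recorded events (insertions, deletions, substitutions in
#' reference coordinates) to a reference string, reproducing the
#' mutated sequence exactly. Used internally by [inject_errors()] and
#' as the replay check in validation.
#'
#' @param ref_seq Reference nucleotide string.
#' @param truth Truth `data.frame` from [inject_errors()].
#' @return The mutated sequence string.
#' @export
apply_truth_events <- function(ref_seq, truth) {
  stopifnot(is.character(ref_seq), length(ref_seq) == 1L)
  if (!nrow(truth)) return(ref_seq)
  ord <- order(truth$ref_pos, decreasing = TRUE)
  s <- ref_seq
  for (i in ord) {
    p <- truth$ref_pos[i]
    type <- truth$type[i]
    if (type == "insertion") {
      s <- paste0(substr(s, 1L, p), truth$bases[i],
                  substr(s, p + 1L, nchar(s)))
    } else if (type == "deletion") {
      s <- paste0(substr(s, 1L, p),
                  substr(s, p + truth$length[i] + 1L, nchar(s)))
    } else {
      substr(s, p + 1L, p + 1L) <- truth$bases[i]
    }
  }
  s
}

#' Truth profile of an injected error set
#'
#' @param truth Truth `data.frame` from [inject_errors()].
#' @return The `error_profile` implied by the recorded categories.
#' @export
truth_profile <- function(truth) {
  error_profile(data.frame(category = truth$category,
                           stringsAsFactors = FALSE))
}
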