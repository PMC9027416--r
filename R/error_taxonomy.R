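#' Error taxonomy categories
#'
#' The classification vocabulary for assembly-vs-reference discordances:
#' homopolymer insertions and deletions of 1-7 bases (`HP_INS_1` ...
#' `HP_INS_7`, `HP_DEL_1` ... `HP_DEL_7`), `SUBSTITUTION`, single and
#' short (2-4 bp) non-homopolymer indels (`INS_1`, `INS_SHORT`, `DEL_1`,
#' `DEL_SHORT`), plus extension categories that make the classifier
#' total: `INS_LONG` / `DEL_LONG` (>= 5 bp non-homopolymer) and
#' `HP_INS_GT7` / `HP_DEL_GT7` (homopolymer runs of more than 7 bases).
#' The extension categories fall outside the published taxonomy and are
#' flagged as such in reports.
#'
#' @return Character vector of all category names, in canonical order.
#' @export
error_categories <- function() {
  c(paste0("HP_INS_", 1:7), paste0("HP_DEL_", 1:7),
    "SUBSTITUTION", "INS_1", "INS_SHORT", "DEL_1", "DEL_SHORT",
    "INS_LONG", "DEL_LONG", "HP_INS_GT7", "HP_DEL_GT7")
}

# categories outside the published vocabulary
extension_categories <- c("INS_LONG", "DEL_LONG", "HP_INS_GT7", "HP_DEL_GT7")

#' Extract discordance events from a normalized alignment
#'
#' Scans a gap-normalized alignment column by column and emits one
#' carrier event per discordance: one insertion per maximal run of gap
#' columns in the reference row, one deletion per maximal run of gap
#' columns in the assembly row, and one substitution per mismatching
#' ungapped column (adjacent mismatch columns stay separate events).
#' Columns containing `N` in either row are skipped unless
#' `count_ambiguous` is set, in which case an N-mismatch column becomes
#' a substitution carrier.
#'
#' Reference coordinates are 0-based: a deletion's `ref_pos` is the left
#' edge of the deleted reference segment; an insertion's `ref_pos` is
#' the reference coordinate immediately following the gap run.
#'
#' @param pair A gap-normalized `aligned_pair` (see [normalize_gaps()];
#'   non-normalized input is rejected).
#' @param count_ambiguous Count N-mismatch columns as substitutions
#'   (default `FALSE`: N columns are ignored).
#' @return A `data.frame` of carrier events ordered by `ref_pos`:
#'   columns `type` (`insertion`/`deletion`/`substitution`), `ref_pos`,
#'   `length`, `bases`.
#' @export
extract_events <- function(pair, count_ambiguous = FALSE) {
  stopifnot(inherits(pair, "aligned_pair"))
  renorm <- normalize_gaps(pair)
  if (!identical(renorm$ref_row, pair$ref_row) ||
      !identical(renorm$asm_row, pair$asm_row))
    stop("alignment is not gap-normalized; run normalize_gaps() first")
  pc <- pair_chars(pair)
  r <- pc$r
  a <- pc$a
  ref_before <- cumsum(r != "-") - (r != "-")  # 0-based ref coord entering col
  ev <- list()
  # insertion runs: gaps in reference row
  ins <- runs_of(r == "-")
  if (nrow(ins)) {
    ev[[length(ev) + 1L]] <- data.frame(
      type = "insertion",
      ref_pos = ref_before[ins$start],
      length = ins$end - ins$start + 1L,
      bases = vapply(seq_len(nrow(ins)), function(k)
        paste(a[ins$start[k]:ins$end[k]], collapse = ""), character(1L)),
      stringsAsFactors = FALSE)
  }
  del <- runs_of(a == "-")
  if (nrow(del)) {
    ev[[length(ev) + 1L]] <- data.frame(
      type = "deletion",
      ref_pos = ref_before[del$start],
      length = del$end - del$start + 1L,
      bases = vapply(seq_len(nrow(del)), function(k)
        paste(r[del$start[k]:del$end[k]], collapse = ""), character(1L)),
      stringsAsFactors = FALSE)
  }
  solid <- r != "-" & a != "-"
  has_n <- r == "N" | a == "N"
  mism <- which(solid & r != a & if (count_ambiguous) TRUE else !has_n)
  if (length(mism)) {
    ev[[length(ev) + 1L]] <- data.frame(
      type = "substitution",
      ref_pos = ref_before[mism],
      length = 1L,
      bases = a[mism],
      stringsAsFactors = FALSE)
  }
  if (!length(ev)) {
    return(data.frame(type = character(), ref_pos = integer(),
                      length = integer(), bases = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, ev)
  out <- out[order(out$ref_pos, match(out$type,
                                      c("deletion", "substitution",
                                        "insertion"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# maximal runs of TRUE in a logical vector -> data.frame(start, end)
runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Classify discordance events
#'
#' Assigns each carrier event from [extract_events()] its taxonomy
#' category, applied in order:
#' 1. a substitution column is `SUBSTITUTION`;
#' 2. an indel whose bases are all one nucleotide `x`, with a qualifying
#'    reference homopolymer run of `x` (for deletions, the run
#'    containing the deleted bases; for insertions, the run adjacent to
#'    the insertion point), is a homopolymer indel `HP_INS_k` /
#'    `HP_DEL_k` (`k` = event length, or the `GT7` bucket past 7);
#' 3. a remaining length-1 indel is `INS_1` / `DEL_1`;
#' 4. length 2-4 is `INS_SHORT` / `DEL_SHORT`;
#' 5. anything longer is `INS_LONG` / `DEL_LONG`.
#'
#' Under the default `hp_criterion = "reference-run"` a run qualifies
#' when it spans at least 2 bases in the reference, before the edit: the
#' reference is the ground truth, so inserting an `A` next to a lone `A`
#' is a plain `INS_1`. The alternative reading, `"resulting-run"`,
#' asks whether the run in the corrected (assembly) sequence reaches 2
#' bases: an insertion then qualifies when the adjacent reference run
#' plus the inserted bases spans >= 2 with at least one matching
#' reference neighbour; deletions are judged on the reference run under
#' both settings.
#'
#' @param events Carrier `data.frame` from [extract_events()].
#' @param reference The reference `circ_seq` the alignment was built
#'   against.
#' @param hp_criterion `"reference-run"` (default) or `"resulting-run"`.
#' @return The events `data.frame` with columns `category`,
#'   `hp_nucleotide`, `hp_run_len` added (the latter two `NA` for
#'   non-homopolymer events).
#' @export
classify_events <- function(events, reference,
                            hp_criterion = c("reference-run",
                                             "resulting-run")) {
  stopifnot(is.data.frame(events), inherits(reference, "circ_seq"))
  hp_criterion <- match.arg(hp_criterion)
  n <- nrow(events)
  category <- character(n)
  hp_nt <- rep(NA_character_, n)
  hp_len <- rep(NA_integer_, n)
  refc <- strsplit(reference$seq, "", fixed = TRUE)[[1L]]
  for (i in seq_len(n)) {
    type <- events$type[i]
    len <- events$length[i]
    bases <- events$bases[i]
    if (type == "substitution") {
      category[i] <- "SUBSTITUTION"
      next
    }
    x <- unique(strsplit(bases, "", fixed = TRUE)[[1L]])
    is_mono <- length(x) == 1L && x != "N"
    hp <- FALSE
    if (is_mono) {
      run_len <- ref_run_length(refc, events$ref_pos[i], len, type, x)
      if (hp_criterion == "reference-run") {
        hp <- run_len >= 2L
      } else if (type == "deletion") {
        hp <- run_len >= 2L
      } else {
        hp <- run_len >= 1L && (run_len + len) >= 2L
      }
      if (hp) {
        hp_nt[i] <- x
        hp_len[i] <- run_len
      }
    }
    stem <- if (type == "insertion") "INS" else "DEL"
    category[i] <- if (hp) {
      if (len <= 7L) paste0("HP_", stem, "_", len)
      else paste0("HP_", stem, "_GT7")
    } else if (len == 1L) {
      paste0(stem, "_1")
    } else if (len <= 4L) {
      paste0(stem, "_SHORT")
    } else {
      paste0(stem, "_LONG")
    }
  }
  events$category <- category
  events$hp_nucleotide <- hp_nt
  events$hp_run_len <- hp_len
  events
}

# Length of the maximal reference run of nucleotide x relevant to an
# indel event: for deletions, the run containing reference positions
# [pos, pos+len); for insertions, the run touching the insertion point
# (positions pos-1 and pos are contiguous when both are x).
ref_run_length <- function(refc, pos, len, type, x) {
  n <- length(refc)
  if (type == "deletion") {
    lo <- pos + 1L          # 1-based first deleted base
    hi <- pos + len         # 1-based last deleted base
  } else {
    lo <- pos + 1L          # 1-based base at the insertion point
    hi <- pos               # and the one before it
    # seed the scan from whichever neighbour matches x
    if (lo <= n && refc[lo] == x) hi <- lo
    else if (pos >= 1L && refc[pos] == x) { lo <- pos; hi <- pos }
    else return(0L)
  }
  while (lo > 1L && refc[lo - 1L] == x) lo <- lo - 1L
  while (hi < n && refc[hi + 1L] == x) hi <- hi + 1L
  hi - lo + 1L
}

#' Tally classified events into an error profile
#'
#' @param events Classified events (see [classify_events()]).
#' @return An `error_profile`: named per-category counts over
#'   [error_categories()] and `total` (each event counts once,
#'   regardless of its length in bases).
#' @export
error_profile <- function(events) {
  stopifnot(is.data.frame(events))
  if (nrow(events) && !"category" %in% names(events))
    stop("events are unclassified; run classify_events() first")
  cats <- error_categories()
  counts <- structure(integer(length(cats)), names = cats)
  if (nrow(events)) {
    tab <- table(factor(events$category, levels = cats))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, total = sum(counts)),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  nz <- x$counts[x$counts > 0L]
  cat(sprintf("<error_profile> total %d\n", x$total))
  if (length(nz)) {
    flagged <- ifelse(names(nz) %in% extension_categories, " *", "")
    cat(paste0("  ", names(nz), ": ", nz, flagged, collapse = "\n"), "\n")
    if (any(names(nz) %in% extension_categories))
      cat("  (* outside the published taxonomy)\n")
  }
  invisible(x)
}

#' Compare an assembly with a reference end to end
#'
#' Convenience wrapper over the whole benchmarking chain for a single
#' assembly: circular normalization, global alignment, gap
#' normalization, event extraction and classification, profile, and
#' p-distance.
#'
#' @param assembly,reference `circ_seq` objects.
#' @param config A [run_config()] (scoring, taxonomy and distance
#'   switches).
#' @return A list: `norm` (`normalization`), `pair` (normalized
#'   `aligned_pair`), `events` (classified), `profile`
#'   (`error_profile`), `p_dist`.
#' @export
compare_to_reference <- function(assembly, reference,
                                 config = run_config()) {
  norm <- normalize_assembly(assembly, reference, k = config$k,
                             anchor_len = config$anchor_len,
                             scoring = config$scoring)
  pair <- global_align(reference, norm$sequence, scoring = config$scoring,
                       max_cells = config$max_cells)
  pair <- normalize_gaps(pair)
  events <- extract_events(pair, count_ambiguous = config$count_ambiguous)
  events <- classify_events(events, reference,
                            hp_criterion = config$hp_criterion)
  list(norm = norm, pair = pair, events = events,
       profile = error_profile(events),
       p_dist = p_distance(pair, gap_convention = config$gap_convention))
}
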