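#' Benchmark run configuration
#'
#' Bundles every switch the pipeline exposes, with the defaults owned
#' by the respective stages: alignment scoring, the p-distance gap
#' convention, the homopolymer criterion, ambiguous-base counting, and
#' the normalization word/anchor sizes. A configuration round-trips
#' losslessly through a flat `key = value` text file
#' ([write_run_config()] / [read_run_config()]), and every report
#' carries a fingerprint of the configuration that produced it.
#'
#' @param scoring A [scoring_scheme()].
#' @param gap_convention `"pairwise-deletion"` or `"gaps-as-difference"`
#'   (see [p_distance()]).
#' @param hp_criterion `"reference-run"` or `"resulting-run"` (see
#'   [classify_events()]).
#' @param count_ambiguous Count N-mismatch columns as substitutions.
#' @param k Orientation-detection word size.
#' @param anchor_len Rotation anchor length.
#' @param max_cells Alignment size guard.
#' @return A `run_config` object.
#' @export
run_config <- function(scoring = scoring_scheme(),
                       gap_convention = c("pairwise-deletion",
                                          "gaps-as-difference"),
                       hp_criterion = c("reference-run", "resulting-run"),
                       count_ambiguous = FALSE,
                       k = 15L, anchor_len = 31L, max_cells = 1e9) {
  structure(list(scoring = scoring,
                 gap_convention = match.arg(gap_convention),
                 hp_criterion = match.arg(hp_criterion),
                 count_ambiguous = isTRUE(count_ambiguous),
                 k = as.integer(k), anchor_len = as.integer(anchor_len),
                 max_cells = max_cells),
            class = "run_config")
}

config_to_pairs <- function(config) {
  c(match = config$scoring$match, mismatch = config$scoring$mismatch,
    gap_open = config$scoring$gap_open,
    gap_extend = config$scoring$gap_extend,
    gap_convention = config$gap_convention,
    hp_criterion = config$hp_criterion,
    count_ambiguous = tolower(as.character(config$count_ambiguous)),
    k = config$k, anchor_len = config$anchor_len,
    max_cells = format(config$max_cells, scientific = FALSE))
}

#' Write a configuration file
#' @param config A [run_config()].
#' @param path Output path (flat `key = value` lines).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  pairs <- config_to_pairs(config)
  writeLines(paste(names(pairs), pairs, sep = " = "), path)
  invisible(path)
}

#' Read a configuration file
#' @param path Path written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, character(1L), 1L)
  vals <- vapply(kv, `[[`, character(1L), 2L)
  g <- function(key, default) if (key %in% keys) vals[[match(key, keys)]]
    else default
  run_config(
    scoring = scoring_scheme(match = as.numeric(g("match", 2)),
                             mismatch = as.numeric(g("mismatch", -3)),
                             gap_open = as.numeric(g("gap_open", -5)),
                             gap_extend = as.numeric(g("gap_extend", -2))),
    gap_convention = g("gap_convention", "pairwise-deletion"),
    hp_criterion = g("hp_criterion", "reference-run"),
    count_ambiguous = g("count_ambiguous", "false") == "true",
    k = as.integer(g("k", 15L)),
    anchor_len = as.integer(g("anchor_len", 31L)),
    max_cells = as.numeric(g("max_cells", 1e9)))
}

#' Fingerprint of a configuration
#'
#' 32-bit FNV-1a hash over the serialized configuration, so any report
#' line is traceable to the exact settings that produced it.
#'
#' @param config A [run_config()].
#' @return An 8-character hexadecimal string.
#' @export
config_fingerprint <- function(config) {
  pairs <- config_to_pairs(config)
  bytes <- utf8ToInt(paste(names(pairs), pairs, sep = "=",
                           collapse = ";"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- bitwXor(h %% 2^31, b) + (h - h %% 2^31)  # xor low bits only
    # multiply mod 2^32 in two halves to stay inside double precision
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Benchmark assemblies against a reference
#'
#' The batch entry point: compares each candidate assembly with the
#' reference (normalization, alignment, error taxonomy, p-distance,
#' and - when annotations are given - the ORF audit) and writes the
#' report set under `out_dir`:
#' \itemize{
#'   \item `report.tsv` - one row per assembly (name, contig status,
#'     length, coverage, p-distance, total errors, orientation,
#'     rotation offset, disrupted genes), with aggregate statistics as
#'     `#`-prefixed footer lines when two or more assemblies succeed;
#'   \item `events_<name>.tsv` - per-event dump (category, length,
#'     1-based reference position, bases, homopolymer context);
#'   \item `profile_<name>.json` - per-category counts and total;
#'   \item `gene_audit_<name>.tsv` - per-PCG audit, when annotated.
#' }
#' A failure on one assembly (orientation tie, rotation failure,
#' degenerate alignment) is reported and recorded without aborting the
#' batch.
#'
#' @param reference Path to a single-record reference FASTA, or a
#'   `circ_seq`.
#' @param assemblies Character vector of assembly FASTA paths (each may
#'   hold several records), or a list of `circ_seq` objects.
#' @param annotations Optional annotation TSV path or `data.frame`.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   file output.
#' @param config A [run_config()].
#' @return Invisibly, a list with `reports` (list of
#'   `assembly_report`), `failures` (named character vector of error
#'   messages), `aggregate` (`aggregate_stats` or `NULL`), `audits`.
#' @export
compare_assemblies <- function(reference, assemblies, annotations = NULL,
                               out_dir = NULL, config = run_config()) {
  if (is.character(reference)) {
    refs <- read_fasta(reference)
    if (length(refs) != 1L)
      stop("reference FASTA must contain exactly one record, found ",
           length(refs))
    reference <- refs[[1L]]
  }
  if (is.character(assemblies)) {
    asms <- list()
    for (path in assemblies) {
      if (!file.exists(path))
        stop("assembly file not found: ", path)
      asms <- c(asms, read_fasta(path))
    }
    assemblies <- asms
  } else if (inherits(assemblies, "circ_seq")) {
    assemblies <- list(assemblies)
  }
  if (is.character(annotations))
    annotations <- read_annotations(annotations, seq_length(reference))
  fp <- config_fingerprint(config)
  message("mitobench compare: ", length(assemblies),
          " assemblies, config ", fp)
  reports <- list()
  audits <- list()
  failures <- character(0L)
  for (asm in assemblies) {
    res <- tryCatch(compare_to_reference(asm, reference, config = config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[asm$id]] <- conditionMessage(res)
      message("  ", asm$id, ": FAILED (", conditionMessage(res), ")")
      next
    }
    report <- summarize_assembly(asm$id, res$norm, res$pair, res$profile,
                                 gap_convention = config$gap_convention)
    if (!is.null(annotations)) {
      proj <- project_annotations(res$pair, annotations)
      audit <- audit_orfs(res$norm$sequence, proj)
      report$disrupted_genes <- audit$gene[audit$disrupted]
      audits[[asm$id]] <- audit
    }
    reports[[asm$id]] <- report
    message(sprintf("  %s: p-dist %.6g, %d errors [config %s]",
                    asm$id, report$p_dist, report$profile$total, fp))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      safe <- gsub("[^A-Za-z0-9._-]", "_", asm$id)
      write_events_tsv(res$events,
                       file.path(out_dir, paste0("events_", safe, ".tsv")))
      jsonlite::write_json(
        c(as.list(res$profile$counts), list(total = res$profile$total)),
        file.path(out_dir, paste0("profile_", safe, ".json")),
        auto_unbox = TRUE, pretty = TRUE)
      if (!is.null(annotations))
        utils::write.table(audits[[asm$id]],
                           file.path(out_dir,
                                     paste0("gene_audit_", safe, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  agg <- if (length(reports) >= 2L)
    aggregate_errors(vapply(reports, function(r) r$profile$total,
                            numeric(1L)))
  else NULL
  if (!is.null(out_dir) && length(reports))
    write_report_tsv(reports, file.path(out_dir, "report.tsv"),
                     aggregate = agg, fingerprint = fp)
  invisible(list(reports = reports, failures = failures, aggregate = agg,
                 audits = audits))
}

# Events TSV: 1-based reference positions in human-readable output.
write_events_tsv <- function(events, path) {
  out <- data.frame(category = events$category, length = events$length,
                    ref_pos = events$ref_pos + 1L, bases = events$bases,
                    hp_nucleotide = events$hp_nucleotide,
                    hp_run_len = events$hp_run_len,
                    outside_taxonomy = events$category %in%
                      extension_categories,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_report_tsv <- function(reports, path, aggregate = NULL,
                             fingerprint = NULL) {
  rows <- do.call(rbind, lapply(reports, report_row))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(fingerprint))
    writeLines(paste0("# mitobench report; config ", fingerprint), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(aggregate)) {
    writeLines(sprintf(
      "# aggregate: n = %d, mean_errors = %.2f, sd_errors = %.2f, min_errors = %g, max_errors = %g",
      aggregate$n, aggregate$mean_errors, aggregate$sd_errors,
      aggregate$min_errors, aggregate$max_errors), con)
  }
  invisible(path)
}

#' Read a report TSV written by [compare_assemblies()]
#' @param path Report path.
#' @return The report rows as a `data.frame` (footer comments dropped).
#' @export
read_report_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Aggregate error totals across report files
#'
#' @param report_paths Two or more report TSVs (see
#'   [compare_assemblies()]); their rows are pooled.
#' @return An `aggregate_stats` over all per-assembly error totals.
#' @export
aggregate_reports <- function(report_paths) {
  if (!length(report_paths))
    stop("need at least one report file")
  totals <- unlist(lapply(report_paths, function(p)
    read_report_tsv(p)$errors))
  aggregate_errors(totals)
}

#' Simulate a benchmark data set
#'
#' Writes the four synthetic outputs to `out_dir`: reference FASTA,
#' annotation TSV, mutated-assembly FASTA, and the truth set as JSON.
#' The generating seeds are echoed into the FASTA headers.
#'
#' @param gspec A [genome_spec()].
#' @param espec An [error_spec()].
#' @param out_dir Output directory.
#' @param rotate_by,revcomp Passed to [inject_errors()].
#' @return Invisibly, a list: `reference`, `annotations`, `assembly`,
#'   `truth`, `paths`.
#' @export
simulate_assembly <- function(gspec, espec, out_dir, rotate_by = 0L,
                              revcomp = FALSE) {
  gen <- generate_reference(gspec)
  inj <- inject_errors(gen$reference, espec, rotate_by = rotate_by,
                       revcomp = revcomp)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- gen$reference
  ref$id <- paste0(ref$id, " genome_seed=", gspec$seed)
  asm <- inj$assembly
  asm$id <- paste0(asm$id, " genome_seed=", gspec$seed,
                   " error_seed=", espec$seed)
  paths <- list(reference = file.path(out_dir, "reference.fasta"),
                annotations = file.path(out_dir, "annotations.tsv"),
                assembly = file.path(out_dir, "assembly.fasta"),
                truth = file.path(out_dir, "truth.json"))
  write_fasta(ref, paths$reference)
  write_annotations(gen$annotations, paths$annotations,
                    chrom = gen$reference$id)
  write_fasta(asm, paths$assembly)
  jsonlite::write_json(list(seed = espec$seed,
                            rotate_by = inj$rotate_by,
                            revcomp = inj$revcomp,
                            events = inj$truth),
                       paths$truth, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  message("simulated ", seq_length(gen$reference), " bp reference, ",
          nrow(inj$truth), " injected events -> ", out_dir)
  invisible(list(reference = gen$reference,
                 annotations = gen$annotations,
                 assembly = inj$assembly, truth = inj$truth,
                 paths = paths))
}
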