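#' Uncorrected p-distance of an aligned pair
#'
#' Proportion of comparable alignment columns at which the two rows
#' differ. Under the default pairwise-deletion convention a column is
#' comparable when both rows carry a non-gap, non-N base, mirroring the
#' behaviour of desktop phylogenetics suites; identical sequences give
#' exactly 0. The `"gaps-as-difference"` switch instead keeps single-gap
#' columns in the denominator and counts each as a difference (columns
#' with `N` stay excluded); with indel-dominated discordance the two
#' conventions differ materially, so the choice is exposed.
#'
#' @param pair An `aligned_pair`.
#' @param gap_convention `"pairwise-deletion"` (default) or
#'   `"gaps-as-difference"`.
#' @return The p-distance in `[0, 1]`.
#' @examples
#' p_distance(aligned_pair("AC-GT", "ACTGA"))  # 1 mismatch / 4 sites
#' @export
p_distance <- function(pair, gap_convention = c("pairwise-deletion",
                                                "gaps-as-difference")) {
  stopifnot(inherits(pair, "aligned_pair"))
  gap_convention <- match.arg(gap_convention)
  pc <- pair_chars(pair)
  r <- pc$r
  a <- pc$a
  no_n <- r != "N" & a != "N"
  solid <- r != "-" & a != "-" & no_n
  diffs <- sum(r[solid] != a[solid])
  comparable <- sum(solid)
  if (gap_convention == "gaps-as-difference") {
    gapcols <- sum((xor(r == "-", a == "-")) & no_n)
    diffs <- diffs + gapcols
    comparable <- comparable + gapcols
  }
  if (comparable == 0L)
    stop("degenerate alignment: no comparable columns")
  diffs / comparable
}

#' Build a per-assembly benchmark report row
#'
#' Collects one assembly's benchmark into a report object shaped like a
#' row of a published accuracy table: name, contig status, ungapped
#' length, pass-through coverage, p-distance, error profile, plus the
#' normalization provenance (orientation, rotation offset). The
#' disrupted-gene list stays empty until [audit_orfs()] results are
#' attached.
#'
#' @param name Assembly display name.
#' @param norm The `normalization` result for this assembly.
#' @param pair The normalized `aligned_pair` used for its metrics.
#' @param profile Its `error_profile`.
#' @param gap_convention Passed to [p_distance()].
#' @return An `assembly_report` object.
#' @export
summarize_assembly <- function(name, norm, pair, profile,
                               gap_convention = "pairwise-deletion") {
  stopifnot(inherits(norm, "normalization"),
            inherits(pair, "aligned_pair"),
            inherits(profile, "error_profile"))
  asm_len <- nchar(gsub("-", "", pair$asm_row, fixed = TRUE))
  stopifnot(asm_len == seq_length(norm$sequence))
  structure(list(name = name,
                 circular = norm$sequence$topology == "circular",
                 length = asm_len,
                 coverage = norm$sequence$coverage,
                 p_dist = p_distance(pair, gap_convention = gap_convention),
                 profile = profile,
                 orientation = norm$orientation,
                 rotation_offset = norm$rotation_offset,
                 disrupted_genes = character(0L)),
            class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf(
    "<assembly_report> %s: %s, %d bp, p-dist %.6g, %d errors\n",
    x$name, if (x$circular) "circular" else "linear", x$length,
    x$p_dist, x$profile$total))
  if (length(x$disrupted_genes))
    cat("  disrupted PCGs:", paste(x$disrupted_genes, collapse = ", "),
        "\n")
  invisible(x)
}

# One human-readable TSV row per report (1-based/percent-free, '.' decimals).
report_row <- function(x) {
  data.frame(assembly = x$name,
             contigs = if (x$circular) "circular" else "linear",
             length_bp = x$length,
             coverage = if (is.null(x$coverage)) NA_real_ else x$coverage,
             p_dist = x$p_dist,
             errors = x$profile$total,
             orientation = x$orientation,
             rotation_offset = x$rotation_offset,
             disrupted_genes = paste(x$disrupted_genes, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Aggregate error totals across assemblies
#'
#' Mean, sample standard deviation (n-1 denominator), minimum and
#' maximum of per-assembly error totals. Values are kept at full
#' precision; round only at presentation time.
#'
#' @param totals Integer vector of per-assembly error totals (length
#'   >= 2, since the sample SD is undefined below that).
#' @return An `aggregate_stats` list: `n`, `mean_errors`, `sd_errors`,
#'   `min_errors`, `max_errors`.
#' @examples
#' aggregate_errors(load_table1_fixture()$errors)
#' @export
aggregate_errors <- function(totals) {
  totals <- as.numeric(totals)
  if (length(totals) < 2L)
    stop("need at least 2 error totals for aggregate statistics")
  if (any(!is.finite(totals)) || any(totals < 0))
    stop("error totals must be finite and nonnegative")
  structure(list(n = length(totals),
                 mean_errors = mean(totals),
                 sd_errors = stats::sd(totals),
                 min_errors = min(totals),
                 max_errors = max(totals)),
            class = "aggregate_stats")
}

#' @export
print.aggregate_stats <- function(x, ...) {
  cat(sprintf(
    "<aggregate_stats> n = %d: mean [S.D.] = %.2f +/- %.2f, range = %g-%g\n",
    x$n, x$mean_errors, x$sd_errors, x$min_errors, x$max_errors))
  invisible(x)
}
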