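#' Read FASTA into circular-sequence records
#'
#' Reads a (multi-record) FASTA file. Sequences are uppercased, `U` is
#' mapped to `T`, and IUPAC ambiguity codes other than `N` collapse to
#' `N`. Topology is taken from the header: a record is circular when its
#' description contains the token `circular=true`, linear otherwise.
#' A `coverage=<x>` token, if present, is carried as coverage metadata.
#'
#' @param path Path to a FASTA file.
#' @return A list of [circ_seq] records, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L)
    stop("FASTA file is empty: ", path)
  headers <- names(recs)
  lapply(seq_along(recs), function(i) {
    header <- headers[[i]]
    toks <- strsplit(trimws(header), "[ \t]+")[[1L]]
    id <- toks[[1L]]
    topology <- if (any(toks == "circular=true")) "circular" else "linear"
    cov <- NULL
    covtok <- grep("^coverage=", toks, value = TRUE)
    if (length(covtok))
      cov <- as.numeric(sub("^coverage=", "", covtok[[1L]]))
    circ_seq(as.character(recs[[i]]), id = id, topology = topology,
             coverage = cov)
  })
}

#' Write circular-sequence records to FASTA
#'
#' Headers carry the topology as a `circular=true` token (omitted for
#' linear records) and coverage metadata as `coverage=<x>` when present,
#' so [read_fasta()] round-trips both. Sequences are wrapped at 70
#' columns.
#'
#' @param seqs A `circ_seq` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "circ_seq")) seqs <- list(seqs)
  stopifnot(all(vapply(seqs, inherits, logical(1L), "circ_seq")))
  headers <- vapply(seqs, function(s) {
    h <- s$id
    if (s$topology == "circular") h <- paste0(h, " circular=true")
    if (!is.null(s$coverage)) h <- paste0(h, " coverage=", s$coverage)
    h
  }, character(1L))
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, character(1L), "seq"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

annotation_kinds <- c("PCG", "tRNA", "rRNA", "CR")

#' Read a gene annotation track
#'
#' Parses a BED-like, tab-separated, 6-column annotation file:
#' `chrom  start  end  gene  kind  strand`, with 0-based half-open
#' coordinates on the reference, `kind` one of `PCG`, `tRNA`, `rRNA`,
#' `CR`, and strand `+` or `-`. Intervals spanning the circular origin
#' are not representable in this track; rotate the reference so that no
#' gene wraps before annotating.
#'
#' @param path Path to the annotation TSV (no header).
#' @param ref_length Reference length used to validate interval bounds.
#' @return A `data.frame` with columns `gene`, `start`, `end`, `strand`,
#'   `kind`, sorted by `start`.
#' @export
read_annotations <- function(path, ref_length) {
  if (!file.exists(path))
    stop("annotation file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "gene",
                                        "kind", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "character",
                                         "character"))
  validate_annotations(df[, c("gene", "start", "end", "strand", "kind")],
                       ref_length)
}

validate_annotations <- function(df, ref_length) {
  stopifnot(is.data.frame(df),
            all(c("gene", "start", "end", "strand", "kind") %in% names(df)))
  bad <- which(!(df$kind %in% annotation_kinds))
  if (length(bad))
    stop("unknown annotation kind '", df$kind[bad[1L]], "' for gene '",
         df$gene[bad[1L]], "'")
  bad <- which(!(df$strand %in% c("+", "-")))
  if (length(bad))
    stop("invalid strand '", df$strand[bad[1L]], "' for gene '",
         df$gene[bad[1L]], "'")
  bad <- which(df$start < 0L | df$end <= df$start)
  if (length(bad))
    stop("invalid interval [", df$start[bad[1L]], ", ", df$end[bad[1L]],
         ") for gene '", df$gene[bad[1L]],
         "' (need 0 <= start < end; wrap-around intervals are not",
         " supported - rotate the reference so no gene spans the origin)")
  bad <- which(df$end > ref_length)
  if (length(bad))
    stop("interval end ", df$end[bad[1L]], " for gene '", df$gene[bad[1L]],
         "' exceeds reference length ", ref_length)
  bad <- which(df$kind == "PCG" & (df$end - df$start) < 6L)
  if (length(bad))
    stop("protein-coding gene '", df$gene[bad[1L]],
         "' is shorter than 6 bp")
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a gene annotation track
#'
#' Inverse of [read_annotations()]: BED-like 6-column TSV.
#'
#' @param annotations Annotation `data.frame` (`gene`, `start`, `end`,
#'   `strand`, `kind`).
#' @param path Output path.
#' @param chrom Chromosome label written in column 1.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, chrom = "ref") {
  out <- data.frame(chrom = chrom, start = annotations$start,
                    end = annotations$end, gene = annotations$gene,
                    kind = annotations$kind, strand = annotations$strand,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Published per-assembly accuracy table
#'
#' Loads the packaged transcription of the published benchmark of 18
#' long-read silky-shark mitogenome assemblies against the short-read
#' reference: assembly name, contig status, length (bp), coverage
#' metadata, uncorrected p-distance to the reference, and total error
#' count. These printed values anchor the package's aggregate-statistics
#' tests without requiring the original sequencing data.
#'
#' @return A `data.frame` with 18 rows and columns `assembly`, `contigs`,
#'   `length_bp`, `coverage`, `p_dist`, `errors`.
#' @examples
#' tab <- load_table1_fixture()
#' aggregate_errors(tab$errors)
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "silky_shark_assembly_metrics.tsv",
                      package = "mitobench", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 18L, all(df$errors >= 0L),
            all(df$p_dist >= 0 & df$p_dist <= 1))
  df
}
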