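ann_row <- function(gene, start, end, strand = "+", kind = "PCG")
  data.frame(gene = gene, start = start, end = end, strand = strand,
             kind = kind, stringsAsFactors = FALSE)

test_that("projection maps intervals through the alignment", {
  s <- rand_seq(40L)
  ident <- aligned_pair(s, s)
  proj <- project_annotations(ident, ann_row("g", 0L, 9L))
  expect_equal(proj$asm_start, 0L)
  expect_equal(proj$asm_end, 9L)

  # a 1 bp insertion inside the gene stretches it by one
  ref <- "AACCGGTTAACCGGTT"
  asm <- "AACCGTGGTTAACCGGTT"  # TG inserted after pos 5? build by alignment
  pair <- normalize_gaps(global_align(circ_seq(ref), circ_seq(asm)))
  proj <- project_annotations(pair, ann_row("g", 0L, 9L))
  expect_equal(proj$asm_end - proj$asm_start, 9L + 2L)
})

test_that("projection agrees with a column-walk oracle under random indels", {
  set.seed(33)
  for (i in 1:15) {
    ref <- circ_seq(rand_seq(120L))
    chars <- strsplit(ref$seq, "")[[1L]]
    for (k in 1:3) {
      at <- sample(10:100, 1L)
      chars <- if (runif(1) < 0.5)
        append(chars, sample(c("A", "C", "G", "T"), 1L), after = at)
      else chars[-at]
    }
    asm <- circ_seq(paste(chars, collapse = ""))
    pair <- normalize_gaps(global_align(ref, asm))
    ann <- rbind(ann_row("g1", 5L, 35L), ann_row("g2", 40L, 80L),
                 ann_row("g3", 90L, 117L))
    proj <- project_annotations(pair, ann)
    for (j in 1:3) {
      oracle <- column_walk_projection(pair$ref_row, pair$asm_row,
                                       ann$start[j], ann$end[j])
      expect_equal(c(proj$asm_start[j], proj$asm_end[j]),
                   unname(oracle), info = paste("case", i, "gene", j))
    }
  }
})

test_that("stop codons follow the vertebrate mitochondrial code", {
  expect_setequal(vertebrate_mito_stops(), c("TAA", "TAG", "AGA", "AGG"))
  # cross-check the hard-coded set against the Biostrings code table
  gc2 <- Biostrings::getGeneticCode("2")
  expect_setequal(vertebrate_mito_stops(), names(gc2)[gc2 == "*"])

  asm <- circ_seq("ATGAAATAA")
  proj <- data.frame(gene = "g", kind = "PCG", strand = "+",
                     ref_start = 0L, ref_end = 9L, asm_start = 0L,
                     asm_end = 9L, stringsAsFactors = FALSE)
  audit <- audit_orfs(asm, proj)
  expect_equal(audit$internal_stops, 0L)
  expect_false(audit$disrupted)

  # AGA is a stop under table 2
  asm <- circ_seq("ATGAGAAAATAA")
  proj$asm_end <- proj$ref_end <- 12L
  audit <- audit_orfs(asm, proj)
  expect_equal(audit$internal_stops, 1L)
  expect_true(audit$disrupted)

  # minus-strand gene: the reverse complement carries the frame
  cds <- "ATGCATCATTAA"
  asm <- circ_seq(revcomp_string(cds))
  proj <- data.frame(gene = "m", kind = "PCG", strand = "-",
                     ref_start = 0L, ref_end = 12L, asm_start = 0L,
                     asm_end = 12L, stringsAsFactors = FALSE)
  audit <- audit_orfs(asm, proj)
  expect_equal(audit$internal_stops, 0L)
  expect_false(audit$disrupted)
})

test_that("clean assemblies audit clean; frameshifts disrupt", {
  gs <- genome_spec(length = 4000L, n_pcg = 3L, n_trna = 4L, n_rrna = 1L,
                    seed = 3L)
  gen <- generate_reference(gs)
  ref <- gen$reference
  ident <- compare_to_reference(ref, ref)
  proj <- project_annotations(ident$pair, gen$annotations)
  audit <- audit_orfs(ref, proj)
  expect_true(all(audit$detected))
  expect_true(all(audit$internal_stops == 0L))
  expect_false(any(audit$disrupted))

  # one 1 bp homopolymer insertion inside a PCG must disrupt it
  pcg <- gen$annotations[gen$annotations$kind == "PCG", ][1L, ]
  refc <- strsplit(ref$seq, "")[[1L]]
  inside <- (pcg$start + 20L):(pcg$end - 20L)
  runpos <- inside[which(refc[inside + 1L] == refc[inside + 2L])][1L]
  truth <- data.frame(category = "HP_INS_1", type = "insertion",
                      ref_pos = runpos + 1L, length = 1L,
                      bases = refc[runpos + 1L], stringsAsFactors = FALSE)
  mut <- circ_seq(apply_truth_events(ref$seq, truth), id = "mut")
  res <- compare_to_reference(mut, ref)
  proj <- project_annotations(res$pair, gen$annotations)
  audit <- audit_orfs(res$norm$sequence, proj)
  hit <- audit[audit$gene == pcg$gene, ]
  expect_equal(hit$frame_shift %% 3L, 1L)
  expect_true(hit$disrupted)
  # stop count agrees with the independent translation oracle
  cds <- substr(res$norm$sequence$seq, hit$asm_start + 1L, hit$asm_end)
  if (hit$strand == "-") cds <- revcomp_string(cds)
  expect_equal(hit$internal_stops, translation_stop_oracle(cds))
})

test_that("disruption grows monotonically with intra-genic frameshifts", {
  gs <- genome_spec(length = 5000L, n_pcg = 4L, n_trna = 4L, n_rrna = 1L,
                    seed = 13L)
  gen <- generate_reference(gs)
  ref <- gen$reference
  pcgs <- gen$annotations[gen$annotations$kind == "PCG", ]
  refc <- strsplit(ref$seq, "")[[1L]]
  disrupted_counts <- integer(0L)
  for (n_hit in 0:3) {
    truth <- NULL
    if (n_hit > 0L) {
      rows <- lapply(seq_len(n_hit), function(g) {
        mid <- (pcgs$start[g] + pcgs$end[g]) %/% 2L
        data.frame(category = "INS_1", type = "insertion", ref_pos = mid,
                   length = 1L,
                   bases = setdiff(c("A", "C", "G", "T"),
                                   refc[c(mid, mid + 1L)])[1L],
                   stringsAsFactors = FALSE)
      })
      truth <- do.call(rbind, rows)
    } else {
      truth <- data.frame(category = character(), type = character(),
                          ref_pos = integer(), length = integer(),
                          bases = character())
    }
    mut <- circ_seq(apply_truth_events(ref$seq, truth), id = "mut")
    res <- compare_to_reference(mut, ref)
    proj <- project_annotations(res$pair, gen$annotations)
    audit <- audit_orfs(res$norm$sequence, proj)
    disrupted_counts <- c(disrupted_counts, sum(audit$disrupted))
  }
  expect_equal(disrupted_counts[1L], 0L)
  expect_true(all(diff(disrupted_counts) >= 0L))
  expect_equal(disrupted_counts[4L], 3L)
})

test_that("a fully deleted gene is reported as not detected", {
  set.seed(77)
  ref <- circ_seq(rand_seq(300L))
  # delete the whole interval [100, 150)
  asm <- circ_seq(paste0(substr(ref$seq, 1, 100), substr(ref$seq, 151, 300)))
  pair <- normalize_gaps(global_align(ref, asm))
  proj <- project_annotations(pair, ann_row("gone", 102L, 148L))
  audit <- audit_orfs(asm, proj)
  expect_false(audit$detected)
})
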