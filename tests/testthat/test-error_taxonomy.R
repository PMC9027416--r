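norm_pair <- function(ref, asm)
  normalize_gaps(global_align(circ_seq(ref), circ_seq(asm)))

test_that("carriers are extracted per maximal run and mismatch column", {
  p <- norm_pair("AACCTT", "AACTT")
  ev <- extract_events(p)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "deletion")
  expect_equal(ev$bases, "C")
  expect_equal(ev$ref_pos, 2L)

  p <- norm_pair("ACGT", "ACGT")
  expect_equal(nrow(extract_events(p)), 0L)

  ev <- extract_events(aligned_pair("AC--GT", "ACTAGT"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "insertion")
  expect_equal(ev$bases, "TA")
  expect_equal(ev$length, 2L)
  expect_equal(ev$ref_pos, 2L)
})

test_that("non-normalized alignments are rejected", {
  expect_error(extract_events(aligned_pair("ACCCT", "AC-CT")),
               "not gap-normalized")
})

test_that("classification follows the homopolymer-first rule order", {
  ref <- circ_seq("AACCTTGG")
  # delete one C out of the CC run
  ev <- classify_events(extract_events(norm_pair(ref$seq, "AACTTGG")), ref)
  expect_equal(ev$category, "HP_DEL_1")
  expect_equal(ev$hp_nucleotide, "C")
  expect_equal(ev$hp_run_len, 2L)

  # insert TT against the TTTT run
  ref2 <- circ_seq("ACGTTTTACG")
  ev <- classify_events(extract_events(norm_pair(ref2$seq, "ACGTTTTTTACG")),
                        ref2)
  expect_equal(ev$category, "HP_INS_2")
  expect_equal(ev$hp_run_len, 4L)

  # deletion of an isolated base
  ref3 <- circ_seq("ACGTA")
  ev <- classify_events(extract_events(norm_pair(ref3$seq, "ACTA")), ref3)
  expect_equal(ev$category, "DEL_1")

  # non-homopolymer 2 bp insertion
  ref4 <- circ_seq("TTGGATCC")
  ev <- classify_events(extract_events(aligned_pair("TTGG--ATCC",
                                                    "TTGGCAATCC")), ref4)
  expect_equal(ev$category, "INS_SHORT")

  # substitution column
  ev <- classify_events(extract_events(norm_pair("ACGTACGT", "ACGAACGT")),
                        circ_seq("ACGTACGT"))
  expect_equal(ev$category, "SUBSTITUTION")
  expect_equal(ev$length, 1L)

  # >= 5 bp falls into the extension categories
  ref5 <- circ_seq("ACGTACGTACGTAGG")
  ev <- classify_events(extract_events(norm_pair(ref5$seq, "ACGTAGG")), ref5)
  expect_equal(ev$category, "DEL_LONG")
})

test_that("the homopolymer criterion switch changes only the boundary case", {
  # inserting A next to a lone A: plain INS_1 against the reference run,
  # homopolymer single insertion if the resulting run counts
  ref <- circ_seq("TCAGT")
  pair <- normalize_gaps(aligned_pair("TCA-GT", "TCAAGT"))
  ev <- extract_events(pair)
  expect_equal(classify_events(ev, ref)$category, "INS_1")
  expect_equal(classify_events(ev, ref,
                               hp_criterion = "resulting-run")$category,
               "HP_INS_1")
  # a true run-2 case is homopolymer under both readings
  ref2 <- circ_seq("TCAAGT")
  pair2 <- normalize_gaps(aligned_pair("TCA-AGT", "TCAAAGT"))
  ev2 <- extract_events(pair2)
  expect_equal(classify_events(ev2, ref2)$category, "HP_INS_1")
  expect_equal(classify_events(ev2, ref2,
                               hp_criterion = "resulting-run")$category,
               "HP_INS_1")
})

test_that("profiles tally events once each, regardless of length", {
  expect_equal(error_profile(data.frame(category = character()))$total, 0L)
  ev <- data.frame(category = c(rep("HP_INS_1", 3L), "SUBSTITUTION"))
  prof <- error_profile(ev)
  expect_equal(prof$total, 4L)
  expect_equal(unname(prof$counts["HP_INS_1"]), 3L)
  expect_equal(sum(prof$counts), prof$total)
})

test_that("event totals and spans obey the conservation invariants", {
  b <- small_benchmark(genome_seed = 31L, error_seed = 32L)
  res <- compare_to_reference(b$inj$assembly, b$gen$reference)
  pc <- strsplit(c(res$pair$ref_row, res$pair$asm_row), "")
  r <- pc[[1L]]; a <- pc[[2L]]
  n_ins_runs <- sum(rle(r == "-")$values)
  n_del_runs <- sum(rle(a == "-")$values)
  n_mismatch <- sum(r != "-" & a != "-" & r != a)
  expect_equal(res$profile$total, n_ins_runs + n_del_runs + n_mismatch)
  # inserted bases account exactly for the length surplus
  ins_len <- sum(res$events$length[res$events$type == "insertion"])
  del_len <- sum(res$events$length[res$events$type == "deletion"])
  expect_equal(seq_length(b$inj$assembly) - seq_length(b$gen$reference),
               ins_len - del_len)
  # deletion reference spans never overlap
  del <- res$events[res$events$type == "deletion", ]
  if (nrow(del) > 1L) {
    del <- del[order(del$ref_pos), ]
    expect_true(all(del$ref_pos[-1L] >=
                      (del$ref_pos + del$length)[-nrow(del)]))
  }
})

test_that("the full pipeline recovers an injected truth profile exactly", {
  counts <- c(HP_INS_1 = 8, HP_DEL_1 = 4, HP_INS_2 = 3, SUBSTITUTION = 3,
              DEL_1 = 2, INS_1 = 2, INS_SHORT = 1, DEL_SHORT = 1)
  for (seed in 1:5) {
    b <- small_benchmark(genome_seed = seed, error_seed = seed + 100L,
                         counts = counts, length = 4000L,
                         rotate_by = seed * 37L, revcomp = seed %% 2L == 0L)
    res <- compare_to_reference(b$inj$assembly, b$gen$reference)
    expect_equal(res$profile$counts, truth_profile(b$inj$truth)$counts,
                 info = paste("seed", seed))
  }
})
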