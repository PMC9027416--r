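test_that("reference generation honors its contract deterministically", {
  spec <- genome_spec(length = 16705L, seed = 1L)
  gen <- generate_reference(spec)
  expect_equal(seq_length(gen$reference), 16705L)
  expect_equal(gen$reference$topology, "circular")
  gen2 <- generate_reference(spec)
  expect_identical(gen2$reference$seq, gen$reference$seq)
  expect_identical(gen2$annotations, gen$annotations)

  kinds <- table(gen$annotations$kind)
  expect_equal(unname(kinds["PCG"]), 13L)
  expect_equal(unname(kinds["tRNA"]), 22L)
  expect_equal(unname(kinds["rRNA"]), 2L)
  # intervals valid, non-overlapping, none wrapping the origin
  ann <- gen$annotations[order(gen$annotations$start), ]
  expect_true(all(ann$start < ann$end))
  expect_true(all(ann$end <= 16705L))
  expect_true(all(ann$start[-1L] >= ann$end[-nrow(ann)]))
})

test_that("realized homopolymer content tracks the target", {
  for (seed in 0:19) {
    gen <- generate_reference(genome_spec(length = 8000L, n_pcg = 6L,
                                          n_trna = 10L, n_rrna = 2L,
                                          seed = seed))
    realized <- regex_hp_fraction(gen$reference$seq)
    expect_lt(abs(realized - 0.45), 0.05)
  }
  # a deliberately homopolymer-rich genome is also reachable
  gen <- generate_reference(genome_spec(length = 8000L, hp_fraction = 0.55,
                                        n_pcg = 2L, n_trna = 10L,
                                        n_rrna = 2L, seed = 4L))
  expect_lt(abs(regex_hp_fraction(gen$reference$seq) - 0.55), 0.05)
})

test_that("every generated PCG is an intact reading frame", {
  gen <- generate_reference(genome_spec(seed = 5L))
  refc <- gen$reference$seq
  pcg <- gen$annotations[gen$annotations$kind == "PCG", ]
  for (i in seq_len(nrow(pcg))) {
    cds <- substr(refc, pcg$start[i] + 1L, pcg$end[i])
    if (pcg$strand[i] == "-") cds <- revcomp_string(cds)
    expect_equal(substr(cds, 1L, 3L), "ATG")
    ncod <- nchar(cds) %/% 3L
    starts <- seq.int(1L, by = 3L, length.out = ncod - 1L)
    codons <- substring(cds, starts, starts + 2L)
    expect_false(any(codons %in% vertebrate_mito_stops()),
                 label = paste("internal stop in", pcg$gene[i]))
  }
  # nad6 sits on the minus strand in the default complement
  expect_equal(pcg$strand[pcg$gene == "nad6"], "-")
})

test_that("impossible gene packings are refused", {
  expect_error(generate_reference(genome_spec(length = 4000L, seed = 2L)),
               "packed")
})

test_that("error injection respects its spec and bookkeeping", {
  gen <- generate_reference(genome_spec(length = 5000L, n_pcg = 3L,
                                        n_trna = 5L, n_rrna = 1L,
                                        seed = 8L))
  ref <- gen$reference

  inj0 <- inject_errors(ref, error_spec(integer(0L), seed = 9L))
  expect_identical(inj0$assembly$seq, ref$seq)
  expect_equal(nrow(inj0$truth), 0L)

  inj1 <- inject_errors(ref, error_spec(c(HP_DEL_1 = 1), seed = 9L))
  expect_equal(seq_length(inj1$assembly), seq_length(ref) - 1L)

  counts <- c(HP_INS_1 = 10, HP_DEL_2 = 3, SUBSTITUTION = 4, INS_1 = 3,
              DEL_1 = 3, INS_SHORT = 2, DEL_SHORT = 2)
  inj <- inject_errors(ref, error_spec(counts, seed = 10L))
  expect_equal(nrow(inj$truth), sum(counts))
  expect_equal(unname(truth_profile(inj$truth)$counts[names(counts)]),
               unname(as.integer(counts)))
  # loci pairwise >= min_spacing apart
  pos <- sort(inj$truth$ref_pos)
  expect_true(all(diff(pos) >= 10L))
  # length bookkeeping
  delta <- sum(inj$truth$length[inj$truth$type == "insertion"]) -
    sum(inj$truth$length[inj$truth$type == "deletion"])
  expect_equal(seq_length(inj$assembly), seq_length(ref) + delta)
})

test_that("truth events verify against the reference and replay exactly", {
  gen <- generate_reference(genome_spec(length = 5000L, n_pcg = 3L,
                                        n_trna = 5L, n_rrna = 1L,
                                        seed = 18L))
  ref <- gen$reference
  inj <- inject_errors(ref, error_spec(c(HP_INS_1 = 8, HP_DEL_1 = 4,
                                         SUBSTITUTION = 4, DEL_SHORT = 2),
                                       seed = 19L),
                       rotate_by = 1500L, revcomp = TRUE)
  # recorded deletion/substitution bases must match the reference text
  for (i in seq_len(nrow(inj$truth))) {
    ev <- inj$truth[i, ]
    if (ev$type == "deletion")
      expect_equal(substr(ref$seq, ev$ref_pos + 1L,
                          ev$ref_pos + ev$length), ev$bases)
    if (ev$type == "substitution")
      expect_false(substr(ref$seq, ev$ref_pos + 1L, ev$ref_pos + 1L) ==
                     ev$bases)
  }
  # independent replay: splice the reference character vector
  refc <- strsplit(ref$seq, "")[[1L]]
  out <- refc
  for (i in order(inj$truth$ref_pos, decreasing = TRUE)) {
    ev <- inj$truth[i, ]
    p <- ev$ref_pos
    if (ev$type == "insertion") {
      out <- append(out, strsplit(ev$bases, "")[[1L]], after = p)
    } else if (ev$type == "deletion") {
      out <- out[-((p + 1L):(p + ev$length))]
    } else {
      out[p + 1L] <- ev$bases
    }
  }
  mutated <- paste(out, collapse = "")
  # undo the simulator's strand/rotation to compare
  undone <- revcomp_string(inj$assembly$seq)
  undone <- rotate_string(undone, seq_length(inj$assembly) - inj$rotate_by)
  expect_identical(undone, mutated)
  expect_identical(apply_truth_events(ref$seq, inj$truth), mutated)
})

test_that("oversubscribed injection requests fail loudly", {
  gen <- generate_reference(genome_spec(length = 5000L, n_pcg = 3L,
                                        n_trna = 5L, n_rrna = 1L,
                                        seed = 28L))
  expect_error(inject_errors(gen$reference,
                             error_spec(c(SUBSTITUTION = 600),
                                        seed = 1L)),
               "exceed")
  expect_error(inject_errors(gen$reference,
                             error_spec(c(HP_DEL_7 = 200), seed = 1L,
                                        min_spacing = 1L)),
               "qualifying|could not place")
})
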