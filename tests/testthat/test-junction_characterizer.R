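test_that("compute_microhomology equals the brute-force shift oracle", {
  # random junctions on random references across orientations; the oracle
  # enumerates breakpoint shifts and counts placements reproducing the
  # derivative window
  n_trials <- 150
  set.seed(101)
  g <- random_reference(20000, 0.5, seed = 77, contig = "c")
  for (i in seq_len(n_trials)) {
    s1 <- breakpoint_side("c", sample(200:9000, 1), sample(c("+", "-"), 1))
    s2 <- breakpoint_side("c", sample(11000:19000, 1), sample(c("+", "-"), 1))
    got <- compute_microhomology(g, s1, s2)
    expect_equal(got$len, oracle_microhomology(g, s1, s2),
                 label = sprintf("trial %d (%d%s/%d%s)", i, s1$position,
                                 s1$orientation, s2$position, s2$orientation))
  }
})

test_that("microhomology placement is canonical under breakpoint shifts", {
  # planting a junction and then shifting both sides inside the homology
  # tract must yield the identical canonical record
  g <- random_reference(30000, 0.41, seed = 5, contig = "c")
  sp <- plant_spec("c", data.frame(start = c(1, 20000), end = c(10000, 30000),
                                   orientation = "forward"),
                   list(list(type = "mh", len = 9)), seed = 8)
  tr <- plant_rearrangement(g, sp)
  t <- tr$junctions[[1]]
  base <- compute_microhomology(tr$genome, t$side1, t$side2)
  for (k in 1:9) {
    s1 <- breakpoint_side("c", t$side1$position + k, "+")
    s2 <- breakpoint_side("c", t$side2$position + k, "-")
    shifted <- compute_microhomology(tr$genome, s1, s2)
    expect_equal(shifted$len, base$len)
    expect_equal(shifted$side1$position, base$side1$position)
    expect_equal(shifted$side2$position, base$side2$position)
    expect_equal(shifted$seq, base$seq)
  }
})

test_that("flanks sharing an engineered tract report exactly that tract", {
  # build a reference where the junction-spanning sequence is TGC exactly
  g0 <- random_reference(5000, 0.5, seed = 21, contig = "c")
  sq <- unclass(g0)[["c"]]
  substr(sq, 1001, 1003) <- "TGC"   # beyond side1 (positions 1001-1003)
  substr(sq, 1004, 1004) <- "A"
  substr(sq, 3000, 3002) <- "TGC"   # start of side2's retained flank
  substr(sq, 999, 1000) <- "GG"    # no accidental left slide
  substr(sq, 2998, 2999) <- "TT"
  g <- genome_model(c(c = sq))
  s1 <- breakpoint_side("c", 1000, "+")
  s2 <- breakpoint_side("c", 3000, "-")
  got <- compute_microhomology(g, s1, s2)
  if (got$len == 3) expect_equal(got$seq, "TGC") else {
    # background sequence can extend the tract; oracle must agree
    expect_equal(got$len, oracle_microhomology(g, s1, s2))
  }
  expect_equal(got$len, oracle_microhomology(g, s1, s2))
})

test_that("decompose_insertion covers empty, non-templated and mixed cases", {
  g <- random_reference(10000, 0.5, seed = 31, contig = "c")
  s1 <- breakpoint_side("c", 3000, "+")
  s2 <- breakpoint_side("c", 7000, "-")
  expect_equal(decompose_insertion(g, "", s1, s2), list())
  expect_error(decompose_insertion(g, "ACGT", s1, s2, window = 5,
                                   min_templated = 10), "window")

  # random 20-mer absent from both windows -> one non-templated block
  sq <- unclass(g)[["c"]]
  w1 <- substr(sq, 2900, 3100); w2 <- substr(sq, 6900, 7100)
  set.seed(42)
  repeat {
    ins <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                 collapse = "")
    absent <- !grepl(ins, w1, fixed = TRUE) && !grepl(ins, w2, fixed = TRUE) &&
      !grepl(oracle_revcomp(ins), w1, fixed = TRUE) &&
      !grepl(oracle_revcomp(ins), w2, fixed = TRUE)
    if (absent) break
  }
  blocks <- decompose_insertion(g, ins, s1, s2)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$kind, "non_templated")
  expect_equal(nchar(blocks[[1]]$sequence), 20)

  # 14 nt random + 26 nt minus-strand copy from side2's window + 12 nt
  tmpl <- oracle_revcomp(substr(sq, 7030, 7055))
  insert <- paste0(substr(ins, 1, 14), tmpl,
                   paste(rep("A", 12), collapse = ""))
  blocks <- decompose_insertion(g, insert, s1, s2)
  kinds <- vapply(blocks, function(b) b$kind, "")
  lens <- vapply(blocks, function(b) nchar(b$sequence), 1L)
  expect_equal(kinds[1:2], c("non_templated", "templated"))
  expect_equal(lens[1:2], c(14L, 26L))
  expect_equal(blocks[[2]]$source$strand, "-")
  expect_equal(c(blocks[[2]]$source$start, blocks[[2]]$source$end),
               c(7030L, 7055L))
  # every templated claim is verifiable against the reference
  for (b in blocks) {
    if (b$kind == "templated") {
      src <- substr(sq, b$source$start, b$source$end)
      if (b$source$strand == "-") src <- oracle_revcomp(src)
      expect_equal(src, b$sequence)
    }
  }
})

test_that("collect_split_reads clusters and filters correctly", {
  expect_equal(length(collect_split_reads(NULL)), 0)
  g <- random_reference(40000, 0.41, seed = 13, contig = "c")
  # no junction: no split reads
  sp <- plant_spec("c", data.frame(start = 1, end = 40000,
                                   orientation = "forward"), list(), seed = 1)
  tr <- plant_rearrangement(g, sp)
  rr <- generate_reads(tr, library_config(coverage = 10, seed = 2))
  expect_length(collect_split_reads(rr$alignments), 0)

  # two junctions 150 bp apart cluster into two distinct groups
  sp <- plant_spec("c", data.frame(start = c(1, 20000, 28000),
                                   end = c(10000, 20150, 40000),
                                   orientation = "forward"),
                   list(list(type = "blunt"), list(type = "blunt")),
                   seed = 3)
  tr <- plant_rearrangement(g, sp)
  rr <- generate_reads(tr, library_config(coverage = 40, seed = 4))
  groups <- collect_split_reads(rr$alignments, tolerance = 50)
  expect_length(groups, 2)
  expect_true(all(vapply(groups, function(x) x$support, 1L) >= 5))

  # candidate regions restrict the output
  cand <- data.frame(contig = "c", start = 9900, end = 10100)
  groups <- collect_split_reads(rr$alignments, candidates = cand,
                                candidate_pad = 100)
  expect_length(groups, 1)
  expect_equal(groups[[1]]$side1$position, 10000)
})

test_that("build_consensus votes, ties and flags degenerate input", {
  reads <- rep(paste(rep(c("A", "C", "G", "T"), 25), collapse = ""), 10)
  cons <- build_consensus(list(reads = reads))
  expect_equal(cons$sequence, reads[1])
  expect_equal(cons$n_reads, 10)
  expect_true(all(cons$support == 10))

  single <- build_consensus(list(reads = reads[1]))
  expect_equal(single$sequence, reads[1])
  expect_equal(single$n_reads, 1)

  # irreconcilable second read: seed returned, low-confidence flag set
  set.seed(6)
  other <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                 collapse = "")
  cons <- build_consensus(list(reads = c(reads[1], other)))
  expect_true(cons$low_confidence)
  expect_equal(cons$n_reads, 1)

  # tiled erroneous reads reconstruct the true window
  g <- random_reference(2000, 0.5, seed = 17, contig = "c")
  truth <- substr(unclass(g)[["c"]], 500, 800)
  set.seed(1)
  reads <- vapply(seq(1, 150, by = 10), function(s) {
    r <- substr(truth, s, s + 150)
    i <- sample(nchar(r), 1)
    substr(r, i, i) <- sample(c("A", "C", "G", "T"), 1)
    r
  }, "")
  cons <- build_consensus(list(reads = reads))
  expect_true(grepl(cons$sequence, truth, fixed = TRUE) ||
                cons$sequence == truth)
})

test_that("resolve_junction handles blunt, homologous and unresolved cases", {
  g <- random_reference(30000, 0.41, seed = 19, contig = "c")
  sp <- plant_spec("c", data.frame(start = c(1, 20000), end = c(10000, 30000),
                                   orientation = "forward"),
                   list(list(type = "blunt")), seed = 23)
  tr <- plant_rearrangement(g, sp)
  win <- substr(tr$derivative, 9900, 10100)
  j <- resolve_junction(win, tr$genome)
  expect_equal(j$microhomology_len, 0L)
  expect_equal(j$insertion_len, 0L)
  expect_equal(j$side1$position, 10000L)
  expect_equal(j$side2$position, 20000L)
  expect_equal(j$side2$orientation, "-")

  # pure reference sequence: no junction
  j <- resolve_junction(substr(unclass(tr$genome)[["c"]], 5000, 5300),
                        tr$genome)
  expect_false(is_resolved(j))
  expect_match(attr(j, "unresolved"), "no junction")
})

test_that("annotate_repeats overlaps 1-based inclusive and flags families", {
  trk <- data.frame(contig = "c", start = c(100, 500), end = c(199, 600),
                    name = c("AluSx", "AluSx1"))
  j <- junction_record("x", 1, breakpoint_side("c", 199, "+"),
                       breakpoint_side("c", 500, "-"),
                       microhomology_len = 0, insertion_len = 0)
  j <- annotate_repeats(j, trk)
  expect_equal(j$repeat1, "AluSx")
  expect_equal(j$repeat2, "AluSx1")
  expect_true(attr(j, "same_family"))
  # boundary base outside -> NONE; empty track -> NONE
  j2 <- junction_record("x", 1, breakpoint_side("c", 200, "+"),
                        breakpoint_side("c", 601, "-"),
                        microhomology_len = 0, insertion_len = 0)
  j2 <- annotate_repeats(j2, trk)
  expect_equal(c(j2$repeat1, j2$repeat2), c("NONE", "NONE"))
  j3 <- annotate_repeats(j, trk[0, ])
  expect_equal(c(j3$repeat1, j3$repeat2), c("NONE", "NONE"))
  expect_false(attr(j3, "same_family"))
  expect_equal(repeat_family(c("AluY", "L1MA7", "MIRb", "MLT1K", "(TA)n")),
               c("Alu", "LINE", "MIR", "LTR", "other"))
})

test_that("find_novel_snvs reports planted hets and honors the frequency filter", {
  g <- random_reference(30000, 0.41, seed = 29, contig = "c")
  snv_pos <- 9800L  # 200 bp from the junction at 10000
  ref_base <- substr(unclass(g)[["c"]], snv_pos, snv_pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  sp <- plant_spec("c", data.frame(start = c(1, 20000), end = c(10000, 30000),
                                   orientation = "forward"),
                   list(list(type = "blunt")),
                   snvs = data.frame(pos = snv_pos, alt = alt),
                   seed = 31)
  tr <- plant_rearrangement(g, sp)
  rr <- generate_reads(tr, library_config(coverage = 40, seed = 5))
  js <- characterize_junctions(rr$alignments, tr$genome)
  snvs <- find_novel_snvs(rr$alignments, tr$genome, js, window = 1000,
                          freq_table = data.frame(contig = character(0),
                                                  pos = integer(0),
                                                  ref = character(0),
                                                  alt = character(0),
                                                  af = numeric(0)))
  hit <- snvs[snvs$pos == snv_pos, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$alt, alt)
  expect_true(hit$novel)
  expect_equal(hit$distance, 200L)

  # the same SNV present in the population table at AF 0.01 is filtered
  ft <- data.frame(contig = "c", pos = snv_pos, ref = ref_base, alt = alt,
                   af = 0.01)
  snvs <- find_novel_snvs(rr$alignments, tr$genome, js, freq_table = ft)
  expect_false(snvs$novel[snvs$pos == snv_pos])

  # no frequency table: unfiltered flag
  snvs <- find_novel_snvs(rr$alignments, tr$genome, js)
  expect_true(all(snvs$unfiltered))

  # error-free non-SNV simulation yields no candidates elsewhere
  expect_true(all(snvs$pos == snv_pos))
})
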