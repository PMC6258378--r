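bundle <- load_fixture()

test_that("build_fragment_graph partitions at breakpoints and CN boundaries", {
  # single deletion junction + matching CN loss
  j <- junction_record("x", 1, breakpoint_side("c", 1000, "+"),
                       breakpoint_side("c", 3000, "-"),
                       microhomology_len = 0, insertion_len = 0)
  cn <- cn_segments("c", 1001, 2999, 1)
  g <- build_fragment_graph(list(j), cn, c(1, 4000))
  expect_equal(nrow(g$nodes), 3)
  expect_equal(g$nodes$copies, c(1L, 0L, 1L))
  expect_length(g$edges, 1)
  expect_length(g$half_edges, 0)
  expect_error(build_fragment_graph(list(j), cn, c(1, 2000)), "outside span")

  # one-sided junctions become half-edges
  j2 <- junction_record("x", 2, breakpoint_side("c", 500, "+"), NULL)
  g2 <- build_fragment_graph(list(j, j2), cn, c(1, 4000))
  expect_length(g2$half_edges, 1)
})

test_that("enumerate_structures recovers unique and ambiguous walks", {
  # no junctions: the reference itself
  g <- build_fragment_graph(list(), cn_segments(character(0), integer(0),
                                                integer(0), integer(0)),
                            c(1, 4000))
  sols <- enumerate_structures(g)
  expect_length(sols, 1)
  expect_equal(sols[[1]]$segments$provenance, "retained")

  # deletion graph: exactly one structure skipping the lost node
  j <- junction_record("x", 1, breakpoint_side("c", 1000, "+"),
                       breakpoint_side("c", 3000, "-"),
                       microhomology_len = 0, insertion_len = 0)
  cn <- cn_segments("c", 1001, 2999, 1)
  sols <- enumerate_structures(build_fragment_graph(list(j), cn, c(1, 4000)))
  expect_length(sols, 1)
  expect_equal(collapse_segments(sols[[1]]$segments),
               data.frame(start = c(1L, 3000L), end = c(1000L, 4000L),
                          orientation = "forward"))

  # DEL-INV-DEL shape: two junctions around a copy-neutral inverted spacer
  j1 <- junction_record("x", 1, breakpoint_side("c", 1000, "+"),
                        breakpoint_side("c", 3000, "+"),
                        microhomology_len = 0, insertion_len = 0)
  j2 <- junction_record("x", 2, breakpoint_side("c", 2001, "-"),
                        breakpoint_side("c", 3501, "-"),
                        microhomology_len = 0, insertion_len = 0)
  cn2 <- cn_segments(c("c", "c"), c(1001, 3001), c(2000, 3500), c(1, 1))
  sols <- enumerate_structures(
    build_fragment_graph(list(j1, j2), cn2, c(1, 4000)))
  expect_length(sols, 1)
  expect_equal(format(structure_to_pattern(sols[[1]])), "DEL-INV-DEL")

  # simulator plant of a 4-fragment shuffle: planted walk recovered
  gref <- random_reference(50000, 0.41, seed = 3, contig = "c")
  plan <- data.frame(start = c(1, 30000, 12000, 40000),
                     end = c(10000, 35000, 20000, 50000),
                     orientation = c("forward", "inverted", "forward",
                                     "forward"))
  tr <- plant_rearrangement(gref, plant_spec("c", plan, seed = 9))
  fg <- build_fragment_graph(tr$junctions, tr$cn, c(1, 50000))
  sols <- enumerate_structures(fg, max_solutions = 64)
  expect_gte(length(sols), 1)
  want <- collapse_segments(tr$structure$segments)
  found <- any(vapply(sols, function(s)
    isTRUE(all.equal(collapse_segments(s$segments), want,
                     check.attributes = FALSE)), TRUE))
  expect_true(found)
})

test_that("the order-ambiguous five-duplication case yields several walks", {
  st <- fixture_case_structure(bundle, "P5513_206")
  ij <- implied_junctions(st)
  sols <- enumerate_structures(
    build_fragment_graph(ij, structure_cn(st), st$span), max_solutions = 64)
  expect_gt(length(sols), 1)
  want <- collapse_segments(st$segments)
  found <- any(vapply(sols, function(s)
    isTRUE(all.equal(collapse_segments(s$segments), want,
                     check.attributes = FALSE)), TRUE))
  expect_true(found)
})

test_that("classify_duplications applies the tandem/interspersed definition", {
  # template + directly-oriented copy immediately after it: tandem
  st <- derivative_structure("t", rbind(
    segment_use(1, 1000), segment_use(500, 1000, "forward",
                                      "duplicate_copy"),
    segment_use(1001, 2000)), "c")
  dc <- classify_duplications(st)
  expect_equal(dc$architecture, "tandem")
  expect_false(dc$adjacent_to_other_duplicate)

  # no duplicates: empty call set
  st0 <- derivative_structure("n", segment_use(1, 1000), "c")
  expect_equal(nrow(classify_duplications(st0)), 0)

  # inverted or displaced copies are interspersed
  st2 <- fixture_case_structure(bundle, "P4855_512")
  dc <- classify_duplications(st2)
  expect_equal(sort(paste(dc$architecture, dc$orientation)),
               c("interspersed inverted", "tandem direct"))

  # invariance under coordinate translation and contig renaming
  st3 <- st2
  st3$segments$start <- st3$segments$start + 12345L
  st3$segments$end <- st3$segments$end + 12345L
  st3$span <- st3$span + 12345L
  st3$contig <- "renamed"
  expect_equal(classify_duplications(st3)$architecture, dc$architecture)
})

test_that("nested deletions inside duplications are reproduced", {
  # the four two-duplication cases each carry a deletion nested in the
  # duplicated segment: the region between the two inserted copies is
  # copy-neutral (the nested deletion balances the extra copy)
  for (cid in c("P06", "P4855_511", "P74", "P2109_150")) {
    st <- fixture_case_structure(bundle, cid)
    pat <- unclass(structure_to_pattern(st))
    expect_equal(pat[c(1, 3)] %in% c("DUP", "DUPinv"), c(TRUE, TRUE),
                 label = cid)
    expect_equal(pat[2], "N", label = cid)
    cop <- st$segments[st$segments$provenance == "duplicate_copy", ]
    gap <- c(min(cop$end) + 1L, max(cop$start) - 1L)
    expect_true(gap[1] < gap[2], label = cid)
  }
})

test_that("junction_equivalence distinguishes identical/compatible/distinct", {
  mk <- function(p1, p2, o1 = "+", o2 = "-", mh = 0) {
    junction_record("x", 1, breakpoint_side("2", p1, o1),
                    breakpoint_side("2", p2, o2), microhomology_len = mh,
                    microhomology_seq = if (mh > 0)
                      paste(rep("A", mh), collapse = "") else NA,
                    insertion_len = 0)
  }
  # the shared nested-deletion junction of the two 2p25.3 carriers
  a <- mk(1114148, 1610546); b <- mk(1114148, 1610546)
  expect_equal(junction_equivalence(a, b), "identical")
  expect_equal(junction_equivalence(a, mk(1114148, 1610546, "-", "+")),
               "distinct")
  expect_equal(junction_equivalence(a, mk(1114151, 1610543), tolerance = 5),
               "compatible")
  expect_equal(junction_equivalence(a, mk(1114151, 1610543), tolerance = 2),
               "distinct")
  # equal coordinates but differing microhomology: compatible, not identical
  expect_equal(junction_equivalence(a, mk(1114148, 1610546, mh = 3)),
               "compatible")
  expect_error(junction_equivalence(a, junction_record(
    "y", 1, breakpoint_side("2", 5, "+"), NULL)), "both sides")
})
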