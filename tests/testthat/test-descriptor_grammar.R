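bundle <- load_fixture()

test_that("parse_descriptor handles the minimal and printed grammars", {
  d <- parse_descriptor("g.[100_200del]")
  expect_length(d$ops, 1)
  expect_equal(d$ops[[1]]$kind, "del")
  expect_equal(c(d$ops[[1]]$start, d$ops[[1]]$end), c(100L, 200L))

  # three-op deletion/inversion/deletion descriptor as printed
  d <- fixture_case_descriptor(bundle, "P2109_123")
  expect_equal(vapply(d$ops, function(o) o$kind, ""), c("del", "inv", "del"))
  expect_equal(d$ops[[1]]$start, 2220422L)
  expect_equal(d$ops[[2]]$end, 2617882L)
  expect_equal(d$accession, "NC_000017.10")

  # payloads, pter/qter, uncertainty
  d <- fixture_case_descriptor(bundle, "P5513_116")
  expect_equal(d$ops[[1]]$kind, "delins")
  expect_equal(d$ops[[1]]$end_raw, "qter")
  expect_equal(d$ops[[1]]$end,
               unname(bundle$contig_lengths["X"]))
  expect_equal(vapply(d$ops[[1]]$payload, function(p) p$orientation, ""),
               c("inverted", "inverted"))
  d <- fixture_case_descriptor(bundle, "P1426_301")
  expect_true(any(vapply(d$ops, function(o) o$uncertain, TRUE)))
  # reference-descending payload range denotes an inverted copy
  d <- fixture_case_descriptor(bundle, "P2109_176")
  expect_equal(d$ops[[1]]$payload[[1]]$orientation, "inverted")
  expect_equal(d$ops[[1]]$payload[[1]]$start, 186383235L)

  expect_error(parse_descriptor("g.[100_200frob]"), "unknown operation")
  expect_error(parse_descriptor("g.[100_200delins[1_2"), "bracket")
  expect_error(parse_descriptor("100_200del"), "bracketed")
})

test_that("parse -> serialize round-trips all 21 printed descriptors", {
  for (cid in bundle$cases$case_id) {
    norm <- bundle$cases$descriptor_norm[bundle$cases$case_id == cid]
    d <- fixture_case_descriptor(bundle, cid)
    expect_equal(serialize_descriptor(d), norm, label = cid)
    # raw printed strings (first alternative where two are printed) parse
    # to the same operations
    raw <- bundle$cases$descriptor_raw[bundle$cases$case_id == cid]
    raw <- strsplit(raw, " or ", fixed = TRUE)[[1]][1]
    draw <- parse_descriptor(raw)
    expect_equal(length(draw$ops), length(d$ops), label = paste(cid, "raw"))
  }
})

test_that("descriptor_to_structure covers identity, dup and payload cases", {
  # empty op list over a span: single forward retained segment
  st <- descriptor_to_structure(list(), c(1, 1000), contig = "c")
  expect_equal(nrow(st$segments), 1)
  expect_equal(st$segments$provenance, "retained")
  expect_equal(c(st$segments$start, st$segments$end), c(1L, 1000L))

  # tandem dup + inverted interspersed copy
  st <- fixture_case_structure(bundle, "P4855_512")
  cop <- st$segments[st$segments$provenance == "duplicate_copy", ]
  expect_equal(nrow(cop), 2)
  expect_setequal(cop$orientation, c("forward", "inverted"))
  dup <- cop[cop$orientation == "forward", ]
  expect_equal(c(dup$start, dup$end), c(44844321L, 46454415L))

  # deletions omitted, inversions flipped in place
  st <- fixture_case_structure(bundle, "P2109_123")
  ret <- st$segments[st$segments$provenance == "retained", ]
  expect_equal(ret$orientation, "inverted")  # only the spacer survives
  expect_equal(c(ret$start, ret$end), c(2484970L, 2617881L))
})

test_that("structure_to_pattern reproduces printed patterns and basics", {
  # unrearranged span
  st <- descriptor_to_structure(list(), c(1, 5000), contig = "c")
  expect_equal(format(structure_to_pattern(st)), "N")

  expect_equal(format(structure_to_pattern(
    fixture_case_structure(bundle, "P2109_123"))), "DEL-INV-DEL")
  expect_equal(format(structure_to_pattern(
    fixture_case_structure(bundle, "P5513_206"))),
    "DUPinv-N-DUP-N-DUP-N-DUPinv-N-DUP")

  # regression: the descriptor-consistent subset of the cohort (the other
  # printed descriptors disagree with their printed patterns; see the
  # methods vignette)
  consistent <- c("P2109_190", "P72", "P2109_302", "P2109_123", "P2109_188",
                  "P81", "P2046_133", "P06", "P4855_511", "P2109_150",
                  "P2109_151", "P4855_512", "P5513_206")
  for (cid in consistent) {
    got <- format(structure_to_pattern(fixture_case_structure(bundle, cid)))
    exp <- bundle$patterns$wgs_pattern[bundle$patterns$case_id == cid]
    expect_equal(got, exp, label = cid)
  }
})

test_that("parse_pattern validates the token vocabulary", {
  expect_equal(unclass(parse_pattern("DEL-INV-DEL")),
               c("DEL", "INV", "DEL"))
  expect_error(parse_pattern("DEL-FOO"), "unknown pattern token")
})

test_that("classify_group partitions the cohort 8/7/6", {
  expect_equal(classify_group(cn_segments("c", 1, 10, 1)), "deletions_only")
  expect_equal(classify_group(cn_segments("c", 1, 10, 3)),
               "duplications_only")
  expect_equal(classify_group(fixture_case_cn(bundle, "P5513_116")),
               "deletions_and_duplications")
  expect_error(classify_group(cn_segments("c", 1, 10, 2)), "no copy-number")
  got <- vapply(bundle$cases$case_id, function(cid)
    classify_group(fixture_case_cn(bundle, cid)), "")
  expect_equal(sum(got == "deletions_only"), 8)
  expect_equal(sum(got == "duplications_only"), 7)
  expect_equal(sum(got == "deletions_and_duplications"), 6)
  # the fixture's own grouping agrees with the classifier
  expect_equal(unname(got), bundle$cases$group)
})
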