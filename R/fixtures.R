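# Bundled cohort fixtures: 21 clustered-CNV cases with CMA copy-number
# profiles, rearrangement descriptors, 83 breakpoint-junction records,
# CMA/WGS pattern strings, expert mechanism labels and the override table.
# Unresolved fields are kept as NA (never coerced to 0): the
# resolved-junction statistic depends on it.

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "svjigsaw")
  if (!nzchar(p)) {
    # during in-source development (tests run via pkgload)
    p <- file.path("inst", "extdata", file)
  }
  if (!file.exists(p)) stop("bundled fixture not found: ", file)
  p
}

.read_fixture_tsv <- function(file) {
  utils::read.delim(.fixture_path(file), sep = "\t", quote = "",
                    stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE)
}

#' Load the bundled clustered-CNV cohort fixture
#'
#' Returns the transcribed cohort tables: per-case metadata and
#' rearrangement descriptors, CMA copy-number segments, the 83-junction
#' table (NA preserved for unresolved fields), CMA/WGS pattern strings,
#' expert mechanism labels, the per-case mechanism override table, and
#' GRCh37 contig lengths used to resolve `pter`/`qter`.
#'
#' @return A list of class `fixture_bundle` with elements `cases`, `cn`,
#'   `junctions`, `patterns`, `mechanism_labels`, `overrides`,
#'   `contig_lengths`.
#' @export
load_fixture <- function() {
  cases <- .read_fixture_tsv("table1_cases.tsv")
  cn <- .read_fixture_tsv("table1_cn.tsv")
  junctions <- .read_fixture_tsv("table2_junctions.tsv")
  patterns <- .read_fixture_tsv("table3_patterns.tsv")
  labels <- .read_fixture_tsv("mechanism_labels.tsv")
  overrides <- .read_fixture_tsv("mechanism_overrides.tsv")
  lens <- .read_fixture_tsv("grch37_lengths.tsv")

  if (nrow(cases) != 21L) stop("fixture must contain 21 cases")
  if (nrow(junctions) != 83L) stop("fixture must contain 83 junctions")
  key <- paste(junctions$case_id, junctions$junction)
  if (anyDuplicated(key)) stop("duplicate (case, junction) in fixture")
  if (!setequal(cases$case_id, junctions$case_id) ||
      !setequal(cases$case_id, patterns$case_id) ||
      !setequal(cases$case_id, labels$case_id) ||
      !all(cn$case_id %in% cases$case_id)) {
    stop("case ids inconsistent across fixture tables")
  }
  if (!all(cases$group %in% c("deletions_only", "duplications_only",
                              "deletions_and_duplications"))) {
    stop("invalid group label in fixture")
  }
  structure(list(cases = cases, cn = cn, junctions = junctions,
                 patterns = patterns, mechanism_labels = labels,
                 overrides = overrides,
                 contig_lengths = stats::setNames(lens$length, lens$contig)),
            class = "fixture_bundle")
}

#' Copy-number profile of one fixture case
#' @param bundle A `fixture_bundle`.
#' @param case_id Case identifier.
#' @return A [cn_segments()] table.
#' @export
fixture_case_cn <- function(bundle, case_id) {
  sub <- bundle$cn[bundle$cn$case_id == case_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("unknown case ", case_id)
  cn_segments(sub$contig, sub$start, sub$end, sub$state)
}

#' Parsed descriptor of one fixture case
#' @inheritParams fixture_case_cn
#' @param normalized Use the normalized descriptor (default) or the raw
#'   printed one.
#' @return A `descriptor` object.
#' @export
fixture_case_descriptor <- function(bundle, case_id, normalized = TRUE) {
  row <- bundle$cases[bundle$cases$case_id == case_id, , drop = FALSE]
  if (nrow(row) == 0) stop("unknown case ", case_id)
  len <- unname(bundle$contig_lengths[row$contig])
  txt <- if (normalized) row$descriptor_norm else row$descriptor_raw
  parse_descriptor(txt, contig_length = len)
}

.descriptor_coord_range <- function(d) {
  vals <- unlist(lapply(d$ops, function(op) {
    c(op$start, op$end,
      unlist(lapply(op$payload, function(p) c(p$start, p$end))))
  }))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("descriptor has no determinate coordinates")
  range(vals)
}

#' Junction records of one fixture case
#'
#' Builds [junction_record()]s from the transcribed junction table. Side
#' orientations are `NA` (the printed table has no orientation column);
#' unresolved fields stay `NA`. Two printed rows carry both microhomology
#' and insertion and are loaded verbatim.
#'
#' @inheritParams fixture_case_cn
#' @return List of [junction_record()]s.
#' @export
fixture_case_junctions <- function(bundle, case_id) {
  sub <- bundle$junctions[bundle$junctions$case_id == case_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("unknown case ", case_id)
  lapply(seq_len(nrow(sub)), function(i) {
    junction_record(
      case_id, sub$junction[i],
      breakpoint_side(as.character(sub$chromosome[i]), sub$side1[i], NA),
      if (is.na(sub$side2[i])) NULL else
        breakpoint_side(as.character(sub$chromosome[i]), sub$side2[i], NA),
      microhomology_len = sub$mh[i], insertion_len = sub$ins[i],
      repeat1 = sub$repeat1[i], repeat2 = sub$repeat2[i],
      allow_mh_with_insertion = TRUE)
  })
}

#' Derivative structure reconstructed from one fixture case's descriptor
#' @inheritParams fixture_case_cn
#' @return A [derivative_structure()].
#' @export
fixture_case_structure <- function(bundle, case_id) {
  d <- fixture_case_descriptor(bundle, case_id)
  row <- bundle$cases[bundle$cases$case_id == case_id, , drop = FALSE]
  span <- .descriptor_coord_range(d)
  descriptor_to_structure(d, span, contig = row$contig, name = case_id)
}
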