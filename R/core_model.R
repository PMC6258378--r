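# Core genomic data types and sequence utilities shared by all modules.
#
# Conventions used throughout the package:
#  * all coordinates are 1-based and inclusive at both ends;
#  * a breakpoint side records the LAST RETAINED reference base of its flank
#    together with the direction that flank is read when approaching the
#    junction ("+" = reference forward ending at `position`, "-" = reverse
#    complement beginning at `position`);
#  * "N" bases never match anything in homology computations.

.VALID_BASES <- c("A", "C", "G", "T", "N")

#' Build a genome model from named contig sequences
#'
#' A genome model is the package's in-memory reference: a set of named
#' uppercase nucleotide strings over the alphabet ACGTN.
#'
#' @param contigs Named character vector (or named list of single strings);
#'   names are contig identifiers, values are nucleotide sequences.
#' @return An object of class `genome_model`: a named character vector with
#'   sequences validated and upper-cased.
#' @export
genome_model <- function(contigs) {
  contigs <- unlist(contigs)
  if (length(contigs) == 0) stop("genome model needs at least one contig")
  nm <- names(contigs)
  if (is.null(nm) || any(!nzchar(nm))) stop("contig names must be non-empty")
  if (anyDuplicated(nm)) stop("contig names must be unique")
  contigs <- toupper(contigs)
  if (any(nchar(contigs) < 1)) stop("contig sequences must be non-empty")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    stop("contig(s) ", paste(nm[bad], collapse = ", "),
         " contain characters outside ACGTN")
  }
  structure(contigs, class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", length(x), " contig(s)\n", sep = "")
  for (nm in names(x)) cat("  ", nm, ": ", nchar(x[[nm]]), " bp\n", sep = "")
  invisible(x)
}

#' Contig lengths of a genome model
#' @param genome A `genome_model`.
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  stats::setNames(nchar(unclass(genome)), names(genome))
}

.get_contig <- function(genome, contig) {
  if (!contig %in% names(genome)) {
    stop("unknown contig '", contig, "'")
  }
  unclass(genome)[[contig]]
}

#' Reverse complement of a nucleotide string
#'
#' Involution over the ACGTN alphabet; N maps to N.
#'
#' @param seq A single nucleotide string (ACGTN, case-insensitive).
#' @return The reverse complement, uppercase.
#' @export
reverse_complement <- function(seq) {
  stopifnot(length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence contains characters outside ACGTN")
  if (!nzchar(seq)) return(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Construct a breakpoint side
#'
#' @param contig Contig name.
#' @param position 1-based index of the last retained reference base of the
#'   side's flank.
#' @param orientation `"+"` if the retained flank is reference-forward ending
#'   at `position`; `"-"` if it is the reverse complement beginning at
#'   `position`. Use `NA` when the orientation could not be established.
#' @return Object of class `breakpoint_side`.
#' @export
breakpoint_side <- function(contig, position, orientation = "+") {
  stopifnot(is.character(contig), length(contig) == 1L, nzchar(contig))
  position <- as.integer(position)
  if (is.na(position) || position < 1L) stop("position must be a positive integer")
  if (!is.na(orientation) && !orientation %in% c("+", "-")) {
    stop("orientation must be '+', '-' or NA")
  }
  structure(list(contig = contig, position = position,
                 orientation = orientation),
            class = "breakpoint_side")
}

#' @export
print.breakpoint_side <- function(x, ...) {
  cat("<side> ", x$contig, ":", x$position, " (", x$orientation, ")\n", sep = "")
  invisible(x)
}

.check_side <- function(genome, side) {
  len <- nchar(.get_contig(genome, side$contig))
  if (side$position < 1L || side$position > len) {
    stop("position ", side$position, " outside contig ", side$contig,
         " (length ", len, ")")
  }
  invisible(len)
}

#' Extract the junction-facing flank of a breakpoint side
#'
#' Returns up to `k` bases of the retained flank read toward the junction.
#' For a `"+"` side these are the reference bases ending at `position`; for
#' a `"-"` side the reverse complement of the bases beginning at `position`.
#' The result is truncated at the contig edge; the `truncated` attribute is
#' `TRUE` when fewer than `k` bases were available.
#'
#' @param genome A `genome_model`.
#' @param side A `breakpoint_side`.
#' @param k Requested flank length (>= 1).
#' @return Character scalar with attribute `truncated` (logical).
#' @export
flank <- function(genome, side, k) {
  stopifnot(k >= 1)
  len <- .check_side(genome, side)
  seq <- .get_contig(genome, side$contig)
  if (identical(side$orientation, "-")) {
    to <- min(side$position + k - 1L, len)
    out <- reverse_complement(substr(seq, side$position, to))
    truncated <- (to - side$position + 1L) < k
  } else {
    from <- max(side$position - k + 1L, 1L)
    out <- substr(seq, from, side$position)
    truncated <- (side$position - from + 1L) < k
  }
  attr(out, "truncated") <- truncated
  out
}

#' Reference base just beyond a breakpoint side
#'
#' The next base that WOULD have been retained had the breakpoint slid one
#' base further toward the junction; used for microhomology sliding.
#' Returns `NA` at a contig edge.
#' @keywords internal
.beyond_side <- function(genome, side, offset = 1L) {
  seq <- .get_contig(genome, side$contig)
  len <- nchar(seq)
  if (identical(side$orientation, "-")) {
    p <- side$position - offset
    if (p < 1L) return(NA_character_)
    chartr("ACGTN", "TGCAN", substr(seq, p, p))
  } else {
    p <- side$position + offset
    if (p > len) return(NA_character_)
    substr(seq, p, p)
  }
}

#' Construct an insertion block
#'
#' Junction insertions decompose into templated blocks (copied from reference
#' sequence near the junction, either strand) and non-templated blocks.
#'
#' @param kind `"templated"` or `"non_templated"`.
#' @param sequence The inserted nucleotides (as they appear in the derivative).
#' @param source For templated blocks, `list(contig =, start =, end =,
#'   strand =)` locating the template; `NULL` for non-templated blocks.
#' @return Object of class `insertion_block`.
#' @export
insertion_block <- function(kind, sequence, source = NULL) {
  kind <- match.arg(kind, c("templated", "non_templated"))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 1) stop("insertion block must be at least 1 bp")
  if (kind == "templated") {
    if (is.null(source)) stop("templated block requires a source")
    stopifnot(all(c("contig", "start", "end", "strand") %in% names(source)))
  } else {
    source <- NULL
  }
  structure(list(kind = kind, sequence = toupper(sequence), source = source),
            class = "insertion_block")
}

#' Construct a breakpoint junction record
#'
#' One resolved (or partially resolved) breakpoint junction: two oriented
#' reference sides plus junction chemistry. `NA` fields mirror unresolved
#' junctions; microhomology and insertion are mutually exclusive (a
#' microhomologous joint has zero bases inserted between the homologous
#' copies).
#'
#' @param case_id,junction_id Case label and junction number within the case.
#' @param side1,side2 `breakpoint_side` objects (side2 may be `NULL` for
#'   one-sided junctions).
#' @param microhomology_len,microhomology_seq Microhomology length/sequence
#'   or `NA`.
#' @param insertion_len Total inserted bases or `NA`.
#' @param insertion_blocks List of `insertion_block`s or `NULL`.
#' @param repeat1,repeat2 Repeat element names overlapping each side
#'   (`"NONE"` when absent).
#' @param support Supporting read count.
#' @param consensus Junction-spanning consensus sequence or `NA`.
#' @return Object of class `junction_record`.
#' @export
junction_record <- function(case_id, junction_id, side1, side2 = NULL,
                            microhomology_len = NA_integer_,
                            microhomology_seq = NA_character_,
                            insertion_len = NA_integer_,
                            insertion_blocks = NULL,
                            repeat1 = "NONE", repeat2 = "NONE",
                            support = 0L, consensus = NA_character_,
                            allow_mh_with_insertion = FALSE) {
  stopifnot(inherits(side1, "breakpoint_side"))
  if (!is.null(side2)) stopifnot(inherits(side2, "breakpoint_side"))
  mh <- if (is.na(microhomology_len)) NA_integer_ else as.integer(microhomology_len)
  ins <- if (is.na(insertion_len)) NA_integer_ else as.integer(insertion_len)
  if (!is.na(mh) && !is.na(microhomology_seq) && mh != nchar(microhomology_seq)) {
    stop("microhomology_len does not match microhomology_seq")
  }
  if (!is.null(insertion_blocks) && length(insertion_blocks) > 0) {
    blen <- sum(vapply(insertion_blocks, function(b) nchar(b$sequence), 1L))
    if (!is.na(ins) && blen != ins) {
      stop("insertion_len does not match the sum of block lengths")
    }
  }
  # the slide-ambiguity definition of microhomology makes MH and insertion
  # mutually exclusive for characterized junctions; externally transcribed
  # tables may annotate flank-edge microhomology next to an insert, so an
  # explicit opt-out exists for such records
  if (!is.na(mh) && !is.na(ins) && mh > 0L && ins > 0L &&
      !allow_mh_with_insertion) {
    stop("microhomology and insertion cannot both be positive at one junction")
  }
  if (support < 0) stop("support must be >= 0")
  structure(list(case_id = case_id, junction_id = as.integer(junction_id),
                 side1 = side1, side2 = side2,
                 microhomology_len = mh, microhomology_seq = microhomology_seq,
                 insertion_len = ins, insertion_blocks = insertion_blocks,
                 repeat1 = repeat1, repeat2 = repeat2,
                 support = as.integer(support), consensus = consensus),
            class = "junction_record")
}

#' Is a junction resolved at nucleotide level?
#'
#' A junction is resolved when both its microhomology and insertion fields
#' are known (possibly zero).
#' @param j A `junction_record`.
#' @return Logical scalar.
#' @export
is_resolved <- function(j) {
  !is.na(j$microhomology_len) && !is.na(j$insertion_len)
}

#' @export
print.junction_record <- function(x, ...) {
  s2 <- if (is.null(x$side2)) "NA" else
    paste0(x$side2$contig, ":", x$side2$position, "(", x$side2$orientation, ")")
  cat("<junction> ", x$case_id, " #", x$junction_id, "  ",
      x$side1$contig, ":", x$side1$position, "(", x$side1$orientation, ") -- ",
      s2, "  MH=", x$microhomology_len, " Ins=", x$insertion_len,
      " support=", x$support, "\n", sep = "")
  invisible(x)
}

#' Build a validated copy-number segment table
#'
#' @param contig,start,end,state Vectors describing 1-based inclusive
#'   intervals with integer copy-number states (2 = diploid normal).
#' @return A `data.frame` of class `cn_segments`, sorted by contig then
#'   start, validated non-overlapping within each contig.
#' @export
cn_segments <- function(contig, start, end, state) {
  df <- data.frame(contig = as.character(contig), start = as.integer(start),
                   end = as.integer(end), state = as.integer(state),
                   stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop("cn segment start > end")
  if (any(df$state < 0)) stop("cn state must be >= 0")
  df <- df[order(df$contig, df$start), , drop = FALSE]
  for (ct in unique(df$contig)) {
    sub <- df[df$contig == ct, ]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)])) {
      stop("overlapping cn segments on contig ", ct)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("cn_segments", "data.frame")
  df
}

#' Construct one segment use of a derivative structure
#'
#' @param start,end Reference interval (1-based inclusive).
#' @param orientation `"forward"` or `"inverted"`.
#' @param provenance `"retained"`, `"duplicate_copy"` or `"uncertain"`.
#' @return A one-row `data.frame`.
#' @export
segment_use <- function(start, end, orientation = "forward",
                        provenance = "retained") {
  orientation <- match.arg(orientation, c("forward", "inverted"))
  provenance <- match.arg(provenance,
                          c("retained", "duplicate_copy", "uncertain"))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end) {
    stop("invalid segment interval")
  }
  data.frame(start = start, end = end, orientation = orientation,
             provenance = provenance, stringsAsFactors = FALSE)
}

#' Construct a derivative chromosome structure
#'
#' An ordered, oriented list of reference segment uses composing one
#' derivative chromosome.
#'
#' @param name Structure label.
#' @param segments `data.frame` with columns `start`, `end`, `orientation`,
#'   `provenance` (rows in derivative order, e.g. from [segment_use()]).
#' @param contig Source contig name.
#' @param span Optional length-2 integer vector: the reference interval the
#'   structure describes (needed to represent deletions touching the span
#'   edges); defaults to the range of the segment uses.
#' @return Object of class `derivative_structure`.
#' @export
derivative_structure <- function(name, segments, contig, span = NULL) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1,
            all(c("start", "end", "orientation", "provenance") %in%
                  colnames(segments)))
  rownames(segments) <- NULL
  if (is.null(span)) span <- c(min(segments$start), max(segments$end))
  structure(list(name = name, segments = segments, contig = contig,
                 span = as.integer(span)),
            class = "derivative_structure")
}

#' @export
print.derivative_structure <- function(x, ...) {
  cat("<derivative_structure> ", x$name, " (", x$contig, "), ",
      nrow(x$segments), " segment(s)\n", sep = "")
  seg <- x$segments
  tag <- ifelse(seg$orientation == "inverted", "inv", "fwd")
  mark <- ifelse(seg$provenance == "duplicate_copy", "*",
                 ifelse(seg$provenance == "uncertain", "?", ""))
  cat(paste0("  [", seg$start, "-", seg$end, " ", tag, mark, "]",
             collapse = "\n"), "\n")
  invisible(x)
}

#' Realize the nucleotide sequence of a derivative structure
#'
#' @param structure A `derivative_structure`.
#' @param genome A `genome_model` containing the source contig.
#' @param inserts Optional character vector of sequences inserted AFTER each
#'   segment (length `nrow(segments)`, last element ignored); used by the
#'   simulator to realize junction insertions.
#' @return Nucleotide string of the derivative.
#' @export
structure_sequence <- function(structure, genome, inserts = NULL) {
  seq <- .get_contig(genome, structure$contig)
  seg <- structure$segments
  parts <- character(0)
  for (i in seq_len(nrow(seg))) {
    s <- substr(seq, seg$start[i], seg$end[i])
    if (seg$orientation[i] == "inverted") s <- reverse_complement(s)
    parts <- c(parts, s)
    if (!is.null(inserts) && i < nrow(seg) && nzchar(inserts[i]) &&
        !is.na(inserts[i])) {
      parts <- c(parts, inserts[i])
    }
  }
  paste(parts, collapse = "")
}

# ---- FASTA I/O ------------------------------------------------------------

#' Read a FASTA file into a genome model
#' @param path FASTA file path.
#' @return A `genome_model`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  genome_model(stats::setNames(as.character(ss), nm))
}

#' Write a genome model to FASTA (60-column lines)
#' @param genome A `genome_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
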