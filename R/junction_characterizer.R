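# Nucleotide-resolution junction characterization: split-read collection
# and clustering, consensus assembly, junction resolution with
# microhomology and insertion decomposition, repeat annotation and
# junction-proximal novel-SNV detection.

# ---- cigar helpers --------------------------------------------------------

.cigar_parse <- function(cig) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cig)[[1]]
  toks <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))[[1]]
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^\\d+", "", toks), stringsAsFactors = FALSE)
}

# query interval (in stored-seq coordinates) and reference span of a record
.record_extent <- function(pos, cigar) {
  cp <- .cigar_parse(cigar)
  qlen <- sum(cp$len[cp$op %in% c("M", "I", "S", "=", "X")])
  lead <- if (nrow(cp) > 0 && cp$op[1] %in% c("S", "H")) cp$len[1] else 0L
  trail <- if (nrow(cp) > 0 && cp$op[nrow(cp)] %in% c("S", "H"))
    cp$len[nrow(cp)] else 0L
  rlen <- sum(cp$len[cp$op %in% c("M", "D", "N", "=", "X")])
  list(q1 = lead + 1L, q2 = qlen - trail, qlen = qlen,
       rs = pos, re = pos + rlen - 1L)
}

.is_supplementary <- function(flag) bitwAnd(flag, 2048L) > 0L
.is_reverse <- function(flag) bitwAnd(flag, 16L) > 0L
.mate_of <- function(flag) if (bitwAnd(flag, 128L) > 0L) 2L else 1L

# ---- split-read collection ------------------------------------------------

#' Collect and cluster junction-bridging split reads
#'
#' Reads whose primary and supplementary records map to two loci are turned
#' into oriented breakpoint-side-pair observations and clustered with a
#' positional tolerance. Member reads are re-oriented so that every read in
#' a group runs in the same derivative direction.
#'
#' @param alignments SAM-like data.frame (see [read_sam()]): columns
#'   `qname`, `flag`, `rname`, `pos`, `cigar`, `seq` (and optionally `sa`).
#' @param candidates Optional data.frame of candidate regions (`contig`,
#'   `start`, `end`); when given, only groups with both sides inside a
#'   padded candidate region are kept.
#' @param tolerance Clustering tolerance in bp (default 50).
#' @param min_support Minimum reads per group (default 2).
#' @param candidate_pad Padding added around candidate regions (default
#'   1000 bp).
#' @return List of `split_read_group` objects: each has `side1`, `side2`
#'   ([breakpoint_side()]s in canonical order), `reads` (co-oriented
#'   sequences), `qnames`, `support`. Records without sequence are skipped
#'   and counted in attribute `skipped`.
#' @export
collect_split_reads <- function(alignments, candidates = NULL,
                                tolerance = 50L, min_support = 2L,
                                candidate_pad = 1000L) {
  if (is.null(alignments) || nrow(alignments) == 0) return(list())
  skipped <- 0L
  obs <- list()
  key <- paste(alignments$qname, vapply(alignments$flag, .mate_of, 1L))
  for (k in unique(key)) {
    recs <- alignments[key == k, , drop = FALSE]
    if (nrow(recs) < 2) next
    if (any(!nzchar(recs$seq) | recs$seq == "*")) { skipped <- skipped + 1L; next }
    # reconstruct original-read coordinates for each mapped piece
    pieces <- lapply(seq_len(nrow(recs)), function(i) {
      ex <- .record_extent(recs$pos[i], recs$cigar[i])
      rev <- .is_reverse(recs$flag[i])
      q1 <- if (rev) ex$qlen - ex$q2 + 1L else ex$q1
      q2 <- if (rev) ex$qlen - ex$q1 + 1L else ex$q2
      list(q1 = q1, q2 = q2, rs = ex$rs, re = ex$re,
           strand = if (rev) "-" else "+", rname = recs$rname[i],
           read = if (rev) reverse_complement(recs$seq[i]) else recs$seq[i])
    })
    pieces <- pieces[order(vapply(pieces, function(p) p$q1, 1L))]
    read_seq <- pieces[[1]]$read
    for (i in seq_len(length(pieces) - 1L)) {
      pl <- pieces[[i]]; pr <- pieces[[i + 1L]]
      s_left <- if (pl$strand == "+") list(contig = pl$rname, pos = pl$re, ori = "+")
      else list(contig = pl$rname, pos = pl$rs, ori = "-")
      s_right <- if (pr$strand == "+") list(contig = pr$rname, pos = pr$rs, ori = "-")
      else list(contig = pr$rname, pos = pr$re, ori = "+")
      obs[[length(obs) + 1L]] <-
        list(left = s_left, right = s_right, read = read_seq, qname = k)
    }
  }
  if (length(obs) == 0) {
    out <- list(); attr(out, "skipped") <- skipped; return(out)
  }

  # canonical orientation of each observation: lesser (contig, pos) first
  canon <- lapply(obs, function(o) {
    flip <- (o$right$contig < o$left$contig) ||
      (o$right$contig == o$left$contig && o$right$pos < o$left$pos)
    if (flip) {
      list(s1 = o$right, s2 = o$left, read = reverse_complement(o$read),
           qname = o$qname)
    } else list(s1 = o$left, s2 = o$right, read = o$read, qname = o$qname)
  })
  ckey <- vapply(canon, function(o)
    paste(o$s1$contig, o$s1$ori, o$s2$contig, o$s2$ori), "")
  groups <- list()
  for (kk in unique(ckey)) {
    sub <- canon[ckey == kk]
    p1 <- vapply(sub, function(o) o$s1$pos, 1L)
    o <- order(p1)
    sub <- sub[o]; p1 <- p1[o]
    p2 <- vapply(sub, function(o) o$s2$pos, 1L)
    # single-linkage clustering on both side positions
    cl <- integer(length(sub)); cur <- 1L; cl[1] <- 1L
    if (length(sub) > 1) for (i in 2:length(sub)) {
      prev <- which(cl == cur)
      if (min(abs(p1[i] - p1[prev])) <= tolerance &&
          min(abs(p2[i] - p2[prev])) <= tolerance) cl[i] <- cur
      else { cur <- cur + 1L; cl[i] <- cur }
    }
    for (g in unique(cl)) {
      mem <- sub[cl == g]
      med1 <- stats::median(vapply(mem, function(o) o$s1$pos, 1L))
      med2 <- stats::median(vapply(mem, function(o) o$s2$pos, 1L))
      groups[[length(groups) + 1L]] <- structure(list(
        side1 = breakpoint_side(mem[[1]]$s1$contig, round(med1),
                                mem[[1]]$s1$ori),
        side2 = breakpoint_side(mem[[1]]$s2$contig, round(med2),
                                mem[[1]]$s2$ori),
        reads = vapply(mem, function(o) o$read, ""),
        qnames = vapply(mem, function(o) o$qname, ""),
        support = length(mem)), class = "split_read_group")
    }
  }
  groups <- Filter(function(g) g$support >= min_support, groups)
  if (!is.null(candidates) && nrow(candidates) > 0) {
    inside <- function(sd) {
      any(candidates$contig == sd$contig &
            candidates$start - candidate_pad <= sd$position &
            candidates$end + candidate_pad >= sd$position)
    }
    groups <- Filter(function(g) inside(g$side1) || inside(g$side2), groups)
  }
  attr(groups, "skipped") <- skipped
  groups
}

#' @export
print.split_read_group <- function(x, ...) {
  cat("<split_read_group> ", x$side1$contig, ":", x$side1$position,
      "(", x$side1$orientation, ") -- ", x$side2$contig, ":",
      x$side2$position, "(", x$side2$orientation, "), support ",
      x$support, "\n", sep = "")
  invisible(x)
}

# ---- consensus assembly ---------------------------------------------------

.best_offset <- function(ref_chars, read_chars, min_overlap = 25L) {
  # ungapped offset of read relative to ref maximizing matches; offset o
  # means read position 1 aligns to ref position o + 1
  nr <- length(ref_chars); nq <- length(read_chars)
  best <- NULL; best_score <- -1L
  for (o in seq.int(-(nq - min_overlap), nr - min_overlap)) {
    i1 <- max(1L, 1L - o); i2 <- min(nq, nr - o)
    if (i2 - i1 + 1L < min_overlap) next
    sc <- sum(read_chars[i1:i2] == ref_chars[(i1:i2) + o])
    if (sc > best_score) { best_score <- sc; best <- o }
  }
  list(offset = best,
       identity = if (is.null(best)) 0 else {
         i1 <- max(1L, 1L - best); i2 <- min(nq, nr - best)
         best_score / (i2 - i1 + 1L)
       })
}

#' Assemble a consensus sequence from a split-read group
#'
#' Star alignment around a seed read (the longest), greedy incorporation of
#' the remaining reads by best ungapped offset, majority vote per column
#' with ties broken in base order A < C < G < T. Reads that cannot be
#' placed (identity below `min_identity` over the overlap) are dropped; if
#' no read can be placed the seed alone is returned with a low-confidence
#' flag.
#'
#' @param group A `split_read_group` (or list with element `reads`).
#' @param min_overlap Minimum overlap for read placement (default 25 bp).
#' @param min_identity Minimum identity over the overlap (default 0.9).
#' @return Object of class `consensus_sequence`: list with `sequence`,
#'   `support` (per-base read depth), `n_reads`, `low_confidence`.
#' @export
build_consensus <- function(group, min_overlap = 25L, min_identity = 0.9) {
  reads <- group$reads
  stopifnot(length(reads) >= 1)
  reads <- reads[order(-nchar(reads))]
  seed <- strsplit(reads[1], "", fixed = TRUE)[[1]]
  # votes: matrix rows A,C,G,T over current consensus coordinates
  bases <- c("A", "C", "G", "T")
  votes <- matrix(0L, nrow = 4, ncol = length(seed),
                  dimnames = list(bases, NULL))
  off0 <- 0L  # offset of consensus column 1 in the global frame
  add_read <- function(chars, o) {
    # o: read pos 1 aligns to consensus column o + 1 (may extend)
    left_ext <- max(0L, -o)
    right_ext <- max(0L, o + length(chars) - ncol(votes))
    if (left_ext > 0L) {
      votes <<- cbind(matrix(0L, 4, left_ext, dimnames = list(bases, NULL)),
                      votes)
      o <- o + left_ext
      off0 <<- off0 - left_ext
    }
    if (right_ext > 0L) {
      votes <<- cbind(votes,
                      matrix(0L, 4, right_ext, dimnames = list(bases, NULL)))
    }
    for (bi in seq_along(bases)) {
      hit <- which(chars == bases[bi])
      if (length(hit) > 0) {
        votes[bi, hit + o] <<- votes[bi, hit + o] + 1L
      }
    }
  }
  add_read(seed, 0L)
  low_conf <- FALSE
  n_used <- 1L
  if (length(reads) > 1) {
    cur <- function() bases[apply(votes, 2, which.max)]
    for (r in reads[-1]) {
      rc_ <- strsplit(r, "", fixed = TRUE)[[1]]
      fit <- .best_offset(cur(), rc_, min_overlap)
      if (is.null(fit$offset) || fit$identity < min_identity) next
      add_read(rc_, fit$offset)
      n_used <- n_used + 1L
    }
    if (n_used == 1L) low_conf <- TRUE
  }
  depth <- colSums(votes)
  keep <- depth > 0L
  # with several contributing reads, trim single-read overhangs whose bases
  # cannot be error-corrected by the majority vote
  if (n_used >= 3L) {
    solid <- which(depth >= 2L)
    if (length(solid) > 0) {
      keep <- keep & seq_along(depth) >= min(solid) &
        seq_along(depth) <= max(solid)
    }
  }
  votes <- votes[, keep, drop = FALSE]
  cons <- bases[apply(votes, 2, which.max)]
  structure(list(sequence = paste(cons, collapse = ""),
                 support = colSums(votes), n_reads = n_used,
                 low_confidence = low_conf),
            class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat("<consensus> ", nchar(x$sequence), " bp from ", x$n_reads,
      " read(s)", if (x$low_confidence) " [low confidence]", "\n", sep = "")
  invisible(x)
}

# ---- microhomology --------------------------------------------------------

#' Compute junction microhomology by breakpoint-slide ambiguity
#'
#' Microhomology is the maximal tract over which the breakpoint can slide
#' in either direction without changing the derivative sequence: the bases
#' just beyond one side's breakpoint equal the bases the other side
#' contributes across the junction. The placement is canonicalized by
#' left-alignment (the junction is slid as far as possible toward lower
#' side-1 flank usage). `N` bases never match.
#'
#' @param genome A [genome_model()].
#' @param side1,side2 [breakpoint_side()]s.
#' @param consensus Unused by the computation (the sides fully determine
#'   the homology); accepted for interface symmetry.
#' @param max_mh Search bound (default 200).
#' @return List with `len`, `seq` (`NA` when `len` is 0), and canonical
#'   `side1`, `side2`.
#' @export
compute_microhomology <- function(genome, side1, side2, consensus = NULL,
                                  max_mh = 200L) {
  seq1 <- .get_contig(genome, side1$contig)
  seq2 <- .get_contig(genome, side2$contig)
  ok_match <- function(a, b) !is.na(a) && !is.na(b) && a != "N" && a == b
  # slide right: side1 extends, side2 shrinks
  right <- 0L
  while (right < max_mh) {
    a <- .beyond_base(seq1, side1, right + 1L)
    b <- .post_base(seq2, side2, right + 1L)
    if (!ok_match(a, b)) break
    right <- right + 1L
  }
  # slide left: side1 shrinks, side2 extends
  left <- 0L
  while (left < max_mh) {
    a <- .flank_base(seq1, side1, left + 1L)
    b <- .ext_base(seq2, side2, left + 1L)
    if (!ok_match(a, b)) break
    left <- left + 1L
  }
  mh <- left + right
  shift1 <- function(sd, k) {
    breakpoint_side(sd$contig,
                    if (identical(sd$orientation, "-")) sd$position + k
                    else sd$position - k, sd$orientation)
  }
  shift2 <- function(sd, k) {
    breakpoint_side(sd$contig,
                    if (identical(sd$orientation, "-")) sd$position - k
                    else sd$position + k, sd$orientation)
  }
  c1 <- shift1(side1, left)
  c2 <- shift2(side2, left)
  mh_seq <- NA_character_
  if (mh > 0L) {
    mh_seq <- paste(vapply(seq_len(mh), function(i)
      .post_base(seq2, c2, i), ""), collapse = "")
  }
  list(len = mh, seq = mh_seq, side1 = c1, side2 = c2)
}

# ---- insertion decomposition ----------------------------------------------

.side_windows <- function(genome, side, window) {
  seq <- .get_contig(genome, side$contig)
  s <- max(1L, side$position - window)
  e <- min(nchar(seq), side$position + window)
  w <- substr(seq, s, e)
  list(fwd = list(seq = w, start = s, end = e, strand = "+"),
       rev = list(seq = reverse_complement(w), start = s, end = e,
                  strand = "-"))
}

#' Decompose a junction insertion into templated and non-templated blocks
#'
#' Greedy left-to-right cover of the inserted sequence by maximal exact
#' matches (either strand) to the reference within `window` bases of both
#' breakpoint sides; matches of at least `min_templated` bases become
#' templated blocks with their source interval and strand, everything else
#' non-templated blocks.
#'
#' @param genome A [genome_model()].
#' @param insert Inserted sequence (may be empty).
#' @param side1,side2 [breakpoint_side()]s.
#' @param window Search window around each side (default 100 bp).
#' @param min_templated Minimum templated block length (default 10 bp).
#' @return List of [insertion_block()]s (empty for an empty insert).
#' @export
decompose_insertion <- function(genome, insert, side1, side2, window = 100L,
                                min_templated = 10L) {
  if (window < min_templated) {
    stop("window must be >= min_templated")
  }
  if (is.na(insert) || !nzchar(insert)) return(list())
  insert <- toupper(insert)
  wins <- c(.side_windows(genome, side1, window),
            .side_windows(genome, side2, window))
  n <- nchar(insert)
  blocks <- list()
  pending <- ""
  flush <- function() {
    if (nzchar(pending)) {
      blocks[[length(blocks) + 1L]] <<- insertion_block("non_templated",
                                                        pending)
      pending <<- ""
    }
  }
  i <- 1L
  while (i <= n) {
    found <- NULL
    for (L in seq.int(min(n - i + 1L, 2L * window + 1L), min_templated)) {
      if (L < min_templated) break
      sub <- substr(insert, i, i + L - 1L)
      for (wi in seq_along(wins)) {
        w <- wins[[wi]]
        off <- regexpr(sub, w$seq, fixed = TRUE)
        if (off > 0) {
          if (w$strand == "+") {
            st <- w$start + off - 1L; en <- st + L - 1L
          } else {
            en <- w$end - off + 1L; st <- en - L + 1L
          }
          side_contig <- if (wi <= 2) side1$contig else side2$contig
          found <- list(len = L, contig = side_contig, start = st, end = en,
                        strand = w$strand, seq = sub)
          break
        }
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) {
      pending <- paste0(pending, substr(insert, i, i))
      i <- i + 1L
    } else {
      flush()
      blocks[[length(blocks) + 1L]] <- insertion_block(
        "templated", found$seq,
        list(contig = found$contig, start = found$start, end = found$end,
             strand = found$strand))
      i <- i + found$len
    }
  }
  flush()
  blocks
}

# ---- junction resolution --------------------------------------------------

.anchor_map <- function(genome, consensus, from_end = FALSE,
                        seed_len = 31L, max_shift = 48L, shift_step = 8L) {
  # locate the consensus prefix (or suffix) in the genome by exact seeding,
  # stepping the probe inward when sequencing noise breaks the outermost
  # k-mer, then extend the match maximally in both directions
  n <- nchar(consensus)
  k <- min(seed_len, n)
  cmp1 <- function(sq, p) substr(sq, p, p)
  for (shift in seq.int(0L, min(max_shift, n - k), by = shift_step)) {
    p0 <- if (from_end) n - k + 1L - shift else 1L + shift
    if (p0 < 1L) break
    probe <- substr(consensus, p0, p0 + k - 1L)
    for (ct in names(genome)) {
      seq <- .get_contig(genome, ct)
      for (strand in c("+", "-")) {
        target <- if (strand == "+") probe else reverse_complement(probe)
        off <- regexpr(target, seq, fixed = TRUE)
        if (off <= 0) next
        if (strand == "+") {
          c1 <- p0; c2 <- p0 + k - 1L; rs <- off; re <- off + k - 1L
          while (c2 < n && re < nchar(seq) &&
                 cmp1(consensus, c2 + 1L) == cmp1(seq, re + 1L)) {
            c2 <- c2 + 1L; re <- re + 1L
          }
          while (c1 > 1L && rs > 1L &&
                 cmp1(consensus, c1 - 1L) == cmp1(seq, rs - 1L)) {
            c1 <- c1 - 1L; rs <- rs - 1L
          }
          return(list(c1 = c1, c2 = c2, rs = rs, re = re, strand = "+",
                      contig = ct))
        } else {
          # consensus position c1 maps to reference re; c2 to rs
          c1 <- p0; c2 <- p0 + k - 1L; rs <- off; re <- off + k - 1L
          while (c2 < n && rs > 1L &&
                 cmp1(consensus, c2 + 1L) ==
                 chartr("ACGTN", "TGCAN", cmp1(seq, rs - 1L))) {
            c2 <- c2 + 1L; rs <- rs - 1L
          }
          while (c1 > 1L && re < nchar(seq) &&
                 cmp1(consensus, c1 - 1L) ==
                 chartr("ACGTN", "TGCAN", cmp1(seq, re + 1L))) {
            c1 <- c1 - 1L; re <- re + 1L
          }
          return(list(c1 = c1, c2 = c2, rs = rs, re = re, strand = "-",
                      contig = ct))
        }
      }
    }
  }
  NULL
}

.map_cpos <- function(anchor, ci) {
  # reference coordinate of consensus position ci under an anchor mapping
  if (anchor$strand == "+") anchor$rs + (ci - anchor$c1)
  else anchor$re - (ci - anchor$c1)
}

#' Resolve a consensus sequence into a junction record
#'
#' The consensus is anchored to the reference by maximal exact extension of
#' its prefix and suffix (either strand, built-in 31-mer seeding). When the
#' two anchors overlap in consensus coordinates the overlap is
#' microhomology; when they leave a gap the gap is inserted sequence, which
#' is decomposed into templated/non-templated blocks. The junction is
#' canonicalized by left-alignment.
#'
#' @param consensus A `consensus_sequence` (or plain string).
#' @param genome A [genome_model()].
#' @param case_id,junction_id Labels for the emitted record.
#' @param min_anchor Minimum anchored bases on each side (default 20).
#' @param window,min_templated Passed to [decompose_insertion()].
#' @param support Read support to attach.
#' @return A [junction_record()]; unresolved consensus yields a record with
#'   `NA` microhomology/insertion fields and attribute `unresolved`.
#' @export
resolve_junction <- function(consensus, genome, case_id = "case",
                             junction_id = 1L, min_anchor = 20L,
                             window = 100L, min_templated = 10L,
                             support = NULL) {
  cseq <- if (inherits(consensus, "consensus_sequence")) consensus$sequence
  else as.character(consensus)
  supp <- if (!is.null(support)) support
  else if (inherits(consensus, "consensus_sequence")) consensus$n_reads
  else 1L
  n <- nchar(cseq)
  a1 <- .anchor_map(genome, cseq, from_end = FALSE)
  a2 <- .anchor_map(genome, cseq, from_end = TRUE)
  unresolved <- function(msg) {
    side <- if (!is.null(a1)) {
      if (a1$strand == "+") breakpoint_side(a1$contig, a1$re, "+")
      else breakpoint_side(a1$contig, a1$rs, "-")
    } else breakpoint_side(names(genome)[1], 1L, NA)
    rec <- junction_record(case_id, junction_id, side1 = side, side2 = NULL,
                           support = supp, consensus = cseq)
    attr(rec, "unresolved") <- msg
    rec
  }
  if (is.null(a1) || is.null(a2)) return(unresolved("anchor not found"))
  if (a1$c2 - a1$c1 + 1L < min_anchor || a2$c2 - a2$c1 + 1L < min_anchor) {
    return(unresolved("anchor too short"))
  }
  if (a1$c2 >= n && a2$c1 <= 1L) {
    return(unresolved("consensus fully reference-aligned (no junction)"))
  }

  # junction in consensus coordinates, left-aligned: side1 ends at the base
  # before the suffix anchor begins
  i1 <- a1$c2; i2 <- a2$c1
  jl <- min(i1, i2 - 1L)           # last side-1 base (leftmost placement)
  side1 <- if (a1$strand == "+") {
    breakpoint_side(a1$contig, .map_cpos(a1, jl), "+")
  } else breakpoint_side(a1$contig, .map_cpos(a1, jl), "-")
  first2 <- max(i2, jl + 1L)       # first consensus base owned by side 2
  side2 <- if (a2$strand == "+") {
    breakpoint_side(a2$contig, .map_cpos(a2, first2), "-")
  } else breakpoint_side(a2$contig, .map_cpos(a2, first2), "+")

  if (i2 > i1 + 1L) {
    insert <- substr(cseq, i1 + 1L, i2 - 1L)
    blocks <- decompose_insertion(genome, insert, side1, side2,
                                  window = window,
                                  min_templated = min_templated)
    junction_record(case_id, junction_id, side1 = side1, side2 = side2,
                    microhomology_len = 0L, insertion_len = nchar(insert),
                    insertion_blocks = blocks, support = supp,
                    consensus = cseq)
  } else {
    mh <- compute_microhomology(genome, side1, side2)
    junction_record(case_id, junction_id, side1 = mh$side1, side2 = mh$side2,
                    microhomology_len = mh$len, microhomology_seq = mh$seq,
                    insertion_len = 0L, support = supp, consensus = cseq)
  }
}

#' Characterize all junctions in a set of alignments
#'
#' Convenience pipeline: [collect_split_reads()], [build_consensus()] and
#' [resolve_junction()] per group.
#'
#' @inheritParams collect_split_reads
#' @param genome A [genome_model()].
#' @param case_id Case label for emitted records.
#' @param ... Passed to [resolve_junction()].
#' @return List of [junction_record()]s, ordered by canonical side-1
#'   coordinate.
#' @export
characterize_junctions <- function(alignments, genome, case_id = "case",
                                   candidates = NULL, tolerance = 50L,
                                   min_support = 2L, ...) {
  groups <- collect_split_reads(alignments, candidates = candidates,
                                tolerance = tolerance,
                                min_support = min_support)
  if (length(groups) == 0) return(list())
  o <- order(vapply(groups, function(g) g$side1$contig, ""),
             vapply(groups, function(g) g$side1$position, 1L))
  groups <- groups[o]
  lapply(seq_along(groups), function(i) {
    cons <- build_consensus(groups[[i]])
    resolve_junction(cons, genome, case_id = case_id, junction_id = i,
                     support = groups[[i]]$support, ...)
  })
}

# ---- repeat annotation ----------------------------------------------------

#' Repeat family of a repeat-element name
#'
#' Name-prefix classes: `Alu`, `LINE` (L1-L4, HAL), `MIR`, `LTR` (LTR, MLT,
#' MER, MST, THE, HERV), otherwise `other`.
#' @param name Repeat element name (e.g. `"AluSx"`).
#' @return Family string.
#' @export
repeat_family <- function(name) {
  vapply(name, function(x) {
    if (is.na(x) || x == "NONE") return("other")
    if (grepl("^Alu", x)) return("Alu")
    if (grepl("^(L1|L2|L3|L4|HAL)", x)) return("LINE")
    if (grepl("^MIR", x)) return("MIR")
    if (grepl("^(LTR|MLT|MER|MST|THE|HERV)", x)) return("LTR")
    "other"
  }, "", USE.NAMES = FALSE)
}

#' Annotate a junction's sides with overlapping repeat elements
#'
#' @param junction A [junction_record()].
#' @param track data.frame with columns `contig`, `start`, `end`, `name`
#'   (1-based inclusive intervals, e.g. from [read_repeat_track()]).
#' @return The junction with `repeat1`/`repeat2` filled (`"NONE"` when no
#'   overlap) and attribute `same_family` set when both sides' repeat
#'   families match (and are not `other`).
#' @export
annotate_repeats <- function(junction, track) {
  hit <- function(sd) {
    if (is.null(sd)) return("NONE")
    i <- which(track$contig == sd$contig & track$start <= sd$position &
                 track$end >= sd$position)
    if (length(i) == 0) "NONE" else track$name[i[1]]
  }
  junction$repeat1 <- hit(junction$side1)
  junction$repeat2 <- hit(junction$side2)
  f1 <- repeat_family(junction$repeat1); f2 <- repeat_family(junction$repeat2)
  attr(junction, "same_family") <-
    junction$repeat1 != "NONE" && junction$repeat2 != "NONE" &&
    f1 == f2 && f1 != "other"
  junction
}

# ---- junction-proximal novel SNVs -----------------------------------------

#' Find novel SNVs near breakpoint junctions
#'
#' Pileup over windows around every junction side; positions where an
#' alternate base reaches the required fraction and depth become SNV
#' candidates. Candidates present in the population frequency table above
#' `af_threshold` are flagged non-novel and removed from the novel list.
#'
#' @param alignments SAM-like data.frame.
#' @param genome A [genome_model()].
#' @param junctions List of [junction_record()]s.
#' @param window Window around each side (default 1000 bp).
#' @param freq_table Optional data.frame (`contig`, `pos`, `ref`, `alt`,
#'   `af`); `NULL` marks all candidates `unfiltered`.
#' @param af_threshold Maximum population frequency for a novel SNV
#'   (default 0: any reported variant is filtered).
#' @param min_frac Minimum alternate-allele read fraction (default 0.25).
#' @param min_depth Minimum depth (default 8).
#' @return data.frame with one row per candidate SNV: `contig`, `pos`,
#'   `ref`, `alt`, `distance`, `af`, `novel`, `unfiltered`.
#' @export
find_novel_snvs <- function(alignments, genome, junctions, window = 1000L,
                            freq_table = NULL, af_threshold = 0,
                            min_frac = 0.25, min_depth = 8L) {
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      distance = integer(0), af = numeric(0),
                      novel = logical(0), unfiltered = logical(0))
  if (is.null(alignments) || nrow(alignments) == 0 || length(junctions) == 0) {
    return(empty)
  }
  sides <- list()
  for (j in junctions) for (sd in list(j$side1, j$side2)) {
    if (!is.null(sd)) sides[[length(sides) + 1L]] <- sd
  }
  # per-contig position set of interest
  want <- list()
  for (sd in sides) {
    lo <- max(1L, sd$position - window); hi <- sd$position + window
    want[[sd$contig]] <- c(want[[sd$contig]], seq.int(lo, hi))
  }
  want <- lapply(want, function(v) sort(unique(v)))
  counts <- list()  # contig -> matrix 4 x positions
  bases <- c("A", "C", "G", "T")
  for (ct in names(want)) {
    counts[[ct]] <- matrix(0L, nrow = 4, ncol = length(want[[ct]]),
                           dimnames = list(bases, NULL))
  }
  for (i in seq_len(nrow(alignments))) {
    ct <- alignments$rname[i]
    if (!ct %in% names(want)) next
    cp <- .cigar_parse(alignments$cigar[i])
    qpos <- 1L; rpos <- alignments$pos[i]
    sq <- alignments$seq[i]
    for (k in seq_len(nrow(cp))) {
      op <- cp$op[k]; ln <- cp$len[k]
      if (op %in% c("M", "=", "X")) {
        idx <- match(seq.int(rpos, rpos + ln - 1L), want[[ct]])
        ok <- which(!is.na(idx))
        if (length(ok) > 0) {
          bvec <- strsplit(substr(sq, qpos, qpos + ln - 1L), "",
                           fixed = TRUE)[[1]]
          for (b in seq_along(bases)) {
            sel <- ok[bvec[ok] == bases[b]]
            if (length(sel) > 0) {
              counts[[ct]][b, idx[sel]] <- counts[[ct]][b, idx[sel]] + 1L
            }
          }
        }
        qpos <- qpos + ln; rpos <- rpos + ln
      } else if (op %in% c("S", "I")) {
        qpos <- qpos + ln
      } else if (op %in% c("D", "N")) {
        rpos <- rpos + ln
      }
    }
  }
  rows <- list()
  for (ct in names(want)) {
    if (!ct %in% names(genome)) next
    seqc <- .get_contig(genome, ct)
    mat <- counts[[ct]]
    depth <- colSums(mat)
    for (ii in which(depth >= min_depth)) {
      pos <- want[[ct]][ii]
      refb <- substr(seqc, pos, pos)
      for (b in seq_along(bases)) {
        if (bases[b] == refb) next
        frac <- mat[b, ii] / depth[ii]
        if (frac >= min_frac) {
          dist <- min(vapply(sides, function(sd)
            if (sd$contig == ct) abs(sd$position - pos) else .Machine$integer.max,
            1L))
          rows[[length(rows) + 1L]] <-
            data.frame(contig = ct, pos = pos, ref = refb, alt = bases[b],
                       distance = dist, af = NA_real_, novel = NA,
                       unfiltered = TRUE)
        }
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  if (!is.null(freq_table)) {
    out$unfiltered <- FALSE
    out$novel <- TRUE
    for (r in seq_len(nrow(out))) {
      hit <- which(freq_table$contig == out$contig[r] &
                     freq_table$pos == out$pos[r] &
                     freq_table$alt == out$alt[r])
      if (length(hit) > 0) {
        out$af[r] <- freq_table$af[hit[1]]
        if (out$af[r] > af_threshold) out$novel[r] <- FALSE
      }
    }
  }
  rownames(out) <- NULL
  out
}
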