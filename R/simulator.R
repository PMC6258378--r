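# Rearrangement simulator: synthetic references, planted derivatives with
# fully specified junction chemistry, and reads/alignments emitted
# analytically from the truth mapping (no external aligner), so that every
# sequence-level operation can be tested hermetically.

#' Generate a random reference genome
#'
#' @param length Contig length (>= 1000).
#' @param gc_fraction Target GC content, strictly between 0 and 1.
#' @param seed RNG seed.
#' @param contig Contig name.
#' @return A [genome_model()] with one contig; reproducible per seed, with
#'   realized GC within binomial fluctuation of the request.
#' @export
random_reference <- function(length, gc_fraction = 0.41, seed = 42L,
                             contig = "chrS") {
  if (length < 1000) stop("reference length must be >= 1000")
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    stop("gc_fraction must be strictly between 0 and 1")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
               collapse = "")
  genome_model(stats::setNames(seq, contig))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_base <- function(base) {
  sample(setdiff(c("A", "C", "G", "T"), toupper(base)), 1L)
}

#' Specify a rearrangement to plant
#'
#' The derivative is described as an ordered, oriented segment plan on one
#' contig; between consecutive segments one junction chemistry is applied.
#'
#' Chemistry elements (one per junction, i.e. `nrow(segments) - 1`):
#' \itemize{
#'   \item `list(type = "blunt")` — clean fusion, MH 0 / Ins 0;
#'   \item `list(type = "mh", len = k)` — k bases of engineered
#'     microhomology (the junction can slide k bases without changing the
#'     derivative);
#'   \item `list(type = "insertion", blocks = list(...))` — inserted
#'     sequence between the flanks; each block is
#'     `list(kind = "non_templated", len = n)` or
#'     `list(kind = "templated", len = n, side = 1|2, offset = o,
#'     strand = "+"|"-")` copying `n` bases from the reference near the
#'     named side (`offset` bases from the breakpoint, within the
#'     templated-search window by default).
#' }
#'
#' @param contig Contig name.
#' @param segments `data.frame(start, end, orientation)` in derivative
#'   order (`orientation` `"forward"`/`"inverted"`).
#' @param chemistry List of chemistry elements as described above.
#' @param snvs Optional `data.frame(pos, alt)` of heterozygous SNVs planted
#'   on the derivative haplotype.
#' @param name Plant label.
#' @param seed RNG seed for random insert content.
#' @return Object of class `plant_spec`.
#' @export
plant_spec <- function(contig, segments, chemistry = NULL, snvs = NULL,
                       name = "plant", seed = 42L) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1,
            all(c("start", "end", "orientation") %in% colnames(segments)))
  nj <- nrow(segments) - 1L
  if (is.null(chemistry)) chemistry <- rep(list(list(type = "blunt")), nj)
  if (length(chemistry) != nj) {
    stop("need one chemistry element per junction (", nj, ")")
  }
  for (ch in chemistry) {
    if (!ch$type %in% c("blunt", "mh", "insertion")) {
      stop("unknown chemistry type ", ch$type)
    }
    if (ch$type == "mh" && (is.null(ch$len) || ch$len < 1)) {
      stop("mh chemistry needs len >= 1")
    }
  }
  structure(list(contig = contig, segments = segments, chemistry = chemistry,
                 snvs = snvs, name = name, seed = seed),
            class = "plant_spec")
}

# oriented junction sides implied by consecutive plan segments
.plan_sides <- function(segments, i) {
  s1 <- if (segments$orientation[i] == "forward") {
    list(position = segments$end[i], orientation = "+")
  } else {
    list(position = segments$start[i], orientation = "-")
  }
  s2 <- if (segments$orientation[i + 1L] == "forward") {
    list(position = segments$start[i + 1L], orientation = "-")
  } else {
    list(position = segments$end[i + 1L], orientation = "+")
  }
  list(s1 = s1, s2 = s2)
}

# i-th reference base beyond a side (reading toward the junction and past it)
.ref_set_beyond <- function(seq, side, i, base) {
  p <- if (side$orientation == "-") side$position - i else side$position + i
  if (p < 1 || p > nchar(seq)) return(seq)
  b <- if (side$orientation == "-") chartr("ACGTN", "TGCAN", base) else base
  substr(seq, p, p) <- b
  seq
}

.post_base <- function(seq, side, i) {
  # i-th derivative base after the junction contributed by side2
  if (side$orientation == "+") {
    p <- side$position - i + 1L
    if (p < 1) return(NA_character_)
    chartr("ACGTN", "TGCAN", substr(seq, p, p))
  } else {
    p <- side$position + i - 1L
    if (p > nchar(seq)) return(NA_character_)
    substr(seq, p, p)
  }
}

.flank_base <- function(seq, side, i) {
  # i-th retained base of a side counting back from the junction
  if (side$orientation == "+") {
    p <- side$position - i + 1L
    if (p < 1) return(NA_character_)
    substr(seq, p, p)
  } else {
    p <- side$position + i - 1L
    if (p > nchar(seq)) return(NA_character_)
    chartr("ACGTN", "TGCAN", substr(seq, p, p))
  }
}

.beyond_base <- function(seq, side, i) {
  # i-th base continuing a side's flank past its breakpoint (the base the
  # flank would gain if the junction slid toward the other side)
  if (side$orientation == "-") {
    p <- side$position - i
    if (p < 1) return(NA_character_)
    chartr("ACGTN", "TGCAN", substr(seq, p, p))
  } else {
    p <- side$position + i
    if (p > nchar(seq)) return(NA_character_)
    substr(seq, p, p)
  }
}

.ext_base <- function(seq, side, i) {
  # i-th base the POST-junction derivative sequence of side 2 would gain at
  # its front if the junction slid left; the reverse complement of the
  # flank continuation, read in derivative orientation
  b <- .beyond_base(seq, side, i)
  if (is.na(b)) NA_character_ else chartr("ACGTN", "TGCAN", b)
}

#' Plant a rearrangement into a genome
#'
#' Builds the derivative segment by segment. For microhomology chemistry
#' the reference is edited so that both flanks share exactly the requested
#' homology tract across the junction; for blunt and insertion junctions
#' accidental microhomology at the joint is removed the same way. Templated
#' insert blocks copy reference sequence from the requested offset near a
#' side (minus-strand blocks are reverse-complemented). The returned truth
#' carries the (edited) genome, the derivative sequence, the expected
#' junction table, copy-number segments and derivative structure.
#'
#' @param genome A [genome_model()].
#' @param spec A [plant_spec()].
#' @return Object of class `simulated_truth`.
#' @export
plant_rearrangement <- function(genome, spec) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  seq <- .get_contig(genome, spec$contig)
  segs <- spec$segments
  nj <- nrow(segs) - 1L
  inserts <- rep("", max(nj, 0L))
  junctions <- list()

  if (nj > 0) for (i in seq_len(nj)) {
    sd <- .plan_sides(segs, i)
    s1 <- breakpoint_side(spec$contig, sd$s1$position, sd$s1$orientation)
    s2 <- breakpoint_side(spec$contig, sd$s2$position, sd$s2$orientation)
    ch <- spec$chemistry[[i]]
    mh_len <- 0L; mh_seq <- NA_character_
    ins_len <- 0L; blocks <- NULL

    if (ch$type == "mh") {
      k <- as.integer(ch$len)
      # engineer: the k bases beyond side1 equal the first k derivative
      # bases after the junction; mismatch at k+1; no left slide
      for (t in seq_len(k)) {
        pb <- .post_base(seq, s2, t)
        if (is.na(pb)) stop("microhomology runs off the contig")
        seq <- .ref_set_beyond(seq, s1, t, pb)
      }
      pb <- .post_base(seq, s2, k + 1L)
      bb <- .beyond_base(seq, s1, k + 1L)
      if (!is.na(pb) && !is.na(bb) && pb == bb) {
        seq <- .ref_set_beyond(seq, s1, k + 1L, .mutate_base(pb))
      }
      fb <- .flank_base(seq, s1, 1L)
      b2 <- .ext_base(seq, s2, 1L)
      if (!is.na(fb) && !is.na(b2) && fb == b2) {
        # mutate the base beyond side2 so the junction cannot slide left
        p <- if (s2$orientation == "-") s2$position - 1L else s2$position + 1L
        substr(seq, p, p) <- .mutate_base(substr(seq, p, p))
      }
      mh_len <- k
      mh_seq <- paste(vapply(seq_len(k), function(t)
        .post_base(seq, s2, t), ""), collapse = "")
    } else {
      # blunt or insertion: forbid any slide in either direction
      pb <- .post_base(seq, s2, 1L); bb <- .beyond_base(seq, s1, 1L)
      if (!is.na(pb) && !is.na(bb) && pb == bb) {
        seq <- .ref_set_beyond(seq, s1, 1L, .mutate_base(pb))
      }
      fb <- .flank_base(seq, s1, 1L); b2 <- .ext_base(seq, s2, 1L)
      if (!is.na(fb) && !is.na(b2) && fb == b2) {
        p <- if (s2$orientation == "-") s2$position - 1L else s2$position + 1L
        substr(seq, p, p) <- .mutate_base(substr(seq, p, p))
      }
    }

    if (ch$type == "insertion") {
      blocks <- list()
      parts <- character(0)
      for (bl in ch$blocks) {
        if (bl$kind == "non_templated") {
          s <- .rand_dna(bl$len)
          blocks[[length(blocks) + 1L]] <-
            insertion_block("non_templated", s)
          parts <- c(parts, s)
        } else {
          side <- if (identical(bl$side, 2L) || identical(bl$side, 2)) s2 else s1
          st <- side$position + as.integer(bl$offset)
          en <- st + as.integer(bl$len) - 1L
          if (st < 1 || en > nchar(seq)) stop("templated source off contig")
          src <- substr(seq, st, en)
          if (identical(bl$strand, "-")) src <- reverse_complement(src)
          blocks[[length(blocks) + 1L]] <-
            insertion_block("templated", src,
                            list(contig = spec$contig, start = st, end = en,
                                 strand = if (identical(bl$strand, "-")) "-"
                                 else "+"))
          parts <- c(parts, src)
        }
      }
      insert <- paste(parts, collapse = "")
      # the insert ends must not extend either flank, or the planted
      # breakpoints would not be canonical: only the reference is edited
      # (never the insert, whose content may be templated)
      first <- substr(insert, 1L, 1L); lastc <- substr(insert, nchar(insert),
                                                       nchar(insert))
      bb <- .beyond_base(seq, s1, 1L)
      if (!is.na(bb) && first == bb) {
        seq <- .ref_set_beyond(seq, s1, 1L, .mutate_base(first))
      }
      b2 <- .ext_base(seq, s2, 1L)
      if (!is.na(b2) && lastc == b2) {
        p <- if (s2$orientation == "-") s2$position - 1L else s2$position + 1L
        substr(seq, p, p) <- .mutate_base(substr(seq, p, p))
      }
      inserts[i] <- insert
      ins_len <- nchar(insert)
    }

    junctions[[i]] <- junction_record(
      case_id = spec$name, junction_id = i, side1 = s1, side2 = s2,
      microhomology_len = mh_len,
      microhomology_seq = if (mh_len > 0) mh_seq else NA_character_,
      insertion_len = ins_len, insertion_blocks = blocks)
  }

  genome2 <- genome_model(stats::setNames(seq, spec$contig))
  st <- derivative_structure(
    spec$name,
    do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
      segment_use(segs$start[i], segs$end[i], segs$orientation[i], "retained")
    })), spec$contig)
  # mark repeated uses of an interval as duplicate copies
  key <- paste(st$segments$start, st$segments$end)
  st$segments$provenance[duplicated(key)] <- "duplicate_copy"
  derivative <- structure_sequence(st, genome2, inserts)

  # planted heterozygous SNVs (derivative haplotype only)
  snv_truth <- NULL
  if (!is.null(spec$snvs) && nrow(spec$snvs) > 0) {
    map <- .derivative_blocks(st, inserts)
    rows <- list()
    for (r in seq_len(nrow(spec$snvs))) {
      pos <- spec$snvs$pos[r]; alt <- toupper(spec$snvs$alt[r])
      hit <- which(map$kind == "ref" & map$rs <= pos & map$re >= pos)
      for (h in hit) {
        d <- if (map$strand[h] == "+") map$ds[h] + (pos - map$rs[h])
        else map$ds[h] + (map$re[h] - pos)
        b <- if (map$strand[h] == "+") alt else chartr("ACGTN", "TGCAN", alt)
        substr(derivative, d, d) <- b
      }
      rows[[r]] <- data.frame(contig = spec$contig, pos = pos,
                              ref = substr(seq, pos, pos), alt = alt)
    }
    snv_truth <- do.call(rbind, rows)
  }

  # expected copy-number profile over the plan's footprint
  bounds <- sort(unique(c(segs$start, segs$end + 1L)))
  cn_rows <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    s <- bounds[i]; e <- bounds[i + 1L] - 1L
    copies <- sum(segs$start <= s & segs$end >= e)
    cn_rows[[i]] <- data.frame(contig = spec$contig, start = s, end = e,
                               state = copies + 1L)
  }
  cn_df <- do.call(rbind, cn_rows)
  cn_df <- cn_df[cn_df$state != 2L | c(TRUE, diff(cn_df$state) != 0)[seq_len(nrow(cn_df))], , drop = FALSE]
  cn <- cn_segments(cn_df$contig, cn_df$start, cn_df$end, cn_df$state)

  structure(list(genome = genome2, derivative = derivative,
                 junctions = junctions, structure = st, inserts = inserts,
                 cn = cn, snvs = snv_truth, spec = spec),
            class = "simulated_truth")
}

#' @export
print.simulated_truth <- function(x, ...) {
  cat("<simulated_truth> ", x$spec$name, ": derivative ",
      nchar(x$derivative), " bp, ", length(x$junctions), " junction(s)\n",
      sep = "")
  invisible(x)
}

# derivative-coordinate blocks of a structure (+ inserts): each row maps a
# derivative interval [ds, de] to reference [rs, re] on a strand, or to an
# inserted sequence
.derivative_blocks <- function(st, inserts = NULL) {
  seg <- st$segments
  ds <- integer(0); de <- integer(0); rs <- integer(0); re <- integer(0)
  strand <- character(0); kind <- character(0)
  cur <- 0L
  for (i in seq_len(nrow(seg))) {
    len <- seg$end[i] - seg$start[i] + 1L
    ds <- c(ds, cur + 1L); de <- c(de, cur + len)
    rs <- c(rs, seg$start[i]); re <- c(re, seg$end[i])
    strand <- c(strand, if (seg$orientation[i] == "inverted") "-" else "+")
    kind <- c(kind, "ref")
    cur <- cur + len
    if (!is.null(inserts) && i <= length(inserts) && nzchar(inserts[i])) {
      ilen <- nchar(inserts[i])
      ds <- c(ds, cur + 1L); de <- c(de, cur + ilen)
      rs <- c(rs, NA_integer_); re <- c(re, NA_integer_)
      strand <- c(strand, "+"); kind <- c(kind, "ins")
      cur <- cur + ilen
    }
  }
  data.frame(ds = ds, de = de, rs = rs, re = re, strand = strand, kind = kind,
             stringsAsFactors = FALSE)
}

#' Sequencing-library configuration for the read simulator
#'
#' Defaults emulate a PCR-free short-read whole-genome library: 2 x 150 bp
#' reads, 350 bp mean insert size, 30x coverage. A mate-pair profile uses
#' long fragments (2-15 kb).
#'
#' @param type `"paired_end"` or `"mate_pair"`.
#' @param read_length Read length in bp.
#' @param fragment_mean,fragment_sd Fragment-size distribution (bp); for
#'   mate-pair libraries the defaults switch to 2-15 kb fragments.
#' @param coverage Mean haploid coverage of the derivative.
#' @param error_rate Per-base substitution error probability.
#' @param seed RNG seed.
#' @return Object of class `library_config`.
#' @export
library_config <- function(type = c("paired_end", "mate_pair"),
                           read_length = 150L, fragment_mean = NULL,
                           fragment_sd = NULL, coverage = 30,
                           error_rate = 0, seed = 1L) {
  type <- match.arg(type)
  if (is.null(fragment_mean)) {
    fragment_mean <- if (type == "paired_end") 350 else 8000
  }
  if (is.null(fragment_sd)) {
    fragment_sd <- if (type == "paired_end") 50 else 2000
  }
  if (read_length > fragment_mean) stop("read length exceeds fragment size")
  if (coverage <= 0) stop("coverage must be > 0")
  structure(list(type = type, read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 coverage = coverage, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "library_config")
}

.apply_errors <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  hit <- which(stats::runif(n) < rate)
  if (length(hit) == 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in hit) v[i] <- .mutate_base(v[i])
  paste(v, collapse = "")
}

#' Simulate reads and split alignments from a planted truth
#'
#' Fragments are sampled uniformly from the derivative at the requested
#' coverage; both fragment-end reads are reported. Each read's alignment is
#' computed analytically from the truth mapping: reads crossing planted
#' junctions become split records (primary plus supplementary, soft-clipped,
#' with `SA` links); bases originating from inserted sequence stay clipped.
#'
#' @param truth A `simulated_truth`.
#' @param lib A [library_config()].
#' @param min_piece Minimum aligned piece length to emit a record (default
#'   20 bp).
#' @return List with `reads` (data.frame `qname`, `mate`, `seq`) and
#'   `alignments` (SAM-like data.frame, see [write_sam()]).
#' @export
generate_reads <- function(truth, lib = library_config(), min_piece = 20L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(lib$seed)
  D <- truth$derivative
  L <- nchar(D)
  if (L <= lib$fragment_mean) stop("derivative shorter than fragment size")
  rl <- lib$read_length
  nfrag <- max(1L, round(lib$coverage * L / (2 * rl)))
  blocks <- .derivative_blocks(truth$structure, truth$inserts)
  contig <- truth$spec$contig

  qn_v <- sprintf("frag%06d", seq_len(nfrag))
  out_reads <- list(qname = rep(qn_v, each = 2L),
                    mate = rep(c(1L, 2L), nfrag),
                    seq = character(2L * nfrag))
  acc <- new.env(parent = emptyenv())
  acc$qname <- character(0); acc$flag <- integer(0); acc$rname <- character(0)
  acc$pos <- integer(0); acc$mapq <- integer(0); acc$cigar <- character(0)
  acc$seq <- character(0); acc$sa <- character(0)
  for (f in seq_len(nfrag)) {
    flen <- as.integer(min(L, max(2L * rl,
                                  round(stats::rnorm(1, lib$fragment_mean,
                                                     lib$fragment_sd)))))
    fs <- sample.int(L - flen + 1L, 1L)
    fe <- fs + flen - 1L
    qn <- qn_v[f]
    r1 <- .apply_errors(substr(D, fs, fs + rl - 1L), lib$error_rate)
    r2 <- .apply_errors(reverse_complement(substr(D, fe - rl + 1L, fe)),
                        lib$error_rate)
    out_reads$seq[2L * f - 1L] <- r1
    out_reads$seq[2L * f] <- r2
    .align_read(acc, qn, 1L, r1, fs, fs + rl - 1L, FALSE, blocks, contig,
                min_piece)
    .align_read(acc, qn, 2L, r2, fe - rl + 1L, fe, TRUE, blocks, contig,
                min_piece)
  }
  aln <- if (length(acc$qname) > 0) {
    data.frame(qname = acc$qname, flag = acc$flag, rname = acc$rname,
               pos = acc$pos, mapq = acc$mapq, cigar = acc$cigar,
               rnext = "*", pnext = 0L, tlen = 0L, seq = acc$seq,
               qual = "*", sa = acc$sa, stringsAsFactors = FALSE)
  } else NULL
  list(reads = data.frame(out_reads, stringsAsFactors = FALSE),
       alignments = aln)
}

# analytic alignment of one read covering derivative interval [a, b];
# appends records to the accumulator environment
.align_read <- function(acc, qname, mate, read_seq, a, b, is_rc, blocks,
                        contig, min_piece) {
  Lr <- nchar(read_seq)
  ov <- blocks[blocks$ds <= b & blocks$de >= a, , drop = FALSE]
  q1 <- integer(0); q2 <- integer(0); rs <- integer(0); re <- integer(0)
  strand <- character(0)
  for (i in seq_len(nrow(ov))) {
    pa <- max(ov$ds[i], a); pb <- min(ov$de[i], b)
    if (ov$kind[i] != "ref") next
    if (pb - pa + 1L < min_piece) next
    if (ov$strand[i] == "+") {
      prs <- ov$rs[i] + (pa - ov$ds[i]); pre <- ov$rs[i] + (pb - ov$ds[i])
    } else {
      pre <- ov$re[i] - (pa - ov$ds[i]); prs <- ov$re[i] - (pb - ov$ds[i])
    }
    if (!is_rc) { pq1 <- pa - a + 1L; pq2 <- pb - a + 1L }
    else { pq1 <- b - pb + 1L; pq2 <- b - pa + 1L }
    ps <- if (!is_rc) ov$strand[i] else if (ov$strand[i] == "+") "-" else "+"
    q1 <- c(q1, as.integer(pq1)); q2 <- c(q2, as.integer(pq2))
    rs <- c(rs, as.integer(prs)); re <- c(re, as.integer(pre))
    strand <- c(strand, ps)
  }
  if (length(q1) == 0) return(invisible())
  o <- order(q1)
  q1 <- q1[o]; q2 <- q2[o]; rs <- rs[o]; re <- re[o]; strand <- strand[o]
  prim <- which.max(q2 - q1)
  n <- length(q1)
  flags <- integer(n); cigs <- character(n); seqs <- character(n)
  rcseq <- if (any(strand == "-")) reverse_complement(read_seq) else NULL
  for (k in seq_len(n)) {
    if (strand[k] == "+") {
      seqs[k] <- read_seq
      lc <- q1[k] - 1L; rc <- Lr - q2[k]
    } else {
      seqs[k] <- rcseq
      lc <- Lr - q2[k]; rc <- q1[k] - 1L
    }
    cigs[k] <- paste0(if (lc > 0) paste0(lc, "S") else "",
                      re[k] - rs[k] + 1L, "M",
                      if (rc > 0) paste0(rc, "S") else "")
    fl <- 0L
    if (strand[k] == "-") fl <- fl + 16L
    fl <- fl + (if (mate == 1L) 64L else 128L)
    if (k != prim) fl <- fl + 2048L
    flags[k] <- fl
  }
  sa <- rep("", n)
  if (n > 1) {
    satok <- paste0(contig, ",", rs, ",", strand, ",", cigs, ",60,0;")
    sa <- vapply(seq_len(n), function(k) paste(satok[-k], collapse = ""), "")
  }
  acc$qname <- c(acc$qname, rep(qname, n))
  acc$flag <- c(acc$flag, flags)
  acc$rname <- c(acc$rname, rep(contig, n))
  acc$pos <- c(acc$pos, rs)
  acc$mapq <- c(acc$mapq, rep(60L, n))
  acc$cigar <- c(acc$cigar, cigs)
  acc$seq <- c(acc$seq, seqs)
  acc$sa <- c(acc$sa, sa)
  invisible()
}
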