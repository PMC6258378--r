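# Assembly of junction records and copy-number segments into candidate
# derivative structures, duplication-architecture classification, and
# junction comparison across cases.

#' Classify the duplications of a derivative structure
#'
#' A duplicated fragment is any `duplicate_copy` segment use whose interval
#' retains at least two copies on the derivative haplotype over the
#' majority of its length (payload copies of regions deleted in place are
#' copy-neutral relocations, not duplications, and are skipped). A
#' duplication is `tandem` when the copy is in direct orientation and sits
#' immediately after derivative material that carries its template (the
#' preceding segment is retained, forward, and reference-continuous with
#' the copy's interval); otherwise it is `interspersed`.
#'
#' @param structure A [derivative_structure()].
#' @param min_dup_fraction Minimum fraction of a copy's length that must be
#'   present in >= 2 derivative copies to call it a duplication (default
#'   0.5).
#' @return `data.frame` with one row per duplication: `start`, `end`,
#'   `architecture` (`tandem`/`interspersed`), `orientation`
#'   (`direct`/`inverted`), `adjacent_to_other_duplicate` (logical).
#'   Zero rows when the structure has no duplications.
#' @export
classify_duplications <- function(structure, min_dup_fraction = 0.5) {
  seg <- structure$segments
  empty <- data.frame(start = integer(0), end = integer(0),
                      architecture = character(0), orientation = character(0),
                      adjacent_to_other_duplicate = logical(0),
                      stringsAsFactors = FALSE)
  idx <- which(seg$provenance == "duplicate_copy")
  if (length(idx) == 0) return(empty)

  # per-copy fraction of interval covered by at least one OTHER segment use
  dup_frac <- function(i) {
    s <- seg$start[i]; e <- seg$end[i]
    others <- seg[-i, , drop = FALSE]
    ov_s <- pmax(others$start, s); ov_e <- pmin(others$end, e)
    ok <- ov_s <= ov_e
    if (!any(ok)) return(0)
    # union length of overlaps
    iv <- cbind(ov_s[ok], ov_e[ok])
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    tot <- 0L; cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
    for (r in seq_len(nrow(iv))[-1]) {
      if (iv[r, 1] <= cur_e + 1L) cur_e <- max(cur_e, iv[r, 2])
      else { tot <- tot + (cur_e - cur_s + 1L); cur_s <- iv[r, 1]; cur_e <- iv[r, 2] }
    }
    tot <- tot + (cur_e - cur_s + 1L)
    tot / (e - s + 1L)
  }

  rows <- lapply(idx, function(i) {
    if (dup_frac(i) < min_dup_fraction) return(NULL)
    direct <- seg$orientation[i] == "forward"
    tandem <- FALSE
    if (direct && i > 1) {
      prv <- seg[i - 1L, ]
      tandem <- prv$provenance == "retained" &&
        prv$orientation == "forward" &&
        seg$start[i] <= prv$end + 1L && prv$end + 1L <= seg$end[i] + 1L
    }
    nb_dup <- (i > 1 && seg$provenance[i - 1L] == "duplicate_copy") ||
      (i < nrow(seg) && seg$provenance[i + 1L] == "duplicate_copy")
    data.frame(start = seg$start[i], end = seg$end[i],
               architecture = if (tandem) "tandem" else "interspersed",
               orientation = if (direct) "direct" else "inverted",
               adjacent_to_other_duplicate = nb_dup,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Junctions implied by adjacent segment uses of a derivative structure
#'
#' Every pair of consecutive segment uses that are not simply
#' reference-adjacent in identical orientation implies a novel junction;
#' the oriented sides follow the package's breakpoint-side convention.
#'
#' @param structure A [derivative_structure()].
#' @param case_id Label attached to the records.
#' @return List of [junction_record()]s (possibly empty).
#' @export
implied_junctions <- function(structure, case_id = structure$name) {
  seg <- structure$segments
  out <- list()
  for (i in seq_len(nrow(seg) - 1L)) {
    a <- seg[i, ]; b <- seg[i + 1L, ]
    ref_adjacent <- a$orientation == "forward" && b$orientation == "forward" &&
      b$start == a$end + 1L
    if (ref_adjacent) next
    s1 <- if (a$orientation == "forward") {
      breakpoint_side(structure$contig, a$end, "+")
    } else breakpoint_side(structure$contig, a$start, "-")
    s2 <- if (b$orientation == "forward") {
      breakpoint_side(structure$contig, b$start, "-")
    } else breakpoint_side(structure$contig, b$end, "+")
    out[[length(out) + 1L]] <-
      junction_record(case_id, length(out) + 1L, s1, s2,
                      microhomology_len = NA, insertion_len = NA)
  }
  out
}

#' Compare two junction records
#'
#' @param a,b `junction_record`s with both sides present.
#' @param tolerance Positional tolerance (bp) for the `compatible` verdict;
#'   `identical` requires exact coordinates.
#' @return `"identical"`, `"compatible"` or `"distinct"`.
#' @export
junction_equivalence <- function(a, b, tolerance = 0L) {
  if (is.null(a$side2) || is.null(b$side2)) {
    stop("junction_equivalence requires both sides of both records")
  }
  sides <- function(j) {
    s <- list(j$side1, j$side2)
    o <- order(vapply(s, function(x) x$contig, ""),
               vapply(s, function(x) x$position, 1L))
    s[o]
  }
  sa <- sides(a); sb <- sides(b)
  same_contigs <- sa[[1]]$contig == sb[[1]]$contig &&
    sa[[2]]$contig == sb[[2]]$contig
  if (!same_contigs) return("distinct")
  d1 <- abs(sa[[1]]$position - sb[[1]]$position)
  d2 <- abs(sa[[2]]$position - sb[[2]]$position)
  ori_ok <- (is.na(sa[[1]]$orientation) || is.na(sb[[1]]$orientation) ||
               sa[[1]]$orientation == sb[[1]]$orientation) &&
    (is.na(sa[[2]]$orientation) || is.na(sb[[2]]$orientation) ||
       sa[[2]]$orientation == sb[[2]]$orientation)
  if (!ori_ok) return("distinct")
  seq_ok <- TRUE
  if (!is.na(a$microhomology_seq) && !is.na(b$microhomology_seq)) {
    seq_ok <- identical(a$microhomology_seq, b$microhomology_seq)
  }
  if (!is.na(a$microhomology_len) && !is.na(b$microhomology_len) &&
      a$microhomology_len != b$microhomology_len) seq_ok <- FALSE
  if (d1 == 0L && d2 == 0L && seq_ok) return("identical")
  if (d1 <= tolerance && d2 <= tolerance) return("compatible")
  "distinct"
}

# ---- fragment graph -------------------------------------------------------

#' Build a fragment graph from junctions and copy-number segments
#'
#' The reference span is partitioned at every junction breakpoint and
#' copy-number boundary; the resulting nodes carry the local copy-number
#' state and the number of copies expected on the derivative haplotype
#' (`state - 1`, at least 0). Junction edges connect oriented node ends;
#' one-sided junctions become half-edges.
#'
#' @param junctions List of `junction_record`s on one contig.
#' @param cn A [cn_segments()] table for the same contig (may be empty).
#' @param span Length-2 vector, the reference interval under analysis.
#' @return Object of class `fragment_graph`: list with `nodes` (data.frame
#'   `start`, `end`, `state`, `copies`), `edges` (junction edges with node
#'   indices and attachment ends), `half_edges`, `span`, `contig`.
#' @export
build_fragment_graph <- function(junctions, cn, span) {
  span <- as.integer(span)
  contig <- if (length(junctions) > 0) junctions[[1]]$side1$contig
  else if (nrow(cn) > 0) cn$contig[1] else "chr"
  bp <- integer(0)
  for (j in junctions) {
    for (sd in list(j$side1, j$side2)) {
      if (is.null(sd)) next
      if (sd$position < span[1] || sd$position > span[2]) {
        stop("junction coordinate ", sd$position, " outside span")
      }
      # a side ending at p (orientation +) cuts after p; a side starting at
      # p (orientation -) cuts before p
      bp <- c(bp, if (identical(sd$orientation, "-")) sd$position - 1L
              else sd$position)
    }
  }
  if (nrow(cn) > 0) bp <- c(bp, cn$start - 1L, cn$end)
  bp <- sort(unique(bp[bp >= span[1] & bp < span[2]]))
  starts <- c(span[1], bp + 1L)
  ends <- c(bp, span[2])
  state <- rep(2L, length(starts))
  if (nrow(cn) > 0) {
    for (i in seq_along(starts)) {
      hit <- cn$start <= starts[i] & cn$end >= ends[i] & cn$contig == contig
      if (any(hit)) state[i] <- cn$state[which(hit)[1]]
    }
  }
  nodes <- data.frame(start = starts, end = ends, state = state,
                      copies = pmax(state - 1L, 0L))
  locate <- function(sd) {
    # returns c(node index, end): "+" attaches at the right end of the node
    # ending at position; "-" at the left end of the node starting at it
    if (identical(sd$orientation, "-")) {
      i <- which(nodes$start == sd$position)
      if (length(i) != 1) stop("side position does not align to a node start")
      c(i, 0L)  # left end
    } else {
      i <- which(nodes$end == sd$position)
      if (length(i) != 1) stop("side position does not align to a node end")
      c(i, 1L)  # right end
    }
  }
  edges <- list(); half <- list()
  for (k in seq_along(junctions)) {
    j <- junctions[[k]]
    if (is.null(j$side2)) {
      half[[length(half) + 1L]] <- list(junction = k, at = locate(j$side1))
    } else {
      edges[[length(edges) + 1L]] <-
        list(junction = k, a = locate(j$side1), b = locate(j$side2))
    }
  }
  structure(list(nodes = nodes, edges = edges, half_edges = half,
                 junctions = junctions, span = span, contig = contig),
            class = "fragment_graph")
}

#' @export
print.fragment_graph <- function(x, ...) {
  cat("<fragment_graph> ", x$contig, ":", x$span[1], "-", x$span[2], "; ",
      nrow(x$nodes), " nodes, ", length(x$edges), " junction edge(s), ",
      length(x$half_edges), " half-edge(s)\n", sep = "")
  invisible(x)
}

#' Enumerate derivative structures consistent with a fragment graph
#'
#' Depth-first search over walks that start at the span's left terminus,
#' end at its right terminus, consume every node exactly its derivative
#' copy count and every junction edge exactly once. Reference-adjacency
#' steps are always permitted between neighbouring nodes with remaining
#' copies. Results are returned in deterministic (lexicographic) order.
#'
#' @param graph A `fragment_graph`.
#' @param max_solutions Cap on the number of structures returned.
#' @return List of [derivative_structure()]s. Zero-length when no
#'   consistent walk exists (an attribute `infeasible` carries diagnostics).
#' @export
enumerate_structures <- function(graph, max_solutions = 64L) {
  nodes <- graph$nodes
  n <- nrow(nodes)
  edges <- graph$edges
  sols <- list()
  seen <- new.env(hash = TRUE)

  # path entries: c(node, dir) with dir +1 forward, -1 inverted
  recurse <- function(node, dir, rem, eleft, path) {
    if (length(sols) >= max_solutions) return(invisible())
    # end position: right end of last node if forward at last node n
    if (node == n && dir == 1L && all(rem == 0L) && !any(eleft)) {
      key <- paste(path, collapse = ";")
      if (!exists(key, envir = seen)) {
        assign(key, TRUE, envir = seen)
        sols[[length(sols) + 1L]] <<- path
      }
      return(invisible())
    }
    # current walk position is the "outgoing" end of (node, dir):
    # forward -> right end (1), inverted -> left end (0)
    out_end <- if (dir == 1L) 1L else 0L
    # 1) junction edges attached at this node end
    for (ei in which(eleft)) {
      e <- edges[[ei]]
      for (ab in list(c(1, 2), c(2, 1))) {
        from <- if (ab[1] == 1) e$a else e$b
        to <- if (ab[1] == 1) e$b else e$a
        if (from[1] != node || from[2] != out_end) next
        nxt <- to[1]
        if (rem[nxt] <= 0L) next
        # entering the next node at end to[2]: entering at its right end
        # means traversing it inverted
        ndir <- if (to[2] == 1L) -1L else 1L
        rem2 <- rem; rem2[nxt] <- rem2[nxt] - 1L
        el2 <- eleft; el2[ei] <- FALSE
        recurse(nxt, ndir, rem2, el2, c(path, paste0(nxt, ":", ndir)))
      }
    }
    # 2) reference adjacency
    nxt <- if (dir == 1L) node + 1L else node - 1L
    if (nxt >= 1L && nxt <= n && rem[nxt] > 0L) {
      rem2 <- rem; rem2[nxt] <- rem2[nxt] - 1L
      recurse(nxt, dir, rem2, eleft, c(path, paste0(nxt, ":", dir)))
    }
    invisible()
  }

  rem <- nodes$copies
  eleft <- rep(TRUE, length(edges))
  if (rem[1] <= 0L) {
    out <- list()
    attr(out, "infeasible") <- "left terminus node has no copies"
    return(out)
  }
  rem[1] <- rem[1] - 1L
  recurse(1L, 1L, rem, eleft, paste0("1:1"))

  if (length(sols) == 0) {
    out <- list()
    attr(out, "infeasible") <- "no walk consumes all node copies and edges"
    return(out)
  }
  sols <- sols[order(vapply(sols, paste, "", collapse = ";"))]
  lapply(seq_along(sols), function(si) {
    steps <- sols[[si]]
    parts <- do.call(rbind, strsplit(steps, ":", fixed = TRUE))
    ni <- as.integer(parts[, 1]); dir <- as.integer(parts[, 2])
    counts <- integer(n)
    segs <- do.call(rbind, lapply(seq_along(ni), function(k) {
      i <- ni[k]
      counts[i] <<- counts[i] + 1L
      segment_use(nodes$start[i], nodes$end[i],
                  if (dir[k] == 1L) "forward" else "inverted",
                  if (counts[i] > 1L) "duplicate_copy" else "retained")
    }))
    derivative_structure(paste0("solution_", si), segs, graph$contig,
                         span = graph$span)
  })
}
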