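# Parser/serializer for HGVS-like complex-rearrangement descriptors
# (a pragmatic subset: del, inv, dup, ins, delins, nested [..;..] payloads,
# pter/qter termini and "?" uncertainty -- exactly the constructs occurring
# in published clustered-CNV case descriptors), plus derivation of
# copy-number/orientation pattern strings and CNV-type group labels.

.PATTERN_TOKENS <- c("DEL", "DUP", "DUPinv", "INV", "N", "DIP")

.norm_descriptor_text <- function(text) {
  x <- gsub("\\s+", "", text)
  # typographic noise seen in printed tables: stray underscore before the
  # ins/delins keyword, and a stray semicolon splitting a range from its
  # delins keyword
  x <- gsub("_(delins|ins)", "\\1", x)
  x <- gsub(";delins", "delins", x, fixed = TRUE)
  x
}

.parse_coord <- function(tok, contig_length = NA_integer_) {
  if (tok == "pter") return(list(value = 1L, raw = tok, uncertain = FALSE))
  if (tok == "qter") {
    return(list(value = if (is.na(contig_length)) NA_integer_ else
      as.integer(contig_length), raw = tok, uncertain = FALSE))
  }
  if (tok == "?") return(list(value = NA_integer_, raw = tok, uncertain = TRUE))
  v <- suppressWarnings(as.integer(tok))
  if (is.na(v)) stop("malformed coordinate '", tok, "'")
  list(value = v, raw = tok, uncertain = FALSE)
}

.coord_re <- "(\\d+|pter|qter|\\?)"

.parse_payload_element <- function(el, contig_length) {
  if (el == "?") {
    return(list(start = NA_integer_, end = NA_integer_, start_raw = "?",
                end_raw = "?", orientation = "forward", uncertain = TRUE))
  }
  m <- regmatches(el, regexec(paste0("^", .coord_re, "_", .coord_re,
                                     "(inv)?$"), el))[[1]]
  if (length(m) == 0) stop("malformed payload element '", el, "'")
  a <- .parse_coord(m[2], contig_length)
  b <- .parse_coord(m[3], contig_length)
  inv <- identical(m[4], "inv")
  s <- a$value; e <- b$value
  # a reference-descending range denotes an inverted copy
  if (!is.na(s) && !is.na(e) && s > e) {
    tmp <- s; s <- e; e <- tmp
    inv <- TRUE
  }
  list(start = s, end = e, start_raw = a$raw, end_raw = b$raw,
       orientation = if (inv) "inverted" else "forward",
       inv_suffix = identical(m[4], "inv"),
       uncertain = a$uncertain || b$uncertain)
}

.split_top <- function(x, sep = ";") {
  depth <- 0L
  out <- character(0)
  buf <- character(0)
  for (ch in strsplit(x, "", fixed = TRUE)[[1]]) {
    if (ch == "[") depth <- depth + 1L
    if (ch == "]") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced brackets in descriptor")
    if (ch == sep && depth == 0L) {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character(0)
    } else buf <- c(buf, ch)
  }
  if (depth != 0L) stop("unbalanced brackets in descriptor")
  c(out, paste(buf, collapse = ""))
}

.parse_clause <- function(clause, contig_length) {
  if (clause == "?") {
    return(list(kind = "uncertain", start = NA_integer_, end = NA_integer_,
                start_raw = "?", end_raw = "?", uncertain = TRUE,
                degenerate = FALSE, payload = NULL, raw = clause))
  }
  m <- regmatches(clause, regexec(
    paste0("^", .coord_re, "_", .coord_re,
           "(delins|ins|del|inv|dup)?(.*)$"), clause))[[1]]
  if (length(m) == 0) stop("malformed clause '", clause, "'")
  a <- .parse_coord(m[2], contig_length)
  b <- .parse_coord(m[3], contig_length)
  kind <- m[4]
  rest <- m[5]
  if (kind == "" && rest == "") {
    kind <- "seg"                       # bare range clause
  } else if (kind %in% c("del", "inv", "dup")) {
    if (nzchar(rest)) stop("trailing text after '", kind, "' in '", clause, "'")
  } else if (!kind %in% c("ins", "delins")) {
    stop("unknown operation suffix in clause '", clause, "'")
  }
  payload <- NULL
  if (kind %in% c("ins", "delins")) {
    if (!nzchar(rest)) stop(kind, " clause lacks a payload: '", clause, "'")
    elems <- if (startsWith(rest, "[")) {
      if (!endsWith(rest, "]")) stop("unbalanced payload brackets in '", clause, "'")
      .split_top(substr(rest, 2L, nchar(rest) - 1L))
    } else rest
    payload <- lapply(elems, .parse_payload_element, contig_length = contig_length)
  }
  s <- a$value; e <- b$value
  degenerate <- FALSE
  if (!is.na(s) && !is.na(e) && s > e) {
    # reversed target interval as printed; width treated as 0
    tmp <- s; s <- e; e <- tmp
    degenerate <- TRUE
  }
  list(kind = kind, start = s, end = e, start_raw = a$raw, end_raw = b$raw,
       uncertain = a$uncertain || b$uncertain ||
         any(vapply(payload, function(p) isTRUE(p$uncertain), TRUE)),
       degenerate = degenerate, payload = payload, raw = clause)
}

#' Parse an HGVS-like complex-rearrangement descriptor
#'
#' Accepts strings of the form `ACCESSION:g.[clause;clause;...]` (the
#' accession prefix is optional) where each clause is one of
#' `A_Bdel`, `A_Binv`, `A_Bdup`, `A_Bins<payload>`, `A_Bdelins<payload>`,
#' a bare range `A_B`, or `?`. Payloads are single ranges or bracketed
#' semicolon-separated lists; each element may carry an `inv` suffix (a
#' reference-descending range also denotes an inverted copy). Coordinates
#' may be numbers, `pter`, `qter` or `?`. Whitespace is tolerated anywhere.
#'
#' @param text Descriptor string.
#' @param contig_length Optional contig length used to resolve `qter`.
#' @return Object of class `descriptor`: list with `accession` and `ops`
#'   (one parsed operation per clause).
#' @export
parse_descriptor <- function(text, contig_length = NA_integer_) {
  x <- .norm_descriptor_text(text)
  accession <- NA_character_
  at <- regexpr(":g.", x, fixed = TRUE)
  if (at > 0) {
    accession <- substr(x, 1L, at - 1L)
    if (grepl("[][]", accession)) stop("malformed accession prefix")
    x <- substr(x, at + 3L, nchar(x))
  } else if (startsWith(x, "g.")) {
    x <- substr(x, 3L, nchar(x))
  }
  if (!startsWith(x, "[") || !endsWith(x, "]")) {
    stop("descriptor body must be bracketed: 'g.[...]'")
  }
  body <- substr(x, 2L, nchar(x) - 1L)
  clauses <- .split_top(body)
  ops <- lapply(clauses, .parse_clause, contig_length = contig_length)
  structure(list(accession = accession, ops = ops), class = "descriptor")
}

.serialize_payload_element <- function(p) {
  if (p$start_raw == "?" && p$end_raw == "?" && is.na(p$start)) return("?")
  paste0(p$start_raw, "_", p$end_raw, if (isTRUE(p$inv_suffix)) "inv" else "")
}

#' Serialize a parsed descriptor back to its string form
#'
#' Inverse of [parse_descriptor()] modulo whitespace: raw coordinate tokens
#' (`pter`, `qter`, `?`, reference-descending ranges) are preserved.
#'
#' @param d A `descriptor` object.
#' @return Descriptor string.
#' @export
serialize_descriptor <- function(d) {
  stopifnot(inherits(d, "descriptor"))
  cl <- vapply(d$ops, function(op) {
    if (op$kind == "uncertain") return("?")
    base <- paste0(op$start_raw, "_", op$end_raw)
    if (op$kind == "seg") return(base)
    if (op$kind %in% c("del", "inv", "dup")) return(paste0(base, op$kind))
    pay <- vapply(op$payload, .serialize_payload_element, "")
    paste0(base, op$kind,
           if (length(pay) > 1) paste0("[", paste(pay, collapse = ";"), "]")
           else pay)
  }, "")
  body <- paste0("[", paste(cl, collapse = ";"), "]")
  if (!is.na(d$accession)) paste0(d$accession, ":g.", body)
  else paste0("g.", body)
}

# ---- derivative structure from descriptor ---------------------------------

#' Rebuild a derivative chromosome structure from descriptor operations
#'
#' Retained reference segments are interleaved with deletions (omitted),
#' inversions (orientation flipped in place), `dup` targets (an extra
#' forward copy immediately 3' of the template) and `ins`/`delins` payload
#' copies placed at their target position in their stated orientation.
#' Payload and dup copies are tagged `duplicate_copy`; clauses or payload
#' elements with unknown coordinates yield `uncertain` segment uses (with
#' unknown intervals dropped from the walk).
#'
#' @param d A `descriptor` object (or list of parsed ops).
#' @param span Length-2 integer vector: the reference interval the walk
#'   covers; must contain all determinate op targets.
#' @param contig Contig name attached to the resulting structure.
#' @param name Structure label.
#' @return A [derivative_structure()].
#' @export
descriptor_to_structure <- function(d, span, contig = "chr",
                                    name = "derivative") {
  ops <- if (inherits(d, "descriptor")) d$ops else d
  span <- as.integer(span)
  stopifnot(length(span) == 2L, span[1] <= span[2])

  del_iv <- list(); inv_iv <- list(); events <- list()
  for (op in ops) {
    if (op$kind == "uncertain") next
    s <- op$start; e <- op$end
    if (op$kind %in% c("del", "delins") && !op$degenerate &&
        !is.na(s) && !is.na(e)) {
      if (s < span[1] || e > span[2]) stop("op target outside span")
      del_iv[[length(del_iv) + 1L]] <- c(s, e)
    }
    if (op$kind == "inv" && !op$degenerate && !is.na(s) && !is.na(e)) {
      inv_iv[[length(inv_iv) + 1L]] <- c(s, e)
    }
    if (op$kind == "dup" && !is.na(s) && !is.na(e)) {
      events[[length(events) + 1L]] <-
        list(at = e + 0.5, elems = list(list(start = s, end = e,
                                             orientation = "forward",
                                             uncertain = FALSE)))
    }
    if (op$kind == "seg" && !is.na(s) && !is.na(e)) {
      # bare range: a copy whose placement the descriptor leaves open
      events[[length(events) + 1L]] <-
        list(at = s - 0.5, elems = list(list(start = s, end = e,
                                             orientation = "forward",
                                             uncertain = TRUE)))
    }
    if (op$kind %in% c("ins", "delins") && !is.null(op$payload)) {
      at <- if (op$kind == "delins") {
        if (is.na(s)) span[1] - 0.25 else s - 0.5
      } else {
        if (is.na(s)) span[1] - 0.25 else s + 0.5
      }
      elems <- Filter(function(p) !is.na(p$start) && !is.na(p$end), op$payload)
      elems <- lapply(elems, function(p) {
        p$uncertain <- isTRUE(p$uncertain) || op$uncertain
        p
      })
      if (length(elems) > 0) {
        events[[length(events) + 1L]] <- list(at = at, elems = elems)
      }
    }
  }

  # elementary retained intervals: span minus deletions, split at inversion
  # boundaries and insertion anchors, orientation flipped where covered by
  # an inversion
  ev_cuts <- vapply(events, function(ev) as.integer(ceiling(ev$at)), 1L)
  cuts <- sort(unique(c(span[1], span[2] + 1L,
                        unlist(lapply(del_iv, function(v) c(v[1], v[2] + 1L))),
                        unlist(lapply(inv_iv, function(v) c(v[1], v[2] + 1L))),
                        ev_cuts)))
  cuts <- cuts[cuts >= span[1] & cuts <= span[2] + 1L]
  pieces <- data.frame(start = cuts[-length(cuts)], end = cuts[-1] - 1L)
  covered_by <- function(iv_list, s, e) {
    any(vapply(iv_list, function(v) v[1] <= s && e <= v[2], TRUE))
  }
  keep <- !vapply(seq_len(nrow(pieces)), function(i)
    covered_by(del_iv, pieces$start[i], pieces$end[i]), TRUE)
  pieces <- pieces[keep, , drop = FALSE]
  if (nrow(pieces) > 0) {
    pieces$orientation <- vapply(seq_len(nrow(pieces)), function(i)
      if (covered_by(inv_iv, pieces$start[i], pieces$end[i])) "inverted"
      else "forward", "")
  }

  # interleave retained pieces and insertion events by reference position
  items <- list()
  for (i in seq_len(nrow(pieces))) {
    items[[length(items) + 1L]] <-
      list(at = pieces$start[i], seg = segment_use(
        pieces$start[i], pieces$end[i], pieces$orientation[i], "retained"))
  }
  for (ev in events) {
    for (el in ev$elems) {
      items[[length(items) + 1L]] <-
        list(at = ev$at, seg = segment_use(
          el$start, el$end, el$orientation,
          if (isTRUE(el$uncertain)) "uncertain" else "duplicate_copy"))
    }
  }
  if (length(items) == 0) stop("descriptor yields an empty structure")
  ord <- order(vapply(items, function(it) it$at, 1), seq_along(items))
  segs <- do.call(rbind, lapply(items[ord], function(it) it$seg))
  # re-merge retained pieces that remained reference-contiguous in the
  # derivative with equal orientation and nothing inserted between them
  out <- segs[1, , drop = FALSE]
  for (i in seq_len(nrow(segs))[-1]) {
    last <- nrow(out)
    if (segs$provenance[i] == "retained" && out$provenance[last] == "retained" &&
        segs$orientation[i] == out$orientation[last] &&
        segs$start[i] == out$end[last] + 1L) {
      out$end[last] <- segs$end[i]
    } else out <- rbind(out, segs[i, ])
  }
  derivative_structure(name, out, contig, span = span)
}

# ---- pattern strings ------------------------------------------------------

#' Derive the copy-number/orientation pattern string of a derivative
#'
#' Walks the rearranged reference span left to right and emits one token per
#' maximal segment: `DEL` where no copy survives on the derivative
#' haplotype, `DUP`/`DUPinv` where extra copies exist (by duplicate
#' orientation), `INV` for copy-neutral segments whose surviving copy is
#' inverted, and `N` otherwise. Distinct duplicate fragments keep distinct
#' tokens even when adjacent; `DEL`/`N` runs are merged. Tokens narrower
#' than `min_token` bases are suppressed unless they are `INV` (copy-neutral
#' inversions are junction-level evidence, not dosage segments).
#'
#' A forward payload copy flanked on both sides (in the derivative) by
#' inverted duplicate copies is treated as part of a block inversion and
#' reported inverted.
#'
#' @param structure A [derivative_structure()].
#' @param cn Optional [cn_segments()] table; when supplied, the walk span is
#'   extended to cover its aberrant segments.
#' @param min_token Minimum width (bp) for non-`INV` tokens (default 2,
#'   i.e. only single-base artifacts of printed coordinates are dropped).
#' @return Character vector of tokens, class `pattern_string`.
#' @export
structure_to_pattern <- function(structure, cn = NULL, min_token = 2L) {
  seg <- structure$segments
  ret <- seg[seg$provenance == "retained", , drop = FALSE]
  cop <- seg[seg$provenance != "retained", , drop = FALSE]

  # effective orientation: block-inversion context rule
  cop_eff <- cop
  if (nrow(cop) > 0) {
    idx_all <- which(seg$provenance != "retained")
    for (k in seq_along(idx_all)) {
      i <- idx_all[k]
      if (seg$orientation[i] == "inverted") next
      lp <- if (i > 1) i - 1L else NA_integer_
      rp <- if (i < nrow(seg)) i + 1L else NA_integer_
      both_inv <- !is.na(lp) && !is.na(rp) &&
        seg$provenance[lp] != "retained" && seg$provenance[rp] != "retained" &&
        seg$orientation[lp] == "inverted" && seg$orientation[rp] == "inverted"
      if (both_inv) cop_eff$orientation[cop_eff$start == seg$start[i] &
                                          cop_eff$end == seg$end[i] &
                                          cop_eff$orientation == "forward"][1] <- "inverted"
    }
  }

  # affected region: copies, inverted retained pieces, and gaps in the
  # retained cover
  aff_s <- integer(0); aff_e <- integer(0)
  if (nrow(cop) > 0) { aff_s <- c(aff_s, cop$start); aff_e <- c(aff_e, cop$end) }
  inv_ret <- ret[ret$orientation == "inverted", , drop = FALSE]
  if (nrow(inv_ret) > 0) { aff_s <- c(aff_s, inv_ret$start); aff_e <- c(aff_e, inv_ret$end) }
  # deletions = gaps in the retained cover over the structure's span
  span <- if (!is.null(structure$span)) structure$span else
    c(min(ret$start), max(ret$end))
  if (nrow(ret) > 0) {
    o <- order(ret$start)
    bnd_s <- c(span[1], ret$end[o] + 1L)
    bnd_e <- c(ret$start[o] - 1L, span[2])
    ok <- bnd_s <= bnd_e
    aff_s <- c(aff_s, bnd_s[ok]); aff_e <- c(aff_e, bnd_e[ok])
  } else {
    aff_s <- c(aff_s, span[1]); aff_e <- c(aff_e, span[2])
  }
  if (!is.null(cn)) {
    ab <- cn[cn$state != 2L & cn$contig == structure$contig, , drop = FALSE]
    if (nrow(ab) > 0) { aff_s <- c(aff_s, ab$start); aff_e <- c(aff_e, ab$end) }
  }
  if (length(aff_s) == 0) {
    return(structure("N", class = "pattern_string"))
  }
  lo <- min(aff_s); hi <- max(aff_e)

  cuts <- sort(unique(c(lo, hi + 1L, seg$start, seg$end + 1L)))
  cuts <- cuts[cuts >= lo & cuts <= hi + 1L]
  iv_s <- cuts[-length(cuts)]; iv_e <- cuts[-1] - 1L

  tok <- character(length(iv_s))
  cover_key <- character(length(iv_s))
  for (i in seq_along(iv_s)) {
    s <- iv_s[i]; e <- iv_e[i]
    r_cov <- which(ret$start <= s & ret$end >= e)
    c_cov <- which(cop_eff$start <= s & cop_eff$end >= e)
    ncopy <- length(r_cov) + length(c_cov)
    if (ncopy == 0L) {
      tok[i] <- "DEL"
    } else if (ncopy >= 2L) {
      inv_extra <- any(cop_eff$orientation[c_cov] == "inverted")
      tok[i] <- if (inv_extra) "DUPinv" else "DUP"
    } else if (length(r_cov) == 1L) {
      tok[i] <- if (ret$orientation[r_cov] == "inverted") "INV" else "N"
    } else {
      tok[i] <- if (cop_eff$orientation[c_cov] == "inverted") "INV" else "N"
    }
    # adjacent-token merging keeps distinct duplicate fragments apart but
    # must not be blocked by retained-piece subdivisions
    cover_key[i] <- if (ncopy >= 2L) paste0("c", paste(c_cov, collapse = ","))
    else paste(c(paste0("r", r_cov), paste0("c", c_cov)), collapse = ",")
  }

  df <- data.frame(tok = tok, s = iv_s, e = iv_e, key = cover_key,
                   stringsAsFactors = FALSE)
  merge_runs <- function(df) {
    if (nrow(df) <= 1) return(df)
    out <- df[1, , drop = FALSE]
    for (i in seq_len(nrow(df))[-1]) {
      last <- nrow(out)
      same <- df$tok[i] == out$tok[last] &&
        (df$tok[i] %in% c("DEL", "N") || df$key[i] == out$key[last])
      if (same) out$e[last] <- df$e[i] else out <- rbind(out, df[i, ])
    }
    out
  }
  df <- merge_runs(df)
  wide <- df$e - df$s + 1L >= min_token | df$tok == "INV"
  df <- merge_runs(df[wide, , drop = FALSE])
  if (nrow(df) == 0) df <- data.frame(tok = "N")
  structure(df$tok, class = "pattern_string")
}

#' Parse a hyphen-joined pattern string into tokens
#' @param x String such as `"DEL-INV-DEL"`.
#' @return Character vector of tokens, class `pattern_string`.
#' @export
parse_pattern <- function(x) {
  toks <- strsplit(x, "-", fixed = TRUE)[[1]]
  bad <- setdiff(toks, .PATTERN_TOKENS)
  if (length(bad) > 0) stop("unknown pattern token(s): ",
                            paste(bad, collapse = ", "))
  if (length(toks) == 0) stop("empty pattern")
  structure(toks, class = "pattern_string")
}

#' Format a pattern token vector as a hyphen-joined string
#' @param x A `pattern_string`.
#' @param ... Unused.
#' @return Character scalar.
#' @export
format.pattern_string <- function(x, ...) paste(unclass(x), collapse = "-")

#' @export
print.pattern_string <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# ---- CNV-type group classification ----------------------------------------

#' Classify a case's CNV profile into deletion/duplication groups
#'
#' @param cn A [cn_segments()] table for one case.
#' @return One of `"deletions_only"`, `"duplications_only"`,
#'   `"deletions_and_duplications"`.
#' @export
classify_group <- function(cn) {
  ab <- cn[cn$state != 2L, , drop = FALSE]
  if (nrow(ab) == 0) stop("no copy-number aberration in profile")
  loss <- any(ab$state < 2L)
  gain <- any(ab$state > 2L)
  if (loss && gain) "deletions_and_duplications"
  else if (loss) "deletions_only"
  else "duplications_only"
}
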