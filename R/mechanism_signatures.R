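# Repair-pathway signature scoring per junction, breakage-fusion-bridge
# detection, case-level mechanism suggestion and cohort summary statistics.

#' Signature-scoring configuration
#'
#' Thresholds (bp unless noted) used by the junction and case classifiers:
#' \itemize{
#'   \item `nhej_mh_max` (4): microhomology 1-4 bp still compatible with
#'     canonical NHEJ;
#'   \item `polq_insert_min`/`polq_insert_max` (5/25): non-templated
#'     insertion scar range typical of Pol-theta alt-NHEJ;
#'   \item `replicative_mh_min`/`replicative_mh_max` (1/5): microhomology
#'     range attributed to replicative template switching (FoSTeS/MMBIR);
#'   \item `ambiguous_nontemplated_insert_gt` (8): a non-templated insert
#'     above this length makes a case's mechanism call ambiguous;
#'   \item `alu_identity_hr_bound` (0.90): Alu-pair identity below which
#'     homologous recombination is considered implausible;
#'   \item `templated_window` (100): search window for templated inserts;
#'   \item `snv_window` (1000): window for junction-proximal SNVs;
#'   \item `nhej_dominance` (0.5): fraction of NHEJ-like junctions above
#'     which a case is considered NHEJ-dominated.
#' }
#'
#' @param nhej_mh_max,polq_insert_min,polq_insert_max,replicative_mh_min,replicative_mh_max,ambiguous_nontemplated_insert_gt,alu_identity_hr_bound,templated_window,snv_window,nhej_dominance
#'   See description.
#' @return List of class `signature_config`.
#' @export
signature_config <- function(nhej_mh_max = 4L, polq_insert_min = 5L,
                             polq_insert_max = 25L, replicative_mh_min = 1L,
                             replicative_mh_max = 5L,
                             ambiguous_nontemplated_insert_gt = 8L,
                             alu_identity_hr_bound = 0.90,
                             templated_window = 100L, snv_window = 1000L,
                             nhej_dominance = 0.5) {
  stopifnot(polq_insert_min <= polq_insert_max,
            replicative_mh_min <= replicative_mh_max,
            nhej_mh_max > 0, templated_window > 0, snv_window > 0)
  structure(list(nhej_mh_max = nhej_mh_max,
                 polq_insert_min = polq_insert_min,
                 polq_insert_max = polq_insert_max,
                 replicative_mh_min = replicative_mh_min,
                 replicative_mh_max = replicative_mh_max,
                 ambiguous_nontemplated_insert_gt =
                   ambiguous_nontemplated_insert_gt,
                 alu_identity_hr_bound = alu_identity_hr_bound,
                 templated_window = templated_window,
                 snv_window = snv_window,
                 nhej_dominance = nhej_dominance),
            class = "signature_config")
}

.junction_nontemplated_len <- function(j) {
  if (is.null(j$insertion_blocks) || length(j$insertion_blocks) == 0) {
    # no decomposition available: treat the whole insert as non-templated
    return(if (is.na(j$insertion_len)) 0L else j$insertion_len)
  }
  sum(vapply(j$insertion_blocks, function(b)
    if (b$kind == "non_templated") nchar(b$sequence) else 0L, 1L))
}

.junction_has_templated <- function(j) {
  !is.null(j$insertion_blocks) &&
    any(vapply(j$insertion_blocks, function(b) b$kind == "templated", TRUE))
}

#' Score repair-pathway signatures of one junction
#'
#' Flags are a pure function of the junction record, its repeat
#' annotations and the configuration: `blunt_NHEJ` (MH 0, Ins 0),
#' `short_MH_NHEJ` (MH 1-4 with at most a small insert), `MMEJ` (MH >= 2
#' or a templated insert), `altNHEJ_polQ_insert` (non-templated insert of
#' 5-25 bp; larger inserts keep the flag with `above_max` evidence),
#' `replicative_MH` (MH 1-5, FoSTeS/MMBIR-compatible),
#' `repeat_mediated_Alu`/`repeat_mediated_LINE` (both sides in the same
#' repeat family), `novel_SNV_nearby` (from `snv_count`).
#'
#' @param j A resolved [junction_record()].
#' @param config A [signature_config()].
#' @param snv_count Number of novel SNVs within the SNV window (default 0).
#' @return Object of class `junction_signature`: list with `flags`
#'   (character vector) and `evidence` (data.frame flag/value/threshold),
#'   or `NULL` (with a warning) for unresolved junctions.
#' @export
score_junction <- function(j, config = signature_config(), snv_count = 0L) {
  if (!is_resolved(j)) {
    warning("junction ", j$case_id, "#", j$junction_id,
            " is unresolved; no signature")
    return(NULL)
  }
  mh <- j$microhomology_len
  ins <- j$insertion_len
  nt <- .junction_nontemplated_len(j)
  flags <- character(0)
  ev <- list()
  note <- function(flag, value, threshold) {
    flags <<- c(flags, flag)
    ev[[length(ev) + 1L]] <<- data.frame(flag = flag, value = value,
                                         threshold = threshold,
                                         stringsAsFactors = FALSE)
  }
  if (mh == 0L && ins == 0L) note("blunt_NHEJ", "MH=0,Ins=0", "exact")
  if (mh >= 1L && mh <= config$nhej_mh_max && ins < config$polq_insert_min) {
    note("short_MH_NHEJ", paste0("MH=", mh),
         paste0("1-", config$nhej_mh_max))
  }
  if (mh >= 2L || .junction_has_templated(j)) {
    note("MMEJ", paste0("MH=", mh, ",templated=",
                        .junction_has_templated(j)), "MH>=2 or templated")
  }
  if (nt >= config$polq_insert_min) {
    note("altNHEJ_polQ_insert", paste0("non_templated=", nt),
         paste0(config$polq_insert_min, "-", config$polq_insert_max,
                if (nt > config$polq_insert_max) " (above_max)" else ""))
  }
  if (mh >= config$replicative_mh_min && mh <= config$replicative_mh_max) {
    note("replicative_MH", paste0("MH=", mh),
         paste0(config$replicative_mh_min, "-", config$replicative_mh_max))
  }
  f1 <- repeat_family(j$repeat1); f2 <- repeat_family(j$repeat2)
  if (f1 == "Alu" && f2 == "Alu") {
    note("repeat_mediated_Alu", paste(j$repeat1, j$repeat2), "same family")
  }
  if (f1 == "LINE" && f2 == "LINE") {
    note("repeat_mediated_LINE", paste(j$repeat1, j$repeat2), "same family")
  }
  if (snv_count > 0) {
    note("novel_SNV_nearby", as.character(snv_count),
         paste0("<", config$snv_window, " bp"))
  }
  structure(list(flags = flags,
                 evidence = if (length(ev)) do.call(rbind, ev)
                 else data.frame(flag = character(0), value = character(0),
                                 threshold = character(0))),
            class = "junction_signature")
}

#' Detect a breakage-fusion-bridge / attempted-ring signature
#'
#' True when a terminal deletion at one end of the chromosome is replaced
#' by an inverted duplicated copy of the opposite terminal region — the
#' footprint left by a breakage-fusion-bridge cycle accompanying an
#' aborted ring-chromosome formation.
#'
#' @param structure A [derivative_structure()] spanning the chromosome.
#' @param cn Optional [cn_segments()] (unused by the decision; reserved).
#' @param contig_length Chromosome length; defaults to the structure span
#'   end.
#' @param terminal_frac How close (fraction of the chromosome) a segment
#'   must come to a chromosome end to count as terminal (default 0.3).
#' @return List with `bfb` (logical) and `evidence` (character).
#' @export
detect_bfb_ring <- function(structure, cn = NULL, contig_length = NULL,
                            terminal_frac = 0.3) {
  seg <- structure$segments
  span <- structure$span
  if (is.null(contig_length)) contig_length <- span[2]
  if (span[1] > contig_length * terminal_frac ||
      span[2] < contig_length * (1 - terminal_frac)) {
    return(list(bfb = FALSE,
                evidence = "not evaluable: span does not reach both chromosome ends"))
  }
  ret <- seg[seg$provenance == "retained", , drop = FALSE]
  cop <- seg[seg$provenance == "duplicate_copy" & seg$orientation == "inverted",
             , drop = FALSE]
  p_lost <- nrow(ret) == 0 || min(ret$start) > span[1]
  q_lost <- nrow(ret) == 0 || max(ret$end) < span[2]
  p_cut <- span[1] + floor(terminal_frac * (contig_length - span[1] + 1))
  q_cut <- span[2] - floor(terminal_frac * (contig_length - span[1] + 1))
  inv_p_copy <- any(cop$start <= p_cut)
  inv_q_copy <- any(cop$end >= q_cut)
  if (q_lost && inv_p_copy) {
    return(list(bfb = TRUE, evidence = paste0(
      "terminal deletion at the q end (retained cover stops at ",
      if (nrow(ret)) max(ret$end) else NA, ") replaced by an inverted ",
      "duplicated copy of the opposite terminus")))
  }
  if (p_lost && inv_q_copy) {
    return(list(bfb = TRUE, evidence = paste0(
      "terminal deletion at the p end (retained cover starts at ",
      if (nrow(ret)) min(ret$start) else NA, ") replaced by an inverted ",
      "duplicated copy of the opposite terminus")))
  }
  list(bfb = FALSE, evidence = "no terminal deletion/inverted-copy exchange")
}

#' Suggest the formation mechanism of one case
#'
#' Documented decision tree: (1) if any resolved junction carries a
#' non-templated insert above `ambiguous_nontemplated_insert_gt` and the
#' case is not dominated by NHEJ-like junctions, the call is `ambiguous`;
#' (2) otherwise a deletions-only case is `chromothripsis`; (3) any case
#' with duplications is `chromoanasynthesis`. Entries in `overrides`
#' (expert judgment shipped as data, never silently applied) replace the
#' tree's call; the returned evidence records both.
#'
#' @param case_id Case label.
#' @param group A group label (see [classify_group()]).
#' @param junctions List of [junction_record()]s for the case.
#' @param config A [signature_config()].
#' @param overrides Optional data.frame (`case_id`, `mechanism`, `reason`).
#' @return List of class `case_mechanism_call`: `case_id`, `group`,
#'   `suggestion`, `tree_suggestion`, `overridden`, `bfb_ring`, `evidence`.
#' @export
call_case_mechanism <- function(case_id, group, junctions,
                                config = signature_config(),
                                overrides = NULL, bfb_ring = FALSE) {
  res <- Filter(is_resolved, junctions)
  tree <- NULL
  ev <- character(0)
  if (length(res) == 0) {
    tree <- "unclassifiable"
    ev <- c(ev, "no junction resolved at nucleotide level")
  } else {
    nt <- vapply(res, .junction_nontemplated_len, 1L)
    nhej_like <- vapply(res, function(j) {
      j$microhomology_len <= config$nhej_mh_max &&
        j$insertion_len < config$polq_insert_min
    }, TRUE)
    big_insert <- any(nt > config$ambiguous_nontemplated_insert_gt)
    dominated <- mean(nhej_like) > config$nhej_dominance
    if (big_insert) {
      ev <- c(ev, paste0("max non-templated insert ", max(nt), " bp > ",
                         config$ambiguous_nontemplated_insert_gt))
      ev <- c(ev, paste0("NHEJ-like junction fraction ",
                         round(mean(nhej_like), 2)))
    }
    if (big_insert && !dominated) {
      tree <- "ambiguous"
    } else if (group == "deletions_only") {
      tree <- "chromothripsis"
      ev <- c(ev, "copy-number profile: losses only")
    } else {
      tree <- "chromoanasynthesis"
      ev <- c(ev, "copy-number profile includes duplications")
    }
  }
  suggestion <- tree
  overridden <- FALSE
  if (!is.null(overrides)) {
    hit <- which(overrides$case_id == case_id)
    if (length(hit) == 1) {
      suggestion <- overrides$mechanism[hit]
      overridden <- TRUE
      ev <- c(ev, paste0("override applied: ", overrides$reason[hit]))
    }
  }
  structure(list(case_id = case_id, group = group, suggestion = suggestion,
                 tree_suggestion = tree, overridden = overridden,
                 bfb_ring = bfb_ring, evidence = ev),
            class = "case_mechanism_call")
}

#' @export
print.case_mechanism_call <- function(x, ...) {
  cat("<mechanism> ", x$case_id, " (", x$group, "): ", x$suggestion,
      if (x$overridden) paste0(" [tree: ", x$tree_suggestion, "]"),
      if (x$bfb_ring) " +BFB/ring", "\n", sep = "")
  invisible(x)
}

#' Summarize junction and duplication statistics over a cohort
#'
#' Computes the cohort-level statistics from a junction table, per-case
#' group labels and duplication calls: totals, resolution, microhomology
#' distribution (MH-bearing means MH >= 2), blunt joints, per-group case
#' counts and junctions per case (means rounded to the nearest integer),
#' and duplication architecture counts with percentages rounded to the
#' nearest integer.
#'
#' @param junctions data.frame with columns `case_id`, `mh`, `ins`
#'   (NA = unresolved).
#' @param groups Named character vector: case_id -> group label.
#' @param duplication_calls Optional data.frame with column `architecture`
#'   and `orientation` (e.g. row-bound results of
#'   [classify_duplications()]).
#' @param dup_fragment_total Optional externally-derived total of
#'   duplicated fragments (e.g. DUP token count from pattern strings);
#'   defaults to `nrow(duplication_calls)`.
#' @return List of class `cohort_summary`.
#' @export
summarize_cohort <- function(junctions, groups, duplication_calls = NULL,
                             dup_fragment_total = NULL) {
  stopifnot(nrow(junctions) >= 1)
  resolved <- !is.na(junctions$mh) & !is.na(junctions$ins)
  mh <- junctions$mh[resolved]
  ins <- junctions$ins[resolved]
  mh_bearing <- mh[mh >= 2L]
  per_case <- table(junctions$case_id)
  gtab <- table(factor(groups, levels = c("deletions_only",
                                          "duplications_only",
                                          "deletions_and_duplications")))
  jn_by_group <- lapply(names(gtab), function(g) {
    ids <- names(groups)[groups == g]
    as.integer(per_case[names(per_case) %in% ids])
  })
  names(jn_by_group) <- names(gtab)
  dup_n <- if (!is.null(dup_fragment_total)) dup_fragment_total
  else if (!is.null(duplication_calls)) nrow(duplication_calls) else NA_integer_
  tandem <- interspersed <- inverted <- NA_integer_
  if (!is.null(duplication_calls) && nrow(duplication_calls) > 0) {
    tandem <- sum(duplication_calls$architecture == "tandem")
    interspersed <- sum(duplication_calls$architecture == "interspersed")
    inverted <- sum(duplication_calls$orientation == "inverted")
  }
  structure(list(
    n_cases = length(unique(junctions$case_id)),
    n_junctions = nrow(junctions),
    n_resolved = sum(resolved),
    mean_junctions_per_case = round(mean(as.integer(per_case))),
    junctions_per_case_range = range(as.integer(per_case)),
    group_case_counts = stats::setNames(as.integer(gtab), names(gtab)),
    group_junction_means = vapply(jn_by_group, function(v)
      if (length(v)) round(mean(v)) else NA_real_, 1),
    group_junction_ranges = lapply(jn_by_group, function(v)
      if (length(v)) range(v) else c(NA_integer_, NA_integer_)),
    n_mh_bearing = length(mh_bearing),
    mh_min = if (length(mh_bearing)) min(mh_bearing) else NA_integer_,
    mh_max = if (length(mh_bearing)) max(mh_bearing) else NA_integer_,
    mh_median = if (length(mh_bearing)) stats::median(mh_bearing)
    else NA_real_,
    n_blunt = sum(mh == 0L & ins == 0L),
    blunt_cases = length(unique(junctions$case_id[resolved][mh == 0L &
                                                             ins == 0L])),
    insertion_sizes = sort(ins[ins > 0L]),
    dup_fragments = dup_n,
    dup_tandem = tandem,
    dup_interspersed = interspersed,
    dup_inverted = inverted,
    pct_interspersed = if (!is.na(dup_n) && !is.na(interspersed) && dup_n > 0)
      round(100 * (dup_n - tandem) / dup_n) else NA_real_,
    pct_inverted = if (!is.na(dup_n) && !is.na(inverted) && dup_n > 0)
      round(100 * inverted / dup_n) else NA_real_),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat("  cases:", x$n_cases, " junctions:", x$n_junctions,
      " resolved:", x$n_resolved, "\n")
  cat("  groups (del/dup/both):",
      paste(x$group_case_counts, collapse = "/"), "\n")
  cat("  junctions/case: mean", x$mean_junctions_per_case, " range",
      paste(x$junctions_per_case_range, collapse = "-"), "\n")
  cat("  MH-bearing (>=2):", x$n_mh_bearing, " max:", x$mh_max,
      " median:", x$mh_median, "\n")
  cat("  blunt:", x$n_blunt, "in", x$blunt_cases, "cases\n")
  cat("  duplicated fragments:", x$dup_fragments, " tandem:", x$dup_tandem,
      " interspersed:", x$pct_interspersed, "%\n")
  invisible(x)
}
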