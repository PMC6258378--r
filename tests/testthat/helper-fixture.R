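# Shared accessors over the bundled cohort fixture.

fixture_groups <- function(bundle) {
  stats::setNames(bundle$cases$group, bundle$cases$case_id)
}

# copy-number profile implied by a derivative structure's copy counts
structure_cn <- function(st) {
  seg <- st$segments
  cuts <- sort(unique(c(seg$start, seg$end + 1L)))
  rows <- lapply(seq_len(length(cuts) - 1L), function(i) {
    s <- cuts[i]; e <- cuts[i + 1L] - 1L
    data.frame(contig = st$contig, start = s, end = e,
               state = sum(seg$start <= s & seg$end >= e) + 1L)
  })
  df <- do.call(rbind, rows)
  cn_segments(df$contig, df$start, df$end, df$state)
}

# collapse reference-contiguous equal-orientation runs so structures built
# at different fragment resolutions can be compared
collapse_segments <- function(seg) {
  out <- seg[1, , drop = FALSE]
  for (i in seq_len(nrow(seg))[-1]) {
    l <- nrow(out)
    joinable <- seg$orientation[i] == out$orientation[l] &&
      ((out$orientation[l] == "forward" && seg$start[i] == out$end[l] + 1L) ||
         (out$orientation[l] == "inverted" && seg$end[i] == out$start[l] - 1L))
    if (joinable) {
      if (out$orientation[l] == "forward") out$end[l] <- seg$end[i]
      else out$start[l] <- seg$start[i]
    } else out <- rbind(out, seg[i, ])
  }
  rownames(out) <- NULL
  out[, c("start", "end", "orientation")]
}
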