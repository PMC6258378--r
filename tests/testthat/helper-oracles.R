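# Independent oracles used by the property tests. These deliberately avoid
# the package's own primitives (plain substr/chartr string work) so that a
# shared bug cannot hide.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(x)), "",
                     fixed = TRUE)[[1]]), collapse = "")
}

# derivative window around a junction, built directly from the reference
# string: W bases entering the junction from side1 plus W bases leaving it
# on side2
.oracle_window <- function(seqs, s1, s2, W) {
  seq1 <- seqs[[s1$contig]]; seq2 <- seqs[[s2$contig]]
  left <- if (s1$orientation == "+") {
    substr(seq1, s1$position - W + 1L, s1$position)
  } else {
    oracle_revcomp(substr(seq1, s1$position, s1$position + W - 1L))
  }
  right <- if (s2$orientation == "+") {
    oracle_revcomp(substr(seq2, s2$position - W + 1L, s2$position))
  } else {
    substr(seq2, s2$position, s2$position + W - 1L)
  }
  paste0(left, right)
}

.oracle_shift <- function(sd, k, which_side) {
  # slide the junction k bases to the right (k < 0: left)
  p <- sd$position
  if (which_side == 1L) {
    p <- if (sd$orientation == "+") p + k else p - k
  } else {
    p <- if (sd$orientation == "+") p - k else p + k
  }
  list(contig = sd$contig, position = p, orientation = sd$orientation)
}

# brute-force microhomology: try every breakpoint shift k and count the
# placements whose derivative CONTENT around the junction is unchanged;
# MH = count - 1. A placement shifted by k describes the same derivative
# when its local window reproduces the corresponding (shifted) slice of a
# wide window built from the original placement.
oracle_microhomology <- function(genome, side1, side2, W = 60L) {
  seqs <- as.list(unclass(genome))
  lens <- vapply(seqs, nchar, 1L)
  s1 <- list(contig = side1$contig, position = side1$position,
             orientation = side1$orientation)
  s2 <- list(contig = side2$contig, position = side2$position,
             orientation = side2$orientation)
  d_big <- .oracle_window(seqs, s1, s2, 2L * W)  # derivative, 2W each side
  n_valid <- 0L
  for (k in seq.int(-W + 1L, W - 1L)) {
    a <- .oracle_shift(s1, k, 1L)
    b <- .oracle_shift(s2, k, 2L)
    if (a$position < W || a$position > lens[[a$contig]] - W) next
    if (b$position < W || b$position > lens[[b$contig]] - W) next
    wk <- .oracle_window(seqs, a, b, W)
    # the shifted placement's window covers derivative offsets
    # [W + k + 1, 3W + k] of the wide window
    if (identical(wk, substr(d_big, W + k + 1L, 3L * W + k))) {
      n_valid <- n_valid + 1L
    }
  }
  n_valid - 1L
}
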