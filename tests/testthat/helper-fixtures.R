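## Shared test utilities: tiny file writers, random duplex construction,
## and the closed-form bulge-placement enumeration oracle for alignments.

NT <- c("A", "C", "G", "U")
WC <- c(A = "U", C = "G", G = "C", U = "A")
GUP <- c(G = "U", U = "G")

write_fasta_file <- function(ids, seqs, path = tempfile(fileext = ".fa")) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

write_fastq_file <- function(seqs, path = tempfile(fileext = ".fq")) {
  writeLines(as.vector(rbind(paste0("@r", seq_along(seqs)), seqs,
                             "+", strrep("I", nchar(seqs)))), path)
  path
}

random_rna <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")

## Build a miRNA + per-position target realizing the given states.
make_planned_duplex <- function(L = 21L, mm_pos = integer(0),
                                gu_pos = integer(0), mirna = NULL) {
  repeat {
    m <- if (is.null(mirna)) random_rna(L) else mirna
    mv <- strsplit(m, "")[[1L]]
    if (all(mv[gu_pos] %in% c("G", "U"))) break
    if (!is.null(mirna)) stop("G:U planned at a non-G/U miRNA position")
  }
  states <- rep("=", L)
  states[mm_pos] <- "x"
  states[gu_pos] <- "o"
  tv <- vapply(seq_len(L), function(p) switch(states[p],
    "=" = WC[[mv[p]]],
    "o" = GUP[[mv[p]]],
    "x" = sample(setdiff(NT, c(WC[[mv[p]]],
                               if (mv[p] %in% names(GUP)) GUP[[mv[p]]])), 1L)
  ), character(1))
  list(mirna = m, target = paste(tv, collapse = ""),
       states = paste(states, collapse = ""))
}

## A duplex data frame row set with given state strings (scores derived,
## MFE ratios supplied or drawn).
duplex_frame <- function(states, mfe_ratio = NULL) {
  n <- length(states)
  if (n == 0L) return(duplex_frame("=")[0L, ])
  if (is.null(mfe_ratio)) mfe_ratio <- round(runif(n, 0.6, 1), 3)
  data.frame(
    mirna_id = sprintf("m%03d", seq_len(n)),
    mirna_seq = vapply(seq_len(n), function(i) random_rna(21L), character(1)),
    transcript_id = sprintf("tx%03d", seq_len(n)),
    cleavage_position = 100L + seq_len(n),
    category = 0L, confidence = "HC", peak_abundance = 10L,
    score = vapply(states, score_duplex, numeric(1), USE.NAMES = FALSE),
    mfe_ratio = mfe_ratio, states = states,
    conservation = "conserved", stringsAsFactors = FALSE
  )
}

## Random state string with bounded defects (inside permissive bounds
## unless loose = TRUE).
random_states <- function(L = 21L, loose = FALSE) {
  states <- rep("=", L)
  n_mm <- sample(0:(if (loose) 5 else 2), 1L)
  pool <- if (loose) seq_len(L) else c(1L, 14:L)
  states[pool[sample.int(length(pool), min(n_mm, length(pool)))]] <- "x"
  free <- which(states == "=")
  n_gu <- sample(0:2, 1L)
  states[free[sample.int(length(free), min(n_gu, length(free)))]] <- "o"
  paste(states, collapse = "")
}

## Closed-form enumeration over all bulge placements (<= 1 gap): the
## independent oracle for the aligner. Coordinates follow the anchored
## geometry coord0(p) = t + 10 - p; a miRNA bulge at q shifts positions
## beyond q (away from the anchor) one coordinate towards the anchor, a
## target bulge shifts them one further out.
enumerate_alignments <- function(mirna_seq, transcript_seq, t) {
  m <- strsplit(mirna_seq, "")[[1L]]
  L <- length(m)
  nt_at <- function(coord) {
    if (coord < 1L || coord > nchar(transcript_seq)) return("")
    substr(transcript_seq, coord, coord)
  }
  state_of <- function(p, coord) {
    tn <- nt_at(coord)
    if (tn == "") return("x")
    if (WC[[m[p]]] == tn) return("=")
    if (m[p] %in% names(GUP) && GUP[[m[p]]] == tn) return("o")
    "x"
  }
  build <- function(gap_pos, gap_kind) {
    states <- character(L)
    for (p in seq_len(L)) {
      if (!is.na(gap_pos) && p == gap_pos) { states[p] <- "-"; next }
      shift <- 0L
      if (!is.na(gap_pos) && gap_pos != 10L) {
        same_arm <- (p > 10L && gap_pos > 10L) || (p < 10L && gap_pos < 10L)
        beyond <- abs(p - 10L) > abs(gap_pos - 10L)
        if (same_arm && beyond)
          shift <- if (gap_kind == "mirna") {
            if (p > 10L) +1L else -1L     # one coordinate towards the anchor
          } else {
            if (p > 10L) -1L else +1L     # one coordinate further out
          }
      }
      states[p] <- state_of(p, t + 10L - p + shift)
    }
    paste(states, collapse = "")
  }
  cands <- data.frame(states = build(NA, NA), gaps = 0L, gappos = NA_integer_,
                      stringsAsFactors = FALSE)
  for (q in setdiff(seq_len(L), 10L)) {
    for (kind in c("mirna", "target")) {
      cands <- rbind(cands, data.frame(states = build(q, kind), gaps = 1L,
                                       gappos = q, stringsAsFactors = FALSE))
    }
  }
  cands$score <- vapply(cands$states, score_duplex, numeric(1),
                        USE.NAMES = FALSE)
  ord <- order(cands$score, cands$gaps, -ifelse(is.na(cands$gappos), 0L,
                                                cands$gappos))
  cands[ord[1L], ]
}
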