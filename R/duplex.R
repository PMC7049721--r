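## Pair-state encoding used throughout: "=" Watson-Crick match, "o" G:U
## wobble, "x" mismatch (or off-transcript position), "-" bulge (gap).

PEN <- c("=" = 0, "o" = 0.5, "x" = 1, "-" = 1)
CORE <- 2:13

position_weight <- function(p) ifelse(p %in% CORE, 2, 1)

pair_state <- function(m_nt, t_nt) {
  if (is.na(t_nt) || t_nt == "") return("x")
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  if (identical(unname(wc[m_nt]), t_nt)) return("=")
  if ((m_nt == "G" && t_nt == "U") || (m_nt == "U" && t_nt == "G")) return("o")
  "x"
}

#' Extract the peak-anchored target-site window
#'
#' Degradome anchoring places miRNA position 10 opposite the cleavage
#' nucleotide (the degradome read's 5' end, coordinate `t`), so the target
#' nucleotide pairing miRNA position `p` sits at transcript coordinate
#' `t + 10 - p` and the site spans `[t - (L - 10) - g, t + 9 + g]` for a
#' miRNA of length `L` and bulge budget `g`. Windows reaching past either
#' transcript end are clipped and flagged truncated.
#'
#' @param transcript_seq transcript sequence (RNA alphabet).
#' @param cleavage_position 1-based transcript coordinate of the degradome
#'   5' end.
#' @param mirna_length miRNA length `L`.
#' @param gap_budget extra nucleotides allowed on each flank for bulges.
#' @return list with `seq` (the clipped window), `start`, `end`,
#'   `cleavage_position`, `tx_len`, `truncated`.
#' @export
extract_site <- function(transcript_seq, cleavage_position, mirna_length,
                         gap_budget = 1L) {
  tx_len <- nchar(transcript_seq)
  t <- cleavage_position
  if (t < 1L || t > tx_len)
    stop("cleavage position ", t, " outside transcript (length ", tx_len, ")")
  ws <- t + 10L - mirna_length - gap_budget
  we <- t + 9L + gap_budget
  start <- max(1L, ws)
  end <- min(tx_len, we)
  list(
    seq = substr(transcript_seq, start, end),
    start = start, end = end,
    cleavage_position = t, tx_len = tx_len,
    truncated = ws < 1L || we > tx_len
  )
}

## Best alignment of one arm of the duplex, walking outward from the anchor.
## positions: miRNA positions in walk order; dir: +1 (5' arm, coordinates
## increase away from the cleavage site) or -1 (3' arm). Moves: pair one
## coordinate; bulge the miRNA nucleotide (no coordinate consumed); bulge a
## target nucleotide (two coordinates consumed, state "-"). Memoized on
## (step, coordinate offset, gaps left).
arm_align <- function(m, positions, dir, site, max_gaps) {
  t <- site$cleavage_position
  nt_at <- function(coord) {
    if (coord < site$start || coord > site$end) return("")
    substr(site$seq, coord - site$start + 1L, coord - site$start + 1L)
  }
  n <- length(positions)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, g) {
    if (i > n)
      return(list(score = 0, gaps = 0L, states = character(0),
                  target = character(0), gappos = integer(0)))
    key <- paste(i, j, g)
    if (!is.null(memo[[key]])) return(memo[[key]])
    p <- positions[i]
    w <- position_weight(p)
    tn <- nt_at(t + dir * j)
    s <- pair_state(m[p], tn)
    sub <- rec(i + 1L, j + 1L, g)
    best <- list(score = PEN[[s]] * w + sub$score, gaps = sub$gaps,
                 states = c(s, sub$states),
                 target = c(if (tn == "") "-" else tn, sub$target),
                 gappos = sub$gappos)
    if (g > 0L) {
      for (consumed in c(0L, 2L)) {  # miRNA bulge / target bulge
        sub <- rec(i + 1L, j + consumed, g - 1L)
        cand <- list(score = 1 * w + sub$score, gaps = sub$gaps + 1L,
                     states = c("-", sub$states), target = c("-", sub$target),
                     gappos = c(p, sub$gappos))
        if (better_alignment(cand, best)) best <- cand
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, max_gaps)
}

## Strict "is a better than b": lower score, then fewer gaps, then gaps
## placed closest to the miRNA 3' end (larger positions preferred).
better_alignment <- function(a, b) {
  if (a$score != b$score) return(a$score < b$score)
  if (a$gaps != b$gaps) return(a$gaps < b$gaps)
  ga <- sort(a$gappos, decreasing = TRUE)
  gb <- sort(b$gappos, decreasing = TRUE)
  for (k in seq_len(min(length(ga), length(gb)))) {
    if (ga[k] != gb[k]) return(ga[k] > gb[k])
  }
  FALSE
}

#' Align a miRNA against an extracted target site
#'
#' Finds the pair-state assignment minimizing the Allen-style score (see
#' [score_duplex()]) over all alignments with at most `max_gaps`
#' single-nucleotide bulges on either strand, with miRNA position 10 held
#' opposite the cleavage nucleotide. Ties prefer fewer gaps, then gaps
#' closest to the miRNA 3' end. Positions falling off a truncated site are
#' reported as mismatches.
#'
#' @param mirna_seq miRNA sequence, 5' to 3' (RNA alphabet, length >= 11).
#' @param site site object from [extract_site()].
#' @param max_gaps bulge allowance (default 1).
#' @return list with `states` (compact string, one character per miRNA
#'   position: `=` match, `o` G:U, `x` mismatch, `-` gap), `target` (the
#'   nucleotide opposite each position, `-` for bulges/off-site), `score`,
#'   and `n_gaps`.
#' @export
align_duplex <- function(mirna_seq, site, max_gaps = 1L) {
  m <- strsplit(normalize_rna(mirna_seq), "")[[1L]]
  L <- length(m)
  if (L < 11L) stop("miRNA shorter than 11 nt cannot be anchored at position 10")
  t <- site$cleavage_position
  anchor_nt <- if (t >= site$start && t <= site$end)
    substr(site$seq, t - site$start + 1L, t - site$start + 1L) else ""
  anchor_state <- pair_state(m[10L], anchor_nt)

  best <- NULL
  for (g5 in 0:max_gaps) {
    a5 <- arm_align(m, 9:1, +1L, site, g5)
    a3 <- arm_align(m, if (L >= 11L) 11:L else integer(0), -1L, site,
                    max_gaps - g5)
    cand <- list(
      score = a5$score + a3$score +
        PEN[[anchor_state]] * position_weight(10L),
      gaps = a5$gaps + a3$gaps,
      gappos = c(a5$gappos, a3$gappos),
      a5 = a5, a3 = a3
    )
    if (is.null(best) || better_alignment(cand, best)) best <- cand
  }
  states <- character(L)
  target <- character(L)
  states[10L] <- anchor_state
  target[10L] <- if (anchor_nt == "") "-" else anchor_nt
  states[9:1] <- best$a5$states
  target[9:1] <- best$a5$target
  if (L >= 11L) {
    states[11:L] <- best$a3$states
    target[11:L] <- best$a3$target
  }
  list(
    states = paste(states, collapse = ""),
    target = paste(target, collapse = ""),
    score = unname(best$score),
    n_gaps = best$gaps
  )
}

#' Allen-style position-weighted duplex score
#'
#' Sum over miRNA positions of the state penalty (match 0, G:U 0.5,
#' mismatch 1, bulge 1) times the position weight: 2 inside the core region
#' (positions 2-13), 1 elsewhere.
#'
#' @param states compact state string (or character vector) as produced by
#'   [align_duplex()].
#' @return numeric score (a non-negative half-integer).
#' @export
score_duplex <- function(states) {
  v <- states_vector(states)
  sum(PEN[v] * position_weight(seq_along(v)))
}

states_vector <- function(states) {
  v <- if (length(states) == 1L && nchar(states[1L]) > 1L)
    strsplit(states, "")[[1L]] else as.character(states)
  if (!all(v %in% names(PEN)))
    stop("invalid pair-state character; expected one of = o x -")
  v
}

#' Per-duplex property counts
#'
#' Counts the features the targeting-criteria family constrains: mismatches,
#' G:U pairs, gaps, adjacent-mismatch occurrences (a run of k mismatches
#' counts k-1), and the same restricted to the core region (positions 2-13;
#' an adjacent pair counts as core when both positions lie inside it).
#'
#' @inheritParams score_duplex
#' @return named numeric vector with elements `n_mm`, `n_gu`, `n_gap`,
#'   `n_adj_mm`, `n_mm_core`, `n_adj_mm_core`.
#' @export
duplex_properties <- function(states) {
  v <- states_vector(states)
  L <- length(v)
  mm <- v == "x"
  adj <- which(mm[-L] & mm[-1L])           # pair (p, p+1) index = p
  core <- seq_len(L) %in% CORE
  c(
    n_mm = sum(mm),
    n_gu = sum(v == "o"),
    n_gap = sum(v == "-"),
    n_adj_mm = length(adj),
    n_mm_core = sum(mm & core),
    n_adj_mm_core = sum(adj %in% 2:12)     # both p and p+1 inside 2..13
  )
}

#' Targeting-criteria parameter set
#'
#' The rule family inferred by the pipeline: positional allowances at the
#' cleavage-flanking positions 10 and 11 (a G:U there counts as a mismatch
#' for the allowance), count caps on mismatches, G:U pairs, adjacent
#' mismatches and gaps (overall and within the core region 2-13), a cap on
#' the position-weighted score, and a lower cutoff on the MFE ratio.
#'
#' @param allow_mm_pos10,allow_mm_pos11 allow a non-Watson-Crick state at
#'   position 10 / 11.
#' @param max_adjacent_mm_core,max_mm_core caps within the core region.
#' @param max_score maximum [score_duplex()] value (half-integers).
#' @param max_mm,max_gu,max_adjacent_mm,max_gaps overall count caps.
#' @param mfe_ratio_cutoff minimum MFE ratio, in `[0, 1]`.
#' @return object of class `targeting_criteria` (a named list).
#' @export
targeting_criteria <- function(allow_mm_pos10 = TRUE, allow_mm_pos11 = TRUE,
                               max_adjacent_mm_core = 0, max_mm_core = 1,
                               max_score = 4.5, max_mm = 3, max_gu = 2,
                               max_adjacent_mm = 1, mfe_ratio_cutoff = 0.7,
                               max_gaps = 1) {
  crit <- list(
    allow_mm_pos10 = isTRUE(allow_mm_pos10),
    allow_mm_pos11 = isTRUE(allow_mm_pos11),
    max_adjacent_mm_core = as.numeric(max_adjacent_mm_core),
    max_mm_core = as.numeric(max_mm_core),
    max_score = as.numeric(max_score),
    max_mm = as.numeric(max_mm),
    max_gu = as.numeric(max_gu),
    max_adjacent_mm = as.numeric(max_adjacent_mm),
    mfe_ratio_cutoff = as.numeric(mfe_ratio_cutoff),
    max_gaps = as.numeric(max_gaps)
  )
  caps <- unlist(crit[grep("^max_", names(crit))])
  if (any(caps < 0)) stop("criteria caps must be >= 0")
  if (crit$mfe_ratio_cutoff < 0 || crit$mfe_ratio_cutoff > 1)
    stop("mfe_ratio_cutoff must lie in [0, 1]")
  structure(crit, class = "targeting_criteria")
}

#' @export
print.targeting_criteria <- function(x, ...) {
  cat("<targeting_criteria>\n")
  for (f in names(x))
    cat(sprintf("  %-22s %s\n", f,
                if (is.logical(x[[f]])) ifelse(x[[f]], "Yes", "No")
                else format(x[[f]], nsmall = 2)))
  invisible(x)
}

#' Highly permissive criteria for the initial target-prediction pass
#'
#' Strictly looser than any criteria set the inference stage can produce,
#' so inference only tightens. All values are user-overridable.
#'
#' @return a [targeting_criteria()] object.
#' @export
permissive_criteria <- function() {
  targeting_criteria(
    allow_mm_pos10 = TRUE, allow_mm_pos11 = TRUE,
    max_adjacent_mm_core = 1, max_mm_core = 2,
    max_score = 7.0, max_mm = 5, max_gu = 4, max_adjacent_mm = 2,
    mfe_ratio_cutoff = 0.5, max_gaps = 1
  )
}

#' Test a duplex against a targeting-criteria set
#'
#' @param states compact state string from [align_duplex()].
#' @param score duplex score; recomputed from `states` when `NULL`.
#' @param mfe_ratio duplex MFE ratio.
#' @param criteria a [targeting_criteria()] object.
#' @return `TRUE` iff every rule holds.
#' @export
passes_criteria <- function(states, score = NULL, mfe_ratio, criteria) {
  v <- states_vector(states)
  if (is.null(score)) score <- score_duplex(v)
  pr <- duplex_properties(v)
  if (!criteria$allow_mm_pos10 && v[10L] != "=") return(FALSE)
  if (!criteria$allow_mm_pos11 && length(v) >= 11L && v[11L] != "=")
    return(FALSE)
  pr[["n_mm"]] <= criteria$max_mm &&
    pr[["n_gu"]] <= criteria$max_gu &&
    pr[["n_gap"]] <= criteria$max_gaps &&
    pr[["n_adj_mm"]] <= criteria$max_adjacent_mm &&
    pr[["n_adj_mm_core"]] <= criteria$max_adjacent_mm_core &&
    pr[["n_mm_core"]] <= criteria$max_mm_core &&
    score <= criteria$max_score &&
    mfe_ratio >= criteria$mfe_ratio_cutoff
}

#' Predict miRNA-mRNA interactions from confident degradome peaks
#'
#' For every (miRNA candidate, confident peak) pair, extracts the
#' peak-anchored site, aligns the duplex, scores it, computes the MFE ratio
#' and keeps interactions passing the (permissive, by default) criteria.
#'
#' @param candidates data frame from [select_candidates()] (or any data
#'   frame with `sequence` and optional `matched_known_ids`,
#'   `conservation` columns).
#' @param transcriptome named character vector from [read_transcriptome()].
#' @param peaks data frame from [confident_peaks()].
#' @param criteria filtering rules; defaults to [permissive_criteria()].
#' @param mfe_backend `"nn"` (built-in nearest-neighbor model) or
#'   `"vienna"` (external RNAduplex, if installed).
#' @return data frame of duplexes: `mirna_id`, `mirna_seq`,
#'   `transcript_id`, `cleavage_position`, `category`, `confidence`,
#'   `peak_abundance`, `score`, `mfe_ratio`, `states`, `conservation`.
#' @export
find_targets <- function(candidates, transcriptome, peaks,
                         criteria = permissive_criteria(),
                         mfe_backend = c("nn", "vienna")) {
  mfe_backend <- match.arg(mfe_backend)
  if (!nrow(candidates) || !nrow(peaks))
    return(empty_duplex_frame())
  rows <- vector("list", nrow(candidates) * nrow(peaks))
  k <- 0L
  for (i in seq_len(nrow(candidates))) {
    mseq <- candidates$sequence[i]
    mid <- mirna_label(candidates, i)
    cons <- if ("conservation" %in% names(candidates))
      candidates$conservation[i] else NA_character_
    for (j in seq_len(nrow(peaks))) {
      tx <- transcriptome[[peaks$transcript_id[j]]]
      if (is.null(tx)) next
      t <- peaks$position[j]
      if (t > nchar(tx)) next
      site <- extract_site(tx, t, nchar(mseq), gap_budget = criteria$max_gaps)
      aln <- align_duplex(mseq, site, max_gaps = criteria$max_gaps)
      ratio <- duplex_mfe_ratio(mseq, aln$target, aln$states,
                                backend = mfe_backend)
      if (!passes_criteria(aln$states, aln$score, ratio, criteria)) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        mirna_id = mid, mirna_seq = mseq,
        transcript_id = peaks$transcript_id[j], cleavage_position = t,
        category = peaks$category[j], confidence = peaks$confidence[j],
        peak_abundance = peaks$abundance[j],
        score = aln$score, mfe_ratio = ratio, states = aln$states,
        conservation = cons, stringsAsFactors = FALSE
      )
    }
  }
  if (!k) return(empty_duplex_frame())
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

mirna_label <- function(candidates, i) {
  if ("matched_known_ids" %in% names(candidates) &&
      nzchar(candidates$matched_known_ids[i]))
    strsplit(candidates$matched_known_ids[i], ",")[[1L]][1L]
  else candidates$sequence[i]
}

empty_duplex_frame <- function() {
  data.frame(
    mirna_id = character(0), mirna_seq = character(0),
    transcript_id = character(0), cleavage_position = integer(0),
    category = integer(0), confidence = character(0),
    peak_abundance = integer(0), score = numeric(0), mfe_ratio = numeric(0),
    states = character(0), conservation = character(0),
    stringsAsFactors = FALSE
  )
}

#' Write / read an interactions table
#'
#' Tab-delimited with the duplex columns of [find_targets()].
#'
#' @param duplexes duplex data frame.
#' @param path file path.
#' @return `path` invisibly (writer); data frame (reader).
#' @export
write_interactions <- function(duplexes, path) {
  utils::write.table(duplexes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_interactions
#' @export
read_interactions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
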