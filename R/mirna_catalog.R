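#' Ungapped homology match between a read and a known miRNA
#'
#' Sense-strand sequence identity with at most `max_mm` mismatches and no
#' gaps. G:U is a mismatch here: this is read-vs-annotation identity, not
#' duplex pairing. Length variants are tolerated up to a 2-nt difference by
#' sliding the shorter sequence along the longer and taking the minimum
#' Hamming distance over offsets; overhangs are not penalized. Lengths
#' differing by more than 2 never match.
#'
#' @param read_seq,known_seq RNA-alphabet sequences.
#' @param max_mm maximum number of mismatches (default 2).
#' @return list with `is_match` (logical) and `n_mismatches` (integer; the
#'   minimum over offsets, `NA` when the length policy rules the pair out).
#' @export
homology_match <- function(read_seq, known_seq, max_mm = 2L) {
  a <- normalize_rna(read_seq)
  b <- normalize_rna(known_seq)
  if (abs(nchar(a) - nchar(b)) > 2L)
    return(list(is_match = FALSE, n_mismatches = NA_integer_))
  short <- if (nchar(a) <= nchar(b)) a else b
  long <- if (nchar(a) <= nchar(b)) b else a
  ls <- nchar(short); ll <- nchar(long)
  sv <- strsplit(short, "")[[1L]]
  lv <- strsplit(long, "")[[1L]]
  mm <- vapply(0:(ll - ls), function(off)
    sum(sv != lv[(off + 1L):(off + ls)]), integer(1))
  best <- min(mm)
  list(is_match = best <= max_mm, n_mismatches = as.integer(best))
}

#' Select miRNA candidates from an sRNA read set
#'
#' Reads with abundance at or above `min_abund` that match at least one
#' known mature miRNA under [homology_match()] become candidates; each
#' candidate lists every matched annotation id. User-supplied miRNAs bypass
#' homology but must still reach `min_abund` in the sRNA sample.
#'
#' @param rs sRNA [read_set()].
#' @param known data frame of known miRNAs as from [read_mirnas()].
#' @param min_abund minimum sRNA abundance (default 5).
#' @param user_supplied optional character vector of miRNA sequences to
#'   admit without a homology requirement.
#' @param max_mm mismatch allowance for [homology_match()].
#' @return data frame with columns `sequence`, `abundance`,
#'   `matched_known_ids` (comma-separated, `""` if none), `conservation`
#'   (see [classify_conservation()]) and `origin`.
#' @export
select_candidates <- function(rs, known, min_abund = 5L,
                              user_supplied = NULL, max_mm = 2L) {
  stopifnot(inherits(rs, "read_set"))
  if (is.null(known) || !nrow(known))
    stop("the known-miRNA list must be non-empty")
  reads <- rs$reads[rs$reads$abundance >= min_abund, , drop = FALSE]
  user_supplied <- if (is.null(user_supplied)) character(0) else
    normalize_rna(user_supplied)

  out <- lapply(seq_len(nrow(reads)), function(i) {
    seq <- reads$sequence[i]
    mm <- vapply(known$sequence, function(k)
      homology_match(seq, k, max_mm)$is_match, logical(1), USE.NAMES = FALSE)
    ids <- known$id[mm]
    if (length(ids))
      data.frame(sequence = seq, abundance = reads$abundance[i],
                 matched_known_ids = paste(ids, collapse = ","),
                 origin = "homology", stringsAsFactors = FALSE)
    else if (seq %in% user_supplied)
      data.frame(sequence = seq, abundance = reads$abundance[i],
                 matched_known_ids = "", origin = "user_supplied",
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(sequence = character(0), abundance = integer(0),
                      matched_known_ids = character(0), origin = character(0),
                      stringsAsFactors = FALSE)
  out$conservation <- vapply(out$sequence, classify_conservation,
                             character(1), known = known, max_mm = max_mm,
                             USE.NAMES = FALSE)
  rownames(out) <- NULL
  out[, c("sequence", "abundance", "matched_known_ids", "conservation",
          "origin")]
}

#' Classify a miRNA as conserved or species-specific
#'
#' Gathers every known miRNA matching the candidate under [homology_match()]
#' (up to two mismatches, any positions, no gaps). A candidate whose matches
#' span more than one clade is `conserved`; one whose matches are confined
#' to a single clade, or that matches nothing, is `species_specific`.
#'
#' @param sequence candidate miRNA sequence.
#' @param known data frame as from [read_mirnas()]; must carry clade
#'   metadata for every matched record.
#' @param max_mm mismatch allowance.
#' @return `"conserved"` or `"species_specific"`.
#' @export
classify_conservation <- function(sequence, known, max_mm = 2L) {
  hits <- vapply(known$sequence, function(k)
    homology_match(sequence, k, max_mm)$is_match, logical(1),
    USE.NAMES = FALSE)
  if (!any(hits)) return("species_specific")
  clades <- known$clade[hits]
  if (anyNA(clades))
    stop("missing clade metadata for matched miRNA record(s): ",
         paste(known$id[hits][is.na(clades)], collapse = ", "))
  if (length(unique(clades)) > 1L) "conserved" else "species_specific"
}
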