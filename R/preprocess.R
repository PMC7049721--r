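#' Discard reads containing ambiguous bases
#'
#' Keeps exactly the reads whose sequences contain only A, C, G, U.
#'
#' @param rs a [read_set()].
#' @return filtered [read_set()]; abundances of surviving reads unchanged.
#' @export
filter_ambiguous <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  keep <- !grepl("[^ACGU]", rs$reads$sequence)
  subset_read_set(rs, keep)
}

subset_read_set <- function(rs, keep) {
  rs$reads <- rs$reads[keep, , drop = FALSE]
  rownames(rs$reads) <- NULL
  rs
}

#' Low-complexity test for a single sequence
#'
#' A sequence fails (returns `FALSE`, i.e. discard) when the most frequent
#' mononucleotide exceeds 75% of positions, the most frequent overlapping
#' dinucleotide exceeds 37.5% of the L-1 windows, or the most frequent
#' overlapping trinucleotide exceeds 25% of the L-2 windows. Comparisons are
#' strictly greater-than, so boundary sequences are retained.
#'
#' @param seq a single sequence (RNA or DNA alphabet).
#' @param thresholds mono/di/tri-nucleotide frequency thresholds.
#' @return `TRUE` to keep, `FALSE` to discard. Sequences shorter than 3 nt
#'   cannot be evaluated against the trinucleotide rule and are discarded
#'   with a warning.
#' @export
low_complexity_pass <- function(seq, thresholds = c(0.75, 0.375, 0.25)) {
  stopifnot(length(seq) == 1L, length(thresholds) == 3L)
  L <- nchar(seq)
  if (L < 3L) {
    warning("sequence shorter than 3 nt cannot be complexity-scored; discarded")
    return(FALSE)
  }
  for (k in 1:3) {
    top <- max(table(substring(seq, 1:(L - k + 1L), k:L)))
    if (top / (L - k + 1L) > thresholds[k]) return(FALSE)
  }
  TRUE
}

#' Apply the low-complexity filter to a read set
#'
#' @inheritParams filter_ambiguous
#' @param thresholds passed to [low_complexity_pass()].
#' @return filtered [read_set()].
#' @export
filter_low_complexity <- function(rs, thresholds = c(0.75, 0.375, 0.25)) {
  stopifnot(inherits(rs, "read_set"))
  keep <- vapply(rs$reads$sequence, low_complexity_pass, logical(1),
                 thresholds = thresholds, USE.NAMES = FALSE)
  subset_read_set(rs, keep)
}

#' Keep only reads with an exact genome match
#'
#' A read survives if it occurs as an exact, full-length, ungapped substring
#' of any genome sequence on either strand.
#'
#' @inheritParams filter_ambiguous
#' @param genome character vector of genome sequences (either alphabet).
#' @return filtered [read_set()].
#' @export
filter_genome_match <- function(rs, genome) {
  stopifnot(inherits(rs, "read_set"))
  if (!length(genome)) stop("genome must be non-empty")
  genome <- normalize_rna(genome)
  haystack <- paste(c(genome, as.character(
    Biostrings::reverseComplement(Biostrings::RNAStringSet(genome))
  )), collapse = "\n")
  keep <- vapply(rs$reads$sequence, function(s)
    grepl(s, haystack, fixed = TRUE), logical(1), USE.NAMES = FALSE)
  subset_read_set(rs, keep)
}

#' Run the optional pre-processing filters
#'
#' @inheritParams filter_ambiguous
#' @param genome genome sequences for [filter_genome_match()], or `NULL` to
#'   skip that stage.
#' @param ambiguous,complexity logical stage toggles.
#' @return filtered [read_set()]. The filters are order-independent (each is
#'   a pure subset of its input), so they are applied in a fixed order.
#' @export
preprocess_reads <- function(rs, genome = NULL, ambiguous = TRUE,
                             complexity = TRUE) {
  if (ambiguous) rs <- filter_ambiguous(rs)
  if (complexity) rs <- filter_low_complexity(rs)
  if (!is.null(genome)) rs <- filter_genome_match(rs, genome)
  rs
}
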