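#' Map degradome reads onto transcripts
#'
#' Each degradome read contributes its full abundance at the 5'-end position
#' of every exact, full-length, sense-strand occurrence in every transcript
#' (multi-mapping reads are counted at each occurrence without
#' apportioning). Overlapping occurrences all count.
#'
#' @param rs degradome [read_set()].
#' @param transcriptome named character vector from [read_transcriptome()].
#' @return data frame of per-transcript 5'-end profiles: `transcript_id`,
#'   `position` (1-based), `abundance` (summed over reads sharing the
#'   position).
#' @export
map_degradome <- function(rs, transcriptome) {
  stopifnot(inherits(rs, "read_set"))
  if (!length(transcriptome)) stop("transcriptome must be loaded")
  subject <- Biostrings::RNAStringSet(transcriptome)
  rows <- list()
  for (i in seq_len(nrow(rs$reads))) {
    hits <- Biostrings::vmatchPattern(rs$reads$sequence[i], subject)
    n <- lengths(hits)
    if (!sum(n)) next
    starts <- unlist(IRanges::start(hits), use.names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = rep(names(transcriptome), n),
      position = starts,
      abundance = rs$reads$abundance[i],
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows))
    return(data.frame(transcript_id = character(0), position = integer(0),
                      abundance = integer(0), stringsAsFactors = FALSE))
  prof <- do.call(rbind, rows)
  agg <- stats::aggregate(abundance ~ transcript_id + position, prof, sum)
  agg <- agg[order(agg$transcript_id, agg$position), ]
  rownames(agg) <- NULL
  agg[, c("transcript_id", "position", "abundance")]
}

#' Categorize degradome peaks on each transcript
#'
#' Positions with abundance greater than 1 are classed by the CleaveLand
#' convention: category 0, the unique transcript maximum; category 1, a
#' maximum attained more than once; category 2, above the mean abundance;
#' category 3, at or below it. The mean is taken over the positions with
#' nonzero signal on that transcript. Positions with abundance 1 receive no
#' category.
#'
#' @param profiles data frame from [map_degradome()].
#' @return data frame `transcript_id`, `position`, `abundance`, `category`.
#' @export
categorize_peaks <- function(profiles) {
  stopifnot(all(c("transcript_id", "position", "abundance") %in%
                  names(profiles)))
  if (!nrow(profiles))
    return(cbind(profiles, category = integer(0)))
  out <- lapply(split(profiles, profiles$transcript_id), function(p) {
    elig <- p$abundance > 1L
    if (!any(elig)) return(NULL)
    M <- max(p$abundance)
    A <- mean(p$abundance)
    q <- p[elig, , drop = FALSE]
    is_max <- q$abundance == M
    cat <- ifelse(is_max, if (sum(p$abundance == M) == 1L) 0L else 1L,
                  ifelse(q$abundance > A, 2L, 3L))
    q$category <- as.integer(cat)
    q
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(cbind(profiles[0, ], category = integer(0)))
  out <- out[order(out$transcript_id, out$position), ]
  rownames(out) <- NULL
  out
}

#' Filter peaks by abundance and assign confidence classes
#'
#' Peaks with abundance below `min_abund` are excluded (low-abundance signal
#' is indistinguishable from random degradation). Surviving peaks of
#' category 0 or 1 (transcript maxima) are high-confidence (`HC`);
#' categories 2 and 3 are low-confidence (`LC`).
#'
#' @param peaks data frame from [categorize_peaks()].
#' @param min_abund minimum peak abundance (default 5).
#' @return `peaks` with a `confidence` column, filtered.
#' @export
confident_peaks <- function(peaks, min_abund = 5L) {
  stopifnot("category" %in% names(peaks))
  keep <- peaks$abundance >= min_abund
  out <- peaks[keep, , drop = FALSE]
  out$confidence <- ifelse(out$category %in% c(0L, 1L), "HC", "LC")
  rownames(out) <- NULL
  out
}
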