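#' Evaluate predictions against validated interactions
#'
#' The matching key is (miRNA sequence, transcript id, cleavage coordinate
#' within `tolerance` nt); predicted records are deduplicated by key first.
#' In the loose sense appropriate to degradome data, TP counts the
#' validated interactions captured by at least one prediction and FP the
#' predictions matching no validated record; sensitivity is `100*TP/P` over
#' the positive class `P` and precision `100*TP/(TP+FP)`. Specificity is
#' deliberately not computed (no comprehensive true-negative class exists).
#'
#' @param predicted duplex data frame (columns `mirna_seq` or
#'   `mirna_sequence`, `transcript_id`, `cleavage_position`).
#' @param validated validated interactions ([read_validated()] format).
#' @param positives positive class; defaults to `validated`.
#' @param tolerance cleavage-coordinate tolerance in nt (default 1, to
#'   absorb off-by-one conventions for which side of the cleaved bond is
#'   recorded).
#' @return list of class `evaluation_result`: `TP`, `FP`, `P`,
#'   `sensitivity`, `precision` (percent; `NA` when undefined, never an
#'   error).
#' @export
evaluate_predictions <- function(predicted, validated, positives = validated,
                                 tolerance = 1L) {
  pred <- normalize_keys(predicted)
  val <- normalize_keys(validated)
  pred <- pred[!duplicated(pred[c("mirna_seq", "transcript_id",
                                  "cleavage_position")]), , drop = FALSE]
  hit_val <- logical(nrow(val))
  hit_pred <- logical(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    j <- which(val$mirna_seq == pred$mirna_seq[i] &
                 val$transcript_id == pred$transcript_id[i] &
                 abs(val$cleavage_position - pred$cleavage_position[i]) <=
                   tolerance)
    if (length(j)) { hit_val[j] <- TRUE; hit_pred[i] <- TRUE }
  }
  TP <- sum(hit_val)
  FP <- sum(!hit_pred)
  P <- nrow(positives)
  structure(list(
    TP = TP, FP = FP, P = P,
    sensitivity = if (P > 0) 100 * TP / P else NA_real_,
    precision = if (TP + FP > 0) 100 * TP / (TP + FP) else NA_real_
  ), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "<evaluation_result> TP=%d FP=%d P=%d  Se=%s%%  PPV=%s%%\n",
    x$TP, x$FP, x$P, fmt_pct(x$sensitivity), fmt_pct(x$precision)
  ))
  invisible(x)
}

## round half up to one decimal, for display only
fmt_pct <- function(x) {
  if (is.na(x)) return("NA")
  sprintf("%.1f", floor(x * 10 + 0.5) / 10)
}

normalize_keys <- function(x) {
  seqcol <- if ("mirna_seq" %in% names(x)) "mirna_seq" else "mirna_sequence"
  if (!all(c(seqcol, "transcript_id", "cleavage_position") %in% names(x)))
    stop("prediction/validation tables need miRNA sequence, transcript id ",
         "and cleavage position columns")
  data.frame(
    mirna_seq = normalize_rna(x[[seqcol]]),
    transcript_id = as.character(x$transcript_id),
    cleavage_position = as.integer(x$cleavage_position),
    stringsAsFactors = FALSE
  )
}

#' Intersection summary of two prediction sets
#'
#' @param predictions_a,predictions_b duplex data frames keyed as in
#'   [evaluate_predictions()].
#' @param tolerance cleavage-coordinate tolerance in nt.
#' @return list with per-set distinct-miRNA and interaction counts, counts
#'   specific to each set, and the shared count (`total_a = shared +
#'   specific_a`).
#' @export
intersect_predictions <- function(predictions_a, predictions_b,
                                  tolerance = 1L) {
  a <- normalize_keys(predictions_a)
  b <- normalize_keys(predictions_b)
  a <- a[!duplicated(a), , drop = FALSE]
  b <- b[!duplicated(b), , drop = FALSE]
  in_other <- function(x, other) vapply(seq_len(nrow(x)), function(i)
    any(other$mirna_seq == x$mirna_seq[i] &
          other$transcript_id == x$transcript_id[i] &
          abs(other$cleavage_position - x$cleavage_position[i]) <= tolerance),
    logical(1))
  shared_a <- if (nrow(a)) in_other(a, b) else logical(0)
  shared_b <- if (nrow(b)) in_other(b, a) else logical(0)
  list(
    n_mirnas_a = length(unique(a$mirna_seq)),
    n_mirnas_b = length(unique(b$mirna_seq)),
    n_interactions_a = nrow(a),
    n_interactions_b = nrow(b),
    specific_a = sum(!shared_a),
    specific_b = sum(!shared_b),
    shared = sum(shared_a)
  )
}
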