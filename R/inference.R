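#' Position-specific property profile
#'
#' Counts and proportions of mismatches, G:U pairs, gaps and matches at each
#' miRNA position over a duplex set; the denominator at position p is the
#' number of duplexes whose miRNA covers p.
#'
#' @param duplexes duplex data frame (needs a `states` column).
#' @param n_positions number of positions profiled (default 21, the typical
#'   miRNA length).
#' @return data frame with `position`, `n` (covering duplexes), counts
#'   `mismatch`, `gu`, `gap`, `match` and matching `*_prop` columns.
#' @export
position_profile <- function(duplexes, n_positions = 21L) {
  if (!nrow(duplexes)) stop("cannot profile an empty duplex set")
  mat <- lapply(duplexes$states, function(s) strsplit(s, "")[[1L]])
  out <- lapply(seq_len(n_positions), function(p) {
    chars <- unlist(lapply(mat, function(v) if (length(v) >= p) v[p]))
    n <- length(chars)
    counts <- c(mismatch = sum(chars == "x"), gu = sum(chars == "o"),
                gap = sum(chars == "-"), match = sum(chars == "="))
    data.frame(position = p, n = n, t(counts),
               t(if (n) counts / n else counts * NA),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  names(out) <- c("position", "n", "mismatch", "gu", "gap", "match",
                  "mismatch_prop", "gu_prop", "gap_prop", "match_prop")
  out
}

## Lower empirical quantile (type 1): smallest achieved value covering at
## least a fraction r of the data.
quantile_lower <- function(x, r) sort(x)[max(1L, ceiling(r * length(x)))]

round_up_half <- function(x) ceiling(x * 2) / 2
round_down_cent <- function(x) floor(x * 100) / 100

## Table-4 field order; used for tie-breaking during joint relaxation.
.criteria_fields <- c("allow_mm_pos10", "allow_mm_pos11",
                      "max_adjacent_mm_core", "max_mm_core", "max_score",
                      "max_mm", "max_gu", "max_adjacent_mm",
                      "mfe_ratio_cutoff", "max_gaps")

#' Infer targeting criteria at a retain rate
#'
#' Derives each threshold marginally so that at least a fraction
#' `retain_rate` of the duplexes satisfies it: count caps are the smallest
#' integers covering that fraction, the score cap is the retain-rate
#' quantile of scores rounded up to the nearest 0.5 (the scoring atom), and
#' the MFE cutoff is the complementary quantile of ratios rounded down to
#' 0.01. The position-10/11 allowances are granted when at least one duplex
#' in the retained quantile (the `ceil(r n)` duplexes of lowest score,
#' highest MFE ratio) carries a non-Watson-Crick state there, so isolated
#' outliers cannot unlock those positions. If the assembled criteria
#' jointly retain less than `retain_rate`, single thresholds are relaxed
#' greedily (the step recovering the most failing duplexes first, ties in
#' criteria-field order) until the joint retention contract holds; the
#' relaxation is bounded by the envelope of the observed duplexes, where
#' retention is 100%.
#'
#' @param duplexes non-empty duplex data frame (columns `states`, `score`,
#'   `mfe_ratio`).
#' @param retain_rate fraction of duplexes the criteria must keep, in
#'   `(0, 1]` (default 0.85).
#' @return a [targeting_criteria()] object.
#' @export
infer_criteria <- function(duplexes, retain_rate = 0.85) {
  if (!nrow(duplexes)) stop("cannot infer criteria from an empty duplex set")
  if (!is.numeric(retain_rate) || retain_rate <= 0 || retain_rate > 1)
    stop("retain_rate must lie in (0, 1]")
  n <- nrow(duplexes)
  props <- t(vapply(duplexes$states, duplex_properties, numeric(6),
                    USE.NAMES = FALSE))
  colnames(props) <- c("n_mm", "n_gu", "n_gap", "n_adj_mm", "n_mm_core",
                       "n_adj_mm_core")

  ## retained-quantile subpopulation for the boolean allowances
  ord <- order(duplexes$score, -duplexes$mfe_ratio,
               duplexes$mirna_id %||% seq_len(n),
               duplexes$transcript_id %||% seq_len(n),
               duplexes$cleavage_position %||% seq_len(n))
  kept <- duplexes$states[ord[seq_len(max(1L, ceiling(retain_rate * n)))]]
  st_at <- function(s, p) if (nchar(s) >= p) substr(s, p, p) else "="
  allow10 <- any(vapply(kept, st_at, character(1), p = 10L) != "=")
  allow11 <- any(vapply(kept, st_at, character(1), p = 11L) != "=")

  crit <- targeting_criteria(
    allow_mm_pos10 = allow10,
    allow_mm_pos11 = allow11,
    max_adjacent_mm_core = quantile_lower(props[, "n_adj_mm_core"], retain_rate),
    max_mm_core = quantile_lower(props[, "n_mm_core"], retain_rate),
    max_score = round_up_half(quantile_lower(duplexes$score, retain_rate)),
    max_mm = quantile_lower(props[, "n_mm"], retain_rate),
    max_gu = quantile_lower(props[, "n_gu"], retain_rate),
    max_adjacent_mm = quantile_lower(props[, "n_adj_mm"], retain_rate),
    mfe_ratio_cutoff = round_down_cent(
      sort(duplexes$mfe_ratio)[n - max(1L, ceiling(retain_rate * n)) + 1L]),
    max_gaps = quantile_lower(props[, "n_gap"], retain_rate)
  )

  ## data envelope: relaxation never needs to go further than this
  envelope <- list(
    allow_mm_pos10 = TRUE, allow_mm_pos11 = TRUE,
    max_adjacent_mm_core = max(props[, "n_adj_mm_core"]),
    max_mm_core = max(props[, "n_mm_core"]),
    max_score = round_up_half(max(duplexes$score)),
    max_mm = max(props[, "n_mm"]),
    max_gu = max(props[, "n_gu"]),
    max_adjacent_mm = max(props[, "n_adj_mm"]),
    mfe_ratio_cutoff = round_down_cent(min(duplexes$mfe_ratio)),
    max_gaps = max(props[, "n_gap"])
  )

  ## vectorized criteria check over the precomputed property matrix
  st10 <- vapply(duplexes$states, st_at, character(1), p = 10L,
                 USE.NAMES = FALSE)
  st11 <- vapply(duplexes$states, st_at, character(1), p = 11L,
                 USE.NAMES = FALSE)
  passes_all <- function(cr) {
    (cr$allow_mm_pos10 | st10 == "=") &
      (cr$allow_mm_pos11 | st11 == "=") &
      props[, "n_mm"] <= cr$max_mm &
      props[, "n_gu"] <= cr$max_gu &
      props[, "n_gap"] <= cr$max_gaps &
      props[, "n_adj_mm"] <= cr$max_adjacent_mm &
      props[, "n_adj_mm_core"] <= cr$max_adjacent_mm_core &
      props[, "n_mm_core"] <= cr$max_mm_core &
      duplexes$score <= cr$max_score &
      duplexes$mfe_ratio >= cr$mfe_ratio_cutoff
  }

  pass <- passes_all(crit)
  while (mean(pass) < retain_rate) {
    best_field <- NULL; best_gain <- -1L
    for (f in .criteria_fields) {
      relaxed <- relax_one(crit, f, envelope)
      if (is.null(relaxed)) next
      gain <- sum(passes_all(relaxed) & !pass)
      if (gain > best_gain) { best_gain <- gain; best_field <- f }
    }
    if (is.null(best_field)) break   # at the envelope: everything passes
    crit <- relax_one(crit, best_field, envelope)
    pass <- passes_all(crit)
  }
  crit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## One relaxation step for a single criteria field, or NULL when the field
## is already at its envelope bound.
relax_one <- function(crit, field, envelope) {
  cur <- crit[[field]]; bound <- envelope[[field]]
  new <- if (is.logical(cur)) {
    if (cur || !bound) return(NULL) else TRUE
  } else if (field == "max_score") {
    if (cur >= bound) return(NULL) else cur + 0.5
  } else if (field == "mfe_ratio_cutoff") {
    if (cur <= bound) return(NULL) else max(bound, cur - 0.01)
  } else {
    if (cur >= bound) return(NULL) else cur + 1
  }
  crit[[field]] <- new
  crit
}

#' Retain-rate sweep
#'
#' Infers criteria at each grid value, filters the duplex set, and counts
#' captured validated / non-validated interactions with the resulting
#' sensitivity and precision.
#'
#' @param duplexes duplex data frame.
#' @param validated validated interactions ([read_validated()] format).
#' @param positives the positive class: validated interactions with HC
#'   peaks and expressed miRNAs; defaults to `validated`.
#' @param grid retain-rate grid (default 0.50 to 1.00 in steps of 0.05).
#' @param tolerance cleavage-coordinate matching tolerance in nt.
#' @return data frame with one row per grid value: `retain_rate`,
#'   `n_captured`, `n_validated`, `n_nonvalidated`, `sensitivity`,
#'   `precision`.
#' @export
retain_sweep <- function(duplexes, validated, positives = validated,
                         grid = seq(0.50, 1.00, by = 0.05), tolerance = 1L) {
  rows <- lapply(grid, function(r) {
    crit <- infer_criteria(duplexes, r)
    keep <- vapply(seq_len(nrow(duplexes)), function(i)
      passes_criteria(duplexes$states[i], duplexes$score[i],
                      duplexes$mfe_ratio[i], crit), logical(1))
    captured <- duplexes[keep, , drop = FALSE]
    ev <- evaluate_predictions(captured, validated, positives,
                               tolerance = tolerance)
    data.frame(retain_rate = r, n_captured = nrow(captured),
               n_validated = ev$TP, n_nonvalidated = ev$FP,
               sensitivity = ev$sensitivity, precision = ev$precision)
  })
  do.call(rbind, rows)
}

#' Sensitivity-gain to precision-loss ratio of a sweep increment
#'
#' The absolute ratio of the sensitivity change to the precision loss
#' across two consecutive sweep rows; `Inf` when precision does not drop.
#'
#' @param row_lo,row_hi consecutive sweep rows (anything with `sensitivity`
#'   and `precision` fields, e.g. one-row data frames).
#' @return non-negative ratio, or `Inf`.
#' @export
se_ppv_ratio <- function(row_lo, row_hi) {
  d_se <- row_hi$sensitivity - row_lo$sensitivity
  d_ppv <- row_hi$precision - row_lo$precision
  if (is.na(d_ppv) || d_ppv >= 0) return(Inf)
  abs(d_se) / abs(d_ppv)
}

#' Select the default retain rate from a sweep
#'
#' Returns the lower endpoint of the first consecutive increment whose
#' sensitivity/precision ratio falls below 1 (the point where precision
#' loss starts outweighing sensitivity gain); the final grid value if no
#' increment qualifies.
#'
#' @param sweep data frame from [retain_sweep()] (at least 2 rows).
#' @return selected retain-rate value.
#' @export
select_retain <- function(sweep) {
  stopifnot(nrow(sweep) >= 2L)
  for (i in seq_len(nrow(sweep) - 1L)) {
    if (se_ppv_ratio(sweep[i, ], sweep[i + 1L, ]) < 1) return(sweep$retain_rate[i])
  }
  sweep$retain_rate[nrow(sweep)]
}

#' Write / read a criteria file
#'
#' Flat `key=value` text with the criteria field names.
#'
#' @param criteria a [targeting_criteria()] object.
#' @param path file path.
#' @return `path` invisibly (writer); [targeting_criteria()] (reader).
#' @export
write_criteria <- function(criteria, path) {
  vals <- vapply(.criteria_fields, function(f) {
    v <- criteria[[f]]
    if (is.logical(v)) ifelse(v, "Yes", "No") else format(v, nsmall = 2)
  }, character(1))
  writeLines(paste0(.criteria_fields, "=", vals), path)
  invisible(path)
}

#' @rdname write_criteria
#' @export
read_criteria <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  args <- lapply(.criteria_fields, function(f) {
    v <- vals[[f]]
    if (v %in% c("Yes", "No")) v == "Yes" else as.numeric(v)
  })
  names(args) <- .criteria_fields
  do.call(targeting_criteria, args)
}
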