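#' Offset chi-square test on position-specific properties
#'
#' Goodness-of-fit of the observed {mismatch, G:U, gap, match} counts at one
#' position against the reference set's category proportions at the same
#' position (expected counts = reference proportions times the observed
#' total). The offset stabilizes empty cells: 0.5 is added to every
#' expected cell that is zero. Degrees of freedom = number of categories
#' minus one.
#'
#' @param profile_obs,profile_ref profiles from [position_profile()]
#'   (raw counts are required).
#' @param position miRNA position to test.
#' @param offset value added to zero expected cells (default 0.5).
#' @return p-value (`NA` when the observed total at the position is 0).
#' @export
chi2_offset_position <- function(profile_obs, profile_ref, position,
                                 offset = 0.5) {
  cats <- c("mismatch", "gu", "gap", "match")
  o <- unlist(profile_obs[profile_obs$position == position, cats])
  r <- unlist(profile_ref[profile_ref$position == position, cats])
  n_obs <- sum(o)
  if (n_obs == 0) return(NA_real_)
  expected <- r / sum(r) * n_obs
  ## offset only matters where something was observed; cells empty in both
  ## sets carry no evidence and contribute nothing
  use <- o > 0 | expected > 0
  expected[expected == 0 & o > 0] <- offset
  stat <- sum((o[use] - expected[use])^2 / expected[use])
  stats::pchisq(stat, df = length(cats) - 1L, lower.tail = FALSE)
}

#' Global offset chi-square over all profiled positions
#'
#' Pools the per-position property counts into one position-by-category
#' contingency and tests the pooled observed counts against the pooled
#' reference proportions, category by category across all positions
#' (df = positions x (categories - 1)).
#'
#' @inheritParams chi2_offset_position
#' @return p-value.
#' @export
chi2_offset_overall <- function(profile_obs, profile_ref, offset = 0.5) {
  cats <- c("mismatch", "gu", "gap", "match")
  stat <- 0; df <- 0L
  for (p in profile_obs$position) {
    o <- unlist(profile_obs[profile_obs$position == p, cats])
    r <- unlist(profile_ref[profile_ref$position == p, cats])
    if (sum(o) == 0 || sum(r) == 0) next
    expected <- r / sum(r) * sum(o)
    use <- o > 0 | expected > 0
    expected[expected == 0 & o > 0] <- offset
    stat <- stat + sum((o[use] - expected[use])^2 / expected[use])
    df <- df + length(cats) - 1L
  }
  if (df == 0L) return(NA_real_)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Per-position Fisher exact test for one property
#'
#' Two-sided Fisher exact test on the 2x2 table of property occurrences at
#' the given position versus the sum over all remaining positions, for the
#' two duplex sets.
#'
#' @param profile_a,profile_b profiles from [position_profile()].
#' @param property `"mismatch"`, `"gu"` or `"gap"`.
#' @param position miRNA position to test.
#' @return two-sided p-value; an all-zero table returns 1 by convention.
#' @export
fisher_position <- function(profile_a, profile_b, property, position) {
  stopifnot(property %in% c("mismatch", "gu", "gap"))
  a_at <- profile_a[[property]][profile_a$position == position]
  a_rest <- sum(profile_a[[property]]) - a_at
  b_at <- profile_b[[property]][profile_b$position == position]
  b_rest <- sum(profile_b[[property]]) - b_at
  tab <- matrix(c(a_at, a_rest, b_at, b_rest), nrow = 2, byrow = TRUE)
  if (all(tab == 0)) return(1)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Subsampled two-sample Kolmogorov-Smirnov test on MFE ratios
#'
#' The larger sample is first subsampled without replacement (seeded) to
#' the smaller sample's size, then a two-sided two-sample KS test compares
#' the subsampled distributions.
#'
#' @param ratios_a,ratios_b numeric vectors of MFE ratios.
#' @param seed integer seed for the subsampling (the test is deterministic
#'   given the seed).
#' @return KS p-value.
#' @export
ks_mfe <- function(ratios_a, ratios_b, seed = 1L) {
  stopifnot(length(ratios_a) > 0, length(ratios_b) > 0)
  n <- min(length(ratios_a), length(ratios_b))
  if (length(ratios_a) != length(ratios_b)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (is.null(old))
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    if (length(ratios_a) > n) ratios_a <- sample(ratios_a, n)
    if (length(ratios_b) > n) ratios_b <- sample(ratios_b, n)
  }
  suppressWarnings(stats::ks.test(ratios_a, ratios_b,
                                  alternative = "two.sided"))$p.value
}

#' Position-by-position statistics table for two duplex sets
#'
#' The reporting layout used for subset comparisons: per position, the
#' offset chi-square p-value and Fisher exact p-values for mismatches, G:U
#' pairs and gaps (set A is the reference/expected distribution).
#'
#' @param duplexes_a,duplexes_b duplex data frames; A is the reference.
#' @param n_positions number of positions (default 21).
#' @return data frame `position`, `chi2_p`, `fisher_mm_p`, `fisher_gu_p`,
#'   `fisher_gap_p`.
#' @export
property_stats_table <- function(duplexes_a, duplexes_b, n_positions = 21L) {
  pa <- position_profile(duplexes_a, n_positions)
  pb <- position_profile(duplexes_b, n_positions)
  data.frame(
    position = pa$position,
    chi2_p = vapply(pa$position, function(p)
      chi2_offset_position(pb, pa, p), numeric(1)),
    fisher_mm_p = vapply(pa$position, function(p)
      fisher_position(pa, pb, "mismatch", p), numeric(1)),
    fisher_gu_p = vapply(pa$position, function(p)
      fisher_position(pa, pb, "gu", p), numeric(1)),
    fisher_gap_p = vapply(pa$position, function(p)
      fisher_position(pa, pb, "gap", p), numeric(1))
  )
}
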