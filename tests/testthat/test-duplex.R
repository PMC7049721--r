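test_that("site extraction follows the anchored cleavage geometry", {
  set.seed(3)
  tx <- random_rna(200)
  s <- extract_site(tx, 100L, 21L, gap_budget = 0L)
  expect_equal(c(s$start, s$end), c(89L, 109L))      # t+10-L .. t+9
  expect_false(s$truncated)
  # miRNA position 1 pairs coordinate t+10-1 = 109, position 21 pairs 89
  expect_equal(substr(s$seq, 109 - s$start + 1, 109 - s$start + 1),
               substr(tx, 109, 109))
  s20 <- extract_site(tx, 100L, 20L, gap_budget = 1L)
  expect_equal(c(s20$start, s20$end), c(89L, 110L))
  trunc <- extract_site(tx, 5L, 21L, gap_budget = 0L)
  expect_true(trunc$truncated)
  expect_equal(trunc$start, 1L)
  expect_error(extract_site(tx, 300L, 21L), "outside")
})

## plant a site for the given states at coordinate t of a random transcript
plant_site <- function(pd, tx_len = 120L, t = 60L) {
  tx <- random_rna(tx_len)
  site <- paste(rev(strsplit(pd$target, "")[[1]][
    strsplit(pd$states, "")[[1]] != "-"]), collapse = "")
  n3 <- sum(strsplit(pd$states, "")[[1]][11:nchar(pd$mirna)] != "-")
  substr(tx, t - n3, t - n3 + nchar(site) - 1L) <- site
  tx
}

test_that("alignment recovers planted pair states", {
  set.seed(9)
  perfect <- make_planned_duplex(21L)
  tx <- plant_site(perfect)
  aln <- align_duplex(perfect$mirna, extract_site(tx, 60L, 21L, 1L), 1L)
  expect_equal(aln$states, strrep("=", 21))
  expect_equal(aln$score, 0)

  gu16 <- make_planned_duplex(21L, gu_pos = 16L)
  aln2 <- align_duplex(gu16$mirna, extract_site(plant_site(gu16), 60L, 21L, 1L), 1L)
  expect_equal(substr(aln2$states, 16, 16), "o")
  expect_equal(gsub("o", "=", aln2$states), strrep("=", 21))

  mm5 <- make_planned_duplex(21L, mm_pos = 5L)
  aln3 <- align_duplex(mm5$mirna, extract_site(plant_site(mm5), 60L, 21L, 1L), 1L)
  expect_equal(substr(aln3$states, 5, 5), "x")
  expect_equal(aln3$score, 2)          # core weight doubles the penalty
})

test_that("scoring applies penalties and core weights additively", {
  L <- 21L
  expect_equal(score_duplex(strrep("=", L)), 0)
  s <- strrep("=", L); substr(s, 5, 5) <- "x"
  expect_equal(score_duplex(s), 2)                    # 1.0 x core weight 2
  s2 <- strrep("=", L); substr(s2, 16, 16) <- "o"; substr(s2, 1, 1) <- "x"
  expect_equal(score_duplex(s2), 1.5)                 # 0.5 + 1.0, both weight 1
  # moving one mismatch from non-core to core adds exactly its penalty again
  set.seed(12)
  for (i in 1:20) {
    base <- random_states(21L)
    if (substr(base, 20, 20) != "=" || substr(base, 5, 5) != "=") next
    a <- base; substr(a, 20, 20) <- "x"
    b <- base; substr(b, 5, 5) <- "x"
    expect_equal(score_duplex(b) - score_duplex(a), 1)
  }
})

test_that("alignment equals the bulge-placement enumeration oracle", {
  set.seed(77)
  for (i in 1:60) {
    L <- sample(19:22, 1)
    pd <- make_planned_duplex(L, mm_pos = sample(setdiff(1:L, 10), sample(0:3, 1)))
    tx <- plant_site(pd, 150L, 70L)
    # mutate the site region a little so bulged alignments can win
    p <- sample(50:90, 1)
    substr(tx, p, p) <- sample(NT, 1)
    site <- extract_site(tx, 70L, L, gap_budget = 1L)
    mine <- align_duplex(pd$mirna, site, max_gaps = 1L)
    oracle <- enumerate_alignments(pd$mirna, tx, 70L)
    expect_equal(mine$score, oracle$score)
    expect_equal(mine$states, oracle$states)
  }
})

test_that("duplex properties count runs and core occurrences correctly", {
  s <- strrep("=", 21)
  substr(s, 14, 16) <- "xxx"                  # run of 3 = 2 adjacent pairs
  pr <- duplex_properties(s)
  expect_equal(unname(pr["n_mm"]), 3)
  expect_equal(unname(pr["n_adj_mm"]), 2)
  expect_equal(unname(pr["n_adj_mm_core"]), 0)
  s2 <- strrep("=", 21)
  substr(s2, 4, 5) <- "xx"; substr(s2, 18, 18) <- "o"
  pr2 <- duplex_properties(s2)
  expect_equal(unname(pr2["n_mm_core"]), 2)
  expect_equal(unname(pr2["n_adj_mm_core"]), 1)
  expect_equal(unname(pr2["n_gu"]), 1)
})

test_that("criteria testing enforces every rule of the family", {
  crit <- permissive_criteria()
  perfect <- strrep("=", 21)
  expect_true(passes_criteria(perfect, mfe_ratio = 1, criteria = crit))

  no10 <- targeting_criteria(allow_mm_pos10 = FALSE, mfe_ratio_cutoff = 0)
  mm10 <- perfect; substr(mm10, 10, 10) <- "x"
  expect_false(passes_criteria(mm10, mfe_ratio = 1, criteria = no10))
  gu10 <- perfect; substr(gu10, 10, 10) <- "o"   # G:U counts as MM at 10
  expect_false(passes_criteria(gu10, mfe_ratio = 1, criteria = no10))

  run3 <- perfect; substr(run3, 14, 16) <- "xxx"
  tight <- targeting_criteria(max_adjacent_mm = 1, max_mm = 5,
                              mfe_ratio_cutoff = 0, max_score = 20)
  expect_false(passes_criteria(run3, mfe_ratio = 1, criteria = tight))
  loose <- targeting_criteria(max_adjacent_mm = 2, max_mm = 5,
                              mfe_ratio_cutoff = 0, max_score = 20)
  expect_true(passes_criteria(run3, mfe_ratio = 1, criteria = loose))

  expect_false(passes_criteria(perfect, mfe_ratio = 0.60,
                               criteria = targeting_criteria(mfe_ratio_cutoff = 0.65)))
  expect_error(targeting_criteria(max_mm = -1), "caps")
  expect_error(targeting_criteria(mfe_ratio_cutoff = 1.2), "mfe_ratio_cutoff")
})

test_that("criteria files round-trip through the key=value format", {
  crit <- targeting_criteria(allow_mm_pos10 = FALSE, max_score = 4.5,
                             mfe_ratio_cutoff = 0.69)
  p <- tempfile()
  write_criteria(crit, p)
  expect_equal(read_criteria(p), crit)
})

test_that("target prediction reports planted HC interactions and applies the peak floor", {
  set.seed(101)
  pd <- make_planned_duplex(21L)
  tx <- c(SYN1 = plant_site(pd, 200L, 90L))
  cands <- data.frame(sequence = pd$mirna, abundance = 50L,
                      matched_known_ids = "syn-miR1",
                      conservation = "conserved", origin = "homology",
                      stringsAsFactors = FALSE)
  deg <- read_set(substr(tx[["SYN1"]], 90, 109), 50L, kind = "degradome")
  peaks <- confident_peaks(categorize_peaks(map_degradome(deg, tx)))
  hits <- find_targets(cands, tx, peaks)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$confidence, "HC")
  expect_equal(hits$category, 0L)
  expect_equal(hits$cleavage_position, 90L)
  expect_equal(hits$states, strrep("=", 21))

  weak <- read_set(substr(tx[["SYN1"]], 90, 109), 4L, kind = "degradome")
  peaks4 <- confident_peaks(categorize_peaks(map_degradome(weak, tx)))
  expect_equal(nrow(find_targets(cands, tx, peaks4)), 0L)

  # determinism
  expect_identical(hits, find_targets(cands, tx, peaks))
})
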