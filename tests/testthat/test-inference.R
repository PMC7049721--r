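test_that("position profiles tabulate per-position property proportions", {
  set.seed(19)
  perfect <- duplex_frame(rep(strrep("=", 21), 10))
  pp <- position_profile(perfect)
  expect_equal(nrow(pp), 21L)
  expect_true(all(pp$mismatch_prop == 0 & pp$gu_prop == 0 & pp$gap_prop == 0))

  s <- strrep("=", 21); substr(s, 5, 5) <- "x"
  mixed <- duplex_frame(c(rep(strrep("=", 21), 3), s))
  pm <- position_profile(mixed)
  expect_equal(pm$mismatch_prop[pm$position == 5], 0.25)
  sums <- pm$mismatch_prop + pm$gu_prop + pm$gap_prop + pm$match_prop
  expect_equal(sums, rep(1, 21))

  # hand-tabulated counts on a small mixed set
  s2 <- strrep("=", 21); substr(s2, 5, 5) <- "o"; substr(s2, 21, 21) <- "x"
  tab <- duplex_frame(c(s, s2, strrep("=", 21)))
  pt <- position_profile(tab)
  expect_equal(pt$mismatch[pt$position == 5], 1)
  expect_equal(pt$gu[pt$position == 5], 1)
  expect_equal(pt$match[pt$position == 5], 1)
  expect_equal(pt$mismatch[pt$position == 21], 1)
  expect_error(position_profile(duplex_frame(character(0))), "empty")
})

test_that("criteria inferred at retain rate 1 keep every input duplex", {
  set.seed(29)
  for (rep in 1:5) {
    d <- duplex_frame(replicate(30, random_states(21L, loose = TRUE)))
    crit <- infer_criteria(d, 1.0)
    pass <- vapply(seq_len(nrow(d)), function(i)
      passes_criteria(d$states[i], d$score[i], d$mfe_ratio[i], crit),
      logical(1))
    expect_true(all(pass))
  }
})

test_that("degenerate all-perfect input collapses every threshold", {
  set.seed(37)
  d <- duplex_frame(rep(strrep("=", 21), 100), mfe_ratio = rep(1, 100))
  crit <- infer_criteria(d, 0.85)
  expect_equal(crit$max_mm, 0)
  expect_equal(crit$max_gu, 0)
  expect_equal(crit$max_gaps, 0)
  expect_equal(crit$max_score, 0)
  expect_equal(crit$mfe_ratio_cutoff, 1)
  expect_false(crit$allow_mm_pos10)
  expect_false(crit$allow_mm_pos11)
})

test_that("the score cap is the retain-rate quantile rounded up to 0.5", {
  set.seed(43)
  # 30 duplexes: 25 with scores <= 3.5, 5 with scores >= 5; the 26th-lowest
  # (ceil(0.85*30)) score is 4.0 after rounding up
  states <- c(
    replicate(25, {
      s <- strrep("=", 21)
      substr(s, sample(14:21, 1), sample(14:21, 1) + 0) <- "x"
      substr(s, 1, 1) <- sample(c("=", "o"), 1)
      s
    }),
    replicate(5, {
      s <- strrep("=", 21); substr(s, 5, 5) <- "x"
      substr(s, 15, 16) <- "xx"; substr(s, 20, 20) <- "x"; s
    })
  )
  d <- duplex_frame(states)
  sorted <- sort(d$score)
  expected <- ceiling(sorted[ceiling(0.85 * 30)] * 2) / 2  # sort-and-index oracle
  crit <- infer_criteria(d, 0.85)
  expect_equal(crit$max_score, expected)
})

test_that("inference retains at least the requested fraction (contract)", {
  set.seed(53)
  for (rep in 1:40) {
    n <- sample(15:60, 1)
    d <- duplex_frame(replicate(n, random_states(21L, loose = TRUE)))
    r <- sample(seq(0.5, 1.0, 0.05), 1)
    crit <- infer_criteria(d, r)
    frac <- mean(vapply(seq_len(n), function(i)
      passes_criteria(d$states[i], d$score[i], d$mfe_ratio[i], crit),
      logical(1)))
    expect_gte(frac, r)
  }
})

test_that("higher retain rates pass a superset; inference is order-invariant", {
  set.seed(61)
  d <- duplex_frame(replicate(40, random_states(21L, loose = TRUE)))
  pass_at <- function(crit) vapply(seq_len(nrow(d)), function(i)
    passes_criteria(d$states[i], d$score[i], d$mfe_ratio[i], crit),
    logical(1))
  p1 <- pass_at(infer_criteria(d, 0.6))
  p2 <- pass_at(infer_criteria(d, 0.85))
  p3 <- pass_at(infer_criteria(d, 1.0))
  expect_true(all(p2[p1]))
  expect_true(all(p3[p2]))

  shuffled <- d[sample(nrow(d)), ]
  expect_equal(infer_criteria(shuffled, 0.85), infer_criteria(d, 0.85))
})

test_that("the sweep counts captured interactions along the grid", {
  set.seed(67)
  states <- replicate(30, random_states(21L))
  d <- duplex_frame(states)
  validated <- data.frame(
    mirna_id = d$mirna_id[1:18], mirna_sequence = d$mirna_seq[1:18],
    transcript_id = d$transcript_id[1:18],
    cleavage_position = d$cleavage_position[1:18], stringsAsFactors = FALSE
  )
  sweep <- retain_sweep(d, validated)
  expect_equal(nrow(sweep), 11L)
  expect_equal(sweep$retain_rate, seq(0.5, 1.0, 0.05))
  expect_true(all(diff(sweep$n_captured) >= 0))
  expect_equal(sweep$n_captured[11], 30L)
  expect_equal(sweep$n_validated[11], 18L)
  expect_equal(sweep$sensitivity[11], 100)
})

test_that("the Se/PPV ratio reproduces the worked increment arithmetic", {
  lo <- list(sensitivity = 75.2, precision = 95.1)
  hi <- list(sensitivity = 83.7, precision = 93.9)
  expect_equal(round(se_ppv_ratio(lo, hi), 1), 7.1)
  expect_identical(se_ppv_ratio(list(sensitivity = 50, precision = 90),
                                list(sensitivity = 51, precision = 90.3)), Inf)
  expect_equal(se_ppv_ratio(list(sensitivity = 50, precision = 90),
                            list(sensitivity = 51, precision = 88)), 0.5)
})

test_that("retain-rate selection picks the first sub-unity increment", {
  sweep <- data.frame(
    retain_rate = seq(0.5, 1.0, 0.05),
    sensitivity = c(20, 30, 40, 50, 60, 75.2, 83.7, 85.7, 85.9, 86.0, 86.1),
    precision = c(99, 99, 99, 98.5, 96, 95.1, 93.9, 92.0, 90.1, 90.0, 89.9)
  )
  # increments up to 0.80-0.85 have ratio >= 1; 0.85-0.90 is 0.2/1.9 < 1
  expect_equal(select_retain(sweep), 0.85)

  flat <- data.frame(retain_rate = seq(0.5, 1.0, 0.05),
                     sensitivity = seq(10, 60, 5), precision = rep(90, 11))
  expect_equal(select_retain(flat), 1.0)   # no precision loss anywhere

  quick <- data.frame(retain_rate = c(0.5, 0.55),
                      sensitivity = c(50, 50.1), precision = c(95, 90))
  expect_equal(select_retain(quick), 0.5)
})
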