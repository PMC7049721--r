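## profile stubs with controlled counts at one position
profile_stub <- function(mismatch, gu, gap, match, position = 5L,
                         n_positions = 21L) {
  out <- data.frame(position = seq_len(n_positions), n = mismatch + gu + gap + match,
                    mismatch = 0, gu = 0, gap = 0, match = mismatch + gu + gap + match)
  out[out$position == position, c("mismatch", "gu", "gap", "match")] <-
    c(mismatch, gu, gap, match)
  out
}

test_that("offset chi-square is 1 on identical distributions and scale-free", {
  obs <- profile_stub(20, 10, 0, 170)
  ref <- profile_stub(20, 10, 0, 170)
  expect_equal(chi2_offset_position(obs, ref, 5L), 1)
  ref10 <- profile_stub(200, 100, 0, 1700)      # reference counts x10
  expect_equal(chi2_offset_position(obs, ref10, 5L),
               chi2_offset_position(obs, ref, 5L))

  # reference all-match, observed half mismatched: offset fills the zero
  # expected cells and the statistic explodes
  obs2 <- profile_stub(50, 0, 0, 50)
  ref2 <- profile_stub(0, 0, 0, 100)
  p <- chi2_offset_position(obs2, ref2, 5L)
  # closed form: mismatch cell E offset to 0.5, empty-in-both cells drop out
  stat <- 49.5^2 / 0.5 + 2500 / 100
  expect_equal(p, pchisq(stat, df = 3, lower.tail = FALSE))
  expect_lt(p, 0.001)
  # empty observed position -> undefined flag
  expect_true(is.na(chi2_offset_position(profile_stub(0, 0, 0, 0), ref, 5L)))
})

test_that("global chi-square pools all positions", {
  obs <- profile_stub(20, 10, 0, 170)
  ref <- profile_stub(20, 10, 0, 170)
  expect_equal(chi2_offset_overall(obs, ref), 1)
  expect_lt(chi2_offset_overall(profile_stub(50, 0, 0, 50),
                                profile_stub(0, 0, 0, 100)), 0.001)
})

test_that("per-position Fisher tests match a hypergeometric enumeration oracle", {
  # identical rows
  pa <- profile_stub(5, 0, 0, 95)
  pb <- profile_stub(5, 0, 0, 95)
  expect_equal(fisher_position(pa, pb, "mismatch", 5L), 1)

  # oracle: two-sided Fisher p by enumerating the hypergeometric support
  fisher_oracle <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  pa2 <- profile_stub(10, 0, 0, 0)
  pb2 <- profile_stub(0, 0, 0, 10)
  pb2$mismatch[pb2$position == 7] <- 10   # all of B's mismatches elsewhere
  p <- fisher_position(pa2, pb2, "mismatch", 5L)
  expect_equal(p, fisher_oracle(10, 0, 0, 10), tolerance = 1e-6)
  expect_equal(round(p, 7), round(1.082509e-05, 7))

  set.seed(97)
  for (i in 1:30) {
    a <- sample(0:25, 1); b <- sample(0:25, 1)
    c <- sample(0:25, 1); d <- sample(0:25, 1)
    if (a + b + c + d == 0) next
    pa3 <- profile_stub(a, 0, 0, 0); pa3$mismatch[pa3$position == 9] <- b
    pb3 <- profile_stub(c, 0, 0, 0); pb3$mismatch[pb3$position == 9] <- d
    expect_equal(fisher_position(pa3, pb3, "mismatch", 5L),
                 fisher_oracle(a, b, c, d), tolerance = 1e-6)
    # symmetry in the set order
    expect_equal(fisher_position(pa3, pb3, "mismatch", 5L),
                 fisher_position(pb3, pa3, "mismatch", 5L))
  }
  # all-zero table convention
  z <- profile_stub(0, 0, 0, 10)
  expect_equal(fisher_position(z, z, "gap", 5L), 1)
})

test_that("KS on MFE ratios subsamples deterministically", {
  x <- seq(0.5, 1, length.out = 60)
  expect_equal(ks_mfe(x, x), 1)               # identical multisets, no subsample
  set.seed(103)
  a <- pmin(1, rnorm(200, 0.9, 0.03))
  b <- pmin(1, rnorm(350, 0.6, 0.05))
  expect_lt(ks_mfe(a, b, seed = 5), 0.001)
  expect_identical(ks_mfe(a, b, seed = 5), ks_mfe(a, b, seed = 5))
})

test_that("the per-position stats table has the reporting shape", {
  set.seed(107)
  da <- duplex_frame(replicate(25, random_states(21L)))
  db <- duplex_frame(replicate(25, random_states(21L, loose = TRUE)))
  tab <- property_stats_table(da, db)
  expect_equal(names(tab),
               c("position", "chi2_p", "fisher_mm_p", "fisher_gu_p",
                 "fisher_gap_p"))
  expect_equal(nrow(tab), 21L)
  ok <- !is.na(unlist(tab[-1]))
  expect_true(all(unlist(tab[-1])[ok] >= 0 & unlist(tab[-1])[ok] <= 1))
})
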