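test_that("point probability matches hand-derived closed forms", {
  expect_equal(ac_point_prob(0, 0, 1e6, 1e6), 0.5, tolerance = 1e-12)
  expect_equal(ac_point_prob(2, 1, 1e6, 1e6), 3 / 16, tolerance = 1e-12)
  expect_equal(ac_point_prob(1, 1, 1e6, 1e6), 0.25, tolerance = 1e-12)
  expect_equal(ac_point_prob(0, 1, 1e6, 2e6), 2 / 9, tolerance = 1e-12)
  expect_error(ac_point_prob(-1, 0, 1e6, 1e6), "non-negative")
  expect_error(ac_point_prob(0.5, 0, 1e6, 1e6), "non-negative integers")
  expect_error(ac_point_prob(1, 1, 0, 1e6), "positive")
})

test_that("log-gamma path agrees with the direct-evaluation oracle on a grid", {
  g <- expand.grid(x = 0:30, y = 0:30, ratio = c(0.5, 1, 2, 5))
  p <- ac_point_prob(g$x, g$y, 1e6, 1e6 * g$ratio)
  o <- mapply(function(x, y, r) ac_point_prob_oracle(x, y, 1e6, 1e6 * r),
              g$x, g$y, g$ratio)
  expect_lt(max(abs(p - o) / o), 1e-10)
  expect_true(all(p > 0 & p <= 1))
  expect_error(ac_point_prob_oracle(150, 100, 1e6, 1e6), "x \\+ y <= 200")
})

test_that("equal-depth closed form C(x+y,x)/2^(x+y+1) holds to x+y = 60", {
  for (s in c(0, 1, 5, 20, 60)) {
    x <- 0:s
    p <- ac_point_prob(x, s - x, 3e6, 3e6)
    expect_equal(p, choose(s, x) / 2^(s + 1), tolerance = 1e-10)
  }
})

test_that("conditional mass identities: sum over y is 1, over x is N1/N2", {
  for (r in c(0.5, 1, 2)) {
    for (x in c(0, 1, 5, 50)) {
      # truncate when the remaining tail mass is negligible
      y <- 0:(2000 + 50 * x)
      expect_equal(sum(ac_point_prob(x, y, 1e6, 1e6 * r)), 1,
                   tolerance = 1e-9)
    }
    y <- 5
    xs <- 0:(4000)
    expect_equal(sum(ac_point_prob(xs, y, 1e6, 1e6 * r)), 1 / r,
                 tolerance = 1e-9)
  }
})

test_that("CDF tail route agrees with direct compensated summation", {
  set.seed(31)
  cases <- expand.grid(x = c(0, 1, 7, 40, 150), y = c(0, 3, 25, 180),
                       r = c(0.5, 1, 1.0004, 2))
  for (i in seq_len(nrow(cases))) {
    x <- cases$x[i]; y <- cases$y[i]
    N1 <- 1e6; N2 <- 1e6 * cases$r[i]
    tails <- srnapool:::.ac_tails_sum(x, y, N1, N2)
    expect_equal(unname(ac_pvalue(x, y, N1, N2)),
                 min(1, 2 * min(tails)), tolerance = 1e-9)
  }
  # extreme counts: the upper tail must not floor at 2 * |1 - N1/N2|
  p_extreme <- ac_pvalue(1769, 448, 187202, 187277)
  expect_lt(p_extreme, 1e-100)
})

test_that("two-sided p-value: symmetry, point containment, mode contract", {
  expect_equal(ac_pvalue(7, 7, 1e6, 1e6), 1)
  expect_equal(ac_pvalue(0, 0, 1e6, 1e6, mode = "point"), 0.5,
               tolerance = 1e-12)
  set.seed(8)
  x <- sample(0:50, 20)
  y <- sample(0:50, 20)
  two <- ac_pvalue(x, y, 1e6, 2e6)
  pt <- ac_pvalue(x, y, 1e6, 2e6, mode = "point")
  expect_true(all(two >= pt - 1e-12))
  expect_true(all(two <= 1))
})

test_that("fold change: ratios, zero handling, sentinels, pseudocount", {
  expect_equal(log2_fold_change(2, 8), 2)
  expect_equal(log2_fold_change(5, 5), 0)
  expect_identical(log2_fold_change(0, 5), Inf)  # exclusive to library 2
  expect_identical(log2_fold_change(5, 0), -Inf) # exclusive to library 1
  expect_true(is.nan(log2_fold_change(0, 0)))
  expect_equal(log2_fold_change(0, 3, pseudocount = 1), 2)
  expect_error(log2_fold_change(-1, 2), ">= 0")
})

test_that("BH step-up matches hand computations and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("BH output is invariant to input order", {
  set.seed(19)
  p <- runif(200)
  adj <- bh_adjust(p)
  perm <- sample(200)
  expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-12)
})

test_that("call_dems: floors, exclusives and significance on a 3-row toy", {
  # mA exclusive to library 2; mB similar counts; mC TPM 0.5 in both (floor)
  p1 <- tpm_normalize(data.frame(mirna = c("mA", "mB", "mC"),
                                 count = c(0, 100, 0.5)), 1e6)
  p2 <- tpm_normalize(data.frame(mirna = c("mA", "mB", "mC"),
                                 count = c(200, 110, 0.5)), 1e6)
  paired <- paired_expression(p1, p2)
  dem <- call_dems(paired, alpha = 0.05, fc_threshold = 1, tpm_floor = 1)
  expect_equal(dem$status, c("up", "not_significant", "filtered_floor"))
  expect_equal(dem$note[1], "exclusive_lib2")
  expect_identical(dem$log2fc[1], Inf)
  expect_true(is.na(dem$p_raw[3]))
  # p-values of the tested rows come from the exact conditional test
  expect_equal(dem$p_raw[1], ac_pvalue(0, 200, 1e6, 1e6), tolerance = 1e-12)
  expect_equal(dem$p_raw[2], ac_pvalue(100, 110, 1e6, 1e6), tolerance = 1e-12)
})

test_that("identical counts yield no calls; low confidence filters a row", {
  df <- data.frame(mirna = paste0("m", 1:4), count = c(50, 80, 120, 200))
  p1 <- tpm_normalize(df, 1e6)
  p2 <- tpm_normalize(df, 1e6)
  dem <- call_dems(paired_expression(p1, p2))
  expect_true(all(dem$status == "not_significant"))
  expect_equal(dem$p_raw, rep(1, 4), tolerance = 1e-9)

  dem2 <- call_dems(paired_expression(p1, p2, confidence = c(1, 0.5, 1, 1)))
  expect_equal(dem2$status[2], "filtered_confidence")
  expect_true(is.na(dem2$p_adj[2]))
})

test_that("floor removes only miRNAs below the floor in both libraries", {
  p1 <- tpm_normalize(data.frame(mirna = c("both_low", "one_side"),
                                 count = c(1, 1)), 2e6)     # TPM 0.5, 0.5
  p2 <- tpm_normalize(data.frame(mirna = c("both_low", "one_side"),
                                 count = c(1, 500)), 2e6)   # TPM 0.5, 250
  dem <- call_dems(paired_expression(p1, p2))
  expect_equal(dem$status[1], "filtered_floor")
  expect_false(dem$status[2] == "filtered_floor")
})

test_that("exact test is calibrated near alpha on simulated null counts", {
  set.seed(123)
  x <- rpois(4000, 100)
  y <- rpois(4000, 100)
  p <- ac_pvalue(x, y, 1e6, 1e6)
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("paired_expression validates alignment and confidence", {
  p1 <- tpm_normalize(data.frame(mirna = c("a", "b"), count = c(1, 2)), 100)
  p2 <- tpm_normalize(data.frame(mirna = c("b", "a"), count = c(1, 2)), 100)
  expect_error(paired_expression(p1, p2), "same miRNAs")
  p3 <- tpm_normalize(data.frame(mirna = c("a", "b"), count = c(1, 2)), 100)
  expect_error(paired_expression(p1, p3, confidence = c(0.5, 1.2)),
               "\\[0, 1\\]")
})
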