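test_that("cosine references order and tie time points as expected", {
  t4 <- c(0, 6, 12, 18)
  r <- jtk_reference(t4, 24, 0)
  expect_equal(which.max(r), 1L)  # peak at t = 0
  expect_equal(which.min(r), 3L)  # trough at t = 12
  # shifting the lag by a full period leaves ranks unchanged
  expect_equal(rank(jtk_reference(t4, 24, 5)), rank(jtk_reference(t4, 24, 29)))
  # replicates at one stamp tie
  r2 <- jtk_reference(c(3, 3, 9), 24, 0)
  expect_equal(r2[1], r2[2])
})

test_that("Kendall S counts concordant minus discordant pairs", {
  ref <- 1:5
  expect_equal(kendall_s(c(10, 20, 30, 40, 50), ref), 10)
  expect_equal(kendall_s(c(50, 40, 30, 20, 10), ref), -10)

  # missing entry: equals brute-force pair count over remaining points
  v <- c(3, NA, 1, 5, 4)
  s_brute <- 0
  idx <- which(!is.na(v))
  for (j in idx) for (k in idx) if (j < k) {
    s_brute <- s_brute + sign(v[k] - v[j]) * sign(ref[k] - ref[j])
  }
  expect_equal(kendall_s(v, ref), s_brute)

  # antisymmetry under value reversal (no ties)
  set.seed(10)
  for (i in 1:20) {
    v <- sample(100, 8)
    r <- rnorm(8)
    expect_equal(kendall_s(-v, r), -kendall_s(v, r))
  }
})

test_that("the exact null matches small-case enumeration and is symmetric", {
  # n = 3, untied: P(S = 3) = 1/6
  null3 <- jtk_exact_null(c(1, 1, 1))
  expect_equal(null3$pmf[null3$s == 3], 1 / 6)

  set.seed(11)
  for (i in 1:10) {
    sizes <- sample(1:3, sample(2:4, 1), replace = TRUE)
    null <- jtk_exact_null(sizes)
    expect_equal(sum(null$pmf), 1, tolerance = 1e-12)
    expect_equal(null$pmf, rev(null$pmf), tolerance = 1e-12)  # P(S=s)=P(S=-s)
  }

  # enumeration oracle on a tied pattern
  ex <- jtk_exact_null(c(2, 1, 2))
  br <- enumerate_s_pmf(c(2, 1, 2))
  expect_equal(ex$pmf[match(br$s, ex$s)], br$pmf, tolerance = 1e-12)
})

test_that("a noiseless cosine is recovered with tau 1 and the exact tail p", {
  # asymmetric hours avoid reference ties, so all 28 pairs are comparable
  t8 <- c(0, 1, 3, 6, 10, 15, 16, 22)
  v <- cos(2 * pi * t8 / 24)
  res <- jtk_test(v, t8, adjust = "none")
  expect_equal(res$best_period, 24)
  expect_equal(res$best_lag, 0)
  expect_equal(res$tau, 1)
  # p equals the enumerated two-sided point mass at |S| = 28
  br <- enumerate_s_pmf(rep(1, 8))
  expect_equal(res$p, sum(br$pmf[abs(br$s) >= 28]))

  bonf <- jtk_test(v, t8, adjust = "bonferroni")
  expect_equal(bonf$p, min(1, res$p * 12))  # 12 distinct references up to sign
})

test_that("degenerate series return p = 1", {
  expect_equal(jtk_test(c(2, 2, 2, 2), c(0, 6, 12, 18))$p, 1)
  expect_equal(jtk_test(c(1, NA, NA, 2), c(0, 6, 12, 18))$p, 1)
  expect_equal(jtk_test(c(1, 5, 2), c(3, 3, 3))$p, 1)
})

test_that("the test is invariant to strictly monotone transforms of values", {
  set.seed(12)
  t <- sort(runif(12, 0, 24))
  v <- cos(2 * pi * (t - 4) / 24) + rnorm(12, 0, 0.5)
  a <- jtk_test(v, t)
  b <- jtk_test(exp(2 * v + 1), t)
  expect_identical(a, b)
})

test_that("replicates at a shared stamp add no pairs between themselves", {
  set.seed(13)
  t <- rep(c(2, 8, 14, 20), each = 2)
  v <- rnorm(8)
  res <- jtk_test(v, t, adjust = "none")
  # comparable pairs: 28 total minus 4 within-stamp pairs = 24
  expect_equal(abs(res$s) <= 24, TRUE)
  null <- jtk_exact_null(c(2, 2, 2, 2))
  expect_equal(max(abs(null$s)), 24)
})

test_that("the screen matches per-series tests and handles missing patterns", {
  set.seed(14)
  n <- 10
  t <- sort(runif(n, 0, 24))
  V <- matrix(rnorm(8 * n), 8, n)
  V[2, c(1, 5)] <- NA
  V[3, 1:8] <- NA  # too few points -> p = 1
  df <- wide(V)
  scr <- run_jtk(df, setNames(t, colnames(df)[-1]))
  res <- tidy(scr)
  for (i in c(1, 2, 4)) {
    single <- jtk_test(V[i, ], t)
    expect_equal(res$p[i], single$p)
    expect_equal(res$s[i], single$s)
    expect_equal(res$best_lag[i], single$best_lag)
  }
  expect_equal(res$p[3], 1)
})

test_that("permutation FDR saturates on null data and vanishes on pure signal", {
  set.seed(15)
  n <- 16
  t <- sort(runif(n, 0, 24))
  # null: white noise, liberal threshold so passers exist
  Vn <- matrix(rnorm(300 * n), 300, n)
  dfn <- wide(Vn)
  scr <- run_jtk(dfn, setNames(t, colnames(dfn)[-1]), adjust = "none",
                 p_threshold = 0.1)
  scr <- jtk_permutation_fdr(scr, dfn, n_perm = 20, seed = 3)
  expect_gt(scr$fdr$fdr, 0.5)  # null data: estimate near 1

  # strong noiseless signal: no null passers expected
  ph <- runif(50, 0, 24)
  Vs <- t(sapply(ph, function(p0) cos(2 * pi * (t - p0) / 24)))
  dfs <- wide(Vs)
  scr2 <- run_jtk(dfs, setNames(t, colnames(dfs)[-1]))
  expect_true(all(tidy(scr2)$passes))
  scr2 <- jtk_permutation_fdr(scr2, dfs, n_perm = 20, seed = 4)
  expect_lt(scr2$fdr$fdr, 0.05)

  # zero observed passers reported as NA with the count, not infinity
  scr3 <- run_jtk(dfn[1:5, ], setNames(t, colnames(dfn)[-1]), p_threshold = 1e-6)
  scr3 <- jtk_permutation_fdr(scr3, dfn[1:5, ], n_perm = 3, seed = 5)
  expect_true(is.na(scr3$fdr$fdr))
  expect_equal(scr3$fdr$n_observed, 0L)
})

test_that("screen results write a TSV with a YAML sidecar", {
  set.seed(16)
  t <- sort(runif(8, 0, 24))
  df <- wide(matrix(rnorm(3 * 8), 3, 8))
  scr <- run_jtk(df, setNames(t, colnames(df)[-1]))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_jtk_results(scr, f)
  expect_equal(nrow(readr::read_tsv(f, show_col_types = FALSE)), 3)
  side <- yaml::read_yaml(paste0(f, ".yaml"))
  expect_equal(side$config$p_threshold, 0.01)
})
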