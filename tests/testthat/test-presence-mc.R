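test_that("subject averaging follows the imputation rules", {
  # no missing replicate: plain mean, rng-independent
  set.seed(1)
  expect_equal(subject_average(c(5, 7), c(0, 0), c(1, 1)), 6)

  # one missing replicate with a zero-variance fit: deterministic draw
  expect_equal(subject_average(c(5, NA), run_mean = c(9, 6), run_sd = c(1, 0)), 5.5)

  # all replicates missing: never imputed, for any rng state
  for (s in 1:20) {
    set.seed(s)
    expect_true(is.na(subject_average(c(NA_real_, NA_real_), c(6, 6), c(1, 1))))
  }
})

test_that("presence classification matches the two-group rule", {
  expect_equal(classify_presence(2, 2), "Missing")
  expect_equal(classify_presence(9, 0), "OnlyA")
  expect_equal(classify_presence(0, 9), "OnlyB")
  expect_equal(classify_presence(5, 4), "Modulated")
  # boundary: exactly min_subjects observing counts as eligible
  expect_equal(classify_presence(3, 3), "Modulated")
  expect_equal(classify_presence(3, 2), "OnlyA")
})

test_that("confidence score reproduces the declared formula and bounds", {
  expect_equal(confidence_score(9, 9, 0), 1)          # maximal evidence
  expect_equal(confidence_score(3, 9, 0), 0)          # defined degenerate corner
  expect_equal(confidence_score(6, 9, 2), -1 / 3)     # f = 0.5, g = 1
  expect_equal(confidence_score(6, 9, 2, reading = "squared"), (0.5 - 4) / (0.5 + 4))
  expect_error(confidence_score(3, 3, 0), "n_tot_i")
})

test_that("pooled t-test matches the closed form and base R", {
  x <- c(1.1, 2.3, 3.1, 4.0); y <- c(2.9, 4.1, 5.2)
  got <- pooled_t_test(x, y)
  # textbook pooled-variance formula, written out independently
  sp2 <- ((3) * var(x) + (2) * var(y)) / 5
  t_ref <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  p_ref <- 2 * pt(-abs(t_ref), 5)
  expect_equal(got$t, t_ref, tolerance = 1e-10)
  expect_equal(got$p, p_ref, tolerance = 1e-10)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)

  expect_equal(pooled_t_test(c(1, 2, 3), c(1, 2, 3)), list(t = 0, p = 1))
  expect_equal(pooled_t_test(c(0, 0, 0, 0), c(1, 1, 1, 1))$p, 0)
})

test_that("without imputation the p-interval degenerates; holes widen it", {
  set.seed(4)
  meta <- tiny_meta()
  m <- matrix(rnorm(12 * 40, 27, 2), 40, 12,
              dimnames = list(sprintf("P%03d", 1:40), meta$run_id))
  # complete matrix: nothing to impute, every simulation is identical
  fit <- run_presence_mc(wide(m), meta, n_sims = 25, seed = 9)
  calls <- tidy(fit)
  expect_true(all(calls$p_low == calls$p_high))

  # replicate-level holes make imputation stochastic; intervals open up
  # (Z-scoring couples proteins within a subject, so holes anywhere
  # perturb every test)
  m2 <- m; m2[1:10, 1] <- NA
  fit2 <- run_presence_mc(wide(m2), meta, n_sims = 25, seed = 9)
  calls2 <- tidy(fit2)
  expect_true(any(calls2$p_low < calls2$p_high))
})

test_that("identical seeds give identical results; status is seed-invariant", {
  sim <- simulate_pineal(n_proteins = 120, seed = 5)
  lfq <- normalize_log2(sim$lfq)
  ctrl <- dplyr::filter(sim$meta, group == "control")
  sub <- lfq[c("protein_id", ctrl$run_id)]

  a <- run_presence_mc(sub, ctrl, n_sims = 20, seed = 123)
  b <- run_presence_mc(sub, ctrl, n_sims = 20, seed = 123)
  expect_identical(a$calls, b$calls)

  statuses <- lapply(1:10, function(s)
    run_presence_mc(sub, ctrl, n_sims = 3, seed = s)$calls$status)
  for (s in statuses[-1]) expect_identical(s, statuses[[1]])
})

test_that("the p-interval brackets the median and collapses without imputation", {
  sim <- simulate_pineal(n_proteins = 150, mcar_rate = 0.1, seed = 6)
  lfq <- normalize_log2(sim$lfq)
  ctrl <- dplyr::filter(sim$meta, group == "control")
  fit <- run_presence_mc(lfq[c("protein_id", ctrl$run_id)], ctrl,
                         n_sims = 60, seed = 11)
  calls <- dplyr::filter(tidy(fit), status == "Modulated")
  expect_true(all(calls$p_low <= calls$p_high))
  expect_true(all(calls$p_low >= 0 & calls$p_high <= 1))
  expect_true(all(calls$significant == (calls$p_high < 0.05)))
})

test_that("confidence scores populate exclusive calls only", {
  sim <- simulate_pineal(n_proteins = 200, seed = 7)
  lfq <- normalize_log2(sim$lfq)
  ctrl <- dplyr::filter(sim$meta, group == "control")
  calls <- tidy(run_presence_mc(lfq[c("protein_id", ctrl$run_id)], ctrl,
                                n_sims = 10, seed = 2))
  excl <- calls$status %in% c("OnlyA", "OnlyB")
  expect_true(all(!is.na(calls$confidence[excl])))
  expect_true(all(is.na(calls$confidence[!excl])))
  expect_true(all(is.na(calls$p_low[excl])))
  expect_true(all(abs(calls$confidence[excl]) <= 1))
})

test_that("the calls table writes with a YAML header and reads back", {
  sim <- simulate_pineal(n_proteins = 30, seed = 8)
  lfq <- normalize_log2(sim$lfq)
  ctrl <- dplyr::filter(sim$meta, group == "control")
  fit <- run_presence_mc(lfq[c("protein_id", ctrl$run_id)], ctrl,
                         n_sims = 5, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_presence_calls(fit, f)
  lines <- readLines(f)
  hdr <- sub("^# ", "", lines[startsWith(lines, "# ")])
  cfg <- yaml::yaml.load(paste(hdr, collapse = "\n"))
  expect_equal(cfg$n_sims, 5)
  body <- readr::read_tsv(f, comment = "#", show_col_types = FALSE)
  expect_equal(nrow(body), 30)
})
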