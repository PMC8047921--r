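# Monte-Carlo presence/absence framework for two-group LFQ comparisons.
#
# Missingness in LFQ data is informative: a subject "observes" a protein when
# at least one of its replicate runs quantified it.  Observedness is fixed by
# the data; imputation only fills replicate-level holes inside observing
# subjects, so the Missing / Only-A / Only-B / Modulated classification is
# identical across simulations and only the t-test p-value fluctuates.

#' Classify a protein's presence pattern between two groups
#'
#' A subject counts as observing a protein when at least one of its replicate
#' runs has a non-missing LFQ.  With fewer than `min_subjects` observing
#' subjects in both groups the protein is `Missing`; with fewer in exactly
#' one group it is exclusive to the other (`OnlyA`/`OnlyB`); otherwise it is
#' `Modulated` and eligible for a two-group test.  The boundary
#' `n_obs == min_subjects` counts as eligible.
#'
#' @param n_obs_a,n_obs_b Observing-subject counts per group (vectorized).
#' @param min_subjects Minimum observing subjects per group (default 3).
#' @return Character vector in `{"Missing","OnlyA","OnlyB","Modulated"}`.
#' @export
classify_presence <- function(n_obs_a, n_obs_b, min_subjects = 3L) {
  stopifnot(min_subjects >= 1L, length(n_obs_a) == length(n_obs_b))
  if (any(n_obs_a < 0 | n_obs_b < 0)) abort("negative observation counts")
  a <- n_obs_a >= min_subjects
  b <- n_obs_b >= min_subjects
  dplyr::case_when(
    a & b ~ "Modulated",
    a & !b ~ "OnlyA",
    !a & b ~ "OnlyB",
    .default = "Missing"
  )
}

#' Confidence score for group-exclusive proteins
#'
#' Bounded rating in `[-1, 1]` for proteins present only in one group:
#' `(f - g) / (f + g)` with `f = (n_obs_i - 3) / (n_tot_i - 3)` the excess
#' observation fraction on the present side `i`, and `g = n_obs_j / 2` the
#' penalty for stray observations on the absent side `j` (so a single stray
#' subject already halves the score's numerator weight).  `f + g = 0` (the
#' minimal-evidence corner) is defined as 0.  An alternative reading
#' squaring the stray count, `g = n_obs_j^2`, is available via `reading`.
#'
#' @param n_obs_i,n_tot_i Observing and total subjects on the present side;
#'   requires `n_tot_i > 3`.
#' @param n_obs_j Observing subjects on the absent side (< 3 by construction).
#' @param reading `"half"` (default, `g = n_obs_j / 2`) or `"squared"`
#'   (`g = n_obs_j^2`).
#' @return Numeric score(s) in `[-1, 1]`.
#' @export
confidence_score <- function(n_obs_i, n_tot_i, n_obs_j, reading = c("half", "squared")) {
  reading <- match.arg(reading)
  if (any(n_tot_i <= 3)) abort("confidence score undefined for n_tot_i <= 3")
  if (any(n_obs_i < 3)) abort("present side must have at least 3 observing subjects")
  if (any(n_obs_i > n_tot_i)) abort("n_obs_i cannot exceed n_tot_i")
  f <- (n_obs_i - 3) / (n_tot_i - 3)
  g <- if (reading == "half") n_obs_j / 2 else n_obs_j^2
  score <- ifelse(f + g == 0, 0, (f - g) / (f + g))
  score
}

#' Two-sided pooled-variance Student t-test
#'
#' The equal-variance two-sample t-test, with explicit degenerate-case
#' conventions for constant data: zero pooled variance with equal means
#' gives `p = 1` (no evidence of a difference), zero pooled variance with
#' unequal means gives `p = 0` (perfect separation).
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @param var_equal Use the pooled-variance form (default `TRUE`); `FALSE`
#'   gives Welch's unequal-variance test.
#' @return A named list with `t` and `p`.
#' @export
pooled_t_test <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("each group needs at least 2 values")
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    df <- nx + ny - 2
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  if (!is.finite(se) || se == 0) {
    if (mx == my) return(list(t = 0, p = 1))
    return(list(t = sign(mx - my) * Inf, p = 0))
  }
  t <- (mx - my) / se
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Row-wise pooled t over matrices (columns = subjects per group), NA-aware.
# Rows must have >= 2 non-missing values per side.
row_pooled_t <- function(A, B) {
  nA <- rowSums(!is.na(A)); nB <- rowSums(!is.na(B))
  mA <- rowMeans(A, na.rm = TRUE); mB <- rowMeans(B, na.rm = TRUE)
  ssA <- rowSums(A^2, na.rm = TRUE) - nA * mA^2
  ssB <- rowSums(B^2, na.rm = TRUE) - nB * mB^2
  ssA <- pmax(ssA, 0); ssB <- pmax(ssB, 0)
  df <- nA + nB - 2
  sp2 <- (ssA + ssB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  p <- 2 * pt(-abs(t), df)
  zerovar <- !is.finite(se) | se == 0
  if (any(zerovar)) {
    eq <- zerovar & (mA == mB)
    t[eq] <- 0; p[eq] <- 1
    ne <- zerovar & (mA != mB)
    t[ne] <- sign(mA[ne] - mB[ne]) * Inf; p[ne] <- 0
  }
  list(t = t, p = p)
}

# Average each subject's replicate runs after filling replicate-level holes.
# X: proteins x runs log-LFQ matrix with NA missing; run_of: subject index per
# column; run_stats: per-run (mean, sd) fitted on observed values.  Cells are
# imputed only where the subject observes the protein in some other run.
impute_and_average <- function(X, subject_of, run_mean, run_sd, subjects) {
  k <- length(subjects)
  out <- matrix(NA_real_, nrow(X), k, dimnames = list(rownames(X), subjects))
  obs <- !is.na(X)
  for (i in seq_len(k)) {
    cols <- which(subject_of == subjects[i])
    sub <- X[, cols, drop = FALSE]
    subobs <- obs[, cols, drop = FALSE]
    any_obs <- rowSums(subobs) > 0
    holes <- which(!subobs & any_obs, arr.ind = TRUE)
    if (nrow(holes)) {
      runs <- cols[holes[, 2]]
      sub[holes] <- rnorm(nrow(holes), run_mean[runs], run_sd[runs])
    }
    out[, i] <- rowMeans(sub)
    out[!any_obs, i] <- NA_real_
  }
  out
}

#' Replicate-level imputation and subject averaging (single subject)
#'
#' The per-subject step of the Monte-Carlo procedure, exposed for testing
#' and inspection: if every replicate is missing the subject value stays
#' missing (no imputation); otherwise each missing replicate is replaced by
#' an independent draw from a normal distribution fitted on that run's
#' observed log-LFQ values, and the replicate mean is returned.
#'
#' @param values Numeric vector of one protein's replicate values (NA = missing).
#' @param run_mean,run_sd Per-replicate-run normal parameters fitted on the
#'   run's observed values, aligned with `values`.
#' @return The subject-level value, or `NA` when all replicates are missing.
#' @export
subject_average <- function(values, run_mean, run_sd) {
  stopifnot(length(values) == length(run_mean), length(values) == length(run_sd))
  miss <- is.na(values)
  if (all(miss)) return(NA_real_)
  if (any(miss)) {
    values[miss] <- rnorm(sum(miss), run_mean[miss], run_sd[miss])
  }
  mean(values)
}

#' Monte-Carlo two-group screen with presence/absence classification
#'
#' Runs the full missing-value-aware contrast between two groups of subjects
#' (day vs night, or control vs autism).  Per simulation: replicate-level
#' holes are imputed from per-run normal fits, replicates are averaged per
#' subject, each subject column is Z-scored across its non-missing proteins,
#' and `Modulated` proteins get a pooled two-sample t-test between the
#' groups' subject values.  Across simulations the per-protein p-values are
#' summarized by a central percentile interval; a protein is significant
#' when the interval's upper bound is below `alpha`.  Group-exclusive
#' proteins get a [confidence_score()] instead of a p-interval.
#'
#' @param df Wide log-scale LFQ tibble (runs as columns; use
#'   [normalize_log2()] first).
#' @param meta Sample metadata (see [read_sample_metadata()]).
#' @param contrast Length-2 character: the two labels compared, in (A, B)
#'   order (default `c("day","night")`).
#' @param contrast_by Metadata column holding the labels: `"daynight"`
#'   (default) or `"group"`.
#' @param n_sims Number of Monte-Carlo simulations (default 2000).
#' @param min_subjects Presence threshold per group (default 3).
#' @param alpha Significance level on the interval's upper bound (default 0.05).
#' @param ci_level Coverage of the percentile interval (default 0.95).
#' @param seed Integer seed; per-simulation substreams are derived from it so
#'   results are reproducible and order-independent.
#' @param test_on `"zscore"` (default) tests subject Z-scores; `"log"` tests
#'   the subject-averaged log-LFQ values directly.
#' @param var_equal Pooled-variance Student test (default `TRUE`).
#' @param confidence_reading Reading of the exclusive-protein confidence
#'   formula; see [confidence_score()].
#' @return A `presence_mc` object; `tidy()` returns the per-protein call
#'   table, `glance()` the per-status counts.
#' @examples
#' sim <- simulate_pineal(n_proteins = 150, seed = 7)
#' lfq <- normalize_log2(sim$lfq)
#' ctrl <- dplyr::filter(sim$meta, group == "control")
#' fit <- run_presence_mc(lfq[c("protein_id", ctrl$run_id)], ctrl,
#'                        n_sims = 50, seed = 7)
#' glance(fit)
#' @export
run_presence_mc <- function(df, meta, contrast = c("day", "night"),
                            contrast_by = c("daynight", "group"),
                            n_sims = 2000L, min_subjects = 3L, alpha = 0.05,
                            ci_level = 0.95, seed = 1L,
                            test_on = c("zscore", "log"), var_equal = TRUE,
                            confidence_reading = c("half", "squared")) {
  contrast_by <- match.arg(contrast_by)
  test_on <- match.arg(test_on)
  confidence_reading <- match.arg(confidence_reading)
  stopifnot(length(contrast) == 2, n_sims >= 1, alpha > 0, alpha < 1,
            ci_level > 0, ci_level < 1)
  meta <- validate_sample_metadata(meta)
  X <- lfq_to_matrix(df)
  if (!all(colnames(X) %in% meta$run_id)) {
    abort("every LFQ column must be a run_id present in `meta`")
  }
  meta <- meta[match(colnames(X), meta$run_id), , drop = FALSE]
  labels <- meta[[contrast_by]]
  keep <- labels %in% contrast
  if (!any(keep)) abort("no runs carry the requested contrast labels")
  X <- X[, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  labels <- labels[keep]

  subjects <- unique(meta$subject_id)
  subject_of <- meta$subject_id
  subj_label <- meta[[contrast_by]][match(subjects, meta$subject_id)]
  in_a <- subj_label == contrast[1]
  in_b <- subj_label == contrast[2]
  if (!any(in_a) || !any(in_b)) {
    abort(paste0("contrast group '", contrast[which(c(!any(in_a), !any(in_b)))[1]],
                 "' has no subjects"))
  }

  # Observedness is imputation-independent: fixed classification.
  obs <- !is.na(X)
  subj_obs <- vapply(subjects, function(s) {
    rowSums(obs[, subject_of == s, drop = FALSE]) > 0
  }, logical(nrow(X)))
  if (nrow(X) == 1L) subj_obs <- matrix(subj_obs, nrow = 1L)
  n_obs_a <- rowSums(subj_obs[, in_a, drop = FALSE])
  n_obs_b <- rowSums(subj_obs[, in_b, drop = FALSE])
  n_tot_a <- sum(in_a); n_tot_b <- sum(in_b)
  status <- classify_presence(n_obs_a, n_obs_b, min_subjects)

  run_stats <- col_stats(X, min_n = 2L, what = "replicate run")
  mod <- which(status == "Modulated")
  if (n_sims < 2 && length(mod)) {
    abort("n_sims must be >= 2 to form a p-value confidence interval")
  }

  seeds <- substream_seeds(seed, n_sims)
  p_mat <- matrix(NA_real_, length(mod), n_sims)
  t_mat <- matrix(NA_real_, length(mod), n_sims)
  for (s in seq_len(n_sims)) {
    set.seed(seeds[s])
    subj_vals <- impute_and_average(X, subject_of, run_stats$mean, run_stats$sd, subjects)
    if (test_on == "zscore") {
      st <- col_stats(subj_vals, min_n = 2L, what = "subject")
      if (any(st$sd == 0)) abort("zero-variance subject column; Z-score undefined")
      subj_vals <- sweep(sweep(subj_vals, 2, st$mean), 2, st$sd, "/")
    }
    if (length(mod)) {
      res <- row_pooled_t(subj_vals[mod, in_a, drop = FALSE],
                          subj_vals[mod, in_b, drop = FALSE])
      p_mat[, s] <- res$p
      t_mat[, s] <- res$t
    }
  }

  lo <- (1 - ci_level) / 2
  calls <- tibble(
    protein_id = rownames(X),
    status = status,
    n_obs_a = as.integer(n_obs_a), n_tot_a = as.integer(n_tot_a),
    n_obs_b = as.integer(n_obs_b), n_tot_b = as.integer(n_tot_b),
    t_mean = NA_real_, p_low = NA_real_, p_high = NA_real_,
    significant = FALSE, confidence = NA_real_
  )
  if (length(mod)) {
    calls$t_mean[mod] <- rowMeans(t_mat)
    calls$p_low[mod] <- apply(p_mat, 1, quantile, probs = lo, names = FALSE)
    calls$p_high[mod] <- apply(p_mat, 1, quantile, probs = 1 - lo, names = FALSE)
    calls$significant[mod] <- calls$p_high[mod] < alpha
  }
  only_a <- status == "OnlyA"; only_b <- status == "OnlyB"
  if (any(only_a)) {
    if (n_tot_a <= 3) {
      warn("confidence score undefined (present side has <= 3 subjects); NA returned")
    } else {
      calls$confidence[only_a] <- confidence_score(
        n_obs_a[only_a], n_tot_a, n_obs_b[only_a], reading = confidence_reading)
    }
  }
  if (any(only_b)) {
    if (n_tot_b <= 3) {
      warn("confidence score undefined (present side has <= 3 subjects); NA returned")
    } else {
      calls$confidence[only_b] <- confidence_score(
        n_obs_b[only_b], n_tot_b, n_obs_a[only_b], reading = confidence_reading)
    }
  }

  structure(list(
    calls = calls,
    config = list(
      contrast = contrast, contrast_by = contrast_by, n_sims = n_sims,
      min_subjects = min_subjects, alpha = alpha, ci_level = ci_level,
      seed = seed, test_on = test_on, var_equal = var_equal,
      confidence_reading = confidence_reading
    )
  ), class = "presence_mc")
}

#' @export
print.presence_mc <- function(x, ...) {
  cfg <- x$config
  cat("<presence_mc> Monte-Carlo two-group screen\n")
  cat("  contrast: ", cfg$contrast[1], " vs ", cfg$contrast[2],
      " (by ", cfg$contrast_by, "), ", cfg$n_sims, " simulations\n", sep = "")
  tab <- table(factor(x$calls$status,
                      levels = c("Missing", "OnlyA", "OnlyB", "Modulated")))
  cat("  status:  ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  cat("  significant (p_high < ", cfg$alpha, "): ",
      sum(x$calls$significant), "\n", sep = "")
  invisible(x)
}

#' Write a presence/absence call table as TSV
#'
#' The run configuration is echoed as a commented YAML header so the file is
#' self-describing.
#'
#' @param x A `presence_mc` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_calls <- function(x, path) {
  stopifnot(inherits(x, "presence_mc"))
  hdr <- strsplit(yaml::as.yaml(x$config), "\n")[[1]]
  writeLines(paste0("# ", hdr), path)
  suppressWarnings(readr::write_tsv(x$calls, path, append = TRUE, col_names = TRUE,
                                    progress = FALSE))
  invisible(path)
}

#' Collapse a run-level table to subject level
#'
#' Averages each subject's replicate runs.  With `impute = "none"` the mean
#' is over observed replicates only (deterministic); with `impute = "draw"`
#' missing replicates of observing subjects are first filled by one draw
#' from the per-run normal fits, exactly as in one [run_presence_mc()]
#' simulation.  Subjects observing no replicate stay missing.
#'
#' @param df Wide log-scale LFQ tibble with run columns.
#' @param meta Sample metadata.
#' @param impute `"none"` (default) or `"draw"`.
#' @param seed Seed for the `"draw"` mode.
#' @return A wide tibble with one column per subject.
#' @export
subject_table <- function(df, meta, impute = c("none", "draw"), seed = 1L) {
  impute <- match.arg(impute)
  meta <- validate_sample_metadata(meta)
  X <- lfq_to_matrix(df)
  if (!all(colnames(X) %in% meta$run_id)) {
    abort("every LFQ column must be a run_id present in `meta`")
  }
  meta <- meta[match(colnames(X), meta$run_id), , drop = FALSE]
  subjects <- unique(meta$subject_id)
  if (impute == "draw") {
    st <- col_stats(X, min_n = 2L, what = "replicate run")
    set.seed(seed %% .Machine$integer.max)
    out <- impute_and_average(X, meta$subject_id, st$mean, st$sd, subjects)
  } else {
    out <- vapply(subjects, function(s) {
      v <- rowMeans(X[, meta$subject_id == s, drop = FALSE], na.rm = TRUE)
      v[is.nan(v)] <- NA_real_
      v
    }, numeric(nrow(X)))
    if (nrow(X) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(rownames(X), subjects))
  }
  matrix_to_lfq(out)
}

#' Times of death per subject, aligned to a subject-level table
#'
#' @param df A subject-level wide tibble (e.g. from [subject_table()]).
#' @param meta Sample metadata.
#' @return Named numeric vector of hours keyed by subject id, in column order.
#' @export
subject_times <- function(df, meta) {
  meta <- validate_sample_metadata(meta)
  cols <- setdiff(names(df), "protein_id")
  idx <- match(cols, meta$subject_id)
  if (anyNA(idx)) abort("columns are not subject ids known to `meta`")
  setNames(meta$time_of_death[idx], cols)
}
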