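# JTK-cycle rhythmicity test, from scratch.
#
# Observed values are scored against lagged cosine reference waveforms by
# Kendall's S (concordant minus discordant pair count); only the rank
# ordering of the reference matters.  Replicates share a time stamp and so
# tie in every reference; tied pairs contribute 0 and never count against a
# series.  The null distribution of S under a uniform permutation of the
# values against a fixed (possibly tied) reference is exact: S = 2J - P
# where J is a Jonckheere-Terpstra statistic, the sum of independent
# Mann-Whitney counts accumulated as reference tie-groups are interleaved
# one by one, so its pmf is a convolution of exact Mann-Whitney pmfs.

#' Cosine reference waveform for the JTK test
#'
#' @param times Numeric time stamps (hours).
#' @param period Period in hours (> 0).
#' @param lag Phase lag in hours; the reference peaks at `t = lag`.
#' @return `cos(2 * pi * (times - lag) / period)`; only its rank ordering is
#'   used downstream.
#' @export
jtk_reference <- function(times, period = 24, lag = 0) {
  stopifnot(period > 0)
  cos(2 * pi * (times - lag) / period)
}

#' Kendall's S between values and a reference
#'
#' `S = sum over j < k of sign(v_k - v_j) * sign(r_k - r_j)` across pairs
#' non-missing in the values and untied in both; ties contribute 0.
#'
#' @param values Numeric vector, `NA` allowed.
#' @param reference Numeric reference aligned to `values`.
#' @return Integer-valued S; `NA` if fewer than 2 non-missing values.
#' @export
kendall_s <- function(values, reference) {
  stopifnot(length(values) == length(reference))
  ok <- !is.na(values)
  v <- values[ok]; r <- reference[ok]
  if (length(v) < 2) return(NA_real_)
  dv <- sign(outer(v, v, "-"))
  dr <- sign(outer(r, r, "-"))
  sum((dv * dr)[upper.tri(dv)])
}

# Exact pmf of the Mann-Whitney count U between two groups of sizes m and n
# under uniform interleaving, by the standard recurrence in probability
# space: p(u; m, n) = m/(m+n) p(u-n; m-1, n) + n/(m+n) p(u; m, n-1).
mw_u_pmf <- function(m, n) {
  if (m == 0 || n == 0) return(1)
  prev <- vector("list", n + 1)
  for (nn in 0:n) prev[[nn + 1]] <- 1  # m' = 0: U = 0 surely
  for (mm in 1:m) {
    cur <- vector("list", n + 1)
    cur[[1]] <- 1                      # n' = 0
    for (nn in 1:n) {
      a <- prev[[nn + 1]]              # p(.; mm-1, nn), support 0..(mm-1)*nn
      b <- cur[[nn]]                   # p(.; mm, nn-1), support 0..mm*(nn-1)
      len <- mm * nn + 1
      pa <- c(rep(0, nn), a, rep(0, len - nn - length(a)))
      pb <- c(b, rep(0, len - length(b)))
      cur[[nn + 1]] <- (mm * pa + nn * pb) / (mm + nn)
    }
    prev <- cur
  }
  prev[[n + 1]]
}

#' Exact null distribution of Kendall's S against a tied reference
#'
#' Distribution of S under a uniform random permutation of (continuous,
#' untied) values against a fixed reference whose tie structure is given by
#' `group_sizes`: the multiplicities of the distinct reference values.  The
#' pmf is obtained by convolving exact Mann-Whitney distributions as tie
#' groups are interleaved; it is symmetric about 0.
#'
#' @param group_sizes Positive integer multiplicities of the distinct
#'   reference values; `sum(group_sizes)` is the number of observations.
#' @return A list with `s` (support, from `-P` to `P` in steps of 2 where
#'   `P` is the number of between-group pairs) and `pmf`.
#' @export
jtk_exact_null <- function(group_sizes) {
  group_sizes <- as.integer(group_sizes)
  stopifnot(all(group_sizes >= 1), sum(group_sizes) >= 2)
  n_tot <- sum(group_sizes)
  pairs_between <- (n_tot^2 - sum(group_sizes^2)) / 2
  pmf <- 1
  m <- 0L
  for (g in group_sizes) {
    if (m > 0L) {
      u <- mw_u_pmf(m, g)
      pmf <- if (length(pmf) == 1) u * pmf else
        if (length(u) == 1) pmf * u else
          stats::convolve(pmf, rev(u), type = "open")
      pmf[pmf < 0] <- 0
    }
    m <- m + g
  }
  pmf <- pmf / sum(pmf)
  list(s = 2 * (seq_along(pmf) - 1) - pairs_between, pmf = pmf)
}

# Two-sided exact tail P(|S_null| >= |s_obs|) from a null object.
jtk_tail_p <- function(null, s_obs) {
  min(1, sum(null$pmf[abs(null$s) >= abs(s_obs)]))
}

# Cache of exact nulls keyed by the sorted group-size pattern.
null_cache_get <- function(cache, group_sizes) {
  key <- paste(sort(group_sizes), collapse = ",")
  if (is.null(cache[[key]])) cache[[key]] <- jtk_exact_null(group_sizes)
  cache[[key]]
}

# Group sizes of the reference tie pattern, restricted to observed points.
reference_groups <- function(reference, observed) {
  r <- round(reference[observed], 9)
  as.integer(table(r))
}

# The (period, lag) search grid, ordered so ties in |S| resolve to the
# smaller lag, then the smaller period.
jtk_grid <- function(periods, lags) {
  grid <- do.call(rbind, lapply(periods, function(p) {
    l <- if (is.null(lags)) seq(0, p - 1, by = 1) else lags
    data.frame(period = p, lag = l)
  }))
  grid[order(grid$lag, grid$period), , drop = FALSE]
}

#' JTK-cycle test for one time series
#'
#' Scores the series against every (period, lag) cosine reference on the
#' grid, keeps the reference maximizing `|S|` (ties broken by smaller lag,
#' then smaller period), and reports the exact two-sided tail probability of
#' that S under the permutation null for the winning reference's tie
#' pattern.  Replicates enter as tied time stamps; missing values are
#' excluded pairwise.
#'
#' @param values Numeric observations (`NA` = missing).
#' @param times Hour stamps aligned to `values`; replicates share a stamp.
#' @param periods Candidate periods in hours (default 24).
#' @param lags Phase lags in hours (default `seq(0, period - 1)` per period,
#'   a 1 h grid).
#' @param adjust `"bonferroni"` (default): multiply the best-reference exact
#'   p by the number of distinct references up to sign reversal (a cosine
#'   lagged by half a period is the negated reference and yields the same
#'   `|S|`), the correction JTK-cycle applies to its reported adjusted p;
#'   `"none"`: report the raw best-reference tail probability, which is
#'   anti-conservative under the null because the best of many correlated
#'   references is selected.
#' @return A one-row tibble: `best_period`, `best_lag`, `s`, `tau`
#'   (S divided by the number of comparable untied pairs), `p`.
#'   Degenerate series (fewer than 3 usable points, fewer than 2 distinct
#'   times, or constant values) return `p = 1`.
#' @examples
#' t <- seq(0, 23, by = 3)
#' jtk_test(cos(2 * pi * (t - 6) / 24), t)
#' @export
jtk_test <- function(values, times, periods = 24, lags = NULL,
                     adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(length(values) == length(times), all(periods > 0))
  degenerate <- tibble(best_period = NA_real_, best_lag = NA_real_,
                       s = NA_real_, tau = NA_real_, p = 1)
  ok <- !is.na(values)
  if (sum(ok) < 3 || length(unique(times[ok])) < 2) return(degenerate)
  if (length(unique(values[ok])) < 2) return(degenerate)

  grid <- jtk_grid(periods, lags)
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    ref <- round(jtk_reference(times, grid$period[i], grid$lag[i]), 9)
    s <- kendall_s(values, ref)
    if (is.null(best) || abs(s) > abs(best$s) + 1e-9) {
      best <- list(s = s, period = grid$period[i], lag = grid$lag[i], ref = ref)
    }
  }
  groups <- reference_groups(best$ref, ok)
  null <- jtk_exact_null(groups)
  p <- jtk_tail_p(null, best$s)
  if (adjust == "bonferroni") {
    n_eff <- nrow(unique(round(cbind(grid$period, grid$lag %% (grid$period / 2)), 9)))
    p <- min(1, p * n_eff)
  }
  n_obs <- sum(ok)
  comparable <- (n_obs^2 - sum(groups^2)) / 2
  tibble(best_period = best$period, best_lag = best$lag, s = best$s,
         tau = best$s / comparable, p = p)
}

# Vectorized screening core.  V: proteins x observations matrix (NA =
# missing); times aligned to columns.  Returns per-protein best reference,
# S, tau and exact p.  Missingness patterns are grouped so pair machinery
# and null distributions are shared.
jtk_screen_core <- function(V, times, periods, lags, adjust) {
  n <- ncol(V)
  grid <- jtk_grid(periods, lags)
  refs <- vapply(seq_len(nrow(grid)), function(i)
    jtk_reference(times, grid$period[i], grid$lag[i]), numeric(n))
  pair_j <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_k <- unlist(lapply(seq_len(n - 1), function(j) (j + 1):n))
  ref_sign <- sign(round(refs[pair_k, , drop = FALSE] - refs[pair_j, , drop = FALSE], 9))

  res <- tibble(best_period = rep(NA_real_, nrow(V)), best_lag = NA_real_,
                s = NA_real_, tau = NA_real_, p = 1)
  obs <- !is.na(V)
  pattern <- apply(obs, 1, function(x) paste(which(x), collapse = ","))
  cache <- new.env(parent = emptyenv())
  for (pat in unique(pattern)) {
    rows <- which(pattern == pat)
    ok <- obs[rows[1], ]
    if (sum(ok) < 3 || length(unique(times[ok])) < 2) next
    pair_ok <- ok[pair_j] & ok[pair_k]
    Vp <- V[rows, , drop = FALSE]
    dv <- sign(Vp[, pair_k, drop = FALSE] - Vp[, pair_j, drop = FALSE])
    dv[, !pair_ok] <- 0
    dv[is.na(dv)] <- 0
    S <- dv %*% ref_sign
    absS <- abs(S)
    best_idx <- max.col(absS, ties.method = "first")
    s_best <- S[cbind(seq_along(rows), best_idx)]
    const <- rowSums(dv != 0) == 0
    for (ii in seq_along(rows)) {
      if (const[ii]) next
      bi <- best_idx[ii]
      groups <- reference_groups(refs[, bi], ok)
      null <- null_cache_get(cache, groups)
      p <- jtk_tail_p(null, s_best[ii])
      if (adjust == "bonferroni") {
        n_eff <- nrow(unique(round(cbind(grid$period, grid$lag %% (grid$period / 2)), 9)))
        p <- min(1, p * n_eff)
      }
      comparable <- (sum(ok)^2 - sum(groups^2)) / 2
      res$best_period[rows[ii]] <- grid$period[bi]
      res$best_lag[rows[ii]] <- grid$lag[bi]
      res$s[rows[ii]] <- s_best[ii]
      res$tau[rows[ii]] <- s_best[ii] / comparable
      res$p[rows[ii]] <- p
    }
  }
  res
}

#' JTK-cycle screen over a protein table
#'
#' Applies [jtk_test()] to every protein in a wide log-scale table whose
#' columns are subjects (or runs), with observation times taken from the
#' sample metadata (`time_of_death`).  Replicate runs enter as tied time
#' stamps.
#'
#' @param df Wide tibble: `protein_id` plus one column per subject or run.
#' @param meta Sample metadata, or a named numeric vector of times keyed by
#'   the table's column names.
#' @inheritParams jtk_test
#' @param p_threshold Rhythmicity call threshold on the exact p (default 0.01).
#' @return A `jtk_screen` object; `tidy()` gives the per-protein table with
#'   a `passes` flag, `glance()` the pass count.
#' @export
run_jtk <- function(df, meta, periods = 24, lags = NULL,
                    adjust = c("bonferroni", "none"), p_threshold = 0.01) {
  adjust <- match.arg(adjust)
  V <- lfq_to_matrix(df)
  if (is.numeric(meta) && !is.null(names(meta))) {
    if (!all(colnames(V) %in% names(meta))) abort("times missing for some columns")
    times <- unname(meta[colnames(V)])
  } else {
    meta <- validate_sample_metadata(meta)
    mm <- match_meta_columns(colnames(V), meta)
    times <- mm$meta$time_of_death
  }
  res <- jtk_screen_core(V, times, periods, lags, adjust)
  res <- dplyr::bind_cols(tibble(protein_id = rownames(V)), res)
  res$passes <- res$p < p_threshold
  structure(list(
    results = res,
    times = times,
    config = list(periods = periods, lags = lags, adjust = adjust,
                  p_threshold = p_threshold)
  ), class = "jtk_screen")
}

#' @export
print.jtk_screen <- function(x, ...) {
  cat("<jtk_screen> JTK-cycle rhythmicity screen\n")
  cat("  proteins: ", nrow(x$results), ", periods: ",
      paste(x$config$periods, collapse = ", "), " h\n", sep = "")
  cat("  passing p < ", x$config$p_threshold, ": ",
      sum(x$results$passes), "\n", sep = "")
  if (!is.null(x$fdr)) {
    cat("  permutation FDR at threshold: ",
        if (is.na(x$fdr$fdr)) "undefined (no passers)" else signif(x$fdr$fdr, 3),
        "\n", sep = "")
  }
  invisible(x)
}

#' Dataset-level permutation FDR for a JTK screen
#'
#' Estimates the false discovery rate at the screen's p threshold by
#' shuffling, within each protein, the assignment of observed values to
#' time stamps and re-running the test.  The estimate is the mean count of
#' null passers per permutation round divided by the observed passer count.
#'
#' @param screen A `jtk_screen` from [run_jtk()].
#' @param df The table the screen was run on.
#' @param n_perm Number of permutation rounds (default 100).
#' @param seed Integer seed.
#' @return The `jtk_screen` with an `fdr` element: a list with `fdr` (NA if
#'   there were no observed passers), `n_observed`, `mean_null_passers`, and
#'   `n_perm`.
#' @export
jtk_permutation_fdr <- function(screen, df, n_perm = 100L, seed = 1L) {
  stopifnot(inherits(screen, "jtk_screen"), n_perm >= 1)
  V <- lfq_to_matrix(df)
  times <- screen$times
  cfg <- screen$config
  n_obs_pass <- sum(screen$results$passes)
  seeds <- substream_seeds(seed, n_perm)
  null_pass <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    set.seed(seeds[r])
    Vp <- t(apply(V, 1, function(x) {
      ok <- which(!is.na(x))
      if (length(ok) > 1) x[ok] <- x[ok][sample.int(length(ok))]
      x
    }))
    res <- jtk_screen_core(Vp, times, cfg$periods, cfg$lags, cfg$adjust)
    null_pass[r] <- sum(res$p < cfg$p_threshold)
  }
  screen$fdr <- list(
    fdr = if (n_obs_pass == 0) NA_real_ else mean(null_pass) / n_obs_pass,
    n_observed = n_obs_pass,
    mean_null_passers = mean(null_pass),
    n_perm = n_perm
  )
  screen
}

#' Write JTK screen results as TSV with a YAML sidecar
#'
#' Writes the per-protein table to `path` and, when a permutation FDR has
#' been computed, a `<path>.yaml` sidecar with the FDR summary and the
#' screen configuration.
#'
#' @param screen A `jtk_screen`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_jtk_results <- function(screen, path) {
  stopifnot(inherits(screen, "jtk_screen"))
  readr::write_tsv(screen$results, path, progress = FALSE)
  side <- list(config = screen$config)
  if (!is.null(screen$fdr)) side$fdr <- screen$fdr
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}
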