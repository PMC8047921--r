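# Synthetic LFQ study generator with known ground truth.
#
# Emulates the structure of a post-mortem pineal LFQ study: ~18 control and
# 7 case subjects with 2 technical replicate runs each, death times spread
# over the 24 h clock, log2 LFQ baselines around 27 +/- 2, and a mixture of
# protein classes — null, day/night step effects, near-circadian sinusoids,
# and group-exclusive presence — on top of left-censored plus random
# missingness.

#' Generate a synthetic LFQ study with ground truth
#'
#' Builds an intensity table, run-level sample metadata, and a truth table,
#' with defaults matching the study design the package targets: 18 control
#' + 7 case subjects, 2 replicate runs each, 2000 proteins, log2 baselines
#' `N(27, 2)`, and death times drawn from a day cluster and a night cluster
#' (autopsy-like collection; `death_times = "uniform"` spreads them evenly).
#' Protein classes and generative model (all effects in log2 units):
#'
#' * `null` — baseline only.
#' * `day_up` / `night_up` — a step of `+step_effect/2` in the favored
#'   condition and `-step_effect/2` in the other, so the realized group
#'   difference is `step_effect`.
#' * `sinusoidal` — `amplitude * cos(2*pi*(t_death - phase)/period)` with
#'   period drawn uniformly in 23-24 h and random phase.
#' * `only_day` / `only_night` — present in one condition, fully masked in
#'   the other (forced all-replicate missingness).
#' * `only_control` — fully masked in the case (autism) group.
#'
#' Subject values add `N(0, subject_sd)` noise; replicates add
#' `N(0, replicate_sd)`.  Intensities are `2^log2value`, then missingness is
#' injected by [inject_missingness()]: run-specific left-censoring (logistic
#' in log2 intensity around the run's `censor_quantile` quantile) plus MCAR
#' drops at `mcar_rate`.
#'
#' @param n_control,n_case Subjects per group (defaults 18 and 7).
#' @param n_replicates Technical replicate runs per subject (default 2).
#' @param n_proteins Number of proteins (default 2000).
#' @param frac Named class fractions (remainder is `null`); defaults
#'   `day_up = night_up = 0.05`, `sinusoidal = only_day = only_night = 0.10`,
#'   `only_control = 0.05`.
#' @param step_effect Day/night step in log2 units (default 2).
#' @param sin_amplitude Sinusoid amplitude in log2 units (default 1.5).
#' @param subject_sd,replicate_sd Between-subject and replicate noise sds in
#'   log2 units (defaults 0.5 and 0.2).
#' @param baseline_mean,baseline_sd Protein log2 baseline distribution
#'   (defaults 27 and 2).
#' @param censor_quantile Per-run left-censor quantile (default 0.05).
#' @param censor_scale Logistic scale of the censoring curve in log2 units
#'   (default 0.3).
#' @param mcar_rate Completely-at-random missingness rate (default 0.02).
#' @param death_times `"clustered"` (default; day cluster `N(14, 3)`, night
#'   cluster `N(3, 3)`, wrapped to `[0, 24)`) or `"uniform"`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list: `lfq` (wide intensity tibble, `NA` = missing), `meta`
#'   (run-level metadata), `truth` (protein_id, class, effect, period,
#'   phase).
#' @export
simulate_pineal <- function(n_control = 18L, n_case = 7L, n_replicates = 2L,
                            n_proteins = 2000L,
                            frac = c(day_up = 0.05, night_up = 0.05,
                                     sinusoidal = 0.10, only_day = 0.10,
                                     only_night = 0.10, only_control = 0.05),
                            step_effect = 2, sin_amplitude = 1.5,
                            subject_sd = 0.5, replicate_sd = 0.2,
                            baseline_mean = 27, baseline_sd = 2,
                            censor_quantile = 0.05, censor_scale = 0.3,
                            mcar_rate = 0.02,
                            death_times = c("clustered", "uniform"),
                            seed = 1L) {
  death_times <- match.arg(death_times)
  stopifnot(n_control >= 1, n_case >= 0, n_replicates >= 1, n_proteins >= 1,
            subject_sd >= 0, replicate_sd >= 0, baseline_sd >= 0,
            mcar_rate >= 0, mcar_rate <= 1,
            censor_quantile >= 0, censor_quantile < 1)
  known <- c("day_up", "night_up", "sinusoidal", "only_day", "only_night",
             "only_control")
  if (!all(names(frac) %in% known)) {
    abort(paste0("unknown class fraction(s): ",
                 paste(setdiff(names(frac), known), collapse = ", ")))
  }
  if (any(frac < 0) || sum(frac) > 1) {
    abort("class fractions must be non-negative and sum to at most 1")
  }
  set.seed(seed %% .Machine$integer.max)

  # --- subjects and runs ---------------------------------------------------
  groups <- c(rep("control", n_control), rep("autism", n_case))
  n_subj <- length(groups)
  subject_id <- sprintf("S%02d", seq_len(n_subj))
  # alternate day/night within each group so both conditions are populated
  daynight <- character(n_subj)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    daynight[idx] <- rep_len(c("day", "night"), length(idx))
  }
  tod <- numeric(n_subj)
  if (death_times == "clustered") {
    centers <- ifelse(daynight == "day", 14, 3)
    tod <- (rnorm(n_subj, centers, 3)) %% 24
    # keep labels honest: day deaths in [7, 19), night outside
    flip <- (daynight == "day") != (tod >= 7 & tod < 19)
    tod[flip] <- ifelse(daynight[flip] == "day",
                        runif(sum(flip), 9, 18), (runif(sum(flip), 21, 30)) %% 24)
  } else {
    tod <- runif(n_subj, 0, 24)
    daynight <- ifelse(tod >= 7 & tod < 19, "day", "night")
  }
  meta <- tibble(
    run_id = paste0(rep(subject_id, each = n_replicates), "_R",
                    rep(seq_len(n_replicates), n_subj)),
    subject_id = rep(subject_id, each = n_replicates),
    group = rep(groups, each = n_replicates),
    daynight = rep(daynight, each = n_replicates),
    time_of_death = rep(round(tod, 2), each = n_replicates)
  )

  # --- protein classes -----------------------------------------------------
  counts <- round(frac * n_proteins)
  classes <- c(rep(names(counts), counts),
               rep("null", n_proteins - sum(counts)))
  protein_id <- sprintf("P%05d", seq_len(n_proteins))
  period <- ifelse(classes == "sinusoidal", runif(n_proteins, 23, 24), NA_real_)
  phase <- ifelse(classes == "sinusoidal", runif(n_proteins, 0, 24), NA_real_)
  effect <- dplyr::case_when(
    classes %in% c("day_up", "night_up") ~ step_effect,
    classes == "sinusoidal" ~ sin_amplitude,
    .default = 0
  )
  truth <- tibble(protein_id = protein_id, class = classes,
                  effect = effect, period = period, phase = phase)

  # --- expression ----------------------------------------------------------
  baseline <- rnorm(n_proteins, baseline_mean, baseline_sd)
  tod_subj <- meta$time_of_death[match(subject_id, meta$subject_id)]
  dn_subj <- daynight
  mean_mat <- matrix(baseline, n_proteins, n_subj)
  is_day <- dn_subj == "day"
  step_rows <- classes %in% c("day_up", "night_up")
  if (any(step_rows)) {
    sgn <- ifelse(classes[step_rows] == "day_up", 1, -1)
    mean_mat[step_rows, ] <- mean_mat[step_rows, ] +
      outer(sgn, ifelse(is_day, 1, -1)) * (step_effect / 2)
  }
  sin_rows <- which(classes == "sinusoidal")
  for (p in sin_rows) {
    mean_mat[p, ] <- mean_mat[p, ] +
      sin_amplitude * cos(2 * pi * (tod_subj - phase[p]) / period[p])
  }
  subj_mat <- mean_mat + matrix(rnorm(n_proteins * n_subj, 0, subject_sd),
                                n_proteins, n_subj)
  rep_idx <- rep(seq_len(n_subj), each = n_replicates)
  run_mat <- subj_mat[, rep_idx, drop = FALSE] +
    matrix(rnorm(n_proteins * n_subj * n_replicates, 0, replicate_sd),
           n_proteins, n_subj * n_replicates)
  dimnames(run_mat) <- list(protein_id, meta$run_id)

  # --- forced class masks --------------------------------------------------
  forced <- matrix(FALSE, n_proteins, ncol(run_mat),
                   dimnames = dimnames(run_mat))
  run_dn <- meta$daynight
  run_grp <- meta$group
  forced[classes == "only_day", run_dn == "night"] <- TRUE
  forced[classes == "only_night", run_dn == "day"] <- TRUE
  forced[classes == "only_control", run_grp != "control"] <- TRUE

  lfq <- inject_missingness(
    matrix_to_lfq(2^run_mat),
    censor_quantile = censor_quantile, censor_scale = censor_scale,
    mcar_rate = mcar_rate, forced_missing = matrix_to_lfq(forced + 0),
    seed = seed + 1L
  )
  list(lfq = lfq, meta = meta, truth = truth)
}

#' Inject left-censored and random missingness into an LFQ table
#'
#' Models LFQ dropout: within each run, intensities near or below the run's
#' `censor_quantile` quantile (on the log2 scale) are dropped with a
#' logistic probability `1 / (1 + exp((log2(x) - threshold) / scale))` —
#' 50% at the threshold, approaching 1 well below it — plus
#' completely-at-random drops at `mcar_rate`.  A `forced_missing` mask (same
#' shape as the table) unconditionally masks cells, used for
#' group-exclusive protein classes.
#'
#' @param df Wide LFQ tibble on the raw intensity scale, complete (no `NA`)
#'   except where forced.
#' @param censor_quantile Per-run quantile anchoring the censoring curve;
#'   `0` disables intensity-dependent censoring (default 0.05).
#' @param censor_scale Logistic scale in log2 units (default 0.3).
#' @param mcar_rate Random drop probability in `[0, 1]` (default 0.02).
#' @param forced_missing Optional logical wide tibble marking cells to mask
#'   unconditionally.
#' @param seed Integer seed.
#' @return The tibble with missing cells set to `NA`.
#' @export
inject_missingness <- function(df, censor_quantile = 0.05, censor_scale = 0.3,
                               mcar_rate = 0.02, forced_missing = NULL,
                               seed = 1L) {
  stopifnot(mcar_rate >= 0, mcar_rate <= 1, censor_scale > 0,
            censor_quantile >= 0, censor_quantile < 1)
  m <- lfq_to_matrix(df)
  set.seed(seed %% .Machine$integer.max)
  drop <- matrix(FALSE, nrow(m), ncol(m))
  if (censor_quantile > 0) {
    lg <- log2(m)
    thr <- apply(lg, 2, quantile, probs = censor_quantile, na.rm = TRUE)
    pmiss <- 1 / (1 + exp(sweep(lg, 2, thr) / censor_scale))
    drop <- drop | (matrix(runif(length(m)), nrow(m)) < pmiss)
  }
  if (mcar_rate > 0) {
    drop <- drop | (matrix(runif(length(m)), nrow(m)) < mcar_rate)
  }
  if (!is.null(forced_missing)) {
    f <- lfq_to_matrix(forced_missing)
    stopifnot(identical(dim(f), dim(m)))
    drop <- drop | (f > 0)
  }
  m[drop] <- NA_real_
  matrix_to_lfq(m)
}

#' Write a synthetic truth table as TSV
#' @param truth Truth tibble from [simulate_pineal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}
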