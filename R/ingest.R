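#' Read a MaxQuant-style LFQ intensity table
#'
#' Reads a tab-delimited protein-group table in the MaxQuant
#' `proteinGroups.txt` dialect: one protein-identifier column plus one LFQ
#' intensity column per run, named `<prefix><run id>`.  A raw intensity of
#' `0`, an empty cell, or the literal string `"NaN"` means the protein was
#' not quantified in that run and becomes `NA`; LFQ zeros are censoring
#' markers, not measurements.
#'
#' @param path Path to a tab-separated file.
#' @param intensity_prefix Prefix selecting the intensity columns; the run id
#'   is the column name with the prefix stripped. Default `"LFQ intensity "`.
#' @param id_column Name of the protein-identifier column
#'   (default `"Majority protein IDs"`).
#' @return A wide LFQ tibble: a `protein_id` character column followed by one
#'   numeric column per run, `NA` marking missing cells, in file row/column
#'   order.
#' @examples
#' sim <- simulate_pineal(n_proteins = 20, seed = 1)
#' f <- tempfile(fileext = ".txt")
#' write_lfq(sim$lfq, f)
#' lfq <- read_lfq(f)
#' lfq[1:3, 1:4]
#' @export
read_lfq <- function(path, intensity_prefix = "LFQ intensity ",
                     id_column = "Majority protein IDs") {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  run_cols <- header[startsWith(header, intensity_prefix)]
  if (length(run_cols) == 0L) {
    abort(paste0("no columns matching intensity prefix '", intensity_prefix, "'"))
  }
  if (anyDuplicated(run_cols)) {
    dup <- unique(run_cols[duplicated(run_cols)])
    abort(paste0("duplicate intensity column(s): ", paste(dup, collapse = ", ")))
  }
  if (!id_column %in% header) {
    abort(paste0("identifier column '", id_column, "' not found"))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, name_repair = "minimal")
  ids <- raw[[id_column]]
  run_ids <- substring(run_cols, nchar(intensity_prefix) + 1L)
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(run_cols),
                 dimnames = list(NULL, run_ids))
  for (j in seq_along(run_cols)) {
    cell <- raw[[run_cols[j]]]
    cell[cell %in% c("", "NaN", "NA")] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad)) {
      abort(paste0(
        "non-numeric intensity '", cell[bad[1]], "' at row ", bad[1],
        ", column '", run_cols[j], "'"
      ))
    }
    vals[, j] <- num
  }
  if (any(vals < 0, na.rm = TRUE)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    abort(paste0("negative intensity at row ", bad[1], ", run '", run_ids[bad[2]], "'"))
  }
  vals[!is.na(vals) & vals == 0] <- NA_real_
  out <- dplyr::bind_cols(tibble(protein_id = ids),
                          as_tibble(vals, .name_repair = "minimal"))
  if (anyDuplicated(out$protein_id)) {
    dup <- unique(out$protein_id[duplicated(out$protein_id)])
    abort(paste0("duplicate protein identifiers: ", paste(head(dup, 5), collapse = ", ")))
  }
  out
}

#' Write a wide LFQ tibble in the MaxQuant dialect
#'
#' Inverse of [read_lfq()]: missing cells are written as `0`, the dialect's
#' marker for a non-quantified protein.
#'
#' @param df Wide LFQ tibble (`protein_id` + one numeric column per run).
#' @param path Output path (tab-separated).
#' @inheritParams read_lfq
#' @return `path`, invisibly.
#' @export
write_lfq <- function(df, path, intensity_prefix = "LFQ intensity ",
                      id_column = "Majority protein IDs") {
  m <- lfq_to_matrix(df)
  m[is.na(m)] <- 0
  out <- as.data.frame(m, check.names = FALSE)
  names(out) <- paste0(intensity_prefix, names(out))
  out <- cbind(setNames(data.frame(rownames(m)), id_column), out)
  readr::write_tsv(as_tibble(out, .name_repair = "minimal"), path, progress = FALSE)
  invisible(path)
}

#' Read and validate run-level sample metadata
#'
#' One row per mass-spectrometry run, with columns `run_id`, `subject_id`,
#' `group` (e.g. control/autism), `daynight` (day/night), and
#' `time_of_death` (hour of day in `[0, 24)`).  Day/night labels are taken
#' from the annotation as given and never derived from `time_of_death`.
#'
#' @param path TSV or CSV file (delimiter sniffed from the header line).
#' @return A tibble with the five required columns (plus any extras),
#'   validated: unique run ids, each run in exactly one subject, times in
#'   `[0, 24)`, non-empty group and day/night labels.
#' @export
read_sample_metadata <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  meta <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  validate_sample_metadata(meta)
}

#' @rdname read_sample_metadata
#' @param meta A data frame to validate in place of reading a file.
#' @export
validate_sample_metadata <- function(meta) {
  required <- c("run_id", "subject_id", "group", "daynight", "time_of_death")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    abort(paste0("metadata is missing column(s): ", paste(missing, collapse = ", ")))
  }
  meta <- as_tibble(meta)
  meta$run_id <- as.character(meta$run_id)
  meta$subject_id <- as.character(meta$subject_id)
  meta$group <- as.character(meta$group)
  meta$daynight <- as.character(meta$daynight)
  if (anyDuplicated(meta$run_id)) {
    dup <- unique(meta$run_id[duplicated(meta$run_id)])
    abort(paste0("run_id assigned more than once: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (any(is.na(meta$group) | meta$group == "") ||
      any(is.na(meta$daynight) | meta$daynight == "")) {
    abort("group and daynight labels must be non-empty")
  }
  if (any(is.na(meta$time_of_death) | meta$time_of_death < 0 | meta$time_of_death >= 24)) {
    abort("time_of_death must lie in [0, 24)")
  }
  per_subject <- tapply(meta$daynight, meta$subject_id, function(x) length(unique(x)))
  if (any(per_subject > 1)) {
    abort("a subject carries conflicting daynight labels across its runs")
  }
  meta
}

#' Write sample metadata as TSV
#' @param meta Metadata tibble (see [read_sample_metadata()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  readr::write_tsv(validate_sample_metadata(meta), path, progress = FALSE)
  invisible(path)
}

#' Log2-transform LFQ intensities
#'
#' Proteomics convention: abundance differences are interpreted as log2
#' fold changes.  Missing cells stay missing; a non-missing zero or negative
#' value is an error (zeros must have been converted to `NA` at read time).
#'
#' @param df Wide LFQ tibble on the raw intensity scale.
#' @return The same tibble with every non-missing value replaced by its
#'   base-2 logarithm.
#' @export
normalize_log2 <- function(df) {
  m <- lfq_to_matrix(df)
  if (any(m <= 0, na.rm = TRUE)) {
    bad <- which(m <= 0, arr.ind = TRUE)[1, ]
    abort(paste0(
      "non-missing, non-positive intensity at protein '", rownames(m)[bad[1]],
      "', column '", colnames(m)[bad[2]], "'; zeros must be masked as missing"
    ))
  }
  matrix_to_lfq(log2(m))
}

#' Z-score a log-LFQ table within each subject
#'
#' Standardizes each column to mean 0 and standard deviation 1 across its
#' non-missing proteins (unbiased n - 1 denominator).  When `meta` is
#' supplied and the columns are run ids, the centering statistics are pooled
#' over each subject's replicate runs so that technical replicates share one
#' standardization; with subject-level columns (or `meta = NULL`) each column
#' is standardized on its own.
#'
#' @param df Wide log-scale LFQ tibble (columns are runs or subjects).
#' @param meta Optional sample metadata mapping run ids to subjects.
#' @return The standardized tibble, missing cells preserved.
#' @export
zscore_by_subject <- function(df, meta = NULL) {
  m <- lfq_to_matrix(df)
  if (!is.null(meta) && all(colnames(m) %in% meta$run_id)) {
    meta <- validate_sample_metadata(meta)
    subj <- meta$subject_id[match(colnames(m), meta$run_id)]
    for (s in unique(subj)) {
      cols <- which(subj == s)
      vals <- m[, cols]
      n <- sum(!is.na(vals))
      if (n < 2) abort(paste0("subject '", s, "' has fewer than 2 non-missing values"))
      mu <- mean(vals, na.rm = TRUE)
      sdev <- sd(vals, na.rm = TRUE)
      if (sdev == 0) abort(paste0("subject '", s, "' has zero variance; Z-score undefined"))
      m[, cols] <- (m[, cols] - mu) / sdev
    }
  } else {
    st <- col_stats(m, min_n = 2L, what = "subject column")
    if (any(st$sd == 0)) {
      bad <- colnames(m)[st$sd == 0]
      abort(paste0("zero variance in column(s): ", paste(head(bad, 5), collapse = ", ")))
    }
    m <- sweep(sweep(m, 2, st$mean), 2, st$sd, "/")
  }
  matrix_to_lfq(m)
}
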