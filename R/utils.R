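# Internal helpers shared across modules.
#
# The package's tabular currency is a "wide LFQ tibble": a `protein_id`
# character column (unique, non-missing) followed by one numeric column per
# run (or per subject, after replicate averaging).  NA encodes a missing
# (non-quantified) cell.  Internally most numerics run on the equivalent
# base matrix with protein_ids as rownames.

lfq_to_matrix <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"protein_id" %in% names(df)) {
    abort("expected a `protein_id` column in the LFQ table")
  }
  ids <- as.character(df[["protein_id"]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate protein_id values: ", paste(head(dup, 5), collapse = ", ")))
  }
  value_cols <- setdiff(names(df), "protein_id")
  if (length(value_cols) == 0L) abort("LFQ table has no intensity columns")
  m <- as.matrix(df[value_cols])
  if (!is.numeric(m)) abort("intensity columns must be numeric")
  rownames(m) <- ids
  m
}

matrix_to_lfq <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(protein_id = rownames(m)), out)
}

# Map the value columns of a wide LFQ tibble onto sample metadata rows.
# Columns may be run ids or subject ids; returns the matched meta rows in
# column order, or aborts if some columns are unknown.
match_meta_columns <- function(cols, meta) {
  if (all(cols %in% meta$run_id)) {
    idx <- match(cols, meta$run_id)
    level <- "run"
  } else if (all(cols %in% meta$subject_id)) {
    subj <- dplyr::distinct(meta, .data$subject_id, .keep_all = TRUE)
    idx <- match(cols, subj$subject_id)
    meta <- subj
    level <- "subject"
  } else {
    missing <- setdiff(cols, union(meta$run_id, meta$subject_id))
    abort(paste0(
      "columns not found in metadata (as run_id or subject_id): ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  list(meta = meta[idx, , drop = FALSE], level = level)
}

# Deterministic per-simulation substreams: one upfront draw of sub-seeds so
# results do not depend on the order simulations are executed in.
substream_seeds <- function(seed, n) {
  withr_seed <- seed %% .Machine$integer.max
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(withr_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Column means and sds over non-missing entries (denominator n - 1).
col_stats <- function(m, min_n = 2L, what = "column") {
  n <- colSums(!is.na(m))
  if (any(n < min_n)) {
    bad <- colnames(m)[n < min_n]
    abort(paste0(
      what, "(s) with fewer than ", min_n, " non-missing values: ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  mu <- colMeans(m, na.rm = TRUE)
  centered <- sweep(m, 2, mu)
  ss <- colSums(centered^2, na.rm = TRUE)
  list(mean = mu, sd = sqrt(ss / (n - 1)), n = n)
}
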