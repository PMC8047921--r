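# broom-style tidiers for the package's result objects.

#' Tidy a Monte-Carlo presence screen
#' @param x A `presence_mc` object.
#' @param ... Unused.
#' @return The per-protein call tibble.
#' @export
tidy.presence_mc <- function(x, ...) x$calls

#' @rdname tidy.presence_mc
#' @export
glance.presence_mc <- function(x, ...) {
  tab <- table(factor(x$calls$status,
                      levels = c("Missing", "OnlyA", "OnlyB", "Modulated")))
  tibble(
    n_proteins = nrow(x$calls),
    n_missing = unname(tab["Missing"]),
    n_only_a = unname(tab["OnlyA"]),
    n_only_b = unname(tab["OnlyB"]),
    n_modulated = unname(tab["Modulated"]),
    n_significant = sum(x$calls$significant),
    n_sims = x$config$n_sims,
    alpha = x$config$alpha
  )
}

#' Tidy a JTK-cycle screen
#' @param x A `jtk_screen` object.
#' @param ... Unused.
#' @return The per-protein results tibble.
#' @export
tidy.jtk_screen <- function(x, ...) x$results

#' @rdname tidy.jtk_screen
#' @export
glance.jtk_screen <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$results),
    n_passing = sum(x$results$passes),
    p_threshold = x$config$p_threshold,
    fdr = if (is.null(x$fdr)) NA_real_ else x$fdr$fdr
  )
}

#' Tidy a BGLS screen
#' @param x A `bgls_screen` object.
#' @param ... Unused.
#' @return The per-protein results tibble.
#' @export
tidy.bgls_screen <- function(x, ...) x$results

#' @rdname tidy.bgls_screen
#' @export
glance.bgls_screen <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$results),
    n_flagged = sum(x$results$flagged),
    threshold = x$config$threshold,
    period_min = x$config$period_min,
    period_max = x$config$period_max
  )
}

#' Tidy a single BGLS periodogram
#' @param x A `bgls` object.
#' @param ... Unused.
#' @return Tibble with `period`, `log_posterior`, `posterior`.
#' @export
tidy.bgls <- function(x, ...) {
  tibble(period = x$period, log_posterior = x$log_posterior,
         posterior = x$posterior)
}

#' @rdname tidy.bgls
#' @export
glance.bgls <- function(x, ...) {
  tibble(best_period = x$best_period,
         concentration = bgls_concentration(x),
         n = x$n)
}

#' Tidy a PPI projection
#' @param x A `ppi_projection` object.
#' @param ... Unused.
#' @return The per-node tibble (node, label, component, degree, in_largest).
#' @export
tidy.ppi_projection <- function(x, ...) x$nodes

#' @rdname tidy.ppi_projection
#' @export
glance.ppi_projection <- function(x, ...) {
  s <- x$summary
  tibble(
    n_labeled = s$n_labeled,
    n_nodes = s$n_nodes,
    n_edges = s$n_edges,
    n_components = s$n_components,
    fraction_in_largest_component = s$fraction_in_largest_component
  )
}
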