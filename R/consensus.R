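# Consensus across detectors and PPI-network projection.

#' Venn region counts for three protein sets
#'
#' Tabulates the seven regions of a three-set Venn diagram (each set alone,
#' the three pairwise-only overlaps, and the triple overlap).  Region counts
#' partition the union, so inclusion-exclusion holds by construction.
#'
#' @param sets Named list of three character vectors (e.g. `jtk`, `bgls`,
#'   `mc`).
#' @return A tibble with columns `region` (e.g. `"jtk"`,
#'   `"jtk&bgls"`, `"jtk&bgls&mc"`) and `count`, plus per-set totals in the
#'   attribute `"set_sizes"`.
#' @examples
#' venn_counts(list(a = c("x", "y"), b = c("y", "z"), c = "z"))
#' @export
venn_counts <- function(sets) {
  stopifnot(is.list(sets), length(sets) == 3)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- c("A", "B", "C")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  key <- member %*% c(1L, 2L, 4L)
  nm <- names(sets)
  regions <- c(nm[1], nm[2], paste0(nm[1], "&", nm[2]), nm[3],
               paste0(nm[1], "&", nm[3]), paste0(nm[2], "&", nm[3]),
               paste0(nm[1], "&", nm[2], "&", nm[3]))
  counts <- vapply(1:7, function(k) sum(key == k), integer(1))
  out <- tibble(region = regions, count = counts)
  attr(out, "set_sizes") <- vapply(sets, length, integer(1))
  out
}

#' Extract the per-method flagged sets and their Venn consensus
#'
#' Collects the protein sets flagged by the three detectors — JTK passers,
#' BGLS-flagged proteins, and Monte-Carlo hits (significant `Modulated`
#' proteins plus, optionally, the group-exclusive calls) — and tabulates
#' their overlap.
#'
#' @param jtk A `jtk_screen`.
#' @param bgls A `bgls_screen`.
#' @param mc A `presence_mc`.
#' @param include_exclusive Count `OnlyA`/`OnlyB` proteins as Monte-Carlo
#'   hits (default `TRUE`, matching a projection input that combines
#'   differential-abundance and exclusive-presence calls).
#' @return A list with `sets` (named list of id vectors) and `venn`
#'   (the [venn_counts()] tibble).
#' @export
consensus_sets <- function(jtk, bgls, mc, include_exclusive = TRUE) {
  stopifnot(inherits(jtk, "jtk_screen"), inherits(bgls, "bgls_screen"),
            inherits(mc, "presence_mc"))
  mc_hits <- mc$calls$protein_id[mc$calls$significant]
  if (include_exclusive) {
    mc_hits <- c(mc_hits, mc$calls$protein_id[mc$calls$status %in% c("OnlyA", "OnlyB")])
  }
  sets <- list(
    jtk = jtk$results$protein_id[jtk$results$passes],
    bgls = bgls$results$protein_id[bgls$results$flagged],
    mc = unique(mc_hits)
  )
  list(sets = sets, venn = venn_counts(sets))
}

#' Load and concatenate binary PPI edge lists
#'
#' Reads one or more two-column tab-separated files of interacting gene
#' symbols, uppercases the symbols, drops self-loops, and deduplicates
#' undirected edges across files while retaining per-edge provenance (the
#' names of the source files contributing each edge).
#'
#' @param paths Character vector of file paths; names, if given, become the
#'   provenance tags (otherwise base names are used).
#' @param header Whether each file carries a header row to skip
#'   (default `FALSE`).
#' @return A `ppi_graph`: a tibble of edges with columns `from`, `to`
#'   (sorted within row), `sources` (comma-joined provenance), carrying the
#'   node set in attribute `"nodes"`.
#' @export
read_ppi_edges <- function(paths, header = FALSE) {
  tags <- names(paths) %||% basename(paths)
  all_edges <- purrr::map2(paths, tags, function(path, tag) {
    lines <- readLines(path)
    if (header && length(lines)) lines <- lines[-1]
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, function(x) sum(nzchar(trimws(x))) != 2, logical(1)))
    if (length(bad)) {
      abort(paste0("malformed row in '", path, "' at line ",
                   bad[1] + as.integer(header), ": expected two tab-separated symbols"))
    }
    a <- toupper(trimws(vapply(parts, `[`, "", 1)))
    b <- toupper(trimws(vapply(parts, `[`, "", 2)))
    self <- a == b
    if (any(self)) {
      inform(paste0(sum(self), " self-loop(s) dropped from '", path, "'"))
    }
    tibble(from = pmin(a, b)[!self], to = pmax(a, b)[!self], source = tag)
  })
  edges <- dplyr::bind_rows(all_edges)
  edges <- edges |>
    dplyr::distinct(.data$from, .data$to, .data$source) |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(sources = paste(sort(unique(.data$source)), collapse = ","),
                     .groups = "drop") |>
    dplyr::arrange(.data$from, .data$to)
  attr(edges, "nodes") <- sort(unique(c(edges$from, edges$to)))
  class(edges) <- c("ppi_graph", class(edges))
  edges
}

#' Project labeled proteins onto a PPI network and summarize
#'
#' Takes the subgraph induced by the labeled proteins that appear in the
#' network and summarizes its structure: node and edge counts, connected
#' components, the fraction of projected nodes inside the largest linked
#' component, and per-label composition (overall and within the largest
#' component).
#'
#' @param edges A `ppi_graph` from [read_ppi_edges()], or any tibble with
#'   `from`/`to` columns.
#' @param labels A data frame with columns `protein_id` (gene symbol) and
#'   `label` (e.g. `"day"`/`"night"`).
#' @return A `ppi_projection` object; `glance()` gives the one-row summary,
#'   `tidy()` the per-node table (node, label, component id, degree).
#' @export
ppi_project <- function(edges, labels) {
  stopifnot(all(c("from", "to") %in% names(edges)),
            all(c("protein_id", "label") %in% names(labels)))
  labels <- dplyr::distinct(as_tibble(labels), .data$protein_id, .keep_all = TRUE)
  labels$protein_id <- toupper(labels$protein_id)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE,
                                     vertices = unique(c(edges$from, edges$to)))
  keep <- intersect(labels$protein_id, igraph::V(g)$name)
  sub <- igraph::induced_subgraph(g, keep)
  n_nodes <- igraph::vcount(sub)
  n_edges <- igraph::ecount(sub)
  if (n_nodes > 0) {
    comp <- igraph::components(sub)
    comp_id <- comp$membership
    largest <- which.max(comp$csize)
    frac_largest <- max(comp$csize) / n_nodes
    nodes <- tibble(
      node = igraph::V(sub)$name,
      label = labels$label[match(igraph::V(sub)$name, labels$protein_id)],
      component = unname(comp_id),
      degree = unname(igraph::degree(sub)),
      in_largest = unname(comp_id) == largest
    )
    label_frac <- prop.table(table(nodes$label))
    label_frac_largest <- if (any(nodes$in_largest)) {
      prop.table(table(nodes$label[nodes$in_largest]))
    } else {
      table(character(0))
    }
    comps <- nodes |>
      dplyr::group_by(.data$component) |>
      dplyr::summarise(size = dplyr::n(),
                       members = paste(sort(.data$node), collapse = ","),
                       .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$size))
  } else {
    nodes <- tibble(node = character(), label = character(),
                    component = integer(), degree = integer(),
                    in_largest = logical())
    frac_largest <- 0
    label_frac <- table(character(0))
    label_frac_largest <- table(character(0))
    comps <- tibble(component = integer(), size = integer(), members = character())
  }
  structure(list(
    graph = sub,
    nodes = nodes,
    components = comps,
    summary = list(
      n_labeled = nrow(labels),
      n_nodes = n_nodes,
      n_edges = n_edges,
      n_components = nrow(comps),
      fraction_in_largest_component = frac_largest,
      label_fractions = as.list(label_frac),
      label_fractions_largest_component = as.list(label_frac_largest)
    )
  ), class = "ppi_projection")
}

#' @export
print.ppi_projection <- function(x, ...) {
  s <- x$summary
  cat("<ppi_projection> induced PPI subnetwork\n")
  cat("  ", s$n_nodes, " nodes (of ", s$n_labeled, " labeled proteins), ",
      s$n_edges, " edges, ", s$n_components, " components\n", sep = "")
  cat("  largest component holds ",
      round(100 * s$fraction_in_largest_component), "% of projected nodes\n", sep = "")
  if (length(s$label_fractions)) {
    cat("  label mix: ",
        paste(names(s$label_fractions),
              paste0(round(100 * unlist(s$label_fractions)), "%"),
              sep = "=", collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}
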