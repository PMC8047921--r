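test_that("Venn regions partition the union for degenerate and random sets", {
  # disjoint sets
  v <- venn_counts(list(a = c("p1", "p2"), b = c("p3", "p4", "p5"),
                        c = c("p6", "p7", "p8", "p9")))
  expect_equal(v$count[v$region == "a"], 2L)
  expect_equal(sum(v$count[grepl("&", v$region)]), 0L)
  expect_equal(sum(v$count), 9L)

  # identical sets: everything in the triple region
  s <- sprintf("p%d", 1:5)
  v2 <- venn_counts(list(a = s, b = s, c = s))
  expect_equal(v2$count[v2$region == "a&b&c"], 5L)
  expect_equal(sum(v2$count), 5L)

  # random sets at realistic scale vs brute-force membership tabulation
  set.seed(30)
  universe <- sprintf("P%04d", 1:2000)
  sets <- list(jtk = sample(universe, 782), bgls = sample(universe, 34),
               mc = sample(universe, 451))
  v3 <- venn_counts(sets)
  inA <- universe %in% sets$jtk
  inB <- universe %in% sets$bgls
  inC <- universe %in% sets$mc
  expect_equal(v3$count[v3$region == "jtk"], sum(inA & !inB & !inC))
  expect_equal(v3$count[v3$region == "jtk&bgls"], sum(inA & inB & !inC))
  expect_equal(v3$count[v3$region == "jtk&bgls&mc"], sum(inA & inB & inC))
  expect_equal(v3$count[v3$region == "bgls&mc"], sum(!inA & inB & inC))
  # inclusion-exclusion: regions partition the union
  expect_equal(sum(v3$count), sum(inA | inB | inC))
})

test_that("PPI loading dedups across files, drops self-loops, keeps provenance", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "set1.tsv"); f2 <- file.path(d, "set2.tsv")
  writeLines(c("a\tB", "C\tD", "E\tE"), f1)   # E-E self-loop; a lowercased
  writeLines(c("B\tA", "D\tF"), f2)           # B-A duplicates A-B
  expect_message(g <- read_ppi_edges(c(f1, f2)), "self-loop")
  expect_equal(nrow(g), 3L)
  ab <- g[g$from == "A" & g$to == "B", ]
  expect_equal(ab$sources, "set1.tsv,set2.tsv")
  expect_setequal(attr(g, "nodes"), c("A", "B", "C", "D", "F"))

  # load order does not change the graph
  g2 <- read_ppi_edges(c(f2, f1))
  expect_equal(g[c("from", "to")], g2[c("from", "to")])

  writeLines(c("A\tB", "oops"), f1)
  expect_error(read_ppi_edges(f1), "malformed row.*line 2")
})

test_that("counting oracle: duplicates and self-loops reduce the edge total", {
  set.seed(31)
  d <- withr::local_tempdir()
  nodes <- sprintf("G%02d", 1:30)
  # manifest: 80 unique pairs, 17 duplicated rows, 3 self-loops = 100 rows
  pool <- t(combn(nodes, 2))
  uniq <- pool[sample(nrow(pool), 80), ]
  dups <- uniq[sample(80, 17), ]
  selfs <- cbind(nodes[1:3], nodes[1:3])
  rows <- rbind(uniq, dups, selfs)[sample(100), ]
  paths <- character(5)
  for (i in 1:5) {
    paths[i] <- file.path(d, paste0("part", i, ".tsv"))
    idx <- seq((i - 1) * 20 + 1, i * 20)
    writeLines(paste(rows[idx, 1], rows[idx, 2], sep = "\t"), paths[i])
  }
  suppressMessages(g <- read_ppi_edges(paths))
  expect_equal(nrow(g), 80L)
})

test_that("projection induces the right subgraph in hand-checkable cases", {
  chain <- tibble::tibble(from = c("A", "B"), to = c("B", "C"))
  pr <- ppi_project(chain, tibble::tibble(protein_id = c("A", "C"),
                                          label = c("day", "night")))
  g <- glance(pr)
  expect_equal(g$n_nodes, 2L)
  expect_equal(g$n_edges, 0L)
  expect_equal(g$n_components, 2L)
  expect_equal(g$fraction_in_largest_component, 0.5)

  k4 <- t(combn(c("A", "B", "C", "D"), 2))
  pr2 <- ppi_project(tibble::tibble(from = k4[, 1], to = k4[, 2]),
                     tibble::tibble(protein_id = c("A", "B", "C", "D"),
                                    label = "day"))
  g2 <- glance(pr2)
  expect_equal(g2$n_nodes, 4L)
  expect_equal(g2$n_edges, 6L)
  expect_equal(g2$fraction_in_largest_component, 1)
  expect_equal(pr2$summary$label_fractions$day, 1)
})

test_that("projection summary equals a union-find component oracle", {
  set.seed(32)
  nodes <- sprintf("G%02d", 1:40)
  pool <- t(combn(nodes, 2))
  edges <- pool[sample(nrow(pool), 50), ]
  etbl <- tibble::tibble(from = edges[, 1], to = edges[, 2])
  labeled <- sample(nodes, 25)
  labels <- tibble::tibble(protein_id = labeled,
                           label = sample(c("day", "night"), 25, replace = TRUE))
  pr <- ppi_project(etbl, labels)

  # oracle: induced edges + union-find components over the labeled nodes
  # that actually appear in the network
  keep <- intersect(labeled, unique(c(etbl$from, etbl$to)))
  ind <- etbl[etbl$from %in% keep & etbl$to %in% keep, ]
  roots <- uf_components(keep, ind$from, ind$to)
  sizes <- table(roots)
  expect_equal(glance(pr)$n_nodes, length(keep))
  expect_equal(glance(pr)$n_edges, nrow(ind))
  expect_equal(glance(pr)$n_components, length(sizes))
  expect_equal(glance(pr)$fraction_in_largest_component,
               max(sizes) / length(keep))
})

test_that("consensus sets collect each detector's calls", {
  sim <- simulate_pineal(n_proteins = 80, seed = 33)
  lfq <- normalize_log2(sim$lfq)
  ctrl <- dplyr::filter(sim$meta, group == "control")
  sub <- lfq[c("protein_id", ctrl$run_id)]
  mc <- run_presence_mc(sub, ctrl, n_sims = 10, seed = 1)
  subj <- subject_table(sub, ctrl, impute = "draw", seed = 1)
  tms <- subject_times(subj, ctrl)
  jtk <- run_jtk(subj, tms)
  bgls <- run_bgls(subj, tms)
  cons <- consensus_sets(jtk, bgls, mc)
  expect_named(cons$sets, c("jtk", "bgls", "mc"))
  expect_equal(sum(cons$venn$count), length(unique(unlist(cons$sets))))
  expect_true(all(cons$sets$jtk %in% sub$protein_id))
})
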