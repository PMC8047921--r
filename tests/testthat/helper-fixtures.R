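# Shared fixtures and independent oracles, all built in code.

# matrix -> wide tibble with a protein_id column
wide <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("P%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(protein_id = rownames(m)),
                   tibble::as_tibble(as.data.frame(m)))
}

# tiny deterministic two-group study: 6 subjects (3 day / 3 night), 2 runs each
tiny_meta <- function() {
  tibble::tibble(
    run_id = paste0(rep(sprintf("S%d", 1:6), each = 2), "_R", rep(1:2, 6)),
    subject_id = rep(sprintf("S%d", 1:6), each = 2),
    group = "control",
    daynight = rep(c("day", "night"), each = 6),
    time_of_death = rep(c(10, 12, 14, 22, 2, 4), each = 2)
  )
}

# all permutations of 1..n (n <= 8)
perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# brute-force null pmf of Kendall S: enumerate every permutation of untied
# values against a reference with the given tie-group sizes
enumerate_s_pmf <- function(group_sizes) {
  n <- sum(group_sizes)
  ref <- rep(seq_along(group_sizes), group_sizes)
  P <- perms_of(n)
  pair_j <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_k <- unlist(lapply(seq_len(n - 1), function(j) (j + 1):n))
  rs <- sign(ref[pair_k] - ref[pair_j])
  vs <- sign(P[, pair_k, drop = FALSE] - P[, pair_j, drop = FALSE])
  s <- as.vector(vs %*% rs)
  tab <- table(s)
  list(s = as.numeric(names(tab)), pmf = as.numeric(tab) / nrow(P))
}

# brute-force 3D marginalization of the flat-prior weighted sinusoid-plus-
# offset model at one angular frequency, by nested adaptive quadrature over
# a wide box centered on the weighted least-squares solution
numeric_bgls_marginal <- function(t, y, w, omega, half_widths = 12) {
  X <- cbind(cos(omega * t), sin(omega * t), 1)
  fit <- lm.wfit(X, y, w)
  V <- chol2inv(chol(crossprod(X, X * w)))
  ctr <- fit$coefficients
  sds <- sqrt(diag(V))
  f_gamma <- function(A, B) {
    g <- function(gam) sapply(gam, function(gg) {
      r <- y - (A * X[, 1] + B * X[, 2] + gg)
      exp(-0.5 * sum(w * r^2))
    })
    integrate(g, ctr[3] - half_widths * sds[3], ctr[3] + half_widths * sds[3],
              rel.tol = 1e-10)$value
  }
  f_B <- function(A) integrate(function(Bv) sapply(Bv, function(B) f_gamma(A, B)),
                               ctr[2] - half_widths * sds[2],
                               ctr[2] + half_widths * sds[2], rel.tol = 1e-9)$value
  integrate(function(Av) sapply(Av, f_B),
            ctr[1] - half_widths * sds[1], ctr[1] + half_widths * sds[1],
            rel.tol = 1e-8)$value
}

# the quoted two-group presence rule, coded independently of the package:
# fewer than m observing subjects in both groups -> Missing; in exactly one
# group -> exclusive to the other; otherwise -> Modulated
quoted_rule <- function(na, nb, m = 3) {
  if (na < m && nb < m) return("Missing")
  if (nb < m) return("OnlyA")
  if (na < m) return("OnlyB")
  "Modulated"
}

# union-find connected components over an edge list (independent oracle)
uf_components <- function(nodes, edges_from, edges_to) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(edges_from)) {
    ra <- find(edges_from[i]); rb <- find(edges_to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(nodes, find, character(1))
}
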