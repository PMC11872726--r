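# Independent oracle implementations used to cross-check the package's own
# routines. These deliberately use different formulas / algorithms / libraries
# than the implementation under test.

# Gini via the relative mean absolute difference (population form):
# G = sum_ij |x_i - x_j| / (2 * S^2 * mean(x))
oracle_gini <- function(counts) {
  x <- counts[counts > 0]
  s <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * s^2 * mean(x))
}

# Shannon entropy through vegan
oracle_shannon <- function(counts) {
  vegan::diversity(counts[counts > 0], index = "shannon")
}

# brute-force AUC: average over all case/control pairs, ties counted 1/2
oracle_auc <- function(scores, labels) {
  cs <- scores[labels]
  ct <- scores[!labels]
  tot <- 0
  for (x in cs) tot <- tot + sum(x > ct) + 0.5 * sum(x == ct)
  tot / (length(cs) * length(ct))
}

# connected components of the <= threshold graph, via igraph; distances
# from integer-coded residues rather than character comparison
oracle_components <- function(junctions, threshold) {
  n <- length(junctions)
  if (n == 1) return(1L)
  len <- nchar(junctions[1])
  m <- vapply(junctions, utf8ToInt, integer(len))
  d <- matrix(0, n, n)
  for (p in seq_len(len)) {
    d <- d + outer(m[p, ], m[p, ], "!=")
  }
  g <- igraph::graph_from_adjacency_matrix(d / len <= threshold,
                                           mode = "undirected", diag = FALSE)
  igraph::components(g)$membership
}

# Gini through the alternative rank-weighted form
# G = 2 * sum(i * x_(i)) / (S * sum(x)) - (S + 1) / S
oracle_gini_fast <- function(counts) {
  x <- sort(counts[counts > 0])
  s <- length(x)
  2 * sum(seq_len(s) * x) / (s * sum(x)) - (s + 1) / s
}

# position-by-position sequon scan (no regular expressions)
oracle_nglyc <- function(aa) {
  ch <- strsplit(aa, "")[[1]]
  n <- length(ch)
  if (n < 3) return(0L)
  cnt <- 0L
  for (i in seq_len(n - 2)) {
    if (ch[i] == "N" && !ch[i + 1] %in% c("P", "X", "*") &&
        ch[i + 2] %in% c("S", "T")) {
      cnt <- cnt + 1L
    }
  }
  cnt
}

# plain unpenalized IRLS for logistic regression
oracle_irls <- function(X, y, max_iter = 100, tol = 1e-12) {
  X <- cbind(1, X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    nb <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(nb - beta)) < tol) return(drop(nb))
    beta <- drop(nb)
  }
  beta
}

# discrete power-law tail index, Clauset-style approximation at xmin = 1
oracle_powerlaw_alpha <- function(x) {
  1 + length(x) / sum(log(x / 0.5))
}

# partition-as-set-of-sets comparison helper
partition_sets <- function(ids, membership) {
  unname(lapply(split(ids, membership), function(v) sort(v)))
}
same_partition <- function(a, b) {
  setequal(lapply(a, paste, collapse = ","), lapply(b, paste, collapse = ","))
}
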