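# Shared fixtures and independent oracles for the test suite.

# random complete-grid dataset with uniform positions
rand_dataset <- function(n = 5, t = 20, seed = 1, extent = 100) {
  set.seed(seed)
  pos <- array(runif(t * n * 2, 0, extent), c(t, n, 2))
  trajectory_dataset(pos, sprintf("a%02d", seq_len(n)), seq_len(t) - 1L)
}

# brute-force distance ranks through sorting only (independent of rank())
oracle_ranks <- function(d) {
  n <- nrow(d)
  r <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(d[i, others])]   # stable sort: ties by animal order
    r[i, ord] <- seq_along(ord)
  }
  r
}

# direct loop evaluation of the indegree-outdegree cluster affinity
oracle_affinity <- function(w, ca, cb, form = "average") {
  dir_sum <- function(from, to) {
    total <- 0
    for (j in from) {
      indeg <- 0; outdeg <- 0
      for (m in to) { indeg <- indeg + w[m, j]; outdeg <- outdeg + w[j, m] }
      total <- total + (indeg / length(to)) * (outdeg / length(to))
    }
    total
  }
  a <- dir_sum(cb, ca) + dir_sum(ca, cb)
  if (form == "average") a / 2 else a
}

# maximum coordinate discrepancy after optimal rigid alignment
procrustes_resid <- function(target, points) {
  pro <- vegan::procrustes(target, points, scale = FALSE)
  max(abs(pro$X - pro$Yrot))
}

# random asymmetric closeness-like matrix (non-negative, zero diagonal)
rand_w <- function(n, seed) {
  set.seed(seed)
  w <- matrix(runif(n * n, 1, n - 1), n, n)
  diag(w) <- 0
  dimnames(w) <- list(sprintf("a%02d", 1:n), sprintf("a%02d", 1:n))
  w
}
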