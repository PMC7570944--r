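test_that("K-means separates well-separated pairs and respects its contract", {
  pts <- rbind(c(0, 0), c(0.3, 0), c(100, 0), c(100.3, 0))
  rownames(pts) <- c("A", "B", "C", "D")
  cl <- kmeans_cluster(pts, 2, seed = 1)
  expect_equal(cl$labels[["A"]], cl$labels[["B"]])
  expect_equal(cl$labels[["C"]], cl$labels[["D"]])
  expect_false(cl$labels[["A"]] == cl$labels[["C"]])
  expect_equal(cl$labels[["A"]], 1L)            # first-occurrence numbering
  expect_error(kmeans_cluster(pts, 4, seed = 1), "k")
  expect_error(kmeans_cluster(pts, 1, seed = 1), "k")
  # deterministic under a fixed seed
  expect_identical(kmeans_cluster(pts, 2, seed = 7)$labels,
                   kmeans_cluster(pts, 2, seed = 7)$labels)
})

test_that("best-of-restarts inertia beats random assignments", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 8), 10, 2))
  cl <- kmeans_cluster(pts, 2, seed = 0, restarts = 20)
  wss <- function(lab) sum(sapply(unique(lab), function(g) {
    m <- pts[lab == g, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }))
  rand_wss <- replicate(200, wss(sample(rep(1:2, 10))))
  expect_lte(cl$inertia, min(rand_wss))
})

test_that("silhouette selection finds planted cluster counts", {
  set.seed(2)
  centres <- rbind(c(0, 0), c(30, 0), c(15, 30))
  pts <- do.call(rbind, lapply(1:3, function(g)
    sweep(matrix(rnorm(6, 0, 0.5), 3, 2), 2, centres[g, ], "+")))
  rownames(pts) <- letters[1:9]
  sel <- silhouette_select_k(pts, seed = 0)
  expect_equal(sel$k, 3)
  expect_equal(length(unique(sel$clusters$labels)), 3)
  expect_true(all(sel$silhouette >= -1 & sel$silhouette <= 1))
  expect_true(sel$k %in% 2:7)
  expect_error(silhouette_select_k(pts[1:3, ]), "at least 4")
})

test_that("cluster degrees average the right rows and columns", {
  w <- example_closeness()
  dg <- cluster_degrees(w, "8", "10")
  expect_equal(unname(dg), c(2.99, 3.06))       # indegree, outdegree
  wr <- rand_w(7, seed = 8)
  cl <- c(2, 5, 7)
  dg2 <- cluster_degrees(wr, 3, cl)
  expect_equal(dg2[["indegree"]], mean(wr[cl, 3]))
  expect_equal(dg2[["outdegree"]], mean(wr[3, cl]))
  expect_error(cluster_degrees(wr, 3, integer(0)), "non-empty")
  expect_error(cluster_degrees(wr, 3, c(2, 3)), "focal")
})

test_that("cluster affinity is symmetric and matches the brute-force oracle", {
  w <- rand_w(8, seed = 13)
  ca <- c(1, 4); cb <- c(2, 6, 8)
  expect_equal(cluster_affinity(w, ca, cb), cluster_affinity(w, cb, ca))
  expect_equal(cluster_affinity(w, ca, cb), oracle_affinity(w, ca, cb))
  expect_equal(cluster_affinity(w, ca, cb, form = "sum"),
               oracle_affinity(w, ca, cb, form = "sum"))
  # singleton identity: the average form is the closeness product
  expect_equal(cluster_affinity(w, 3, 7), w[3, 7] * w[7, 3])
  expect_equal(cluster_affinity(w, 3, 7, form = "sum"), 2 * w[3, 7] * w[7, 3])
  expect_error(cluster_affinity(w, c(1, 2), c(2, 3)), "disjoint")
})

test_that("the hierarchy has N-1 structurally consistent merges", {
  w <- rand_w(2, seed = 1)
  d2 <- ahc_build(w)
  expect_equal(d2$height, w[1, 2] * w[2, 1])
  for (seed in 1:5) {
    n <- sample(4:8, 1)
    w <- rand_w(n, seed = seed + 100)
    dend <- ahc_build(w)
    expect_equal(nrow(dend$merge), n - 1)
    expect_setequal(dend$order, seq_len(n))
    expect_equal(dend$sizes[n - 1], n)
    for (s in seq_len(n - 1)) {
      mm <- dend$merge_members[[s]]
      expect_equal(dend$sizes[s], length(mm$left) + length(mm$right))
      expect_length(intersect(mm$left, mm$right), 0)
    }
  }
})

test_that("planted block structure is separated by the final merge", {
  # two groups: tiny closeness products within, large across
  set.seed(77)
  n <- 8
  w <- matrix(6, n, n)
  grp <- rep(1:2, each = 4)
  for (i in 1:n) for (j in 1:n)
    if (i != j && grp[i] == grp[j]) w[i, j] <- runif(1, 1, 2)
  diag(w) <- 0
  dimnames(w) <- list(letters[1:8], letters[1:8])
  dend <- ahc_build(w)
  last <- dend$merge_members[[n - 1]]
  expect_true(setequal(last$left, which(grp == grp[last$left[1]])))
  expect_true(setequal(last$right, setdiff(1:n, last$left)))
})

test_that("max polarity merges the largest affinity first", {
  w <- rand_w(5, seed = 55)
  dmin <- ahc_build(w)
  dmax <- ahc_build(w, polarity = "max")
  prods <- outer(1:5, 1:5, Vectorize(function(i, j)
    if (i < j) w[i, j] * w[j, i] else NA))
  expect_equal(dmin$height[1], min(prods, na.rm = TRUE))
  expect_equal(dmax$height[1], max(prods, na.rm = TRUE))
})

test_that("dendrograms convert to hclust and round-trip through Newick", {
  w <- example_closeness()
  dend <- ahc_build(w)
  hc <- as.hclust(dend)
  expect_s3_class(hc, "hclust")
  expect_equal(sort(hc$labels[hc$order]), sort(rownames(w)))
  path <- withr::local_tempfile(fileext = ".nwk")
  dendrogram_to_newick(dend, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, rownames(w))
  expect_equal(ape::Ntip(phy), 10)
  # topology survives: the first-merged pair is a cherry in the tree
  first <- rownames(w)[unlist(dend$merge_members[[1]])]
  mrca <- ape::getMRCA(phy, first)
  expect_equal(sort(ape::extract.clade(phy, mrca)$tip.label), sort(first))
  # two-leaf tree has the half-height branch shape
  w2 <- rand_w(2, seed = 2)
  dendrogram_to_newick(ahc_build(w2), path)
  phy2 <- ape::read.tree(path)
  expect_equal(unname(phy2$edge.length),
               rep(w2[1, 2] * w2[2, 1] / 2, 2))
})
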