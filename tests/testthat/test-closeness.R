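test_that("pairwise distances are Euclidean and match a double loop", {
  pos <- array(0, c(1, 2, 2))
  pos[1, 2, ] <- c(3, 4)
  ds <- trajectory_dataset(pos, c("A", "B"), 0L)
  d <- pairwise_distance_matrix(ds, 0L)
  expect_equal(d["A", "B"], 5)                       # 3-4-5 triangle
  expect_equal(diag(d), c(A = 0, B = 0))
  expect_error(pairwise_distance_matrix(ds, 99L), "not in the dataset")

  ds10 <- rand_dataset(n = 10, t = 1, seed = 3)
  d10 <- pairwise_distance_matrix(ds10, 0L)
  for (i in 1:10) for (j in 1:10)
    expect_equal(d10[i, j],
                 sqrt(sum((ds10$positions[1, i, ] - ds10$positions[1, j, ])^2)))
})

test_that("rank rows are permutations and agree with a sorting oracle", {
  for (seed in 1:20) {
    ds <- rand_dataset(n = sample(3:10, 1), t = 1, seed = seed)
    d <- pairwise_distance_matrix(ds, 0L)
    r <- rank_matrix(d)
    n <- nrow(r)
    for (i in seq_len(n))
      expect_setequal(r[i, -i], seq_len(n - 1))
    expect_equal(unname(r), oracle_ranks(d))
  }
})

test_that("distance ties rank by animal order", {
  # exactly equidistant animals: every row must follow animal order
  d <- matrix(1, 3, 3); diag(d) <- 0
  dimnames(d) <- list(c("A", "B", "C"), c("A", "B", "C"))
  r <- rank_matrix(d)
  expect_equal(unname(r), rbind(c(0, 1, 2), c(1, 0, 2), c(1, 2, 0)))
  # collinear at x = 0, 1, 3: middle animal is everyone's nearest
  d2 <- as.matrix(dist(c(0, 1, 3)))
  r2 <- rank_matrix(d2)
  expect_equal(unname(r2[1, ]), c(0, 1, 2))
  expect_equal(unname(r2[3, ]), c(2, 1, 0))
})

test_that("closeness is the time-mean of rank matrices", {
  # static herd: W equals the single-snapshot rank matrix
  ds1 <- rand_dataset(n = 6, t = 1, seed = 11)
  pos <- ds1$positions[rep(1, 40), , , drop = FALSE]
  static <- trajectory_dataset(pos, ds1$animals, 0:39)
  r <- rank_matrix(pairwise_distance_matrix(ds1, 0L))
  expect_equal(closeness_matrix(static), r + 0, ignore_attr = FALSE)

  # two timeslots: W is the elementwise mean of the two rank matrices
  ds2 <- rand_dataset(n = 7, t = 2, seed = 12)
  r1 <- rank_matrix(pairwise_distance_matrix(ds2, 0L))
  r2 <- rank_matrix(pairwise_distance_matrix(ds2, 1L))
  expect_equal(unname(closeness_matrix(ds2)), unname((r1 + r2) / 2))
})

test_that("every closeness row sums to N(N-1)/2 exactly", {
  for (seed in 1:5) {
    n <- sample(3:10, 1)
    ds <- rand_dataset(n = n, t = 25, seed = seed)
    w <- closeness_matrix(ds)
    expect_equal(unname(rowSums(w)), rep(n * (n - 1) / 2, n))
    expect_true(all(w[row(w) != col(w)] >= 1 & w[row(w) != col(w)] <= n - 1))
  }
})

test_that("permuting animal order permutes all matrices consistently", {
  ds <- rand_dataset(n = 6, t = 15, seed = 21)
  perm <- c(4, 1, 6, 2, 5, 3)
  dsp <- trajectory_dataset(ds$positions[, perm, , drop = FALSE],
                            ds$animals[perm], ds$timeslots)
  for (f in list(closeness_matrix, variation_matrix)) {
    m <- f(ds); mp <- f(dsp)
    expect_equal(unname(mp), unname(m[perm, perm]))
  }
})

test_that("variation is the population variance of reciprocal rank", {
  # constant ranks give zero dispersion
  ds1 <- rand_dataset(n = 5, t = 1, seed = 31)
  pos <- ds1$positions[rep(1, 30), , , drop = FALSE]
  static <- trajectory_dataset(pos, ds1$animals, 0:29)
  expect_true(all(variation_matrix(static) == 0))

  # rank alternating 1, 2 has variance of {1, 1/2} = 0.0625
  pos <- array(0, c(4, 3, 2))
  for (t in 1:4) {          # animal C swaps between near and far of A
    pos[t, 2, ] <- c(1, 0)
    pos[t, 3, ] <- if (t %% 2 == 1) c(0, 0.5) else c(0, 5)
  }
  ds <- trajectory_dataset(pos, c("A", "B", "C"), 0:3)
  dv <- variation_matrix(ds)
  expect_equal(dv["A", "C"], 0.0625)
  expect_equal(variation_matrix(ds, stat = "sd")["A", "C"], 0.25)
  expect_true(all(dv >= 0 & dv <= 0.25))
})

test_that("reciprocal products symmetrise asymmetric matrices", {
  w <- rand_w(6, seed = 41)
  d <- symmetric_dissimilarity(w)
  expect_identical(d, t(d))
  expect_true(all(d >= 0))
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_equal(d[2, 5], w[2, 5] * w[5, 2])
  # symmetric input: output is the elementwise square
  s <- (w + t(w)) / 2
  expect_equal(symmetric_dissimilarity(s), s * s)
  w[1, 2] <- -1
  expect_error(symmetric_dissimilarity(w), "non-negative")
})

test_that("the directed graph export round-trips the closeness matrix", {
  w <- example_closeness()
  path <- withr::local_tempfile(fileext = ".csv")
  to_weighted_graph(w, path)
  edges <- read.csv(path)
  expect_equal(nrow(edges), 90)                      # N (N - 1) edges
  expect_equal(edges$weight[edges$src == 1 & edges$dst == 2], 6.06)
  expect_equal(read_edge_list(path), w)
  w2 <- rand_w(4, seed = 5)
  to_weighted_graph(w2, path)
  expect_equal(read_edge_list(path), w2)
})
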