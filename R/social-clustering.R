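# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.embedding_points <- function(points) {
  if (inherits(points, "herd_embedding")) points$points
  else if (is.matrix(points)) points
  else stop("`points` must be a herd_embedding or a numeric matrix")
}

#' K-means clustering of embedded animals
#'
#' Best-of-`restarts` K-means (random initial centroids drawn from the data,
#' best total within-cluster sum of squares kept), deterministic for a given
#' seed. Labels are canonicalised to first-occurrence order so that the
#' numbering is reproducible.
#'
#' @param points a `herd_embedding` or an `N x d` coordinate matrix.
#' @param k number of clusters, `2 <= k <= N - 1`.
#' @param seed RNG seed (default 0).
#' @param restarts number of random restarts (default 50).
#' @return object of class `herd_clusters`: list with `labels` (named
#'   integer vector), `k`, `inertia`, `centers`.
#' @export
kmeans_cluster <- function(points, k, seed = 0, restarts = 50) {
  x <- .embedding_points(points)
  n <- nrow(x)
  if (k < 2 || k > n - 1)
    stop("`k` must satisfy 2 <= k <= N - 1 (N = ", n, ")")
  km <- .with_seed(seed, stats::kmeans(x, centers = k, nstart = restarts))
  labels <- match(km$cluster, unique(km$cluster))
  names(labels) <- rownames(x)
  structure(list(labels = labels, k = k, inertia = km$tot.withinss,
                 centers = km$centers),
            class = "herd_clusters")
}

#' @export
print.herd_clusters <- function(x, ...) {
  cat("K-means clustering: k =", x$k, " inertia =", signif(x$inertia, 6), "\n")
  for (g in seq_len(x$k))
    cat(sprintf("  cluster %d: %s\n", g,
                paste(names(x$labels)[x$labels == g], collapse = ", ")))
  invisible(x)
}

#' Select the number of clusters by silhouette analysis
#'
#' Runs [kmeans_cluster()] for every `k` in `k_range` and returns the `k`
#' maximising the mean silhouette width (Euclidean distances in the
#' embedding; singleton clusters have silhouette width 0, the
#' \pkg{cluster}-package convention). Ties go to the smaller `k`.
#'
#' @param points a `herd_embedding` or coordinate matrix with `N >= 4` rows.
#' @param k_range integer vector of candidate `k`; default
#'   `2:min(8, N - 2)`.
#' @param seed,restarts passed to [kmeans_cluster()].
#' @return list with `k` (selected), `clusters` (the `herd_clusters` at the
#'   selected `k`), and `silhouette` (named vector of mean widths per
#'   candidate `k`).
#' @export
silhouette_select_k <- function(points, k_range = NULL, seed = 0,
                                restarts = 50) {
  x <- .embedding_points(points)
  n <- nrow(x)
  if (n < 4) stop("silhouette selection needs at least 4 animals")
  if (is.null(k_range)) k_range <- 2:min(8, n - 2)
  if (any(k_range < 2 | k_range > n - 1)) stop("k_range outside [2, N - 1]")
  dd <- stats::dist(x)
  fits <- lapply(k_range, function(k)
    kmeans_cluster(x, k, seed = seed, restarts = restarts))
  widths <- vapply(fits, function(f)
    mean(cluster::silhouette(f$labels, dd)[, "sil_width"]), numeric(1))
  names(widths) <- k_range
  best <- which.max(widths)   # first maximum = smallest k on ties
  list(k = k_range[best], clusters = fits[[best]], silhouette = widths)
}

.resolve_members <- function(w, members) {
  labels <- rownames(w)
  if (is.character(members)) {
    idx <- match(members, labels)
    if (anyNA(idx)) stop("unknown animal identifier(s): ",
                         paste(members[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(members)
}

#' Average in- and outdegree of an animal with respect to a cluster
#'
#' Given the asymmetric closeness matrix `W`, the indegree of animal `i`
#' from cluster `C` is the mean of the column entries `W[j, i]` over `j` in
#' `C`, and the outdegree is the mean of the row entries `W[i, j]`. Both are
#' small when `i` habitually stays near the members of `C`.
#'
#' @param w closeness matrix.
#' @param animal focal animal (index or identifier).
#' @param members cluster members (indices or identifiers); must be
#'   non-empty and must not contain the focal animal.
#' @return named numeric vector `c(indegree, outdegree)`.
#' @export
cluster_degrees <- function(w, animal, members) {
  i <- .resolve_members(w, animal)
  cl <- .resolve_members(w, members)
  if (length(cl) == 0) stop("cluster must be non-empty")
  if (i %in% cl) stop("cluster must not contain the focal animal")
  c(indegree = mean(w[cl, i]), outdegree = mean(w[i, cl]))
}

#' Affinity between two disjoint clusters
#'
#' The affinity of animal `j` towards cluster `C` is the product of its
#' indegree and outdegree with respect to `C` (see [cluster_degrees()]).
#' The directed cluster affinity `A(Cb -> Ca)` sums this product over the
#' members of `Cb`, and the symmetric affinity adds the two directions.
#' With `form = "average"` (the default) the symmetric sum is halved, so
#' that for two singletons the affinity reduces to the closeness product
#' `W[i, j] * W[j, i]`. Under the rank convention (small = close) a small
#' affinity marks a strongly bonded pair of clusters.
#'
#' @param w closeness matrix.
#' @param ca,cb disjoint non-empty member sets (indices or identifiers).
#' @param form `"average"` (default; singleton affinity equals the
#'   closeness product) or `"sum"` (the raw two-directional sum, twice the
#'   average). A global factor of two never changes merge order.
#' @return a single numeric affinity, symmetric in `ca`, `cb`.
#' @export
cluster_affinity <- function(w, ca, cb, form = c("average", "sum")) {
  form <- match.arg(form)
  ca <- .resolve_members(w, ca); cb <- .resolve_members(w, cb)
  if (length(ca) == 0 || length(cb) == 0) stop("clusters must be non-empty")
  if (length(intersect(ca, cb)) > 0) stop("clusters must be disjoint")
  dir_aff <- function(from, to) {
    sum(vapply(from, function(j) {
      dg <- cluster_degrees(w, j, to)
      dg[["indegree"]] * dg[["outdegree"]]
    }, numeric(1)))
  }
  a <- dir_aff(cb, ca) + dir_aff(ca, cb)
  if (form == "average") a / 2 else a
}

#' Agglomerative hierarchical clustering under the indegree-outdegree affinity
#'
#' Starts from singleton clusters and repeatedly merges the pair of active
#' clusters with extremal [cluster_affinity()]. With the default polarity
#' `"min"` the most-bonded pair (smallest closeness-rank product) merges
#' first and merge heights read as dissimilarities; `"max"` preserves the
#' literal maximum-affinity rule for users who invert the rank convention.
#' Ties are broken towards the earliest pair in animal order.
#'
#' This linkage is not one of the standard reducible linkages, so heights
#' can be non-monotonic; inversions are reported via a message and rendered
#' as computed rather than forced monotone.
#'
#' @param w closeness matrix, `N >= 2`.
#' @param polarity `"min"` (default) or `"max"`.
#' @param form affinity form passed to [cluster_affinity()].
#' @return object of class `herd_dendrogram`: list with `merge` (hclust-style
#'   `(N-1) x 2` table), `height` (the affinity at each merge), `labels`,
#'   `order`, `sizes` (cluster size after each merge), `merge_members`
#'   (the member index sets joined at each step), `polarity`, `form`.
#' @seealso [as.hclust.herd_dendrogram()], [dendrogram_to_newick()]
#' @export
ahc_build <- function(w, polarity = c("min", "max"),
                      form = c("average", "sum")) {
  polarity <- match.arg(polarity); form <- match.arg(form)
  if (!is.matrix(w) || nrow(w) != ncol(w)) stop("`w` must be a square matrix")
  n <- nrow(w)
  if (n < 2) stop("need at least 2 animals")
  labels <- rownames(w)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  active <- lapply(seq_len(n), identity)    # member index sets
  node_id <- -seq_len(n)                    # hclust convention: leaves < 0
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  sizes <- integer(n - 1)
  merge_members <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(active)
    best_val <- if (polarity == "min") Inf else -Inf
    best_pair <- NULL
    for (a in seq_len(m - 1)) {
      for (b in (a + 1):m) {
        val <- cluster_affinity(w, active[[a]], active[[b]], form = form)
        better <- if (polarity == "min") val < best_val else val > best_val
        if (better) { best_val <- val; best_pair <- c(a, b) }
      }
    }
    a <- best_pair[1]; b <- best_pair[2]
    merge[step, ] <- c(node_id[a], node_id[b])
    height[step] <- best_val
    sizes[step] <- length(active[[a]]) + length(active[[b]])
    merge_members[[step]] <- list(left = active[[a]], right = active[[b]])
    active[[a]] <- c(active[[a]], active[[b]])
    node_id[a] <- step
    active[[b]] <- NULL
    node_id <- node_id[-b]
  }
  inversions <- sum(diff(height) < 0)
  if (inversions > 0)
    message(inversions, " height inversion(s): the affinity linkage is not ",
            "monotone; heights are reported as computed")
  structure(
    list(merge = merge, height = height, labels = labels,
         order = .leaf_order(merge, n), sizes = sizes,
         merge_members = merge_members, polarity = polarity, form = form),
    class = "herd_dendrogram")
}

.leaf_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1L)
}

#' @export
print.herd_dendrogram <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("Affinity dendrogram on %d animals (%s polarity, %s affinity)\n",
              n, x$polarity, x$form))
  first <- x$merge_members[[1]]
  cat(sprintf("First merge: {%s} + {%s} at height %.4f\n",
              paste(x$labels[first$left], collapse = ","),
              paste(x$labels[first$right], collapse = ","), x$height[1]))
  invisible(x)
}

#' Convert an affinity dendrogram to an hclust object
#'
#' @param x a `herd_dendrogram`.
#' @param ... ignored.
#' @return an object of class `hclust` (heights may be non-monotonic).
#' @export
as.hclust.herd_dendrogram <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = x$order,
         labels = x$labels, method = "indegree-outdegree affinity",
         call = match.call(), dist.method = "closeness-rank product"),
    class = "hclust")
}

#' Merge table of an affinity dendrogram
#'
#' @param x a `herd_dendrogram`.
#' @param ... ignored.
#' @return data frame with columns `left`, `right` (hclust node coding:
#'   negative = leaf index), `height`, `size`.
#' @export
as.data.frame.herd_dendrogram <- function(x, ...) {
  data.frame(left = x$merge[, 1], right = x$merge[, 2],
             height = x$height, size = x$sizes)
}

#' Write a dendrogram in Newick format
#'
#' Branch lengths derive from the merge heights (each child branch spans
#' half the height difference, the hclust-to-phylo convention); the result
#' parses with any standard Newick reader. Height inversions can produce
#' negative branch lengths, which Newick tolerates.
#'
#' @param dendrogram a `herd_dendrogram`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dendrogram_to_newick <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "herd_dendrogram"))
  phy <- ape::as.phylo(as.hclust(dendrogram))
  ape::write.tree(phy, file = path)
  invisible(path)
}
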