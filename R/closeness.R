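#' Pairwise Euclidean distance matrix at one timeslot
#'
#' @param dataset a [trajectory_dataset()].
#' @param t timeslot index as stored in `dataset$timeslots`.
#' @return symmetric `N x N` matrix of distances in metres, zero diagonal,
#'   labelled by animal.
#' @export
pairwise_distance_matrix <- function(dataset, t) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  ti <- match(t, dataset$timeslots)
  if (is.na(ti)) stop("timeslot ", t, " is not in the dataset")
  xy <- dataset$positions[ti, , , drop = TRUE]
  d <- as.matrix(stats::dist(xy))
  dimnames(d) <- list(dataset$animals, dataset$animals)
  d
}

#' Per-timeslot distance rank matrix
#'
#' Row `i` ranks every other animal by ascending distance from animal `i`:
#' entry `(i, j)` is the rank of `j` in `i`'s sorted distance list (1 =
#' nearest, `N - 1` = farthest). The diagonal is 0. Ties are broken by animal
#' order (the earlier identifier gets the smaller rank), which makes the
#' ranking deterministic; exact ties have probability zero for continuous
#' positions.
#'
#' @param distances symmetric numeric matrix with zero diagonal (see
#'   [pairwise_distance_matrix()]).
#' @return integer matrix of the same dimension; each off-diagonal row is a
#'   permutation of `1:(N-1)`.
#' @export
rank_matrix <- function(distances) {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances))
    stop("`distances` must be a square matrix")
  if (any(abs(diag(distances)) > 0))
    stop("`distances` must have a zero diagonal")
  n <- nrow(distances)
  r <- matrix(0L, n, n, dimnames = dimnames(distances))
  for (i in seq_len(n))
    r[i, -i] <- as.integer(rank(distances[i, -i], ties.method = "first"))
  r
}

# All per-timeslot rank matrices as a T x N x N integer array.
# Shared backend of closeness_matrix() and variation_matrix().
.rank_array <- function(dataset) {
  p <- dataset$positions
  tt <- dim(p)[1]; n <- dim(p)[2]
  out <- array(0L, c(tt, n, n))
  for (ti in seq_len(tt)) {
    d <- as.matrix(stats::dist(p[ti, , , drop = TRUE]))
    for (i in seq_len(n))
      out[ti, i, -i] <- as.integer(rank(d[i, -i], ties.method = "first"))
  }
  out
}

#' Time-averaged closeness matrix
#'
#' Entry `(i, j)` is the mean over all timeslots of the rank of animal `j`
#' in animal `i`'s distance list. Small values mean the pair habitually
#' stays close; each row sums to `N (N - 1) / 2` exactly because every
#' per-timeslot row is a permutation of `1:(N-1)`. The matrix is generally
#' asymmetric: the two animals of a pair need not value the bond equally.
#' It can be read as the edge-weight matrix of a bidirectional weighted
#' graph (see [to_weighted_graph()]).
#'
#' @param dataset a [trajectory_dataset()].
#' @param transpose if `TRUE`, return the transpose, i.e. orient rows as
#'   "attention received" rather than "i's own view". Symmetric products
#'   ([symmetric_dissimilarity()]) are unaffected by this choice.
#' @return numeric `N x N` matrix, zero diagonal, off-diagonal values in
#'   `[1, N - 1]`, labelled by animal.
#' @export
closeness_matrix <- function(dataset, transpose = FALSE) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  r <- .rank_array(dataset)
  w <- apply(r, c(2, 3), mean)
  if (transpose) w <- t(w)
  dimnames(w) <- list(dataset$animals, dataset$animals)
  w
}

#' Reciprocal-rank variation matrix
#'
#' Entry `(i, j)` is the dispersion over time of the reciprocal rank
#' `1 / R_ij(t)`, computed as the population variance
#' `mean(x^2) - mean(x)^2` (or its square root with `stat = "sd"`). A value
#' of zero means the pair's relative standing never changed; large values
#' flag unstable relationships. Since `1 / R` lies in `[1/(N-1), 1]`, the
#' variance is bounded by 0.25.
#'
#' @param dataset a [trajectory_dataset()].
#' @param stat `"variance"` (default) or `"sd"`.
#' @return numeric `N x N` matrix, zero diagonal, non-negative entries,
#'   labelled by animal.
#' @export
variation_matrix <- function(dataset, stat = c("variance", "sd")) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  stat <- match.arg(stat)
  r <- .rank_array(dataset)
  inv <- 1 / r
  inv[r == 0L] <- 0      # diagonal placeholder, excluded below
  m1 <- apply(inv, c(2, 3), mean)
  m2 <- apply(inv^2, c(2, 3), mean)
  v <- pmax(m2 - m1^2, 0)
  diag(v) <- 0
  if (stat == "sd") v <- sqrt(v)
  dimnames(v) <- list(dataset$animals, dataset$animals)
  v
}

#' Symmetrise an asymmetric matrix by reciprocal products
#'
#' Entry `(i, j)` of the result is the product of the `(i, j)` and `(j, i)`
#' entries of the input, which is symmetric by construction. Applied to a
#' closeness matrix this yields the dissimilarity fed to
#' [classical_mds()] and [ahc_build()]; applied to a variation matrix it
#' yields the dissimilarity used for repulsion analysis.
#'
#' @param asym non-negative square matrix with zero diagonal.
#' @return symmetric non-negative matrix with zero diagonal and the same
#'   labels.
#' @export
symmetric_dissimilarity <- function(asym) {
  if (!is.matrix(asym) || nrow(asym) != ncol(asym))
    stop("`asym` must be a square matrix")
  if (any(asym < 0)) stop("`asym` must be non-negative")
  if (any(abs(diag(asym)) > 0)) stop("`asym` must have a zero diagonal")
  asym * t(asym)
}

#' Export a closeness matrix as a directed weighted graph
#'
#' Writes all `N (N - 1)` directed edges `src,dst,weight` with
#' `weight = W[src, dst]`. With `format = "graphml"` the graph is written
#' through the igraph package instead.
#'
#' @param w closeness matrix (square, labelled).
#' @param path output file path.
#' @param format `"edgelist"` (CSV, default) or `"graphml"` (requires
#'   igraph).
#' @return `path`, invisibly.
#' @seealso [read_edge_list()]
#' @export
to_weighted_graph <- function(w, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (!is.matrix(w) || nrow(w) != ncol(w)) stop("`w` must be a square matrix")
  labels <- rownames(w)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(w)))
  n <- nrow(w)
  idx <- which(diag(n) == 0, arr.ind = TRUE)
  edges <- data.frame(src = labels[idx[, 1]], dst = labels[idx[, 2]],
                      weight = w[idx], stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$src, labels), match(edges$dst, labels)), ]
  if (format == "edgelist") {
    utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
  } else {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop("GraphML export needs the igraph package")
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = labels)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Rebuild a closeness matrix from an exported edge list
#'
#' @param path CSV file written by [to_weighted_graph()].
#' @return square numeric matrix with zero diagonal and the edge-list
#'   labels.
#' @export
read_edge_list <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("src", "dst", "weight") %in% names(e)))
    stop("edge list needs columns src, dst, weight")
  labels <- unique(c(e$src, e$dst))
  n <- length(labels)
  w <- matrix(0, n, n, dimnames = list(labels, labels))
  w[cbind(match(e$src, labels), match(e$dst, labels))] <- e$weight
  w
}
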