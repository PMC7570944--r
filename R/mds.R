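#' Double-centre a squared dissimilarity matrix
#'
#' Computes `B = -1/2 * C %*% (D * D) %*% C` where
#' `C = I - (1/N) * ones(N, N)` and the square is elementwise. `B` is the
#' inner-product (Gram) matrix whose spectral decomposition yields the
#' classical multidimensional scaling coordinates.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @return symmetric matrix with zero row and column sums.
#' @export
double_center <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("`d` must be a square matrix")
  if (max(abs(d - t(d))) > 1e-8) stop("`d` must be symmetric")
  n <- nrow(d)
  cmat <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * cmat %*% (d * d) %*% cmat
  (b + t(b)) / 2
}

#' Classical multidimensional scaling
#'
#' Embeds a symmetric dissimilarity matrix into `dims` abstract coordinates:
#' the Gram matrix from [double_center()] is eigendecomposed and the
#' coordinates are `eigenvector * sqrt(eigenvalue)` for the `dims`
#' algebraically largest eigenvalues. The axes have no physical meaning and
#' the configuration is defined only up to rotation and reflection;
#' comparisons against a reference layout must go through Procrustes
#' alignment.
#'
#' Rank-product dissimilarities need not be Euclidean, so retained
#' eigenvalues can be non-positive: those coordinate columns are set to zero
#' with a warning rather than taking square roots of negatives. Axis signs
#' are canonicalised so that the first nonzero loading of each retained
#' eigenvector is positive, making results reproducible across eigensolvers.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal; `N` must be
#'   at least `dims + 1`.
#' @param dims number of retained dimensions (default 2).
#' @return object of class `herd_embedding`: list with `points` (`N x dims`
#'   matrix, columns centred on zero), `eigenvalues` (the retained
#'   eigenvalues, descending), `all_eigenvalues`, and `labels`.
#' @export
classical_mds <- function(d, dims = 2) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("`d` must be a square matrix")
  n <- nrow(d)
  if (n < dims + 1) stop("need at least dims + 1 animals for the embedding")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  b <- double_center(d)
  e <- eigen(b, symmetric = TRUE)
  vals <- e$values[seq_len(dims)]
  vecs <- e$vectors[, seq_len(dims), drop = FALSE]
  for (j in seq_len(dims)) {
    nz <- which(abs(vecs[, j]) > 1e-12)
    if (length(nz) > 0 && vecs[nz[1], j] < 0) vecs[, j] <- -vecs[, j]
  }
  if (any(vals <= 0)) {
    warning("retained eigenvalue(s) <= 0; the corresponding coordinate ",
            "column is set to zero (non-Euclidean dissimilarity)")
  }
  pts <- vecs %*% diag(sqrt(pmax(vals, 0)), dims)
  dimnames(pts) <- list(labels, paste0("dim", seq_len(dims)))
  structure(
    list(points = pts, eigenvalues = vals, all_eigenvalues = e$values,
         labels = labels),
    class = "herd_embedding")
}

#' @export
print.herd_embedding <- function(x, ...) {
  cat("Classical MDS embedding:", nrow(x$points), "animals in",
      ncol(x$points), "dimensions\n")
  cat("Retained eigenvalues:",
      paste(signif(x$eigenvalues, 5), collapse = ", "), "\n")
  cat("Central animal (nearest centroid):", central_animal(x), "\n")
  invisible(x)
}

#' Scatter plot of an embedding with animal labels
#'
#' @param x a `herd_embedding`.
#' @param labels cluster labels used for plotting symbols (optional).
#' @param ... passed to [graphics::plot()].
#' @export
plot.herd_embedding <- function(x, labels = NULL, ...) {
  pch <- if (is.null(labels)) 19 else as.integer(factor(labels)) + 14L
  graphics::plot(x$points, pch = pch, asp = 1,
                 xlab = "dimension 1 (abstract)",
                 ylab = "dimension 2 (abstract)", ...)
  graphics::text(x$points, labels = x$labels, pos = 3, cex = 0.8)
  graphics::points(0, 0, pch = 3, col = "grey40")
  invisible(x)
}

#' Animal nearest the embedding centroid
#'
#' The coordinate columns of a classical MDS embedding are centred, so the
#' centroid is the origin and the most central animal -- the one whose
#' average (squared) dissimilarity to the rest of the group is smallest as
#' seen by the retained dimensions -- is the point of minimal norm. In the
#' closeness embedding this is the group's most influential individual.
#'
#' @param embedding a `herd_embedding`.
#' @return the identifier of the central animal (length-1 character).
#' @export
central_animal <- function(embedding) {
  stopifnot(inherits(embedding, "herd_embedding"))
  embedding$labels[which.min(rowSums(embedding$points^2))]
}

#' Write embedding coordinates as CSV
#'
#' @param embedding a `herd_embedding`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_embedding_csv <- function(embedding, path) {
  stopifnot(inherits(embedding, "herd_embedding"))
  df <- data.frame(animal = embedding$labels, embedding$points,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
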