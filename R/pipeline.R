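#' Bundled ten-cattle closeness matrix
#'
#' The package's worked example: the published time-averaged closeness
#' matrix of ten yearling cattle recorded for 25 minutes at 10 Hz in a
#' 150 x 50 m paddock (17,933 valid timeslots). Values are mean distance
#' ranks, printed to two decimals; each row sums to 45 = N(N-1)/2 up to
#' rounding. Small entries mean the row animal habitually stayed near the
#' column animal.
#'
#' @return a 10 x 10 numeric matrix with animal labels `"1"`..`"10"`.
#' @seealso [verify_table1()]
#' @export
example_closeness <- function() {
  read_matrix_csv(system.file("extdata", "cattle10_closeness.csv",
                              package = "herdrank", mustWork = TRUE))
}

#' Validate a closeness-matrix fixture
#'
#' Checks the structural invariants a time-averaged rank matrix must
#' satisfy -- each row sums to `N(N-1)/2` within `tol`, off-diagonal
#' entries lie in `[1, N-1]` up to printing precision, the diagonal is
#' zero -- and reports the headline analysis results: the animal nearest
#' the MDS centroid and the first pair merged by the affinity hierarchy.
#' Column sums are reported too; they need not sum to `N(N-1)/2` because
#' the matrix is asymmetric.
#'
#' @param path labelled matrix CSV; defaults to the bundled ten-cattle
#'   example.
#' @param tol row-sum tolerance (default 0.05, the rounding budget of a
#'   two-decimal table).
#' @return object of class `table1_report`: list with `pass`, `row_sums`,
#'   `col_sums`, `central_animal`, `first_merge` (pair of labels),
#'   `first_merge_height`, `failures` (character vector, empty on pass).
#' @export
verify_table1 <- function(path = NULL, tol = 0.05) {
  w <- if (is.null(path)) example_closeness() else read_matrix_csv(path)
  n <- nrow(w)
  expected <- n * (n - 1) / 2
  failures <- character(0)
  rs <- rowSums(w); cs <- colSums(w)
  if (any(abs(rs - expected) > tol))
    failures <- c(failures, sprintf(
      "row sum(s) deviate from %g by more than %g (worst %.3f)",
      expected, tol, max(abs(rs - expected))))
  off <- w[row(w) != col(w)]
  if (any(off < 1 - 0.005 | off > (n - 1) + 0.005))
    failures <- c(failures, sprintf(
      "off-diagonal entries outside [1, %d]", n - 1))
  if (any(abs(diag(w)) > 0))
    failures <- c(failures, "nonzero diagonal")
  emb <- classical_mds(symmetric_dissimilarity(w))
  dend <- ahc_build(w)
  first <- dend$merge_members[[1]]
  structure(
    list(pass = length(failures) == 0, row_sums = rs, col_sums = cs,
         central_animal = central_animal(emb),
         first_merge = rownames(w)[c(first$left, first$right)],
         first_merge_height = dend$height[1],
         failures = failures),
    class = "table1_report")
}

#' @export
print.table1_report <- function(x, ...) {
  cat("Closeness fixture check:", if (x$pass) "PASS" else "FAIL", "\n")
  if (!x$pass) for (f in x$failures) cat("  !", f, "\n")
  cat(sprintf("  row sums: %.2f .. %.2f | column sums: %.2f .. %.2f%s\n",
              min(x$row_sums), max(x$row_sums),
              min(x$col_sums), max(x$col_sums),
              if (max(abs(x$col_sums - mean(x$row_sums))) > 0.05)
                " (asymmetric, as expected)" else ""))
  cat("  MDS-central animal:", x$central_animal, "\n")
  cat(sprintf("  first affinity merge: {%s, %s} at height %.4f\n",
              x$first_merge[1], x$first_merge[2], x$first_merge_height))
  invisible(x)
}

#' Run the complete analysis pipeline
#'
#' Orchestrates every stage on either a trajectory dataset or a
#' ready-made closeness matrix and writes all artifacts plus a JSON run
#' manifest into `out_dir`. From a dataset the stages are: closeness and
#' variation matrices, their product-symmetrised dissimilarities, MDS
#' embeddings of both, K-means clustering (silhouette-selected or fixed
#' k), the affinity dendrogram (Newick + merge table), the directed
#' closeness graph, and the spatial herd statistics. From a closeness
#' matrix the rank and spatial stages are skipped.
#'
#' @param dataset a [trajectory_dataset()], or `NULL` when starting from a
#'   closeness matrix.
#' @param closeness an `N x N` closeness matrix; computed from `dataset`
#'   when omitted.
#' @param out_dir output directory (created).
#' @param k_policy `"silhouette"` (default) or `"fixed"`.
#' @param k_social number of social clusters when `k_policy = "fixed"`.
#' @param k_spatial clusters for the per-timeslot spatial K-means
#'   (default 4).
#' @param stride snapshot spacing in timeslots (default 1500).
#' @param seed RNG seed used by every stochastic stage (default 0).
#' @param restarts K-means restarts for the social clustering (default 50).
#' @return (invisibly) a named list of the artifact paths written.
#' @export
run_full_analysis <- function(dataset = NULL, closeness = NULL,
                              out_dir = "herdrank-run",
                              k_policy = c("silhouette", "fixed"),
                              k_social = 4, k_spatial = 4, stride = 1500,
                              seed = 0, restarts = 50) {
  k_policy <- match.arg(k_policy)
  if (is.null(dataset) && is.null(closeness))
    stop("provide a dataset or a closeness matrix")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  put <- function(name, file) { paths[[name]] <<- file.path(out_dir, file) }

  if (!is.null(dataset)) {
    stopifnot(inherits(dataset, "trajectory_dataset"))
    if (is.null(closeness)) closeness <- closeness_matrix(dataset)
  }
  put("closeness", "closeness.csv")
  write_matrix_csv(closeness, paths$closeness)
  put("graph", "closeness_edges.csv")
  to_weighted_graph(closeness, paths$graph)

  d_close <- symmetric_dissimilarity(closeness)
  put("dissimilarity_closeness", "dissimilarity_closeness.csv")
  write_matrix_csv(d_close, paths$dissimilarity_closeness)
  emb <- classical_mds(d_close)
  put("embedding_closeness", "embedding_closeness.csv")
  write_embedding_csv(emb, paths$embedding_closeness)

  clusters <- if (k_policy == "silhouette")
    silhouette_select_k(emb, seed = seed, restarts = restarts)$clusters
  else kmeans_cluster(emb, k_social, seed = seed, restarts = restarts)
  put("clusters", "clusters.csv")
  utils::write.csv(
    data.frame(animal = names(clusters$labels),
               cluster = as.integer(clusters$labels)),
    paths$clusters, row.names = FALSE, quote = FALSE)

  dend <- ahc_build(closeness)
  put("dendrogram", "dendrogram.newick")
  dendrogram_to_newick(dend, paths$dendrogram)
  put("merge_table", "merge_table.csv")
  utils::write.csv(as.data.frame(dend), paths$merge_table,
                   row.names = FALSE, quote = FALSE)

  if (!is.null(dataset)) {
    dv <- variation_matrix(dataset)
    put("variation", "variation.csv")
    write_matrix_csv(dv, paths$variation)
    d_var <- symmetric_dissimilarity(dv)
    put("dissimilarity_variation", "dissimilarity_variation.csv")
    write_matrix_csv(d_var, paths$dissimilarity_variation, digits = 8)
    put("embedding_variation", "embedding_variation.csv")
    write_embedding_csv(classical_mds(d_var), paths$embedding_variation)

    stats <- herd_statistics(dataset, k = k_spatial, seed = seed)
    write_herd_stats(stats, out_dir)
    put("alone", "alone.csv"); put("comembership", "comembership.csv")
    put("size_profile", "size_profile.csv")

    snaps <- snapshot_series(dataset, stride = stride, k = k_spatial,
                             seed = seed)
    snap_df <- do.call(rbind, lapply(snaps, function(s)
      data.frame(timeslot = s$timeslot, animal = names(s$labels),
                 cluster = as.integer(s$labels),
                 connector = names(s$labels) %in% s$connectors)))
    put("snapshots", "snapshots.csv")
    utils::write.csv(snap_df, paths$snapshots, row.names = FALSE,
                     quote = FALSE)
  }

  manifest <- list(
    package = "herdrank",
    version = as.character(utils::packageVersion("herdrank")),
    seed = seed,
    parameters = list(k_policy = k_policy, k_social = k_social,
                      k_spatial = k_spatial, stride = stride,
                      restarts = restarts,
                      central_animal = central_animal(emb),
                      selected_k = clusters$k),
    artifacts = lapply(paths, basename))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths$manifest <- manifest_path
  invisible(paths)
}
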