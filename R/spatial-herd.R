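# K-means guarded against coincident animals and unlucky initialisations.
# Returns canonicalised labels (first-occurrence order).
.kmeans_positions <- function(xy, k, seed, restarts) {
  uniq <- unique(round(xy, 12))
  distinct <- nrow(uniq)
  keff <- min(k, distinct)
  if (keff == 1L) {
    labels <- rep(1L, nrow(xy))
  } else if (keff == distinct) {
    # one cluster per distinct location: trivially the optimal partition
    labels <- match(
      apply(round(xy, 12), 1, paste, collapse = ","),
      unique(apply(round(xy, 12), 1, paste, collapse = ",")))
  } else {
    km <- NULL
    for (attempt in 0:4) {
      km <- tryCatch(
        .with_seed(seed + attempt,
                   stats::kmeans(xy, centers = keff, nstart = restarts)),
        error = function(e) NULL)
      if (!is.null(km)) break
    }
    if (is.null(km)) stop("K-means failed on a degenerate snapshot")
    labels <- match(km$cluster, unique(km$cluster))
  }
  labels
}

#' Spatial K-means clustering of one timeslot
#'
#' Clusters the `N` physical positions at timeslot `t` into (at most) `k`
#' groups of animals standing close together, and identifies each cluster's
#' "connector": the member nearest the cluster centroid (ties broken by
#' animal order). When fewer than `k` distinct positions exist the
#' effective number of clusters is reduced accordingly.
#'
#' The RNG is re-seeded deterministically per timeslot (`seed + t`) so that
#' whole-experiment sweeps are reproducible without artificially correlating
#' consecutive snapshots.
#'
#' @param dataset a [trajectory_dataset()].
#' @param t timeslot (a value of `dataset$timeslots`).
#' @param k requested number of clusters (default 4); must not exceed `N`.
#' @param seed base RNG seed (default 0).
#' @param restarts K-means restarts per snapshot (default 10).
#' @return object of class `herd_snapshot`: list with `timeslot`, `labels`
#'   (named integer vector in first-occurrence order), `centroids`
#'   (`K' x 2`, metres), `connectors` (one identifier per cluster), `k`
#'   (requested) and `k_effective`.
#' @export
snapshot_clusters <- function(dataset, t, k = 4, seed = 0, restarts = 10) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  n <- length(dataset$animals)
  if (k > n) stop("`k` must not exceed the number of animals")
  if (k < 1) stop("`k` must be at least 1")
  ti <- match(t, dataset$timeslots)
  if (is.na(ti)) stop("timeslot ", t, " is not in the dataset")
  xy <- dataset$positions[ti, , , drop = TRUE]
  labels <- .kmeans_positions(xy, k, seed + as.integer(t), restarts)
  names(labels) <- dataset$animals
  keff <- max(labels)
  centroids <- t(vapply(seq_len(keff), function(g)
    colMeans(xy[labels == g, , drop = FALSE]), numeric(2)))
  connectors <- vapply(seq_len(keff), function(g) {
    members <- which(labels == g)
    d2 <- rowSums((xy[members, , drop = FALSE] -
                     matrix(centroids[g, ], length(members), 2,
                            byrow = TRUE))^2)
    dataset$animals[members[which.min(d2)]]
  }, character(1))
  structure(
    list(timeslot = t, labels = labels, centroids = centroids,
         connectors = connectors, k = k, k_effective = keff),
    class = "herd_snapshot")
}

#' @export
print.herd_snapshot <- function(x, ...) {
  cat("Snapshot at timeslot", x$timeslot, ":", x$k_effective, "clusters\n")
  for (g in seq_len(x$k_effective))
    cat(sprintf("  cluster %d (connector %s): %s\n", g, x$connectors[g],
                paste(names(x$labels)[x$labels == g], collapse = ", ")))
  invisible(x)
}

#' Spatial clustering at regularly spaced timeslots
#'
#' Applies [snapshot_clusters()] at the first stored timeslot and every
#' `stride`-th one thereafter (by grid position, so a 10 Hz recording with
#' `stride = 1500` yields one snapshot every 150 s).
#'
#' @param dataset a [trajectory_dataset()].
#' @param stride spacing in timeslots (default 1500); `stride >= 1`.
#' @param k,seed,restarts passed to [snapshot_clusters()].
#' @return list of `herd_snapshot` objects.
#' @export
snapshot_series <- function(dataset, stride = 1500, k = 4, seed = 0,
                            restarts = 10) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  if (stride < 1) stop("`stride` must be at least 1")
  picks <- dataset$timeslots[seq(1L, length(dataset$timeslots), by = stride)]
  lapply(picks, function(t)
    snapshot_clusters(dataset, t, k = k, seed = seed, restarts = restarts))
}

#' Whole-experiment spatial herd statistics
#'
#' Runs the per-timeslot spatial K-means over every timeslot and tallies:
#' how often each animal was alone (a singleton cluster), how often each
#' pair shared a cluster, and the proportion of time each animal spent in
#' clusters of each size. High alone counts indicate social repulsion or
#' avoidance; a large co-membership row sum marks a central, influential
#' individual.
#'
#' @param dataset a [trajectory_dataset()].
#' @param k requested clusters per timeslot (default 4).
#' @param seed base RNG seed; each timeslot re-seeds with `seed + t`.
#' @param restarts K-means restarts per snapshot (default 10).
#' @return object of class `herd_stats`: list with `alone_counts` (named
#'   integer), `comembership` (`N x N` symmetric count matrix, zero
#'   diagonal), `size_profile` (`N x N` matrix of row-wise proportions,
#'   column `s` = share of timeslots spent in a cluster of size `s`),
#'   `total_timeslots`, `k`.
#' @export
herd_statistics <- function(dataset, k = 4, seed = 0, restarts = 10) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  n <- length(dataset$animals)
  if (k > n) stop("`k` must not exceed the number of animals")
  tt <- length(dataset$timeslots)
  alone <- integer(n)
  comem <- matrix(0L, n, n)
  size_counts <- matrix(0L, n, n)   # animal x cluster size
  for (ti in seq_len(tt)) {
    t <- dataset$timeslots[ti]
    xy <- dataset$positions[ti, , , drop = TRUE]
    labels <- .kmeans_positions(xy, k, seed + as.integer(t), restarts)
    csize <- tabulate(labels)[labels]
    alone <- alone + (csize == 1L)
    size_counts[cbind(seq_len(n), csize)] <-
      size_counts[cbind(seq_len(n), csize)] + 1L
    same <- outer(labels, labels, "==")
    diag(same) <- FALSE
    comem <- comem + same
  }
  dimnames(comem) <- list(dataset$animals, dataset$animals)
  names(alone) <- dataset$animals
  dimnames(size_counts) <- list(dataset$animals, seq_len(n))
  structure(
    list(alone_counts = alone, comembership = comem,
         size_profile = size_counts / tt, total_timeslots = tt, k = k),
    class = "herd_stats")
}

#' @export
print.herd_stats <- function(x, ...) {
  cat("Herd statistics over", x$total_timeslots, "timeslots (k =", x$k, ")\n")
  cat("Alone counts:\n")
  print(x$alone_counts)
  cat("Most connected animal (largest co-membership row sum):",
      names(which.max(rowSums(x$comembership))), "\n")
  invisible(x)
}

#' Write herd statistics to CSV files
#'
#' Writes `alone.csv` (animal, count), `comembership.csv` (labelled count
#' matrix) and `size_profile.csv` (animal by cluster-size proportions) into
#' a directory.
#'
#' @param stats a `herd_stats` object.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_herd_stats <- function(stats, dir) {
  stopifnot(inherits(stats, "herd_stats"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(animal = names(stats$alone_counts),
               count = as.integer(stats$alone_counts)),
    file.path(dir, "alone.csv"), row.names = FALSE, quote = FALSE)
  write_matrix_csv(stats$comembership + 0, file.path(dir, "comembership.csv"))
  df <- data.frame(animal = rownames(stats$size_profile),
                   stats$size_profile, check.names = FALSE)
  utils::write.csv(df, file.path(dir, "size_profile.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
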