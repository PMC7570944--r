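#' Configuration for the synthetic herd simulator
#'
#' Builds and validates the parameter set for [simulate_herd()]. The
#' defaults describe a "strong-effect" herd of ten animals in a 150 x 50 m
#' paddock sampled at 10 Hz: one leader, seven followers and two loners,
#' with follower attraction 0.3, loner repulsion 0.2 and 1 m per-slot step
#' noise.
#'
#' Roles:
#' * `leader` -- slow bounded random walk (step noise scaled by
#'   `leader_step_scale`); the common attractor of the herd.
#' * `follower` -- drawn towards the leader with gain `attraction` each
#'   slot. Followers assigned to a bonded subgroup share a satellite
#'   target: the leader position plus a fixed subgroup-specific offset of
#'   length `subgroup_offset`, so the subgroup grazes together slightly
#'   apart from the main knot.
#' * `loner` -- episodic: alternates between social bouts (follower
#'   dynamics) and solo bouts during which it is repelled from the herd
#'   centroid with gain `repulsion`. Bout switching is a two-state Markov
#'   process (`solo_entry_prob`, `solo_exit_prob`), so loners are alone for
#'   a substantial fraction of slots without being permanently exiled --
#'   the pattern actually seen in socially repelled livestock.
#'
#' Deterministic drifts are capped at `max_drift` metres per slot (a speed
#' limit that keeps the exponential repulsion bounded) and positions are
#' reflected at the paddock walls to avoid boundary pile-ups.
#'
#' @param n_animals number of animals (default 10).
#' @param roles character vector of per-animal roles
#'   (`"leader"`/`"follower"`/`"loner"`); default 1 leader, 7 followers,
#'   2 loners.
#' @param subgroup optional integer vector of bonded-subgroup ids
#'   (`NA` = none).
#' @param n_timeslots number of timeslots T (default 5000).
#' @param dt seconds per slot (metadata; default 0.1).
#' @param paddock width and height in metres (default `c(150, 50)`).
#' @param attraction follower gain in `[0, 1]` (default 0.3).
#' @param repulsion loner solo-bout gain `>= 0` (default 0.2).
#' @param step_noise per-slot step standard deviation in metres (default 1).
#' @param leader_step_scale leader step noise as a fraction of `step_noise`
#'   (default 0.2): the leader wanders slowly enough for the herd to track.
#' @param max_drift cap on the deterministic drift per slot, metres
#'   (default 5).
#' @param solo_entry_prob per-slot probability that a social loner starts a
#'   solo bout (default 1/600).
#' @param solo_exit_prob per-slot probability that a solo loner rejoins
#'   (default 1/400); the defaults give a stationary solo fraction of 0.4.
#' @param subgroup_offset distance in metres between the leader and a
#'   bonded subgroup's shared satellite target (default 8); offsets point
#'   in distinct directions per subgroup.
#' @param seed RNG seed (default 0).
#' @param init optional `N x 2` matrix of initial positions; default
#'   uniform in the paddock.
#' @return a validated list of class `herd_sim_config`.
#' @export
herd_sim_config <- function(n_animals = 10,
                            roles = c("leader", rep("follower", 7),
                                      rep("loner", 2)),
                            subgroup = rep(NA_integer_, n_animals),
                            n_timeslots = 5000, dt = 0.1,
                            paddock = c(150, 50),
                            attraction = 0.3, repulsion = 0.2,
                            step_noise = 1, leader_step_scale = 0.2,
                            max_drift = 5,
                            solo_entry_prob = 1 / 600,
                            solo_exit_prob = 1 / 400,
                            subgroup_offset = 8,
                            seed = 0, init = NULL) {
  if (length(roles) != n_animals) stop("`roles` must have one entry per animal")
  if (!all(roles %in% c("leader", "follower", "loner")))
    stop("roles must be leader, follower or loner")
  if (any(roles == "follower") && !any(roles == "leader"))
    stop("at least one leader is required when followers are present")
  if (attraction < 0 || attraction > 1) stop("`attraction` must be in [0, 1]")
  if (repulsion < 0) stop("`repulsion` must be >= 0")
  if (length(paddock) != 2 || any(paddock <= 0))
    stop("`paddock` must be two positive lengths (metres)")
  if (n_timeslots < 1) stop("`n_timeslots` must be at least 1")
  if (step_noise < 0) stop("`step_noise` must be >= 0")
  if (length(subgroup) != n_animals)
    stop("`subgroup` must have one entry per animal")
  if (!is.null(init)) {
    init <- as.matrix(init)
    if (!all(dim(init) == c(n_animals, 2)))
      stop("`init` must be an N x 2 matrix")
  }
  structure(
    list(n_animals = n_animals, roles = roles,
         subgroup = as.integer(subgroup),
         n_timeslots = as.integer(n_timeslots), dt = dt, paddock = paddock,
         attraction = attraction, repulsion = repulsion,
         step_noise = step_noise, leader_step_scale = leader_step_scale,
         max_drift = max_drift, solo_entry_prob = solo_entry_prob,
         solo_exit_prob = solo_exit_prob, subgroup_offset = subgroup_offset,
         seed = seed, init = init),
    class = "herd_sim_config")
}

# fold a coordinate back into [0, lim] by reflection
.reflect <- function(v, lim) {
  v <- v %% (2 * lim)
  ifelse(v > lim, 2 * lim - v, v)
}

.cap <- function(v, cap) {
  nrm <- sqrt(sum(v^2))
  if (nrm > cap) v * (cap / nrm) else v
}

#' Simulate a herd with planted social structure
#'
#' Discrete-time synchronous update of all animals under the role dynamics
#' described in [herd_sim_config()]. Identical seeds give bit-identical
#' datasets; positions stay inside the paddock at every slot.
#'
#' @param config a [herd_sim_config()].
#' @return list with `dataset` (a [trajectory_dataset()], timeslots
#'   `0:(T-1)`, animals `a01`, `a02`, ...) and `truth` (list with `roles`,
#'   `subgroup`, `leader`, `loners`, `followers` -- the planted ground
#'   truth).
#' @export
simulate_herd <- function(config = herd_sim_config()) {
  stopifnot(inherits(config, "herd_sim_config"))
  n <- config$n_animals
  tt <- config$n_timeslots
  w <- config$paddock[1]; h <- config$paddock[2]
  roles <- config$roles
  leader <- which(roles == "leader")[1]
  animals <- sprintf("a%02d", seq_len(n))
  groups <- sort(unique(config$subgroup[!is.na(config$subgroup)]))
  offsets <- if (length(groups) > 0) {
    ang <- 2 * pi * (seq_along(groups) - 1) / length(groups)
    stats::setNames(
      lapply(seq_along(groups), function(g)
        config$subgroup_offset * c(cos(ang[g]), sin(ang[g]))),
      groups)
  } else list()
  out <- array(NA_real_, c(tt, n, 2))
  .with_seed(config$seed, {
    pos <- if (is.null(config$init))
      cbind(stats::runif(n, 0, w), stats::runif(n, 0, h))
    else config$init
    solo <- rep(FALSE, n)
    out[1, , ] <- pos
    for (ti in seq_len(tt - 1L)) {
      cen <- colMeans(pos)
      new <- pos
      for (i in seq_len(n)) {
        if (roles[i] == "loner")
          solo[i] <- if (solo[i]) stats::runif(1) >= config$solo_exit_prob
                     else stats::runif(1) < config$solo_entry_prob
        target <- if (roles[i] == "leader") NULL
          else if (roles[i] == "loner" && solo[i]) NULL
          else if (!is.na(config$subgroup[i]))
            pos[leader, ] + offsets[[as.character(config$subgroup[i])]]
          else pos[leader, ]
        drift <-
          if (roles[i] == "leader") c(0, 0)
          else if (roles[i] == "loner" && solo[i])
            config$repulsion * (pos[i, ] - cen)
          else config$attraction * (target - pos[i, ])
        noise_scale <- if (roles[i] == "leader")
          config$leader_step_scale * config$step_noise else config$step_noise
        step <- stats::rnorm(2, 0, 1) * noise_scale
        new[i, ] <- pos[i, ] + .cap(drift, config$max_drift) + step
      }
      new[, 1] <- .reflect(new[, 1], w)
      new[, 2] <- .reflect(new[, 2], h)
      pos <- new
      out[ti + 1L, , ] <- pos
    }
  })
  dataset <- trajectory_dataset(out, animals, 0:(tt - 1L), dt = config$dt)
  truth <- list(roles = stats::setNames(roles, animals),
                subgroup = stats::setNames(config$subgroup, animals),
                leader = animals[leader],
                loners = animals[roles == "loner"],
                followers = animals[roles == "follower"])
  list(dataset = dataset, truth = truth)
}

# step index at which each pair of animals first shares a cluster in the
# merge sequence; returns an N x N matrix of steps
.pair_merge_step <- function(dendrogram, n) {
  step_mat <- matrix(NA_integer_, n, n)
  for (s in seq_along(dendrogram$merge_members)) {
    mm <- dendrogram$merge_members[[s]]
    for (i in mm$left) for (j in mm$right) {
      step_mat[i, j] <- s
      step_mat[j, i] <- s
    }
  }
  step_mat
}

#' Check that the pipeline recovers a planted herd structure
#'
#' Runs the full rank-closeness pipeline on a simulated dataset and
#' compares the outcome with the planted ground truth:
#'
#' * `leader_central` -- the planted leader is the animal nearest the
#'   centroid of the closeness-product MDS embedding;
#' * `loners_singleton` -- every planted loner is a singleton cluster under
#'   silhouette-selected K-means on that embedding;
#' * `loners_alone` -- the planted loners hold the largest spatial alone
#'   counts;
#' * `subgroups_first` -- (only when bonded subgroups are planted) every
#'   within-subgroup pair joins in the affinity hierarchy before any pair
#'   straddling two different subgroups.
#'
#' Failures are reported, never raised.
#'
#' @param dataset the simulated [trajectory_dataset()].
#' @param truth the ground-truth list from [simulate_herd()].
#' @param k_spatial clusters for the spatial statistics (default 4).
#' @param seed RNG seed for the clustering stages (default 0).
#' @param restarts K-means restarts (default 50 social, 10 spatial).
#' @return object of class `herd_recovery`: list with logical `checks`,
#'   `details` (central animal, selected k, alone counts, ...), and
#'   `pass` (all applicable checks true).
#' @export
recovery_report <- function(dataset, truth, k_spatial = 4, seed = 0,
                            restarts = 50) {
  w <- closeness_matrix(dataset)
  d <- symmetric_dissimilarity(w)
  emb <- classical_mds(d)
  sel <- silhouette_select_k(emb, seed = seed, restarts = restarts)
  stats <- herd_statistics(dataset, k = k_spatial, seed = seed, restarts = 10)
  dend <- ahc_build(w)

  central <- central_animal(emb)
  checks <- list(leader_central = identical(central, truth$leader))
  loners <- truth$loners
  if (length(loners) > 0) {
    sizes <- table(sel$clusters$labels)
    checks$loners_singleton <-
      all(sizes[as.character(sel$clusters$labels[loners])] == 1)
    ranked <- sort(stats$alone_counts, decreasing = TRUE)
    checks$loners_alone <-
      setequal(names(ranked)[seq_along(loners)], loners) &&
      min(stats$alone_counts[loners]) >
        max(stats$alone_counts[setdiff(names(ranked), loners)])
  }

  has_sub <- any(!is.na(truth$subgroup))
  if (has_sub) {
    n <- length(dataset$animals)
    steps <- .pair_merge_step(dend, n)
    sub <- truth$subgroup
    within <- c(); cross <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (!is.na(sub[i]) && !is.na(sub[j])) {
        if (sub[i] == sub[j]) within <- c(within, steps[i, j])
        else cross <- c(cross, steps[i, j])
      }
    }
    checks$subgroups_first <- length(within) > 0 &&
      (length(cross) == 0 || max(within) < min(cross))
  }

  structure(
    list(checks = checks,
         details = list(central_animal = central, selected_k = sel$k,
                        cluster_labels = sel$clusters$labels,
                        alone_counts = stats$alone_counts,
                        first_merge_height = dend$height[1]),
         pass = all(unlist(checks))),
    class = "herd_recovery")
}

#' @export
print.herd_recovery <- function(x, ...) {
  cat("Recovery report:", if (x$pass) "PASS" else "FAIL", "\n")
  for (nm in names(x$checks))
    cat(sprintf("  %-18s %s\n", nm, if (x$checks[[nm]]) "pass" else "FAIL"))
  cat("  central animal:", x$details$central_animal,
      " selected k:", x$details$selected_k, "\n")
  invisible(x)
}
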