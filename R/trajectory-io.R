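#' Construct a trajectory dataset
#'
#' A `trajectory_dataset` holds the planar positions of `N` animals on a
#' shared grid of `T` integer timeslots. Every (timeslot, animal) cell is
#' populated; incomplete slots must be resolved beforehand (see
#' [align_timeslots()]). The animal ordering is fixed at construction and
#' determines the row/column order of every matrix derived downstream.
#'
#' @param positions numeric array of dimension `T x N x 2` (metres); the
#'   third dimension is (x, y).
#' @param animals character vector of `N` distinct animal identifiers.
#' @param timeslots integer vector of `T` distinct, strictly increasing
#'   timeslot indices.
#' @param dt seconds per timeslot. Metadata only: no computation in the
#'   package uses it. Default 0.1 (a 10 Hz localisation system).
#' @return An object of class `trajectory_dataset` with elements
#'   `positions`, `animals`, `timeslots`, `dt`.
#' @seealso [read_positions_csv()], [align_timeslots()], [simulate_herd()]
#' @export
trajectory_dataset <- function(positions, animals, timeslots, dt = 0.1) {
  positions <- unname(positions)
  if (length(dim(positions)) != 3L || dim(positions)[3] != 2L)
    stop("`positions` must be a T x N x 2 array")
  n <- dim(positions)[2]
  tt <- dim(positions)[1]
  animals <- as.character(animals)
  timeslots <- as.integer(timeslots)
  if (length(animals) != n) stop("length(animals) must match dim(positions)[2]")
  if (length(timeslots) != tt) stop("length(timeslots) must match dim(positions)[1]")
  if (anyDuplicated(animals)) stop("animal identifiers must be distinct")
  if (anyDuplicated(timeslots)) stop("timeslots must be distinct")
  if (is.unsorted(timeslots, strictly = TRUE)) stop("timeslots must be increasing")
  if (n < 2L) stop("a trajectory dataset needs at least 2 animals")
  if (tt < 1L) stop("a trajectory dataset needs at least 1 timeslot")
  if (any(timeslots < 0L)) stop("timeslots must be non-negative")
  if (!all(is.finite(positions))) stop("coordinates must be finite")
  structure(
    list(positions = positions, animals = animals, timeslots = timeslots,
         dt = dt),
    class = "trajectory_dataset")
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  cat("Trajectory dataset:", length(x$animals), "animals x",
      length(x$timeslots), "timeslots (dt =", x$dt, "s)\n")
  cat("Animals:", paste(x$animals, collapse = ", "), "\n")
  rng <- apply(x$positions, 3, range)
  cat(sprintf("Extent: x [%.1f, %.1f] m, y [%.1f, %.1f] m\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2]))
  invisible(x)
}

#' @export
dim.trajectory_dataset <- function(x) dim(x$positions)

#' Align position records onto a complete timeslot grid
#'
#' Keeps exactly the timeslots at which all animals have a record, so that
#' every per-timeslot rank row is well defined. Duplicated (timeslot, animal)
#' pairs are resolved by keeping the last record. Dropped timeslots trigger a
#' warning; imputation is deliberately not offered.
#'
#' @param records data frame with columns `timeslot` (integer), `animal`
#'   (character), `x`, `y` (metres).
#' @param animal_order optional character vector fixing the animal ordering;
#'   defaults to lexicographic.
#' @param dt seconds per timeslot (metadata).
#' @return A [trajectory_dataset()].
#' @export
align_timeslots <- function(records, animal_order = NULL, dt = 0.1) {
  req <- c("timeslot", "animal", "x", "y")
  if (!all(req %in% names(records)))
    stop("records need columns: ", paste(req, collapse = ", "))
  records$animal <- as.character(records$animal)
  records$timeslot <- as.integer(records$timeslot)
  animals <- if (is.null(animal_order)) sort(unique(records$animal))
             else as.character(animal_order)
  if (!setequal(animals, unique(records$animal)))
    stop("`animal_order` must contain exactly the observed animal identifiers")
  # keep the last record per (timeslot, animal)
  dup <- duplicated(records[, c("timeslot", "animal")], fromLast = TRUE)
  records <- records[!dup, ]
  slot_sets <- split(records$timeslot, records$animal)
  common <- Reduce(intersect, slot_sets)
  if (length(common) == 0L)
    stop("no timeslot is populated for all animals (empty intersection)")
  all_slots <- sort(unique(records$timeslot))
  dropped <- setdiff(all_slots, common)
  if (length(dropped) > 0L)
    warning(sprintf("dropped %d of %d timeslots with incomplete coverage",
                    length(dropped), length(all_slots)))
  common <- sort(common)
  n <- length(animals); tt <- length(common)
  keep <- records[records$timeslot %in% common, ]
  ti <- match(keep$timeslot, common)
  ai <- match(keep$animal, animals)
  pos <- array(NA_real_, c(tt, n, 2))
  pos[cbind(ti, ai, 1L)] <- keep$x
  pos[cbind(ti, ai, 2L)] <- keep$y
  trajectory_dataset(pos, animals, common, dt = dt)
}

#' Read a long-format trajectory CSV
#'
#' Expects one row per (timeslot, animal) observation. Column names default
#' to `timeslot,animal,x,y` and can be remapped through `columns`. The result
#' passes through [align_timeslots()], so incomplete timeslots are dropped
#' with a warning.
#'
#' @param path CSV file path (UTF-8, decimal point).
#' @param columns named character vector mapping the canonical names
#'   `timeslot`, `animal`, `x`, `y` to the file's column names.
#' @param animal_order optional explicit animal ordering (default
#'   lexicographic).
#' @param dt seconds per timeslot (metadata).
#' @return A [trajectory_dataset()].
#' @export
read_positions_csv <- function(path,
                               columns = c(timeslot = "timeslot",
                                           animal = "animal",
                                           x = "x", y = "y"),
                               animal_order = NULL, dt = 0.1) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols) > 0L)
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  rec <- data.frame(timeslot = raw[[columns[["timeslot"]]]],
                    animal = as.character(raw[[columns[["animal"]]]]),
                    x = raw[[columns[["x"]]]],
                    y = raw[[columns[["y"]]]],
                    stringsAsFactors = FALSE)
  for (col in c("timeslot", "x", "y")) {
    v <- suppressWarnings(as.numeric(rec[[col]]))
    bad <- which(is.na(v) & !is.na(rec[[col]]))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric value in column '%s' at data row %d",
                   col, bad[1]))
    if (anyNA(v))
      stop(sprintf("missing value in column '%s' at data row %d",
                   col, which(is.na(v))[1]))
    rec[[col]] <- v
  }
  align_timeslots(rec, animal_order = animal_order, dt = dt)
}

#' Write a trajectory dataset as long-format CSV
#'
#' Inverse of [read_positions_csv()]: one `timeslot,animal,x,y` row per cell,
#' in the same dialect that the reader accepts, so that write-then-read
#' round-trips the dataset.
#'
#' @param dataset a [trajectory_dataset()].
#' @param path output file path.
#' @param digits coordinate precision in significant digits (default 10).
#' @return `path`, invisibly.
#' @export
write_positions_csv <- function(dataset, path, digits = 10) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  tt <- length(dataset$timeslots); n <- length(dataset$animals)
  df <- data.frame(
    timeslot = rep(dataset$timeslots, times = n),
    animal = rep(dataset$animals, each = tt),
    x = signif(as.vector(dataset$positions[, , 1]), digits),
    y = signif(as.vector(dataset$positions[, , 2]), digits))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a labelled square matrix as CSV
#'
#' Header row and leading column carry the animal identifiers; values are
#' printed with at least four decimal places.
#'
#' @param m square numeric matrix.
#' @param path output file path.
#' @param labels character vector of row/column labels; defaults to
#'   `rownames(m)`.
#' @param digits decimal places (default 6, minimum 4).
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path, labels = rownames(m), digits = 6) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("`m` must be a square matrix")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  if (length(labels) != nrow(m))
    stop("labels length does not match matrix dimension")
  if (digits < 4) stop("matrix CSVs keep at least 4 decimal places")
  out <- format(round(m, digits), trim = TRUE, scientific = FALSE)
  df <- data.frame(animal = labels, out, stringsAsFactors = FALSE)
  colnames(df) <- c("animal", labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labelled square matrix CSV
#'
#' @param path file written by [write_matrix_csv()] (or any CSV whose first
#'   column and header carry matching labels).
#' @return numeric matrix with `dimnames`.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) stop("matrix CSV is not square: ", path)
  if (!identical(labels, colnames(m)))
    stop("row and column labels disagree in ", path)
  storage.mode(m) <- "double"
  dimnames(m) <- list(labels, labels)
  m
}
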