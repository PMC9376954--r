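#' Cutoff-based single-linkage cluster identification
#'
#' Two peptides are directly linked when any bead of one lies within
#' `cutoff` (minimum-image distance, inclusive) of any bead of the other;
#' clusters are the connected components of this link graph. Every bead
#' (backbone, side chain, and terminal caps) participates in the contact
#' definition. The default cutoff is 0.55 nm (5.5 A).
#'
#' @param frame A `cg_frame`.
#' @param topology A `cg_topology`.
#' @param cutoff Contact distance in nm.
#' @return A `cluster_assignment`: `labels` (cluster id per peptide, 1-based,
#'   ordered by first appearance), `sizes` (peptide counts per cluster), and
#'   the frame `time`.
#' @export
find_clusters <- function(frame, topology, cutoff = 0.55) {
  nc <- topology$n_chains
  pairs <- cpp_contact_pairs(frame$pos, frame$L,
                             topology$beads$chain - 1L, cutoff)
  labels <- union_find(nc, pairs + 1L)
  sizes <- tabulate(labels)
  structure(list(labels = labels, sizes = sizes, time = frame$time,
                 cutoff = cutoff),
            class = "cluster_assignment")
}

# Connected components from an edge list; labels numbered by first appearance.
union_find <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]] # path halving
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1])
      b <- find(edges[e, 2])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (t = %g ns, cutoff %g nm): %d peptides in %d cluster(s); sizes: %s\n",
              x$time, x$cutoff, length(x$labels), length(x$sizes),
              paste(sort(x$sizes, decreasing = TRUE), collapse = " ")))
  invisible(x)
}

#' Cluster-size census of one assignment
#'
#' @param assignment A `cluster_assignment`.
#' @return Named numeric vector `n1`, `n2`, `n3`, `nc` (free monomers,
#'   dimers, trimers, and the total number of clusters of every size,
#'   monomers included).
#' @export
cluster_census <- function(assignment) {
  s <- assignment$sizes
  c(n1 = sum(s == 1), n2 = sum(s == 2), n3 = sum(s == 3), nc = length(s))
}

#' Kinetic observables from an ensemble of trajectories
#'
#' Runs the cluster analysis on every frame of every repeat and aggregates
#' the per-frame censuses into across-repeat means and standard deviations
#' of the mean. When repeats carry different time grids, each is aligned to
#' the first repeat's grid by nearest-frame lookup.
#'
#' @param trajectories A list of `cg_trajectory` objects (the repeats).
#' @param topology A `cg_topology`.
#' @param cutoff Contact distance in nm.
#' @return A `kinetic_curves` data frame with columns `time_ns`, then
#'   `<x>_mean` and `<x>_sem` for x in n1, n2, n3, nc; attribute
#'   `n_repeats`.
#' @export
curves_from_trajectories <- function(trajectories, topology, cutoff = 0.55) {
  if (length(trajectories) == 0) stop("empty trajectory ensemble")
  grid <- vapply(trajectories[[1]]$frames, `[[`, numeric(1), "time")
  census_of <- function(traj) {
    tt <- vapply(traj$frames, `[[`, numeric(1), "time")
    idx <- vapply(grid, function(g) which.min(abs(tt - g)), integer(1))
    t(vapply(idx, function(f)
      cluster_census(find_clusters(traj$frames[[f]], topology, cutoff)),
      numeric(4)))
  }
  per_rep <- lapply(trajectories, census_of)
  arr <- simplify2array(per_rep) # time x 4 x rep
  dimnames(arr) <- NULL
  R <- length(trajectories)
  mean_ <- apply(arr, c(1, 2), mean)
  sem_ <- if (R > 1) apply(arr, c(1, 2), sd) / sqrt(R) else matrix(0, length(grid), 4)
  out <- data.frame(time_ns = grid,
                    n1_mean = mean_[, 1], n1_sem = sem_[, 1],
                    n2_mean = mean_[, 2], n2_sem = sem_[, 2],
                    n3_mean = mean_[, 3], n3_sem = sem_[, 3],
                    nc_mean = mean_[, 4], nc_sem = sem_[, 4])
  rownames(out) <- NULL
  structure(out, n_repeats = R, class = c("kinetic_curves", "data.frame"))
}

#' Write kinetic curves to CSV
#'
#' Column schema: `time_ns, n1_mean, n1_sem, n2_mean, n2_sem, n3_mean,
#' n3_sem, nc_mean, nc_sem`; the repeat count is stored in a leading
#' `# n_repeats =` comment line.
#'
#' @param curves A `kinetic_curves`.
#' @param path Output path.
#' @export
write_curves_csv <- function(curves, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_repeats = %d", attr(curves, "n_repeats") %||% 1L), con)
  write.csv(as.data.frame(curves), con, row.names = FALSE)
  invisible(path)
}

#' Read kinetic curves from CSV
#'
#' @param path File written by [write_curves_csv()] (or any CSV with the
#'   same column schema).
#' @return A `kinetic_curves`.
#' @export
read_curves_csv <- function(path) {
  first <- readLines(path, n = 1)
  reps <- if (startsWith(first, "#")) {
    as.integer(sub(".*=\\s*", "", first))
  } else 1L
  df <- read.csv(path, comment.char = "#")
  need <- c("time_ns", "n1_mean", "n2_mean", "n3_mean", "nc_mean")
  if (!all(need %in% names(df)))
    stop("curve CSV must contain columns: ", paste(need, collapse = ", "))
  for (s in c("n1_sem", "n2_sem", "n3_sem", "nc_sem"))
    if (is.null(df[[s]])) df[[s]] <- 0
  structure(df, n_repeats = reps, class = c("kinetic_curves", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
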