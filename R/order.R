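# Chains are short (a few nm) relative to the box, so unwrapping a chain
# relative to its first bead via minimum image is exact.
.unwrap_chain <- function(pos, L) {
  ref <- pos[1, ]
  sweep(min_image_disp(matrix(ref, nrow(pos), 3, byrow = TRUE), pos, L),
        2, ref, `+`)
}

#' Normalized end-to-end vectors of peptides in a cluster
#'
#' For each selected peptide, the unit vector from its first to its last
#' backbone (`B`) bead; terminal caps and side chains are excluded. The
#' chain is unwrapped (minimum image) before the difference is taken.
#'
#' @param frame A `cg_frame`.
#' @param topology A `cg_topology`.
#' @param chains Integer vector of peptide (chain) indices; default all.
#' @return M x 3 matrix of unit vectors, one row per peptide.
#' @export
end_to_end_units <- function(frame, topology, chains = NULL) {
  if (is.null(chains)) chains <- seq_len(topology$n_chains)
  if (length(chains) == 0) stop("empty peptide selection")
  U <- matrix(0, length(chains), 3)
  for (m in seq_along(chains)) {
    sel <- topology$beads$chain == chains[m] & topology$beads$kind == "B"
    p <- .unwrap_chain(frame$pos[sel, , drop = FALSE], frame$L)
    v <- p[nrow(p), ] - p[1, ]
    len <- sqrt(sum(v^2))
    if (len < 1e-9)
      stop("degenerate (zero-length) end-to-end vector for peptide ", chains[m])
    U[m, ] <- v / len
  }
  U
}

#' End-to-end correlation parameter
#'
#' The directional order of a cluster:
#' `C_n = 1/(M(M-1)) * sum_{i != j} (n_i . n_j)^2`,
#' the average squared dot product over ordered pairs of distinct peptide
#' end-to-end unit vectors. Equals 1 when all chains are mutually parallel
#' or antiparallel and 1/3 in expectation for independent random
#' orientations. `method = "qtensor"` instead returns the rescaled largest
#' eigenvalue of the nematic Q-tensor, an alternative descriptor with the
#' same limits.
#'
#' @param units M x 3 matrix of unit vectors (from [end_to_end_units()]).
#' @param method `"pairwise"` (default) or `"qtensor"`.
#' @return `C_n` in `[0, 1]`; `NA` (with a warning) when M < 2.
#' @export
cn_parameter <- function(units, method = c("pairwise", "qtensor")) {
  method <- match.arg(method)
  M <- nrow(units)
  if (M < 2) {
    warning("C_n undefined for a cluster of fewer than 2 peptides")
    return(NA_real_)
  }
  G <- tcrossprod(units) # gram matrix of dot products
  if (method == "pairwise") {
    (sum(G^2) - M) / (M * (M - 1))
  } else {
    Q <- (3 * crossprod(units) / M - diag(3)) / 2
    lam <- max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
    # S in [0,1]; map to the same [1/3, 1] -> value scale as the pairwise form
    (2 * lam + 1) / 3
  }
}

#' Backbone mass centers of peptides
#'
#' Mass-weighted center of each peptide's backbone (`B`) beads, computed on
#' the minimum-image-unwrapped chain (side chains and terminal caps are
#' excluded).
#'
#' @inheritParams end_to_end_units
#' @return M x 3 matrix of centers (nm).
#' @export
backbone_centers <- function(frame, topology, chains = NULL) {
  if (is.null(chains)) chains <- seq_len(topology$n_chains)
  if (length(chains) == 0) stop("empty peptide selection")
  C <- matrix(0, length(chains), 3)
  for (m in seq_along(chains)) {
    sel <- topology$beads$chain == chains[m] & topology$beads$kind == "B"
    p <- .unwrap_chain(frame$pos[sel, , drop = FALSE], frame$L)
    w <- topology$beads$mass[sel]
    C[m, ] <- colSums(p * w) / sum(w)
  }
  C
}

#' Backbone-backbone correlation parameter
#'
#' The local positional order of a cluster. For each peptide `i`, neighbors
#' are the peptides whose backbone mass centers lie within the shell
#' `0.8 <= r <= 2.4` nm (minimum image). Over all unordered pairs `(j, k)`
#' of distinct neighbors of `i`, the absolute cosine `|u_ij . u_ik|` of the
#' unit center-to-center vectors is averaged; `C_BB` is the mean over all
#' peptides with at least two shell neighbors. Collinear neighbor lattices
#' give 1; orthogonal neighbor directions give 0.
#'
#' @param frame A `cg_frame`.
#' @param topology A `cg_topology`.
#' @param chains Peptide indices forming the cluster; default all.
#' @param shell Numeric length-2: inner and outer shell radii in nm.
#' @return `C_BB` in `[0, 1]`; `NA` (with a warning) when no peptide has
#'   two shell neighbors. Attribute `n_contributing` counts the peptides
#'   that entered the average.
#' @export
cbb_parameter <- function(frame, topology, chains = NULL,
                          shell = c(0.8, 2.4)) {
  centers <- backbone_centers(frame, topology, chains)
  M <- nrow(centers)
  L <- frame$L
  vals <- numeric(0)
  for (i in seq_len(M)) {
    d <- min_image_disp(matrix(centers[i, ], M, 3, byrow = TRUE), centers, L)
    r <- sqrt(rowSums(d^2))
    nb <- which(r >= shell[1] & r <= shell[2] & seq_len(M) != i)
    if (length(nb) < 2) next
    U <- d[nb, , drop = FALSE] / r[nb]
    G <- abs(tcrossprod(U))
    vals <- c(vals, mean(G[upper.tri(G)]))
  }
  if (length(vals) == 0) {
    warning("C_BB undefined: no peptide has >= 2 shell neighbors")
    return(structure(NA_real_, n_contributing = 0L))
  }
  structure(mean(vals), n_contributing = length(vals))
}

#' Order descriptors for every cluster of a frame
#'
#' @param frame A `cg_frame`.
#' @param topology A `cg_topology`.
#' @param assignment Optional `cluster_assignment` (computed with defaults
#'   when missing).
#' @param shell Shell radii for `C_BB` (nm).
#' @param min_size Smallest cluster size to report (default 2).
#' @return Data frame with columns `cluster`, `M`, `cn`, `cbb`.
#' @export
order_descriptors <- function(frame, topology, assignment = NULL,
                              shell = c(0.8, 2.4), min_size = 2) {
  if (is.null(assignment)) assignment <- find_clusters(frame, topology)
  ids <- which(assignment$sizes >= min_size)
  res <- lapply(ids, function(cl) {
    members <- which(assignment$labels == cl)
    cn <- cn_parameter(end_to_end_units(frame, topology, members))
    cbb <- suppressWarnings(cbb_parameter(frame, topology, members, shell))
    data.frame(cluster = cl, M = length(members), cn = cn,
               cbb = as.numeric(cbb))
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Default phase boundaries in the (C_n, C_BB) plane
#'
#' Threshold regions separating the four aggregate morphologies. These
#' boundaries are a package default fitted to the constructed geometric
#' fixtures (provenance: `"fitted to fixtures"`); they are *not* measured
#' from any published production data, and classification is
#' boundary-set-dependent by contract.
#'
#' Regions (checked in order, ties resolved toward the more ordered label):
#' single-ribbon fibril if `C_BB >= 0.8`; multi-ribbon/annular if
#' `C_n >= 0.6` and `C_BB >= 0.5`; amyloid-glass if `C_n >= 0.4` or
#' `C_BB >= 0.4`; otherwise amorphous. The four regions tile the unit
#' square without overlap.
#'
#' @return A `phase_boundaries` list of thresholds.
#' @export
phase_boundaries <- function() {
  structure(
    list(single_ribbon_cbb = 0.8,
         multi_cn = 0.6, multi_cbb = 0.5,
         glass_cn = 0.4, glass_cbb = 0.4,
         provenance = "fitted to fixtures"),
    class = "phase_boundaries"
  )
}

#' Classify aggregate morphology from the order descriptors
#'
#' Deterministic region lookup in the (C_n, C_BB) plane. Labels:
#' `"single-ribbon"`, `"multi-ribbon/annular"`, `"amyloid-glass"`,
#' `"amorphous"`; undefined descriptors give `"unclassified"`.
#'
#' @param cn,cbb Descriptor values (vectorized).
#' @param boundaries A [phase_boundaries()] set.
#' @return Character vector of labels.
#' @export
classify_phase <- function(cn, cbb, boundaries = phase_boundaries()) {
  b <- boundaries
  mapply(function(x, y) {
    if (is.na(x) || is.na(y)) return("unclassified")
    if (y >= b$single_ribbon_cbb) return("single-ribbon")
    if (x >= b$multi_cn && y >= b$multi_cbb) return("multi-ribbon/annular")
    if (x >= b$glass_cn || y >= b$glass_cbb) return("amyloid-glass")
    "amorphous"
  }, cn, cbb, USE.NAMES = FALSE)
}

#' Windowed potential-energy statistics of a trajectory
#'
#' Per-frame total potential energy (with the model's term breakdown)
#' over a frame window, with its mean and standard deviation. Used to
#' characterize the energetics of final aggregates.
#'
#' @param trajectory A `cg_trajectory`.
#' @param topology A `cg_topology`.
#' @param ff A `cg_forcefield`.
#' @param window Integer frame indices (default: all frames).
#' @return List with `mean`, `sd`, `energies` (per frame), `times`.
#' @export
aggregate_energy_series <- function(trajectory, topology, ff, window = NULL) {
  if (is.null(window)) window <- seq_along(trajectory$frames)
  if (length(window) == 0) stop("empty frame window")
  e <- vapply(window, function(f)
    suppressWarnings(system_energy_forces(trajectory$frames[[f]], topology,
                                          ff))$energy$total, numeric(1))
  list(mean = mean(e), sd = if (length(e) > 1) sd(e) else 0, energies = e,
       times = vapply(trajectory$frames[window], `[[`, numeric(1), "time"))
}
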