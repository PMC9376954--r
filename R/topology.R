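#' Build the bead topology for a multi-chain peptide system
#'
#' Each chain of `n_residues` residues carries one backbone bead `B` and one
#' side-chain bead `S` per residue plus two terminal caps: `TN` bonded to the
#' first backbone bead and `TC` bonded to the last (2n + 2 beads per chain).
#' Bonds: (n-1) backbone `BB`, two terminal `BT`, n side-chain `BS`.
#' Angles: (n-2) `BBB` along the backbone and, for each side chain `S_i`, one
#' `BBS` angle with every existing backbone neighbor of `B_i` (two for
#' interior residues, one at the chain ends; 2(n-1) in total). Terminal caps
#' take part in no angle term. Nonbonded exclusions are exactly the bonded
#' pairs; 1-3 pairs interact through the Lennard-Jones terms.
#'
#' @param n_residues Residues per chain (>= 2).
#' @param n_chains Number of identical chains (>= 1).
#' @param mass Bead mass in amu (uniform).
#' @return A `cg_topology`: data frames `beads` (id, kind, chain, residue,
#'   mass), `bonds` (i, j, class, chain), `angles` (i, j, k, class, chain;
#'   j is the vertex), and `exclusions` (the bonded pairs).
#' @examples
#' top <- build_topology(8, 1)
#' nrow(top$beads)  # 18
#' @export
build_topology <- function(n_residues, n_chains = 1, mass = 72) {
  if (!is.numeric(n_residues) || n_residues < 2)
    stop("n_residues must be >= 2 (no backbone angle is definable otherwise)")
  if (!is.numeric(n_chains) || n_chains < 1)
    stop("n_chains must be >= 1")
  n <- as.integer(n_residues)
  nc <- as.integer(n_chains)
  per <- 2L * n + 2L

  # single-chain template, ids 1..per: TN, B1, S1, B2, S2, ..., Bn, Sn, TC
  B <- function(i) 2L * i
  S <- function(i) 2L * i + 1L
  kind <- c("TN", rep(c("B", "S"), n), "TC")
  residue <- c(1L, rep(seq_len(n), each = 2L), n)

  bi <- cbind(B(seq_len(n - 1L)), B(seq_len(n - 1L) + 1L))
  bonds1 <- rbind(
    data.frame(i = bi[, 1], j = bi[, 2], class = "BB"),
    data.frame(i = c(1L, B(n)), j = c(B(1L), per), class = "BT"),
    data.frame(i = B(seq_len(n)), j = S(seq_len(n)), class = "BS")
  )

  ang_bbb <- if (n >= 3) {
    i <- seq.int(2L, n - 1L)
    data.frame(i = B(i - 1L), j = B(i), k = B(i + 1L), class = "BBB")
  } else {
    data.frame(i = integer(), j = integer(), k = integer(), class = character())
  }
  left <- seq.int(2L, n)     # S_i with backbone neighbor B_{i-1}
  right <- seq_len(n - 1L)   # S_i with backbone neighbor B_{i+1}
  ang_bbs <- rbind(
    data.frame(i = B(left - 1L), j = B(left), k = S(left), class = "BBS"),
    data.frame(i = B(right + 1L), j = B(right), k = S(right), class = "BBS")
  )
  angles1 <- rbind(ang_bbb, ang_bbs)

  off <- rep((seq_len(nc) - 1L) * per, each = nrow(bonds1))
  bonds <- data.frame(
    i = rep(bonds1$i, nc) + off,
    j = rep(bonds1$j, nc) + off,
    class = rep(bonds1$class, nc),
    chain = rep(seq_len(nc), each = nrow(bonds1))
  )
  offa <- rep((seq_len(nc) - 1L) * per, each = nrow(angles1))
  angles <- data.frame(
    i = rep(angles1$i, nc) + offa,
    j = rep(angles1$j, nc) + offa,
    k = rep(angles1$k, nc) + offa,
    class = rep(angles1$class, nc),
    chain = rep(seq_len(nc), each = nrow(angles1))
  )
  beads <- data.frame(
    id = seq_len(per * nc),
    kind = rep(kind, nc),
    chain = rep(seq_len(nc), each = per),
    residue = rep(residue, nc),
    mass = mass
  )

  structure(
    list(
      beads = beads, bonds = bonds, angles = angles,
      exclusions = bonds[, c("i", "j")],
      n_residues = n, n_chains = nc, beads_per_chain = per
    ),
    class = "cg_topology"
  )
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("cg_topology: %d chain(s) x %d residues; %d beads, %d bonds, %d angles\n",
              x$n_chains, x$n_residues, nrow(x$beads), nrow(x$bonds),
              nrow(x$angles)))
  invisible(x)
}

#' Create a coordinate frame
#'
#' A frame holds unwrapped bead positions (nm), optional velocities (nm/ps),
#' the cubic box edge `L` (nm), and a time stamp (ns). Coordinates may lie
#' outside `[0, L)`; every distance computation applies the minimum-image
#' convention.
#'
#' @param positions Numeric n x 3 matrix (nm).
#' @param L Cubic box edge in nm (> 0).
#' @param velocities Optional n x 3 matrix (nm/ps).
#' @param time Time stamp in ns.
#' @return A `cg_frame`.
#' @export
cg_frame <- function(positions, L, velocities = NULL, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  if (!is.numeric(L) || L <= 0) stop("box edge L must be > 0")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    if (!all(dim(velocities) == dim(positions)))
      stop("velocities must match positions in shape")
  }
  structure(list(pos = positions, vel = velocities, L = L, time = time),
            class = "cg_frame")
}

#' @export
print.cg_frame <- function(x, ...) {
  cat(sprintf("cg_frame: %d beads, L = %g nm, t = %g ns%s\n", nrow(x$pos),
              x$L, x$time, if (is.null(x$vel)) "" else ", with velocities"))
  invisible(x)
}

#' Wrap coordinates into the primary box
#'
#' Positions are stored unwrapped; this utility maps them into `[0, L)` for
#' export or visualization.
#'
#' @param frame A `cg_frame`.
#' @return The frame with wrapped positions.
#' @export
wrap_frame <- function(frame) {
  frame$pos <- frame$pos - frame$L * floor(frame$pos / frame$L)
  frame
}

# Displacement of points b relative to a under the minimum-image convention.
min_image_disp <- function(a, b, L) {
  d <- b - a
  d - L * round(d / L)
}
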