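# Assembles the C++ engine arguments from a topology + force field.
.engine_args <- function(topology, ff) {
  bk <- setNames(ff$bonds$k, ff$bonds$class)
  br <- setNames(ff$bonds$r0, ff$bonds$class)
  ak <- setNames(ff$angles$k, ff$angles$class)
  a0 <- setNames(ff$angles$theta0, ff$angles$class)
  if (ff$angle_form != "cosine")
    stop("the compiled engine implements the cosine-harmonic angle form; ",
         "use angle_energy(..., form = 'harmonic') for pointwise evaluation")
  if (ff$repulsive_form != "lj12")
    stop("the compiled engine implements the lj12 terminus repulsion")
  list(
    bonds = cbind(topology$bonds$i, topology$bonds$j) - 1L,
    bond_k = unname(bk[topology$bonds$class]),
    bond_r0 = unname(br[topology$bonds$class]),
    angles = cbind(topology$angles$i, topology$angles$j, topology$angles$k) - 1L,
    ang_k = unname(ak[topology$angles$class]),
    ang_cos0 = unname(cos(a0[topology$angles$class] * pi / 180)),
    kind = .kind_code(topology$beads$kind) - 1L,
    sig = ff$nonbonded$sigma,
    eps = ff$nonbonded$epsilon,
    rep = matrix(as.integer(ff$nonbonded$repulsive), 4, 4)
  )
}

#' System potential energy and forces
#'
#' Evaluates the total potential energy (with a per-term breakdown: bond,
#' angle, Lennard-Jones, repulsive terminus term) and the analytic forces,
#' the exact negative gradient of the implemented energy. Nonbonded terms
#' skip exactly the bonded (excluded) pairs, use the minimum-image convention
#' for every distance, and are truncated (and by default shifted to zero) at
#' the force-field cutoff. Identical-terminus pairs use the repulsive-only
#' form; every other pair the standard 12-6 potential.
#'
#' @param frame A `cg_frame` consistent with `topology`.
#' @param topology A `cg_topology`.
#' @param ff A `cg_forcefield`.
#' @param bonded_only Logical; if `TRUE` all nonbonded terms are skipped.
#' @return A list with `energy` (named: bond, angle, lj, replj, total),
#'   `forces` (n x 3, kJ mol^-1 nm^-1), and `overlap` (`TRUE` when any
#'   nonbonded pair is closer than the 0.05 nm hard floor; the energy is
#'   still returned, with a warning).
#' @export
system_energy_forces <- function(frame, topology, ff, bonded_only = FALSE) {
  if (nrow(frame$pos) != nrow(topology$beads))
    stop("frame has ", nrow(frame$pos), " beads but topology describes ",
         nrow(topology$beads))
  a <- .engine_args(topology, ff)
  out <- cpp_energy_forces(frame$pos, frame$L, a$bonds, a$bond_k, a$bond_r0,
                           a$angles, a$ang_k, a$ang_cos0, a$kind, a$sig,
                           a$eps, a$rep, ff$cutoff, ff$shift, bonded_only)
  overlap <- isTRUE(!bonded_only && is.finite(out$min_nonbonded_dist) &&
                      out$min_nonbonded_dist < 0.05)
  if (overlap)
    warning(sprintf("overlapping beads: closest nonbonded pair at %.4f nm",
                    out$min_nonbonded_dist))
  list(
    energy = list(bond = out$bond, angle = out$angle, lj = out$lj,
                  replj = out$replj, total = out$total),
    forces = out$forces,
    overlap = overlap
  )
}
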