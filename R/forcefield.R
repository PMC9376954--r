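#' Construct the two-bead peptide force field
#'
#' Builds the full parameter set of the minimal two-beads-per-residue peptide
#' model: harmonic bonds, cosine-harmonic angles, and the Lennard-Jones
#' nonbonded matrix over the four bead kinds (backbone `B`, side chain `S`,
#' N-terminal cap `TN`, C-terminal cap `TC`). All constants except the two
#' scan parameters are fixed:
#'
#' * bonds: `k_BB = k_BT = 1250` kJ mol^-1 nm^-2 with `r0 = 0.35` nm,
#'   `k_BS = 5000` kJ mol^-1 nm^-2 with `r0 = r0_BS` (scanned, 0.40-0.70 nm);
#' * angles: `theta0_BBB = 150` deg, `theta0_BBS = 105` deg,
#'   `k_theta = 1000` kJ/mol for both;
#' * nonbonded: `sigma_BB = 0.47` nm, `eps_BB = 4.5`, `eps_BS = 2.0`,
#'   `eps_SS = 1.0`, all terminal sigmas `0.40` nm with `eps_ST = eps_BT =
#'   0.5`; opposite termini attract with `eps = 4.0` while identical termini
#'   (`TN`-`TN`, `TC`-`TC`) interact through a purely repulsive `r^-12` term
#'   with `eps = 4.0` (mimicking like-charge repulsion of charged ends).
#'
#' `sigma_SS` is the second scan parameter (0.37-0.45 nm). `sigma_BS` is
#' derived by the arithmetic-mean combination rule
#' `(sigma_BB + sigma_SS) / 2` (configurable via `combine`).
#'
#' @param sigma_SS Side-chain Lennard-Jones radius in nm (scanned parameter).
#' @param r0_BS Equilibrium backbone-side-chain bond length in nm (scanned).
#' @param cutoff Nonbonded cutoff in nm. The potential is shifted to zero at
#'   the cutoff when `shift = TRUE`.
#' @param shift Logical; shift nonbonded potentials to zero at the cutoff.
#' @param combine Combination rule for `sigma_BS`: `"arithmetic"` (default)
#'   or `"geometric"`.
#' @param angle_form `"cosine"` (default) for `V = k/2 (cos t - cos t0)^2`,
#'   or `"harmonic"` for `V = k/2 (t - t0)^2` with `t` in radians.
#' @param repulsive_form `"lj12"` (default) for the `4 eps (sigma/r)^12` term
#'   between identical termini, or `"wca"` for the Weeks-Chandler-Andersen
#'   cut-and-shifted alternative.
#' @param mass Bead mass in amu (same for every bead; MARTINI-standard 72).
#' @return An object of class `cg_forcefield`.
#' @examples
#' ff <- default_forcefield(sigma_SS = 0.41, r0_BS = 0.55)
#' ff$nonbonded$sigma["B", "S"]  # arithmetic mean of 0.47 and 0.41
#' @export
default_forcefield <- function(sigma_SS = 0.41, r0_BS = 0.55, cutoff = 1.2,
                               shift = TRUE,
                               combine = c("arithmetic", "geometric"),
                               angle_form = c("cosine", "harmonic"),
                               repulsive_form = c("lj12", "wca"),
                               mass = 72) {
  if (!is.numeric(sigma_SS) || length(sigma_SS) != 1 || sigma_SS <= 0)
    stop("sigma_SS must be a single positive number (nm)")
  if (!is.numeric(r0_BS) || length(r0_BS) != 1 || r0_BS <= 0)
    stop("r0_BS must be a single positive number (nm)")
  combine <- match.arg(combine)
  angle_form <- match.arg(angle_form)
  repulsive_form <- match.arg(repulsive_form)
  if (sigma_SS < 0.37 || sigma_SS > 0.45)
    message("sigma_SS = ", sigma_SS, " nm is outside the scanned range [0.37, 0.45]")
  if (r0_BS < 0.40 || r0_BS > 0.70)
    message("r0_BS = ", r0_BS, " nm is outside the scanned range [0.40, 0.70]")

  bonds <- data.frame(
    class = c("BB", "BT", "BS"),
    k = c(1250, 1250, 5000),
    r0 = c(0.35, 0.35, r0_BS),
    stringsAsFactors = FALSE
  )
  angles <- data.frame(
    class = c("BBB", "BBS"),
    k = c(1000, 1000),
    theta0 = c(150, 105),
    stringsAsFactors = FALSE
  )

  k <- .bead_kinds
  sigma <- matrix(0.40, 4, 4, dimnames = list(k, k))
  eps <- matrix(0, 4, 4, dimnames = list(k, k))
  rep <- matrix(FALSE, 4, 4, dimnames = list(k, k))

  sigma["B", "B"] <- 0.47
  sigma["S", "S"] <- sigma_SS
  sigma_BS <- switch(combine,
    arithmetic = (0.47 + sigma_SS) / 2,
    geometric = sqrt(0.47 * sigma_SS)
  )
  sigma["B", "S"] <- sigma["S", "B"] <- sigma_BS
  # every pair involving a terminal cap keeps sigma = 0.40 (preset above)

  eps["B", "B"] <- 4.5
  eps["B", "S"] <- eps["S", "B"] <- 2.0
  eps["S", "S"] <- 1.0
  eps["B", "TN"] <- eps["TN", "B"] <- 0.5
  eps["B", "TC"] <- eps["TC", "B"] <- 0.5
  eps["S", "TN"] <- eps["TN", "S"] <- 0.5
  eps["S", "TC"] <- eps["TC", "S"] <- 0.5
  eps["TN", "TC"] <- eps["TC", "TN"] <- 4.0   # opposite termini attract
  eps["TN", "TN"] <- 4.0                      # identical termini repel
  eps["TC", "TC"] <- 4.0
  rep["TN", "TN"] <- rep["TC", "TC"] <- TRUE

  structure(
    list(
      bonds = bonds, angles = angles,
      nonbonded = list(sigma = sigma, epsilon = eps, repulsive = rep),
      sigma_SS = sigma_SS, r0_BS = r0_BS,
      cutoff = cutoff, shift = shift, combine = combine,
      angle_form = angle_form, repulsive_form = repulsive_form,
      mass = mass
    ),
    class = "cg_forcefield"
  )
}

#' @export
print.cg_forcefield <- function(x, ...) {
  cat("Two-bead peptide force field\n")
  cat(sprintf("  scan parameters: sigma_SS = %.3f nm, r0_BS = %.3f nm\n",
              x$sigma_SS, x$r0_BS))
  cat(sprintf("  nonbonded cutoff %.2f nm (%s), sigma_BS rule: %s\n",
              x$cutoff, if (x$shift) "potential-shifted" else "truncated",
              x$combine))
  cat(sprintf("  angle form: %s, terminus repulsion: %s, bead mass %g amu\n",
              x$angle_form, x$repulsive_form, x$mass))
  invisible(x)
}

#' Harmonic bond potential
#'
#' `V(r) = k/2 (r - r0)^2`, the raw (untruncated) bonded term.
#'
#' @param r Distance in nm (vectorized).
#' @param k Force constant in kJ mol^-1 nm^-2.
#' @param r0 Equilibrium length in nm.
#' @return Energy in kJ/mol.
#' @export
bond_energy <- function(r, k, r0) {
  stopifnot(all(r >= 0))
  0.5 * k * (r - r0)^2
}

#' Cosine-harmonic angle potential
#'
#' `V(theta) = k/2 (cos theta - cos theta0)^2` with angles in degrees
#' (default), or the harmonic-in-angle form `k/2 (theta - theta0)^2` in
#' radians when `form = "harmonic"`.
#'
#' @param theta Angle in degrees (vectorized).
#' @param k Force constant in kJ/mol (cosine form) or kJ mol^-1 rad^-2.
#' @param theta0 Equilibrium angle in degrees.
#' @param form `"cosine"` or `"harmonic"`.
#' @return Energy in kJ/mol.
#' @export
angle_energy <- function(theta, k, theta0, form = c("cosine", "harmonic")) {
  form <- match.arg(form)
  stopifnot(all(theta >= 0 & theta <= 180))
  if (form == "cosine") {
    0.5 * k * (cos(theta * pi / 180) - cos(theta0 * pi / 180))^2
  } else {
    0.5 * k * ((theta - theta0) * pi / 180)^2
  }
}

#' Lennard-Jones 12-6 pair potential (raw form)
#'
#' `V(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6)`, untruncated. The system
#' energy routines apply the cutoff and potential shift; this raw form is
#' exposed for analysis and testing.
#'
#' @param r Distance in nm (vectorized, must be > 0).
#' @param sigma LJ radius in nm.
#' @param epsilon Well depth in kJ/mol.
#' @return Energy in kJ/mol.
#' @export
lj_pair_energy <- function(r, sigma, epsilon) {
  if (any(r <= 0)) stop("lj_pair_energy: r must be > 0 (singular at r = 0)")
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6^2 - sr6)
}

#' Purely repulsive terminus-terminus potential (raw form)
#'
#' `V(r) = 4 eps (sigma/r)^12`, the repulsion-only Lennard-Jones term used
#' between identical terminal caps (mimicking like-charge repulsion).
#' `form = "wca"` gives the Weeks-Chandler-Andersen alternative: the full LJ
#' potential cut and shifted at its minimum `2^(1/6) sigma`.
#'
#' @inheritParams lj_pair_energy
#' @param form `"lj12"` (default) or `"wca"`.
#' @return Energy in kJ/mol; strictly positive and decreasing for `"lj12"`.
#' @export
replj_pair_energy <- function(r, sigma, epsilon, form = c("lj12", "wca")) {
  form <- match.arg(form)
  if (any(r <= 0)) stop("replj_pair_energy: r must be > 0 (singular at r = 0)")
  if (form == "lj12") {
    4 * epsilon * (sigma / r)^12
  } else {
    rmin <- 2^(1 / 6) * sigma
    ifelse(r < rmin, lj_pair_energy(r, sigma, epsilon) + epsilon, 0)
  }
}

#' Serialize a force field to a flat key-value file
#'
#' Writes every parameter as `key = value` lines; [read_forcefield()] inverts
#' the operation losslessly.
#'
#' @param ff A `cg_forcefield`.
#' @param path Output file path.
#' @export
write_forcefield <- function(ff, path) {
  kv <- c(
    sprintf("sigma_SS = %.17g", ff$sigma_SS),
    sprintf("r0_BS = %.17g", ff$r0_BS),
    sprintf("cutoff = %.17g", ff$cutoff),
    sprintf("shift = %s", ff$shift),
    sprintf("combine = %s", ff$combine),
    sprintf("angle_form = %s", ff$angle_form),
    sprintf("repulsive_form = %s", ff$repulsive_form),
    sprintf("mass = %.17g", ff$mass)
  )
  writeLines(kv, path)
  invisible(path)
}

#' Read a force field from a flat key-value file
#'
#' @param path File written by [write_forcefield()].
#' @return A `cg_forcefield`.
#' @export
read_forcefield <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(parts, `[[`, "", 1))
  vals <- trimws(vapply(parts, `[[`, "", 2))
  kv <- setNames(as.list(vals), keys)
  default_forcefield(
    sigma_SS = as.numeric(kv$sigma_SS), r0_BS = as.numeric(kv$r0_BS),
    cutoff = as.numeric(kv$cutoff), shift = as.logical(kv$shift),
    combine = kv$combine, angle_form = kv$angle_form,
    repulsive_form = kv$repulsive_form, mass = as.numeric(kv$mass)
  )
}

#' Export a GROMACS-dialect topology file (convenience)
#'
#' Writes an `.itp`-like text file (atoms, bonds, angles, pair types) for a
#' single chain, for cross-checking the model in GROMACS-aware tools. This is
#' a convenience export, not a validated GROMACS input.
#'
#' @param topology A `cg_topology` (single chain is exported).
#' @param ff A `cg_forcefield`.
#' @param path Output path.
#' @export
write_itp <- function(topology, ff, path) {
  b <- topology$beads[topology$beads$chain == 1, ]
  bonds <- topology$bonds[topology$bonds$chain == 1, ]
  angles <- topology$angles[topology$angles$chain == 1, ]
  bk <- setNames(ff$bonds$k, ff$bonds$class)
  br <- setNames(ff$bonds$r0, ff$bonds$class)
  ak <- setNames(ff$angles$k, ff$angles$class)
  a0 <- setNames(ff$angles$theta0, ff$angles$class)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("; two-bead peptide model, convenience export", con)
  writeLines("[ moleculetype ]", con)
  writeLines("PEP   1", con)
  writeLines("[ atoms ]", con)
  for (i in seq_len(nrow(b)))
    writeLines(sprintf("%5d %4s %5d PEP %4s %5d 0.0 %8.3f",
                       i, b$kind[i], b$residue[i], b$kind[i], i, b$mass[i]), con)
  writeLines("[ bonds ]", con)
  for (i in seq_len(nrow(bonds)))
    writeLines(sprintf("%5d %5d 1 %8.4f %10.1f", bonds$i[i], bonds$j[i],
                       br[bonds$class[i]], bk[bonds$class[i]]), con)
  writeLines("[ angles ]", con)
  for (i in seq_len(nrow(angles)))
    writeLines(sprintf("%5d %5d %5d 2 %8.2f %10.1f", angles$i[i], angles$j[i],
                       angles$k[i], a0[angles$class[i]], ak[angles$class[i]]), con)
  invisible(path)
}
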