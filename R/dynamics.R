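#' Simulation protocol settings
#'
#' Defaults follow the reference protocol of the model: 15 fs time step,
#' 303 K, inverse friction coefficient 0.17 ps (read as the GROMACS-style
#' time constant tau, with per-bead friction gamma = m / tau), cubic box of
#' edge 35 nm with periodic boundaries in all directions.
#'
#' @param n_steps Number of integration steps.
#' @param dt_fs Time step in fs.
#' @param temperature Thermostat temperature in K.
#' @param tau_ps Inverse friction coefficient (ps); `Inf` disables friction
#'   and noise, giving plain symplectic leapfrog.
#' @param L Cubic box edge in nm (used when building initial frames).
#' @param seed Integer seed. Thermal noise uses `seed`; Maxwell-Boltzmann
#'   velocity initialization uses its own stream seeded with `seed + 1`.
#' @param sample_every Store a frame every this many steps.
#' @return A `dynamics_settings` list.
#' @export
dynamics_settings <- function(n_steps, dt_fs = 15, temperature = 303,
                              tau_ps = 0.17, L = 35, seed = 1,
                              sample_every = 1000) {
  stopifnot(dt_fs > 0, tau_ps > 0, n_steps >= 1, sample_every >= 1, L > 0)
  structure(list(n_steps = as.integer(n_steps), dt_fs = dt_fs,
                 temperature = temperature, tau_ps = tau_ps, L = L,
                 seed = as.integer(seed),
                 sample_every = as.integer(sample_every)),
            class = "dynamics_settings")
}

# Single chain built at the exact bonded-energy minimum: planar backbone
# zigzag with 150 deg interior angles; each side chain sits on the exterior
# bisector at its residue, which satisfies every 105 deg BBS angle exactly
# ((360 - 150)/2 = 105). Terminal caps continue the backbone zigzag.
chain_template <- function(n_residues, ff) {
  n <- n_residues
  delta <- 15 * pi / 180
  heading <- function(i) if (i %% 2 == 1) delta else -delta # bond i, 0..n
  u <- t(vapply(0:n, function(i) c(cos(heading(i)), sin(heading(i)), 0),
                numeric(3)))  # rows: phantom bond 0, real bonds 1..n-1, phantom n
  B <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) B[i + 1, ] <- B[i, ] + 0.35 * u[i + 1, ]
  S <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    d <- -(u[i + 1, ] - u[i, ]) # exterior bisector via adjacent bond headings
    d <- d / sqrt(sum(d^2))
    S[i, ] <- B[i, ] + ff$r0_BS * d
  }
  TN <- B[1, ] - 0.35 * u[1, ]
  TC <- B[n, ] + 0.35 * u[n + 1, ]
  pos <- matrix(0, 2 * n + 2, 3)
  pos[1, ] <- TN
  pos[2 * seq_len(n), ] <- B
  pos[2 * seq_len(n) + 1, ] <- S
  pos[2 * n + 2, ] <- TC
  pos
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Place straight monomers at random positions and orientations
#'
#' Inserts `n_chains` chains, each in its straight equilibrium-geometry
#' conformation, at uniformly random center-of-mass positions and uniform
#' random orientations in a cubic box of edge `L`. No bead of a new chain
#' may come closer than `min_dist` (minimum image) to a bead of an already
#' placed chain; insertion is retried up to `max_tries` times per chain.
#'
#' @param n_chains Number of chains.
#' @param n_residues Residues per chain.
#' @param L Box edge in nm.
#' @param seed Integer seed (reproducible placement).
#' @param ff Force field (supplies `r0_BS` for the chain geometry).
#' @param min_dist Insertion floor between beads of different chains (nm).
#' @param max_tries Insertion attempts per chain before giving up.
#' @return A `cg_frame` (no velocities, time 0).
#' @export
place_monomers <- function(n_chains, n_residues, L, seed = 1,
                           ff = default_forcefield(), min_dist = 0.5,
                           max_tries = 500) {
  set.seed(seed)
  template <- chain_template(n_residues, ff)
  template <- sweep(template, 2, colMeans(template)) # center on COM
  m <- nrow(template)
  placed <- matrix(numeric(0), 0, 3)
  for (ch in seq_len(n_chains)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- template %*% t(random_rotation())
      cand <- sweep(cand, 2, runif(3, 0, L), `+`)
      if (nrow(placed) == 0) { ok <- TRUE; break }
      d2 <- .min_cross_dist2(cand, placed, L)
      if (d2 >= min_dist^2) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf(paste0("could not insert chain %d after %d tries: density ",
                          "%.4f chains/nm^3 too high for a %.2f nm floor"),
                   ch, max_tries, n_chains / L^3, min_dist))
    placed <- rbind(placed, cand)
  }
  cg_frame(placed, L = L, time = 0)
}

# squared minimum cross distance between two bead sets under minimum image
.min_cross_dist2 <- function(A, B, L) {
  d2 <- matrix(0, nrow(A), nrow(B))
  for (c in 1:3) {
    d <- outer(A[, c], B[, c], `-`)
    d <- d - L * round(d / L)
    d2 <- d2 + d * d
  }
  min(d2)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param topology A `cg_topology` (bead masses).
#' @param temperature Temperature in K.
#' @return n x 3 matrix of velocities (nm/ps). Uses the current RNG state.
#' @export
maxwell_velocities <- function(topology, temperature) {
  n <- nrow(topology$beads)
  sd_v <- sqrt(.kB * temperature / topology$beads$mass)
  matrix(rnorm(3 * n, 0, rep(sd_v, 3)), n, 3)
}

#' Instantaneous kinetic temperature
#'
#' `T = 2 KE / (3 n kB)` from bead masses and velocities.
#'
#' @param frame A `cg_frame` with velocities.
#' @param topology A `cg_topology`.
#' @return Temperature in K.
#' @export
instantaneous_temperature <- function(frame, topology) {
  if (is.null(frame$vel)) stop("frame has no velocities")
  ke <- 0.5 * sum(topology$beads$mass * rowSums(frame$vel^2))
  2 * ke / (3 * nrow(frame$pos) * .kB)
}

#' Run stochastic (Langevin) leapfrog dynamics
#'
#' Integrates the Langevin equations with a leapfrog scheme: full-step
#' deterministic kick `v <- v + F/m dt`, exact Ornstein-Uhlenbeck velocity
#' mixing `v <- a v + sqrt((1 - a^2) kB T / m) xi` with `a = exp(-dt/tau)`
#' (the fluctuation-dissipation-matched noise), then drift
#' `x <- x + v dt`. The friction+noise step doubles as the thermostat; with
#' `tau_ps = Inf` the scheme reduces to plain symplectic leapfrog.
#' Coordinates are stored unwrapped; distances always use minimum image.
#'
#' @param frame Starting `cg_frame`. If it carries no velocities they are
#'   drawn from the Maxwell-Boltzmann distribution at the run temperature
#'   (seeded with `settings$seed + 1`, a stream separate from the noise).
#' @param topology A `cg_topology`.
#' @param ff A `cg_forcefield`.
#' @param settings A [dynamics_settings()].
#' @param interactions `"full"`, `"bonded_only"`, or `"off"` (free beads;
#'   used for thermostat verification).
#' @return A `cg_trajectory`: list of sampled `cg_frame`s (positions,
#'   velocities, time stamps in ns) plus the settings used.
#' @export
run_dynamics <- function(frame, topology, ff, settings,
                         interactions = c("full", "bonded_only", "off")) {
  interactions <- match.arg(interactions)
  if (nrow(frame$pos) != nrow(topology$beads))
    stop("frame/topology size mismatch")
  vel <- frame$vel
  if (is.null(vel)) {
    set.seed(settings$seed + 1L)
    vel <- maxwell_velocities(topology, settings$temperature)
  }
  a <- .engine_args(topology, ff)
  dt_ps <- settings$dt_fs / 1000
  set.seed(settings$seed)
  out <- cpp_run_dynamics(frame$pos, vel, topology$beads$mass, frame$L,
                          a$bonds, a$bond_k, a$bond_r0, a$angles, a$ang_k,
                          a$ang_cos0, a$kind, a$sig, a$eps, a$rep, ff$cutoff,
                          ff$shift, interactions == "bonded_only",
                          interactions == "off", dt_ps, settings$tau_ps,
                          settings$temperature, settings$n_steps,
                          settings$sample_every, frame$time * 1000)
  n_frames <- length(out$times)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    frames[[f]] <- cg_frame(out$trajectory[, , f], L = frame$L,
                            velocities = out$velocities[, , f],
                            time = out$times[f] / 1000)
  }
  structure(list(frames = frames, settings = settings,
                 interactions = interactions),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  n <- length(x$frames)
  cat(sprintf("cg_trajectory: %d frames, %d beads, t = %g..%g ns\n", n,
              nrow(x$frames[[1]]$pos), x$frames[[1]]$time, x$frames[[n]]$time))
  invisible(x)
}

#' Energy minimization (steepest descent with quasi-Newton polish)
#'
#' Stage one is steepest descent with a backtracking line search: a step
#' along the force is halved until the energy does not increase, and grown
#' after each accepted step; robust far from a minimum. Because steepest
#' descent converges only linearly on the stiff bond terms, a limited-memory
#' BFGS refinement (analytic gradient) polishes the structure to the force
#' tolerance when `polish = TRUE` (default). Terminates when the largest
#' force component drops below `tol`.
#'
#' @param frame Starting `cg_frame`.
#' @param topology A `cg_topology`.
#' @param ff A `cg_forcefield`.
#' @param mode `"full"` or `"bonded_only"` (ignore all nonbonded terms).
#' @param tol Convergence threshold on the maximum force component
#'   (kJ mol^-1 nm^-1).
#' @param max_steps Steepest-descent step budget.
#' @param polish Run the L-BFGS refinement stage.
#' @return The minimized `cg_frame` with attributes `converged`, `steps`,
#'   and `energy`. If the force tolerance is not reached within the budget
#'   the best frame found is returned with a warning and
#'   `converged = FALSE`.
#' @export
minimize <- function(frame, topology, ff, mode = c("full", "bonded_only"),
                     tol = 1e-4, max_steps = 2000, polish = TRUE) {
  mode <- match.arg(mode)
  bonded_only <- mode == "bonded_only"
  x <- frame$pos
  dm <- dim(x)
  ef <- function(p) {
    fr <- frame
    fr$pos <- p
    suppressWarnings(system_energy_forces(fr, topology, ff, bonded_only))
  }
  cur <- ef(x)
  gamma <- 1e-4 # nm per (kJ mol^-1 nm^-1)
  steps <- 0L
  converged <- FALSE
  while (steps < max_steps) {
    if (max(abs(cur$forces)) < tol) { converged <- TRUE; break }
    repeat {
      trial <- x + gamma * cur$forces
      new <- ef(trial)
      if (new$energy$total <= cur$energy$total || gamma < 1e-14) break
      gamma <- gamma / 2
    }
    if (new$energy$total > cur$energy$total) break # line search stalled
    x <- trial
    cur <- new
    gamma <- gamma * 1.2
    steps <- steps + 1L
  }
  if (!converged && polish) {
    for (round in 1:5) {
      opt <- optim(as.numeric(x),
                   fn = function(v) ef(matrix(v, dm[1], dm[2]))$energy$total,
                   gr = function(v) -as.numeric(ef(matrix(v, dm[1],
                                                          dm[2]))$forces),
                   method = "L-BFGS-B",
                   control = list(maxit = 2000, factr = 1))
      x <- matrix(opt$par, dm[1], dm[2])
      cur <- ef(x)
      if (max(abs(cur$forces)) < tol) break
    }
  }
  if (max(abs(cur$forces)) < tol) converged <- TRUE
  if (!converged)
    warning(sprintf("minimize: not converged after %d steps (max |F| = %.3g)",
                    steps, max(abs(cur$forces))))
  out <- frame
  out$pos <- x
  attr(out, "converged") <- converged
  attr(out, "steps") <- steps
  attr(out, "energy") <- cur$energy
  out
}

#' Measure bond lengths and angles of a frame
#'
#' Convenience geometry report: every bond length (nm, minimum image) and
#' every angle (degrees) defined by the topology, tagged by class.
#'
#' @param frame A `cg_frame`.
#' @param topology A `cg_topology`.
#' @return A list with data frames `bonds` (class, length) and `angles`
#'   (class, theta).
#' @export
measure_geometry <- function(frame, topology) {
  p <- frame$pos
  L <- frame$L
  d <- min_image_disp(p[topology$bonds$i, , drop = FALSE],
                      p[topology$bonds$j, , drop = FALSE], L)
  blen <- sqrt(rowSums(d^2))
  a <- min_image_disp(p[topology$angles$j, , drop = FALSE],
                      p[topology$angles$i, , drop = FALSE], L)
  b <- min_image_disp(p[topology$angles$j, , drop = FALSE],
                      p[topology$angles$k, , drop = FALSE], L)
  ca <- rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  theta <- acos(pmin(1, pmax(-1, ca))) * 180 / pi
  list(bonds = data.frame(class = topology$bonds$class, length = blen),
       angles = data.frame(class = topology$angles$class, theta = theta))
}
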