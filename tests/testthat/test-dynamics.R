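test_that("monomer placement is reproducible, respects the insertion floor, and uses equilibrium geometry", {
  fr1 <- place_monomers(20, 8, L = 15, seed = 31, ff = ff_default)
  fr2 <- place_monomers(20, 8, L = 15, seed = 31, ff = ff_default)
  expect_identical(fr1$pos, fr2$pos)
  expect_equal(nrow(fr1$pos), 20 * 18)
  top <- build_topology(8, 20)
  # inter-chain floor: no two beads of different chains closer than 0.5 nm
  mind <- Inf
  for (a in 1:19) {
    A <- fr1$pos[top$beads$chain == a, ]
    for (b in (a + 1):20) {
      B <- fr1$pos[top$beads$chain == b, ]
      mind <- min(mind, fibrilsim:::.min_cross_dist2(A, B, fr1$L))
    }
  }
  expect_gte(sqrt(mind), 0.5)
  # single chain: all bonded terms at their minima
  fr <- place_monomers(1, 8, L = 35, seed = 5, ff = ff_default)
  e <- system_energy_forces(fr, build_topology(8, 1), ff_default,
                            bonded_only = TRUE)
  expect_equal(e$energy$total, 0, tolerance = 1e-18)
  # infeasible density errors out with a diagnostic
  expect_error(place_monomers(30, 8, L = 3, seed = 1, ff = ff_default,
                              max_tries = 20), "density")
})

test_that("trajectories are bit-identical for identical settings and seed", {
  fr <- place_monomers(4, 8, L = 8, seed = 2, ff = ff_default)
  top <- build_topology(8, 4)
  st <- dynamics_settings(n_steps = 500, sample_every = 100, seed = 99)
  t1 <- run_dynamics(fr, top, ff_default, st)
  t2 <- run_dynamics(fr, top, ff_default, st)
  expect_identical(t1$frames[[5]]$pos, t2$frames[[5]]$pos)
  expect_identical(t1$frames[[5]]$vel, t2$frames[[5]]$vel)
  # and time stamps follow dt * sample_every
  expect_equal(t1$frames[[2]]$time - t1$frames[[1]]$time,
               100 * 15e-6) # 100 steps of 15 fs, in ns
})

test_that("the thermostat holds non-interacting beads at the target temperature", {
  top <- build_topology(2, 100) # 600 free beads
  fr <- place_monomers(100, 2, L = 30, seed = 8, ff = ff_default)
  st <- dynamics_settings(n_steps = 3000, sample_every = 10, seed = 17)
  tr <- run_dynamics(fr, top, ff_default, st, interactions = "off")
  temps <- vapply(tr$frames, instantaneous_temperature, numeric(1),
                  topology = top)
  # discard the first tenth (velocity equilibration), then equipartition
  expect_equal(mean(temps[-(1:30)]), 303, tolerance = 0.02)
})

test_that("zero temperature with friction drains all kinetic energy", {
  top <- build_topology(2, 10)
  fr <- place_monomers(10, 2, L = 20, seed = 3, ff = ff_default)
  set.seed(1)
  fr$vel <- maxwell_velocities(top, 303)
  st <- dynamics_settings(n_steps = 400, sample_every = 40, seed = 5,
                          temperature = 0)
  tr <- run_dynamics(fr, top, ff_default, st, interactions = "off")
  ke <- vapply(tr$frames, function(f) sum(f$vel^2), numeric(1))
  expect_true(all(diff(ke) < 0))
  expect_lt(ke[length(ke)] / ke[1], 1e-10)
})

test_that("with friction off the leapfrog conserves the bond-oscillator energy", {
  top <- build_topology(2, 1)
  fr <- r8_frame()
  fr <- cg_frame(fibrilsim:::chain_template(2, ff_default), L = 35)
  fr$pos[2, 1] <- fr$pos[2, 1] + 0.01 # stretch one bond
  fr$vel <- matrix(0, 6, 3)
  st <- dynamics_settings(n_steps = 10000, dt_fs = 2, tau_ps = Inf,
                          sample_every = 1, seed = 1)
  tr <- run_dynamics(fr, top, ff_default, st, interactions = "bonded_only")
  ke <- vapply(tr$frames, function(f) 0.5 * sum(72 * rowSums(f$vel^2)),
               numeric(1))
  pe <- vapply(tr$frames, function(f)
    system_energy_forces(f, top, ff_default, bonded_only = TRUE)$energy$total,
    numeric(1))
  # leapfrog stores half-step velocities: the conserved energy pairs the
  # on-step potential with the average of the two adjacent half-step KEs
  n <- length(ke)
  etot <- pe[1:(n - 1)] + 0.5 * (ke[1:(n - 1)] + ke[2:n])
  expect_lt((max(etot) - min(etot)) / mean(etot), 0.001)
})

test_that("instantaneous temperature has the right zero and scaling", {
  top <- build_topology(3, 2)
  fr <- place_monomers(2, 3, L = 10, seed = 1, ff = ff_default)
  fr$vel <- matrix(0, nrow(fr$pos), 3)
  expect_identical(instantaneous_temperature(fr, top), 0)
  set.seed(2)
  fr$vel <- matrix(rnorm(length(fr$pos)), ncol = 3)
  t1 <- instantaneous_temperature(fr, top)
  fr$vel <- 2 * fr$vel
  expect_equal(instantaneous_temperature(fr, top), 4 * t1)
  fr$vel <- NULL
  expect_error(instantaneous_temperature(fr, top), "velocities")
})

test_that("Maxwell-Boltzmann initialization reproduces the target temperature", {
  top <- build_topology(8, 700) # 12600 beads
  set.seed(10)
  v <- maxwell_velocities(top, 303)
  fr <- cg_frame(matrix(0, nrow(top$beads), 3), L = 35, velocities = v)
  expect_equal(instantaneous_temperature(fr, top), 303, tolerance = 0.01)
})

test_that("bonded-only minimization of a perturbed chain recovers every equilibrium value", {
  fr <- perturbed_r8(sd = 0.02, seed = 4)
  mn <- minimize(fr, top_r8, ff_default, mode = "bonded_only", tol = 1e-5)
  g <- measure_geometry(mn, top_r8)
  expect_equal(g$bonds$length[g$bonds$class == "BB"], rep(0.35, 7),
               tolerance = 1e-6)
  expect_equal(g$bonds$length[g$bonds$class == "BT"], rep(0.35, 2),
               tolerance = 1e-6)
  expect_equal(g$bonds$length[g$bonds$class == "BS"], rep(0.55, 8),
               tolerance = 1e-6)
  expect_equal(g$angles$theta[g$angles$class == "BBB"], rep(150, 6),
               tolerance = 1e-5)
  expect_equal(g$angles$theta[g$angles$class == "BBS"], rep(105, 6 + 8),
               tolerance = 1e-5)
  # descent contract and fixed point
  e0 <- system_energy_forces(fr, top_r8, ff_default, TRUE)$energy$total
  expect_lte(attr(mn, "energy")$total, e0)
  mn2 <- minimize(mn, top_r8, ff_default, mode = "bonded_only", tol = 1e-5)
  expect_lt(max(abs(mn2$pos - mn$pos)), 1e-5)
})
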