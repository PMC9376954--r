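test_that("the rate rule applies the monomer factor q symmetrically", {
  p <- kinetic_params(2, 0.5, 3, N = 6, V = 10)
  rr <- rate_rule(p)
  expect_equal(rr$kp[1, 1], 6)       # monomer-monomer: q k+
  expect_equal(rr$kp[1, 4], 6)
  expect_equal(rr$kp[4, 1], 6)
  expect_equal(rr$kp[3, 3], 2)
  expect_equal(rr$km[1, 5], 1.5)
  expect_equal(rr$km[2, 4], 0.5)
  expect_identical(rr$kp, t(rr$kp))
  expect_identical(rr$km, t(rr$km))
})

test_that("the RHS reproduces the hand-derived monomer and dimer fluxes", {
  p <- kinetic_params(2, 0.5, 3, N = 4, V = 10)
  # monomers only: the dimer gain is (1/2) q k+ c1^2
  c0 <- c(4 / 10, 0, 0, 0)
  r <- smoluchowski_rhs(c0, p)
  expect_equal(r[2], 0.5 * 3 * 2 * (0.4)^2)
  expect_equal(r[1], -2 * r[2]) # two monomers consumed per dimer formed
  # pure dimers: each C2 -> 2 C1 event occurs at rate q k- c2 / 2 and
  # releases two monomers, so dc1/dt = q k- c2
  cd <- c(0, 2 / 10, 0, 0)
  r2 <- smoluchowski_rhs(cd, p)
  expect_equal(r2[1], 3 * 0.5 * 0.2)
  expect_error(smoluchowski_rhs(c(-1, 0, 0, 0), p), "negative")
})

test_that("mass is conserved by the RHS for random states and parameters", {
  set.seed(3)
  for (k in 1:10) {
    N <- sample(4:40, 1)
    p <- kinetic_params(runif(1, 0.5, 10), runif(1, 0, 1), runif(1, 0.5, 5),
                        N = N, V = runif(1, 5, 100))
    cc <- runif(N, 0, 1 / p$V)
    expect_equal(sum(seq_len(N) * smoluchowski_rhs(cc, p)), 0,
                 tolerance = 1e-12)
    # the fast solver path agrees with the reference RHS exactly
    expect_equal(fibrilsim:::.rhs_fast(cc, p), smoluchowski_rhs(cc, p),
                 tolerance = 1e-12)
  }
})

test_that("irreversible constant-kernel coagulation matches the closed form", {
  # k- = 0, q = 1: n_c(t) = N / (1 + k+ c0 t / 2) until truncation matters
  p <- kinetic_params(5, 0, 1, N = 72, V = 35^3)
  tt <- seq(0, 200, 5)
  sol <- solve_kinetics(p, times = tt)
  c0 <- 72 / 35^3
  expect_equal(sol$curves$nc_mean, 72 / (1 + 5 * c0 * tt / 2),
               tolerance = 1e-7)
})

test_that("with no aggregation a pure-monomer state is constant", {
  p <- kinetic_params(0, 0.5, 2, N = 10, V = 10)
  sol <- solve_kinetics(p, times = seq(0, 50, 10))
  expect_equal(sol$counts[, 1], rep(10, 6))
  expect_equal(rowSums(sol$counts[, -1]), rep(0, 6))
})

test_that("the long-time ODE state is stationary and detailed-balanced", {
  p <- kinetic_params(2, 1, 2.5, N = 8, V = 20)
  tt <- c(0, 10^seq(-2, 3.5, length.out = 30))
  sol <- solve_kinetics(p, times = tt, rtol = 1e-12, atol = 1e-14)
  endc <- sol$counts[nrow(sol$counts), ]
  # stationarity: RHS norm at the endpoint
  expect_lt(max(abs(smoluchowski_rhs(endc / p$V, p))), 1e-10)
  res <- detailed_balance_residuals(p, endc)
  expect_lt(max(abs(res$residual)), 1e-8)
  # agrees with the analytic product-form equilibrium
  expect_equal(endc, equilibrium_state(p), tolerance = 1e-8)
  # q does not move the equilibrium
  p2 <- kinetic_params(2, 1, 7.7, N = 8, V = 20)
  expect_equal(equilibrium_state(p2), equilibrium_state(p))
  # irreversible limit reports non-equilibrium
  p0 <- kinetic_params(2, 0, 2, N = 8, V = 20)
  expect_error(detailed_balance_residuals(p0, endc), "k_minus = 0")
  # non-stationary input is rejected
  expect_error(detailed_balance_residuals(p, c(8, rep(0, 7))),
               "not stationary")
})

test_that("Gillespie realizations conserve mass exactly and are seed-deterministic", {
  p <- table2_row1()
  tt <- kinetic_grid()
  set.seed(11)
  m1 <- gillespie_run(p, sample_times = tt)
  set.seed(11)
  m2 <- gillespie_run(p, sample_times = tt)
  expect_identical(m1, m2)
  expect_true(all(m1 %*% seq_len(72) == 72))
  # irreversible: the total cluster count never increases
  pk <- kinetic_params(7.84, 0, 3.07, N = 72, V = 35^3)
  set.seed(4)
  m3 <- gillespie_run(pk, sample_times = tt)
  expect_true(all(diff(rowSums(m3)) <= 0))
  expect_error(gillespie_run(p, init_counts = c(3, rep(0, 71)),
                             sample_times = tt), "sum")
})

test_that("the two-state master equation follows its hand-derived relaxation", {
  # N = 2: states {2 monomers} and {1 dimer}; a = q k+ / V (association),
  # b = q k- / 2 (equal-split dissociation). E[dimers](t) relaxes to
  # a/(a+b) with rate a+b.
  p <- kinetic_params(3, 0.8, 2, N = 2, V = 10)
  a <- 2 * 3 / 10
  b <- 2 * 0.8 / 2
  tt <- seq(0, 6, 0.25)
  me <- master_equation_solve(p, tt)
  expect_equal(length(me$states), 2)
  want <- a / (a + b) * (1 - exp(-(a + b) * tt))
  expect_equal(unname(me$means[, 2]), want, tolerance = 1e-7)
  expect_equal(unname(me$means[1, ]), c(2, 0)) # t = 0 equals the start
  expect_error(master_equation_solve(kinetic_params(1, 1, 1, N = 12), tt),
               "capped")
})

test_that("the stationary master-equation distribution balances every transition", {
  p <- kinetic_params(2, 0.9, 1.7, N = 6, V = 8)
  me <- master_equation_solve(p, c(0, 1))
  G <- me$generator
  ev <- eigen(G)
  i0 <- which.min(abs(ev$values))
  expect_lt(abs(ev$values[i0]), 1e-10)
  pst <- Re(ev$vectors[, i0])
  pst <- pst / sum(pst)
  # stochastic detailed balance: G[to,from] p[from] = G[from,to] p[to]
  nS <- length(pst)
  for (sfrom in 1:nS) for (sto in 1:nS) {
    if (sfrom == sto || G[sto, sfrom] == 0) next
    expect_equal(G[sto, sfrom] * pst[sfrom], G[sfrom, sto] * pst[sto],
                 tolerance = 1e-8)
  }
})

test_that("SSA ensemble means agree with the exact master equation at N = 8", {
  p <- kinetic_params(3, 0.05, 2, N = 8, V = 30)
  tt <- seq(0, 40, 4)
  me <- master_equation_solve(p, tt)
  nr <- 4000
  s1 <- matrix(0, length(tt), 8)
  s2 <- s1
  set.seed(9)
  for (r in seq_len(nr)) {
    m <- gillespie_run(p, sample_times = tt)
    s1 <- s1 + m
    s2 <- s2 + m^2
  }
  mean_ <- s1 / nr
  sem_ <- sqrt(pmax((s2 / nr - mean_^2), 0) / (nr - 1))
  z <- abs(mean_ - me$means) / pmax(sem_, 1e-9)
  expect_lt(max(z[-1, ]), 3) # within 3 Monte-Carlo standard errors
})

test_that("ensemble averaging reports mean and standard error of the mean", {
  p <- kinetic_params(3, 0.05, 2, N = 8, V = 30)
  tt <- seq(0, 20, 5)
  cur <- gillespie_ensemble(p, 200, tt, seed = 13)
  expect_equal(cur$n1_mean[1], 8)
  expect_equal(cur$nc_mean[1], 8)
  expect_true(all(cur$n1_sem[-1] > 0))
  expect_equal(attr(cur, "n_repeats"), 200)
  # determinism of the whole ensemble under its seed
  cur2 <- gillespie_ensemble(p, 200, tt, seed = 13)
  expect_identical(as.data.frame(cur), as.data.frame(cur2))
})
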