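#' Kinetic parameters of the three-parameter aggregation model
#'
#' The reversible coagulation-fragmentation model has a single aggregation
#' rate constant `k_plus` (nm^3/ns) and fragmentation rate constant
#' `k_minus` (ns^-1) for all cluster pairs/channels *not* involving a
#' monomer, while monomer association and dissociation are faster by the
#' common factor `q`: `k+_{i,j} = q k+` and `k-_{i,j} = q k-` whenever
#' `i` or `j` equals 1. Because every channel shares the ratio `k+/k-`,
#' the model preserves detailed balance.
#'
#' @param k_plus Aggregation rate constant, nm^3/ns (>= 0).
#' @param k_minus Fragmentation rate constant, ns^-1 (>= 0).
#' @param q Monomer rate ratio (> 0).
#' @param N Total monomer count = maximum cluster size (>= 2).
#' @param V System volume in nm^3 (default the 35 nm reference box).
#' @return A `kinetic_params` list.
#' @export
kinetic_params <- function(k_plus, k_minus, q, N = 72, V = 35^3) {
  stopifnot(k_plus >= 0, k_minus >= 0, q > 0, N >= 2, V > 0)
  structure(list(k_plus = k_plus, k_minus = k_minus, q = q,
                 N = as.integer(N), V = V),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "kinetic_params: k+ = %.4g nm^3/ns, k- = %.4g ns^-1, q = %.4g (N = %d, V = %.4g nm^3)\n",
    x$k_plus, x$k_minus, x$q, x$N, x$V))
  invisible(x)
}

#' Size-dependent rate-constant lookup
#'
#' @param params A [kinetic_params()].
#' @return List of two N x N matrices `kp` and `km` with
#'   `kp[i, j] = q k+` when `i` or `j` is 1, else `k+` (and likewise `km`);
#'   both symmetric.
#' @export
rate_rule <- function(params) {
  N <- params$N
  mono <- outer(seq_len(N) == 1, seq_len(N) == 1, `|`)
  fac <- 1 + (params$q - 1) * mono
  list(kp = params$k_plus * fac, km = params$k_minus * fac)
}

# Per-size total fragmentation event rate and channel table.
# Channels of size i: unordered (j, k = i - j), j <= k. Event rate of
# channel (j,k) is km[j,k] * m_i / (1 + delta_jk): the equal-split factor
# mirrors the c_i^2/2 pairing factor on the aggregation side, which is what
# makes every channel ratio k+/k- and preserves detailed balance.
.frag_table <- function(params) {
  N <- params$N
  km <- rate_rule(params)$km
  lapply(seq_len(N), function(i) {
    if (i < 2) return(list(j = integer(0), rate = numeric(0), total = 0))
    j <- seq_len(i %/% 2)
    rate <- km[cbind(j, i - j)] / ifelse(j == i - j, 2, 1)
    list(j = j, rate = rate, total = sum(rate))
  })
}

#' Right-hand side of the modified Smoluchowski equations
#'
#' Mean-field rate equations for the concentrations `c_i` (nm^-3) of
#' clusters of `i` monomers, truncated at the system size `N` (no channels
#' beyond size N; the system is finite and closed):
#'
#' `dc_i/dt = 1/2 sum_{j+k=i} (k+_{jk} c_j c_k - k-_{jk} c_i)
#'           - sum_{j=1}^{N-i} (k+_{ij} c_i c_j - k-_{ij} c_{i+j})`
#'
#' The 1/2 prevents double counting in the ordered sum over `j + k = i`;
#' equal-size pairing carries the `c_i^2/2` factor, and the matching
#' stoichiometric factors for `2C_i -> C_2i` and `C_2i -> 2C_i` are built
#' into the symmetric form. Mass `sum_i i c_i` is conserved identically.
#'
#' @param conc Numeric vector of length `N`: concentrations (nm^-3).
#' @param params A [kinetic_params()].
#' @return `dc/dt`, numeric length `N` (nm^-3 ns^-1).
#' @export
smoluchowski_rhs <- function(conc, params) {
  N <- params$N
  if (length(conc) != N) stop("state must have length N = ", N)
  if (any(conc < 0)) stop("negative concentrations")
  rr <- rate_rule(params)
  dc <- numeric(N)
  for (i in seq_len(N)) {
    gain_a <- 0
    loss_f <- 0
    if (i >= 2) {
      j <- seq_len(i - 1)
      gain_a <- 0.5 * sum(rr$kp[cbind(j, i - j)] * conc[j] * conc[i - j])
      loss_f <- 0.5 * sum(rr$km[cbind(j, i - j)]) * conc[i]
    }
    loss_a <- 0
    gain_f <- 0
    if (i < N) {
      j <- seq_len(N - i)
      loss_a <- conc[i] * sum(rr$kp[cbind(i, j)] * conc[j])
      gain_f <- sum(rr$km[cbind(i, j)] * conc[i + j])
    }
    dc[i] <- gain_a - loss_f - loss_a + gain_f
  }
  dc
}

#' Integrate the kinetic model
#'
#' Solves the modified Smoluchowski equations with a stiff-capable
#' integrator (`deSolve::lsoda`) and reports cluster *numbers*
#' `n_i(t) = c_i(t) V` plus the total count `n_c = sum_i n_i`.
#'
#' @param params A [kinetic_params()].
#' @param init_counts Initial cluster numbers, length `N` (default: all
#'   monomers, `n_1(0) = N`).
#' @param times Output time grid in ns (increasing, starting at the initial
#'   time).
#' @param rtol,atol Solver tolerances.
#' @return A list: `curves` (`kinetic_curves`-schema data frame with the
#'   model values in the `*_mean` columns), `counts` (time x N matrix of
#'   `n_i`), `times`. Mass conservation is verified to `1e-6 * N`.
#' @export
solve_kinetics <- function(params, init_counts = NULL, times,
                           rtol = 1e-8, atol = 1e-12) {
  N <- params$N
  if (is.null(init_counts)) init_counts <- c(N, numeric(N - 1))
  if (length(init_counts) != N) stop("init_counts must have length N")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  deriv <- function(t, y, p) list(.rhs_fast(y, params))
  sol <- deSolve::lsoda(init_counts / params$V, times, deriv, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0) stop("kinetics ODE solver failed")
  counts <- unname(sol[, -1, drop = FALSE]) * params$V
  mass <- counts %*% seq_len(N)
  if (max(abs(mass - sum(seq_len(N) * init_counts))) > 1e-6 * N)
    warning("mass conservation violated beyond solver tolerance")
  curves <- data.frame(time_ns = times,
                       n1_mean = counts[, 1], n1_sem = 0,
                       n2_mean = counts[, 2], n2_sem = 0,
                       n3_mean = counts[, 3], n3_sem = 0,
                       nc_mean = rowSums(counts), nc_sem = 0)
  class(curves) <- c("kinetic_curves", "data.frame")
  attr(curves, "n_repeats") <- NA_integer_
  list(curves = curves, counts = counts, times = times)
}

# Vectorized RHS used inside the solver. Exploits the two-level rate rule:
# every channel involving a monomer carries the extra factor q, so the loss
# and fragmentation-gain sums reduce to cumulative sums, and only the
# aggregation-gain convolution needs a loop over sizes.
.rhs_fast <- function(conc, params) {
  N <- params$N
  kp <- params$k_plus
  km <- params$k_minus
  q <- params$q
  i <- seq_len(N)
  S <- cumsum(conc)
  tot <- S[N]

  loss_a <- numeric(N)
  if (N >= 2) {
    ii <- 2:(N - 1)
    if (N >= 3)
      loss_a[ii] <- conc[ii] * kp * (q * conc[1] + (S[N - ii] - conc[1]))
    loss_a[1] <- conc[1] * q * kp * S[N - 1]
  }

  gain_f <- numeric(N)
  if (N >= 3) {
    ii <- 2:(N - 1)
    gain_f[ii] <- km * (q * conc[ii + 1] + (tot - S[ii + 1]))
  }
  gain_f[1] <- q * km * (tot - conc[1])

  loss_f <- numeric(N)
  if (N >= 2) {
    ii <- 2:N
    loss_f[ii] <- 0.5 * km * ((ii - 1) + (q - 1) * (2 - (ii == 2))) * conc[ii]
  }

  gain_a <- numeric(N)
  for (ii in 2:N) {
    jj <- seq_len(ii - 1)
    conv <- sum(conc[jj] * conc[ii - jj])
    gain_a[ii] <- 0.5 * kp *
      (conv + (q - 1) * (2 - (ii == 2)) * conc[1] * conc[ii - 1])
  }
  gain_a - loss_f - loss_a + gain_f
}

#' One Gillespie realization of the stochastic kinetics
#'
#' Exact stochastic simulation of the aggregation-fragmentation jump
#' process. Propensities: aggregation `C_i + C_j -> C_{i+j}` at
#' `k+_{ij} m_i m_j / V` for `i != j` and `k+_{ii} m_i (m_i - 1) / (2V)`
#' for equal sizes (the number of (i,i) pairs); fragmentation
#' `C_i -> C_j + C_{i-j}` per unordered channel at `k-_{j,i-j} m_i`
#' (halved for the equal-split channel, matching the pairing convention and
#' preserving detailed balance). Mass `sum_i i m_i` is conserved exactly at
#' every event. Uses the current RNG state; seed with `set.seed()` for
#' reproducibility.
#'
#' @param params A [kinetic_params()].
#' @param init_counts Initial integer counts (default all monomers).
#' @param sample_times Increasing sample grid in ns; the state is recorded
#'   by thinning the event sequence at these times.
#' @return Integer matrix `length(sample_times) x N` of cluster counts.
#' @export
gillespie_run <- function(params, init_counts = NULL, sample_times) {
  N <- params$N
  V <- params$V
  if (is.null(init_counts)) init_counts <- c(N, integer(N - 1))
  if (sum(seq_len(N) * init_counts) != N)
    stop("initial counts must satisfy sum(i * m_i) = N")
  rr <- rate_rule(params)
  frag <- .frag_table(params)
  frag_tot <- vapply(frag, `[[`, numeric(1), "total")
  m <- as.integer(init_counts)
  t <- sample_times[1]
  out <- matrix(0L, length(sample_times), N)
  out[1, ] <- m
  next_s <- 2L
  nS <- length(sample_times)
  repeat {
    sizes <- which(m > 0L)
    # aggregation propensities over unordered size pairs (a <= b)
    ns_ <- length(sizes)
    a <- rep(sizes, times = ns_)
    b <- rep(sizes, each = ns_)
    keep <- a <= b & a + b <= N
    a <- a[keep]
    b <- b[keep]
    arate <- ifelse(a == b,
                    rr$kp[cbind(a, b)] * m[a] * (m[a] - 1L) / (2 * V),
                    rr$kp[cbind(a, b)] * m[a] * m[b] / V)
    pos <- arate > 0
    a <- a[pos]; b <- b[pos]; arate <- arate[pos]
    fr_sizes <- sizes[sizes >= 2L]
    fr_rate <- frag_tot[fr_sizes] * m[fr_sizes]
    total <- sum(arate) + sum(fr_rate)
    if (total <= 0) { # absorbing (e.g. k- = 0 and a single maximal cluster)
      if (next_s <= nS)
        out[next_s:nS, ] <- matrix(m, nS - next_s + 1L, N, byrow = TRUE)
      break
    }
    t <- t + rexp(1, total)
    while (next_s <= nS && sample_times[next_s] <= t) {
      out[next_s, ] <- m
      next_s <- next_s + 1L
    }
    if (next_s > nS) break
    # pick the event
    u <- runif(1) * total
    na <- length(arate)
    done <- FALSE
    if (na) {
      ca <- cumsum(arate)
      if (u <= ca[na]) {
        e <- which(u <= ca)[1]
        ea <- a[e]; eb <- b[e]
        m[ea] <- m[ea] - 1L
        m[eb] <- m[eb] - 1L
        m[ea + eb] <- m[ea + eb] + 1L
        done <- TRUE
      } else {
        u <- u - ca[na]
      }
    }
    if (!done) {
      cf <- cumsum(fr_rate)
      e <- which(u <= cf)[1]
      if (is.na(e)) e <- length(fr_rate) # guard against rounding
      i <- fr_sizes[e]
      # choose the split channel within the fragmenting size
      ch <- frag[[i]]
      j <- ch$j[which(runif(1) * ch$total <= cumsum(ch$rate))[1]]
      m[i] <- m[i] - 1L
      m[j] <- m[j] + 1L
      m[i - j] <- m[i - j] + 1L
    }
  }
  out
}

#' Ensemble of Gillespie realizations, averaged into kinetic curves
#'
#' @param params A [kinetic_params()].
#' @param n_reps Number of stochastic repetitions.
#' @param sample_times Sample grid in ns.
#' @param seed Integer seed for the ensemble.
#' @param init_counts Initial counts (default all monomers).
#' @param keep_counts If `TRUE`, also return the per-repeat count arrays
#'   summed over repeats (for mean cluster-size spectra).
#' @return A `kinetic_curves` data frame (across-repeat mean and standard
#'   deviation of the mean per time point); attribute `n_repeats`. With
#'   `keep_counts`, attribute `mean_counts` (time x N matrix).
#' @export
gillespie_ensemble <- function(params, n_reps, sample_times, seed = 1,
                               init_counts = NULL, keep_counts = FALSE) {
  set.seed(seed)
  nS <- length(sample_times)
  s1 <- matrix(0, nS, 4)  # running sums of (n1, n2, n3, nc)
  s2 <- matrix(0, nS, 4)
  csum <- if (keep_counts) matrix(0, nS, params$N) else NULL
  for (r in seq_len(n_reps)) {
    m <- gillespie_run(params, init_counts, sample_times)
    obs <- cbind(m[, 1], m[, 2], m[, 3], rowSums(m))
    s1 <- s1 + obs
    s2 <- s2 + obs^2
    if (keep_counts) csum <- csum + m
  }
  mean_ <- s1 / n_reps
  sem_ <- if (n_reps > 1) {
    sqrt(pmax((s2 - n_reps * mean_^2) / (n_reps - 1), 0) / n_reps)
  } else matrix(0, nS, 4)
  out <- data.frame(time_ns = sample_times,
                    n1_mean = mean_[, 1], n1_sem = sem_[, 1],
                    n2_mean = mean_[, 2], n2_sem = sem_[, 2],
                    n3_mean = mean_[, 3], n3_sem = sem_[, 3],
                    nc_mean = mean_[, 4], nc_sem = sem_[, 4])
  class(out) <- c("kinetic_curves", "data.frame")
  attr(out, "n_repeats") <- n_reps
  if (keep_counts) attr(out, "mean_counts") <- csum / n_reps
  out
}

# All integer partitions of n (list of count vectors m of length n with
# sum(i * m_i) = n), enumerated recursively.
.partitions <- function(n) {
  parts <- list()
  rec <- function(remaining, maxpart, acc) {
    if (remaining == 0) {
      m <- integer(n)
      tab <- table(acc)
      m[as.integer(names(tab))] <- as.integer(tab)
      parts[[length(parts) + 1L]] <<- m
      return(invisible())
    }
    for (p in seq_len(min(remaining, maxpart))) rec(remaining - p, p, c(acc, p))
  }
  rec(n, n, integer(0))
  parts
}

#' Exact master-equation solution for small systems
#'
#' Enumerates every cluster-size configuration (integer partition of `N`)
#' and integrates the linear master equation with the same event rates as
#' [gillespie_run()], giving the exact ensemble means `E[m_i(t)]`. The
#' state space grows as the partition number, so `N` is capped at 10
#' (42 states).
#'
#' @param params A [kinetic_params()] with `N <= 10`.
#' @param times Output grid in ns.
#' @param init_counts Initial configuration (default all monomers).
#' @return List: `means` (time x N matrix of `E[m_i]`), `probs` (time x
#'   n_states), `states` (list of count vectors), `generator` (the rate
#'   matrix, states x states), `times`.
#' @export
master_equation_solve <- function(params, times, init_counts = NULL) {
  N <- params$N
  if (N > 10)
    stop("N = ", N, " too large: the partition state space (p(", N,
         ") states) is capped at N = 10")
  if (is.null(init_counts)) init_counts <- c(N, integer(N - 1))
  states <- .partitions(N)
  key <- vapply(states, paste, character(1), collapse = ",")
  idx <- setNames(seq_along(states), key)
  V <- params$V
  rr <- rate_rule(params)
  nS <- length(states)
  G <- matrix(0, nS, nS) # G[to, from]
  for (s in seq_len(nS)) {
    m <- states[[s]]
    sizes <- which(m > 0L)
    for (a in sizes) for (b in sizes[sizes >= a]) {
      if (a + b > N) next
      rate <- if (a == b) rr$kp[a, b] * m[a] * (m[a] - 1) / (2 * V)
              else rr$kp[a, b] * m[a] * m[b] / V
      if (rate <= 0) next
      m2 <- m
      m2[a] <- m2[a] - 1L
      m2[b] <- m2[b] - 1L
      m2[a + b] <- m2[a + b] + 1L
      to <- idx[[paste(m2, collapse = ",")]]
      G[to, s] <- G[to, s] + rate
      G[s, s] <- G[s, s] - rate
    }
    for (i in sizes[sizes >= 2]) {
      for (j in seq_len(i %/% 2)) {
        rate <- rr$km[j, i - j] * m[i] / (if (j == i - j) 2 else 1)
        if (rate <= 0) next
        m2 <- m
        m2[i] <- m2[i] - 1L
        m2[j] <- m2[j] + 1L
        m2[i - j] <- m2[i - j] + 1L
        to <- idx[[paste(m2, collapse = ",")]]
        G[to, s] <- G[to, s] + rate
        G[s, s] <- G[s, s] - rate
      }
    }
  }
  p0 <- numeric(nS)
  k0 <- paste(as.integer(init_counts), collapse = ",")
  if (is.null(idx[[k0]])) stop("init_counts is not a partition of N")
  p0[idx[[k0]]] <- 1
  sol <- deSolve::lsoda(p0, times, function(t, y, p) list(as.numeric(G %*% y)),
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  probs <- sol[, -1, drop = FALSE]
  Smat <- do.call(rbind, states)
  means <- probs %*% Smat
  list(means = means, probs = probs, states = states, generator = G,
       times = times)
}

#' Detailed-balance residuals of a stationary state
#'
#' For a stationary concentration state, compares the forward flux of every
#' aggregation channel `(j, k)` with the backward flux of its fragmentation
#' channel. Because all channels share the rate ratio `k+/k-`, a stationary
#' state of the model balances every channel individually; the residuals
#' quantify how exactly.
#'
#' @param params A [kinetic_params()] with `k_minus > 0`.
#' @param counts Stationary cluster numbers `n_i` (length N), e.g. the
#'   endpoint of a long [solve_kinetics()] run.
#' @param stationarity_tol Maximum allowed `|dn/dt|` (counts/ns) for the
#'   input to be accepted as stationary.
#' @return Data frame with columns `j`, `k`, `forward`, `backward`,
#'   `residual` (relative: `(fwd - back) / max(fwd, back)`, 0 when both
#'   vanish).
#' @export
detailed_balance_residuals <- function(params, counts,
                                       stationarity_tol = 1e-6) {
  N <- params$N
  if (params$k_minus == 0)
    stop("k_minus = 0: the irreversible model has no detailed-balanced ",
         "stationary state with coexisting aggregates")
  conc <- counts / params$V
  rate <- smoluchowski_rhs(conc, params) * params$V
  if (max(abs(rate)) > stationarity_tol)
    stop(sprintf("state is not stationary: max |dn/dt| = %.3g counts/ns",
                 max(abs(rate))))
  rr <- rate_rule(params)
  res <- list()
  for (j in seq_len(N %/% 2)) {
    for (k in j:(N - j)) {
      pair_fac <- if (j == k) 2 else 1
      fwd <- rr$kp[j, k] * conc[j] * conc[k] / pair_fac
      bwd <- rr$km[j, k] * conc[j + k] / pair_fac
      denom <- max(fwd, bwd)
      res[[length(res) + 1]] <- data.frame(
        j = j, k = k, forward = fwd, backward = bwd,
        residual = if (denom > 0) (fwd - bwd) / denom else 0)
    }
  }
  do.call(rbind, res)
}

#' Analytic detailed-balanced equilibrium of the truncated model
#'
#' The uniform channel ratio `K = k+/k-` forces `c_{j+k} = K c_j c_k` at
#' equilibrium, so `c_i = K^(i-1) c_1^i`; the monomer concentration is fixed
#' by mass conservation `sum_i i c_i V = N` (solved by bisection on
#' `log c_1`). Independent of `q`.
#'
#' @param params A [kinetic_params()] with `k_minus > 0`.
#' @return Equilibrium counts `n_i` (length N).
#' @export
equilibrium_state <- function(params) {
  stopifnot(params$k_minus > 0)
  N <- params$N
  lK <- log(params$k_plus) - log(params$k_minus)
  i <- seq_len(N)
  mass <- function(lx1) {
    lw <- (i - 1) * lK + i * lx1
    sum(i * exp(lw)) * params$V - N
  }
  lo <- -700
  hi <- log(N / params$V) + 1
  while (mass(hi) < 0) hi <- hi + 1
  root <- uniroot(mass, c(lo, hi), tol = 1e-14)$root
  exp((i - 1) * lK + i * root) * params$V
}
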