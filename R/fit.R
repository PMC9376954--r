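#' Fit the three-parameter kinetic model to observed curves
#'
#' Globally fits `(k+, k-, q)` by minimizing the sum of squared differences
#' between the model's `n1`, `n2`, `n3`, `nc` curves (from
#' [solve_kinetics()]) and the observed curves, over every time point, with
#' equal weights per curve and point by default. The optimizer is a
#' derivative-free Nelder-Mead simplex on `log(k+, k-, q)` (positivity by
#' construction), restarted from `multi_start` perturbed initial guesses;
#' the best final cost wins.
#'
#' @param observed A `kinetic_curves` data frame (columns `time_ns`,
#'   `n1_mean`, `n2_mean`, `n3_mean`, `nc_mean`), e.g. from
#'   [curves_from_trajectories()] or [gillespie_ensemble()].
#' @param guess A [kinetic_params()] with the starting values (also fixes
#'   `N` and `V`).
#' @param weights Optional named list/vector of per-curve weights
#'   (`n1`, `n2`, `n3`, `nc`); default all 1.
#' @param multi_start Number of optimizer starts (the first is the
#'   unperturbed guess; the rest perturb it log-normally, sd 0.5).
#' @param seed Seed for the start perturbations.
#' @param control Passed to [stats::optim()] (Nelder-Mead).
#' @return An object of class `smol_fit` with components `params` (fitted
#'   [kinetic_params()]), `cost`, `convergence`, `starts` (per-start
#'   summary), `observed`, `fitted` (model curves at the observed grid).
#' @seealso [coef.smol_fit()], [predict.smol_fit()], [simulate.smol_fit()]
#' @export
fit_kinetics <- function(observed, guess, weights = NULL, multi_start = 5,
                         seed = 1, control = list(maxit = 500,
                                                  reltol = 1e-10)) {
  need <- c("time_ns", "n1_mean", "n2_mean", "n3_mean", "nc_mean")
  if (!all(need %in% names(observed)))
    stop("observed curves must contain columns: ", paste(need, collapse = ", "))
  w <- c(n1 = 1, n2 = 1, n3 = 1, nc = 1)
  if (!is.null(weights)) w[names(weights)] <- unlist(weights)
  times <- observed$time_ns
  obs <- as.matrix(observed[, c("n1_mean", "n2_mean", "n3_mean", "nc_mean")])
  N <- guess$N
  V <- guess$V
  # the solver needs a strictly increasing grid; the cost is a plain sum
  # over points, so solve on the sorted unique grid and map back
  tsort <- sort(unique(times))
  tmap <- match(times, tsort)

  model_curves <- function(p) {
    mod <- solve_kinetics(p, times = tsort, rtol = 1e-7, atol = 1e-10)
    as.matrix(mod$curves[tmap, c("n1_mean", "n2_mean", "n3_mean",
                                 "nc_mean")])
  }

  objective <- function(logp) {
    p <- kinetic_params(exp(logp[1]), exp(logp[2]), exp(logp[3]), N, V)
    fit <- try(model_curves(p), silent = TRUE)
    if (inherits(fit, "try-error")) return(1e12)
    sum(t((fit - obs)^2) * w)
  }

  set.seed(seed)
  lp0 <- log(c(guess$k_plus, guess$k_minus, guess$q))
  starts <- rbind(lp0,
                  if (multi_start > 1)
                    t(lp0 + matrix(rnorm(3 * (multi_start - 1), 0, 0.5),
                                   3, multi_start - 1)))
  runs <- apply(starts, 1, function(s)
    optim(s, objective, method = "Nelder-Mead", control = control),
    simplify = FALSE)
  costs <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(costs)]]
  fitted_params <- kinetic_params(exp(best$par[1]), exp(best$par[2]),
                                  exp(best$par[3]), N, V)
  fitted_mat <- model_curves(fitted_params)
  fitted_curves <- data.frame(time_ns = times,
                              n1_mean = fitted_mat[, 1], n1_sem = 0,
                              n2_mean = fitted_mat[, 2], n2_sem = 0,
                              n3_mean = fitted_mat[, 3], n3_sem = 0,
                              nc_mean = fitted_mat[, 4], nc_sem = 0)
  class(fitted_curves) <- c("kinetic_curves", "data.frame")

  structure(list(
    params = fitted_params,
    cost = best$value,
    convergence = best$convergence,
    converged = best$convergence == 0,
    starts = data.frame(
      k_plus = exp(starts[, 1]), k_minus = exp(starts[, 2]),
      q = exp(starts[, 3]), cost = costs,
      convergence = vapply(runs, `[[`, numeric(1), "convergence")),
    weights = w,
    observed = observed,
    fitted = fitted_curves,
    call = match.call()
  ), class = "smol_fit")
}

#' @export
coef.smol_fit <- function(object, ...) {
  with(object$params, c(k_plus = k_plus, k_minus = k_minus, q = q))
}

#' @export
print.smol_fit <- function(x, ...) {
  cat("Three-parameter aggregation-fragmentation kinetic fit\n")
  cat(sprintf("  k+ = %.4g nm^3/ns, k- = %.4g ns^-1 (%.4g x 1e-5), q = %.4g\n",
              x$params$k_plus, x$params$k_minus, x$params$k_minus * 1e5,
              x$params$q))
  cat(sprintf("  cost (sum of squares) = %.4g over %d time points; %s\n",
              x$cost, nrow(x$observed),
              if (x$converged) "converged" else
                paste0("NOT converged (code ", x$convergence, ")")))
  invisible(x)
}

#' @export
summary.smol_fit <- function(object, ...) {
  res <- residuals(object)
  out <- list(params = coef(object), cost = object$cost,
              converged = object$converged,
              n_points = nrow(object$observed),
              rmse_per_curve = sqrt(colMeans(res^2)),
              starts = object$starts)
  class(out) <- "summary.smol_fit"
  out
}

#' @export
print.summary.smol_fit <- function(x, ...) {
  cat("Kinetic fit summary\n  parameters:\n")
  print(x$params)
  cat(sprintf("  cost = %.6g (%s), %d time points\n", x$cost,
              if (x$converged) "converged" else "not converged", x$n_points))
  cat("  per-curve RMSE:\n")
  print(x$rmse_per_curve)
  cat("  optimizer starts:\n")
  print(x$starts, digits = 4)
  invisible(x)
}

#' Model curves at new time points
#'
#' @param object A `smol_fit`.
#' @param times Time grid in ns (default: the observed grid).
#' @param ... Unused.
#' @return A `kinetic_curves` data frame of model values.
#' @export
predict.smol_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$observed$time_ns
  solve_kinetics(object$params, times = times)$curves
}

#' Residuals of a kinetic fit
#'
#' @param object A `smol_fit`.
#' @param ... Unused.
#' @return Matrix (time x 4) of observed minus fitted, columns n1, n2, n3,
#'   nc.
#' @export
residuals.smol_fit <- function(object, ...) {
  cols <- c("n1_mean", "n2_mean", "n3_mean", "nc_mean")
  out <- as.matrix(object$observed[, cols]) - as.matrix(object$fitted[, cols])
  colnames(out) <- c("n1", "n2", "n3", "nc")
  out
}

#' Simulate stochastic kinetics from a fitted model
#'
#' Draws Gillespie ensembles at the fitted parameters.
#'
#' @param object A `smol_fit`.
#' @param nsim Number of realizations.
#' @param seed Integer seed.
#' @param times Sample grid in ns (default: the observed grid).
#' @param ... Unused.
#' @return A `kinetic_curves` data frame of ensemble means/SEMs.
#' @export
simulate.smol_fit <- function(object, nsim = 100, seed = 1, times = NULL,
                              ...) {
  if (is.null(times)) times <- object$observed$time_ns
  gillespie_ensemble(object$params, nsim, times, seed = seed)
}

#' Plot a kinetic fit
#'
#' Observed curves (points) and fitted model (lines) for n1, n2, n3, nc.
#'
#' @param x A `smol_fit`.
#' @param log_time Use a log time axis (t = 0 dropped).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.smol_fit <- function(x, log_time = FALSE, ...) {
  cols <- c("n1_mean", "n2_mean", "n3_mean", "nc_mean")
  t_ <- x$observed$time_ns
  keep <- if (log_time) t_ > 0 else rep(TRUE, length(t_))
  matplot(t_[keep], as.matrix(x$observed[keep, cols]), pch = 1, cex = 0.4,
          col = 1:4, log = if (log_time) "x" else "",
          xlab = "time (ns)", ylab = "count", ...)
  matplot(t_[keep], as.matrix(x$fitted[keep, cols]), type = "l", lty = 1,
          col = 1:4, add = TRUE)
  legend("topright", c("n1", "n2", "n3", "nc"), col = 1:4, lty = 1, bty = "n")
  invisible(x)
}
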