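# Finite-difference cross-check of front propagation.
#
# The travelling-wave solutions of the reduced equation
#   u' - D u'' + gamma u (u - 1)(u - sigma) = 0,   r = t - x,
# correspond to fronts M(t, x) = u(t - x) of the 1-D evolution equation
#   M_t = D M_xx - gamma M (M - 1)(M - sigma),
# moving at unit speed toward increasing x.  The simulator discretizes
# the line with second-order central differences, Neumann (zero-flux)
# boundaries, and classical fixed-step RK4 time stepping at
# dt = 0.2 h^2 / D (well inside the explicit stability limit).

#' Simulate the one-dimensional reduction
#'
#' @param model a `bac_model` with numeric `gamma` and `sigma` (`d` is
#'   not used directly; pass the effective diffusion below).
#' @param D_eff effective diffusion coefficient (e.g. `2 d` for the
#'   diagonal travelling wave with `|k|^2 = 2`).
#' @param u0 initial profile: function of `x`, or numeric vector of
#'   length `n`.
#' @param xlim domain interval.
#' @param n number of grid points.
#' @param t_end final time.
#' @param n_save number of saved time slices (including `t = 0`).
#' @param cfl time-step factor: `dt = cfl * h^2 / D_eff`.
#' @return object of class `sim_result`: `x`, `times`, `values`
#'   (`n_save` rows), scheme metadata.
#' @export
simulate_1d <- function(model, D_eff, u0, xlim = c(-100, 100), n = 401,
                        t_end = 20, n_save = 41, cfl = 0.2) {
  stopifnot(is.numeric(model$gamma), is.numeric(model$sigma), D_eff > 0)
  g <- model$gamma; s <- model$sigma
  x <- seq(xlim[1], xlim[2], length.out = n)
  h <- x[2] - x[1]
  y0 <- if (is.function(u0)) u0(x) else u0
  stopifnot(length(y0) == n, all(is.finite(y0)))
  # diffusive CFL bound, capped by the reaction timescale 1/gamma
  dt <- min(cfl * h^2 / D_eff, 0.1 / max(g, 1e-12), t_end / 50)
  nstep <- ceiling(t_end / dt)
  times <- seq(0, t_end, length.out = nstep + 1)
  rhs <- function(t, M, parms) {
    Ml <- c(M[2], M[-n]); Mr <- c(M[-1], M[n - 1])   # Neumann ghosts
    list(D_eff * (Ml - 2 * M + Mr) / h^2 - g * M * (M - 1) * (M - s))
  }
  bound <- 10 * (max(abs(y0)) + 1)
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "rk4")
  vals <- out[, -1, drop = FALSE]
  if (!all(is.finite(vals)) || max(abs(vals)) > bound)
    stop("instability detected: solution norm exceeded ", bound,
         " (reduce dt or refine the grid)")
  keep <- unique(round(seq(1, nrow(vals), length.out = n_save)))
  structure(list(x = x, times = times[keep],
                 values = vals[keep, , drop = FALSE],
                 h = h, dt = dt, D_eff = D_eff,
                 scheme = "central second order + RK4, Neumann"),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("1-D simulation: ", length(x$x), " points, h = ",
      format(x$h, digits = 4), ", dt = ", format(x$dt, digits = 4),
      ", t in [0, ", max(x$times), "]\n  scheme: ", x$scheme, "\n",
      sep = "")
  invisible(x)
}

#' Front speed from level crossings
#'
#' Locates the unique crossing of `level` in each saved profile by
#' linear interpolation and fits a line to crossing position versus time
#' over the second half of the time window (the transient is excluded).
#'
#' @param sim a `sim_result`.
#' @param level tracked level; defaults to the midpoint `(1 + sigma) / 2`
#'   convention used by the front checks, which must then be supplied.
#' @return object of class `speed_estimate`: `speed`, `fit_rms`,
#'   `crossings` (time, position).
#' @export
measure_speed <- function(sim, level) {
  pos <- vapply(seq_along(sim$times), function(i) {
    M <- sim$values[i, ]
    ab <- (M[-length(M)] - level) * (M[-1] - level)
    idx <- which(ab < 0)
    flat <- which(M == level)
    if (length(idx) + length(flat) == 0)
      stop("tracked level ", level, " is not crossed at t = ",
           sim$times[i])
    if (length(idx) > 1)
      stop("tracked level ", level, " crossed more than once at t = ",
           sim$times[i])
    if (length(idx) == 0) return(sim$x[flat[1]])
    j <- idx[1]
    w <- (level - sim$values[i, j]) /
      (sim$values[i, j + 1] - sim$values[i, j])
    sim$x[j] + w * (sim$x[j + 1] - sim$x[j])
  }, numeric(1))
  half <- sim$times >= max(sim$times) / 2
  fit <- stats::lm(pos[half] ~ sim$times[half])
  structure(list(speed = unname(stats::coef(fit)[2]),
                 fit_rms = sqrt(mean(stats::resid(fit)^2)),
                 level = level,
                 crossings = data.frame(time = sim$times, position = pos)),
            class = "speed_estimate")
}

#' @export
print.speed_estimate <- function(x, ...) {
  cat("Front speed at level ", format(x$level, digits = 4), ": ",
      format(x$speed, digits = 6), " (fit RMS ",
      format(x$fit_rms, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Derived kink front versus simulation
#'
#' Builds the derived single-tanh parameter set on the diagonal
#' reduction (`gamma = 1/(d (sigma+1)^2)`, effective diffusion `2 d`,
#' `kappa = -(sigma-1)^2 / (16 d^2 (sigma+1)^2)`), initializes the
#' simulator with the closed-form kink at `t = 0` (`r = -x`), and
#' measures the front speed at the midpoint level `(1 + sigma)/2`.  The
#' travelling variable is `r = t - x`, so the exact speed is 1.  The
#' domain spans at least 40 kink widths with the front at the center.
#'
#' @param d diffusion coefficient of the underlying model.
#' @param sigma survival-rate parameter.
#' @param widths domain size in units of the kink width `1/sqrt(-kappa)`.
#' @param t_end simulation horizon (default: time to travel 8 widths,
#'   at least 10).
#' @param n grid points.
#' @return list with the measured `speed`, relative `speed_error`, the
#'   end-level errors `end_errors` (against `1` and `sigma`), the
#'   closed-form/simulation `shape_linf` at the final time, and the
#'   underlying objects.
#' @export
kink_front_check <- function(d, sigma, widths = 40, t_end = NULL,
                             n = 401) {
  gamma <- 1 / (d * (sigma + 1)^2)
  kappa <- -(sigma - 1)^2 / (16 * d^2 * (sigma + 1)^2)
  w <- sqrt(-kappa)
  width <- 1 / w
  a0 <- (sigma + 1) / 2
  a1 <- -2 * d * (sigma + 1)
  cf <- function(r) a0 + a1 * (-w * tanh(w * r))
  if (is.null(t_end)) t_end <- max(10, 8 * width)
  L <- widths * width / 2
  model <- bac_model(d = d, gamma = gamma, sigma = sigma)
  sim <- simulate_1d(model, D_eff = 2 * d, u0 = function(x) cf(-x),
                     xlim = c(-L, L), n = n, t_end = t_end)
  sp <- measure_speed(sim, level = (1 + sigma) / 2)
  final <- sim$values[nrow(sim$values), ]
  exact <- cf(max(sim$times) - sim$x)
  list(speed = sp$speed, speed_error = abs(sp$speed - 1),
       end_errors = c(left = abs(final[1] - 1),
                      right = abs(final[length(final)] - sigma)),
       shape_linf = max(abs(final - exact)),
       width = width, sim = sim, speed_fit = sp, closed_form = cf)
}
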