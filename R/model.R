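# The bistable Allen-Cahn biofilm model:
#   M_t - d (M_xx + M_yy) + gamma M^3 - gamma (1 + sigma) M^2
#                         + gamma sigma M = 0,
# where M(t, x, y) is the microbial density on a rectangular surface,
# d > 0 the diffusion coefficient, gamma > 0 the growth rate and
# sigma in [0, 1] the survival-rate parameter.  The reaction polynomial
# factors exactly as gamma * M * (M - 1) * (M - sigma), so the uniform
# steady states are M = 0, sigma, 1.

.param_ok <- function(p) is.numeric(p) || is.name(p) || is.call(p)

#' Construct the bistable Allen-Cahn biofilm model
#'
#' Parameters may be numeric or symbolic (quoted names); all downstream
#' solvers work symbolically and substitute numbers late, because the
#' expansion methods constrain `d`, `gamma` and `sigma` themselves.
#'
#' @param d diffusion coefficient (numeric > 0, or a symbol).
#' @param gamma growth rate (numeric > 0, or a symbol).
#' @param sigma survival-rate parameter (numeric, nominally in \[0, 1\],
#'   or a symbol).  Numeric values outside \[0, 1\] draw a warning, not an
#'   error: solver-derived parameter sets may determine `sigma` from
#'   auxiliary constants and leave the nominal interval.
#' @param domain optional plotting rectangle `c(e, g, n, m)` meaning
#'   `x` in \[e, g\], `y` in \[n, m\] (plotting only).
#' @return an object of class `bac_model` with the residual expression in
#'   `$residual` (a call over `M` and its jet coordinates).
#' @examples
#' bac_model()                      # fully symbolic
#' bac_model(d = 0.5, gamma = 1, sigma = 0.3)
#' @export
bac_model <- function(d = quote(d), gamma = quote(gamma),
                      sigma = quote(sigma), domain = NULL) {
  stopifnot(.param_ok(d), .param_ok(gamma), .param_ok(sigma))
  if (is.numeric(d) && d <= 0) stop("diffusion coefficient d must be > 0")
  if (is.numeric(gamma) && gamma <= 0) stop("growth rate gamma must be > 0")
  if (is.numeric(sigma) && (sigma < 0 || sigma > 1))
    warning("sigma = ", sigma, " lies outside the nominal interval [0, 1]")
  if (!is.null(domain)) stopifnot(is.numeric(domain), length(domain) == 4)
  residual <- bquote(M_t - .(d) * M_xx - .(d) * M_yy + .(gamma) * M^3 -
                       .(gamma) * (1 + .(sigma)) * M^2 +
                       .(gamma) * .(sigma) * M)
  structure(list(d = d, gamma = gamma, sigma = sigma, domain = domain,
                 residual = residual),
            class = "bac_model")
}

#' @export
print.bac_model <- function(x, ...) {
  cat("Bistable Allen-Cahn biofilm model\n")
  cat("  residual: ", deparse(x$residual), " = 0\n", sep = "")
  cat("  d = ", deparse(x$d), ", gamma = ", deparse(x$gamma),
      ", sigma = ", deparse(x$sigma), "\n", sep = "")
  invisible(x)
}

# residual as an exact polynomial on jet space (parameters symbolic or
# numeric as stored in the model)
model_residual_rp <- function(model) rp_from_call(model$residual)

# reaction F(M) = gamma M (M - 1)(M - sigma) and its derivative, as calls
model_reaction <- function(model) {
  bquote(.(model$gamma) * M^3 - .(model$gamma) * (1 + .(model$sigma)) * M^2 +
           .(model$gamma) * .(model$sigma) * M)
}

# M_t solved from the equation (evolution form), as a ratpoly
model_mt_rhs_rp <- function(model) {
  r <- model_residual_rp(model)
  rp_sub(rp_var("M_t"), r)   # M_t - residual = RHS
}

#' Residual of the model equation on a candidate field
#'
#' Substitutes a field `M(t, x, y)` into the equation and returns the
#' leftover.  Symbolic fields (calls in `t`, `x`, `y`) give an exact
#' symbolic residual; 1-D fields (no `y` dependence) are handled by the
#' same rule since the `y`-derivatives vanish.  Gridded fields (a list
#' with `tt`, `xx` coordinate vectors and a matrix `values` of
#' `M[i, j] = M(tt[i], xx[j])`) give a pointwise numeric residual on the
#' interior grid using second-order central differences.
#'
#' @param model a `bac_model`.
#' @param field a call in `t`, `x`, `y`, or a gridded-field list as above.
#' @return a call (symbolic field) or a numeric matrix (gridded field).
#' @examples
#' m <- bac_model()
#' pde_residual(m, quote(0 * t))              # equilibrium 0
#' sym_is_zero(pde_residual(m, quote(1 + 0 * t)))
#' @export
pde_residual <- function(model, field) {
  if (is.list(field) && !is.null(field$values)) {
    return(.pde_residual_grid(model, field))
  }
  if (is.numeric(field)) field <- substitute(f + 0 * t, list(f = field))
  pars <- unlist(lapply(list(model$d, model$gamma, model$sigma), sym_vars))
  known <- c("t", "x", "y", pars,
             c("d", "gamma", "sigma", "kappa", "tau", "A1", "B1",
               "b1", "b2", "b3", "pm"))   # solver/library parameters
  bad <- setdiff(sym_vars(field), known)
  if (length(bad))
    stop("field references unknown variables: ", paste(bad, collapse = ", "))
  reps <- list(
    M    = field,
    M_t  = sym_d(field, "t"),
    M_xx = sym_d(sym_d(field, "x"), "x"),
    M_yy = sym_d(sym_d(field, "y"), "y")
  )
  sym_subs(model$residual, reps)
}

.pde_residual_grid <- function(model, field) {
  stopifnot(is.numeric(model$d), is.numeric(model$gamma),
            is.numeric(model$sigma))
  tt <- field$tt; xx <- field$xx; v <- field$values
  stopifnot(nrow(v) == length(tt), ncol(v) == length(xx))
  dt <- diff(tt)[1]; dx <- diff(xx)[1]
  it <- 2:(length(tt) - 1); ix <- 2:(length(xx) - 1)
  Mt  <- (v[it + 1, ix] - v[it - 1, ix]) / (2 * dt)
  Mxx <- (v[it, ix + 1] - 2 * v[it, ix] + v[it, ix - 1]) / dx^2
  M   <- v[it, ix]
  g <- model$gamma; s <- model$sigma
  Mt - model$d * Mxx + g * M^3 - g * (1 + s) * M^2 + g * s * M
}
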