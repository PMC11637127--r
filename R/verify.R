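# Independent verification of cataloged solutions: residual reports
# against the reduced equations and the full PDE, and the exact
# plane-wave lift argument.

#' Residual report of a closed-form solution
#'
#' Substitutes the solution (and its parameter set's constraints) into
#' the target reduced equation or the full model equation and reports the
#' three-valued symbolic status plus the maximum absolute residual over a
#' seeded sample window (points within 0.05 of a detected singularity are
#' rejected and resampled).
#'
#' @param sol a `closed_form_solution`.
#' @param target an `ord_ode`, or a `bac_model` (the solution is lifted
#'   through its travelling-variable definition).
#' @param seed sampling seed.
#' @param n number of sample points.
#' @return object of class `residual_report`.
#' @export
residual_report <- function(sol, target, seed = 0, n = 25) {
  expr <- sol$expr
  if (inherits(target, "ord_ode")) {
    u1 <- sym_d(expr, "r"); u2 <- sym_d(u1, "r")
    res <- sym_subs(target$expr, list(u = expr, u1 = u1, u2 = u2))
    target_id <- target$source
  } else if (inherits(target, "bac_model")) {
    field <- sym_subs(expr, list(r = sol$r_def))
    res <- pde_residual(target, field)
    target_id <- "model_pde"
  } else stop("target must be an ord_ode or a bac_model")
  res <- sym_subs(res, sol$assignments)   # set constraints on d, gamma, ...
  status <- sym_is_zero(res, seed = seed, n = n,
                        sampler = .verify_sampler)
  # numeric max |residual| over the sample protocol
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  free <- sym_vars(res)
  worst <- NA_real_; got <- 0L; tries <- 0L
  while (got < n && tries < 40L * n) {
    tries <- tries + 1L
    vals <- stats::setNames(lapply(free, .verify_sampler), free)
    v <- tryCatch(sym_eval(res, vals), error = function(e) NA_real_)
    if (length(v) != 1 || !is.finite(v) || abs(v) > 1e10) next
    worst <- max(worst, abs(v), na.rm = TRUE)
    got <- got + 1L
  }
  structure(list(target = target_id,
                 solution = paste0(sol$method, "/", sol$entry_id,
                                   if (!is.na(sol$set_source))
                                     paste0("/eq", sol$set_source)),
                 symbolic_status = status,
                 residual_expression = if (status != "zero") res else NULL,
                 numeric_max_abs = worst, sample_seed = seed),
            class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat("Residual of ", x$solution, " in ", x$target, ": ",
      x$symbolic_status, " (max |res| = ",
      format(x$numeric_max_abs, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Exact PDE lift of a derived travelling-wave set
#'
#' Establishes, by two exact symbolic computations, that every solution
#' assembled from a derived parameter set solves the full model equation
#' in `(t, x, y)`:
#' 1. substituting `M = u(t - kx x - ky y)` into the equation reproduces
#'    the reduced equation exactly (an identity in the jet polynomials),
#' 2. the set satisfies every coefficient equation of its algebraic
#'    system exactly, so the assembled profile solves the reduced
#'    equation wherever the auxiliary function obeys its defining
#'    relation.
#' A seeded numeric spot check of the lifted field guards the
#' composition.
#'
#' @param pset a derived `parameter_set` (sqrt-free assignments).
#' @param k wave vector of the reduction the set was solved on.
#' @param entry library entry used for the spot check (default the tanh
#'   kink / hyperbolic case of the set's method).
#' @param seed seed for the spot check.
#' @return list with `reduction_exact`, `system_exact` (logicals) and
#'   `spot_max_abs`.
#' @export
pde_lift_check <- function(pset, k, entry = NULL, seed = 0) {
  model <- bac_model()
  ode <- reduce_plane_wave(model, k)
  printed <- paper_odes(model)[[as.character(
    if (sum(k^2) == 2) "28" else if (k[1] == 1) "23" else "18")]]
  reduction_exact <- rp_equal(ode$rp, printed$rp)
  sys <- build_algebraic_system(printed, pset$method)
  st <- verify_parameter_set(sys, pset, seed = seed)
  system_exact <- all(st == "zero")
  if (is.null(entry)) {
    lib <- switch(pset$method, tanh = tanh_library(),
                  gg2 = gg2_library(), aux = aux_library())
    entry <- lib[[which(vapply(lib, function(e)
      e$family == "hyperbolic", logical(1)))[1]]]
  }
  sol <- assemble_solutions(pset, list(entry),
                            r_def = bquote(t - .(k[1]) * x - .(k[2]) * y))[[1]]
  field <- sym_subs(sol$expr, list(r = sol$r_def))
  res <- sym_subs(pde_residual(model, field), sol$assignments)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  free <- sym_vars(res)
  worst <- 0; got <- 0L; tries <- 0L
  while (got < 25L && tries < 500L) {
    tries <- tries + 1L
    vals <- stats::setNames(lapply(free, .verify_sampler), free)
    # stay clear of the branch's own degeneracies: a draw that blows up
    # one of the set's parameter values sits next to a zero of a branch
    # condition (e.g. sigma near 1/2 for the a0 = 1/2 family)
    pv <- vapply(pset$assignments, function(a) {
      x <- tryCatch(sym_eval(a, vals), error = function(e) NA_real_)
      if (length(x) == 1) x else NA_real_
    }, numeric(1))
    if (any(!is.finite(pv)) || any(abs(pv) > 1e3)) next
    v <- tryCatch(sym_eval(res, vals), error = function(e) NA_real_)
    if (!is.finite(v)) next
    sc <- .expr_scale(res, vals)
    if (!is.finite(sc)) next
    worst <- max(worst, abs(v) / max(1, sc))
    got <- got + 1L
  }
  list(reduction_exact = reduction_exact, system_exact = system_exact,
       spot_max_abs = worst)
}
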