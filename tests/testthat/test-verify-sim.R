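# Verification machinery and the finite-difference front cross-check.

test_that("residual reports separate exact solutions from published near-misses", {
  po <- paper_odes()
  # the equilibrium u = 1 solves the |k|^2 = 1 reduction
  triv <- structure(list(expr = quote(1 + 0 * r), r_def = quote(t - y),
                         method = "tanh", set_source = NA_character_,
                         set_branch = "", set_provenance = "derived",
                         entry_id = "const", entry_branch = 1,
                         family = "constant", conditions = "",
                         vacuous = FALSE, assignments = list()),
                    class = "closed_form_solution")
  expect_identical(residual_report(triv, po[["18"]])$symbolic_status,
                   "zero")
  # derived kink set solves the |k|^2 = 2 reduction
  sys <- build_algebraic_system(po[["28"]], "tanh")
  der <- Filter(function(x) grepl("b1=0", x$branch, fixed = TRUE) &&
                  grepl("(sigma+1)/2", x$branch, fixed = TRUE),
                solve_parameter_sets(sys)$sets)[[1]]
  sol <- Filter(function(x) x$entry_id == "neg_tanh",
                assemble_solutions(der, r_def = quote(t - x - y)))[[1]]
  rep1 <- residual_report(sol, po[["28"]])
  expect_identical(rep1$symbolic_status, "zero")
  expect_lt(rep1$numeric_max_abs, 1e-10)
  # the published counterpart set leaves a nonzero residual
  psol <- Filter(function(x) x$entry_id == "neg_tanh",
                 assemble_solutions(paper_parameter_sets()[["123"]],
                                    r_def = quote(t - x - y)))[[1]]
  rep2 <- residual_report(psol, po[["28"]])
  expect_identical(rep2$symbolic_status, "nonzero")
  expect_gt(rep2$numeric_max_abs, 1e-8)
})

test_that("derived travelling waves lift to exact solutions of the full equation", {
  po <- paper_odes()
  for (pair in list(list("18", "gg2", c(0, 1)),
                    list("28", "tanh", c(1, 1)))) {
    sys <- build_algebraic_system(po[[pair[[1]]]], pair[[2]])
    sets <- solve_parameter_sets(sys)$sets
    der <- Filter(function(x) grepl("(sigma+1)/2", x$branch,
                                    fixed = TRUE), sets)[[1]]
    chk <- pde_lift_check(der, pair[[3]])
    expect_true(chk$reduction_exact)
    expect_true(chk$system_exact)
    expect_lt(chk$spot_max_abs, 1e-8)
  }
})

test_that("uniform equilibria stay put and the pointwise dynamics escape the unstable state upward", {
  m <- bac_model(d = 1, gamma = 1, sigma = 0.4)
  sim <- simulate_1d(m, D_eff = 1, u0 = function(x) rep(0.4, length(x)),
                     xlim = c(-10, 10), n = 101, t_end = 5)
  expect_lt(max(abs(sim$values - 0.4)), 1e-10)
  # with diffusion off and a start between sigma and 1, the reaction
  # drives the state to the stable equilibrium 1
  sim2 <- simulate_1d(m, D_eff = 1e-9,
                      u0 = function(x) rep(0.7, length(x)),
                      xlim = c(-1, 1), n = 21, t_end = 40)
  expect_lt(max(abs(sim2$values[nrow(sim2$values), ] - 1)), 1e-4)
})

test_that("with the reaction off, Neumann walls conserve the discrete mean", {
  m <- bac_model(d = 1, gamma = 1e-300, sigma = 0.5)
  u0 <- function(x) 0.5 + 0.3 * exp(-x^2)
  sim <- simulate_1d(m, D_eff = 0.8, u0 = u0, xlim = c(-10, 10), n = 101,
                     t_end = 5)
  # trapezoid-weighted mean is the discrete mass conserved by the
  # Neumann ghost stencil
  w <- c(0.5, rep(1, ncol(sim$values) - 2), 0.5)
  means <- as.numeric(sim$values %*% w) / sum(w)
  expect_lt(max(abs(means - means[1])), 1e-8)
})

test_that("the scheme converges at second order on the kink benchmark", {
  coarse <- kink_front_check(0.5, 0.3, n = 201)
  fine <- kink_front_check(0.5, 0.3, n = 401)
  ratio <- coarse$shape_linf / fine$shape_linf
  expect_gt(ratio, 3)   # halving h cuts the error by about 4
  expect_lt(ratio, 6)
})

test_that("speed measurement recovers an exact synthetic translation", {
  x <- seq(-50, 50, length.out = 401)
  times <- seq(0, 10, length.out = 21)
  vals <- t(vapply(times, function(tt)
    0.75 + 0.25 * tanh(0.3 * (x - 1.7 * tt)), numeric(length(x))))
  sim <- structure(list(x = x, times = times, values = vals,
                        h = x[2] - x[1], dt = NA, D_eff = NA,
                        scheme = "synthetic"), class = "sim_result")
  sp <- measure_speed(sim, 0.75)
  expect_equal(sp$speed, 1.7, tolerance = 1e-6)
  # an equilibrium field has no crossing
  flat <- sim; flat$values <- matrix(0.5, length(times), length(x))
  expect_error(measure_speed(flat, 0.75), "not crossed")
})

test_that("the derived kink moves at unit speed and connects sigma to 1", {
  k <- kink_front_check(1, 0.5)
  expect_lt(k$speed_error, 0.02)
  expect_lt(max(k$end_errors), 0.01)
  expect_lt(k$shape_linf, 0.01)
})
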