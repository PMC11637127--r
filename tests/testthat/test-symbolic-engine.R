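# The exact polynomial / rational-function engine and the call-tree
# differentiator that everything else builds on.

test_that("exact polynomial arithmetic satisfies ring identities on random inputs", {
  set.seed(42)
  for (i in 1:20) {
    p <- random_poly_call(c("x", "y"), deg = 2, nterms = 3)
    q <- random_poly_call(c("x", "z"), deg = 2, nterms = 3)
    s <- random_poly_call(c("y", "z"), deg = 1, nterms = 2)
    lhs <- bquote((.(p) + .(q)) * .(s))
    rhs <- bquote(.(p) * .(s) + .(q) * .(s))
    expect_identical(sym_is_zero(bquote(.(lhs) - .(rhs))), "zero")
    # derivative is a ring derivation: (pq)' = p'q + pq'
    d_lhs <- acwave:::rp_deriv(acwave:::rp_from_call(bquote(.(p) * .(q))), "x")
    d_rhs <- acwave:::rp_add(
      acwave:::rp_mul(acwave:::rp_deriv(acwave:::rp_from_call(p), "x"),
                      acwave:::rp_from_call(q)),
      acwave:::rp_mul(acwave:::rp_from_call(p),
                      acwave:::rp_deriv(acwave:::rp_from_call(q), "x")))
    expect_true(acwave:::rp_equal(d_lhs, d_rhs))
  }
})

test_that("rational-function equality cancels common factors exactly", {
  f <- acwave:::rf_from_call(quote((x^2 - y^2) / (x - y)))
  expect_true(acwave:::rf_equal(f, acwave:::rf_from_call(quote(x + y))))
  g <- acwave:::rf_simplify(
    acwave:::rf_from_call(quote((2 * x^2 + 4 * x * y + 2 * y^2) /
                                  (x + y))))
  expect_true(acwave:::rp_is_zero(
    acwave:::rp_sub(g$num, acwave:::rp_from_call(quote(2 * x + 2 * y)))))
})

test_that("chain-rule differentiation matches central finite differences", {
  exprs <- list(quote(tanh(sqrt(2) * r) * sech(r)^2),
                quote(coth(r) + csch(0.5 * r)),
                quote(sec(0.3 * r) * tan(0.3 * r)),
                quote(exp(-r^2 / 2) / (1 + r^2)),
                quote(csc(0.4 * r) + cot(0.4 * r)))
  for (e in exprs) {
    de <- sym_d(e, "r")
    for (r0 in c(0.6, 1.3, -0.9)) {
      h <- 1e-6
      fd <- (sym_eval(e, list(r = r0 + h)) -
               sym_eval(e, list(r = r0 - h))) / (2 * h)
      expect_equal(sym_eval(de, list(r = r0)), fd, tolerance = 1e-6)
    }
  }
})

test_that("unknown-function differentiation follows the chain rule structurally", {
  d1 <- sym_d(quote(u(x^2 + 2 * x - 2 * y + y^2)), "x")
  # evaluates as u1(g) * g_x for any concrete derivative function u1
  env <- list(x = 0.7, y = -0.3)
  got <- eval(d1, c(env, list(u1 = function(z) sin(z))),
              acwave::math_env())
  want <- sin(0.7^2 + 1.4 + 0.6 + 0.09) * (2 * 0.7 + 2)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("three-valued zero test distinguishes identities from near-misses", {
  expect_identical(sym_is_zero(quote(sinh(x)^2 - cosh(x)^2 + 1)), "zero")
  expect_identical(sym_is_zero(quote(sech(x)^2 + tanh(x)^2 - 1)), "zero")
  expect_identical(sym_is_zero(quote(tanh(x) - x)), "nonzero")
  expect_identical(sym_is_zero(quote((x + y)^2 - x^2 - 2 * x * y - y^2)),
                   "zero")  # decided exactly, not by sampling
})

test_that("total derivatives thread the chain rule through the jet", {
  expect_identical(total_derivative(quote(M), "x"), quote(M_x))
  expect_identical(sym_is_zero(bquote(
    .(total_derivative(quote(t * M), "t")) - (M + t * M_t))), "zero")
  expect_identical(sym_is_zero(bquote(
    .(total_derivative(quote(M_x^2), "x")) - 2 * M_x * M_xx)), "zero")
  # D_x and D_y commute on a nontrivial jet polynomial
  p <- quote(t * M * M_x + M_y^2)
  dxy <- total_derivative(total_derivative(p, "x"), "y")
  dyx <- total_derivative(total_derivative(p, "y"), "x")
  expect_identical(sym_is_zero(bquote(.(dxy) - .(dyx))), "zero")
})
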