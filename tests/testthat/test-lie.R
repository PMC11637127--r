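# Lie point symmetries: prolongation, determining equations, the
# 4-dimensional algebra, and the commutator table.

test_that("prolongation of translations is trivial and of phi = M is diagonal", {
  pr <- prolong2(vector_field(chi1 = 1))
  for (nm in c("phi_t", "phi_x", "phi_y", "phi_xx", "phi_yy"))
    expect_identical(pr[[nm]], 0)
  # linear-in-M coefficient: phi = M gives phi^t = M_t, phi^xx = M_xx
  prM <- prolong2(vector_field(phi = quote(M)))
  expect_identical(sym_is_zero(bquote(.(prM$phi_t) - M_t)), "zero")
  expect_identical(sym_is_zero(bquote(.(prM$phi_xx) - M_xx)), "zero")
  expect_identical(sym_is_zero(bquote(.(prM$phi_yy) - M_yy)), "zero")
})

test_that("the prolonged rotation annihilates the Laplacian combination", {
  b <- generator_basis()
  pr <- acwave:::prolong2_rp(acwave:::vf_rp(b$X4))
  # X4^(2) applied to (M_xx + M_yy) is phi_xx + phi_yy
  lap_action <- acwave:::rp_add(pr$phi_xx, pr$phi_yy)
  expect_true(acwave:::rp_is_zero(lap_action))
})

test_that("each basis generator leaves the equation invariant exactly", {
  m <- bac_model()
  for (g in generator_basis())
    expect_identical(invariance_residual(m, g), 0)
  # a dilation is not a symmetry for generic gamma
  expect_false(identical(
    invariance_residual(m, vector_field(chi1 = quote(t), chi2 = quote(x))),
    0))
})

test_that("determining equations force a 4-dimensional algebra with the published general solution", {
  m <- bac_model()
  sys <- determining_equations(m, degree = 2)
  sol <- solve_determining(sys)
  expect_identical(sol$n_free, 4L)
  expect_identical(sol$general$phi, 0)
  # the computed basis spans exactly the canonical generators
  for (g in generator_basis())
    expect_false(is.null(acwave:::.vf_in_basis(g, sol$fields)))
  for (f in sol$fields)
    expect_false(is.null(acwave:::.vf_in_basis(f, generator_basis())))
  # the published general infinitesimals (chi1 = C3, chi2 = -C1 y + C4,
  # chi3 = C1 x + C2, phi = 0) satisfy every determining equation
  gen <- vector_field(chi1 = 3, chi2 = quote(-2 * y + 4),
                      chi3 = quote(2 * x + 2), phi = 0)
  res <- acwave:::det_substitute(sys, acwave:::vf_to_coefs(sys, gen))
  expect_true(all(vapply(res, acwave:::rp_is_zero, logical(1))))
  # a scaling candidate violates at least one determining equation
  res2 <- acwave:::det_substitute(
    sys, acwave:::vf_to_coefs(sys, vector_field(chi1 = quote(t),
                                                chi2 = quote(x))))
  expect_false(all(vapply(res2, acwave:::rp_is_zero, logical(1))))
})

test_that("commutator table matches the published structure constants", {
  b <- generator_basis()
  tab <- commutator_table(b)
  cc <- tab$constants
  expected <- array(0, dim = c(4, 4, 4))
  expected[2, 4, 3] <- -1   # [X2, X4] = -X3
  expected[4, 2, 3] <- 1
  expected[3, 4, 2] <- 1    # [X3, X4] = X2
  expected[4, 3, 2] <- -1
  expect_equal(cc, expected)
  expect_true(all(cc[1, , ] == 0), info = "X1 is central")
})

test_that("bracket antisymmetry and Jacobi hold for random polynomial fields", {
  set.seed(7)
  for (i in 1:6) {
    a <- random_vf(); b <- random_vf(); c <- random_vf()
    ab <- lie_bracket(a, b); ba <- lie_bracket(b, a)
    for (comp in c("chi1", "chi2", "chi3", "phi"))
      expect_true(acwave:::rp_is_zero(acwave:::rp_add(
        acwave:::rp_from_call(ab[[comp]]),
        acwave:::rp_from_call(ba[[comp]]))))
    jac <- Reduce(function(p, q) {
      # accumulate [[a,b],c] + [[b,c],a] + [[c,a],b] componentwise
      Map(function(x, y) acwave:::rp_add(x, y), p, q)
    }, list(acwave:::vf_rp(lie_bracket(lie_bracket(a, b), c)),
            acwave:::vf_rp(lie_bracket(lie_bracket(b, c), a)),
            acwave:::vf_rp(lie_bracket(lie_bracket(c, a), b))))
    expect_true(all(vapply(jac, acwave:::rp_is_zero, logical(1))))
  }
})
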