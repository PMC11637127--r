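# The model container: residual structure, parameter validation, the
# factorized reaction, and uniform steady states.

test_that("residual carries the printed coefficient pattern", {
  m <- bac_model()
  rp <- acwave:::model_residual_rp(m)
  co <- acwave:::rp_coeffs(rp, "M")
  expect_true(acwave:::rp_equal(co[["3"]],
                                acwave:::rp_from_call(quote(gamma))))
  expect_true(acwave:::rp_equal(co[["2"]],
                                acwave:::rp_from_call(quote(-(gamma * (1 + sigma))))))
  expect_true(acwave:::rp_equal(co[["1"]],
                                acwave:::rp_from_call(quote(gamma * sigma))))
})

test_that("reaction factors exactly as gamma * M * (M - 1) * (M - sigma)", {
  m <- bac_model()
  reaction <- bquote(.(m$residual) - (M_t - d * M_xx - d * M_yy))
  factored <- quote(gamma * M * (M - 1) * (M - sigma))
  expect_identical(sym_is_zero(bquote(.(reaction) - .(factored))), "zero")
})

test_that("numeric parameter validation enforces the sign constraints", {
  expect_error(bac_model(d = -1), "d must be > 0")
  expect_error(bac_model(gamma = 0), "gamma must be > 0")
  expect_warning(bac_model(sigma = 1.4), "outside the nominal interval")
  expect_silent(bac_model(d = 0.5, gamma = 1, sigma = 0.3))
})

test_that("the uniform steady states are exactly 0, sigma and 1", {
  m <- bac_model()
  for (c0 in list(0, 1, quote(sigma))) {
    res <- pde_residual(m, bquote(.(c0) + 0 * t))
    expect_identical(sym_is_zero(res), "zero")
  }
  # any other constant leaves gamma * c (c - 1)(c - sigma)
  res <- pde_residual(m, quote(0.25 + 0 * t))
  expect_identical(sym_is_zero(res), "nonzero")
  expect_identical(
    sym_is_zero(bquote(.(res) -
                         gamma * 0.25 * (0.25 - 1) * (0.25 - sigma))),
    "zero")
})

test_that("residual is linear in the second-derivative jets", {
  m <- bac_model()
  rp <- acwave:::model_residual_rp(m)
  for (v in c("M_xx", "M_yy"))
    expect_identical(acwave:::rp_degree(rp, v), 1L)
})

test_that("fields with unknown variables are rejected", {
  expect_error(pde_residual(bac_model(), quote(z^2 + t)),
               "unknown variables")
})

test_that("gridded residual vanishes to stencil order on an exact front", {
  d <- 0.5; sigma <- 0.3
  gamma <- 1 / (d * (sigma + 1)^2)
  w <- sqrt((sigma - 1)^2 / (16 * d^2 * (sigma + 1)^2))
  u <- function(r) (sigma + 1) / 2 + 2 * d * (sigma + 1) * w * tanh(w * r)
  m1 <- bac_model(d = 2 * d, gamma = gamma, sigma = sigma)  # 1-D: D_eff = 2d
  tt <- seq(0, 1, length.out = 41)
  xx <- seq(-15, 15, length.out = 301)
  vals <- outer(tt, xx, function(a, b) u(a - b))
  res <- pde_residual(m1, list(tt = tt, xx = xx, values = vals))
  expect_lt(max(abs(res)), 5e-3)   # second-order stencil truncation
})
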