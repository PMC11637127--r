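# Similarity and plane-wave reductions, faithfulness audits.

test_that("plane-wave reduction reproduces the printed travelling-wave equations", {
  m <- bac_model()
  po <- paper_odes(m)
  o18 <- reduce_plane_wave(m, c(0, 1))
  o23 <- reduce_plane_wave(m, c(1, 0))
  o28 <- reduce_plane_wave(m, c(1, 1))
  expect_true(acwave:::rp_equal(o18$rp, po[["18"]]$rp))
  expect_true(acwave:::rp_equal(o23$rp, po[["23"]]$rp))
  expect_true(acwave:::rp_equal(o28$rp, po[["28"]]$rp))
  expect_error(reduce_plane_wave(m, c(0, 0)), "nonzero")
})

test_that("only |k|^2 enters the reduced equation (rotational invariance)", {
  m <- bac_model()
  # rational direction pairs with equal squared norm
  same_norm <- list(list(c(1, 0), c(0, 1)),
                    list(c(1, 0), c(3 / 5, 4 / 5)),
                    list(c(3 / 5, 4 / 5), c(5 / 13, 12 / 13)),
                    list(c(1, 1), c(-1, 1)),
                    list(c(3, 4), c(5, 0)))
  for (pr in same_norm)
    expect_true(acwave:::rp_equal(reduce_plane_wave(m, pr[[1]])$rp,
                                  reduce_plane_wave(m, pr[[2]])$rp))
  # different norms give different equations
  expect_false(acwave:::rp_equal(reduce_plane_wave(m, c(1, 0))$rp,
                                 reduce_plane_wave(m, c(1, 1))$rp))
})

test_that("every stored invariant is annihilated by its generator", {
  m <- bac_model()
  for (cs in c("X1", "X2", "X3", "X4")) {
    red <- reduce_by_generator(m, cs)
    expect_true(acwave:::invariants_annihilated(red), info = cs)
  }
  # in particular the rotation annihilates x^2 + y^2 exactly
  b <- generator_basis()
  expect_true(acwave:::rp_is_zero(acwave:::vf_apply_rp(
    acwave:::vf_rp(b$X4), acwave:::rp_from_call(quote(x^2 + y^2)))))
})

test_that("translation reductions are faithful; their chains close exactly", {
  m <- bac_model()
  for (cs in c("X2", "X3")) {
    red <- reduce_by_generator(m, cs)
    v <- verify_reduction(red)
    expect_true(v$faithful, info = cs)
    expect_identical(v$leftover, 0)
  }
  red4 <- reduce_by_generator(m, "X4")
  expect_true(verify_reduction(red4)$faithful)  # via the k = (1,1) route
})

test_that("the time-translation second stage is as printed, with the exact leftover", {
  m <- bac_model()
  red <- reduce_by_generator(m, "X1")
  expect_identical(unname(red$provenance["stage2"]), "as_printed")
  v <- verify_reduction(red)
  expect_false(v$faithful)
  # leftover = -4 d ((r + 1) u'' + u'): a u1 term and an r-dependent
  # factor on u2 that the printed equation drops
  expect_identical(
    sym_is_zero(bquote(.(v$leftover) -
                         (-(4 * d * ((r + 1) * u2 + u1))))), "zero")
  # the faithful variable-coefficient equation is stored alongside
  expect_identical(red$ode$source, "faithful_12")
  expect_match(paste(deparse(red$ode$expr), collapse = " "), "r \\+ 2")
})

test_that("reduced equations respect the declared shape constraints", {
  expect_error(ord_ode(quote(u1 - u^4)), "degree")
  expect_error(ord_ode(quote(u3 - u^2)), "second order")
  o <- paper_odes()[["18"]]
  expect_identical(acwave:::rp_degree(o$rp, "u"), 3L)
})
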