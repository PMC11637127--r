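# Expansion methods: balance, libraries, algebraic systems, derived and
# published parameter sets, assembly and classification.

test_that("homogeneous balance gives N = 1 on every cubic reduction, and fails correctly otherwise", {
  po <- paper_odes()
  for (key in names(po))
    for (m in c("aux", "gg2", "tanh"))
      expect_identical(homogeneous_balance(po[[key]], m), 1L)
  expect_identical(homogeneous_balance(ord_ode(quote(u2 - u^2)), "tanh"), 2L)
  # a first-order cubic balances at N = 1/2: method inapplicable
  expect_error(homogeneous_balance(ord_ode(quote(u1 - u^3)), "tanh"),
               "non-integer")
})

test_that("all library entries satisfy their defining relations below 1e-10", {
  ls <- library_soundness(seed = 0)
  expect_identical(length(aux_library()), 16L)
  expect_identical(length(gg2_library()), 3L)
  expect_identical(length(tanh_library()), 5L)
  expect_true(all(is.finite(ls$max_residual)))
  expect_true(all(ls$max_residual < 1e-10))
})

test_that("generated algebraic systems match hand expansions at key coefficients", {
  po <- paper_odes()
  sys_t <- build_algebraic_system(po[["28"]], "tanh")
  i <- match("S^3", sys_t$labels)
  expect_true(acwave:::rp_equal(
    sys_t$equations[[i]],
    acwave:::rp_from_call(quote(gamma * a1^3 - 4 * d * a1))))
  sys_g <- build_algebraic_system(po[["18"]], "gg2")
  j <- match("S^2", sys_g$labels)
  expect_true(acwave:::rp_equal(
    sys_g$equations[[j]],
    acwave:::rp_from_call(
      quote(a1 * kappa + gamma * a1^2 * (3 * a0 - (1 + sigma))))))
  # the zero ansatz satisfies every aux equation trivially
  sys_a <- build_algebraic_system(po[["13"]], "aux")
  for (e in sys_a$equations) {
    z <- acwave:::rp_subst(acwave:::rp_subst(e, "a0", 0), "a1", 0)
    expect_true(acwave:::rp_is_zero(z))
  }
})

test_that("derived (G'/G^2) sets are exact and the (sigma+1)/2 branch carries the published a0, a1, d", {
  sys <- build_algebraic_system(paper_odes()[["18"]], "gg2")
  res <- solve_parameter_sets(sys)
  expect_identical(length(res$sets), 3L)
  for (s in res$sets)
    expect_true(all(verify_parameter_set(sys, s) == "zero"))
  s <- Filter(function(x) grepl("(sigma+1)/2", x$branch, fixed = TRUE),
              res$sets)[[1]]
  rfc <- function(e) acwave:::rf_from_call(e)
  expect_true(acwave:::rf_equal(rfc(s$assignments$a0),
                                rfc(quote((sigma + 1) / 2))))
  expect_true(acwave:::rf_equal(rfc(s$assignments$a1),
                                rfc(quote(-2 * kappa / (gamma * (sigma + 1))))))
  expect_true(acwave:::rf_equal(rfc(s$assignments$d),
                                rfc(quote(2 / (gamma * (sigma + 1)^2)))))
  # tau carries (sigma - 1)^2 where the published set prints
  # sigma^2 + 6 sigma + 1
  expect_true(acwave:::rf_equal(
    rfc(s$assignments$tau),
    rfc(quote(-gamma^2 * (sigma + 1)^2 * (sigma - 1)^2 / (16 * kappa)))))
})

test_that("derived tanh sets are exact; the single-tanh branch carries the published a0, a1, gamma", {
  sys <- build_algebraic_system(paper_odes()[["28"]], "tanh")
  res <- solve_parameter_sets(sys)
  expect_gte(length(res$sets), 6L)
  for (s in res$sets)
    expect_true(all(verify_parameter_set(sys, s) == "zero"))
  s <- Filter(function(x) grepl("b1=0", x$branch, fixed = TRUE) &&
                grepl("(sigma+1)/2", x$branch, fixed = TRUE),
              res$sets)[[1]]
  rfc <- function(e) acwave:::rf_from_call(e)
  expect_true(acwave:::rf_equal(rfc(s$assignments$a0),
                                rfc(quote((sigma + 1) / 2))))
  expect_true(acwave:::rf_equal(rfc(s$assignments$a1),
                                rfc(quote(-2 * d * (sigma + 1)))))
  expect_true(acwave:::rf_equal(rfc(s$assignments$gamma),
                                rfc(quote(1 / (d * (sigma + 1)^2)))))
  expect_true(acwave:::rf_equal(
    rfc(s$assignments$kappa),
    rfc(quote(-(sigma - 1)^2 / (16 * d^2 * (sigma + 1)^2)))))
  # the two-sided branch reproduces the derived counterpart of the
  # published second set: b1 = -kappa a1 and the /64 kappa
  s2 <- Filter(function(x) grepl("a1,b1!=0", x$branch, fixed = TRUE) &&
                 grepl("(sigma+1)/2", x$branch, fixed = TRUE),
               res$sets)[[1]]
  expect_true(acwave:::rf_equal(
    rfc(s2$assignments$kappa),
    rfc(quote(-(sigma - 1)^2 / (64 * d^2 * (sigma + 1)^2)))))
  expect_true(acwave:::rf_equal(
    rfc(s2$assignments$b1),
    rfc(quote(-(sigma - 1)^2 / (32 * d * (sigma + 1))))))
})

test_that("derived auxiliary sets cover the three equilibrium constant terms with the published structure", {
  sys <- build_algebraic_system(paper_odes()[["13"]], "aux")
  res <- solve_parameter_sets(sys)
  expect_identical(length(res$sets), 6L)   # 3 roots x 2 sqrt branches
  branches <- vapply(res$sets, function(s) s$branch, character(1))
  expect_identical(sum(grepl("a0 = 0", branches, fixed = TRUE)), 2L)
  expect_identical(sum(grepl("a0 = 1", branches, fixed = TRUE)), 2L)
  expect_identical(sum(grepl("a0 = sigma", branches, fixed = TRUE)), 2L)
  for (s in res$sets)
    expect_true(all(verify_parameter_set(sys, s) == "zero"))
  # the a0 = sigma branch reproduces the published gamma and a1^2
  s <- Filter(function(x) grepl("a0 = sigma", x$branch, fixed = TRUE),
              res$sets)[[1]]
  vals <- list(b1 = 0.7, b2 = 1.1, b3 = -0.8, d = 0.9)
  expect_equal(sym_eval(s$assignments$gamma, vals),
               9 * 1.1^2 * 0.9 / (2 * -0.8) - 16 * 0.7 * 0.9,
               tolerance = 1e-12)
  expect_equal(sym_eval(s$assignments$a1, vals)^2,
               16 * 0.8^2 / (9 * 1.1^2 - 32 * 0.7 * -0.8),
               tolerance = 1e-12)
  expect_equal(sym_eval(s$assignments$sigma, vals),
               sym_eval(s$assignments$a0, vals), tolerance = 1e-14)
})

test_that("published-set audit: exact where exact, sigma = 0 kills every gg2/tanh residual", {
  aud <- audit_paper_sets(c("62", "96", "114", "123", "130"))
  expect_true(all(aud$status[aud$set %in% c("62", "96")] == "zero"))
  for (key in c("114", "123", "130")) {
    sub <- aud[aud$set == key, ]
    expect_true(any(sub$status == "nonzero"), info = key)
    expect_true(all(sub$zero_at_sigma0), info = key)
  }
})

test_that("published set 79 does not satisfy its system under any printed sign pairing", {
  # its sigma component lacks a factor 3 on the radical term; with that
  # factor restored both branches are exact
  sys <- build_algebraic_system(paper_odes()[["13"]], "aux")
  aud <- audit_paper_sets("79")
  expect_true(any(aud$status == "nonzero"))
  Dd <- quote(sqrt(b2^2 * (9 * b2^2 - 32 * b1 * b3) * d^2))
  for (s1 in c(1, -1)) {
    fixed <- parameter_set(list(
      a0 = 1,
      a1 = sym_subs(bquote((pm * .(Dd) + 3 * b2^2 * d) /
                             (4 * b1 * b2 * d)), list(pm = s1)),
      gamma = sym_subs(bquote((mp * 3 * .(Dd) + 9 * b2^2 * d -
                                 16 * b1 * b3 * d) / (4 * b3)),
                       list(mp = -s1)),
      sigma = sym_subs(bquote((mp * 3 * .(Dd) - 9 * b2^2 * d +
                                 32 * b1 * b3 * d) / (16 * b1 * b3 * d)),
                       list(mp = -s1))), "aux")
    expect_true(all(verify_parameter_set(sys, fixed) == "zero"))
  }
})

test_that("derived and published sets agree where expected (concordance table)", {
  cc <- derived_vs_paper_concordance()
  expect_true(all(cc$agrees))
  expect_setequal(cc$component[cc$set == "114"], c("a0", "a1", "d", "tau"))
  expect_setequal(cc$component[cc$set == "123"],
                  c("a0", "a1", "gamma", "kappa"))
})

test_that("assembly attaches conditions, flags vacuous cases, and reproduces the published kink family", {
  pp <- paper_parameter_sets()
  sols <- assemble_solutions(pp[["123"]], r_def = quote(t - x - y))
  expect_identical(length(sols), 5L)
  vac <- vapply(sols, function(s) s$vacuous, logical(1))
  ids <- vapply(sols, function(s) s$entry_id, character(1))
  # the set forces kappa < 0, so the kappa > 0 (tan/cot) cases are vacuous
  expect_true(all(vac[ids %in% c("pos_tan", "pos_cot")]))
  expect_false(any(vac[ids %in% c("neg_tanh", "neg_coth")]))
  # the tanh case equals the published family expression
  got <- Filter(function(s) s$entry_id == "neg_tanh", sols)[[1]]$expr
  printed_125 <- quote(((sigma + 1) / 2) + (-2 * d * (sigma + 1)) *
                         (-sqrt(-(-(sigma^2 + 6 * sigma + 1) /
                                    (16 * d^2 * (sigma + 1)^2))) *
                            tanh(sqrt(-(-(sigma^2 + 6 * sigma + 1) /
                                          (16 * d^2 * (sigma + 1)^2))) * r)))
  for (vals in list(list(d = 0.4, sigma = 0.35, r = 0.8),
                    list(d = 1.1, sigma = 0.6, r = -1.4))) {
    expect_equal(sym_eval(got, vals), sym_eval(printed_125, vals),
                 tolerance = 1e-12)
  }
})

test_that("derived kink solutions connect the equilibria sigma and 1", {
  sys <- build_algebraic_system(paper_odes()[["28"]], "tanh")
  s <- Filter(function(x) grepl("b1=0", x$branch, fixed = TRUE) &&
                grepl("(sigma+1)/2", x$branch, fixed = TRUE),
              solve_parameter_sets(sys)$sets)[[1]]
  sol <- Filter(function(x) x$entry_id == "neg_tanh",
                assemble_solutions(s, r_def = quote(t - x - y)))[[1]]
  for (vals in list(list(d = 0.5, sigma = 0.3), list(d = 1, sigma = 0.7))) {
    e <- sym_subs(sol$expr, vals)
    lims <- sort(c(sym_eval(e, list(r = -1e5)), sym_eval(e, list(r = 1e5))))
    expect_equal(lims, sort(c(vals$sigma, 1)), tolerance = 1e-10)
  }
})

test_that("classifier labels canonical profiles correctly", {
  cases <- list(
    list(quote(1 + tanh(r)), "kink"),
    list(quote(1 - tanh(r)), "anti-kink"),
    list(quote(2 + sech(r)^2), "bright"),
    list(quote(2 - sech(r)^2), "dark"),
    list(quote(coth(r)), "singular"),
    list(quote(csch(r)), "singular"),
    list(quote(tan(r)), "periodic"),
    list(quote(sec(1.1 * r)), "periodic"),
    list(quote(1 / (r^2 + 1)), "rational"),
    list(quote(3 + 0 * r), "constant"))
  for (cs in cases)
    expect_identical(as.character(classify_solution(cs[[1]])), cs[[2]],
                     info = deparse(cs[[1]]))
})
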