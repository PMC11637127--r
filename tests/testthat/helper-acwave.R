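# shared helpers for the test suite

expect_sym_zero <- function(expr, ...) {
  expect_identical(sym_is_zero(expr, ...), "zero")
}

# random small polynomial in the given variables (exact rational
# coefficients), as a call
random_poly_call <- function(vars, deg = 2, nterms = 4) {
  terms <- lapply(seq_len(nterms), function(i) {
    co <- sample(c(-3:-1, 1:3), 1)
    mono <- co
    for (v in vars) {
      k <- sample(0:deg, 1)
      if (k > 0) mono <- bquote(.(mono) * .(as.name(v))^.(k))
    }
    mono
  })
  Reduce(function(a, b) bquote(.(a) + .(b)), terms)
}

# a random point vector field with low-degree polynomial components
random_vf <- function() {
  vector_field(chi1 = random_poly_call(c("t", "x"), deg = 1, nterms = 2),
               chi2 = random_poly_call(c("x", "y"), deg = 1, nterms = 2),
               chi3 = random_poly_call(c("y", "M"), deg = 1, nterms = 2),
               phi = random_poly_call(c("t", "M"), deg = 1, nterms = 2))
}

# the three expansion methods paired with the reduction each was applied
# to in the source analysis
method_ode_pairs <- function() {
  list(aux = "13", gg2 = "18", tanh = "28")
}
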