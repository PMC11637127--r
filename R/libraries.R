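# Closed-form solution libraries for the three auxiliary equations.
#
# aux : (S')^2 = b1 S^2 + b2 S^3 + b3 S^4          (generalized auxiliary)
# gg2 : H'    = tau + kappa H^2                    (ratio variable G'/G^2)
# tanh: S'    = kappa + S^2                        (extended modified tanh)
#
# Each entry stores the closed form actually satisfying its defining
# relation.  Several published forms contain typographical slips (a
# missing square, sech for csch, a stray b1 factor); those entries carry
# `corrected = TRUE` and keep the published expression in `as_printed`.
# The `pm` symbol in a closed form is the +/- branch selector, replaced by
# +1 or -1 at evaluation.  Every entry provides a seeded sampler drawing
# parameter values that satisfy its validity conditions, used by the
# residual soundness checks.

.aux_entry <- function(id, family, closed_form, cond_str, sampler,
                       branches = c(1, -1), corrected = FALSE,
                       as_printed = NULL) {
  structure(list(id = id, family = family, closed_form = closed_form,
                 conditions = cond_str, sampler = sampler,
                 branches = branches, corrected = corrected,
                 as_printed = as_printed),
            class = "aux_entry")
}

#' @export
print.aux_entry <- function(x, ...) {
  cat("[", x$id, "] (", x$family, ") S(r) = ",
      deparse(x$closed_form), "   {", x$conditions, "}",
      if (x$corrected) "  [corrected]" else "", "\n", sep = "")
  invisible(x)
}

# deterministic uniform draw helper
.udraw <- function(lo, hi) stats::runif(1, lo, hi)

#' Auxiliary-function library for the generalized auxiliary equation
#'
#' The sixteen closed-form solutions of
#' `(S')^2 = b1 S^2 + b2 S^3 + b3 S^4`, grouped into hyperbolic,
#' trigonometric, exponential and rational families, with their validity
#' conditions (`zeta = b2^2 - 4 b1 b3`).  Entries are numbered by family
#' position (h1..h8, t1..t4, e1..e2, r1..r2).
#'
#' @return list of 16 `aux_entry` objects.
#' @export
aux_library <- function() {
  zeta <- quote(b2^2 - 4 * b1 * b3)
  list(
    .aux_entry("h1", "hyperbolic",
      quote(-(b1 * b2 * sech(sqrt(b1) / 2 * r)^2) /
              (b2^2 - b1 * b3 * (1 + pm * tanh(sqrt(b1) / 2 * r))^2)),
      "b1 > 0", function() list(b1 = .udraw(.5, 1.5), b2 = .udraw(.5, 1.5),
                                b3 = .udraw(-1.2, -.4)),
      corrected = TRUE,
      as_printed = quote(-(b1 * b2 * sech(sqrt(b1) / 2 * r)^2) /
                           (b2^2 - b1 * b3 * (1 + pm * tanh(sqrt(b1) / 2 * r))))),
    .aux_entry("h2", "hyperbolic",
      quote((b1 * b2 * csch(sqrt(b1) / 2 * r)^2) /
              (b2^2 - b1 * b3 * (1 + pm * coth(sqrt(b1) / 2 * r))^2)),
      "b1 > 0", function() list(b1 = .udraw(.5, 1.5), b2 = .udraw(.5, 1.5),
                                b3 = .udraw(-1.2, -.4)),
      corrected = TRUE,
      as_printed = quote((b1 * b2 * csch(sqrt(b1) / 2 * r)^2) /
                           (b2^2 - b1 * b3 * (1 + pm * coth(sqrt(b1) / 2 * r))))),
    .aux_entry("h3", "hyperbolic",
      quote((2 * b1 * sech(sqrt(b1) * r)) /
              (pm * sqrt(b2^2 - 4 * b1 * b3) - b2 * sech(sqrt(b1) * r))),
      "b1 > 0, zeta > 0",
      function() { b1 <- .udraw(.5, 1.2); b2 <- .udraw(.8, 1.4)
        list(b1 = b1, b2 = b2, b3 = b2^2 / (4 * b1) - .udraw(.3, 1)) },
      corrected = TRUE,
      as_printed = quote((2 * b1 * sech(sqrt(b1) * r)^2) /
                           (pm * sqrt(b2^2 - 4 * b1 * b3) -
                              b2 * sech(sqrt(b1) * r)))),
    .aux_entry("h4", "hyperbolic",
      quote((2 * b1 * csch(sqrt(b1) * r)) /
              (pm * sqrt(-(b2^2 - 4 * b1 * b3)) - b2 * csch(sqrt(b1) * r))),
      "b1 > 0, zeta < 0",
      function() { b1 <- .udraw(.5, 1.2); b2 <- .udraw(.4, .9)
        list(b1 = b1, b2 = b2, b3 = b2^2 / (4 * b1) + .udraw(.3, 1)) },
      corrected = TRUE,
      as_printed = quote((2 * b1 * csch(sqrt(b1) * r)^2) /
                           (pm * sqrt(-(b2^2 - 4 * b1 * b3)) -
                              b2 * sech(sqrt(b1) * r)))),
    .aux_entry("h5", "hyperbolic",
      quote(-(b1 * sech(sqrt(b1) / 2 * r)^2) /
              (b2 + pm * 2 * sqrt(b1 * b3) * tanh(sqrt(b1) / 2 * r))),
      "b1 > 0, b3 > 0",
      function() list(b1 = .udraw(.6, 1.4), b2 = .udraw(.5, 1.2),
                      b3 = .udraw(.4, 1.1))),
    .aux_entry("h6", "hyperbolic",
      quote((b1 * csch(sqrt(b1) / 2 * r)^2) /
              (b2 + pm * 2 * sqrt(b1 * b3) * coth(sqrt(b1) / 2 * r))),
      "b1 > 0, b3 > 0",
      function() list(b1 = .udraw(.6, 1.4), b2 = .udraw(.5, 1.2),
                      b3 = .udraw(.4, 1.1))),
    .aux_entry("h7", "hyperbolic",
      quote(-(b1 / b2) * (1 + pm * tanh(sqrt(b1) / 2 * r))),
      "b1 > 0, zeta = 0",
      function() { b1 <- .udraw(.6, 1.4); b3 <- .udraw(.4, 1.1)
        list(b1 = b1, b2 = 2 * sqrt(b1 * b3), b3 = b3) }),
    .aux_entry("h8", "hyperbolic",
      quote(-(b1 / b2) * (1 + pm * coth(sqrt(b1) / 2 * r))),
      "b1 > 0, zeta = 0",
      function() { b1 <- .udraw(.6, 1.4); b3 <- .udraw(.4, 1.1)
        list(b1 = b1, b2 = 2 * sqrt(b1 * b3), b3 = b3) }),
    .aux_entry("t1", "trigonometric",
      quote(-(b1 * sec(sqrt(-b1) / 2 * r)^2) /
              (b2 + pm * 2 * sqrt(-b1 * b3) * tan(sqrt(-b1) / 2 * r))),
      "b1 < 0, b3 > 0",
      function() list(b1 = .udraw(-1.4, -.6), b2 = .udraw(.5, 1.2),
                      b3 = .udraw(.4, 1.1))),
    .aux_entry("t2", "trigonometric",
      quote(-(b1 * csc(sqrt(-b1) / 2 * r)^2) /
              (b2 + pm * 2 * sqrt(-b1 * b3) * cot(sqrt(-b1) / 2 * r))),
      "b1 < 0, b3 > 0",
      function() list(b1 = .udraw(-1.4, -.6), b2 = .udraw(.5, 1.2),
                      b3 = .udraw(.4, 1.1))),
    .aux_entry("t3", "trigonometric",
      quote((2 * b1 * sec(sqrt(-b1) * r)) /
              (pm * sqrt(b2^2 - 4 * b1 * b3) - b2 * sec(sqrt(-b1) * r))),
      "b1 < 0, zeta > 0",
      function() list(b1 = .udraw(-1.2, -.5), b2 = .udraw(.8, 1.4),
                      b3 = .udraw(.3, 1)),
      corrected = TRUE,
      as_printed = quote((2 * b1 * sec(sqrt(-b1) * r)^2) /
                           (pm * sqrt(b2^2 - 4 * b1 * b3) -
                              b2 * sec(sqrt(-b1) * r)))),
    .aux_entry("t4", "trigonometric",
      quote((2 * b1 * csc(sqrt(-b1) * r)) /
              (pm * sqrt(b2^2 - 4 * b1 * b3) - b2 * csc(sqrt(-b1) * r))),
      "b1 < 0, zeta > 0",
      function() list(b1 = .udraw(-1.2, -.5), b2 = .udraw(.8, 1.4),
                      b3 = .udraw(.3, 1)),
      corrected = TRUE,
      as_printed = quote((2 * b1 * csc(sqrt(-b1) * r)^2) /
                           (pm * sqrt(b2^2 - 4 * b1 * b3) -
                              b2 * sec(sqrt(-b1) * r)))),
    .aux_entry("e1", "exponential",
      quote((4 * b1 * exp(pm * sqrt(b1) * r)) /
              ((exp(pm * sqrt(b1) * r) - b2)^2 - 4 * b1 * b3)),
      "b1 > 0",
      function() list(b1 = .udraw(.6, 1.4), b2 = .udraw(.5, 1.2),
                      b3 = .udraw(.3, .9))),
    .aux_entry("e2", "exponential",
      quote((pm * 4 * b1 * exp(pm * sqrt(b1) * r)) /
              (1 - 4 * b1 * b3 * exp(pm * 2 * sqrt(b1) * r))),
      "b1 > 0, b2 = 0",
      function() list(b1 = .udraw(.6, 1.4), b2 = 0, b3 = .udraw(.3, .9))),
    .aux_entry("r1", "rational",
      quote((4 * b2) / (b2^2 * r^2 - 4 * b3)),
      "b1 = 0",
      function() list(b1 = 0, b2 = .udraw(.5, 1.2), b3 = .udraw(-1, -.3)),
      branches = 1, corrected = TRUE,
      as_printed = quote((pm * b1 * b2) / (b2^2 * r^2 - b1 * b3))),
    .aux_entry("r2", "rational",
      quote(pm / (sqrt(b3) * r)),
      "b1 = 0, b2 = 0",
      function() list(b1 = 0, b2 = 0, b3 = .udraw(.4, 1.2)))
  )
}

#' Case library for the (G'/G^2) ratio variable
#'
#' The three sign cases of `H' = tau + kappa H^2`, with arbitrary
#' constants `A1`, `B1`.  The stored closed forms satisfy the defining
#' relation exactly on their domains; the published case expressions (kept
#' in `as_printed`) solve the relation with the roles of `kappa` and
#' `tau` interchanged (and, for the oscillatory case, a sign of the
#' prefactor), so they are recorded but not used for residual work.
#'
#' @return list of 3 `aux_entry` objects (cases `ktpos`, `ktneg`, `k0`).
#' @export
gg2_library <- function() {
  list(
    .aux_entry("ktpos", "trigonometric",
      quote((sqrt(kappa * tau) / kappa) *
              (A1 * cos(sqrt(kappa * tau) * r) +
                 B1 * sin(sqrt(kappa * tau) * r)) /
              (B1 * cos(sqrt(kappa * tau) * r) -
                 A1 * sin(sqrt(kappa * tau) * r))),
      "kappa * tau > 0",
      function() list(kappa = .udraw(.4, 1.2), tau = .udraw(.4, 1.2),
                      A1 = .udraw(.5, 1.5), B1 = .udraw(.5, 1.5)),
      branches = 1, corrected = TRUE,
      as_printed = quote(sqrt(kappa / tau) *
                           (A1 * cos(sqrt(kappa * tau) * r) +
                              B1 * sin(sqrt(kappa * tau) * r)) /
                           (A1 * sin(sqrt(kappa * tau) * r) -
                              B1 * cos(sqrt(kappa * tau) * r)))),
    .aux_entry("ktneg", "hyperbolic",
      quote(-(sqrt(-(kappa * tau)) / kappa) *
              (A1 * sinh(sqrt(-(kappa * tau)) * r) +
                 B1 * cosh(sqrt(-(kappa * tau)) * r)) /
              (A1 * cosh(sqrt(-(kappa * tau)) * r) +
                 B1 * sinh(sqrt(-(kappa * tau)) * r))),
      "kappa * tau < 0",
      function() list(kappa = -.udraw(.4, 1.2), tau = .udraw(.4, 1.2),
                      A1 = .udraw(.8, 1.5), B1 = .udraw(.1, .6)),
      branches = 1, corrected = TRUE,
      as_printed = quote(-sqrt(abs(kappa * tau)) / tau +
                           sqrt(abs(kappa * tau)) / 2 *
                           (A1 * sinh(2 * sqrt(abs(kappa * tau)) * r) +
                              B1 * cosh(2 * sqrt(abs(kappa * tau)) * r)) /
                           (A1 * cosh(2 * sqrt(abs(kappa * tau)) * r) +
                              B1 * sinh(2 * sqrt(abs(kappa * tau)) * r)))),
    .aux_entry("k0", "rational",
      quote(tau * r + B1),
      "kappa = 0, tau != 0",
      function() list(kappa = 0, tau = .udraw(.4, 1.2),
                      A1 = .udraw(.5, 1.5), B1 = .udraw(.5, 1.5)),
      branches = 1, corrected = TRUE,
      as_printed = quote(-A1 / (tau * (A1 * r + B1))))
  )
}

#' Case library for the extended modified tanh scheme
#'
#' The five published solutions of `S' = kappa + S^2` (all exact as
#' printed): tanh and coth forms for `kappa < 0`, `-1/r` for `kappa = 0`,
#' tan and cot forms for `kappa > 0`.
#'
#' @return list of 5 `aux_entry` objects.
#' @export
tanh_library <- function() {
  list(
    .aux_entry("neg_tanh", "hyperbolic",
      quote(-sqrt(-kappa) * tanh(sqrt(-kappa) * r)), "kappa < 0",
      function() list(kappa = -.udraw(.4, 1.4)), branches = 1),
    .aux_entry("neg_coth", "hyperbolic",
      quote(-sqrt(-kappa) * coth(sqrt(-kappa) * r)), "kappa < 0",
      function() list(kappa = -.udraw(.4, 1.4)), branches = 1),
    .aux_entry("zero", "rational",
      quote(-1 / r), "kappa = 0",
      function() list(kappa = 0), branches = 1),
    .aux_entry("pos_tan", "trigonometric",
      quote(sqrt(kappa) * tan(sqrt(kappa) * r)), "kappa > 0",
      function() list(kappa = .udraw(.4, 1.4)), branches = 1),
    .aux_entry("pos_cot", "trigonometric",
      quote(-sqrt(kappa) * cot(sqrt(kappa) * r)), "kappa > 0",
      function() list(kappa = .udraw(.4, 1.4)), branches = 1)
  )
}

# defining-relation residual of one library entry at sampled parameters:
# returns max relative residual over `n` sample points of r
.entry_residual <- function(entry, method, branch = 1, seed = 0, n = 25) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pars <- entry$sampler()
  cf <- sym_subs(entry$closed_form, list(pm = branch))
  ds <- sym_d(cf, "r")
  resid <- switch(method,
    aux  = bquote((.(ds))^2 - (b1 * (.(cf))^2 + b2 * (.(cf))^3 +
                                b3 * (.(cf))^4)),
    gg2  = bquote(.(ds) - (tau + kappa * (.(cf))^2)),
    tanh = bquote(.(ds) - (kappa + (.(cf))^2)))
  worst <- 0; got <- 0; tries <- 0
  while (got < n && tries < 40 * n) {
    tries <- tries + 1
    r <- stats::runif(1, -2, 2)
    if (abs(r) < 0.05) next
    vals <- c(pars, list(r = r))
    v <- tryCatch(sym_eval(resid, vals), error = function(e) NA_real_)
    s <- tryCatch(abs(sym_eval(cf, vals)), error = function(e) NA_real_)
    if (!is.finite(v) || !is.finite(s) || s > 1e6) next  # pole vicinity
    worst <- max(worst, abs(v) / max(1, s^4))
    got <- got + 1
  }
  if (got < n) return(NA_real_)
  worst
}

#' Soundness audit of the solution libraries
#'
#' Evaluates the defining-relation residual of every library entry (all
#' branches) at seeded random parameter values satisfying the entry's
#' validity conditions and 25 sample points of the travelling variable,
#' skipping points near poles.
#'
#' @param seed RNG seed for the sampled parameters and points.
#' @return data frame with method, entry id, branch, family, whether the
#'   published form needed correction, and the max relative residual.
#' @export
library_soundness <- function(seed = 0) {
  rows <- list()
  libs <- list(aux = aux_library(), gg2 = gg2_library(),
               tanh = tanh_library())
  for (m in names(libs)) {
    for (e in libs[[m]]) {
      for (br in e$branches) {
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, id = e$id, branch = br, family = e$family,
          corrected = e$corrected,
          max_residual = .entry_residual(e, m, branch = br, seed = seed),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
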