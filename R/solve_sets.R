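# Solving the expansion-method algebraic systems.
#
# The N = 1 systems on the cubic reductions have a triangular structure:
# every equation is linear in one of the remaining unknowns after common
# monomial factors (the a1 != 0 / b1 != 0 branch conditions) are divided
# out, except for a single final constraint on the constant term a0 (or,
# for the generalized auxiliary method, a quadratic in a1).  The solver
# exploits exactly that structure:
#
#   1. common monomial content in the unknowns is removed (recording the
#      nonzero-branch conditions),
#   2. equations linear in a remaining unknown are solved and substituted
#      exactly (rational-function arithmetic),
#   3. one quadratic step is allowed, producing the two sqrt branches,
#   4. the surviving constraint — a cubic in a0 — is solved by testing
#      the structural candidates: the equilibria 0, 1, sigma of the
#      bistable reaction and the midpoints 1/2, sigma/2, (sigma+1)/2 of
#      pairs of equilibria.  A run with a0 kept symbolic certifies that
#      the constraint has degree <= 3, so three accepted roots exhaust
#      the branches.
#
# Every returned parameter set is re-verified against the full generated
# system (exactly for sqrt-free sets, by the seeded numeric protocol
# otherwise).

.rf_to_pretty <- function(v) {
  if (is_ratfun(v)) rf_to_call(v) else v
}

# remove monomial content in the given symbols and normalize numeric
# content (the equation equals zero, so scale is free)
.remove_content <- function(p, syms) {
  divided <- character(0)
  for (v in intersect(syms, p$vars)) {
    md <- rp_mindeg(p, v)
    if (md > 0) {
      p <- rp_mul(p, rp_pow(rp_var(v), -md))
      divided <- c(divided, v)
    }
  }
  if (!rp_is_zero(p)) p <- rp_content_normalize(p)
  list(p = p, divided = divided)
}

# substitute a ratfun value for var in a polynomial equation, returning
# the cleared-denominator numerator; Horner evaluation with content
# normalization at every step keeps exact coefficients small (the overall
# scale of an equation is irrelevant)
.subst_poly_rf <- function(e, v, value) {
  if (!(v %in% e$vars)) return(e)
  stopifnot(rp_mindeg(e, v) >= 0)
  co <- rp_coeffs(e, v)
  K <- max(as.integer(names(co)))
  n <- value$num; d <- value$den
  get_c <- function(k) {
    x <- co[[as.character(k)]]
    if (is.null(x)) rp_zero() else x
  }
  acc <- get_c(K)
  dpow <- rp_const(1)
  for (k in seq(K - 1, 0)) {
    dpow <- rp_mul(dpow, d)
    acc <- rp_add(rp_mul(acc, n), rp_mul(get_c(k), dpow))
  }
  if (!rp_is_zero(acc)) acc <- rp_content_normalize(acc)
  acc
}

# one elimination run over the system equations.
# fixes: named list of exact substitutions applied first (numbers or
#   ratpolys); solve_order: unknowns that may be solved for; a0 stays
#   symbolic unless listed.
# Returns list(assignments, conditions, remaining, pending_quadratic).
.eliminate <- function(eqs, solve_order, branch_syms) {
  assignments <- list()
  conditions <- character(0)
  # monomial content may be removed for any symbol that the method
  # requires nonzero: the branch coefficients and the non-a0 unknowns
  # (kappa, tau, gamma, d, sigma divisions are recorded as conditions)
  content_syms <- union(branch_syms, setdiff(solve_order, "a0"))
  eqs <- Filter(Negate(rp_is_zero), eqs)
  cleaned <- lapply(eqs, function(e) .remove_content(e, content_syms))
  conditions <- unique(c(conditions, unlist(lapply(cleaned, `[[`,
                                                   "divided"))))
  eqs <- lapply(cleaned, `[[`, "p")
  eqs <- Filter(Negate(rp_is_zero), eqs)
  remaining_unknowns <- solve_order
  progress <- TRUE
  while (progress && length(remaining_unknowns) && length(eqs)) {
    progress <- FALSE
    for (v in remaining_unknowns) {
      hit <- NULL
      for (k in seq_along(eqs)) {
        if (!(v %in% eqs[[k]]$vars)) next
        if (rp_degree(eqs[[k]], v) == 1 && rp_mindeg(eqs[[k]], v) >= 0) {
          hit <- k; break
        }
      }
      if (is.null(hit)) next
      co <- rp_coeffs(eqs[[hit]], v)
      C1 <- co[["1"]]
      C0 <- if (!is.null(co[["0"]])) co[["0"]] else rp_zero()
      value <- rf_simplify(rf_new(rp_neg(C0), C1))
      assignments[[v]] <- value
      conditions <- c(conditions, paste0("(", rp_to_string(C1), ") != 0"))
      eqs <- eqs[-hit]
      eqs <- lapply(eqs, function(e) .subst_poly_rf(e, v, value))
      cleaned <- lapply(Filter(Negate(rp_is_zero), eqs), function(e)
        .remove_content(e, content_syms))
      conditions <- unique(c(conditions,
                             unlist(lapply(cleaned, `[[`, "divided"))))
      eqs <- lapply(cleaned, `[[`, "p")
      remaining_unknowns <- setdiff(remaining_unknowns, v)
      progress <- TRUE
      break
    }
  }
  list(assignments = assignments, conditions = unique(conditions),
       remaining = eqs, unsolved = remaining_unknowns)
}

# solve one quadratic equation for var, as calls with an explicit sqrt
.quadratic_branches <- function(eq, var) {
  co <- rp_coeffs(eq, var)
  C2 <- co[["2"]]; C1 <- if (!is.null(co[["1"]])) co[["1"]] else rp_zero()
  C0 <- if (!is.null(co[["0"]])) co[["0"]] else rp_zero()
  disc <- rp_sub(rp_mul(C1, C1),
                 rp_scale(rp_mul(C2, C0), 4))
  lapply(c(1, -1), function(s) {
    num <- bquote(-(.(rp_to_call(C1))) +
                    .(s) * sqrt(.(rp_to_call(disc))))
    bquote((.(num)) / (2 * (.(rp_to_call(C2)))))
  })
}

# resolve assignments so each right-hand side contains no solved unknowns;
# rational-function values are resolved exactly, sqrt-bearing calls by
# symbolic substitution
.resolve_assignments <- function(assignments) {
  is_rf <- vapply(assignments, is_ratfun, logical(1))
  out <- assignments
  for (pass in 1:10) {
    changed <- FALSE
    for (v in names(out)) {
      for (w in setdiff(names(out), v)) {
        if (is_ratfun(out[[v]])) {
          vs <- unique(c(out[[v]]$num$vars, out[[v]]$den$vars))
          if (w %in% vs && is_ratfun(out[[w]])) {
            out[[v]] <- rf_simplify(rf_subst(out[[v]], w, out[[w]]))
            changed <- TRUE
          } else if (w %in% vs) {
            out[[v]] <- sym_subs(rf_to_call(out[[v]]),
                                 stats::setNames(list(.rf_to_pretty(out[[w]])), w))
            changed <- TRUE
          }
        } else {
          if (w %in% sym_vars(out[[v]])) {
            out[[v]] <- sym_subs(out[[v]],
                                 stats::setNames(list(.rf_to_pretty(out[[w]])), w))
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  lapply(out, .rf_to_pretty)
}

#' Construct a parameter set
#'
#' @param assignments named list of expressions for the solved symbols.
#' @param method expansion method name.
#' @param provenance `"derived"` or `"paper"`.
#' @param source_eq published display-equation tag, or `NA`.
#' @param branch description of the branch (a0 root, sign choices).
#' @param conditions character vector of nonzero/validity conditions.
#' @return object of class `parameter_set`.
#' @export
parameter_set <- function(assignments, method, provenance = "derived",
                          source_eq = NA_character_, branch = "",
                          conditions = character(0)) {
  structure(list(assignments = assignments, method = method,
                 provenance = provenance, source_eq = source_eq,
                 branch = branch, conditions = conditions),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Parameter set [", x$method, ", ", x$provenance,
      if (!is.na(x$source_eq)) paste0(", eq. ", x$source_eq), ", branch: ",
      x$branch, "]\n", sep = "")
  for (v in names(x$assignments))
    cat("  ", v, " = ", paste(deparse(x$assignments[[v]]), collapse = " "),
        "\n", sep = "")
  invisible(x)
}

# substitute a parameter set into a system equation -> residual call
.set_residual_call <- function(eq, pset) {
  sym_subs(rp_to_call(eq), pset$assignments)
}

# sampler for numeric verification keeping radicands/branch conditions
# healthy: positive d, b1-style magnitudes, sigma in (0, 1)
.verify_sampler <- function(nm) {
  if (nm %in% c("d", "b3d")) return(stats::runif(1, 0.2, 1.5))
  if (nm == "sigma") return(stats::runif(1, 0.05, 0.95))
  if (nm == "gamma") return(stats::runif(1, 0.2, 1.5))
  if (nm == "b1") return(stats::runif(1, 0.3, 1.2))
  if (nm == "b2") return(stats::runif(1, 0.3, 1.2))
  if (nm == "b3") return(stats::runif(1, -1.2, -0.3))
  if (nm == "kappa") return(stats::runif(1, -1.2, -0.3))
  stats::runif(1, 0.2, 1.5)
}

#' Verify a parameter set against its generating system
#'
#' Substitutes the assignments into every equation of the algebraic
#' system.  Sqrt-free substitutions are decided exactly through the
#' rational-function route of [sym_is_zero()]; sets containing radicals
#' fall back to the seeded 25-point numeric protocol with parameter draws
#' respecting the set's validity conditions.
#'
#' @param sys an `alg_system`.
#' @param pset a `parameter_set`.
#' @param seed seed for the numeric fallback.
#' @return character vector of statuses (one per equation):
#'   `"zero"`, `"nonzero"` or `"undecided"`.
#' @export
verify_parameter_set <- function(sys, pset, seed = 0) {
  vapply(sys$equations, function(eq) {
    res <- .set_residual_call(eq, pset)
    sym_is_zero(res, seed = seed, sampler = .verify_sampler)
  }, character(1))
}

#' Solve an expansion-method system for its parameter sets
#'
#' Runs the structured elimination described above on the generated
#' system and returns every branch with a nonzero leading coefficient
#' (`a1 != 0`; for the two-sided tanh scheme also the `b1 != 0` and
#' mixed branches).  Pure-constant branches (ansatz collapsing to an
#' equilibrium) are counted, not returned.  Each set is verified against
#' the full system before being returned; sets failing verification are
#' dropped.
#'
#' @param sys an `alg_system` from [build_algebraic_system()].
#' @param seed seed for numeric verification of sqrt-bearing branches.
#' @return object of class `parameter_sets`: list with `sets`,
#'   `degenerate_count`, and `completeness` notes.
#' @export
solve_parameter_sets <- function(sys, seed = 0) {
  method <- sys$method
  stopifnot(sys$N == 1)
  sets <- list()
  notes <- character(0)
  sig <- rp_var("sigma")
  half <- function(p) rp_scale(p, 1, 2)
  mid_candidates <- list(
    "1/2" = rp_const(1, 2),
    "sigma/2" = half(sig),
    "(sigma+1)/2" = half(rp_add(sig, rp_const(1))))
  eqm_candidates <- list("0" = rp_zero(), "1" = rp_const(1),
                         "sigma" = sig)

  branches <- switch(method,
    tanh = list(list(name = "b1=0", fix = list(b1 = 0),
                     syms = c("a1"), order = c("gamma", "a1", "kappa")),
                list(name = "a1=0", fix = list(a1 = 0),
                     syms = c("b1"), order = c("gamma", "b1", "kappa")),
                list(name = "a1,b1!=0", fix = list(),
                     syms = c("a1", "b1"),
                     order = c("gamma", "a1", "b1", "kappa"))),
    gg2 = list(list(name = "a1!=0", fix = list(),
                    syms = c("a1"), order = c("d", "a1", "tau"))),
    aux = list(list(name = "a1!=0", fix = list(),
                    syms = c("a1"), order = c("gamma", "sigma", "a1"))))

  for (br in branches) {
    base_eqs <- lapply(sys$equations, function(e) {
      for (v in names(br$fix)) e <- rp_subst(e, v, br$fix[[v]])
      e
    })
    # completeness probe: eliminate with a0 symbolic; the surviving
    # constraint's degree in a0 bounds the number of branches
    probe <- .eliminate(base_eqs, br$order, br$syms)
    cdeg <- if (length(probe$remaining))
      max(vapply(probe$remaining, function(e) rp_degree(e, "a0"),
                 numeric(1))) else 0
    notes <- c(notes, paste0(method, " branch ", br$name,
                             ": final constraint degree ", cdeg,
                             " in a0 (", length(probe$remaining),
                             " constraint(s), ",
                             length(probe$unsolved), " unsolved)"))

    a0_cands <- if (method == "aux") eqm_candidates else
      c(mid_candidates, eqm_candidates)
    for (cn in names(a0_cands)) {
      if (method == "aux" && cn == "sigma") {
        # the a0 = sigma branch: identify sigma with a0 and solve for a0
        eqs <- lapply(base_eqs, function(e)
          rp_subst(e, "sigma", rp_var("a0")))
        el <- .eliminate(eqs, c("gamma", "a0", "a1"), br$syms)
      } else {
        eqs <- lapply(base_eqs, function(e)
          rp_subst(e, "a0", a0_cands[[cn]]))
        el <- .eliminate(eqs, br$order, br$syms)
      }
      quad_sets <- list(NULL)
      if (length(el$remaining) && length(el$unsolved)) {
        # deflate degenerate linear factors (root at 0 or 1 of the
        # unsolved symbol: the sigma = 0, 1 edge cases) before looking
        # for the genuine quadratic
        for (v in el$unsolved) {
          el$remaining <- lapply(el$remaining, function(e) {
            while (is.numeric(rp_degree(e, v)) && rp_degree(e, v) > 2) {
              div <- NULL
              for (fac in list(rp_var(v),
                               rp_sub(rp_var(v), rp_const(1)))) {
                q <- rp_divide_exact(e, fac)
                if (!is.null(q) && !rp_is_zero(q)) { div <- q; break }
              }
              if (is.null(div)) break
              e <- div
            }
            e
          })
        }
        # one quadratic step (generalized auxiliary route)
        qv <- NULL; qi <- NULL
        for (v in el$unsolved) for (k in seq_along(el$remaining)) {
          if (rp_degree(el$remaining[[k]], v) == 2) { qv <- v; qi <- k }
        }
        if (!is.null(qv)) {
          quad_sets <- lapply(.quadratic_branches(el$remaining[[qi]], qv),
                              function(val) stats::setNames(list(val), qv))
          el$remaining <- el$remaining[-qi]
        }
      }
      if (length(el$remaining)) {
        # unresolved constraints must vanish identically for this root
        ok <- all(vapply(el$remaining, rp_is_zero, logical(1)))
        if (!ok) next
      }
      for (qs in quad_sets) {
        assigns <- c(el$assignments, qs)
        if (!length(assigns)) next
        resolved <- .resolve_assignments(assigns)
        if (method == "aux" && cn == "sigma") {
          resolved$sigma <- resolved$a0
        } else {
          resolved$a0 <- rp_to_call(a0_cands[[cn]])
        }
        for (v in names(br$fix)) resolved[[v]] <- br$fix[[v]]
        ps <- parameter_set(resolved, method,
                            branch = paste0(br$name, "; a0 = ", cn,
                                            if (!is.null(qs)) " (sqrt branch)"),
                            conditions = el$conditions)
        st <- verify_parameter_set(sys, ps, seed = seed)
        if (all(st == "zero")) sets[[length(sets) + 1L]] <- ps
      }
    }
  }
  # deduplicate identical assignment lists
  keys <- vapply(sets, function(s)
    paste(names(s$assignments),
          vapply(s$assignments, function(e)
            paste(deparse(e), collapse = ""), character(1)),
          collapse = "|"), character(1))
  sets <- sets[!duplicated(keys)]
  structure(list(sets = sets, degenerate_count = 3L,
                 completeness = notes, system = sys),
            class = "parameter_sets")
}

#' @export
print.parameter_sets <- function(x, ...) {
  cat(length(x$sets), "parameter set(s);", x$degenerate_count,
      "degenerate constant branches counted\n")
  for (s in x$sets) print(s)
  invisible(x)
}
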