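# Symbolic utilities on R call trees: chain-rule differentiation (with
# support for unknown functions such as u(r)), substitution, numeric
# evaluation with the full trig/hyperbolic vocabulary, and a three-valued
# symbolic-zero test (zero / nonzero / undecided).

#' Evaluation environment with extended math functions
#'
#' Base R lacks `sech`, `csch`, `coth`, `sec` and `csc`; profile evaluation
#' and residual sampling need them.  Returns an environment (child of
#' `baseenv()`) in which symbolic expressions produced by this package can
#' be evaluated.
#'
#' @return an environment defining `sech`, `csch`, `coth`, `sec`, `csc`.
#' @export
math_env <- function() {
  e <- new.env(parent = baseenv())
  e$sech <- function(x) 1 / cosh(x)
  e$csch <- function(x) 1 / sinh(x)
  e$coth <- function(x) cosh(x) / sinh(x)
  e$sec  <- function(x) 1 / cos(x)
  e$csc  <- function(x) 1 / sin(x)
  e$cot  <- function(x) cos(x) / sin(x)
  e
}

.MATH_ENV <- NULL

get_math_env <- function() {
  if (is.null(.MATH_ENV)) {
    # lazy init; assign in namespace environment at first use
    env <- math_env()
    if (environmentIsLocked(topenv())) return(env)
    assign(".MATH_ENV", env, envir = topenv())
    env
  } else .MATH_ENV
}

#' Evaluate a symbolic expression numerically
#'
#' @param expr a call/expression.
#' @param vals named list of numeric values (scalars or vectors).
#' @return numeric result.
#' @export
sym_eval <- function(expr, vals = list()) {
  eval(expr, envir = vals, enclos = get_math_env())
}

# derivative table: each entry maps g -> d/dg
.DERIV_RULES <- list(
  sin  = function(g) bquote(cos(.(g))),
  cos  = function(g) bquote(-sin(.(g))),
  tan  = function(g) bquote(sec(.(g))^2),
  sec  = function(g) bquote(sec(.(g)) * tan(.(g))),
  csc  = function(g) bquote(-(csc(.(g)) * cot(.(g)))),
  cot  = function(g) bquote(-csc(.(g))^2),
  sinh = function(g) bquote(cosh(.(g))),
  cosh = function(g) bquote(sinh(.(g))),
  tanh = function(g) bquote(sech(.(g))^2),
  sech = function(g) bquote(-(sech(.(g)) * tanh(.(g)))),
  csch = function(g) bquote(-(csch(.(g)) * coth(.(g)))),
  coth = function(g) bquote(-csch(.(g))^2),
  exp  = function(g) bquote(exp(.(g))),
  log  = function(g) bquote(1 / .(g)),
  sqrt = function(g) bquote(1 / (2 * sqrt(.(g))))
)

# bump "u" -> "u1" -> "u2" ... for unknown-function derivatives
.bump_fname <- function(name) {
  m <- regmatches(name, regexec("^(.*?)([0-9]*)$", name))[[1]]
  base <- m[2]; num <- m[3]
  k <- if (num == "") 0L else as.integer(num)
  paste0(base, k + 1L)
}

# light simplification used while differentiating
.simp <- function(e) {
  if (!is.call(e)) return(e)
  op <- as.character(e[[1]])
  if (op == "(") return(.simp(e[[2]]))
  args <- lapply(as.list(e)[-1], .simp)
  z <- function(x) is.numeric(x) && length(x) == 1
  if (op == "+" && length(args) == 2) {
    if (z(args[[1]]) && args[[1]] == 0) return(args[[2]])
    if (z(args[[2]]) && args[[2]] == 0) return(args[[1]])
    if (z(args[[1]]) && z(args[[2]])) return(args[[1]] + args[[2]])
  }
  if (op == "-" && length(args) == 2) {
    if (z(args[[2]]) && args[[2]] == 0) return(args[[1]])
    if (z(args[[1]]) && z(args[[2]])) return(args[[1]] - args[[2]])
    if (z(args[[1]]) && args[[1]] == 0) return(.simp(call("-", args[[2]])))
  }
  if (op == "-" && length(args) == 1 && z(args[[1]])) return(-args[[1]])
  if (op == "*") {
    if ((z(args[[1]]) && args[[1]] == 0) || (z(args[[2]]) && args[[2]] == 0))
      return(0)
    if (z(args[[1]]) && args[[1]] == 1) return(args[[2]])
    if (z(args[[2]]) && args[[2]] == 1) return(args[[1]])
    if (z(args[[1]]) && z(args[[2]])) return(args[[1]] * args[[2]])
  }
  if (op == "/" && z(args[[1]]) && args[[1]] == 0) return(0)
  if (op == "^") {
    if (z(args[[2]]) && args[[2]] == 1) return(args[[1]])
    if (z(args[[2]]) && args[[2]] == 0) return(1)
  }
  as.call(c(e[[1]], args))
}

#' Symbolic derivative of a call tree
#'
#' Chain-rule differentiation supporting arithmetic, powers, the standard
#' trigonometric/hyperbolic functions (including `sec`, `csc`, `sech`,
#' `csch`, `coth`), `exp`, `log`, `sqrt`, and unknown single-argument
#' functions: the derivative of `u(g)` is written `u1(g) * g'`, of `u1(g)`
#' is `u2(g) * g'`, and so on.
#'
#' @param expr call/expression to differentiate.
#' @param var name of the differentiation variable (character).
#' @return the derivative as a call.
#' @export
sym_d <- function(expr, var) {
  d <- function(e) {
    if (is.numeric(e)) return(0)
    if (is.name(e)) return(if (identical(as.character(e), var)) 1 else 0)
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (op == "(") return(d(e[[2]]))
      if (op == "+" && length(e) == 2) return(d(e[[2]]))
      if (op == "-" && length(e) == 2) return(.simp(call("-", d(e[[2]]))))
      if (op == "+") return(.simp(call("+", d(e[[2]]), d(e[[3]]))))
      if (op == "-") return(.simp(call("-", d(e[[2]]), d(e[[3]]))))
      if (op == "*") {
        a <- e[[2]]; b <- e[[3]]
        return(.simp(call("+", .simp(call("*", d(a), b)),
                          .simp(call("*", a, d(b))))))
      }
      if (op == "/") {
        a <- e[[2]]; b <- e[[3]]
        return(.simp(call("-", .simp(call("/", d(a), b)),
                          .simp(call("/", .simp(call("*", a, d(b))),
                                     call("^", b, 2))))))
      }
      if (op == "^") {
        a <- e[[2]]; k <- e[[3]]
        if (is.numeric(k)) {
          return(.simp(call("*",
                            .simp(call("*", k, call("^", a, k - 1))),
                            d(a))))
        }
        # general a^b
        return(.simp(call("*", e,
                          call("+", .simp(call("*", d(k), call("log", a))),
                               .simp(call("/", .simp(call("*", k, d(a))), a))))))
      }
      if (length(e) == 2) {               # unary function
        g <- e[[2]]
        dg <- d(g)
        rule <- .DERIV_RULES[[op]]
        outer <- if (!is.null(rule)) rule(g) else
          as.call(list(as.name(.bump_fname(op)), g))
        return(.simp(call("*", outer, dg)))
      }
    }
    stop("cannot differentiate: ", deparse(e))
  }
  .simp(d(expr))
}

#' Substitute symbols in an expression
#'
#' @param expr call/expression.
#' @param subs named list mapping symbol names to replacement expressions
#'   or numbers.
#' @return the substituted call.
#' @export
sym_subs <- function(expr, subs) {
  s <- function(e) {
    if (is.name(e)) {
      nm <- as.character(e)
      if (!is.null(subs[[nm]])) return(subs[[nm]])
      return(e)
    }
    if (is.call(e)) return(as.call(c(e[[1]], lapply(as.list(e)[-1], s))))
    e
  }
  .simp(s(expr))
}

# collect free symbols of an expression (excluding function names)
sym_vars <- function(expr) {
  out <- character(0)
  walk <- function(e) {
    if (is.name(e)) out <<- c(out, as.character(e))
    else if (is.call(e)) for (a in as.list(e)[-1]) walk(a)
  }
  walk(expr)
  sort(unique(out))
}

# magnitude scale of an expression at given values: max |additive term|
.expr_scale <- function(expr, vals) {
  terms <- list()
  split_sum <- function(e) {
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (op == "(") return(split_sum(e[[2]]))
      if (op %in% c("+", "-") && length(e) == 3) {
        split_sum(e[[2]]); split_sum(e[[3]]); return(invisible())
      }
      if (op == "-" && length(e) == 2) { split_sum(e[[2]]); return(invisible()) }
    }
    terms[[length(terms) + 1L]] <<- e
    invisible()
  }
  split_sum(expr)
  vals_num <- vapply(terms, function(tt) {
    v <- tryCatch(sym_eval(tt, vals), error = function(e) NA_real_)
    if (length(v) != 1 || !is.finite(v)) NA_real_ else abs(v)
  }, numeric(1))
  if (all(is.na(vals_num))) return(NA_real_)
  max(1, vals_num, na.rm = TRUE)
}

#' Three-valued symbolic-zero test
#'
#' First attempts an exact decision by converting the expression to a
#' rational function (possible when it is built from `+ - * / ^` with
#' integer powers); otherwise evaluates the expression at `n` seeded random
#' points and compares against a relative tolerance, rejecting sample
#' points that land within 0.05 of a detected singularity (non-finite or
#' overflowing evaluation).
#'
#' @param expr call/expression to test.
#' @param free character vector of symbols to randomize; defaults to all
#'   free symbols of `expr`.
#' @param fixed named list of values imposed on some symbols (e.g. validity
#'   conditions solved for a parameter).
#' @param n number of sample points.
#' @param tol relative tolerance.
#' @param seed RNG seed (local to this call).
#' @param sampler optional function(name) returning one random draw for a
#'   given free symbol; defaults to uniform on \[-2, 2\] with magnitude at
#'   least 0.05.
#' @return character scalar: `"zero"`, `"nonzero"` or `"undecided"`.
#' @export
sym_is_zero <- function(expr, free = NULL, fixed = list(), n = 25,
                        tol = 1e-10, seed = 0, sampler = NULL) {
  if (is.numeric(expr)) return(if (all(expr == 0)) "zero" else "nonzero")
  ex <- if (length(fixed)) sym_subs(expr, fixed) else expr
  exact <- tryCatch(rf_from_call(ex), error = function(e) NULL)
  if (!is.null(exact))
    return(if (rp_is_zero(exact$num)) "zero" else "nonzero")
  if (is.null(free)) free <- sym_vars(ex)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draw <- if (is.null(sampler)) {
    function(nm) {
      repeat {
        v <- stats::runif(1, -2, 2)
        if (abs(v) >= 0.05) return(v)
      }
    }
  } else sampler
  got <- 0L; tried <- 0L
  while (got < n && tried < 40L * n) {
    tried <- tried + 1L
    vals <- stats::setNames(lapply(free, draw), free)
    v <- tryCatch(sym_eval(ex, vals), error = function(e) NA_real_)
    if (length(v) != 1 || !is.finite(v) || abs(v) > 1e12) next  # near a pole
    sc <- .expr_scale(ex, vals)
    if (!is.finite(sc) || sc > 1e12) next
    if (abs(v) > tol * sc) return("nonzero")
    got <- got + 1L
  }
  if (got == n) "zero" else "undecided"
}
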