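# Building the algebraic systems of the expansion methods.
#
# The truncated ansatz (a0 + a1 S + ... , plus inverse powers for the
# two-sided tanh scheme) is substituted into a reduced ODE; derivatives of
# the auxiliary function S(r) are eliminated through its defining
# relation, and the result is collected as a (Laurent) polynomial in S.
# Every coefficient must vanish, giving a polynomial system in the ansatz
# coefficients and the model parameters.
#
# For the generalized auxiliary equation the relation fixes only (S')^2,
# so intermediate expressions live in the quadratic extension
# { A(S) + B(S) S' : (S')^2 = P(S) }, implemented as pairs (A, B).

.aux_P <- function() rp_from_call(quote(b1 * S^2 + b2 * S^3 + b3 * S^4))

# pair algebra over (S')^2 = P(S)
.pr <- function(A, B = rp_zero()) list(A = A, B = B)
.pr_add <- function(x, y) .pr(rp_add(x$A, y$A), rp_add(x$B, y$B))
.pr_mul <- function(x, y, P)
  .pr(rp_add(rp_mul(x$A, y$A), rp_mul(rp_mul(x$B, y$B), P)),
      rp_add(rp_mul(x$A, y$B), rp_mul(x$B, y$A)))
.pr_pow <- function(x, k, P) {
  out <- .pr(rp_const(1))
  for (i in seq_len(k)) out <- .pr_mul(out, x, P)
  out
}
# d/dr on the pair: (A + B S')' = A_S S' + B_S (S')^2 + B S''
# with S'' = P'(S) / 2
.pr_dr <- function(x, P) {
  dP2 <- rp_scale(rp_deriv(P, "S"), 1, 2)
  .pr(rp_add(rp_mul(rp_deriv(x$B, "S"), P), rp_mul(x$B, dP2)),
      rp_deriv(x$A, "S"))
}

#' Algebraic system of an expansion method on a reduced equation
#'
#' Substitutes the order-`N` ansatz of the chosen method into the reduced
#' equation, eliminates derivatives of the auxiliary function through its
#' defining relation, clears inverse powers, and collects coefficients of
#' the powers of the auxiliary variable (for the generalized auxiliary
#' equation, of its derivative as well).  Each returned equation is an
#' exact polynomial in the unknown coefficients and the model parameters
#' that must vanish.
#'
#' @param ode an `ord_ode` with symbolic model parameters and no explicit
#'   dependence on `r`.
#' @param method `"aux"`, `"gg2"` or `"tanh"`.
#' @param N truncation order from [homogeneous_balance()].
#' @return object of class `alg_system`.
#' @export
build_algebraic_system <- function(ode, method = c("aux", "gg2", "tanh"),
                                   N = homogeneous_balance(ode, method)) {
  method <- match.arg(method)
  stopifnot(N >= 1)
  if ("r" %in% ode$rp$vars)
    stop("expansion methods apply to constant-coefficient reductions only")
  S <- rp_var("S")
  acoef <- function(i) rp_var(paste0("a", i))
  U <- rp_from_call(quote(a0))
  for (i in seq_len(N)) U <- rp_add(U, rp_mul(acoef(i), rp_pow(S, i)))
  unknowns <- c("a0", paste0("a", seq_len(N)))

  if (method %in% c("gg2", "tanh")) {
    dS <- if (method == "gg2") rp_from_call(quote(tau + kappa * S^2)) else
      rp_from_call(quote(kappa + S^2))
    if (method == "tanh") {
      for (i in seq_len(N))
        U <- rp_add(U, rp_mul(rp_var(paste0("b", i)), rp_pow(S, -i)))
      unknowns <- c(unknowns, paste0("b", seq_len(N)), "kappa")
    } else {
      unknowns <- c(unknowns, "tau", "kappa")
    }
    Dr <- function(p) rp_mul(rp_deriv(p, "S"), dS)
    U1 <- Dr(U); U2 <- Dr(U1)
    full <- rp_subst(rp_subst(rp_subst(ode$rp, "u2", U2), "u1", U1),
                     "u", U)
    shift <- max(0L, -rp_mindeg(full, "S"))
    full <- rp_mul(full, rp_pow(S, shift))
    eqs <- rp_coeffs(full, "S")
    labels <- paste0("S^", as.integer(names(eqs)) - shift)
  } else {
    P <- .aux_P()
    unknowns <- c(unknowns, "b1", "b2", "b3")
    Up <- .pr(U)
    U1 <- .pr_dr(Up, P); U2 <- .pr_dr(U1, P)
    # compose the ODE polynomial term by term in the pair algebra
    full <- .pr(rp_zero())
    orp <- ode$rp
    pow_of <- function(v, i) {
      col <- match(v, orp$vars)
      if (is.na(col)) 0L else orp$expo[i, col]
    }
    for (i in seq_along(orp$num)) {
      expo <- orp$expo[i, , drop = FALSE]
      coef_expo <- expo
      for (v in c("u", "u1", "u2"))
        if (v %in% orp$vars) coef_expo[1, match(v, orp$vars)] <- 0L
      coef <- .rp_collapse(orp$vars, coef_expo, orp$num[i], orp$den[i])
      term <- .pr(coef)
      for (v in list(c("u", 1), c("u1", 2), c("u2", 3))) {
        k <- pow_of(v[1], i)
        if (k > 0) {
          val <- switch(v[1], u = Up, u1 = U1, u2 = U2)
          term <- .pr_mul(term, .pr_pow(val, k, P), P)
        }
      }
      full <- .pr_add(full, term)
    }
    eqs <- c(rp_coeffs(full$A, "S"),
             lapply(rp_coeffs(full$B, "S"), identity))
    nA <- length(rp_coeffs(full$A, "S"))
    labels <- c(paste0("S^", names(rp_coeffs(full$A, "S"))),
                if (length(eqs) > nA)
                  paste0("S'*S^", names(eqs)[-seq_len(nA)]))
  }
  keep <- !vapply(eqs, rp_is_zero, logical(1))
  structure(list(method = method, N = N, ode = ode,
                 unknowns = unknowns,
                 equations = eqs[keep], labels = labels[keep]),
            class = "alg_system")
}

#' @export
print.alg_system <- function(x, ...) {
  cat("Algebraic system (", x$method, ", N = ", x$N, "): ",
      length(x$equations), " equations\n", sep = "")
  for (i in seq_along(x$equations))
    cat("  [", x$labels[i], "]  ", rp_to_string(x$equations[[i]]),
        " = 0\n", sep = "")
  invisible(x)
}
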