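# Lie point symmetries of the bistable Allen-Cahn equation.
#
# A point vector field  X = chi1 d/dt + chi2 d/dx + chi3 d/dy + phi d/dM
# with components depending on (t, x, y, M) is prolonged to second order,
# the invariance condition is applied to the equation, the time derivative
# is eliminated through the equation itself, and the result is split by
# monomials into an overdetermined linear system (the determining
# equations) for the infinitesimals.  The infinitesimals are sought in a
# finite-dimensional polynomial ansatz; the linear system is solved by
# exact rational elimination at generic rational parameter values, and
# every nullspace vector is then re-verified against the fully symbolic
# determining equations, so the reported algebra is exact.

POINT_VARS <- c("t", "x", "y", "M")

#' Construct a point vector field
#'
#' @param chi1,chi2,chi3,phi coefficient expressions of d/dt, d/dx, d/dy,
#'   d/dM; calls or numbers in the variables `t`, `x`, `y`, `M`.
#' @param label optional short name.
#' @return object of class `vector_field`.
#' @examples
#' vector_field(chi2 = quote(y), chi3 = quote(-x), label = "rotation")
#' @export
vector_field <- function(chi1 = 0, chi2 = 0, chi3 = 0, phi = 0,
                         label = NULL) {
  comps <- list(chi1 = chi1, chi2 = chi2, chi3 = chi3, phi = phi)
  for (nm in names(comps)) {
    v <- sym_vars(comps[[nm]])
    bad <- setdiff(v, POINT_VARS)
    if (length(bad))
      stop("component ", nm, " may depend only on (t, x, y, M); found: ",
           paste(bad, collapse = ", "))
  }
  structure(c(comps, list(label = label)), class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  if (!is.null(x$label)) cat(x$label, ": ", sep = "")
  parts <- character(0)
  sym <- c("d/dt", "d/dx", "d/dy", "d/dM")
  comps <- list(x$chi1, x$chi2, x$chi3, x$phi)
  for (i in 1:4) {
    if (is.numeric(comps[[i]]) && all(comps[[i]] == 0)) next
    parts <- c(parts, paste0("(", deparse(comps[[i]]), ") ", sym[i]))
  }
  if (!length(parts)) parts <- "0"
  cat(paste(parts, collapse = " + "), "\n")
  invisible(x)
}

vf_rp <- function(vf) lapply(vf[c("chi1", "chi2", "chi3", "phi")],
                             rp_from_call)

vf_is_zero <- function(vf) {
  all(vapply(vf_rp(vf), rp_is_zero, logical(1)))
}

# apply the field as a first-order differential operator to a ratpoly in
# (t, x, y, M)
vf_apply_rp <- function(comps, f) {
  out <- rp_zero()
  for (i in seq_along(POINT_VARS)) {
    df <- rp_deriv(f, POINT_VARS[i])
    if (!rp_is_zero(df)) out <- rp_add(out, rp_mul(comps[[i]], df))
  }
  out
}

# ---- prolongation --------------------------------------------------------

# second prolongation coefficients as ratpolys; comps is the list from
# vf_rp().  Uses the standard total-derivative recursion
#   phi^v  = D_v(phi) - M_t D_v(chi1) - M_x D_v(chi2) - M_y D_v(chi3)
#   phi^vv = D_v(phi^v) - M_tv D_v(chi1) - M_xv D_v(chi2) - M_yv D_v(chi3)
prolong2_rp <- function(comps) {
  first <- function(v) {
    rp_sub(rp_total_derivative(comps$phi, v),
           rp_add(rp_add(
             rp_mul(rp_var("M_t"), rp_total_derivative(comps$chi1, v)),
             rp_mul(rp_var("M_x"), rp_total_derivative(comps$chi2, v))),
             rp_mul(rp_var("M_y"), rp_total_derivative(comps$chi3, v))))
  }
  second <- function(phiv, v) {
    rp_sub(rp_total_derivative(phiv, v),
           rp_add(rp_add(
             rp_mul(rp_var(jet_name(paste0("t", v))),
                    rp_total_derivative(comps$chi1, v)),
             rp_mul(rp_var(jet_name(paste0("x", v))),
                    rp_total_derivative(comps$chi2, v))),
             rp_mul(rp_var(jet_name(paste0("y", v))),
                    rp_total_derivative(comps$chi3, v))))
  }
  phi_t <- first("t"); phi_x <- first("x"); phi_y <- first("y")
  list(phi_t = phi_t, phi_x = phi_x, phi_y = phi_y,
       phi_xx = second(phi_x, "x"), phi_yy = second(phi_y, "y"))
}

#' Second prolongation of a point vector field
#'
#' Extends the field's action to first and second derivatives of `M`
#' through the total-derivative recursion, returning the coefficients
#' `phi_t`, `phi_x`, `phi_y`, `phi_xx`, `phi_yy` as expressions over the
#' second-order jet.
#'
#' @param vf a `vector_field`.
#' @return object of class `prolonged_field` with the five coefficient
#'   expressions and the base field.
#' @examples
#' prolong2(vector_field(chi1 = 1))   # time translation: all zero
#' @export
prolong2 <- function(vf) {
  pr <- prolong2_rp(vf_rp(vf))
  structure(list(base = vf,
                 phi_t = rp_to_call(pr$phi_t),
                 phi_x = rp_to_call(pr$phi_x),
                 phi_y = rp_to_call(pr$phi_y),
                 phi_xx = rp_to_call(pr$phi_xx),
                 phi_yy = rp_to_call(pr$phi_yy)),
            class = "prolonged_field")
}

#' @export
print.prolonged_field <- function(x, ...) {
  cat("Second prolongation of:\n  ")
  print(x$base)
  for (nm in c("phi_t", "phi_x", "phi_y", "phi_xx", "phi_yy"))
    cat("  ", nm, " = ", deparse(x[[nm]]), "\n", sep = "")
  invisible(x)
}

# ---- invariance condition ------------------------------------------------

# the invariance residual of the model under vf, with M_t, M_tx, M_ty
# eliminated through the equation; exact ratpoly in the remaining jets,
# base variables and (symbolic) model parameters
invariance_residual_rp <- function(model, vf) {
  comps <- if (is.list(vf) && is_ratpoly(vf[[1]])) vf else vf_rp(vf)
  pr <- prolong2_rp(comps)
  rrp <- model_residual_rp(model)
  # dF/dM part: derivative of the residual with respect to M
  dFdM <- rp_deriv(rrp, "M")
  d_rp <- rp_from_call(model$d)
  E <- rp_add(pr$phi_t,
              rp_add(rp_neg(rp_mul(d_rp, rp_add(pr$phi_xx, pr$phi_yy))),
                     rp_mul(comps$phi, dFdM)))
  rhs <- model_mt_rhs_rp(model)                     # M_t on solutions
  E <- rp_subst(E, "M_tx", rp_total_derivative(rhs, "x"))
  E <- rp_subst(E, "M_ty", rp_total_derivative(rhs, "y"))
  rp_subst(E, "M_t", rhs)
}

#' Exact invariance check of a vector field
#'
#' Applies the second prolongation of `vf` to the model residual and
#' reduces modulo the equation; the result is zero exactly when `vf`
#' generates a point symmetry.
#'
#' @param model a `bac_model` (parameters may be symbolic).
#' @param vf a `vector_field`.
#' @return the leftover expression (a call); `0` for a symmetry.
#' @export
invariance_residual <- function(model, vf) {
  rp_to_call(invariance_residual_rp(model, vf))
}

# ---- determining equations ----------------------------------------------

# monomial basis of total degree <= deg in (t, x, y, M)
.ansatz_monomials <- function(deg) {
  out <- list()
  for (i in 0:deg) for (j in 0:(deg - i)) for (k in 0:(deg - i - j))
    for (l in 0:(deg - i - j - k))
      out[[length(out) + 1L]] <- c(t = i, x = j, y = k, M = l)
  out
}

.mono_rp <- function(expo) {
  p <- rp_const(1)
  for (v in names(expo)) if (expo[[v]] > 0)
    p <- rp_mul(p, rp_var(v, expo[[v]]))
  p
}

#' Determining equations for the infinitesimals
#'
#' Seeks the infinitesimals `chi1, chi2, chi3, phi` as polynomials of
#' total degree at most `degree` in `(t, x, y, M)` with unknown constant
#' coefficients.  The invariance condition is formed exactly, the time
#' derivative (and its prolongations) are eliminated through the equation,
#' and the residual is split by monomials in the independent jet
#' coordinates and base variables.  Each resulting equation is linear and
#' homogeneous in the unknown ansatz coefficients, with coefficients that
#' are exact polynomials in the model parameters.
#'
#' @param model a `bac_model`; keep parameters symbolic for the generic
#'   algebra.
#' @param degree polynomial ansatz degree (default 2; the known algebra
#'   of the equation is linear, so 2 leaves headroom).
#' @return object of class `determining_system`: unknown labels, and the
#'   list of equations (each a sparse linear form over the unknowns).
#' @export
determining_equations <- function(model, degree = 2) {
  monos <- .ansatz_monomials(degree)
  comps <- c("chi1", "chi2", "chi3", "phi")
  unknowns <- list()
  for (cc in comps) for (m in monos)
    unknowns[[length(unknowns) + 1L]] <- list(comp = cc, expo = m)
  labels <- vapply(unknowns, function(u) {
    mono <- rp_to_call(.mono_rp(u$expo))
    paste0(u$comp, "[", paste(deparse(mono), collapse = ""), "]")
  }, character(1))

  param_vars <- unique(unlist(lapply(
    list(model$d, model$gamma, model$sigma), sym_vars)))
  zero <- rp_zero()
  eqs <- new.env(parent = emptyenv())   # key -> list of (i, coeff ratpoly)
  for (i in seq_along(unknowns)) {
    u <- unknowns[[i]]
    comps_rp <- list(chi1 = zero, chi2 = zero, chi3 = zero, phi = zero)
    comps_rp[[u$comp]] <- .mono_rp(u$expo)
    E <- invariance_residual_rp(model, comps_rp)
    if (rp_is_zero(E)) next
    split_vars <- setdiff(E$vars, param_vars)
    # group terms of E by their monomial in the non-parameter variables
    keycols <- match(split_vars, E$vars)
    keys <- if (length(keycols))
      do.call(paste, c(as.data.frame(E$expo[, keycols, drop = FALSE],
                                     col.names = split_vars),
                       sep = ",")) else rep("1", length(E$num))
    keys <- paste(paste(split_vars, collapse = "|"), keys, sep = "::")
    for (k in unique(keys)) {
      sel <- keys == k
      expo <- E$expo[sel, , drop = FALSE]
      if (length(keycols)) expo[, keycols] <- 0L
      coeff <- .rp_collapse(E$vars, expo, E$num[sel], E$den[sel])
      if (rp_is_zero(coeff)) next
      cur <- if (is.null(eqs[[k]])) list() else eqs[[k]]
      cur[[length(cur) + 1L]] <- list(i = i, coeff = coeff)
      eqs[[k]] <- cur
    }
  }
  keys <- ls(eqs)
  structure(list(model = model, degree = degree, unknowns = unknowns,
                 labels = labels, param_vars = param_vars,
                 equations = lapply(keys, function(k) eqs[[k]]),
                 keys = keys),
            class = "determining_system")
}

#' @export
print.determining_system <- function(x, ...) {
  cat("Determining system: ", length(x$equations),
      " equations in ", length(x$unknowns),
      " ansatz coefficients (degree ", x$degree, " ansatz)\n", sep = "")
  invisible(x)
}

# substitute a rational coefficient vector into every determining equation;
# returns list of ratpolys in the parameters (all zero for a solution)
det_substitute <- function(sys, coefs) {
  stopifnot(length(coefs) == length(sys$unknowns))
  lapply(sys$equations, function(eq) {
    acc <- rp_zero()
    for (term in eq) {
      ci <- coefs[term$i]
      if (ci != 0) acc <- rp_add(acc, rp_scale(term$coeff, ci))
    }
    acc
  })
}

# express a vector_field in the ansatz coordinate system (exact; errors if
# the field is not a polynomial of degree <= ansatz degree)
vf_to_coefs <- function(sys, vf) {
  comps <- vf_rp(vf)
  coefs <- numeric(length(sys$unknowns))
  for (i in seq_along(sys$unknowns)) {
    u <- sys$unknowns[[i]]
    p <- comps[[u$comp]]
    if (rp_is_zero(p)) next
    # coefficient of the monomial u$expo in p
    sel <- rep(TRUE, length(p$num))
    for (v in c("t", "x", "y", "M")) {
      col <- match(v, p$vars)
      pow <- if (is.na(col)) rep(0L, length(p$num)) else p$expo[, col]
      sel <- sel & (pow == u$expo[[v]])
    }
    if (any(sel)) {
      stopifnot(sum(sel) == 1)
      coefs[i] <- p$num[sel] / p$den[sel]
    }
  }
  # verify exactness of the representation
  for (cc in c("chi1", "chi2", "chi3", "phi")) {
    rec <- rp_zero()
    for (i in seq_along(sys$unknowns)) {
      u <- sys$unknowns[[i]]
      if (u$comp == cc && coefs[i] != 0)
        rec <- rp_add(rec, rp_scale(.mono_rp(u$expo), coefs[i]))
    }
    if (!rp_equal(rec, comps[[cc]]))
      stop("field component ", cc,
           " is not a polynomial within the ansatz degree")
  }
  coefs
}

# ---- exact rational linear algebra --------------------------------------

# reduced row echelon form over Q; A given as numerator and denominator
# matrices.  Returns list(N, D, pivots).
rat_rref <- function(N, D) {
  n <- nrow(N); m <- ncol(N)
  # normalize a row to coprime integers (content removed); keeps the
  # exact arithmetic well inside the representable integer range
  normalize <- function(nu, de) {
    if (all(nu == 0)) return(list(num = nu, den = rep(1, m)))
    l <- 1
    for (dd in unique(de)) l <- .chk_exact(l * dd / gcd_vec(l, dd))
    nu <- .chk_exact(nu * (l / de))
    g <- 0
    for (v in nu) g <- gcd_vec(g, v)
    list(num = nu / max(g, 1), den = rep(1, m))
  }
  for (i in seq_len(n)) {
    r <- normalize(N[i, ], D[i, ])
    N[i, ] <- r$num; D[i, ] <- r$den
  }
  # rows are now coprime integers; eliminate fraction-free
  # (row_i <- row_i * p - row_pivot * f, content removed), so entries stay
  # integers of modest size throughout
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(m)) {
    if (row > n) break
    piv <- which(N[row:n, col] != 0)
    if (!length(piv)) next
    piv <- piv[1] + row - 1L
    if (piv != row) N[c(row, piv), ] <- N[c(piv, row), ]
    for (i in seq_len(n)) {
      if (i == row || N[i, col] == 0) next
      f <- N[i, col]; p <- N[row, col]
      g <- gcd_vec(f, p)
      s <- .chk_exact(N[i, ] * (p / g) - N[row, ] * (f / g))
      r <- normalize(s, rep(1, m))
      N[i, ] <- r$num
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  # pivot rows are unscaled: row k has pivot entry N[k, pivots[k]]
  list(N = N, D = matrix(1, n, m), pivots = pivots)
}

# nullspace basis (columns) of the rational matrix N/D; each column is
# scaled by the lcm of its denominators so entries are exact integers
rat_nullspace <- function(N, D) {
  m <- ncol(N)
  rr <- rat_rref(N, D)
  free <- setdiff(seq_len(m), rr$pivots)
  basis <- matrix(0, nrow = m, ncol = length(free))
  for (j in seq_along(free)) {
    fc <- free[j]
    bn <- numeric(m); bd <- rep(1, m)
    bn[fc] <- 1
    for (i in seq_along(rr$pivots)) {
      # unscaled pivot row i: x[pivot_i] = -N[i, fc] / N[i, pivot_i]
      if (rr$N[i, fc] != 0) {
        r <- rat_reduce(-rr$N[i, fc], rr$N[i, rr$pivots[i]])
        bn[rr$pivots[i]] <- r$num
        bd[rr$pivots[i]] <- r$den
      }
    }
    l <- 1
    for (dd in unique(bd)) l <- .chk_exact(l * dd / gcd_vec(l, dd))
    bi <- bn * (l / bd)
    g <- 0
    for (v in bi) g <- gcd_vec(g, v)
    basis[, j] <- bi / max(g, 1)
  }
  basis
}

# ---- solving the determining system -------------------------------------

# fixed generic rational parameter draws (values are arbitrary generic
# rationals given as num/den pairs; three draws guard against accidental
# degeneracy)
.GENERIC_DRAWS <- list(
  list(d = c(2, 3), gamma = c(5, 7), sigma = c(3, 11)),
  list(d = c(7, 5), gamma = c(3, 2), sigma = c(5, 13)),
  list(d = c(9, 4), gamma = c(11, 3), sigma = c(7, 17)))

#' Solve the determining equations
#'
#' Builds the exact linear system at three generic rational values of the
#' model parameters, computes its rational nullspace, and then verifies
#' each nullspace vector against the fully symbolic determining equations
#' (coefficients polynomial in `d`, `gamma`, `sigma`).  Vectors that fail
#' the symbolic check (solutions special to a parameter draw) are dropped
#' and recorded as branch conditions.
#'
#' @param sys a `determining_system`.
#' @return object of class `lie_solution`: `n_free` (the dimension of the
#'   symmetry algebra within the ansatz), `fields` (a basis of
#'   `vector_field`s), `general` (component expressions with free
#'   constants `C1`, `C2`, ...), and `branch_notes`.
#' @export
solve_determining <- function(sys) {
  nunk <- length(sys$unknowns)
  rows_n <- list(); rows_d <- list()
  for (draw in .GENERIC_DRAWS) {
    for (eq in sys$equations) {
      rn <- numeric(nunk); rd <- rep(1, nunk)
      for (term in eq) {
        r <- rp_eval_rat(term$coeff, draw)
        rn[term$i] <- r[1]; rd[term$i] <- r[2]
      }
      rows_n[[length(rows_n) + 1L]] <- rn
      rows_d[[length(rows_d) + 1L]] <- rd
    }
  }
  N <- do.call(rbind, rows_n); D <- do.call(rbind, rows_d)
  basis <- rat_nullspace(N, D)
  # symbolic verification of each basis vector
  keep <- logical(ncol(basis)); notes <- character(0)
  for (j in seq_len(ncol(basis))) {
    res <- det_substitute(sys, basis[, j])
    ok <- all(vapply(res, rp_is_zero, logical(1)))
    keep[j] <- ok
    if (!ok)
      notes <- c(notes, paste0(
        "nullspace vector ", j, " solves the system only at special ",
        "parameter values (dropped from the generic algebra)"))
  }
  basis <- basis[, keep, drop = FALSE]
  fields <- lapply(seq_len(ncol(basis)), function(j)
    .coefs_to_vf(sys, basis[, j], label = paste0("N", j)))
  general <- .general_field(sys, basis)
  structure(list(n_free = ncol(basis), fields = fields, general = general,
                 branch_notes = notes, basis_matrix = basis, system = sys),
            class = "lie_solution")
}

.coefs_to_vf <- function(sys, coefs, label = NULL) {
  comps <- list(chi1 = rp_zero(), chi2 = rp_zero(), chi3 = rp_zero(),
                phi = rp_zero())
  for (i in seq_along(sys$unknowns)) {
    if (coefs[i] == 0) next
    u <- sys$unknowns[[i]]
    comps[[u$comp]] <- rp_add(comps[[u$comp]],
                              rp_scale(.mono_rp(u$expo), coefs[i]))
  }
  vector_field(rp_to_call(comps$chi1), rp_to_call(comps$chi2),
               rp_to_call(comps$chi3), rp_to_call(comps$phi), label = label)
}

.general_field <- function(sys, basis) {
  k <- ncol(basis)
  out <- list(chi1 = 0, chi2 = 0, chi3 = 0, phi = 0)
  for (j in seq_len(k)) {
    vf <- .coefs_to_vf(sys, basis[, j])
    Cj <- as.name(paste0("C", j))
    for (cc in names(out)) {
      comp <- vf[[cc]]
      if (is.numeric(comp) && all(comp == 0)) next
      piece <- .simp(call("*", Cj, comp))
      out[[cc]] <- if (is.numeric(out[[cc]]) && out[[cc]] == 0) piece else
        call("+", out[[cc]], piece)
    }
  }
  out
}

#' @export
print.lie_solution <- function(x, ...) {
  cat("Symmetry algebra: ", x$n_free, " free constants\n", sep = "")
  cat("General infinitesimals:\n")
  for (cc in c("chi1", "chi2", "chi3", "phi"))
    cat("  ", cc, " = ", deparse(x$general[[cc]]), "\n", sep = "")
  if (length(x$branch_notes))
    cat("Branch notes:\n ", paste(x$branch_notes, collapse = "\n  "), "\n")
  invisible(x)
}

# ---- generators, commutators --------------------------------------------

#' Basis of the symmetry algebra
#'
#' The four point-symmetry generators of the equation for generic
#' parameters: time translation, the two space translations, and the
#' rotation in the (x, y) plane.
#'
#' @return list of `vector_field`s `X1 = d/dt`, `X2 = d/dx`, `X3 = d/dy`,
#'   `X4 = y d/dx - x d/dy`.
#' @export
generator_basis <- function() {
  list(X1 = vector_field(chi1 = 1, label = "X1"),
       X2 = vector_field(chi2 = 1, label = "X2"),
       X3 = vector_field(chi3 = 1, label = "X3"),
       X4 = vector_field(chi2 = quote(y), chi3 = quote(-x), label = "X4"))
}

#' Lie bracket of two point vector fields
#'
#' `[a, b] = a b - b a` acting as first-order operators on functions of
#' `(t, x, y, M)`; the result is again a point vector field, computed
#' exactly.
#'
#' @param a,b `vector_field`s with polynomial components.
#' @return a `vector_field`.
#' @examples
#' b <- generator_basis()
#' lie_bracket(b$X2, b$X4)   # -X3
#' @export
lie_bracket <- function(a, b) {
  ca <- vf_rp(a); cb <- vf_rp(b)
  comp <- function(i) rp_sub(vf_apply_rp(ca, cb[[i]]),
                             vf_apply_rp(cb, ca[[i]]))
  vector_field(rp_to_call(comp(1)), rp_to_call(comp(2)),
               rp_to_call(comp(3)), rp_to_call(comp(4)))
}

# express a vector field exactly in a basis; NULL if not in the span
.vf_in_basis <- function(vf, basis) {
  # coordinates over the monomials of all components
  vecs <- lapply(c(list(vf), basis), function(f) {
    comps <- vf_rp(f)
    out <- list()
    for (cc in names(comps)) {
      p <- comps[[cc]]
      if (rp_is_zero(p)) next
      for (i in seq_along(p$num)) {
        key <- paste(cc, paste(p$vars, p$expo[i, ], collapse = ";"))
        out[[key]] <- p$num[i] / p$den[i]
      }
    }
    out
  })
  keys <- unique(unlist(lapply(vecs, names)))
  tab <- vapply(vecs, function(v)
    vapply(keys, function(k) if (is.null(v[[k]])) 0 else v[[k]],
           numeric(1)), numeric(length(keys)))
  tab <- matrix(tab, nrow = length(keys))
  target <- tab[, 1]; B <- tab[, -1, drop = FALSE]
  fit <- tryCatch(qr.solve(B, target), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  if (max(abs(B %*% fit - target)) > 1e-9) return(NULL)
  round(fit, 9)
}

#' Commutator table of a basis
#'
#' Computes all pairwise Lie brackets, expresses each in the given basis
#' (exactly), and checks antisymmetry, the zero diagonal, closure and the
#' Jacobi identity.
#'
#' @param basis list of `vector_field`s (default [generator_basis()]).
#' @return object of class `commutator_table`: an `n x n x n` array of
#'   structure constants `c[i, j, k]` with
#'   `[X_i, X_j] = sum_k c[i, j, k] X_k`.
#' @export
commutator_table <- function(basis = generator_basis()) {
  n <- length(basis)
  cc <- array(0, dim = c(n, n, n))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    br <- lie_bracket(basis[[i]], basis[[j]])
    if (vf_is_zero(br)) next
    co <- .vf_in_basis(br, basis)
    if (is.null(co))
      stop("bracket [", i, ",", j, "] is not in the span of the basis")
    cc[i, j, ] <- co
  }
  # antisymmetry and Jacobi
  for (i in seq_len(n)) for (j in seq_len(n))
    stopifnot(all(cc[i, j, ] + cc[j, i, ] == 0))
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    jac <- numeric(n)
    for (m in seq_len(n))
      jac <- jac + cc[i, j, m] * cc[m, k, ] +
        cc[j, k, m] * cc[m, i, ] + cc[k, i, m] * cc[m, j, ]
    stopifnot(all(abs(jac) < 1e-12))
  }
  structure(list(constants = cc,
                 names = if (!is.null(names(basis))) names(basis) else
                   paste0("X", seq_len(n))),
            class = "commutator_table")
}

#' @export
print.commutator_table <- function(x, ...) {
  n <- length(x$names)
  out <- matrix("0", n, n, dimnames = list(x$names, x$names))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    co <- x$constants[i, j, ]
    if (all(co == 0)) next
    terms <- character(0)
    for (k in seq_len(n)) {
      if (co[k] == 0) next
      pre <- if (co[k] == 1) "" else if (co[k] == -1) "-" else
        paste0(co[k], "*")
      terms <- c(terms, paste0(pre, x$names[k]))
    }
    out[i, j] <- paste(terms, collapse = "+")
  }
  print(out, quote = FALSE)
  invisible(x)
}
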