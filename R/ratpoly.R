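# Exact sparse multivariate (Laurent) polynomials over the rationals.
#
# A `ratpoly` is a list with
#   vars : character vector of variable names, sorted,
#   expo : integer matrix (one row per term, one column per variable),
#   num  : numeric vector of integer-valued numerators,
#   den  : numeric vector of integer-valued (positive) denominators.
# Coefficients are exact rationals kept as num/den pairs of doubles; all
# arithmetic guards against leaving the exactly-representable integer range.
# Negative exponents are permitted, so the same engine serves Laurent
# expansions in an auxiliary-function variable.

MAX_EXACT <- 2^52

.chk_exact <- function(x) {
  if (any(abs(x) > MAX_EXACT))
    stop("exact rational arithmetic overflow (coefficient beyond 2^52)")
  x
}

gcd_vec <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    t <- b
    b <- ifelse(b > 0, a %% b, 0)
    a <- t
  }
  ifelse(a == 0, 1, a)
}

# reduce num/den to lowest terms, den > 0
rat_reduce <- function(num, den) {
  stopifnot(all(den != 0))
  s <- ifelse(den < 0, -1, 1)
  num <- num * s; den <- den * s
  g <- gcd_vec(num, den)
  list(num = num / g, den = den / g)
}

rat_add <- function(n1, d1, n2, d2) {
  g <- gcd_vec(d1, d2)
  rat_reduce(.chk_exact(n1 * (d2 / g) + n2 * (d1 / g)),
             .chk_exact(d1 * (d2 / g)))
}

rat_mul <- function(n1, d1, n2, d2) {
  # cross-reduce first to delay overflow
  g1 <- gcd_vec(n1, d2); g2 <- gcd_vec(n2, d1)
  rat_reduce(.chk_exact((n1 / g1) * (n2 / g2)),
             .chk_exact((d1 / g2) * (d2 / g1)))
}

# convert a numeric scalar to a rational (continued-fraction expansion,
# denominators up to 1e7); rejects constants with no close small rational
as_rat <- function(x) {
  if (x == round(x)) return(list(num = x, den = 1))
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
  z <- x
  for (i in 1:40) {
    a <- floor(z)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > 1e7) break
    if (abs(x - h / k) < 1e-12 * max(1, abs(x)))
      return(rat_reduce(h, k))
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    if (abs(z - a) < 1e-14) break
    z <- 1 / (z - a)
  }
  stop("numeric constant is not exactly rational: ", x)
}

rp_zero <- function() {
  structure(list(vars = character(0),
                 expo = matrix(integer(0), nrow = 0, ncol = 0),
                 num = numeric(0), den = numeric(0)),
            class = "ratpoly")
}

rp_const <- function(num, den = 1) {
  if (length(num) == 1 && is.numeric(num) && den == 1 && num != round(num)) {
    r <- as_rat(num); num <- r$num; den <- r$den
  }
  if (num == 0) return(rp_zero())
  r <- rat_reduce(num, den)
  structure(list(vars = character(0),
                 expo = matrix(integer(0), nrow = 1, ncol = 0),
                 num = r$num, den = r$den),
            class = "ratpoly")
}

rp_var <- function(name, pow = 1L) {
  structure(list(vars = name,
                 expo = matrix(as.integer(pow), nrow = 1, ncol = 1),
                 num = 1, den = 1),
            class = "ratpoly")
}

is_ratpoly <- function(x) inherits(x, "ratpoly")

# align two polynomials on the union of their variables (sorted)
.rp_align <- function(p, q) {
  vars <- sort(union(p$vars, q$vars))
  pad <- function(z) {
    m <- matrix(0L, nrow = nrow(z$expo), ncol = length(vars),
                dimnames = list(NULL, vars))
    if (length(z$vars)) m[, z$vars] <- z$expo
    m
  }
  list(vars = vars, pe = pad(p), qe = pad(q))
}

# collapse duplicate monomials, drop zero coefficients
.rp_collapse <- function(vars, expo, num, den) {
  if (nrow(expo) == 0 || length(num) == 0) return(rp_zero())
  key <- if (ncol(expo)) do.call(paste, c(as.data.frame(expo), sep = ",")) else
    rep("1", nrow(expo))
  ord <- order(key)
  key <- key[ord]; expo <- expo[ord, , drop = FALSE]
  num <- num[ord]; den <- den[ord]
  grp <- cumsum(!duplicated(key))
  ng <- grp[length(grp)]
  onum <- numeric(ng); oden <- numeric(ng)
  first <- !duplicated(key)
  onum <- num[first]; oden <- den[first]
  if (any(!first)) {
    idx <- which(!first)
    for (i in idx) {
      g <- grp[i]
      r <- rat_add(onum[g], oden[g], num[i], den[i])
      onum[g] <- r$num; oden[g] <- r$den
    }
  }
  oexpo <- expo[first, , drop = FALSE]
  keep <- onum != 0
  if (!any(keep)) return(rp_zero())
  oexpo <- oexpo[keep, , drop = FALSE]
  onum <- onum[keep]; oden <- oden[keep]
  # drop variables that no longer occur
  used <- colSums(oexpo != 0) > 0
  structure(list(vars = vars[used],
                 expo = oexpo[, used, drop = FALSE],
                 num = onum, den = oden),
            class = "ratpoly")
}

rp_add <- function(p, q) {
  if (rp_is_zero(p)) return(q)
  if (rp_is_zero(q)) return(p)
  a <- .rp_align(p, q)
  .rp_collapse(a$vars, rbind(a$pe, a$qe), c(p$num, q$num), c(p$den, q$den))
}

rp_neg <- function(p) { p$num <- -p$num; p }

rp_sub <- function(p, q) rp_add(p, rp_neg(q))

rp_scale <- function(p, num, den = 1) {
  if (num == 0 || rp_is_zero(p)) return(rp_zero())
  if (num != round(num) || den != round(den)) {
    r1 <- as_rat(num); r2 <- as_rat(den)
    num <- r1$num * r2$den; den <- r1$den * r2$num
  }
  r <- rat_mul(p$num, p$den, num, den)
  p$num <- r$num; p$den <- r$den
  p
}

rp_mul <- function(p, q) {
  if (rp_is_zero(p) || rp_is_zero(q)) return(rp_zero())
  a <- .rp_align(p, q)
  np <- nrow(a$pe); nq <- nrow(a$qe)
  ip <- rep(seq_len(np), times = nq)
  iq <- rep(seq_len(nq), each = np)
  expo <- a$pe[ip, , drop = FALSE] + a$qe[iq, , drop = FALSE]
  r <- rat_mul(p$num[ip], p$den[ip], q$num[iq], q$den[iq])
  .rp_collapse(a$vars, expo, r$num, r$den)
}

rp_pow <- function(p, k) {
  k <- as.integer(k)
  if (k < 0) {
    # only a single Laurent monomial is invertible
    if (nrow(p$expo) != 1) stop("cannot invert a non-monomial polynomial")
    p$expo <- p$expo * k
    r <- rat_reduce(p$den^(-k), p$num^(-k))
    p$num <- .chk_exact(r$num); p$den <- .chk_exact(r$den)
    return(p)
  }
  out <- rp_const(1)
  base <- p
  while (k > 0) {
    if (k %% 2L == 1L) out <- rp_mul(out, base)
    k <- k %/% 2L
    if (k > 0) base <- rp_mul(base, base)
  }
  out
}

rp_is_zero <- function(p) length(p$num) == 0

rp_is_const <- function(p) length(p$num) == 0 ||
  (length(p$num) == 1 && (ncol(p$expo) == 0 || all(p$expo == 0)))

rp_equal <- function(p, q) rp_is_zero(rp_sub(p, q))

# partial derivative with respect to one variable (Laurent rule included)
rp_deriv <- function(p, var) {
  if (!(var %in% p$vars)) return(rp_zero())
  j <- match(var, p$vars)
  k <- p$expo[, j]
  keep <- k != 0
  if (!any(keep)) return(rp_zero())
  expo <- p$expo[keep, , drop = FALSE]
  r <- rat_mul(p$num[keep], p$den[keep], k[keep], rep(1, sum(keep)))
  expo[, j] <- expo[, j] - 1L
  .rp_collapse(p$vars, expo, r$num, r$den)
}

# substitute a ratpoly (or rational constant) for a variable
rp_subst <- function(p, var, value) {
  if (!(var %in% p$vars)) return(p)
  if (is.numeric(value)) value <- rp_const(value)
  j <- match(var, p$vars)
  k <- p$expo[, j]
  if (any(k < 0) && rp_is_zero(value))
    stop("substituting zero into a negative power")
  out <- rp_zero()
  for (i in seq_along(p$num)) {
    term <- structure(list(vars = p$vars,
                           expo = p$expo[i, , drop = FALSE],
                           num = p$num[i], den = p$den[i]),
                      class = "ratpoly")
    term$expo[1, j] <- 0L
    term <- .rp_collapse(term$vars, term$expo, term$num, term$den)
    out <- rp_add(out, rp_mul(term, rp_pow(value, k[i])))
  }
  out
}

# numeric evaluation in an environment/list of variable values
rp_eval <- function(p, env) {
  if (rp_is_zero(p)) return(0)
  vals <- vapply(p$vars, function(v) {
    if (is.null(env[[v]])) stop("no value for variable ", v)
    as.numeric(env[[v]])
  }, numeric(1))
  terms <- p$num / p$den
  if (length(p$vars))
    terms <- terms * apply(p$expo, 1, function(e) prod(vals^e))
  sum(terms)
}

# scale a polynomial to coprime integer coefficients (content 1); the
# scaling factor is dropped, so use only where overall scale is irrelevant
# (equations equal to zero) or tracked by the caller
rp_content_normalize <- function(p) {
  if (rp_is_zero(p)) return(p)
  l <- 1
  for (dd in unique(p$den)) l <- .chk_exact(l * dd / gcd_vec(l, dd))
  num <- .chk_exact(p$num * (l / p$den))
  g <- 0
  for (v in num) g <- gcd_vec(g, v)
  p$num <- num / max(g, 1)
  p$den <- rep(1, length(num))
  p
}

# exact multivariate polynomial division: returns q with a = q * b, or
# NULL when b does not divide a (monomial-wise reduction in lex order)
rp_divide_exact <- function(a, b) {
  if (rp_is_zero(a)) return(rp_zero())
  if (rp_is_zero(b)) return(NULL)
  lead <- function(p) {
    # lexicographically largest exponent row
    key <- do.call(order, c(as.data.frame(-p$expo), list(seq_len(nrow(p$expo)))))
    i <- key[1]
    list(expo = p$expo[i, , drop = FALSE], num = p$num[i], den = p$den[i],
         vars = p$vars)
  }
  q <- rp_zero()
  rem <- a
  for (step in 1:2000) {
    if (rp_is_zero(rem)) return(q)
    al <- .rp_align(rem, b)
    remA <- rem; bA <- b
    remA$expo <- al$pe; remA$vars <- al$vars
    bA$expo <- al$qe; bA$vars <- al$vars
    lr <- lead(remA); lb <- lead(bA)
    de <- lr$expo - lb$expo
    if (any(de < 0)) return(NULL)
    co <- rat_mul(lr$num, lr$den, lb$den, lb$num)
    mono <- .rp_collapse(al$vars, de, co$num, co$den)
    q <- rp_add(q, mono)
    rem <- rp_sub(rem, rp_mul(mono, b))
  }
  NULL
}

# reduce a rational function: cancel numeric/monomial content and try
# exact polynomial division both ways
rf_simplify <- function(a) {
  a <- as_rf(a)
  if (rp_is_zero(a$num)) return(rf_new(rp_zero()))
  # normalize numeric content of both parts, folding the net rational
  # scale back into the numerator (keeps integer growth in check)
  cont <- function(p) {
    l <- 1
    for (dd in unique(p$den)) l <- .chk_exact(l * dd / gcd_vec(l, dd))
    g <- 0
    for (v in .chk_exact(p$num * (l / p$den))) g <- gcd_vec(g, v)
    c(max(g, 1), l)   # p = (g/l) * normalized
  }
  cn <- cont(a$num); cd <- cont(a$den)
  a$num <- rp_content_normalize(a$num)
  a$den <- rp_content_normalize(a$den)
  a$num <- rp_scale(a$num, cn[1] * cd[2], cn[2] * cd[1])
  q <- rp_divide_exact(a$num, a$den)
  if (!is.null(q)) return(rf_new(q))
  q <- rp_divide_exact(a$den, a$num)
  if (!is.null(q)) {
    # a = 1 / q; put the numeric content of q into the numerator
    return(rf_new(rp_const(1), q))
  }
  # cancel common monomial content
  common <- intersect(a$num$vars, a$den$vars)
  for (v in common) {
    mn <- min(rp_mindeg(a$num, v), rp_mindeg(a$den, v))
    if (mn > 0) {
      a$num <- rp_mul(a$num, rp_pow(rp_var(v), -mn))
      a$den <- rp_mul(a$den, rp_pow(rp_var(v), -mn))
    }
  }
  a
}

# exact rational evaluation: vals maps variable name -> c(num, den)
rp_eval_rat <- function(p, vals) {
  out_n <- 0; out_d <- 1
  for (i in seq_along(p$num)) {
    tn <- p$num[i]; td <- p$den[i]
    for (j in seq_along(p$vars)) {
      e <- p$expo[i, j]
      if (e == 0) next
      v <- vals[[p$vars[j]]]
      if (is.null(v)) stop("no value for variable ", p$vars[j])
      if (e > 0) {
        r <- rat_mul(tn, td, v[1]^e, v[2]^e)
      } else {
        r <- rat_mul(tn, td, v[2]^(-e), v[1]^(-e))
      }
      tn <- r$num; td <- r$den
    }
    r <- rat_add(out_n, out_d, tn, td)
    out_n <- r$num; out_d <- r$den
  }
  c(out_n, out_d)
}

rp_degree <- function(p, var) {
  if (!(var %in% p$vars)) return(if (rp_is_zero(p)) -Inf else 0L)
  max(p$expo[, match(var, p$vars)])
}

rp_mindeg <- function(p, var) {
  if (!(var %in% p$vars)) return(if (rp_is_zero(p)) Inf else 0L)
  min(p$expo[, match(var, p$vars)])
}

# coefficients of powers of `var`: named list "<power>" -> ratpoly
rp_coeffs <- function(p, var) {
  if (rp_is_zero(p)) return(list())
  if (!(var %in% p$vars)) return(setNames(list(p), "0"))
  j <- match(var, p$vars)
  ks <- p$expo[, j]
  out <- list()
  for (k in sort(unique(ks))) {
    keep <- ks == k
    expo <- p$expo[keep, , drop = FALSE]
    expo[, j] <- 0L
    out[[as.character(k)]] <-
      .rp_collapse(p$vars, expo, p$num[keep], p$den[keep])
  }
  out
}

# ---- conversion: R call/expression -> ratpoly ----------------------------

rp_from_call <- function(e) {
  if (is.numeric(e)) return(rp_const(e))
  if (is.name(e)) return(rp_var(as.character(e)))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(rp_from_call(e[[2]]))
    if (op == "+" && length(e) == 2) return(rp_from_call(e[[2]]))
    if (op == "-" && length(e) == 2) return(rp_neg(rp_from_call(e[[2]])))
    if (op == "+") return(rp_add(rp_from_call(e[[2]]), rp_from_call(e[[3]])))
    if (op == "-") return(rp_sub(rp_from_call(e[[2]]), rp_from_call(e[[3]])))
    if (op == "*") return(rp_mul(rp_from_call(e[[2]]), rp_from_call(e[[3]])))
    if (op == "^") {
      k <- e[[3]]
      if (!is.numeric(k) || k != round(k))
        stop("only integer powers convert to polynomials")
      return(rp_pow(rp_from_call(e[[2]]), k))
    }
    if (op == "/") {
      den <- rp_from_call(e[[3]])
      if (rp_is_const(den)) {
        if (rp_is_zero(den)) stop("division by zero")
        return(rp_scale(rp_from_call(e[[2]]), den$den, den$num))
      }
      if (nrow(den$expo) == 1)          # monomial: Laurent division
        return(rp_mul(rp_from_call(e[[2]]), rp_pow(den, -1L)))
      stop("division by a non-monomial polynomial; use a ratfun")
    }
  }
  stop("cannot convert to polynomial: ", deparse(e))
}

# ---- conversion: ratpoly -> R call (for display / evaluation) ------------

.mono_call <- function(vars, expo) {
  f <- NULL
  for (j in seq_along(vars)) {
    k <- expo[j]
    if (k == 0) next
    piece <- if (k == 1) as.name(vars[j]) else
      call("^", as.name(vars[j]), as.numeric(k))
    f <- if (is.null(f)) piece else call("*", f, piece)
  }
  f
}

rp_to_call <- function(p) {
  if (rp_is_zero(p)) return(0)
  # order terms for stable printing: by exponent rows descending
  out <- NULL
  for (i in seq_along(p$num)) {
    co <- p$num[i] / p$den[i]
    mono <- if (length(p$vars)) .mono_call(p$vars, p$expo[i, ]) else NULL
    piece <-
      if (is.null(mono)) {
        if (p$den[i] == 1) p$num[i] else call("/", p$num[i], p$den[i])
      } else if (p$num[i] == 1 && p$den[i] == 1) {
        mono
      } else if (p$num[i] == -1 && p$den[i] == 1) {
        call("-", mono)
      } else if (p$den[i] == 1) {
        call("*", p$num[i], mono)
      } else {
        call("*", call("/", p$num[i], p$den[i]), mono)
      }
    out <- if (is.null(out)) piece else call("+", out, piece)
  }
  out
}

rp_to_string <- function(p) paste(deparse(rp_to_call(p), width.cutoff = 500),
                                  collapse = " ")

#' @export
print.ratpoly <- function(x, ...) {
  cat(rp_to_string(x), "\n")
  invisible(x)
}

# ---- rational functions (pairs of ratpolys) ------------------------------

rf_new <- function(num, den = rp_const(1)) {
  if (rp_is_zero(den)) stop("zero denominator")
  structure(list(num = num, den = den), class = "ratfun")
}

is_ratfun <- function(x) inherits(x, "ratfun")

as_rf <- function(x) {
  if (is_ratfun(x)) return(x)
  if (is_ratpoly(x)) return(rf_new(x))
  if (is.numeric(x)) return(rf_new(rp_const(x)))
  rf_from_call(x)
}

rf_add <- function(a, b) {
  a <- as_rf(a); b <- as_rf(b)
  rf_new(rp_add(rp_mul(a$num, b$den), rp_mul(b$num, a$den)),
         rp_mul(a$den, b$den))
}

rf_neg <- function(a) { a <- as_rf(a); a$num <- rp_neg(a$num); a }

rf_sub <- function(a, b) rf_add(a, rf_neg(b))

rf_mul <- function(a, b) {
  a <- as_rf(a); b <- as_rf(b)
  rf_new(rp_mul(a$num, b$num), rp_mul(a$den, b$den))
}

rf_div <- function(a, b) {
  a <- as_rf(a); b <- as_rf(b)
  if (rp_is_zero(b$num)) stop("division by zero rational function")
  rf_new(rp_mul(a$num, b$den), rp_mul(a$den, b$num))
}

rf_pow <- function(a, k) {
  a <- as_rf(a); k <- as.integer(k)
  if (k < 0) return(rf_pow(rf_div(rf_new(rp_const(1)), a), -k))
  rf_new(rp_pow(a$num, k), rp_pow(a$den, k))
}

rf_is_zero <- function(a) rp_is_zero(as_rf(a)$num)

# equality by cross-multiplication (no gcd needed)
rf_equal <- function(a, b) {
  a <- as_rf(a); b <- as_rf(b)
  rp_is_zero(rp_sub(rp_mul(a$num, b$den), rp_mul(b$num, a$den)))
}

rf_from_call <- function(e) {
  if (is.numeric(e)) return(rf_new(rp_const(e)))
  if (is.name(e)) return(rf_new(rp_var(as.character(e))))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(rf_from_call(e[[2]]))
    if (op == "+" && length(e) == 2) return(rf_from_call(e[[2]]))
    if (op == "-" && length(e) == 2) return(rf_neg(rf_from_call(e[[2]])))
    if (op == "+") return(rf_add(rf_from_call(e[[2]]), rf_from_call(e[[3]])))
    if (op == "-") return(rf_sub(rf_from_call(e[[2]]), rf_from_call(e[[3]])))
    if (op == "*") return(rf_mul(rf_from_call(e[[2]]), rf_from_call(e[[3]])))
    if (op == "/") return(rf_div(rf_from_call(e[[2]]), rf_from_call(e[[3]])))
    if (op == "^") {
      k <- e[[3]]
      if (is.call(k) && identical(as.character(k[[1]]), "-"))
        k <- -as.numeric(k[[2]])
      if (!is.numeric(k) || k != round(k))
        stop("only integer powers convert to rational functions")
      return(rf_pow(rf_from_call(e[[2]]), k))
    }
  }
  stop("cannot convert to rational function: ", deparse(e))
}

rf_to_call <- function(a) {
  a <- as_rf(a)
  if (rp_is_zero(a$num)) return(0)
  if (rp_is_const(a$den)) {
    p <- rp_scale(a$num, a$den$den, a$den$num)
    return(rp_to_call(p))
  }
  call("/", rp_to_call(a$num), call("(", rp_to_call(a$den)))
}

#' @export
print.ratfun <- function(x, ...) {
  cat(paste(deparse(rf_to_call(x), width.cutoff = 500), collapse = " "), "\n")
  invisible(x)
}

rf_subst <- function(a, var, value) {
  a <- as_rf(a)
  if (is.numeric(value)) value <- rf_new(rp_const(value))
  if (is_ratpoly(value)) value <- rf_new(value)
  # substitute into num and den separately; value may be a ratfun
  sub_poly <- function(p) {
    if (!(var %in% p$vars)) return(rf_new(p))
    out <- rf_new(rp_zero())
    j <- match(var, p$vars)
    for (i in seq_along(p$num)) {
      expo <- p$expo[i, , drop = FALSE]
      k <- expo[1, j]; expo[1, j] <- 0L
      term <- .rp_collapse(p$vars, expo, p$num[i], p$den[i])
      out <- rf_add(out, rf_mul(rf_new(term), rf_pow(value, k)))
    }
    out
  }
  rf_div(sub_poly(a$num), sub_poly(a$den))
}
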