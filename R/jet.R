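# Jet-space calculus for a scalar unknown M(t, x, y).
#
# Jet coordinates are named "M" and "M_<indices>" with indices a sorted
# word over {t, x, y}: M_t, M_x, M_y, M_tx, M_xx, M_xyy, ...  Total
# derivatives act on exact polynomials (ratpoly) in the base variables,
# the jet coordinates and any free parameters.

BASE_VARS <- c("t", "x", "y")

is_jet_var <- function(v) v == "M" | grepl("^M_[txy]+$", v)

# M_<word> with the word re-sorted into t < x < y order
jet_name <- function(word) {
  if (nchar(word) == 0) return("M")
  idx <- sort(factor(strsplit(word, "")[[1]], levels = c("t", "x", "y")))
  paste0("M_", paste(as.character(idx), collapse = ""))
}

jet_promote <- function(v, var) {
  word <- if (v == "M") "" else sub("^M_", "", v)
  jet_name(paste0(word, var))
}

# total derivative of a ratpoly on jet space:
#   D_v = d/dv + sum_J M_{J+v} d/dM_J
rp_total_derivative <- function(p, var) {
  stopifnot(var %in% BASE_VARS)
  out <- rp_deriv(p, var)
  for (v in p$vars) {
    if (!is_jet_var(v)) next
    dp <- rp_deriv(p, v)
    if (rp_is_zero(dp)) next
    out <- rp_add(out, rp_mul(rp_var(jet_promote(v, var)), dp))
  }
  out
}

#' Total derivative on jet space
#'
#' Applies the total-derivative operator `D_t`, `D_x` or `D_y` to an
#' expression over the jet of an unknown `M(t, x, y)`: the chain rule
#' threads through `M` and its derivative coordinates, so for example
#' `D_x(M) = M_x` and `D_x(M_x^2) = 2 M_x M_xx`.  Jet coordinates are
#' written `M`, `M_t`, `M_x`, `M_xx`, `M_xy`, ... (indices sorted t, x, y).
#'
#' @param expr expression (call) polynomial in the base variables, jet
#'   coordinates and parameters.
#' @param var one of `"t"`, `"x"`, `"y"`.
#' @return the total derivative, as a call.
#' @examples
#' total_derivative(quote(M), "x")        # M_x
#' total_derivative(quote(t * M), "t")    # M + t * M_t
#' total_derivative(quote(M_x^2), "x")    # 2 * M_x * M_xx
#' @export
total_derivative <- function(expr, var) {
  var <- match.arg(var, BASE_VARS)
  rp_to_call(rp_total_derivative(rp_from_call(expr), var))
}
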