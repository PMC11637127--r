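# Homogeneous balance: fix the truncation order N of the expansion ansatz
# by matching the effective degree of the highest derivative against the
# strongest nonlinearity.  For all three methods implemented here the
# auxiliary relation raises the degree by one per derivative (S' is
# quadratic in S, and for the generalized auxiliary equation S'' is cubic
# while S' enters squared), so a term u^(k) has effective degree N + k and
# u^p has degree p N.

#' Truncation order by homogeneous balance
#'
#' Balances `N + k = p N` where `k` is the highest derivative order and
#' `p` the highest polynomial degree in `u` of the reduced equation; for
#' the cubic second-order reductions of the model this gives `N = 1` under
#' every method.
#'
#' @param ode an `ord_ode`.
#' @param method one of `"aux"`, `"gg2"`, `"tanh"` (the degree rule is the
#'   same for all three; the argument records which ansatz the result
#'   parameterizes).
#' @return integer `N >= 1`.
#' @examples
#' homogeneous_balance(paper_odes()[["13"]], "aux")   # 1
#' @export
homogeneous_balance <- function(ode, method = c("aux", "gg2", "tanh")) {
  method <- match.arg(method)
  rp <- ode$rp
  k <- if ("u2" %in% rp$vars) 2L else if ("u1" %in% rp$vars) 1L else 0L
  p <- rp_degree(rp, "u")
  if (k == 0) stop("equation has no derivative term to balance")
  if (p < 2) stop("equation has no nonlinearity to balance")
  N <- k / (p - 1)
  if (N != round(N) || N < 1)
    stop("homogeneous balance gives non-integer or non-positive N = ",
         format(N), "; method inapplicable")
  as.integer(N)
}
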