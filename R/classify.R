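# Numeric classification of wave profiles.
#
# The label is decided from a sampled profile u(r) on a window:
#   periodic   : repeating structure (with or without poles, so tan/cot
#                and sec/csc families count as periodic),
#   singular   : non-periodic profile with poles (coth/csch families),
#   kink       : bounded monotone increasing with distinct finite limits,
#   anti-kink  : bounded monotone decreasing with distinct finite limits,
#   bright     : localized hump above a flat background,
#   dark       : localized dip below a flat background,
#   rational   : localized profile with algebraic (power-law) tails,
#   constant / unclassified otherwise.

#' Classify a wave profile
#'
#' @param sol a `closed_form_solution`, or a call in `r`.
#' @param params named list of numeric values for every free symbol of
#'   the profile other than `r`.
#' @param window numeric length-2 sampling window for `r`.
#' @param n number of sample points.
#' @return character label, with a `diagnostics` attribute.
#' @export
classify_solution <- function(sol, params = list(), window = c(-10, 10),
                              n = 2001) {
  expr <- if (inherits(sol, "closed_form_solution")) sol$expr else sol
  expr <- sym_subs(expr, params)
  free <- setdiff(sym_vars(expr), "r")
  if (length(free))
    stop("profile still contains free symbols: ",
         paste(free, collapse = ", "))
  r <- seq(window[1], window[2], length.out = n)
  u <- tryCatch(sym_eval(expr, list(r = r)), error = function(e) NULL)
  if (is.null(u) || length(u) != n)
    u <- vapply(r, function(ri)
      tryCatch(sym_eval(expr, list(r = ri)), error = function(e) NA_real_),
      numeric(1))
  diag <- list()
  finite <- is.finite(u) & abs(u) < 1e8
  if (!any(finite)) return(structure("unclassified", diagnostics = diag))
  # robust pole mask: samples deviating enormously from the bulk spread
  # are the shoulders of a singularity (IQR stays finite for localized
  # humps, unlike the median absolute deviation)
  med <- stats::median(u[finite])
  iqr <- stats::IQR(u[finite])
  thr <- 100 * max(iqr, 1e-12)
  finite <- finite & abs(u - med) <= thr
  u_f <- u[finite]
  if (length(u_f) < n / 4) return(structure("unclassified",
                                            diagnostics = diag))
  scale <- max(1e-12, diff(range(u_f)))
  jumps <- sum(abs(diff(ifelse(finite, u, NA))) >
                 20 * max(stats::IQR(u_f), 1e-12), na.rm = TRUE)
  has_poles <- any(!finite) || jumps > 0
  diag$poles <- sum(!finite) + jumps

  per <- .detect_period(r, u, finite, scale)
  diag$period <- per
  if (!is.na(per)) return(structure("periodic", diagnostics = diag))
  if (has_poles) return(structure("singular", diagnostics = diag))

  # bounded, pole-free profile
  if (scale < 1e-9 * max(1, abs(mean(u_f))))
    return(structure("constant", diagnostics = diag))
  edge <- max(3L, round(0.05 * n))
  iL <- seq_len(edge); iR <- n - seq_len(edge) + 1L
  uL <- mean(u[iL][finite[iL]]); uR <- mean(u[iR][finite[iR]])
  du <- diff(u)
  mono_frac <- max(mean(du >= -1e-9 * scale), mean(du <= 1e-9 * scale))
  diag$limits <- c(uL, uR); diag$mono_frac <- mono_frac
  if (abs(uL - uR) > 0.1 * scale && mono_frac > 0.999) {
    return(structure(if (uR > uL) "kink" else "anti-kink",
                     diagnostics = diag))
  }
  if (abs(uL - uR) <= 0.1 * scale) {
    base <- (uL + uR) / 2
    up <- max(u_f) - base; down <- base - min(u_f)
    # tail decay: algebraic tails leave a visible residue far out
    iq <- which.min(abs(r - 0.4 * window[2]))
    tail_ratio <- abs(u[n - 2] - base) /
      max(abs(u[iq] - base), 1e-300)
    diag$tail_ratio <- tail_ratio
    algebraic <- is.finite(tail_ratio) && tail_ratio > 0.02 &&
      abs(u[n - 2] - base) > 1e-6 * scale
    if (max(up, down) > 1e-6 * max(1, abs(base))) {
      if (algebraic) return(structure("rational", diagnostics = diag))
      return(structure(if (up > down) "bright" else "dark",
                       diagnostics = diag))
    }
  }
  structure("unclassified", diagnostics = diag)
}

# period detection: pole spacing or mean-crossing spacing, confirmed by a
# shift test on the finite samples
.detect_period <- function(r, u, finite, scale) {
  n <- length(r)
  dr <- r[2] - r[1]
  cand <- numeric(0)
  # pole locations: masked samples plus large jumps between consecutive
  # samples (a pole can slip between grid points with both neighbours
  # finite); cluster into groups and use the group centers
  iqr_u <- stats::IQR(u[finite])
  jump <- which(abs(diff(ifelse(finite, u, NA))) >
                  20 * max(iqr_u, 1e-12))
  pole_idx <- sort(unique(c(which(!finite), jump)))
  if (length(pole_idx) >= 3) {
    brk <- c(0, which(diff(pole_idx) > 2), length(pole_idx))
    centers <- vapply(seq_len(length(brk) - 1), function(i)
      mean(r[pole_idx[(brk[i] + 1):brk[i + 1]]]), numeric(1))
    if (length(centers) >= 3) {
      gaps <- diff(centers)
      if (stats::sd(gaps) < 0.05 * mean(gaps))
        cand <- c(cand, mean(gaps), 2 * mean(gaps))
    }
  }
  u_m <- u; u_m[!finite] <- NA
  mu <- mean(u_m, na.rm = TRUE)
  sgn <- sign(u_m - mu)
  cross <- which(diff(sgn) != 0 & !is.na(diff(sgn)))
  if (length(cross) >= 5) {
    gaps <- diff(r[cross])
    gaps <- gaps[gaps > 3 * dr]
    if (length(gaps) >= 3 && stats::sd(gaps) < 0.05 * mean(gaps))
      cand <- c(cand, 2 * mean(gaps))
  }
  # bulk samples only (pole shoulders excluded) compared by correlation
  # and relative RMS, which tolerates the grid-snapped phase error
  bulk <- finite & abs(u_m - stats::median(u_m, na.rm = TRUE)) <=
    10 * max(stats::IQR(u_m, na.rm = TRUE), 1e-12)
  for (P in unique(cand)) {
    k0 <- round(P / dr)
    for (k in unique(pmax(5, k0 + (-1:1)))) {
      if (k > n / 2) next
      ia <- seq_len(n - k); ib <- ia + k
      ok <- bulk[ia] & bulk[ib]
      if (sum(ok) < n / 4) next
      a <- u_m[ia][ok]; b <- u_m[ib][ok]
      if (stats::sd(a) < 1e-12) next
      rmsd <- sqrt(mean((a - b)^2)) / stats::sd(a)
      if (stats::cor(a, b) > 0.998 && rmsd < 0.1) return(k * dr)
    }
  }
  NA_real_
}
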