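# Assembling closed-form travelling-wave solutions: parameter set +
# auxiliary-function library entry + travelling-variable definition.

#' Assemble closed-form solutions from a parameter set
#'
#' Substitutes each library entry (every +/- branch) into the truncated
#' ansatz of the set's method, then applies the set's assignments, giving
#' explicit profiles `u(r)`.  Validity is the conjunction of the entry's
#' domain condition and the set's constraints; entries whose domain
#' condition is violated by the set's own assignments (for example a
#' `kappa > 0` case under a set that forces `kappa < 0`) are emitted with
#' `vacuous = TRUE`, not dropped.
#'
#' @param pset a `parameter_set`.
#' @param entries library entries ([aux_library()], [gg2_library()] or
#'   [tanh_library()]); defaults to the library of the set's method.
#' @param r_def travelling-variable definition attached to the solutions
#'   (a call in `t`, `x`, `y`), e.g. `quote(t - x - y)`.
#' @param check_seed seed for the numeric vacuity probe.
#' @return list of `closed_form_solution` objects.
#' @export
assemble_solutions <- function(pset, entries = NULL, r_def = quote(t - x),
                               check_seed = 0) {
  if (is.null(entries))
    entries <- switch(pset$method, aux = aux_library(),
                      gg2 = gg2_library(), tanh = tanh_library())
  a <- pset$assignments
  zero_val <- function(v) is.null(v) || (is.numeric(v) && all(v == 0))
  out <- list()
  for (e in entries) {
    for (br in e$branches) {
      cf <- sym_subs(e$closed_form, list(pm = br))
      u <- a$a0
      if (!zero_val(a$a1)) u <- bquote(.(u) + (.(a$a1)) * (.(cf)))
      if (pset$method == "tanh" && !zero_val(a$b1))
        u <- bquote(.(u) + (.(a$b1)) / (.(cf)))
      # substitute remaining set assignments (kappa, tau, gamma, ...)
      reps <- a[setdiff(names(a), c("a0", "a1", "b1"))]
      u <- sym_subs(u, reps)
      vac <- .entry_vacuous(e, pset, check_seed)
      out[[length(out) + 1L]] <- structure(
        list(expr = u, r_def = r_def, method = pset$method,
             set_source = pset$source_eq, set_branch = pset$branch,
             set_provenance = pset$provenance,
             entry_id = e$id, entry_branch = br, family = e$family,
             conditions = paste(c(e$conditions, pset$conditions),
                                collapse = "; "),
             vacuous = isTRUE(vac), assignments = a),
        class = "closed_form_solution")
    }
  }
  out
}

# does the set force the entry's domain condition to fail?  Probed at
# seeded draws of the free symbols; TRUE only if it fails at every draw.
.entry_vacuous <- function(entry, pset, seed = 0) {
  cond <- .condition_calls(entry$conditions)
  if (!length(cond)) return(FALSE)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fails <- 0L; total <- 0L
  for (i in 1:12) {
    vals <- list()
    syms <- unique(unlist(lapply(cond, function(cc)
      sym_vars(sym_subs(cc, pset$assignments)))))
    for (nm in syms) vals[[nm]] <- .verify_sampler(nm)
    ok <- tryCatch(all(vapply(cond, function(cc)
      isTRUE(sym_eval(sym_subs(cc, pset$assignments), vals)),
      logical(1))), error = function(e) NA)
    if (is.na(ok)) next
    total <- total + 1L
    if (!ok) fails <- fails + 1L
  }
  total > 0L && fails == total
}

# parse a condition string like "b1 > 0, zeta > 0" / "kappa = 0" into
# calls usable for evaluation (zeta expanded; "=" read as near-equality)
.condition_calls <- function(cond_str) {
  if (is.null(cond_str) || !nzchar(cond_str)) return(list())
  parts <- strsplit(cond_str, ",")[[1]]
  out <- list()
  for (p in parts) {
    p <- trimws(p)
    p <- gsub("zeta", "(b2^2 - 4 * b1 * b3)", p)
    p <- gsub("!=", "!=", p, fixed = TRUE)
    if (grepl("!=", p)) {
      sides <- strsplit(p, "!=")[[1]]
      out[[length(out) + 1L]] <-
        bquote(abs(.(str2lang(sides[1])) - .(str2lang(sides[2]))) > 1e-9)
    } else if (grepl("=", p) && !grepl("[<>]", p)) {
      sides <- strsplit(p, "=")[[1]]
      out[[length(out) + 1L]] <-
        bquote(abs(.(str2lang(sides[1])) - .(str2lang(sides[2]))) < 1e-9)
    } else {
      out[[length(out) + 1L]] <- str2lang(p)
    }
  }
  out
}

#' @export
print.closed_form_solution <- function(x, ...) {
  cat("Closed-form solution [", x$method,
      if (!is.na(x$set_source)) paste0(", set eq. ", x$set_source),
      ", entry ", x$entry_id,
      if (x$entry_branch != 1) paste0(" (branch ", x$entry_branch, ")"),
      if (x$vacuous) ", VACUOUS", "]\n", sep = "")
  cat("  u(r) = ", paste(deparse(x$expr), collapse = "\n          "),
      "\n", sep = "")
  cat("  r = ", deparse(x$r_def), "   {", x$conditions, "}\n", sep = "")
  invisible(x)
}
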