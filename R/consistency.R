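#' Saaty random indices
#'
#' The classic random consistency indices `RI(n)` for reciprocal matrices of
#' order 1..10, used to scale the consistency index into the consistency
#' ratio.
#'
#' @return A named numeric vector mapping matrix order to `RI`.
#' @export
saaty_ri <- function() {
  c(`1` = 0, `2` = 0, `3` = 0.58, `4` = 0.90, `5` = 1.12,
    `6` = 1.24, `7` = 1.32, `8` = 1.41, `9` = 1.45, `10` = 1.49)
}

#' Saaty consistency ratio of a crisp comparison matrix
#'
#' Computes the principal eigenvalue `lambda_max` by power iteration, the
#' consistency index `CI = (lambda_max - n)/(n - 1)` and the consistency
#' ratio `CR = CI / RI(n)`. Matrices of order 1 and 2 are consistent by
#' construction (`CR = 0`). Judgments are conventionally accepted when
#' `CR < 0.1`.
#'
#' @param a Positive reciprocal square numeric matrix.
#' @param ri_table Named map from matrix order to random index
#'   (default [saaty_ri()]).
#' @param variant Label recording which crisp reduction of a fuzzy matrix
#'   produced `a` (`"plain"`, `"modal"`, or `"bounds_geomean"`).
#' @return An object of class `"consistency_report"`: list with
#'   `lambda_max`, `ci`, `cr`, `ri`, `n`, `variant`, `accepted`.
#' @seealso [fuzzy_cr_variants()]
#' @export
consistency_ratio <- function(a, ri_table = saaty_ri(),
                              variant = c("plain", "modal",
                                          "bounds_geomean")) {
  variant <- match.arg(variant)
  a <- as.matrix(a)
  n <- nrow(a)
  if (n == 1L) {
    lam <- a[1, 1]; ci <- 0; cr <- 0; ri <- 0
  } else {
    lam <- principal_eigenvector(a)$lambda_max
    ci <- (lam - n) / (n - 1)
    if (n <= 2L) {
      cr <- 0; ri <- 0
    } else {
      key <- as.character(n)
      if (!key %in% names(ri_table))
        stop("no random index available for matrix order n = ", n,
             call. = FALSE)
      ri <- ri_table[[key]]
      cr <- ci / ri
    }
  }
  structure(list(lambda_max = lam, ci = ci, cr = cr, ri = ri, n = n,
                 variant = variant, accepted = cr < 0.1),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, digits = 4, ...) {
  cat("<consistency_report> [", x$variant, "] n = ", x$n,
      ", lambda_max = ", signif(x$lambda_max, digits + 2),
      ", CI = ", signif(x$ci, digits),
      ", CR = ", signif(x$cr, digits), " (RI = ", x$ri, ") -> ",
      if (x$accepted) "accepted (CR < 0.1)" else "REJECTED (CR >= 0.1)",
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.consistency_report <- function(x, ...) {
  data.frame(variant = x$variant, n = x$n, lambda_max = x$lambda_max,
             ci = x$ci, cr = x$cr, ri = x$ri, accepted = x$accepted)
}

#' Consistency ratios of a fuzzy comparison matrix
#'
#' A fuzzy matrix has no single `lambda_max`; two crisp reductions are in
#' common use and both are reported: `CRm`, the consistency ratio of the
#' matrix of modal values `m_ij`, and `CRg`, that of the matrix of geometric
#' means of the bounds `sqrt(l_ij * u_ij)`.
#'
#' @param x A reciprocal-valid [fcm()].
#' @inheritParams consistency_ratio
#' @return A list with components `modal` and `bounds_geomean`, each a
#'   `"consistency_report"`.
#' @export
fuzzy_cr_variants <- function(x, ri_table = saaty_ri()) {
  stopifnot(inherits(x, "fcm"))
  list(modal = consistency_ratio(x$m, ri_table, variant = "modal"),
       bounds_geomean = consistency_ratio(sqrt(x$l * x$u), ri_table,
                                          variant = "bounds_geomean"))
}
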