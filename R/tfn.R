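#' Triangular fuzzy number
#'
#' Constructs a triangular fuzzy number (TFN), the basic carrier of judgment
#' uncertainty in fuzzy pairwise comparison. A TFN `(l, m, u)` has membership
#' rising linearly from the smallest plausible value `l` to the most plausible
#' (modal) value `m` and falling back to the largest plausible value `u`. All
#' judgments handled here are positive ratios, so `0 < l <= m <= u` is
#' enforced. A TFN with `l == m == u` is a valid crisp (degenerate) number.
#'
#' @param l Lower bound (smallest plausible ratio), a positive scalar.
#' @param m Modal value; defaults to `l`.
#' @param u Upper bound; defaults to `m`. So `tfn(3)` is the crisp number 3.
#'
#' @return An object of class `"tfn"`: a named numeric triple `(l, m, u)`.
#' @examples
#' tfn(2, 3, 4)
#' tfn(1)          # crisp 1
#' tfn_invert(tfn(2, 3, 4))
#' @seealso [tfn_invert()], [tfn_multiply()], [tfn_geomean()], [defuzzify()]
#' @export
tfn <- function(l, m = l, u = m) {
  x <- c(l = as.numeric(l)[1L], m = as.numeric(m)[1L], u = as.numeric(u)[1L])
  if (anyNA(x) || any(!is.finite(x)))
    stop("tfn components must be finite numbers", call. = FALSE)
  if (x[["l"]] <= 0)
    stop("tfn components must be positive (judgments are positive ratios)",
         call. = FALSE)
  if (x[["l"]] > x[["m"]] || x[["m"]] > x[["u"]])
    stop("tfn requires l <= m <= u; got (", paste(signif(x, 6), collapse = ", "),
         ")", call. = FALSE)
  structure(x, class = "tfn")
}

#' @rdname tfn
#' @param x Object to coerce or test: a numeric triple `(l, m, u)` or a
#'   length-one numeric (crisp value).
#' @export
as_tfn <- function(x) {
  if (inherits(x, "tfn")) return(x)
  x <- as.numeric(x)
  if (length(x) == 1L) return(tfn(x))
  if (length(x) == 3L) return(tfn(x[1L], x[2L], x[3L]))
  stop("cannot coerce length-", length(x), " vector to tfn", call. = FALSE)
}

#' @rdname tfn
#' @export
is_tfn <- function(x) inherits(x, "tfn")

#' @export
print.tfn <- function(x, digits = 4, ...) {
  cat("<tfn> (", paste(signif(unclass(x), digits), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' @export
format.tfn <- function(x, digits = 4, ...) {
  paste0("(", paste(signif(unclass(x), digits), collapse = ", "), ")")
}

#' Reciprocal of a triangular fuzzy number
#'
#' The fuzzy reciprocal `1/(l, m, u) = (1/u, 1/m, 1/l)`; bounds swap so the
#' result is again ordered. This is the operation that fills the lower
#' triangle of a reciprocal comparison matrix from the upper one.
#'
#' @param a A [tfn()] (or coercible).
#' @return A `tfn`. Inverting twice recovers `a` up to floating error.
#' @examples
#' tfn_invert(tfn(1.815, 2.228, 2.634))  # ~ (0.380, 0.449, 0.551)
#' @export
tfn_invert <- function(a) {
  a <- as_tfn(a)
  tfn(1 / a[["u"]], 1 / a[["m"]], 1 / a[["l"]])
}

#' Componentwise product of triangular fuzzy numbers
#'
#' Standard TFN multiplication `(a.l b.l, a.m b.m, a.u b.u)` (the usual
#' first-order approximation for positive TFNs), as needed by the fuzzy
#' geometric mean.
#'
#' @param a,b [tfn()] objects (or coercible).
#' @return A `tfn`.
#' @export
tfn_multiply <- function(a, b) {
  a <- as_tfn(a); b <- as_tfn(b)
  tfn(a[["l"]] * b[["l"]], a[["m"]] * b[["m"]], a[["u"]] * b[["u"]])
}

#' Componentwise geometric mean of triangular fuzzy numbers
#'
#' The n-th root of the componentwise product, i.e. the fuzzy geometric mean
#' used both for aggregating a panel of expert judgments cell by cell and for
#' the row means of Buckley's weight derivation.
#'
#' @param items A non-empty list of [tfn()] objects (or coercibles).
#' @return A `tfn`.
#' @examples
#' tfn_geomean(list(tfn(2), tfn(8)))  # crisp (4, 4, 4)
#' @export
tfn_geomean <- function(items) {
  if (!is.list(items) || length(items) == 0L)
    stop("tfn_geomean requires a non-empty list of tfn", call. = FALSE)
  comps <- vapply(items, function(x) unclass(as_tfn(x)), numeric(3))
  g <- exp(rowMeans(log(comps)))
  tfn(g[[1L]], g[[2L]], g[[3L]])
}

#' Defuzzify a triangular fuzzy number
#'
#' Converts a TFN to a single crisp value. The default is the Liou-Wang total
#' integral value with optimism level `alpha`:
#' `alpha * (m + u) / 2 + (1 - alpha) * (l + m) / 2`, which at `alpha = 0.5`
#' reduces to the familiar `(l + 2m + u) / 4`. The centroid `(l + m + u) / 3`
#' is also available. Either way the result lies inside `[l, u]` and is
#' monotone under componentwise dominance.
#'
#' @param a A [tfn()] (or coercible).
#' @param method `"total_integral"` (Liou-Wang, default) or `"centroid"`.
#' @param alpha Optimism level in `[0, 1]`, used by `total_integral` only:
#'   0 is fully pessimistic (left integral), 1 fully optimistic (right).
#' @return A numeric scalar in `[a$l, a$u]`.
#' @examples
#' defuzzify(tfn(0.346, 0.425, 0.517))            # (l + 2m + u)/4
#' defuzzify(tfn(1, 2, 3), method = "centroid")   # 2
#' @export
defuzzify <- function(a, method = c("total_integral", "centroid"),
                      alpha = 0.5) {
  a <- as_tfn(a)
  method <- match.arg(method)
  if (method == "total_integral") {
    if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
        alpha < 0 || alpha > 1)
      stop("alpha must be a single number in [0, 1]", call. = FALSE)
    alpha * (a[["m"]] + a[["u"]]) / 2 + (1 - alpha) * (a[["l"]] + a[["m"]]) / 2
  } else {
    (a[["l"]] + a[["m"]] + a[["u"]]) / 3
  }
}
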