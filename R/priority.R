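#' Buckley fuzzy geometric-mean weights
#'
#' Derives fuzzy local priorities from a fuzzy comparison matrix by Buckley's
#' geometric-mean method: the fuzzy row mean `r_i` is the componentwise
#' geometric mean of row `i`, and the fuzzy weight is
#' `w_i = r_i (*) (sum_k r_k)^(-1)`, where the fuzzy sum is componentwise and
#' the fuzzy reciprocal reverses bounds. This is the derivation that, after
#' total-integral defuzzification at `alpha = 0.5`, reproduces the published
#' paradigm weights of the bundled worked example to three decimals.
#'
#' @param x A reciprocal-valid [fcm()].
#' @return An object of class `"fuzzy_weights"`: list with `labels`, `r`
#'   (n x 3 matrix of row geometric means, columns `l, m, u`), and `w`
#'   (n x 3 matrix of fuzzy weights).
#' @seealso [defuzzify_weights()], [chang_extent_weights()]
#' @export
buckley_fuzzy_weights <- function(x) {
  stopifnot(inherits(x, "fcm"))
  geo <- function(g) exp(rowMeans(log(g)))
  r <- cbind(l = geo(x$l), m = geo(x$m), u = geo(x$u))
  s <- colSums(r)                       # componentwise fuzzy sum of the r_i
  w <- cbind(l = r[, "l"] / s[["u"]],   # divide by reversed bounds
             m = r[, "m"] / s[["m"]],
             u = r[, "u"] / s[["l"]])
  rownames(r) <- rownames(w) <- x$labels
  structure(list(labels = x$labels, r = r, w = w), class = "fuzzy_weights")
}

#' @export
print.fuzzy_weights <- function(x, digits = 4, ...) {
  cat("<fuzzy_weights> Buckley fuzzy geometric-mean weights\n")
  print(signif(x$w, digits))
  invisible(x)
}

#' Defuzzify a fuzzy weight vector into crisp priorities
#'
#' Maps each fuzzy weight to a crisp ("certain") value by [defuzzify()] and
#' normalises to obtain the final priority vector; ranks are assigned by
#' descending normalised weight with ties broken stably by input order.
#'
#' @param fw A `"fuzzy_weights"` object from [buckley_fuzzy_weights()].
#' @param alpha Optimism level of the total-integral defuzzifier
#'   (default 0.5, i.e. `(l + 2m + u)/4`).
#' @param method Defuzzification method, see [defuzzify()].
#' @return An object of class `"priority_vector"`: list with `labels`,
#'   `certain` (defuzzified, unnormalised), `normal` (summing to 1), `ranks`,
#'   `method`, and `alpha`.
#' @export
defuzzify_weights <- function(fw, alpha = 0.5,
                              method = c("total_integral", "centroid")) {
  stopifnot(inherits(fw, "fuzzy_weights"))
  method <- match.arg(method)
  certain <- apply(fw$w, 1L, function(row)
    defuzzify(tfn(row[[1L]], row[[2L]], row[[3L]]), method = method,
              alpha = alpha))
  new_priority_vector(fw$labels, certain, method = "buckley", alpha = alpha)
}

new_priority_vector <- function(labels, certain, method, alpha = NA_real_) {
  normal <- certain / sum(certain)
  ranks <- rank_stable(normal)
  structure(list(labels = labels,
                 certain = stats::setNames(certain, labels),
                 normal = stats::setNames(normal, labels),
                 ranks = stats::setNames(ranks, labels),
                 method = method, alpha = alpha),
            class = "priority_vector")
}

# descending ranks, ties broken by input order (rank 1 = highest weight)
rank_stable <- function(w) {
  as.integer(rank(-w, ties.method = "first"))
}

#' @export
print.priority_vector <- function(x, digits = 3, ...) {
  cat("<priority_vector> method:", x$method,
      if (!is.na(x$alpha)) paste0("(alpha = ", x$alpha, ")"), "\n")
  df <- as.data.frame(x)
  df$certain <- round(df$certain, digits)
  df$normal <- round(df$normal, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.priority_vector <- function(x, ...) {
  data.frame(label = x$labels, certain = unname(x$certain),
             normal = unname(x$normal), rank = unname(x$ranks))
}

#' Chang extent-analysis weights
#'
#' Derives crisp priorities from a fuzzy comparison matrix by Chang's extent
#' analysis. The fuzzy synthetic extent of row `i` is
#' `S_i = (sum_j a_ij) (*) (sum_ij a_ij)^(-1)`; the degree of possibility
#' `V(S_i >= S_j)` is 1 when `m_i >= m_j`, 0 when `l_j >= u_i`, and
#' `(l_j - u_i) / ((m_i - u_i) - (m_j - l_j))` otherwise; the weight of
#' element `i` is `min_j V(S_i >= S_j)` normalised over elements.
#'
#' Extent analysis can legitimately assign exact zero weight to an element
#' whose extent lies entirely below another's — on the bundled worked
#' example it zeroes the efficiency paradigm — so it is offered as an
#' alternative derivation, not the default.
#'
#' @param x A reciprocal-valid [fcm()].
#' @return A `"priority_vector"`; `certain` holds the unnormalised minimum
#'   possibility degrees `d_i`.
#' @export
chang_extent_weights <- function(x) {
  stopifnot(inherits(x, "fcm"))
  S <- cbind(l = rowSums(x$l) / sum(x$u),   # total sum inverted: bounds swap
             m = rowSums(x$m) / sum(x$m),
             u = rowSums(x$u) / sum(x$l))
  n <- nrow(S)
  poss <- function(i, j) {
    if (S[i, "m"] >= S[j, "m"]) return(1)
    if (S[j, "l"] >= S[i, "u"]) return(0)
    (S[j, "l"] - S[i, "u"]) /
      ((S[i, "m"] - S[i, "u"]) - (S[j, "m"] - S[j, "l"]))
  }
  d <- vapply(seq_len(n), function(i)
    min(vapply(setdiff(seq_len(n), i), function(j) poss(i, j), numeric(1))),
    numeric(1))
  if (all(d <= 0))
    stop("extent analysis is degenerate: every minimum possibility degree ",
         "is zero, weights cannot be normalised", call. = FALSE)
  pv <- new_priority_vector(x$labels, d, method = "extent")
  pv$extents <- S
  pv
}

#' Principal eigenvector of a crisp comparison matrix
#'
#' Power iteration on a positive matrix: the normalised iterate converges to
#' the principal (Perron) eigenvector, whose components are the local
#' priorities; `lambda_max` is estimated as the mean of the componentwise
#' Rayleigh ratios `(A w)_i / w_i`.
#'
#' @param a Positive square numeric matrix.
#' @param tol Convergence tolerance on successive normalised iterates
#'   (default `1e-10`).
#' @param max_iter Iteration cap (default 10000).
#' @return List with `weights` (summing to 1), `lambda_max`, and
#'   `iterations`.
#' @export
principal_eigenvector <- function(a, tol = 1e-10, max_iter = 10000L) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a) || any(!is.finite(a)) || any(a <= 0))
    stop("a must be a positive square matrix", call. = FALSE)
  n <- nrow(a)
  if (n == 1L)
    return(list(weights = stats::setNames(1, rownames(a)), lambda_max = a[1, 1],
                iterations = 0L))
  w <- rep(1 / n, n)
  resid <- numeric(0)
  for (it in seq_len(max_iter)) {
    w2 <- as.vector(a %*% w)
    w2 <- w2 / sum(w2)
    r <- max(abs(w2 - w))
    resid <- c(resid, r)
    w <- w2
    if (r < tol) {
      lambda <- mean(as.vector(a %*% w) / w)
      names(w) <- rownames(a)
      return(list(weights = w, lambda_max = lambda, iterations = it))
    }
  }
  stop("power iteration did not converge within ", max_iter,
       " iterations (last residuals: ",
       paste(signif(utils::tail(resid, 5), 3), collapse = ", "), ")",
       call. = FALSE)
}
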