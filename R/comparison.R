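#' Fuzzy pairwise comparison matrix
#'
#' A square reciprocal matrix of triangular fuzzy numbers expressing, cell by
#' cell, how strongly element `i` dominates element `j` with regard to some
#' control criterion ("context"). Internally the matrix is stored as three
#' aligned numeric grids (lower, modal, upper), which keeps all matrix-level
#' operations vectorised.
#'
#' @param l,m,u Square numeric matrices of identical dimension holding the
#'   lower, modal and upper components of each cell.
#' @param labels Element names (defaults to the row names of `m`, else
#'   `E1..En`).
#' @param context Optional name of the control criterion the comparisons are
#'   made with regard to.
#'
#' @return An object of class `"fcm"`: a list with components `l`, `m`, `u`
#'   (labelled matrices), `labels`, and `context`.
#' @seealso [validate_reciprocal()], [aggregate_panel()],
#'   [buckley_fuzzy_weights()], [chang_extent_weights()]
#' @export
fcm <- function(l, m, u, labels = NULL, context = NULL) {
  for (nm in c("l", "m", "u")) {
    g <- get(nm)
    if (!is.matrix(g) || !is.numeric(g) || nrow(g) != ncol(g))
      stop("component '", nm, "' must be a square numeric matrix",
           call. = FALSE)
  }
  n <- nrow(m)
  if (nrow(l) != n || nrow(u) != n)
    stop("l, m, u must have identical dimensions", call. = FALSE)
  if (n < 2L)
    stop("a comparison matrix needs at least 2 elements", call. = FALSE)
  if (any(!is.finite(l)) || any(!is.finite(m)) || any(!is.finite(u)))
    stop("matrix entries must be finite", call. = FALSE)
  if (any(l <= 0))
    stop("matrix entries must be positive", call. = FALSE)
  if (any(l > m + 1e-12) || any(m > u + 1e-12))
    stop("each cell must satisfy l <= m <= u", call. = FALSE)
  if (is.null(labels)) labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("E", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels))
    stop("labels must be ", n, " unique element names", call. = FALSE)
  dn <- list(labels, labels)
  dimnames(l) <- dimnames(m) <- dimnames(u) <- dn
  structure(list(l = l, m = m, u = u, labels = labels, context = context),
            class = "fcm")
}

#' @rdname fcm
#' @param x A crisp (ordinary numeric) positive square matrix to lift to a
#'   degenerate fuzzy comparison matrix with `l = m = u`.
#' @export
as_fcm <- function(x, labels = NULL, context = NULL) {
  if (inherits(x, "fcm")) return(x)
  x <- as.matrix(x)
  fcm(x, x, x, labels = labels, context = context)
}

#' @rdname fcm
#' @param i,j Row and column indices (integer or label).
#' @export
tfn_at <- function(x, i, j) {
  stopifnot(inherits(x, "fcm"))
  tfn(x$l[i, j], x$m[i, j], x$u[i, j])
}

#' @export
print.fcm <- function(x, digits = 3, ...) {
  n <- length(x$labels)
  cat("<fcm> ", n, "x", n, " fuzzy comparison matrix",
      if (!is.null(x$context)) paste0(" [wrt ", x$context, "]"), "\n",
      sep = "")
  cells <- matrix("", n, n, dimnames = list(x$labels, x$labels))
  for (i in seq_len(n)) for (j in seq_len(n))
    cells[i, j] <- paste0("(", signif(x$l[i, j], digits), ",",
                          signif(x$m[i, j], digits), ",",
                          signif(x$u[i, j], digits), ")")
  print(cells, quote = FALSE)
  invisible(x)
}

#' @export
dim.fcm <- function(x) dim(x$m)

#' Check the reciprocal structure of a fuzzy comparison matrix
#'
#' A valid comparison matrix has a crisp unit diagonal and lower-triangle
#' cells equal to the fuzzy reciprocals of their mirrored upper-triangle
#' cells. Structural violations (non-unit diagonal) are errors; reciprocity
#' is measured and reported against `tol`, since matrices transcribed at
#' finite precision are reciprocal only approximately.
#'
#' @param x An [fcm()].
#' @param tol Absolute tolerance on the componentwise deviation
#'   `|a_ji - 1/a_ij|` (default `1e-6`, suitable for machine-built matrices;
#'   use ~`5e-3` for matrices transcribed at 3 decimals).
#' @return An object of class `"reciprocity_report"`: list with `ok`,
#'   `max_deviation`, `worst` (the offending `(i, j)` pair), `tol`, and a
#'   data frame `failures` of all cells exceeding `tol`.
#' @export
validate_reciprocal <- function(x, tol = 1e-6) {
  stopifnot(inherits(x, "fcm"))
  n <- length(x$labels)
  dg <- cbind(diag(x$l), diag(x$m), diag(x$u))
  if (max(abs(dg - 1)) > 1e-9) {
    bad <- which(rowSums(abs(dg - 1) > 1e-9) > 0)
    stop("diagonal must be crisp (1,1,1); offending element(s): ",
         paste(x$labels[bad], collapse = ", "), call. = FALSE)
  }
  max_dev <- 0
  worst <- c(NA_integer_, NA_integer_)
  fail <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    inv <- tfn_invert(tfn_at(x, i, j))
    dev <- max(abs(unclass(tfn_at(x, j, i)) - unclass(inv)))
    if (dev > max_dev) { max_dev <- dev; worst <- c(j, i) }
    if (dev > tol)
      fail[[length(fail) + 1L]] <- data.frame(
        row = x$labels[j], col = x$labels[i], deviation = dev)
  }
  failures <- if (length(fail)) do.call(rbind, fail) else
    data.frame(row = character(), col = character(), deviation = numeric())
  structure(list(ok = nrow(failures) == 0L, max_deviation = max_dev,
                 worst = worst, tol = tol, failures = failures),
            class = "reciprocity_report")
}

#' @export
print.reciprocity_report <- function(x, ...) {
  cat("<reciprocity_report> ", if (x$ok) "PASS" else "FAIL",
      " (max componentwise deviation ", signif(x$max_deviation, 4),
      ", tol ", x$tol, ")\n", sep = "")
  if (!x$ok) print(x$failures)
  invisible(x)
}

#' Aggregate a panel of expert comparison matrices
#'
#' Combines the matrices of several experts answering the same comparison
#' question into one group matrix by the cell-wise componentwise geometric
#' mean. The geometric mean is the standard group-AHP aggregation rule
#' because it is the one that preserves reciprocity exactly: the aggregate of
#' reciprocal matrices is reciprocal.
#'
#' @param matrices A non-empty list of [fcm()] objects with identical labels.
#' @return An [fcm()] with the same labels and context.
#' @examples
#' a <- as_fcm(matrix(c(1, 1/3, 3, 1), 2, 2, byrow = TRUE))
#' b <- as_fcm(matrix(c(1, 1/2, 2, 1), 2, 2, byrow = TRUE))
#' aggregate_panel(list(a, b))
#' @export
aggregate_panel <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L)
    stop("aggregate_panel requires a non-empty list of fcm", call. = FALSE)
  if (inherits(matrices, "expert_panel")) matrices <- matrices$matrices
  if (!all(vapply(matrices, inherits, logical(1), "fcm")))
    stop("all panel members must be fcm objects", call. = FALSE)
  ref <- matrices[[1L]]
  for (k in seq_along(matrices)) {
    if (!identical(matrices[[k]]$labels, ref$labels))
      stop("panel member ", k, " has mismatched labels", call. = FALSE)
  }
  gm <- function(comp) {
    logs <- lapply(matrices, function(m) log(m[[comp]]))
    exp(Reduce(`+`, logs) / length(logs))
  }
  fcm(gm("l"), gm("m"), gm("u"), labels = ref$labels, context = ref$context)
}
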