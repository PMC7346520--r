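#' Assemble the unweighted supermatrix
#'
#' Places each local priority vector into the block of the supermatrix it
#' governs: the column of node `s`, restricted to the rows of cluster `C`,
#' receives the priority vector of `C`'s elements with regard to `s`, for
#' every dependency edge `s -> C`; all other blocks are zero. Node order is
#' clusters in declaration order, elements in declaration order within each
#' cluster, goal (if any) last. Columns of the unweighted supermatrix may
#' sum to more than one when a node influences several clusters.
#'
#' @param network An [anp_network()].
#' @param local_priorities Named list keyed `"source -> target"` (see the
#'   network's `edges`; [edge_key()] builds the key) whose values are
#'   `"priority_vector"` objects — or bare named numeric vectors summing
#'   to 1 — over the target cluster's elements.
#' @return An object of class `"supermatrix"`: list with `mat` (labelled
#'   numeric matrix), `nodes`, `network`, and `stage = "unweighted"`.
#' @seealso [weight_supermatrix()], [limit_supermatrix()],
#'   [synthesize_priorities()]
#' @export
assemble_supermatrix <- function(network, local_priorities) {
  stopifnot(inherits(network, "anp_network"))
  nodes <- network_nodes(network)
  mat <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  edges <- network$edges
  for (k in seq_len(nrow(edges))) {
    key <- edge_key(edges$source[k], edges$target[k])
    pv <- local_priorities[[key]]
    if (is.null(pv))
      stop("no local priority vector supplied for dependency '", key, "'",
           call. = FALSE)
    v <- if (inherits(pv, "priority_vector")) pv$normal else pv
    members <- network$clusters[[edges$target[k]]]
    if (is.null(names(v)) || !setequal(names(v), members))
      stop("priority vector for '", key, "' must be named over the elements ",
           "of cluster '", edges$target[k], "'", call. = FALSE)
    mat[members, edges$source[k]] <- v[members]
  }
  structure(list(mat = mat, nodes = nodes, network = network,
                 stage = "unweighted"), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, digits = 3, ...) {
  cat("<supermatrix> stage:", x$stage, "(", nrow(x$mat), "x", ncol(x$mat),
      ")\n")
  print(round(x$mat, digits))
  invisible(x)
}

# cluster of each node; the goal counts as its own (pseudo-)cluster
node_clusters <- function(network) {
  cl <- network$element_cluster
  if (!is.null(network$goal))
    cl <- c(cl, stats::setNames(network$goal, network$goal))
  cl
}

#' Weight the supermatrix into a column-stochastic matrix
#'
#' Scales every block of each column by the weight of its row cluster with
#' regard to the column node's cluster and renormalises, so that every
#' nonzero column sums to one (the stochastic form required before taking
#' limits). Without a cluster matrix, the clusters contributing to a column
#' receive equal weight — equivalent to plain column normalisation.
#'
#' @param sm An unweighted `"supermatrix"`.
#' @param cluster_matrix Optional numeric matrix of cluster-level weights:
#'   rows are influenced clusters, columns are controlling contexts
#'   (cluster names and/or the goal); each used column should sum to 1 over
#'   the clusters it weights. Missing contexts fall back to equal weights.
#' @return A `"supermatrix"` with `stage = "weighted"`.
#' @export
weight_supermatrix <- function(sm, cluster_matrix = NULL) {
  stopifnot(inherits(sm, "supermatrix"))
  if (sm$stage != "unweighted")
    stop("expected an unweighted supermatrix", call. = FALSE)
  network <- sm$network
  ncl <- node_clusters(network)
  mat <- sm$mat
  for (node in sm$nodes) {
    col <- mat[, node]
    if (all(col == 0)) next
    row_cl <- ncl[sm$nodes]
    contributing <- unique(row_cl[col != 0])
    ctx <- ncl[[node]]
    wts <- rep(1, length(contributing))
    names(wts) <- contributing
    if (!is.null(cluster_matrix) && ctx %in% colnames(cluster_matrix)) {
      avail <- intersect(contributing, rownames(cluster_matrix))
      if (length(avail) < length(contributing))
        stop("cluster matrix lacks rows for cluster(s) ",
             paste(setdiff(contributing, avail), collapse = ", "),
             " influencing column '", node, "'", call. = FALSE)
      wts <- cluster_matrix[contributing, ctx]
      names(wts) <- contributing
    }
    if (sum(wts) <= 0)
      stop("all cluster weights are zero for nonzero column '", node, "'",
           call. = FALSE)
    scaled <- col * as.numeric(wts[row_cl])
    scaled[is.na(scaled)] <- 0
    total <- sum(scaled)
    if (total <= 0)
      stop("column '", node, "' lost all mass under cluster weighting",
           call. = FALSE)
    mat[, node] <- scaled / total
  }
  sm$mat <- mat
  sm$stage <- "weighted"
  sm
}

# check that every column is (sub)stochastic: sums ~0 or ~1
assert_column_stochastic <- function(mat, tol = 1e-8, what = "supermatrix") {
  cs <- colSums(mat)
  bad <- which(abs(cs) > tol & abs(cs - 1) > tol)
  if (length(bad))
    stop(what, " is not column-stochastic: column(s) ",
         paste(colnames(mat)[bad], collapse = ", "), " sum to ",
         paste(signif(cs[bad], 6), collapse = ", "), call. = FALSE)
  invisible(cs)
}

#' Limit supermatrix
#'
#' Raises the weighted (column-stochastic) supermatrix to high powers until
#' the long-run influence stabilises, the Markov-chain reading of network
#' feedback. Powers are taken by repeated squaring; after the squaring orbit
#' settles, a short orbit search distinguishes three outcomes: a fixed point
#' (primitive case, all columns converged), a cycle of period `p` (the limit
#' is then the Cesaro average of one period), or total extinction of mass
#' (strict hierarchies, whose powers are nilpotent) — in that last case the
#' cumulative influence `A + A^2 + ...` is column-normalised instead, which
#' reproduces the classical top-down weight products.
#'
#' Column stochasticity is re-checked at every squaring step rather than
#' assumed.
#'
#' @param sm A weighted `"supermatrix"`.
#' @param tol Convergence tolerance on the max absolute entry change
#'   (default `1e-9`).
#' @param max_squarings Cap on squaring steps (default 64; `2^64`-th power).
#' @param sink_policy How to treat zero columns (elements that influence
#'   nothing): `"zero"` leaves them (default), `"uniform"` replaces them by
#'   the uniform distribution over all elements before iterating.
#' @return A `"supermatrix"` with `stage = "limit"`. Attribute `"limit_info"`
#'   records the number of squarings, the detected period (1 = primitive),
#'   and whether the nilpotent fallback was used.
#' @export
limit_supermatrix <- function(sm, tol = 1e-9, max_squarings = 64L,
                              sink_policy = c("zero", "uniform")) {
  stopifnot(inherits(sm, "supermatrix"))
  if (sm$stage != "weighted")
    stop("expected a weighted supermatrix", call. = FALSE)
  sink_policy <- match.arg(sink_policy)
  a <- sm$mat
  n <- nrow(a)
  if (sink_policy == "uniform") {
    zero_cols <- which(colSums(a) == 0)
    if (length(zero_cols)) {
      el <- sm$network$elements
      for (j in zero_cols) a[el, j] <- 1 / length(el)
    }
  }
  assert_column_stochastic(a, what = "weighted supermatrix")

  s <- a
  residuals <- numeric(0)
  squarings <- 0L
  for (k in seq_len(max_squarings)) {
    s2 <- s %*% s
    squarings <- k
    r <- max(abs(s2 - s))
    residuals <- c(residuals, r)
    s <- s2
    assert_column_stochastic(s, tol = 1e-6,
                             what = paste0("supermatrix power (squaring ", k,
                                           ")"))
    if (r < tol) break
  }

  info <- list(squarings = squarings, period = NA_integer_,
               nilpotent_fallback = FALSE, residuals = residuals)

  if (max(abs(s)) < tol) {
    # powers vanish: acyclic (hierarchy) structure; accumulate influence
    b <- a
    p <- a
    for (k in seq_len(n + 1L)) {
      p <- p %*% a
      if (max(abs(p)) < tol) break
      b <- b + p
    }
    cs <- colSums(b)
    nz <- cs > tol
    b[, nz] <- sweep(b[, nz, drop = FALSE], 2L, cs[nz], `/`)
    info$nilpotent_fallback <- TRUE
    sm$mat <- b
  } else {
    # orbit search from the settled squaring iterate: fixed point or cycle
    max_period <- max(2L * n, 16L)
    orbit <- list(s)
    p_found <- NA_integer_
    cur <- s
    for (p in seq_len(max_period)) {
      cur <- cur %*% a
      if (max(abs(cur - s)) < sqrt(tol)) { p_found <- p; break }
      orbit[[p + 1L]] <- cur
    }
    if (is.na(p_found))
      stop("limit supermatrix did not converge: no fixed point or cycle of ",
           "period <= ", max_period, " detected after ", squarings,
           " squarings (last residuals: ",
           paste(signif(utils::tail(residuals, 5), 3), collapse = ", "), ")",
           call. = FALSE)
    lim <- Reduce(`+`, orbit[seq_len(p_found)]) / p_found
    info$period <- p_found
    sm$mat <- lim
  }
  sm$stage <- "limit"
  attr(sm, "limit_info") <- info
  sm
}

#' Synthesise final priorities from the limit supermatrix
#'
#' Reads the stationary column of the limit supermatrix, restricts it to
#' element rows, and renormalises into overall element priorities; cluster
#' priorities are the sums of their members' overall priorities and
#' within-cluster weights the ratios. When the network has a goal node its
#' column is used (for hierarchies it is the only informative one);
#' otherwise the nonzero limit columns are checked for agreement and
#' averaged.
#'
#' @param limit A `"supermatrix"` with `stage = "limit"`.
#' @param network The [anp_network()] (defaults to the one stored in the
#'   supermatrix).
#' @param tol Tolerance for the column-agreement check (default `1e-6`).
#' @return An object of class `"anp_synthesis"`: list with `elements` (data
#'   frame: element, cluster, overall, within_cluster, rank) and `clusters`
#'   (data frame: cluster, priority, rank).
#' @export
synthesize_priorities <- function(limit, network = limit$network,
                                  tol = 1e-6) {
  stopifnot(inherits(limit, "supermatrix"))
  if (limit$stage != "limit")
    stop("expected a limit-stage supermatrix", call. = FALSE)
  el <- network$elements
  mat <- limit$mat
  goal <- network$goal
  if (!is.null(goal) && sum(mat[el, goal]) > tol) {
    v <- mat[el, goal]
  } else {
    cs <- colSums(mat[el, , drop = FALSE])
    nz <- which(cs > tol)
    if (!length(nz))
      stop("limit supermatrix carries no mass on element rows; ",
           "nothing to synthesise", call. = FALSE)
    cols <- sweep(mat[el, nz, drop = FALSE], 2L, cs[nz], `/`)
    spread <- max(apply(cols, 1L, function(r) diff(range(r))))
    if (spread > tol)
      stop("limit columns disagree (max spread ", signif(spread, 3),
           " > tol ", tol, "); the network may not have a unique limit",
           call. = FALSE)
    v <- rowMeans(cols)
  }
  overall <- v / sum(v)
  cl_of <- network$element_cluster[el]
  cl_pr <- tapply(overall, cl_of, sum)[names(network$clusters)]
  within <- overall / as.numeric(cl_pr[cl_of])
  elements <- data.frame(element = el, cluster = unname(cl_of),
                         overall = unname(overall),
                         within_cluster = unname(within),
                         rank = rank_stable(overall))
  clusters <- data.frame(cluster = names(network$clusters),
                         priority = as.numeric(cl_pr),
                         rank = rank_stable(as.numeric(cl_pr)))
  structure(list(elements = elements, clusters = clusters),
            class = "anp_synthesis")
}

#' @export
print.anp_synthesis <- function(x, digits = 3, ...) {
  cat("<anp_synthesis>\nClusters:\n")
  cl <- x$clusters; cl$priority <- round(cl$priority, digits)
  print(cl, row.names = FALSE)
  cat("Elements:\n")
  el <- x$elements
  el$overall <- round(el$overall, digits)
  el$within_cluster <- round(el$within_cluster, digits)
  print(el, row.names = FALSE)
  invisible(x)
}
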