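#' ANP decision network
#'
#' Defines the structure of an Analytic Network Process model: named clusters
#' of elements, directed dependency edges, and an optional goal node. A
#' dependency `source -> target` declares that the elements of cluster
#' `target` are pairwise-compared with regard to `source`; `source` may be an
#' element, the goal, or a cluster name (shorthand for "every element of that
#' cluster"). An edge is *inner* when the source lies in the target cluster
#' and *outer* otherwise.
#'
#' @param clusters Named list of character vectors; names are cluster names,
#'   values the ordered element names of each cluster. Element names must be
#'   globally unique and distinct from cluster and goal names.
#' @param dependencies Data frame with columns `source` and `target` (target
#'   is always a cluster name); an optional `kind` column (`"inner"` /
#'   `"outer"`) is checked against the inferred kind if present.
#' @param goal Optional goal node name.
#' @return An object of class `"anp_network"`: list with `clusters`, `goal`,
#'   `elements` (ordered), `element_cluster` (lookup), and `edges` (the
#'   dependency list expanded to element-level sources, with inferred
#'   `kind`).
#' @examples
#' net <- anp_network(
#'   clusters = list(A = c("a1", "a2"), B = c("b1")),
#'   dependencies = data.frame(source = c("goal", "goal", "A"),
#'                             target = c("A", "B", "B")),
#'   goal = "goal")
#' net
#' @export
anp_network <- function(clusters, dependencies = NULL, goal = NULL) {
  if (!is.list(clusters) || is.null(names(clusters)) ||
      any(names(clusters) == ""))
    stop("clusters must be a named list of element-name vectors",
         call. = FALSE)
  cl_names <- names(clusters)
  if (anyDuplicated(cl_names))
    stop("cluster names must be unique", call. = FALSE)
  clusters <- lapply(clusters, as.character)
  if (any(lengths(clusters) == 0L))
    stop("every cluster needs at least one element", call. = FALSE)
  elements <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(elements))
    stop("element names must be globally unique; duplicated: ",
         paste(unique(elements[duplicated(elements)]), collapse = ", "),
         call. = FALSE)
  if (length(intersect(elements, cl_names)))
    stop("element names must not collide with cluster names", call. = FALSE)
  if (!is.null(goal)) {
    goal <- as.character(goal)[1L]
    if (goal %in% c(elements, cl_names))
      stop("goal name must not collide with elements or clusters",
           call. = FALSE)
  }
  el_cluster <- stats::setNames(
    rep(cl_names, lengths(clusters)), elements)

  edges <- data.frame(source = character(), target = character(),
                      kind = character())
  if (!is.null(dependencies) && nrow(as.data.frame(dependencies)) > 0L) {
    dependencies <- as.data.frame(dependencies)
    if (!all(c("source", "target") %in% names(dependencies)))
      stop("dependencies must have columns 'source' and 'target'",
           call. = FALSE)
    rows <- list()
    for (k in seq_len(nrow(dependencies))) {
      src <- as.character(dependencies$source[k])
      tgt <- as.character(dependencies$target[k])
      if (!tgt %in% cl_names)
        stop("dependency target '", tgt, "' is not a cluster", call. = FALSE)
      srcs <- if (src %in% cl_names) clusters[[src]]
      else if (src %in% elements || identical(src, goal)) src
      else stop("dependency source '", src,
                "' is neither an element, a cluster, nor the goal",
                call. = FALSE)
      for (s in srcs) {
        kind <- if (!identical(s, goal) && el_cluster[[s]] == tgt) "inner"
        else "outer"
        if ("kind" %in% names(dependencies) &&
            !is.na(dependencies$kind[k]) &&
            nzchar(dependencies$kind[k]) &&
            dependencies$kind[k] != kind)
          stop("dependency ", src, " -> ", tgt, " declared '",
               dependencies$kind[k], "' but is '", kind, "'", call. = FALSE)
        rows[[length(rows) + 1L]] <-
          data.frame(source = s, target = tgt, kind = kind)
      }
    }
    edges <- unique(do.call(rbind, rows))
    rownames(edges) <- NULL
  }
  structure(list(clusters = clusters, goal = goal, elements = elements,
                 element_cluster = el_cluster, edges = edges),
            class = "anp_network")
}

#' @export
print.anp_network <- function(x, ...) {
  cat("<anp_network> ", length(x$clusters), " clusters, ",
      length(x$elements), " elements",
      if (!is.null(x$goal)) paste0(", goal '", x$goal, "'"), "\n", sep = "")
  for (cl in names(x$clusters))
    cat("  ", cl, ": ", paste(x$clusters[[cl]], collapse = ", "), "\n",
        sep = "")
  if (nrow(x$edges)) {
    cat("  dependencies (element-level):\n")
    for (k in seq_len(nrow(x$edges)))
      cat("    ", x$edges$source[k], " -> ", x$edges$target[k],
          " [", x$edges$kind[k], "]\n", sep = "")
  }
  invisible(x)
}

#' @rdname anp_network
#' @param x An `anp_network`.
#' @export
network_nodes <- function(x) {
  stopifnot(inherits(x, "anp_network"))
  c(x$elements, x$goal)
}

#' Key under which the local priority vector for a dependency edge is stored
#'
#' @param source Source node name (element or goal).
#' @param target Target cluster name.
#' @return The string `"source -> target"`.
#' @export
edge_key <- function(source, target) paste(source, "->", target)
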