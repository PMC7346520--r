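#' Read an ANP network definition from YAML or JSON
#'
#' The expected layout is
#' ```yaml
#' goal: allocation
#' clusters:
#'   - name: Efficiency
#'     elements: [total_population, non_resident_patients]
#' dependencies:
#'   - {source: allocation, target: Efficiency, kind: outer}
#' ```
#' JSON files with the same shape are accepted.
#'
#' @param path Path to the network file.
#' @return An [anp_network()].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$clusters))
    stop("network file ", path, " has no 'clusters' section", call. = FALSE)
  cl_list <- cfg$clusters
  if (is.data.frame(cl_list)) cl_list <- split(cl_list, seq_len(nrow(cl_list)))
  clusters <- list()
  for (cl in cl_list) {
    if (is.null(cl$name) || is.null(cl$elements))
      stop("each cluster needs 'name' and 'elements' (", path, ")",
           call. = FALSE)
    clusters[[as.character(cl$name)]] <- unlist(cl$elements)
  }
  deps <- NULL
  if (!is.null(cfg$dependencies)) {
    dl <- cfg$dependencies
    if (is.data.frame(dl)) {
      deps <- dl
    } else {
      deps <- do.call(rbind, lapply(dl, function(d)
        data.frame(source = d$source, target = d$target,
                   kind = if (is.null(d$kind)) NA_character_ else d$kind)))
    }
  }
  anp_network(clusters, dependencies = deps, goal = cfg$goal)
}

#' Read expert judgments from a long-format CSV
#'
#' The file must have columns `expert, question, row, col` plus either
#' `l, m, u` (triangular fuzzy judgments) or `score` (crisp 9-point scores,
#' fuzzified through `scale`). Only upper-triangle cells (and optionally the
#' redundant mirrors) need to be given; diagonals are fixed at `(1,1,1)` and
#' missing mirrors are completed by fuzzy inversion. Every unordered element
#' pair must be judged by every expert listed for a question: an absent pair
#' is a completeness error naming `(question, row, col)`.
#'
#' @param path CSV path.
#' @param labels Optional named list mapping question id to the ordered
#'   element labels of that question (e.g. the target cluster's elements);
#'   defaults to first-appearance order within the file.
#' @param scale A [fuzzy_scale()] used when a `score` column is present.
#' @return A named list (one entry per question) of lists of [fcm()]
#'   matrices, one per expert, i.e. the panel sets consumed by
#'   [aggregate_panel()] and [run_pipeline()].
#' @export
read_judgments <- function(path, labels = NULL, scale = fuzzy_scale()) {
  if (!file.exists(path))
    stop("judgments file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert", "question", "row", "col")
  if (!all(need %in% names(df)))
    stop("judgments CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  fuzzy_cols <- all(c("l", "m", "u") %in% names(df))
  if (!fuzzy_cols && !"score" %in% names(df))
    stop("judgments CSV needs either columns l,m,u or a score column",
         call. = FALSE)
  out <- list()
  for (q in unique(df$question)) {
    dq <- df[df$question == q, , drop = FALSE]
    labs <- if (!is.null(labels[[q]])) labels[[q]] else
      unique(c(dq$row, dq$col))
    n <- length(labs)
    panel <- list()
    for (ex in unique(dq$expert)) {
      de <- dq[dq$expert == ex, , drop = FALSE]
      L <- M <- U <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
      diag(L) <- diag(M) <- diag(U) <- 1
      for (k in seq_len(nrow(de))) {
        i <- de$row[k]; j <- de$col[k]
        if (!i %in% labs || !j %in% labs)
          stop("question '", q, "': unknown element label '",
               setdiff(c(i, j), labs)[1L], "'", call. = FALSE)
        tri <- if (fuzzy_cols) tfn(de$l[k], de$m[k], de$u[k])
        else scale_to_tfn(de$score[k], scale)
        L[i, j] <- tri[["l"]]; M[i, j] <- tri[["m"]]; U[i, j] <- tri[["u"]]
      }
      for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
        if (is.na(M[i, j]) && !is.na(M[j, i])) {
          inv <- tfn_invert(tfn(L[j, i], M[j, i], U[j, i]))
          L[i, j] <- inv[["l"]]; M[i, j] <- inv[["m"]]; U[i, j] <- inv[["u"]]
        }
      }
      miss <- which(is.na(M), arr.ind = TRUE)
      if (nrow(miss))
        stop("question '", q, "', expert '", ex, "': missing judgment for (",
             labs[miss[1L, 1L]], ", ", labs[miss[1L, 2L]], ")",
             call. = FALSE)
      panel[[as.character(ex)]] <- fcm(L, M, U, labels = labs,
                                       context = as.character(q))
    }
    out[[as.character(q)]] <- panel
  }
  out
}

#' Write an expert panel to the long-format judgments CSV
#'
#' @param panels Either an `"expert_panel"` (written under question id
#'   `question`) or a named list of panels keyed by question id, each a list
#'   of [fcm()] matrices.
#' @param path Output CSV path.
#' @param question Question id used when `panels` is a single panel.
#' @return The path, invisibly.
#' @export
write_judgments <- function(panels, path, question = "Q1") {
  if (inherits(panels, "expert_panel"))
    panels <- stats::setNames(list(panels$matrices), question)
  rows <- list()
  for (q in names(panels)) {
    mats <- panels[[q]]
    if (inherits(mats, "expert_panel")) mats <- mats$matrices
    for (e in seq_along(mats)) {
      m <- mats[[e]]
      n <- length(m$labels)
      for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
        rows[[length(rows) + 1L]] <- data.frame(
          expert = e, question = q, row = m$labels[i], col = m$labels[j],
          l = m$l[i, j], m = m$m[i, j], u = m$u[i, j])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

fanp_extdata <- function(file) {
  path <- system.file("extdata", file, package = "fanp")
  if (path == "")
    stop("bundled file ", file, " not found; is the package installed?",
         call. = FALSE)
  path
}

#' Bundled worked example: aggregate paradigm comparison
#'
#' The published aggregate fuzzy pairwise comparison of the three
#' drug-allocation paradigms (efficiency, equity & access, effectiveness)
#' with regard to the allocation goal, from the expert-panel study shipped
#' as the package's worked example. Entries are as printed at 3 decimals, so
#' reciprocity holds only to ~4e-3.
#'
#' @return An [fcm()] of dimension 3.
#' @seealso [reproduce_paradigm_weights()]
#' @export
allocation_example_matrix <- function() {
  df <- utils::read.csv(fanp_extdata("paradigm_aggregate.csv"),
                        stringsAsFactors = FALSE)
  labs <- unique(df$row)
  n <- length(labs)
  L <- M <- U <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  for (k in seq_len(nrow(df))) {
    L[df$row[k], df$col[k]] <- df$l[k]
    M[df$row[k], df$col[k]] <- df$m[k]
    U[df$row[k], df$col[k]] <- df$u[k]
  }
  fcm(L, M, U, labels = labs, context = "scarce drug allocation")
}

#' Bundled worked example: allocation network
#'
#' The three-paradigm, eight-indicator ANP network of the scarce-drug
#' allocation study. The dependency list is a plausible reconstruction (the
#' study names only the efficiency -> equity & access arrow explicitly and
#' shows goal-to-cluster and within-cluster influence diagrammatically).
#'
#' @return An [anp_network()].
#' @export
allocation_example_network <- function() {
  read_network(fanp_extdata("allocation_network.yaml"))
}

#' Bundled worked example: published final weights (reference only)
#'
#' The final within-cluster, overall, and cluster weights the study reports.
#' These depend on appendix supermatrices that were never published, so they
#' are shipped strictly as reference values for orientation — the package
#' does not recompute them.
#'
#' @return A data frame with columns `cluster`, `element`,
#'   `within_cluster_weight`, `overall_weight`, `cluster_weight`,
#'   `cluster_rank`.
#' @export
allocation_reference_weights <- function() {
  utils::read.csv(fanp_extdata("reference_weights.csv"),
                  stringsAsFactors = FALSE)
}
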