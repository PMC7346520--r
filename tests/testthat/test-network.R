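test_that("network construction validates structure and infers edge kinds", {
  net <- anp_network(
    clusters = list(A = c("a1", "a2"), B = "b1"),
    dependencies = data.frame(source = c("g", "A"), target = c("A", "B")),
    goal = "g")
  expect_identical(net$elements, c("a1", "a2", "b1"))
  expect_identical(network_nodes(net), c("a1", "a2", "b1", "g"))
  # cluster-level source expands to its elements
  expect_identical(net$edges$source, c("g", "a1", "a2"))
  expect_identical(net$edges$kind, c("outer", "outer", "outer"))
  inner <- anp_network(list(A = c("a1", "a2")),
                       data.frame(source = "A", target = "A"))
  expect_identical(unique(inner$edges$kind), "inner")
  expect_error(anp_network(list(A = "x", B = "x")), "unique")
  expect_error(anp_network(list(A = "A2", B = "A")), "collide")
  expect_error(anp_network(list(A = "a"),
                           data.frame(source = "a", target = "Z")),
               "not a cluster")
  expect_error(anp_network(list(A = c("a1", "a2")),
                           data.frame(source = "A", target = "A",
                                      kind = "outer")),
               "declared")
})

test_that("supermatrix assembly places blocks where dependencies point", {
  # pure hierarchy: single nonzero block under the goal column
  net <- anp_network(list(Criteria = c("c1", "c2", "c3")),
                     data.frame(source = "g", target = "Criteria"),
                     goal = "g")
  v <- c(c1 = 0.6, c2 = 0.3, c3 = 0.1)
  sm <- assemble_supermatrix(net, list("g -> Criteria" = v))
  expect_equal(unname(sm$mat[c("c1", "c2", "c3"), "g"]), c(0.6, 0.3, 0.1))
  expect_equal(sum(sm$mat) - sum(sm$mat[, "g"]), 0)
  # two singleton clusters with mutual dependence: a swap matrix
  net2 <- anp_network(list(A = "a", B = "b"),
                      data.frame(source = c("a", "b"), target = c("B", "A")))
  sm2 <- assemble_supermatrix(net2, list("a -> B" = c(b = 1),
                                         "b -> A" = c(a = 1)))
  expect_equal(unname(sm2$mat), matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(assemble_supermatrix(net2, list("a -> B" = c(b = 1))),
               "b -> A")
  expect_error(assemble_supermatrix(net2, list("a -> B" = c(wrong = 1),
                                               "b -> A" = c(a = 1))),
               "named over the elements")
})

test_that("the bundled network yields zero blocks exactly off its edges", {
  net <- allocation_example_network()
  lp <- list()
  for (k in seq_len(nrow(net$edges))) {
    members <- net$clusters[[net$edges$target[k]]]
    lp[[edge_key(net$edges$source[k], net$edges$target[k])]] <-
      stats::setNames(rep(1 / length(members), length(members)), members)
  }
  sm <- assemble_supermatrix(net, lp)
  expect_identical(dim(sm$mat), c(9L, 9L))
  # an element column is nonzero in cluster C's rows iff an edge element -> C
  for (node in sm$nodes) {
    for (cl in names(net$clusters)) {
      has_edge <- any(net$edges$source == node & net$edges$target == cl)
      block <- sm$mat[net$clusters[[cl]], node]
      expect_identical(any(block != 0), has_edge)
    }
  }
})

test_that("cluster weighting yields column-stochastic supermatrices", {
  net <- anp_network(list(A = c("a1", "a2"), B = c("b1", "b2")),
                     data.frame(source = c("A", "A", "B", "B"),
                                target = c("A", "B", "A", "B")))
  lp <- list()
  for (k in seq_len(nrow(net$edges))) {
    members <- net$clusters[[net$edges$target[k]]]
    w <- c(0.7, 0.3)
    lp[[edge_key(net$edges$source[k], net$edges$target[k])]] <-
      stats::setNames(w, members)
  }
  un <- assemble_supermatrix(net, lp)
  expect_equal(unname(colSums(un$mat)), rep(2, 4))  # pre-weighting excess
  w_eq <- weight_supermatrix(un)
  expect_equal(unname(colSums(w_eq$mat)), rep(1, 4), tolerance = 1e-12)
  cm <- matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  w_cm <- weight_supermatrix(un, cm)
  expect_equal(unname(colSums(w_cm$mat)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(w_cm$mat["a1", "a1"]), 0.8 * 0.7)
  expect_equal(unname(w_cm$mat["b1", "a1"]), 0.2 * 0.7)
  # hierarchy: single contributing block per column, weighting is a no-op
  hnet <- anp_network(list(C = c("c1", "c2")),
                      data.frame(source = "g", target = "C"), goal = "g")
  hun <- assemble_supermatrix(hnet, list("g -> C" = c(c1 = 0.6, c2 = 0.4)))
  expect_equal(weight_supermatrix(hun)$mat, hun$mat)
})

test_that("limit supermatrix matches closed-form stationary distributions", {
  chain <- as_weighted_supermatrix(matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2))
  lim <- limit_supermatrix(chain)
  expect_equal(unname(lim$mat[, 1]), c(2 / 3, 1 / 3), tolerance = 1e-8)
  expect_equal(unname(lim$mat[, 2]), c(2 / 3, 1 / 3), tolerance = 1e-8)
  flat <- as_weighted_supermatrix(matrix(0.5, 2, 2))
  expect_equal(limit_supermatrix(flat)$mat, flat$mat, tolerance = 1e-12)
  # period-2 cycle: Cesaro average
  swap <- as_weighted_supermatrix(matrix(c(0, 1, 1, 0), 2, 2))
  lim2 <- limit_supermatrix(swap)
  expect_equal(unname(lim2$mat), matrix(0.5, 2, 2), tolerance = 1e-9)
  expect_identical(attr(lim2, "limit_info")$period, 2L)
  # period-3 cycle, which plain squaring alone can never settle
  rot <- matrix(0, 3, 3); rot[2, 1] <- rot[3, 2] <- rot[1, 3] <- 1
  lim3 <- limit_supermatrix(as_weighted_supermatrix(rot))
  expect_equal(unname(lim3$mat), matrix(1 / 3, 3, 3), tolerance = 1e-9)
  expect_error(limit_supermatrix(as_weighted_supermatrix(diag(2) * 2)),
               "column-stochastic")
})

test_that("limit columns equal the dense dominant eigenvector (oracle)", {
  set.seed(81)
  for (k in 1:20) {
    n <- sample(2:6, 1)
    a <- rand_column_stochastic(n)
    lim <- limit_supermatrix(as_weighted_supermatrix(a))
    expect_equal(unname(colSums(lim$mat)), rep(1, n), tolerance = 1e-9)
    stationary <- eigen_stationary(a)
    for (j in seq_len(n))
      expect_equal(unname(lim$mat[, j]), stationary, tolerance = 1e-8)
  }
})

test_that("strict hierarchies synthesise to top-down weight products", {
  net <- anp_network(list(Criteria = c("c1", "c2"),
                          Alts = c("x", "y", "z")),
                     data.frame(source = c("g", "Criteria"),
                                target = c("Criteria", "Alts")),
                     goal = "g")
  v <- c(c1 = 0.7, c2 = 0.3)
  W <- list("c1 -> Alts" = c(x = 0.5, y = 0.3, z = 0.2),
            "c2 -> Alts" = c(x = 0.1, y = 0.2, z = 0.7))
  lp <- c(list("g -> Criteria" = v), W)
  lim <- limit_supermatrix(weight_supermatrix(assemble_supermatrix(net, lp)))
  expect_true(attr(lim, "limit_info")$nilpotent_fallback)
  syn <- synthesize_priorities(lim)
  alt_truth <- 0.7 * W[["c1 -> Alts"]] + 0.3 * W[["c2 -> Alts"]]
  alts <- syn$elements[syn$elements$cluster == "Alts", ]
  expect_equal(alts$within_cluster, unname(alt_truth), tolerance = 1e-9)
  crits <- syn$elements[syn$elements$cluster == "Criteria", ]
  expect_equal(crits$within_cluster, c(0.7, 0.3), tolerance = 1e-9)
})

test_that("synthesis arithmetic, ranks and permutation equivariance", {
  net <- anp_network(list(A = c("e1", "e2"), B = c("e3", "e4")),
                     data.frame(source = c("A", "A", "B", "B"),
                                target = c("A", "B", "A", "B")))
  mat <- matrix(rep(c(0.1, 0.2, 0.3, 0.4), 4), 4, 4,
                dimnames = list(net$elements, net$elements))
  lim <- structure(list(mat = mat, nodes = net$elements, network = net,
                        stage = "limit"), class = "supermatrix")
  syn <- synthesize_priorities(lim)
  expect_equal(syn$clusters$priority, c(0.3, 0.7), tolerance = 1e-12)
  expect_equal(syn$elements$within_cluster[1:2], c(1 / 3, 2 / 3),
               tolerance = 1e-12)
  expect_identical(syn$elements$rank, c(4L, 3L, 2L, 1L))
  expect_identical(syn$clusters$rank, c(2L, 1L))

  # relabeling elements permutes every output identically
  net_p <- anp_network(list(B = c("e3", "e4"), A = c("e1", "e2")),
                       data.frame(source = c("A", "A", "B", "B"),
                                  target = c("A", "B", "A", "B")))
  perm <- c("e3", "e4", "e1", "e2")
  lim_p <- structure(list(mat = mat[perm, perm], nodes = perm,
                          network = net_p, stage = "limit"),
                     class = "supermatrix")
  syn_p <- synthesize_priorities(lim_p)
  merged <- merge(syn$elements, syn_p$elements, by = "element")
  expect_equal(merged$overall.x, merged$overall.y, tolerance = 1e-12)
  expect_equal(merged$within_cluster.x, merged$within_cluster.y,
               tolerance = 1e-12)
})
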