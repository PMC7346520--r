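test_that("Buckley weights reproduce the published fuzzy weight vector", {
  fw <- buckley_fuzzy_weights(published_fcm())
  # frozen from direct evaluation: r_i / reversed componentwise sum
  expect_equal(unname(fw$w[1, ]), c(0.135198, 0.165434, 0.205342),
               tolerance = 1e-5)
  expect_equal(unname(fw$w[2, ]), c(0.346346, 0.425132, 0.516853),
               tolerance = 1e-5)
  expect_equal(unname(fw$w[3, ]), c(0.340252, 0.409434, 0.494653),
               tolerance = 1e-5)
  expect_equal(unname(colSums(fw$r)), c(2.953863, 3.261965, 3.594402),
               tolerance = 1e-5)
})

test_that("Buckley weights solve symmetric and 2x2 cases in closed form", {
  ones <- as_fcm(matrix(1, 3, 3))
  expect_equal(unname(buckley_fuzzy_weights(ones)$w),
               matrix(1 / 3, 3, 3), tolerance = 1e-12)
  two <- as_fcm(matrix(c(1, 0.5, 2, 1), 2, 2))
  w <- buckley_fuzzy_weights(two)$w
  expect_equal(unname(w[1, ]), rep(2 / 3, 3), tolerance = 1e-12)
  expect_equal(unname(w[2, ]), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("defuzzified priorities match the published weight columns", {
  pv <- defuzzify_weights(buckley_fuzzy_weights(published_fcm()))
  expect_equal(round(unname(pv$certain), 3), c(0.168, 0.428, 0.413))
  expect_equal(round(unname(pv$normal), 3), c(0.166, 0.424, 0.409))
  expect_equal(unname(pv$ranks), c(3L, 1L, 2L))
  expect_equal(sum(pv$normal), 1, tolerance = 1e-12)
})

test_that("defuzzified priorities: ties, degeneracy and rank invariance", {
  sym <- defuzzify_weights(buckley_fuzzy_weights(as_fcm(matrix(1, 3, 3))))
  expect_equal(unname(sym$normal), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(unname(sym$ranks), 1:3)       # stable tie-break
  # crisp-degenerate weights defuzzify to their modal values
  crisp <- as_fcm(consistent_matrix_from_weights(c(0.5, 0.3, 0.2)))
  pv <- defuzzify_weights(buckley_fuzzy_weights(crisp))
  expect_equal(unname(pv$certain),
               unname(buckley_fuzzy_weights(crisp)$w[, "m"]),
               tolerance = 1e-12)
  set.seed(41)
  for (k in 1:20) {
    pv <- defuzzify_weights(buckley_fuzzy_weights(rand_reciprocal_fcm(4)))
    expect_equal(sum(pv$normal), 1, tolerance = 1e-12)
    expect_identical(order(-pv$certain), order(-pv$normal))
  }
})

test_that("extent analysis zeroes non-overlapping extents on the published matrix", {
  pv <- chang_extent_weights(published_fcm())
  # frozen from brute-force evaluation of all pairwise possibility degrees
  expect_equal(unname(pv$normal), c(0, 0.4659291, 0.5340709),
               tolerance = 1e-6)
  # efficiency's extent lies entirely below equity's: possibility 0
  expect_lt(pv$extents["Efficiency", "u"],
            pv$extents["Equity and Access", "l"])
  expect_equal(unname(pv$certain), c(0, 0.8724106, 1), tolerance = 1e-6)
})

test_that("extent analysis handles uniform and crisp dominant cases", {
  expect_equal(unname(chang_extent_weights(as_fcm(matrix(1, 3, 3)))$normal),
               rep(1 / 3, 3), tolerance = 1e-12)
  # crisp extents with one strict dominator: indicator weights
  crisp <- as_fcm(consistent_matrix_from_weights(c(0.02, 0.49, 0.49)))
  pv <- chang_extent_weights(crisp)
  expect_equal(unname(pv$normal), c(0, 0.5, 0.5), tolerance = 1e-12)
  dom <- as_fcm(consistent_matrix_from_weights(c(0.7, 0.2, 0.1)))
  expect_equal(unname(chang_extent_weights(dom)$normal), c(1, 0, 0),
               tolerance = 1e-12)
})

test_that("power iteration recovers generating weights of consistent matrices", {
  a <- matrix(c(1, 2, 6, 0.5, 1, 3, 1 / 6, 1 / 3, 1), 3, 3, byrow = TRUE)
  pe <- principal_eigenvector(a)
  expect_equal(unname(pe$weights), c(0.6, 0.3, 0.1), tolerance = 1e-9)
  expect_equal(pe$lambda_max, 3, tolerance = 1e-9)
  set.seed(51)
  for (n in c(3, 5, 8)) {
    w <- stats::runif(n, 0.05, 1); w <- w / sum(w)
    pe <- principal_eigenvector(consistent_matrix_from_weights(w))
    expect_equal(unname(pe$weights), w, tolerance = 1e-9)
    expect_equal(pe$lambda_max, n, tolerance = 1e-9)
  }
  expect_equal(principal_eigenvector(matrix(1, 1, 1))$lambda_max, 1)
  expect_error(principal_eigenvector(matrix(-1, 2, 2)), "positive")
  expect_error(principal_eigenvector(rand_reciprocal_crisp(3), max_iter = 1L),
               "converge")
})

test_that("power iteration agrees with the modal published matrix and oracles", {
  m <- published_fcm()$m
  pe <- principal_eigenvector(m)
  expect_equal(unname(pe$weights), c(0.165446, 0.425125, 0.409429),
               tolerance = 1e-5)
  expect_equal(pe$lambda_max, 3.019879, tolerance = 1e-5)
  # dual oracles: dense eigen solve and characteristic-polynomial roots
  set.seed(61)
  for (k in 1:10) {
    a <- rand_reciprocal_crisp(sample(3:4, 1))
    pe <- principal_eigenvector(a)
    expect_equal(pe$lambda_max, max(Re(eigen(a)$values)), tolerance = 1e-8)
    expect_equal(pe$lambda_max, charpoly_lambda_max(a), tolerance = 1e-6)
  }
})

test_that("consistency ratio follows the Saaty construction", {
  rep <- consistency_ratio(consistent_matrix_from_weights(c(0.5, 0.3, 0.2)))
  expect_equal(rep$ci, 0, tolerance = 1e-9)
  expect_equal(rep$cr, 0, tolerance = 1e-9)
  expect_true(rep$accepted)
  modal <- consistency_ratio(published_fcm()$m)
  expect_equal(modal$ci, 0.0099394, tolerance = 1e-5)
  expect_equal(modal$cr, 0.017137, tolerance = 1e-5)
  expect_identical(modal$ri, 0.58)
  expect_true(modal$accepted)
  expect_equal(consistency_ratio(matrix(c(1, 4, 0.25, 1), 2, 2))$cr, 0)
  big <- consistent_matrix_from_weights(rep(1 / 11, 11))
  expect_error(consistency_ratio(big), "random index")
})

test_that("fuzzy consistency variants reduce the matrix as documented", {
  x <- published_fcm()
  v <- fuzzy_cr_variants(x)
  expect_equal(sqrt(x$l[1, 2] * x$u[1, 2]), 0.4575806, tolerance = 1e-6)
  expect_equal(v$modal$cr, 0.017137, tolerance = 1e-5)
  expect_equal(v$bounds_geomean$cr, 0.0199195, tolerance = 1e-5)
  expect_identical(v$modal$variant, "modal")
  expect_identical(v$bounds_geomean$variant, "bounds_geomean")
  # crisp-degenerate matrix: both variants equal the plain CR
  crisp <- as_fcm(rand_reciprocal_crisp(3))
  plain <- consistency_ratio(crisp$m)
  both <- fuzzy_cr_variants(crisp)
  expect_equal(both$modal$cr, plain$cr, tolerance = 1e-12)
  expect_equal(both$bounds_geomean$cr, plain$cr, tolerance = 1e-12)
  # consistent l, m, u grids give zero everywhere
  cons <- as_fcm(consistent_matrix_from_weights(c(0.6, 0.3, 0.1)))
  vc <- fuzzy_cr_variants(cons)
  expect_equal(vc$modal$cr, 0, tolerance = 1e-9)
  expect_equal(vc$bounds_geomean$cr, 0, tolerance = 1e-9)
})

test_that("Buckley equals eigenvector weights on consistent crisp matrices", {
  set.seed(71)
  for (k in 1:10) {
    w <- stats::runif(4, 0.05, 1); w <- w / sum(w)
    crisp <- as_fcm(consistent_matrix_from_weights(w))
    pv <- defuzzify_weights(buckley_fuzzy_weights(crisp))
    expect_equal(unname(pv$normal), w, tolerance = 1e-9)
  }
})
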