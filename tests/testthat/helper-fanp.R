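# shared fixtures and independent oracles for the test suite

# the published aggregate paradigm comparison, built from its printed values
published_fcm <- function() {
  labs <- c("Efficiency", "Equity and Access", "Effectiveness")
  L <- matrix(c(1, 0.38, 0.302,
                1.815, 1, 1.063,
                2.472, 0.74, 1), 3, 3, byrow = TRUE)
  M <- matrix(c(1, 0.449, 0.35,
                2.228, 1, 1.197,
                2.853, 0.835, 1), 3, 3, byrow = TRUE)
  U <- matrix(c(1, 0.551, 0.405,
                2.634, 1, 1.351,
                3.315, 0.941, 1), 3, 3, byrow = TRUE)
  dimnames(L) <- dimnames(M) <- dimnames(U) <- list(labs, labs)
  fcm(L, M, U, labels = labs)
}

# random positive reciprocal crisp matrix (judgment-scale magnitudes)
rand_reciprocal_crisp <- function(n) {
  a <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    v <- exp(stats::runif(1, -log(9), log(9)))
    a[i, j] <- v; a[j, i] <- 1 / v
  }
  a
}

# random reciprocal fuzzy comparison matrix
rand_reciprocal_fcm <- function(n, delta = 0.5) {
  fuzzify_crisp_matrix(rand_reciprocal_crisp(n), delta = delta)
}

# independent lambda_max oracle: characteristic polynomial by
# Faddeev-LeVerrier recursion, dominant real root via polyroot
charpoly_lambda_max <- function(a) {
  n <- nrow(a)
  coefs <- numeric(n + 1)          # coefficients of lambda^n ... lambda^0
  coefs[1] <- 1
  mk <- diag(n)
  for (k in seq_len(n)) {
    mk <- a %*% mk
    if (k > 1) mk <- mk + coefs[k] * a
    coefs[k + 1] <- -sum(diag(mk)) / k
  }
  roots <- polyroot(rev(coefs))
  re <- Re(roots)[abs(Im(roots)) < 1e-6]
  max(re)
}

# random primitive column-stochastic matrix (strictly positive entries)
rand_column_stochastic <- function(n) {
  a <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  sweep(a, 2, colSums(a), `/`)
}

# wrap a column-stochastic matrix as a weighted supermatrix over one cluster
as_weighted_supermatrix <- function(mat) {
  n <- nrow(mat)
  labs <- paste0("e", seq_len(n))
  dimnames(mat) <- list(labs, labs)
  net <- anp_network(clusters = list(C = labs))
  structure(list(mat = mat, nodes = labs, network = net, stage = "weighted"),
            class = "supermatrix")
}

# dominant-eigenvector oracle via LAPACK (independent of power iteration)
eigen_stationary <- function(mat) {
  e <- eigen(mat)
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v / sum(v)
}

expect_tfn_equal <- function(a, b, tol = 1e-9) {
  expect_equal(unname(unclass(as_tfn(a))), unname(unclass(as_tfn(b))),
               tolerance = tol)
}
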