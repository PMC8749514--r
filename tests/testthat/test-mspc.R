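# Independent brute-force oracle: standardize by loops, eigendecompose the
# Gram matrix, and accumulate T2 term by term.
oracle_t2 <- function(X, Xnew, R) {
  N <- nrow(X); P <- ncol(X)
  ctr <- numeric(P); scl <- numeric(P)
  for (j in 1:P) {
    ctr[j] <- sum(X[, j]) / N
    scl[j] <- sqrt(sum((X[, j] - ctr[j])^2) / (N - 1))
  }
  Z <- matrix(0, N, P)
  for (i in 1:N) for (j in 1:P) Z[i, j] <- (X[i, j] - ctr[j]) / scl[j]
  eg <- eigen(t(Z) %*% Z, symmetric = TRUE)
  out <- numeric(nrow(Xnew))
  for (i in seq_len(nrow(Xnew))) {
    z <- (Xnew[i, ] - ctr) / scl
    acc <- 0
    for (r in 1:R) {
      proj <- sum(z * eg$vectors[, r])
      acc <- acc + proj^2 / eg$values[r]
    }
    out[i] <- acc
  }
  out
}

test_that("standardisation centres and scales, and applies stored statistics", {
  set.seed(31)
  X <- matrix(rnorm(100 * 5, mean = 7, sd = 3), 100, 5)
  m <- mspc(X, ncomp = 2)
  Z <- standardize(m, X)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 5), tolerance = 1e-12)
})

test_that("zero-variance training features are dropped with a warning", {
  set.seed(32)
  X <- cbind(a = rnorm(50), b = rep(4, 50), c = rnorm(50))
  expect_warning(m <- mspc(X, ncomp = 1), "zero-variance")
  expect_equal(m$feature_names, c("a", "c"))
  expect_equal(m$dropped, "b")
  expect_error(suppressWarnings(mspc(matrix(1, 30, 2))), "no non-degenerate")
})

test_that("training T2 values sum to the number of retained components", {
  set.seed(33)
  for (i in 1:8) {
    N <- sample(20:120, 1); P <- sample(3:8, 1)
    R <- sample(seq_len(P - 1), 1)
    X <- matrix(rnorm(N * P), N, P) %*% matrix(rnorm(P * P), P, P)
    m <- mspc(X, ncomp = R)
    expect_equal(sum(m$t2_train), R, tolerance = 1e-8)
  }
})

test_that("control limit splits training samples at the calibration percentile", {
  set.seed(34)
  X <- matrix(rnorm(200 * 6), 200, 6)
  m <- mspc(X, ncomp = 1, percentile = 90)
  expect_equal(sum(m$t2_train <= m$control_limit), 180)
  expect_equal(sum(m$t2_train > m$control_limit), 20)
})

test_that("near-collinear data concentrate on the first component", {
  set.seed(35)
  t <- rnorm(300)
  X <- outer(t, c(1, 2, -1, 0.5)) + matrix(rnorm(300 * 4, sd = 1e-3), 300, 4)
  m <- mspc(X, ncomp = 1)
  expect_gt(m$all_singular_values[1]^2 / sum(m$all_singular_values^2), 0.99)
})

test_that("T2 is zero at the training mean and quadratic along the loading", {
  set.seed(36)
  X <- matrix(rnorm(150 * 4), 150, 4)
  m <- mspc(X, ncomp = 1)
  expect_equal(t2_statistic(m, stats::setNames(m$center, m$feature_names)), 0,
               tolerance = 1e-20)
  v1 <- drop(m$loadings)
  for (delta in c(0.5, 2, 7)) {
    x <- m$center + delta * v1 * m$scale   # z-space displacement delta * v1
    expect_equal(t2_statistic(m, stats::setNames(x, m$feature_names)),
                 (delta / m$singular_values[1])^2, tolerance = 1e-10)
  }
})

test_that("T2 matches the brute-force eigendecomposition oracle", {
  set.seed(37)
  for (R in c(1, 2)) {
    X <- matrix(rnorm(20 * 5), 20, 5)
    colnames(X) <- paste0("f", 1:5)
    Xnew <- matrix(rnorm(10 * 5), 10, 5)
    colnames(Xnew) <- paste0("f", 1:5)
    m <- mspc(X, ncomp = R)
    expect_equal(predict(m, Xnew, type = "t2"), oracle_t2(X, Xnew, R),
                 tolerance = 1e-10)
    expect_equal(sum(predict(m, X, type = "t2")), R, tolerance = 1e-8)
  }
})

test_that("T2 is invariant to a common orthogonal rotation in z-space", {
  set.seed(38)
  Z <- scale(matrix(rnorm(80 * 4), 80, 4) %*% diag(c(3, 2, 1, 0.5)))
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  Znew <- matrix(rnorm(15 * 4), 15, 4)
  m1 <- mspc(Z, ncomp = 2, scale = FALSE)
  m2 <- mspc(Z %*% Q, ncomp = 2, scale = FALSE)
  expect_equal(predict(m1, Znew, type = "t2"),
               predict(m2, Znew %*% Q, type = "t2"), tolerance = 1e-8)
})

test_that("detection flags the calibrated fraction and saturates under shift", {
  set.seed(39)
  X <- matrix(rnorm(200 * 4), 200, 4)
  colnames(X) <- paste0("f", 1:4)
  m <- mspc(X, ncomp = 4, percentile = 90)
  df <- cbind(data.frame(t_end = 1:200), as.data.frame(X))
  s <- detect(m, df)
  expect_equal(mean(s$anomaly), 0.10)

  shifted <- X
  shifted[, 2] <- shifted[, 2] + 10 * sd(X[, 2])
  expect_true(all(predict(m, shifted, type = "t2") > m$control_limit))
})

test_that("missing features yield missing scores, never zero", {
  set.seed(40)
  X <- matrix(rnorm(60 * 3), 60, 3)
  colnames(X) <- c("a", "b", "c")
  m <- mspc(X, ncomp = 1)
  Xn <- as.data.frame(X[1:5, ])
  Xn$b[2] <- NA
  out <- predict(m, Xn)
  expect_true(is.na(out$t2[2]) && is.na(out$anomaly[2]))
  expect_false(anyNA(out$t2[-2]))
  allna <- Xn; allna[] <- NA
  expect_true(all(is.na(predict(m, allna)$t2)))
  expect_error(predict(m, Xn[, c("a", "b")]), "missing from input")
})

test_that("model serialisation round-trips scores and refuses bad files", {
  set.seed(41)
  X <- matrix(rnorm(80 * 5), 80, 5)
  colnames(X) <- paste0("f", 1:5)
  m <- mspc(X, ncomp = 2)
  probe <- matrix(rnorm(20 * 5), 20, 5); colnames(probe) <- paste0("f", 1:5)
  f <- withr::local_tempfile(fileext = ".json")
  save_mspc(m, f)
  m2 <- load_mspc(f)
  expect_lt(max(abs(predict(m, probe, type = "t2") -
                    predict(m2, probe, type = "t2"))), 1e-12)
  expect_equal(m2$control_limit, m$control_limit)

  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$schema <- "mspc-99"
  jsonlite::write_json(obj, f, digits = NA, auto_unbox = TRUE)
  expect_error(load_mspc(f), "schema")

  obj$schema <- "mspc-1"
  obj$feature_names <- obj$feature_names[1:3]  # tampered feature list
  jsonlite::write_json(obj, f, digits = NA, auto_unbox = TRUE)
  expect_error(load_mspc(f), "corrupt")
})
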