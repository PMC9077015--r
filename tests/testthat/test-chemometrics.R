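test_that("PCA recovers a rank-1 matrix with one component", {
  set.seed(1)
  x <- outer(rnorm(10), rnorm(6))
  m <- fitPCA(x, n_components = 1, scaling = scalingSpec(scaling = "none"))
  expect_equal(unname(r2x(m)[1]), 1, tolerance = 1e-10)
})

test_that("duplicated sample rows give duplicated score rows", {
  set.seed(2)
  x <- matrix(rnorm(8 * 12), 8, 12)
  xx <- rbind(x, x[3, ])
  m <- fitPCA(xx, n_components = 2)
  expect_equal(unname(scores(m)[9, ]), unname(scores(m)[3, ]), tolerance = 1e-10)
})

test_that("PCA matches a dense eigendecomposition oracle up to sign", {
  set.seed(3)
  x <- matrix(rnorm(10 * 50), 10, 50)
  m <- fitPCA(x, n_components = 3)
  # oracle: eigendecomposition of the covariance of the scaled matrix
  xs <- scale(x)
  ev <- eigen(crossprod(xs) / (nrow(x) - 1))
  for (k in 1:3) {
    expect_equal(abs(unname(loadings2(m)[, k])), abs(ev$vectors[, k]),
                 tolerance = 1e-8)
    expect_equal(unname(r2x(m)[k]), ev$values[k] / sum(ev$values),
                 tolerance = 1e-8)
  }
})

test_that("OPLS-DA with no orthogonal component reduces to single-component PLS", {
  set.seed(4)
  x <- matrix(rnorm(14 * 30), 14, 30)
  y <- rep(c("a", "b"), each = 7)
  m <- fitOPLSDA(x, y, n_orth = 0)
  xs <- scale(x)
  yc <- rep(c(0, 1), each = 7) - 0.5
  w <- drop(crossprod(xs, yc)); w <- w / sqrt(sum(w^2))
  expect_equal(abs(unname(scores(m)[, 1])), abs(drop(xs %*% w)),
               tolerance = 1e-8)
})

test_that("well-separated classes are perfectly split by the predictive score", {
  gen <- generateSpectra(syntheticConfig(seed = 6))
  bm <- normalizeBuckets(bucketSpectra(gen$spectra, bucketSpec()))
  g <- groupLabels(bm); x <- bucketValues(bm)
  sel <- g %in% c("control", "model")
  m <- fitOPLSDA(x[sel, ], g[sel], n_orth = 1)
  t <- scores(m)[, 1]
  split <- tapply(t, g[sel], mean)
  expect_true(all(sign(t[g[sel] == "control"]) == sign(split["control"])))
  expect_true(all(sign(t[g[sel] == "model"]) == sign(split["model"])))
})

test_that("predictive scores are orthogonal to every orthogonal score", {
  set.seed(5)
  x <- matrix(rnorm(16 * 40), 16, 40)
  y <- rep(c("a", "b"), each = 8)
  for (no in 1:3) {
    m <- fitOPLSDA(x, y, n_orth = no)
    t <- scores(m)[, 1]
    for (k in seq_len(no))
      expect_lt(abs(sum((t - mean(t)) * m@scoresOrth[, k])), 1e-8)
  }
})

test_that("appending pure-noise orthogonal structure barely moves class separation", {
  set.seed(9)
  n <- 16
  ys <- rep(c("a", "b"), each = n / 2)
  xs <- matrix(rnorm(n * 100), n, 100)
  xs[, 1:10] <- xs[, 1:10] + outer(as.numeric(ys == "b"), rep(1.5, 10))
  sepa <- function(t) {
    d <- abs(diff(tapply(t, ys, mean)))
    d / sqrt(mean(tapply(t, ys, var)))
  }
  set.seed(10)
  yc <- as.numeric(factor(ys)) - 1.5
  v <- rnorm(n)
  v <- v - yc * sum(v * yc) / sum(yc^2)  # class-orthogonal sample pattern
  ortho <- outer(v, rnorm(200))
  # the appended structure carries no class covariance, so the predictive
  # component ignores it: separation is unchanged
  m0 <- fitOPLSDA(xs, ys, n_orth = 0)
  m1 <- fitOPLSDA(cbind(xs, ortho), ys, n_orth = 0)
  expect_equal(sepa(scores(m1)[, 1]), sepa(scores(m0)[, 1]), tolerance = 0.05)
  # with one orthogonal component the model absorbs the planted structure
  m2 <- fitOPLSDA(cbind(xs, ortho), ys, n_orth = 1)
  expect_gt(abs(cor(m2@scoresOrth[, 1], v)), 0.95)
})

test_that("Q2 equals 1 when the class is perfectly predicted in every fold", {
  y <- rep(c("a", "b"), each = 10)
  ind <- as.numeric(y == "b")
  x <- cbind(ind, 2 * ind)  # x encodes the class exactly; PRESS must be zero
  q <- crossValidateQ2(x, y, n_orth = 0, folds = 5,
                       scaling = scalingSpec(scaling = "none"), seed = 1)
  expect_equal(as.numeric(q), 1, tolerance = 1e-10)
})

test_that("Q2 never exceeds R2Y on synthetic fits", {
  for (s in 1:5) {
    set.seed(s)
    n <- 16
    x <- matrix(rnorm(n * 25), n, 25)
    y <- rep(c("a", "b"), each = n / 2)
    x[, 1:5] <- x[, 1:5] + outer(as.numeric(y == "b"), rep(s / 3, 5))
    m <- fitOPLSDA(x, y, n_orth = 1)
    q <- as.numeric(crossValidateQ2(x, y, n_orth = 1, folds = 7, seed = s))
    expect_lte(q, r2y(m) + 1e-8)
  }
})

test_that("randomly permuted labels on structureless data give nonpositive Q2", {
  set.seed(99)
  neg <- 0
  for (i in 1:100) {
    x <- matrix(rnorm(40 * 100), 40, 100)
    y <- sample(rep(c("a", "b"), each = 20))
    q <- crossValidateQ2(x, y, n_orth = 1, folds = 7, seed = i)
    if (as.numeric(q) <= 0) neg <- neg + 1
  }
  expect_gte(neg, 90)
})

test_that("a fold whose training set loses a class is a stratification error", {
  x <- matrix(rnorm(8 * 4), 8, 4)
  y <- c(rep("a", 7), "b")
  expect_error(crossValidateQ2(x, y, folds = 8, seed = 1), "stratification")
})

test_that("critical |r| reproduces the tabulated Pearson cutoffs", {
  expect_equal(round(criticalR(8, 0.05), 3), 0.707)
  expect_equal(criticalR(12, 0.05), 0.576, tolerance = 1e-3)
  expect_lt(criticalR(8, 0.9999), 0.01)
  expect_error(criticalR(2), "n must be")
})

test_that("critical |r| matches numeric inversion of the null density of r", {
  # null density of the sample correlation: f(r) ~ (1 - r^2)^((n - 4) / 2)
  for (n in c(8, 12, 20)) {
    dens <- function(r) (1 - r^2)^((n - 4) / 2)
    Z <- integrate(dens, -1, 1)$value
    tail <- function(rc) integrate(dens, rc, 1)$value / Z
    rstar <- uniroot(function(rc) tail(rc) - 0.025, c(0.01, 0.999),
                     tol = 1e-10)$root
    expect_equal(criticalR(n, 0.05), rstar, tolerance = 1e-6)
  }
})

test_that("correlation loadings match a naive per-column oracle", {
  set.seed(12)
  x <- matrix(rnorm(16 * 20), 16, 20)
  colnames(x) <- sprintf("%.4f", seq(0.5, by = 0.004, length.out = 20))
  y <- rep(c("a", "b"), each = 8)
  x[, 1] <- x[, 1] + 3 * (y == "b")
  m <- fitOPLSDA(x, y, n_orth = 1)
  cl <- correlationLoadings(m, x)
  t <- scores(m)[, 1]
  for (j in c(1, 5, 20))
    expect_equal(cl$r[j], cor(t, x[, j]), tolerance = 1e-12)
  # a column equal to t correlates perfectly
  x3 <- x
  x3[, 5] <- t
  cl3 <- correlationLoadings(m, x3)
  expect_equal(cl3$r[5], 1, tolerance = 1e-12)
  # a seeded noise column independent of t stays under the n = 16 threshold
  expect_lt(abs(cl$r[10]), attr(cl, "threshold"))
})

test_that("constant columns get r = 0 with a warning", {
  set.seed(13)
  x <- matrix(rnorm(12 * 4), 12, 4)
  x[, 2] <- 1
  y <- rep(c("a", "b"), each = 6)
  m <- fitOPLSDA(x, y, n_orth = 0)
  expect_warning(cl <- correlationLoadings(m, x), "constant")
  expect_equal(cl$r[2], 0)
})

test_that("biomarker selection lifts planted effects with correct directions", {
  gen <- generateSpectra(syntheticConfig(seed = 21))
  bm <- normalizeBuckets(bucketSpectra(gen$spectra, bucketSpec()))
  g <- groupLabels(bm); x <- bucketValues(bm)
  sel <- g %in% c("control", "model")
  m <- fitOPLSDA(x[sel, ], g[sel], n_orth = 1)
  cl <- correlationLoadings(m, x[sel, ], n = 8)
  bio <- selectBiomarkers(cl, gen$truth$bucket_map)
  expect_true(all(c("valine", "lipids") %in% bio$metabolite))
  expect_equal(bio$direction[bio$metabolite == "valine"], "down")
  expect_equal(bio$direction[bio$metabolite == "lipids"], "up")
  expect_equal(bio$direction[bio$metabolite == "beta-glucose"], "down")
})

test_that("no bucket past the threshold yields an empty biomarker table", {
  cl <- data.frame(variable = "1.0000", ppm = 1, r = 0.1, covariance = 1,
                   selected = FALSE)
  out <- selectBiomarkers(cl, data.frame(metabolite = "x", lo = 0.9, hi = 1.1))
  expect_equal(nrow(out), 0L)
})
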