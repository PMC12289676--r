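test_that("full-rank NIPALS with all components reproduces OLS predictions", {
  set.seed(1)
  x <- matrix(rnorm(60), 12, 5)
  y <- rnorm(12)
  fit <- nipals_plsr(x, y, ncomp = 5)
  pred_pls <- predict(fit, x)
  pred_ols <- fitted(lm(y ~ x))
  expect_lt(max(abs(pred_pls - pred_ols)), 1e-8)
})

test_that("scores are orthogonal, weights unit-norm, explained variance well-behaved", {
  set.seed(2)
  x <- matrix(rnorm(100), 20, 5)
  y <- matrix(rnorm(40), 20, 2)
  fit <- nipals_plsr(x, y, ncomp = 3)
  g <- crossprod(fit$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_equal(unname(colSums(fit$weights^2)), rep(1, 3), tolerance = 1e-10)
  expect_true(all(fit$explained_y >= -1e-12))
  expect_lte(sum(fit$explained_y), 1 + 1e-9)
  # reconstruction error of Y is non-increasing in the component count
  errs <- vapply(1:3, function(a) {
    f <- nipals_plsr(x, y, ncomp = a)
    sum((y - predict(f, x))^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("a response equal to one orthogonal predictor is explained by one component", {
  set.seed(3)
  # orthogonal, column-centered predictor block (QR of a centered matrix)
  x <- qr.Q(qr(scale(matrix(rnorm(80), 16, 5), scale = FALSE)))
  colnames(x) <- paste0("p", 1:5)
  y <- x[, 1]
  fit <- nipals_plsr(x, y, ncomp = 1)
  expect_equal(fit$explained_y[1], 1, tolerance = 1e-10)
  expect_equal(select_ncomp(x, y, threshold = 0.80), 1L)
})

test_that("ncomp selection follows the cumulative explained-variance rule", {
  set.seed(4)
  n <- 40
  # two orthogonal X-drivers feeding two responses: each component explains
  # about half of the Y block, so the 80% rule needs exactly two
  t1 <- rnorm(n); t2 <- rnorm(n)
  x <- cbind(t1, t2, matrix(rnorm(n * 3), n))
  y <- cbind(y1 = scale(t1)[, 1] + rnorm(n, 0, 0.15),
             y2 = scale(t2)[, 1] + rnorm(n, 0, 0.15))
  expect_equal(select_ncomp(x, y, threshold = 0.80), 2L)
  # impossible threshold falls back to max_comp with a warning
  set.seed(5)
  yn <- rnorm(20)
  xn <- matrix(rnorm(100), 20, 5)
  expect_warning(nc <- select_ncomp(xn, yn, threshold = 0.99, max_comp = 2),
                 "max_comp")
  expect_identical(nc, 2L)
})

test_that("zero-variance columns are rejected by name", {
  x <- cbind(a = rnorm(10), b = rep(1, 10))
  expect_error(nipals_plsr(x, rnorm(10), 1), "b")
})

test_that("VIP follows the weighted-share formula with mean square one", {
  # single component, weights (1, 0): VIP = (sqrt(2), 0)
  set.seed(6)
  n <- 30
  x1 <- rnorm(n)
  x <- cbind(p1 = x1, p2 = rnorm(n))
  fit <- nipals_plsr(cbind(p1 = x1, p2 = rnorm(n)), 2 * x1, ncomp = 1)
  v <- vip(fit)
  expect_equal(unname(v["p1"]), sqrt(2), tolerance = 1e-2)
  expect_lt(v["p2"], 0.3)
  # exact algebraic identities on random fits
  set.seed(7)
  for (i in 1:100) {
    n <- sample(10:25, 1); p <- sample(3:8, 1)
    m <- sample(1:3, 1)
    xx <- matrix(rnorm(n * p), n, p)
    yy <- matrix(rnorm(n * m), n, m)
    f <- nipals_plsr(xx, yy, ncomp = sample(1:3, 1))
    vv <- vip(f)
    expect_equal(mean(vv^2), 1, tolerance = 1e-9)
    expect_equal(sum(vv^2), p, tolerance = 1e-9)
    expect_true(all(vv >= 0))
  }
})

test_that("VIP screening uses a strict threshold in descending order", {
  fit <- list(weights = matrix(c(1, 0), 2, 1,
                               dimnames = list(c("a", "b"), NULL)),
              explained_y = 0.9)
  class(fit) <- "plsr_fit"
  expect_identical(screen_vip(fit), "a")
  # all-equal VIPs sit exactly at 1 and are excluded by strict inequality
  fit2 <- list(weights = matrix(sqrt(c(0.5, 0.5)), 2, 1,
                                dimnames = list(c("a", "b"), NULL)),
               explained_y = 0.5)
  class(fit2) <- "plsr_fit"
  expect_identical(screen_vip(fit2), character(0))
})

test_that("the one-component weight vector is proportional to X'y", {
  set.seed(8)
  x <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  fit <- nipals_plsr(x, y, ncomp = 1)
  xa <- scale(x); ya <- scale(y)
  w_closed <- drop(crossprod(xa, ya)); w_closed <- w_closed / sqrt(sum(w_closed^2))
  expect_equal(abs(unname(fit$weights[, 1])), abs(w_closed), tolerance = 1e-8)
})

test_that("autoscaled NIPALS is invariant to affine predictor rescaling", {
  set.seed(9)
  x <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  f1 <- nipals_plsr(x, y, ncomp = 2)
  x2 <- sweep(sweep(x, 2, c(10, 0.1, 3), "*"), 2, c(1, 2, -5), "+")
  f2 <- nipals_plsr(x2, y, ncomp = 2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("NIPALS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(10)
  x <- matrix(rnorm(120), 24, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- x[, 1] - 0.5 * x[, 3] + rnorm(24, 0, 0.5)
  fit <- nipals_plsr(x, y, ncomp = 2)
  ref <- mixOmics::pls(x, y, ncomp = 2, scale = TRUE, mode = "regression")
  # scores agree up to per-component sign
  for (a in 1:2) {
    r <- cor(fit$scores[, a], ref$variates$X[, a])
    expect_gt(abs(r), 1 - 1e-6)
  }
  v_ref <- mixOmics::vip(ref)[, 2]
  expect_equal(unname(vip(fit)), unname(v_ref), tolerance = 1e-6)
})
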