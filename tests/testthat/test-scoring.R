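test_that("ulcer index applies the macroscopic banding rules", {
  expect_identical(ulcer_index(data.frame(length_mm = numeric(0),
                                          width_mm = numeric(0))), 0L)
  expect_identical(
    ulcer_index(data.frame(length_mm = 2.5, width_mm = 0.5)), 3L)
  # punctate (1.5 is not punctate, band <2 -> 2) plus 3-4 band doubled by width
  expect_identical(
    ulcer_index(data.frame(length_mm = c(1.5, 3.5), width_mm = c(0.4, 1.2))),
    10L)
  # band edges: closed on the left of each stated range
  expect_identical(ulcer_index(data.frame(length_mm = 3, width_mm = 0.2)), 3L)
  expect_identical(ulcer_index(data.frame(length_mm = 4, width_mm = 0.2)), 4L)
  expect_identical(ulcer_index(data.frame(length_mm = 4.1, width_mm = 0.2)), 5L)
  expect_identical(ulcer_index(data.frame(length_mm = 0.5, width_mm = 0.2)), 1L)
  expect_error(ulcer_index(data.frame(length_mm = -1, width_mm = 0)),
               "nonnegative")
})

test_that("ulcer index is additive over lesion lists", {
  set.seed(4)
  a <- data.frame(length_mm = runif(6, 0, 6), width_mm = runif(6, 0, 2))
  b <- data.frame(length_mm = runif(4, 0, 6), width_mm = runif(4, 0, 2))
  expect_identical(ulcer_index(rbind(a, b)),
                   ulcer_index(a) + ulcer_index(b))
})

test_that("min-max normalization maps orientations onto [0, 1]", {
  expect_equal(minmax_normalize(c(1, 2, 3), "positive"), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(1, 2, 3), "negative"), c(1, 0.5, 0))
  set.seed(9)
  v <- rnorm(20)
  expect_equal(minmax_normalize(v, "positive") + minmax_normalize(v, "negative"),
               rep(1, 20))
  expect_error(minmax_normalize(rep(2, 5), "positive"), "degenerate")
})

test_that("entropy weights reward dispersion and sum to one", {
  m <- cbind(a = c(0, 0.5, 1), b = c(0, 0.5, 1))
  expect_equal(unname(entropy_weights(m)), c(0.5, 0.5))
  m2 <- cbind(flat = rep(0.4, 4), vary = c(0, 1, 0.2, 0.9))
  w2 <- entropy_weights(m2)
  expect_equal(unname(w2["flat"]), 0)
  expect_equal(sum(w2), 1)
  # symmetric 3 x 2 case, cross-checked against a direct evaluation of the
  # entropy formula
  m3 <- cbind(x = c(0, 0.5, 1), y = c(1, 0.5, 0))
  direct <- apply(m3, 2, function(col) {
    p <- col / sum(col)
    -sum(ifelse(p > 0, p * log(p), 0)) / log(nrow(m3))
  })
  expect_equal(unname(entropy_weights(m3)),
               unname((1 - direct) / sum(1 - direct)))
  expect_equal(unname(entropy_weights(m3)), c(0.5, 0.5))
  expect_error(entropy_weights(cbind(rep(1, 3), rep(2, 3))), "undefined")
})

test_that("entropy weights are permutation-equivariant in columns", {
  set.seed(11)
  m <- matrix(runif(40), 8, 5, dimnames = list(NULL, letters[1:5]))
  w <- entropy_weights(m)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(unname(entropy_weights(m[, perm])), unname(w[perm]))
})

test_that("composite indices hit the extremes and respect fixed weights", {
  tab <- data.frame(UI = c(10, 2, 6), HS = c(8, 1, 4))
  spec <- composite_spec("MRS", c("UI", "HS"), "negative", c(0.5269, 0.4731))
  ci <- composite_index(tab, spec)
  expect_equal(ci$scores[2], 1)     # best (lowest) damage on both components
  expect_equal(ci$scores[1], 0)     # worst on both
  expect_true(all(ci$scores >= 0 & ci$scores <= 1))
  # half-way normalized values give the weighted mean 0.5
  tab2 <- data.frame(EGF = c(0, 5, 10), EGFR = c(0, 5, 10))
  spec2 <- composite_spec("RF", c("EGF", "EGFR"), "positive",
                          c(0.6304, 0.3696))
  expect_equal(composite_index(tab2, spec2)$scores[2], 0.5)
  expect_error(composite_index(data.frame(UI = 1:3), spec), "missing")
})

test_that("improving one component never decreases a composite", {
  set.seed(21)
  spec_w <- composite_spec("T", c("a", "b", "c"),
                           c("positive", "negative", "positive"),
                           weights = c(0.5, 0.3, 0.2))
  for (rep in 1:20) {
    tab <- data.frame(a = runif(10), b = runif(10), c = runif(10))
    i <- sample(which(tab$a < max(tab$a)), 1)
    tab2 <- tab
    # favorable move on a positive component, staying inside the envelope
    tab2$a[i] <- runif(1, tab$a[i], max(tab$a))
    expect_gte(composite_index(tab2, spec_w)$scores[i] + 1e-12,
               composite_index(tab, spec_w)$scores[i])
    # favorable move on a negative component (toward the minimum)
    j <- sample(which(tab$b > min(tab$b)), 1)
    tab3 <- tab
    tab3$b[j] <- runif(1, min(tab$b), tab$b[j])
    expect_gte(composite_index(tab3, spec_w)$scores[j] + 1e-12,
               composite_index(tab, spec_w)$scores[j])
  }
})

test_that("z-scoring standardizes and is affine-invariant", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(3)
  v <- rnorm(50, 5, 2)
  z <- zscore(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore(3 * v + 7), z)
  expect_error(zscore(rep(1, 4)), "degenerate")
})

test_that("the six published composite specs carry unit weight sums", {
  specs <- published_composites()
  expect_named(specs, c("MRS", "RF", "GIC", "SIC", "LF", "HIC"))
  for (s in specs) {
    expect_s3_class(s, "composite_spec")
    expect_equal(sum(s$weights), 1, tolerance = 1e-4)
    expect_true(all(s$weights >= 0))
    expect_length(s$orientations, length(s$components))
  }
  expect_equal(unname(specs$MRS$weights), c(0.5269, 0.4731))
  expect_equal(unname(specs$RF$weights), c(0.6304, 0.3696))
})
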