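chain_dag <- function() {
  path_dag(data.frame(from = c("X", "M"), to = c("M", "Y")),
           c(X = "exogenous", M = "mediator", Y = "outcome"))
}

test_that("path DAG construction validates roles and acyclicity", {
  expect_s3_class(chain_dag(), "path_dag")
  expect_error(path_dag(data.frame(from = "M", to = "X"),
                        c(X = "exogenous", M = "mediator")), "exogenous")
  expect_error(path_dag(data.frame(from = c("A", "B"), to = c("B", "A")),
                        c(A = "mediator", B = "mediator")), "cyclic")
  expect_error(path_dag(data.frame(from = "A", to = "B"),
                        c(A = "exogenous")), "missing role")
})

test_that("basis set matches textbook cases", {
  # chain: one claim, X _||_ Y | M
  bs <- basis_set(chain_dag())
  expect_length(bs, 1)
  expect_identical(bs[[1]]$x, "X")
  expect_identical(bs[[1]]$y, "Y")
  expect_identical(bs[[1]]$conditioning, "M")
  # saturated triangle: no non-adjacent pairs
  tri <- path_dag(data.frame(from = c("X", "X", "M"), to = c("M", "Y", "Y")),
                  c(X = "exogenous", M = "mediator", Y = "outcome"))
  expect_length(basis_set(tri), 0)
  # two parallel mediators: claims are M1 _||_ M2 | X and X _||_ Y | {M1, M2}
  par <- path_dag(
    data.frame(from = c("X", "X", "M1", "M2"), to = c("M1", "M2", "Y", "Y")),
    c(X = "exogenous", M1 = "mediator", M2 = "mediator", Y = "outcome"))
  bs2 <- basis_set(par)
  keys <- vapply(bs2, function(cl)
    paste(sort(c(cl$x, cl$y)), collapse = "~"), character(1))
  expect_setequal(keys, c("M1~M2", "X~Y"))
  cond <- lapply(bs2, `[[`, "conditioning")
  names(cond) <- keys
  expect_identical(sort(cond[["M1~M2"]]), "X")
  expect_identical(sort(cond[["X~Y"]]), c("M1", "M2"))
})

test_that("basis-set claims agree with a brute-force d-separation oracle", {
  set.seed(42)
  n_checked <- 0
  for (n in 3:5) {
    for (rep in 1:30) {
      edges <- random_dag_edges(n)
      if (nrow(edges) == 0) next
      nodes <- LETTERS[seq_len(n)]
      roles <- stats::setNames(
        ifelse(nodes %in% edges$to, "mediator", "exogenous"), nodes)
      dag <- path_dag(edges, roles)
      bs <- basis_set(dag)
      # every emitted claim is d-separated given its conditioning set
      for (cl in bs) {
        expect_true(dsep_oracle(edges, cl$x, cl$y, cl$conditioning))
        n_checked <- n_checked + 1
      }
      # the claim pairs are exactly the non-adjacent pairs with at least one
      # endogenous member
      adj <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
      pairs <- combn(nodes, 2)
      expected <- character(0)
      for (k in seq_len(ncol(pairs))) {
        a <- pairs[1, k]; b <- pairs[2, k]
        if (paste(a, b) %in% adj) next
        if (!(a %in% edges$to) && !(b %in% edges$to)) next
        expected <- c(expected, paste(a, b))
      }
      got <- vapply(bs, function(cl)
        paste(sort(c(cl$x, cl$y))[1], sort(c(cl$x, cl$y))[2]), character(1))
      expect_setequal(got, expected)
    }
  }
  expect_gt(n_checked, 50)
})

test_that("claim tests detect dependence and tolerate duplicated conditioning", {
  set.seed(5)
  x <- rnorm(100)
  d <- data.frame(X = x, Y = x, M = rnorm(100))
  # perfect dependence: summary.lm warns about the exact fit, p is ~0
  suppressWarnings({
    expect_lt(test_claim(list(x = "X", y = "Y",
                              conditioning = character(0)), d), 1e-10)
    cl <- list(x = "X", y = "Y", conditioning = c("M", "M"))
    cl2 <- list(x = "X", y = "Y", conditioning = "M")
    expect_equal(test_claim(cl, d), test_claim(cl2, d))
  })
})

test_that("Fisher's C follows the chi-squared combination rule", {
  fc <- fishers_c(0.5)
  expect_equal(fc$c_stat, -2 * log(0.5))
  expect_identical(fc$df, 2L)
  expect_equal(fc$p_value, 0.5, tolerance = 1e-12)
  # k = 1 identity p_C = p1, over a grid
  set.seed(8)
  for (p1 in runif(50)) {
    expect_equal(fishers_c(p1)$p_value, p1, tolerance = 1e-10)
  }
  # saturated convention
  expect_identical(fishers_c(numeric(0)), list(c_stat = 0, df = 0L,
                                               p_value = 1.0))
  expect_warning(fishers_c(c(0, 0.5)), "clamped")
})

test_that("piecewise SEM fits component models and the AIC identity holds", {
  set.seed(11)
  n <- 150
  x <- rnorm(n)
  m <- 0.7 * x + rnorm(n, 0, 0.7)
  y <- 0.6 * m + rnorm(n, 0, 0.8)
  d <- data.frame(X = x, M = m, Y = y)
  fit <- fit_psem(chain_dag(), d)
  expect_equal(nrow(fit$paths), 2)
  expect_equal(fit$df, 2L)
  # K: two component models, each slope + intercept + residual variance
  expect_equal(fit$k_params, 6)
  expect_equal(fit$aic, fit$c_stat + 2 * fit$k_params)
  # saturated triangle: C = 0, p = 1, AIC = 2K
  tri <- path_dag(data.frame(from = c("X", "X", "M"), to = c("M", "Y", "Y")),
                  c(X = "exogenous", M = "mediator", Y = "outcome"))
  fit_tri <- fit_psem(tri, d)
  expect_equal(fit_tri$c_stat, 0)
  expect_equal(fit_tri$p_value, 1)
  expect_equal(fit_tri$aic, 2 * fit_tri$k_params)
})

test_that("pruning removes weak paths one at a time and logs removals", {
  set.seed(12)
  n <- 200
  x <- rnorm(n)
  m <- 0.7 * x + rnorm(n, 0, 0.7)
  y <- 0.6 * m + rnorm(n, 0, 0.8)   # no direct X -> Y effect
  d <- data.frame(X = x, M = m, Y = y)
  tri <- path_dag(data.frame(from = c("X", "X", "M"), to = c("M", "Y", "Y")),
                  c(X = "exogenous", M = "mediator", Y = "outcome"))
  fit <- fit_psem(tri, d)
  pruned <- prune_paths(fit, d, alpha = 0.05)
  expect_false(pruned$empty)
  expect_equal(nrow(pruned$removed),
               nrow(fit$paths) - nrow(pruned$paths))
  expect_true(all(pruned$paths$p < 0.05))
  # the spurious direct path is the one removed
  if (nrow(pruned$removed) == 1) {
    expect_identical(pruned$removed$from, "X")
    expect_identical(pruned$removed$to, "Y")
  }
  # a fit whose paths are all significant is a fixed point
  again <- prune_paths(pruned, d, alpha = 0.05)
  expect_identical(again$paths, pruned$paths)
})

test_that("initial DAG wiring follows the term/mediator/outcome roles", {
  em <- list(response = "Y_MRS", terms = c("ZR^2", "ZR:PR"))
  class(em) <- "effect_model"
  dag <- build_initial_dag(list(em), list(Y_MRS = "NFkB_L"))
  expect_setequal(dag$nodes, c("ZR^2", "ZR:PR", "NFkB_L", "Y_MRS"))
  e <- paste(dag$edges$from, dag$edges$to)
  expect_setequal(e, c("ZR^2 Y_MRS", "ZR:PR Y_MRS", "ZR^2 NFkB_L",
                       "ZR:PR NFkB_L", "NFkB_L Y_MRS"))
  expect_identical(unname(dag$roles[c("ZR^2", "NFkB_L", "Y_MRS")]),
                   c("exogenous", "mediator", "outcome"))
  # no mediators: direct edges only
  dag0 <- build_initial_dag(list(em))
  expect_equal(nrow(dag0$edges), 2)
  # name collision between a term and a mediator is rejected
  expect_error(build_initial_dag(list(em), list(Y_MRS = "ZR^2")), "collision")
})
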