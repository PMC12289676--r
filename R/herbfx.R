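#' Polynomial term expansion over herb doses
#'
#' Builds the design matrix of linear, quadratic and pairwise interaction
#' terms over the herb doses: for `k` herbs there are `k + k + choose(k, 2)`
#' columns (27 for six herbs), ordered linear, then quadratic, then
#' interactions. Doses are optionally Z-scored per herb before expansion so
#' that quadratic and interaction terms are formed on a common scale;
#' expanded columns can additionally be Z-scored for penalised fitting.
#'
#' Column naming: `ZR`, `ZR^2`, `ZR:PR` (interaction herbs kept in the input
#' column order, first before second).
#'
#' @param doses a `"dose_matrix"` or a plain numeric matrix/data.frame of
#'   doses (runs x herbs, named columns).
#' @param scale_doses Z-score each dose column before expansion (default
#'   TRUE).
#' @param scale_terms Z-score each expanded column (default FALSE; the SPRA
#'   driver turns this on).
#' @return numeric matrix, rows as in `doses`, one column per term, with a
#'   `"terms"` attribute (data.frame: term, kind, herb1, herb2).
#' @export
expand_poly_terms <- function(doses, scale_doses = TRUE, scale_terms = FALSE) {
  d <- if (inherits(doses, "dose_matrix")) doses$doses else as.matrix(doses)
  herbs <- colnames(d)
  if (is.null(herbs)) stop("dose columns must be named")
  if (anyDuplicated(herbs)) stop("duplicate herb names in dose matrix")
  if (ncol(d) < 2) stop("polynomial expansion needs at least 2 herbs")
  if (scale_doses) d <- apply(d, 2, zscore)
  x <- poly_columns(d)
  if (scale_terms) {
    tn <- attr(x, "terms")
    x2 <- apply(x, 2, zscore)
    attr(x2, "terms") <- tn
    x <- x2
  }
  x
}

# raw linear/quadratic/interaction columns from a (possibly pre-scaled)
# dose matrix; shared by the SPRA expansion and the study simulator
poly_columns <- function(d) {
  herbs <- colnames(d)
  k <- length(herbs)
  pairs <- utils::combn(k, 2)
  terms <- data.frame(
    term = c(herbs,
             paste0(herbs, "^2"),
             paste0(herbs[pairs[1, ]], ":", herbs[pairs[2, ]])),
    kind = rep(c("linear", "quad", "inter"), c(k, k, ncol(pairs))),
    herb1 = c(herbs, herbs, herbs[pairs[1, ]]),
    herb2 = c(rep(NA, 2 * k), herbs[pairs[2, ]]),
    stringsAsFactors = FALSE
  )
  x <- cbind(d, d^2,
             d[, pairs[1, ], drop = FALSE] * d[, pairs[2, ], drop = FALSE])
  colnames(x) <- terms$term
  attr(x, "terms") <- terms
  x
}

#' Per-run response means
#'
#' The response modelled against the design is the mean of a pharmacological
#' indicator over the animals of each uniform-design formulation run.
#'
#' @param animals data.frame with a `run` column (`"run1"`..`"runN"` or run
#'   ids matching the dose matrix rows; non-design animals carry `NA` or
#'   another value) and the response column.
#' @param response name of the response column.
#' @param runs optional character vector giving the run order (defaults to
#'   the sorted unique design runs present).
#' @return named numeric vector, one mean per run, in `runs` order.
#' @export
run_means <- function(animals, response, runs = NULL) {
  stopifnot(response %in% names(animals), "run" %in% names(animals))
  keep <- !is.na(animals$run) & animals$run != ""
  a <- animals[keep, , drop = FALSE]
  if (is.null(runs)) runs <- sort(unique(a$run))
  counts <- table(factor(a$run, levels = runs))
  if (any(counts == 0)) {
    stop(sprintf("run(s) with zero animals: %s",
                 paste(names(counts)[counts == 0], collapse = ", ")))
  }
  out <- tapply(a[[response]], factor(a$run, levels = runs), mean)
  stats::setNames(as.numeric(out), runs)
}

#' LASSO screening of polynomial terms
#'
#' Cross-validated LASSO over the standardized term matrix; terms with a
#' nonzero coefficient at the penalty minimising the CV error survive. With
#' fewer observations than the requested fold count the screen falls back to
#' leave-one-out CV (the only stable choice at n = 7 runs). Fold assignment
#' is fixed from `seed`, making the screen deterministic.
#'
#' @param x standardized term matrix (n x p).
#' @param y response vector.
#' @param nfolds requested fold count (default 10; capped at n by LOO
#'   fallback).
#' @param seed integer seed fixing the fold assignment.
#' @return character vector of surviving term names (possibly empty).
#' @export
lasso_screen <- function(x, y, nfolds = 10, seed = 1) {
  n <- length(y)
  stopifnot(nrow(x) == n, n >= 3)
  if (n < nfolds) {
    message(sprintf("lasso_screen: n = %d < %d folds; using leave-one-out CV",
                    n, nfolds))
    foldid <- seq_len(n)
  } else {
    foldid <- withr_seed(seed, sample(rep(seq_len(nfolds), length.out = n)))
  }
  cv <- glmnet::cv.glmnet(x, y, alpha = 1, foldid = foldid,
                          standardize = FALSE, grouped = FALSE)
  beta <- stats::coef(cv, s = "lambda.min")[-1, 1]
  names(beta)[beta != 0]
}

# evaluate expr with a local RNG seed, restoring the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Bidirectional stepwise AIC refinement
#'
#' Starting from the LASSO survivors, iteratively evaluates every single-term
#' addition (restricted to the candidate set) and deletion, applies the move
#' with the best AIC improvement, and stops at a local AIC minimum. The
#' selected-term count is capped at `n - 2` so every reported model retains
#' residual degrees of freedom. Ties in AIC prefer deletion, then the
#' lexicographically first term. The final OLS fit supplies coefficients,
#' R-squared and p-values.
#'
#' @param x term matrix (columns named; typically standardized).
#' @param y response vector.
#' @param candidates term names the search may add (default: all columns of
#'   `x`).
#' @param start term names of the starting model (default: `candidates`).
#' @param max_terms cap on selected terms (default `length(y) - 2`).
#' @param max_iter hard iteration cap (default 50).
#' @return an `"effect_model"`: list with `response`, `terms`, `coefficients`
#'   (raw), `std_coefficients`, `intercept`, `p_values`, `r_squared`,
#'   `model_p`, `aic`, `n`.
#' @export
stepwise_refine <- function(x, y, candidates = colnames(x), start = candidates,
                            max_terms = length(y) - 2L, max_iter = 50L) {
  n <- length(y)
  stopifnot(nrow(x) == n, n > 2)
  x <- as.matrix(x)
  max_terms <- min(max_terms, n - 2L)
  current <- sort(intersect(start, colnames(x)))
  if (length(current) > max_terms) {
    # seed the search within the cap: keep the terms most correlated with y
    r <- abs(apply(x[, current, drop = FALSE], 2, stats::cor, y = y))
    current <- sort(names(sort(r, decreasing = TRUE))[seq_len(max_terms)])
  }
  while (length(current) && is.null(ols_fit(x, y, current))) {
    # rank-deficient start (aliased terms): drop the weakest term
    r <- abs(apply(x[, current, drop = FALSE], 2, stats::cor, y = y))
    current <- setdiff(current, names(which.min(r)))
  }
  aic_of <- function(terms) {
    fit <- ols_fit(x, y, terms)
    if (is.null(fit)) return(Inf)
    stats::AIC(fit)
  }
  best_aic <- aic_of(current)
  for (iter in seq_len(max_iter)) {
    moves <- list()
    for (tm in sort(current)) {              # deletions first (tie preference)
      moves[[length(moves) + 1L]] <-
        list(terms = setdiff(current, tm), what = "del", term = tm)
    }
    if (length(current) < max_terms) {
      for (tm in sort(setdiff(candidates, current))) {
        moves[[length(moves) + 1L]] <-
          list(terms = sort(c(current, tm)), what = "add", term = tm)
      }
    }
    if (!length(moves)) break
    aics <- vapply(moves, function(m) aic_of(m$terms), numeric(1))
    if (min(aics) >= best_aic - 1e-10) break   # local minimum
    pick <- moves[[which.min(aics)]]
    current <- pick$terms
    best_aic <- min(aics)
  }
  effect_model(x, y, current)
}

ols_fit <- function(x, y, terms) {
  if (length(terms) == 0) {
    return(stats::lm(y ~ 1))
  }
  df <- data.frame(y = y, x[, terms, drop = FALSE], check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  if (anyNA(stats::coef(fit))) return(NULL)   # singular selection
  fit
}

effect_model <- function(x, y, terms, response = "y") {
  fit <- ols_fit(x, y, terms)
  if (is.null(fit)) {
    stop(sprintf("singular design for terms: %s", paste(terms, collapse = ", ")))
  }
  sm <- summary(fit)
  cf <- stats::coef(sm)
  if (length(terms)) {
    co <- cf[-1, 1]
    pv <- cf[-1, 4]
    names(co) <- names(pv) <- terms
    sdx <- apply(x[, terms, drop = FALSE], 2, stats::sd)
    std <- co * sdx / stats::sd(y)
    r2 <- sm$r.squared
    fstat <- sm$fstatistic
    model_p <- if (is.null(fstat)) NA_real_ else {
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    }
  } else {
    co <- pv <- std <- stats::setNames(numeric(0), character(0))
    r2 <- 0
    model_p <- NA_real_
  }
  structure(
    list(response = response, terms = terms,
         intercept = unname(stats::coef(fit)[1]),
         coefficients = co, std_coefficients = std, p_values = pv,
         r_squared = r2, model_p = unname(model_p),
         aic = stats::AIC(fit), n = length(y)),
    class = "effect_model"
  )
}

#' @export
print.effect_model <- function(x, ...) {
  cat(sprintf("Effect model for %s: %d term(s), R^2 = %.4f, n = %d\n",
              x$response, length(x$terms), x$r_squared, x$n))
  if (length(x$terms)) {
    print(data.frame(term = x$terms,
                     beta = unname(x$coefficients),
                     std_beta = unname(x$std_coefficients),
                     p = unname(x$p_values)))
  }
  invisible(x)
}

#' Stepwise polynomial regression analysis (SPRA)
#'
#' The dose-effect driver: per-run means of the response are regressed on the
#' polynomial herb-dose terms. Doses are Z-scored, expanded into linear /
#' quadratic / interaction terms, and the term columns Z-scored again; LASSO
#' (leave-one-out CV at n = 7 runs) screens candidate terms and bidirectional
#' stepwise AIC refinement produces the final model. Standardized
#' coefficients carry the sign and magnitude semantics of the radar-chart
#' displays (negative values = suppressive effects).
#'
#' @param doses a `"dose_matrix"` (rows = design runs).
#' @param animals per-animal indicator table with `run` and the response
#'   column.
#' @param response response column name (e.g. a composite score `Y_MRS`).
#' @param lasso run the LASSO screen before stepwise (default TRUE).
#' @param seed seed for the CV fold assignment.
#' @return an `"effect_model"` for `response`.
#' @export
fit_spra <- function(doses, animals, response, lasso = TRUE, seed = 1) {
  stopifnot(inherits(doses, "dose_matrix"))
  runs <- rownames(doses$doses)
  y <- run_means(animals, response, runs = runs)
  x <- expand_poly_terms(doses, scale_doses = TRUE, scale_terms = TRUE)
  candidates <- colnames(x)
  if (lasso) {
    survivors <- lasso_screen(x, y, seed = seed)
    if (length(survivors) == 0) {
      # null screen: report the intercept-only model
      em <- effect_model(x, y, character(0), response = response)
      return(em)
    }
  } else {
    survivors <- candidates
  }
  em <- stepwise_refine(x, y, candidates = survivors, start = survivors)
  em$response <- response
  em
}

#' Export an effect model as a tidy data.frame
#'
#' @param model an `"effect_model"`.
#' @return data.frame with columns term, beta, std_beta, p.
#' @export
effect_model_table <- function(model) {
  stopifnot(inherits(model, "effect_model"))
  data.frame(
    response = model$response,
    term = model$terms,
    beta = unname(model$coefficients),
    std_beta = unname(model$std_coefficients),
    p = unname(model$p_values),
    stringsAsFactors = FALSE
  )
}
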