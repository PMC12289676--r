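#' NIPALS partial least squares regression
#'
#' Fits a PLS2 regression of `Y` (n x m) on `X` (n x p) by the NIPALS
#' algorithm with X-deflation: both blocks are autoscaled (column mean 0,
#' sample SD 1) internally; for each component the weight/score/loading
#' iteration runs until the X-score changes by less than `tol` (or `max_iter`
#' iterations, an error). X-weights are unit-norm and successive X-scores are
#' mutually orthogonal. Per-component explained Y-variance is the reduction
#' in deflated-Y sum of squares relative to the autoscaled total.
#'
#' @param x predictor matrix (n x p), named columns.
#' @param y response matrix or vector (n x m).
#' @param ncomp number of latent components, at most `min(n - 1, p)`.
#' @param tol convergence tolerance on the score update (default 1e-10).
#' @param max_iter iteration cap per component (default 2000).
#' @return object of class `"plsr_fit"`: list with `weights` (p x A, unit
#'   columns), `x_loadings` (p x A), `scores` (n x A), `y_loadings` (m x A),
#'   `coefficients` (p x m, autoscaled), `coefficients_raw` (original
#'   scale, with `intercept`), `explained_y` (length A), `ncomp`, scaling
#'   vectors, and dimension names.
#' @export
nipals_plsr <- function(x, y, ncomp, tol = 1e-10, max_iter = 2000L) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  stopifnot(nrow(y) == n, n >= 2)
  p <- ncol(x)
  m <- ncol(y)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(p))
  if (is.null(colnames(y))) colnames(y) <- paste0("Y", seq_len(m))
  if (ncomp > min(n - 1, p)) {
    stop(sprintf("ncomp = %d exceeds min(n - 1, p) = %d", ncomp, min(n - 1, p)))
  }
  xm <- colMeans(x); xs <- apply(x, 2, stats::sd)
  ym <- colMeans(y); ys <- apply(y, 2, stats::sd)
  bad <- c(colnames(x)[xs == 0], colnames(y)[ys == 0])
  if (length(bad)) {
    stop(sprintf("zero-variance column(s): %s", paste(bad, collapse = ", ")))
  }
  xa <- sweep(sweep(x, 2, xm), 2, xs, "/")
  ya <- sweep(sweep(y, 2, ym), 2, ys, "/")
  ss_y_total <- sum(ya^2)

  W <- matrix(0, p, ncomp, dimnames = list(colnames(x), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(colnames(x), NULL))
  Tt <- matrix(0, n, ncomp)
  Q <- matrix(0, m, ncomp, dimnames = list(colnames(y), NULL))
  expl <- numeric(ncomp)
  Xd <- xa; Yd <- ya
  for (a in seq_len(ncomp)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xd, u))
      w <- w / sqrt(sum(w^2))
      tt <- drop(Xd %*% w)
      q <- drop(crossprod(Yd, tt)) / sum(tt^2)
      if (m == 1) { t_new <- tt; break }
      u <- drop(Yd %*% q) / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) <
            tol * max(1, sqrt(sum(tt^2)))) { t_new <- tt; break }
      t_old <- tt
      if (it == max_iter) {
        stop(sprintf("NIPALS did not converge in %d iterations (component %d)",
                     max_iter, a))
      }
      t_new <- tt
    }
    pa <- drop(crossprod(Xd, t_new)) / sum(t_new^2)
    ss_before <- sum(Yd^2)
    Yd <- Yd - tcrossprod(t_new, q)
    ss_after <- sum(Yd^2)
    Xd <- Xd - tcrossprod(t_new, pa)
    W[, a] <- w; P[, a] <- pa; Tt[, a] <- t_new; Q[, a] <- q
    expl[a] <- (ss_before - ss_after) / ss_y_total
  }
  # B = W (P'W)^-1 Q' on the autoscaled scale
  B <- W %*% solve(crossprod(P, W), t(Q))
  dimnames(B) <- list(colnames(x), colnames(y))
  # back-transform to the raw scale
  Braw <- sweep(sweep(B, 2, ys, "*"), 1, xs, "/")
  intercept <- ym - drop(crossprod(Braw, xm))
  structure(
    list(weights = W, x_loadings = P, scores = Tt, y_loadings = Q,
         coefficients = B, coefficients_raw = Braw, intercept = intercept,
         explained_y = expl, ncomp = ncomp,
         x_center = xm, x_scale = xs, y_center = ym, y_scale = ys,
         n = n),
    class = "plsr_fit"
  )
}

#' Predict from a NIPALS PLSR fit
#'
#' @param object a `"plsr_fit"`.
#' @param newdata predictor matrix on the raw scale (default: refit data not
#'   stored; must be supplied).
#' @param ... unused.
#' @return fitted response matrix on the raw scale.
#' @export
predict.plsr_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  sweep(x %*% object$coefficients_raw, 2, object$intercept, "+")
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat(sprintf("NIPALS PLSR: %d components, %d predictors, %d response(s), n = %d\n",
              x$ncomp, nrow(x$weights), nrow(x$y_loadings), x$n))
  cat("  explained Y-variance per component:",
      paste(sprintf("%.3f", x$explained_y), collapse = ", "), "\n")
  invisible(x)
}

#' Select the number of PLSR components
#'
#' Smallest number of components whose cumulative explained Y-variance
#' exceeds `threshold` (default 0.80). If the threshold is never exceeded
#' within `max_comp` components, `max_comp` is returned with a warning.
#'
#' @param x,y data blocks as in [nipals_plsr()].
#' @param threshold cumulative explained-variance threshold in (0, 1).
#' @param max_comp largest component count tried (default
#'   `min(n - 1, p, 10)`).
#' @return integer component count.
#' @export
select_ncomp <- function(x, y, threshold = 0.80,
                         max_comp = min(nrow(as.matrix(x)) - 1,
                                        ncol(as.matrix(x)), 10L)) {
  stopifnot(threshold > 0, threshold < 1)
  # fit incrementally so no deeper (noise-dominated) components are ever
  # extracted than the rule requires
  cum <- 0
  for (a in seq_len(max_comp)) {
    fit <- nipals_plsr(x, y, ncomp = a)
    cum <- cumsum(fit$explained_y)
    if (cum[a] > threshold) return(as.integer(a))
  }
  max_comp <- as.integer(max_comp)
  warning(sprintf(
    "cumulative explained Y-variance (%.3f) never exceeded %.2f; using max_comp = %d",
    cum[max_comp], threshold, max_comp))
  max_comp
}


#' Variable importance in projection
#'
#' Standard VIP scores: `VIP_j = sqrt(p * sum_a SS_a * w_ja^2 / sum_a SS_a)`
#' where `SS_a` is the Y-variance explained by component `a` and the weight
#' columns are unit-norm. The mean squared VIP is exactly 1, so VIP > 1
#' flags predictors contributing more than an average share.
#'
#' @param fit a `"plsr_fit"`.
#' @return named nonnegative vector of length p.
#' @export
vip <- function(fit) {
  stopifnot(inherits(fit, "plsr_fit"))
  ss <- fit$explained_y
  if (sum(ss) <= 0) stop("undefined VIP: zero total explained Y-variance")
  p <- nrow(fit$weights)
  w2 <- fit$weights^2            # columns already unit-norm
  v <- sqrt(p * drop(w2 %*% ss) / sum(ss))
  stats::setNames(v, rownames(fit$weights))
}

#' Screen predictors by VIP
#'
#' @param fit a `"plsr_fit"`.
#' @param threshold VIP cutoff (strict inequality; default 1.0).
#' @return character vector of selected predictor names, by descending VIP.
#' @export
screen_vip <- function(fit, threshold = 1.0) {
  v <- vip(fit)
  sel <- v[v > threshold]
  names(sort(sel, decreasing = TRUE))
}
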