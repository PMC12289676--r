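#' Spearman rank-correlation matrix
#'
#' Rank correlations (rank-then-Pearson with average ranks for ties) between
#' two variable sets, with p-values from the t approximation on `n - 2`
#' degrees of freedom and optional Benjamini-Hochberg adjustment across the
#' whole matrix. Constant variables yield `NA` cells rather than an error.
#'
#' @param table data.frame with the variables as columns.
#' @param rows,cols character vectors of variable names (default: all
#'   numeric columns for both).
#' @param adjust apply BH adjustment across all tested pairs (default FALSE,
#'   matching an unadjusted presentation; `p_adj` is reported either way).
#' @return object of class `"cor_matrix"`: list with `rho`, `p`, `p_adj`
#'   matrices (rows x cols) and `n`.
#' @export
spearman_matrix <- function(table, rows = NULL, cols = NULL, adjust = FALSE) {
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  if (is.null(rows)) rows <- num
  if (is.null(cols)) cols <- num
  stopifnot(all(rows %in% names(table)), all(cols %in% names(table)))
  n <- nrow(table)
  if (n < 4) stop("spearman_matrix needs at least 4 observations")
  rho <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(rows, cols))
  p <- rho
  for (a in rows) {
    for (b in cols) {
      xa <- table[[a]]; xb <- table[[b]]
      if (stats::sd(xa) == 0 || stats::sd(xb) == 0) next  # flagged missing
      r <- stats::cor(xa, xb, method = "spearman")
      rho[a, b] <- r
      p[a, b] <- if (abs(r) >= 1) 0 else {
        tt <- r * sqrt((n - 2) / (1 - r^2))
        2 * stats::pt(-abs(tt), df = n - 2)
      }
    }
  }
  p_adj <- p
  tested <- !is.na(p)
  p_adj[tested] <- stats::p.adjust(p[tested], method = "BH")
  structure(list(rho = rho, p = p, p_adj = if (adjust) p_adj else p_adj,
                 n = n, adjusted = adjust),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat(sprintf("Spearman correlation matrix (%d x %d, n = %d)\n",
              nrow(x$rho), ncol(x$rho), x$n))
  print(round(x$rho, 3))
  invisible(x)
}

#' Long-format correlation table
#'
#' @param x a `"cor_matrix"`.
#' @return data.frame with columns var1, var2, rho, p, p_adj, n.
#' @export
cor_matrix_long <- function(x) {
  stopifnot(inherits(x, "cor_matrix"))
  g <- expand.grid(var1 = rownames(x$rho), var2 = colnames(x$rho),
                   stringsAsFactors = FALSE)
  data.frame(g,
             rho = as.vector(x$rho),
             p = as.vector(x$p),
             p_adj = as.vector(x$p_adj),
             n = x$n)
}
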