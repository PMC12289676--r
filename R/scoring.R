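#' Macroscopic ulcer index
#'
#' Scores each hemorrhagic lesion on the 0-5 macroscopic scale by length band
#' (punctate lesions score 1; length < 2 mm scores 2; 2-3 mm scores 3;
#' above 3 up to 4 mm scores 4; above 4 mm scores 5), doubles the score when
#' the erosion width exceeds 1 mm, and sums lesion scores into the ulcer
#' index (UI). An empty lesion list scores 0 (no lesions). Length bands are
#' closed on the left of each stated range.
#'
#' @param lesions data.frame with columns `length_mm`, `width_mm`, and an
#'   optional logical `punctate` (small round lesions; defaults to
#'   `length_mm < 1`). Zero rows is a valid "no lesions" record.
#' @return integer ulcer index (sum of lesion scores).
#' @examples
#' ulcer_index(data.frame(length_mm = c(1.5, 3.5), width_mm = c(0.4, 1.2)))
#' @export
ulcer_index <- function(lesions) {
  if (is.null(lesions) || nrow(lesions) == 0) return(0L)
  stopifnot(all(c("length_mm", "width_mm") %in% names(lesions)))
  len <- lesions$length_mm
  wid <- lesions$width_mm
  if (any(len < 0) || any(wid < 0)) {
    stop("lesion dimensions must be nonnegative")
  }
  punct <- if ("punctate" %in% names(lesions)) {
    as.logical(lesions$punctate)
  } else {
    len < 1
  }
  score <- ifelse(punct, 1L,
           ifelse(len < 2, 2L,
           ifelse(len <= 3, 3L,
           ifelse(len <= 4, 4L, 5L))))
  score <- ifelse(wid > 1, 2L * score, score)
  as.integer(sum(score))
}

#' Min-max normalization with indicator orientation
#'
#' Rescales an indicator to `[0, 1]` so that 1 is always the favorable end:
#' positive indicators (higher is better) map as
#' `(W - Wmin) / (Wmax - Wmin)`; negative indicators (lower is better) map as
#' `(Wmax - W) / (Wmax - Wmin)`.
#'
#' @param values numeric vector of raw indicator values `Wj`.
#' @param orientation `"positive"` or `"negative"`.
#' @return numeric vector in `[0, 1]` with extremes exactly 0 and 1.
#' @export
minmax_normalize <- function(values, orientation = c("positive", "negative")) {
  orientation <- match.arg(orientation)
  wmin <- min(values)
  wmax <- max(values)
  if (wmax <= wmin) {
    stop("degenerate column: constant values cannot be min-max normalized")
  }
  if (orientation == "positive") {
    (values - wmin) / (wmax - wmin)
  } else {
    (wmax - values) / (wmax - wmin)
  }
}

#' Entropy-weight-method weights
#'
#' Shannon-entropy objective weighting: with normalized indicator matrix
#' `x` (samples x indicators, entries >= 0), proportions
#' `p_ij = x_ij / sum_i x_ij`, entropy `e_j = -(1/ln n) sum_i p_ij ln p_ij`
#' (with `0 ln 0 = 0`), and weights `E_j = (1 - e_j) / sum_k (1 - e_k)`.
#' A constant (zero-dispersion) column carries no information and gets
#' weight 0.
#'
#' @param normalized numeric matrix, samples in rows, indicators in columns,
#'   entries nonnegative (typically min-max normalized).
#' @return weight vector `Ej`, nonnegative, summing to 1.
#' @export
entropy_weights <- function(normalized) {
  x <- as.matrix(normalized)
  n <- nrow(x)
  if (n < 2) stop("entropy weights need at least 2 samples")
  if (any(x < 0)) stop("entropy weights need nonnegative entries")
  e <- apply(x, 2, function(col) {
    s <- sum(col)
    if (s == 0) return(1)          # all-zero column: maximal entropy by convention
    p <- col / s
    plogp <- ifelse(p > 0, p * log(p), 0)
    -sum(plogp) / log(n)
  })
  d <- 1 - e
  d[abs(d) < 1e-12] <- 0      # constant columns: entropy 1 up to rounding
  if (all(d == 0)) {
    stop("undefined weights: every column is constant (zero information)")
  }
  w <- d / sum(d)
  names(w) <- colnames(x)
  w
}

#' Composite index specification
#'
#' Defines a named composite efficacy index as a weighted sum of min-max
#' normalized component indicators. Orientation marks whether higher
#' (`"positive"`) or lower (`"negative"`) raw values are favorable. When
#' `weights` is `NULL` the entropy weight method supplies them at scoring
#' time.
#'
#' @param name composite name (e.g. `"MRS"`).
#' @param components character vector of indicator column names.
#' @param orientations `"positive"`/`"negative"` per component (recycled if
#'   length 1).
#' @param weights optional fixed weights `Ej` (nonnegative, summing to 1
#'   within 1e-4).
#' @return object of class `"composite_spec"`.
#' @export
composite_spec <- function(name, components, orientations, weights = NULL) {
  if (length(orientations) == 1) {
    orientations <- rep(orientations, length(components))
  }
  stopifnot(length(orientations) == length(components),
            all(orientations %in% c("positive", "negative")))
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(components), all(weights >= 0))
    if (abs(sum(weights) - 1) > 1e-4) {
      stop("supplied weights must sum to 1")
    }
  }
  structure(
    list(name = name, components = components,
         orientations = stats::setNames(orientations, components),
         weights = if (is.null(weights)) NULL else
           stats::setNames(weights, components)),
    class = "composite_spec"
  )
}

#' @export
print.composite_spec <- function(x, ...) {
  cat(sprintf("Composite index Y_%s: %s\n", x$name,
              paste(sprintf("%s (%s)", x$components, x$orientations),
                    collapse = ", ")))
  if (!is.null(x$weights)) {
    cat("  fixed weights:", paste(sprintf("%.4f", x$weights), collapse = ", "),
        "\n")
  } else {
    cat("  weights: entropy weight method at scoring time\n")
  }
  invisible(x)
}

#' Score a composite efficacy index
#'
#' Each component is min-max normalized with its orientation over the rows of
#' `table`; the composite is `Y_s = sum_j Ej * normalized_sj`. Weights come
#' from the spec when fixed, otherwise from [entropy_weights()] on the
#' normalized component matrix.
#'
#' @param table data.frame of per-sample indicator values containing every
#'   spec component.
#' @param spec a `"composite_spec"`.
#' @return list with `scores` (numeric vector, one per row of `table`, in
#'   `[0, 1]`) and `weights` (the `Ej` used).
#' @export
composite_index <- function(table, spec) {
  stopifnot(inherits(spec, "composite_spec"))
  missing_cols <- setdiff(spec$components, names(table))
  if (length(missing_cols)) {
    stop(sprintf("composite %s: missing component column(s): %s",
                 spec$name, paste(missing_cols, collapse = ", ")))
  }
  norm <- vapply(spec$components, function(cn) {
    minmax_normalize(table[[cn]], spec$orientations[[cn]])
  }, numeric(nrow(table)))
  dim(norm) <- c(nrow(table), length(spec$components))
  colnames(norm) <- spec$components
  w <- if (is.null(spec$weights)) entropy_weights(norm) else spec$weights
  scores <- drop(norm %*% w[spec$components])
  list(scores = scores, weights = w)
}

#' Z-score standardization
#'
#' Centers to mean 0 and scales to sample standard deviation 1.
#'
#' @param values numeric vector, length >= 2, nonconstant.
#' @return standardized vector.
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("zscore needs at least 2 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("degenerate column: zero variance")
  (values - mean(values)) / s
}

#' Published composite index specifications
#'
#' The six composite efficacy indices with their published entropy weights:
#' Y_MRS (ulcer index UI + histology score HS; damage scores, lower
#' favorable), Y_RF (EGF + EGFR; higher favorable), Y_GIC / Y_SIC / Y_HIC
#' (gastric / serum / hepatic inflammatory cytokines; lower favorable) and
#' Y_LF (ALT + AST + TBIL; lower favorable).
#'
#' @return named list of `"composite_spec"` objects.
#' @export
published_composites <- function() {
  list(
    MRS = composite_spec("MRS", c("UI", "HS"), "negative",
                         c(0.5269, 0.4731)),
    RF  = composite_spec("RF", c("EGF", "EGFR"), "positive",
                         c(0.6304, 0.3696)),
    GIC = composite_spec("GIC", c("IL1b_G", "IL6_G", "TNFa_G"), "negative",
                         c(0.2373, 0.3023, 0.4604)),
    SIC = composite_spec("SIC", c("IL1b_S", "IL6_S", "TNFa_S"), "negative",
                         c(0.3627, 0.4121, 0.2252)),
    LF  = composite_spec("LF", c("ALT", "AST", "TBIL"), "negative",
                         c(0.3444, 0.3246, 0.3310)),
    HIC = composite_spec("HIC", c("IL6_L", "TNFa_L"), "negative",
                         c(0.5424, 0.4576))
  )
}
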