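#' Good-lattice-point uniform design
#'
#' Constructs a U_n(n^s) uniform design table by the good-lattice-point (GLP)
#' rule: the level of run `i` for the factor with generator `g` is
#' `((i * g - 1) mod n_runs) + 1`, so every column is a permutation of
#' `1..n_runs`. Candidate generators are the integers in `[1, n_runs)` coprime
#' with `n_runs`; when `generators` is omitted, the subset of size `n_factors`
#' minimising the centered L2 discrepancy of the resulting table is chosen
#' (ties broken by the lexicographically smallest generator set).
#'
#' @param n_runs number of runs (and levels per factor), at least 2.
#' @param n_factors number of factors; at most the count of integers in
#'   `[1, n_runs)` coprime with `n_runs` (6 for `n_runs = 7`).
#' @param generators optional integer vector of distinct generators, each
#'   coprime with `n_runs`, one per factor.
#' @return An object of class `"ud_design"`: a list with `levels` (integer
#'   matrix, runs x factors), `generators`, `n_runs`, `n_factors`.
#' @examples
#' glp_design(7, 6)
#' @export
glp_design <- function(n_runs, n_factors, generators = NULL) {
  stopifnot(length(n_runs) == 1, length(n_factors) == 1)
  n_runs <- as.integer(n_runs)
  n_factors <- as.integer(n_factors)
  if (n_runs < 2L) stop("n_runs must be at least 2")
  if (n_factors < 1L) stop("n_factors must be at least 1")
  candidates <- which(vapply(seq_len(n_runs - 1L), function(g) {
    gcd(g, n_runs) == 1L
  }, logical(1)))
  if (n_factors > length(candidates)) {
    stop(sprintf(
      "n_factors = %d exceeds capacity: at most %d factors for n_runs = %d",
      n_factors, length(candidates), n_runs
    ))
  }
  if (is.null(generators)) {
    generators <- select_generators(n_runs, n_factors, candidates)
  } else {
    generators <- as.integer(generators)
    if (length(generators) != n_factors) {
      stop("length(generators) must equal n_factors")
    }
    if (anyDuplicated(generators)) stop("generators must be distinct")
    bad <- generators[vapply(generators, function(g) gcd(g, n_runs) != 1L,
                             logical(1))]
    if (length(bad)) {
      stop(sprintf("generator(s) not coprime with n_runs = %d: %s",
                   n_runs, paste(bad, collapse = ", ")))
    }
  }
  levels <- glp_levels(n_runs, generators)
  structure(
    list(levels = levels, generators = generators,
         n_runs = n_runs, n_factors = n_factors),
    class = "ud_design"
  )
}

gcd <- function(a, b) {
  while (b != 0L) {
    tmp <- a %% b
    a <- b
    b <- tmp
  }
  abs(a)
}

glp_levels <- function(n_runs, generators) {
  i <- seq_len(n_runs)
  levels <- vapply(generators, function(g) ((i * g - 1L) %% n_runs) + 1L,
                   integer(n_runs))
  dim(levels) <- c(n_runs, length(generators))
  dimnames(levels) <- list(
    paste0("run", i),
    paste0("F", seq_along(generators))
  )
  levels
}

select_generators <- function(n_runs, n_factors, candidates) {
  subsets <- utils::combn(candidates, n_factors, simplify = FALSE)
  cd2 <- vapply(subsets, function(g) {
    cd2_from_levels(glp_levels(n_runs, g), n_runs)
  }, numeric(1))
  # lexicographic tie-break: combn emits subsets in lexicographic order,
  # which.min returns the first minimiser
  as.integer(subsets[[which.min(cd2)]])
}

#' Centered L2 discrepancy of a design table
#'
#' Uniformity criterion of Hickernell's closed form, computed on levels mapped
#' to `(level - 0.5) / n_runs` in the unit cube. Lower values indicate a more
#' uniform spread of the design points.
#'
#' @param table a `"ud_design"` object from [glp_design()].
#' @return the squared centered L2 discrepancy, a nonnegative scalar.
#' @export
centered_l2_discrepancy <- function(table) {
  stopifnot(inherits(table, "ud_design"))
  if (length(table$levels) == 0) stop("empty design table")
  cd2_from_levels(table$levels, table$n_runs)
}

cd2_from_levels <- function(levels, n_runs) {
  u <- (levels - 0.5) / n_runs
  n <- nrow(u)
  s <- ncol(u)
  a <- abs(u - 0.5)
  term1 <- (13 / 12)^s
  term2 <- (2 / n) * sum(apply(1 + 0.5 * a - 0.5 * a^2, 1, prod))
  # pairwise product term via per-dimension outer sums
  m <- matrix(1, n, n)
  for (j in seq_len(s)) {
    aj <- a[, j]
    m <- m * (1 + 0.5 * outer(aj, aj, "+") -
                0.5 * abs(outer(u[, j], u[, j], "-")))
  }
  term3 <- sum(m) / n^2
  term1 - term2 + term3
}

#' Map design levels to herb doses
#'
#' Linear, equally spaced mapping of levels `1..n_runs` onto per-herb dose
#' ranges: `dose = low + (level - 1) / (n_runs - 1) * (high - low)` so level 1
#' sits at the low end and level `n_runs` at the high end of each range.
#'
#' @param table a `"ud_design"` object.
#' @param dose_ranges a named list (or 2-row matrix / data.frame with rows
#'   `low`, `high`) of `c(low, high)` gram ranges, one per factor; names become
#'   the herb names.
#' @return An object of class `"dose_matrix"`: list with `doses` (numeric
#'   matrix runs x herbs, grams), `herb_names`, `dose_ranges`.
#' @export
scale_doses <- function(table, dose_ranges) {
  stopifnot(inherits(table, "ud_design"))
  if (is.data.frame(dose_ranges)) dose_ranges <- as.list(dose_ranges)
  if (is.matrix(dose_ranges)) {
    dose_ranges <- lapply(seq_len(ncol(dose_ranges)),
                          function(j) dose_ranges[, j])
    names(dose_ranges) <- colnames(dose_ranges)
  }
  if (length(dose_ranges) != table$n_factors) {
    stop(sprintf("expected %d dose ranges, got %d",
                 table$n_factors, length(dose_ranges)))
  }
  herb_names <- names(dose_ranges)
  if (is.null(herb_names)) {
    herb_names <- colnames(table$levels)
    names(dose_ranges) <- herb_names
  }
  for (r in dose_ranges) {
    if (length(r) != 2 || !is.numeric(r) || r[1] >= r[2]) {
      stop("each dose range must be a numeric c(low, high) with low < high")
    }
  }
  frac <- (table$levels - 1) / (table$n_runs - 1)
  doses <- vapply(seq_along(dose_ranges), function(j) {
    r <- dose_ranges[[j]]
    r[1] + frac[, j] * (r[2] - r[1])
  }, numeric(table$n_runs))
  dim(doses) <- dim(table$levels)
  dimnames(doses) <- list(rownames(table$levels), herb_names)
  structure(
    list(doses = doses, herb_names = herb_names, dose_ranges = dose_ranges),
    class = "dose_matrix"
  )
}

#' Default herb dose ranges
#'
#' The reference six-herb formulation uses ZR 4 g, GCR 6 g, LAR 9 g, CR 6 g,
#' FF 4 g and PR 6 g; default design ranges span that reference dose +/- 50%.
#'
#' @return named list of `c(low, high)` gram ranges for the six herbs.
#' @export
default_dose_ranges <- function() {
  ref <- mhwp_reference_doses()
  lapply(ref, function(d) c(0.5 * d, 1.5 * d))
}

#' Reference formulation doses (grams per daily human dose)
#' @return named numeric vector for the six herbs.
#' @export
mhwp_reference_doses <- function() {
  c(ZR = 4, GCR = 6, LAR = 9, CR = 6, FF = 4, PR = 6)
}

#' Body-surface-area interspecies dose conversion
#'
#' Converts a human daily dose to an animal-equivalent dose per kilogram:
#' `(human_daily_dose_g / human_mass_kg) * factor`. The standard rat
#' conversion factor is 6.3, which maps a 35 g / 70 kg (0.5 g/kg/day) human
#' dose to 3.15 g/kg/day in the rat.
#'
#' @param human_daily_dose_g human daily dose in grams.
#' @param human_mass_kg reference human body mass in kilograms.
#' @param factor BSA-based conversion factor (6.3 for rat).
#' @return animal dose in g per kg body weight per day.
#' @examples
#' bsa_convert(35, 70, 6.3) # 3.15
#' @export
bsa_convert <- function(human_daily_dose_g, human_mass_kg, factor = 6.3) {
  if (any(c(human_daily_dose_g, human_mass_kg, factor) <= 0)) {
    stop("all inputs to bsa_convert must be positive")
  }
  (human_daily_dose_g / human_mass_kg) * factor
}

#' @export
print.ud_design <- function(x, ...) {
  cat(sprintf("Uniform design U_%d(%d^%d), generators: %s\n",
              x$n_runs, x$n_runs, x$n_factors,
              paste(x$generators, collapse = ", ")))
  print(x$levels)
  invisible(x)
}

#' @export
print.dose_matrix <- function(x, ...) {
  cat(sprintf("Dose matrix: %d runs x %d herbs (grams)\n",
              nrow(x$doses), ncol(x$doses)))
  print(round(x$doses, 3))
  invisible(x)
}

#' Write a dose matrix as CSV
#'
#' One row per run with a leading `run` id column and one column per herb.
#'
#' @param x a `"dose_matrix"`.
#' @param path output file path.
#' @export
write_doses_csv <- function(x, path) {
  stopifnot(inherits(x, "dose_matrix"))
  df <- data.frame(run = rownames(x$doses), x$doses, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
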