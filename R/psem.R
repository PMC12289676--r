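#' Construct a mediation path DAG
#'
#' A directed acyclic graph over herb-dose terms (exogenous), mediators and
#' outcomes, stored as an edge list with node roles. Exogenous terms may not
#' receive edges.
#'
#' @param edges data.frame with character columns `from`, `to`.
#' @param roles named character vector mapping every node to
#'   `"exogenous"`, `"mediator"` or `"outcome"`.
#' @return object of class `"path_dag"`: list with `edges`, `nodes`, `roles`,
#'   and a topological order `order`.
#' @export
path_dag <- function(edges, roles) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      stringsAsFactors = FALSE)
  nodes <- union(unique(c(edges$from, edges$to)), names(roles))
  if (!all(nodes %in% names(roles))) {
    stop(sprintf("missing role(s) for node(s): %s",
                 paste(setdiff(nodes, names(roles)), collapse = ", ")))
  }
  stopifnot(all(roles %in% c("exogenous", "mediator", "outcome")))
  exo_with_parents <- intersect(edges$to, names(roles)[roles == "exogenous"])
  if (length(exo_with_parents)) {
    stop(sprintf("exogenous node(s) may not have parents: %s",
                 paste(unique(exo_with_parents), collapse = ", ")))
  }
  ord <- topo_sort(nodes, edges)
  if (is.null(ord)) stop("graph is cyclic: no topological order exists")
  structure(list(edges = edges, nodes = nodes, roles = roles[nodes],
                 order = ord),
            class = "path_dag")
}

topo_sort <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  avail <- sort(nodes[indeg == 0])
  edges_left <- edges
  while (length(avail)) {
    v <- avail[1]               # deterministic: alphabetical among sources
    avail <- avail[-1]
    out <- c(out, v)
    kids <- edges_left$to[edges_left$from == v]
    edges_left <- edges_left[edges_left$from != v, , drop = FALSE]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) avail <- sort(c(avail, k))
    }
  }
  if (length(out) != length(nodes)) return(NULL)
  out
}

dag_parents <- function(dag, node) {
  sort(unique(dag$edges$from[dag$edges$to == node]))
}

#' @export
print.path_dag <- function(x, ...) {
  cat(sprintf("Path DAG: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  for (r in c("exogenous", "mediator", "outcome")) {
    nn <- names(x$roles)[x$roles == r]
    if (length(nn)) cat(sprintf("  %s: %s\n", r, paste(nn, collapse = ", ")))
  }
  if (nrow(x$edges)) {
    cat(paste(sprintf("  %s -> %s", x$edges$from, x$edges$to),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Build the initial mediation DAG
#'
#' Wires the variable-selection results into the starting path model: every
#' selected dose term points at its outcome and at each mediator screened
#' for that outcome; every screened mediator points at the outcome.
#'
#' @param effect_models list of `"effect_model"` objects (one per outcome;
#'   their `response` names the outcome node).
#' @param vip_selected named list: outcome -> character vector of screened
#'   mediator names (may be empty).
#' @return a `"path_dag"`.
#' @export
build_initial_dag <- function(effect_models, vip_selected = list()) {
  edges <- data.frame(from = character(0), to = character(0))
  roles <- character(0)
  for (em in effect_models) {
    out <- em$response
    meds <- vip_selected[[out]]
    if (is.null(meds)) meds <- character(0)
    clash <- intersect(em$terms, meds)
    if (length(clash)) {
      stop(sprintf("name collision between terms and mediators: %s",
                   paste(clash, collapse = ", ")))
    }
    roles[out] <- "outcome"
    for (tm in em$terms) {
      roles[tm] <- "exogenous"
      edges <- rbind(edges, data.frame(from = tm, to = out))
      for (md in meds) edges <- rbind(edges, data.frame(from = tm, to = md))
    }
    for (md in meds) {
      roles[md] <- "mediator"
      edges <- rbind(edges, data.frame(from = md, to = out))
    }
  }
  edges <- unique(edges)
  path_dag(edges, roles)
}

#' D-separation basis set of a DAG
#'
#' Shipley's union basis set: one independence claim per non-adjacent pair
#' of nodes, with the topologically later node as the regression response and
#' the union of both nodes' parents (minus the pair itself) as the
#' conditioning set. Pairs in which both nodes are parentless (exogenous) are
#' excluded: exogenous variables — here the correlated dose terms of the
#' design — are allowed to covary freely, so their associations are not
#' claims the model makes. Claims are emitted in a deterministic order
#' (pairs by topological position).
#'
#' @param dag a `"path_dag"`.
#' @return list of claims, each a list with `x` (regressor of interest),
#'   `y` (response, downstream), `conditioning` (character vector).
#' @export
basis_set <- function(dag) {
  stopifnot(inherits(dag, "path_dag"))
  ord <- dag$order
  adj <- paste(dag$edges$from, dag$edges$to)
  claims <- list()
  if (length(ord) < 2) return(claims)
  for (i in seq_len(length(ord) - 1)) {
    for (j in seq((i + 1), length(ord))) {
      a <- ord[i]; b <- ord[j]        # b is topologically later
      if (paste(a, b) %in% adj || paste(b, a) %in% adj) next
      pa_a <- dag_parents(dag, a)
      pa_b <- dag_parents(dag, b)
      if (length(pa_a) == 0 && length(pa_b) == 0) next  # both exogenous
      cond <- setdiff(union(pa_a, pa_b), c(a, b))
      claims[[length(claims) + 1L]] <-
        list(x = a, y = b, conditioning = cond)
    }
  }
  claims
}

#' Test one independence claim
#'
#' The claim X independent of Y given Z is tested by the two-sided t-test on
#' X's coefficient in the OLS regression of Y on X and the conditioning set
#' (matching the Gaussian component models of the piecewise SEM).
#'
#' @param claim a claim from [basis_set()].
#' @param data data.frame holding every claim variable.
#' @return the p-value.
#' @export
test_claim <- function(claim, data) {
  vars <- unique(c(claim$y, claim$x, claim$conditioning))
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop(sprintf("claim variable(s) absent from data: %s",
                 paste(miss, collapse = ", ")))
  }
  cond <- setdiff(unique(claim$conditioning), c(claim$x, claim$y))
  rhs <- c(claim$x, cond)
  df <- data[, c(claim$y, rhs), drop = FALSE]
  if (nrow(df) <= length(rhs) + 2) {
    stop("too few observations for the conditioning set")
  }
  fit <- stats::lm(stats::reformulate(sprintf("`%s`", rhs),
                                      response = sprintf("`%s`", claim$y)),
                   data = df)
  cf <- stats::coef(summary(fit))
  row <- rownames(cf) == sprintf("`%s`", claim$x) |
         rownames(cf) == claim$x
  if (!any(row)) stop(sprintf("singular design: %s dropped", claim$x))
  cf[which(row)[1], 4]
}

#' Fisher's C statistic
#'
#' Combines the k basis-set claim p-values as `C = -2 * sum(log(p_i))`,
#' referred to a chi-squared distribution with `2k` degrees of freedom. The
#' model is adequate (consistent with the data) when the upper-tail
#' probability `p_C` is large. With no claims (saturated model) the
#' convention `(C, df, p) = (0, 0, 1)` applies. Zero p-values are clamped at
#' 1e-300 with a warning.
#'
#' @param pvalues numeric vector of claim p-values in (0, 1].
#' @return list with `c_stat`, `df`, `p_value`.
#' @export
fishers_c <- function(pvalues) {
  k <- length(pvalues)
  if (k == 0) return(list(c_stat = 0, df = 0L, p_value = 1.0))
  stopifnot(all(pvalues <= 1), all(pvalues >= 0))
  if (any(pvalues == 0)) {
    warning("claim p-value(s) of 0 clamped at 1e-300")
    pvalues[pvalues == 0] <- 1e-300
  }
  c_stat <- -2 * sum(log(pvalues))
  df <- 2L * k
  list(c_stat = c_stat, df = df,
       p_value = stats::pchisq(c_stat, df, lower.tail = FALSE))
}

#' Fit a piecewise structural equation model
#'
#' Fits one Gaussian OLS per non-exogenous node on its parents, collects
#' standardized path coefficients and p-values, tests every d-separation
#' basis-set claim, and summarises global adequacy by Fisher's C with
#' `df = 2k` and `AIC = C + 2K`, where `K` counts all estimated likelihood
#' parameters (slopes, intercepts and residual variances) across component
#' models.
#'
#' @param dag a `"path_dag"`.
#' @param data data.frame with a column per DAG node.
#' @return object of class `"psem_fit"`: `paths` (data.frame from, to,
#'   beta, std_beta, p), `claims` (data.frame x, y, conditioning, p),
#'   `c_stat`, `df`, `p_value`, `k_params`, `aic`, `dag`.
#' @export
fit_psem <- function(dag, data) {
  stopifnot(inherits(dag, "path_dag"))
  miss <- setdiff(dag$nodes, names(data))
  if (length(miss)) {
    stop(sprintf("DAG node(s) absent from data: %s",
                 paste(miss, collapse = ", ")))
  }
  responses <- dag$nodes[dag$roles != "exogenous"]
  responses <- responses[vapply(responses,
                                function(v) length(dag_parents(dag, v)) > 0,
                                logical(1))]
  paths <- NULL
  k_params <- 0
  for (v in responses) {
    pa <- dag_parents(dag, v)
    fit <- stats::lm(stats::reformulate(sprintf("`%s`", pa),
                                        response = sprintf("`%s`", v)),
                     data = data)
    sm <- stats::coef(summary(fit))
    rn <- gsub("`", "", rownames(sm))
    k_params <- k_params + nrow(sm) + 1      # + residual variance
    for (p_ in pa) {
      i <- which(rn == p_)
      if (!length(i)) stop(sprintf("singular component model for %s", v))
      sb <- sm[i, 1] * stats::sd(data[[p_]]) / stats::sd(data[[v]])
      paths <- rbind(paths, data.frame(
        from = p_, to = v, beta = sm[i, 1], std_beta = sb, p = sm[i, 4],
        stringsAsFactors = FALSE))
    }
  }
  claims <- basis_set(dag)
  claim_p <- vapply(claims, test_claim, numeric(1), data = data)
  fc <- fishers_c(claim_p)
  claims_df <- if (length(claims)) {
    data.frame(
      x = vapply(claims, `[[`, character(1), "x"),
      y = vapply(claims, `[[`, character(1), "y"),
      conditioning = vapply(claims, function(cl)
        paste(cl$conditioning, collapse = "+"), character(1)),
      p = claim_p, stringsAsFactors = FALSE)
  } else {
    data.frame(x = character(0), y = character(0),
               conditioning = character(0), p = numeric(0))
  }
  structure(
    list(paths = paths, claims = claims_df,
         c_stat = fc$c_stat, df = fc$df, p_value = fc$p_value,
         k_params = k_params, aic = fc$c_stat + 2 * k_params,
         dag = dag),
    class = "psem_fit"
  )
}

#' @export
print.psem_fit <- function(x, ...) {
  cat(sprintf(
    "Piecewise SEM: %d path(s), %d independence claim(s)\n",
    if (is.null(x$paths)) 0L else nrow(x$paths), nrow(x$claims)))
  cat(sprintf("  Fisher's C = %.3f, df = %d, p = %.3f, AIC = %.2f\n",
              x$c_stat, x$df, x$p_value, x$aic))
  if (!is.null(x$paths)) print(x$paths, row.names = FALSE)
  invisible(x)
}

#' Prune non-significant paths from a piecewise SEM
#'
#' Iteratively removes the single path with the largest p-value at or above
#' `alpha`, refits, and recomputes Fisher's C, until every retained path is
#' significant. Nodes left without edges are dropped from the DAG. Pruning
#' everything yields an empty-model result (flagged, not an error).
#'
#' @param fit a `"psem_fit"`.
#' @param data the data used for the fit.
#' @param alpha significance threshold (default 0.05).
#' @return the final `"psem_fit"` with a `removed` data.frame (from, to, p)
#'   logging the pruned paths, and `empty = TRUE` when nothing remains.
#' @export
prune_paths <- function(fit, data, alpha = 0.05) {
  stopifnot(inherits(fit, "psem_fit"))
  removed <- data.frame(from = character(0), to = character(0),
                        p = numeric(0), stringsAsFactors = FALSE)
  current <- fit
  repeat {
    if (is.null(current$paths) || nrow(current$paths) == 0) {
      current$removed <- removed
      current$empty <- TRUE
      return(current)
    }
    worst <- which.max(current$paths$p)
    if (current$paths$p[worst] < alpha) break
    drop_edge <- current$paths[worst, c("from", "to")]
    removed <- rbind(removed,
                     data.frame(from = drop_edge$from, to = drop_edge$to,
                                p = current$paths$p[worst]))
    edges <- current$dag$edges
    keep <- !(edges$from == drop_edge$from & edges$to == drop_edge$to)
    edges <- edges[keep, , drop = FALSE]
    if (nrow(edges) == 0) {
      current$paths <- current$paths[0, , drop = FALSE]
      next
    }
    nodes_left <- unique(c(edges$from, edges$to))
    dag <- path_dag(edges, current$dag$roles[nodes_left])
    current <- fit_psem(dag, data)
  }
  current$removed <- removed
  current$empty <- FALSE
  current
}

#' Export a DAG as edge-list CSV or DOT
#'
#' @param dag a `"path_dag"`.
#' @param path output file; format chosen by extension (`.csv` or `.dot`).
#' @export
write_dag <- function(dag, path) {
  stopifnot(inherits(dag, "path_dag"))
  if (grepl("\\.dot$", path)) {
    lines <- c("digraph paths {",
               sprintf('  "%s" [role="%s"];', dag$nodes, dag$roles),
               sprintf('  "%s" -> "%s";', dag$edges$from, dag$edges$to),
               "}")
    writeLines(lines, path)
  } else {
    df <- data.frame(from = dag$edges$from, to = dag$edges$to,
                     from_role = dag$roles[dag$edges$from],
                     to_role = dag$roles[dag$edges$to])
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
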