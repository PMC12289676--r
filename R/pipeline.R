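#' Run the full analysis pipeline
#'
#' One-command orchestration of the whole framework: simulate (or load) a
#' study, score the composite efficacy indices, fit the dose-effect models
#' (SPRA) per composite, run the mediator-block PLSR with VIP screening,
#' assemble and prune the piecewise SEM, and compute the liver-gastric
#' Spearman matrix. Per-stage outputs are written as CSV/JSON when `out_dir`
#' is given, together with a machine-readable run manifest carrying the seed
#' and a config hash; re-running with an identical config reproduces
#' byte-identical tables.
#'
#' @param config a `"study_config"` (simulated input) or a list with element
#'   `tables` naming pre-built `animals`, `doses`, `genera`, `peaks` tables.
#' @param composites list of `"composite_spec"` (default
#'   [published_composites()]).
#' @param responses composite names to model with SPRA (default all).
#' @param vip_threshold VIP screening cutoff (default 1.0).
#' @param ncomp_threshold cumulative explained-Y-variance rule (default
#'   0.80).
#' @param alpha pSEM pruning threshold (default 0.05).
#' @param out_dir optional output directory.
#' @param seed seed for the stochastic stages (LASSO folds); the simulation
#'   seed lives in the config.
#' @return list with `study`, `scored` (animal table + composite columns),
#'   `effect_models`, `plsr` (per-block fits, VIP tables, screened sets),
#'   `psem` (per-outcome list of initial and pruned fits), `correlations`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = study_config(),
                         composites = published_composites(),
                         responses = names(composites),
                         vip_threshold = 1.0,
                         ncomp_threshold = 0.80,
                         alpha = 0.05,
                         out_dir = NULL,
                         seed = 1) {
  stages <- character(0)
  # stage 1: data
  if (inherits(config, "study_config")) {
    study <- simulate_study(config)
    stages <- c(stages, "simulate")
  } else if (is.list(config) && !is.null(config$tables)) {
    study <- structure(c(config$tables, list(ground_truth = NULL)),
                       class = "study_dataset")
    stages <- c(stages, "load")
  } else {
    stop("config must be a study_config or a list with $tables")
  }
  # stage 2: composite scoring
  scored <- study$animals
  weights_used <- list()
  for (nm in names(composites)) {
    cs <- composites[[nm]]
    if (!all(cs$components %in% names(scored))) next
    ci <- composite_index(scored, cs)
    scored[[paste0("Y_", nm)]] <- ci$scores
    weights_used[[nm]] <- ci$weights
  }
  stages <- c(stages, "score")
  # stage 3: SPRA per composite
  ud_animals <- scored[!is.na(scored$run), , drop = FALSE]
  effect_models <- list()
  for (nm in responses) {
    ycol <- paste0("Y_", nm)
    if (!ycol %in% names(scored)) next
    effect_models[[ycol]] <- fit_spra(study$doses, scored, ycol, seed = seed)
  }
  stages <- c(stages, "spra")
  # stage 4: PLSR + VIP per mediator block (UD + reference animals)
  dosed <- !is.na(scored$run)
  ycols <- intersect(paste0("Y_", responses), names(scored))
  yblock <- as.matrix(scored[dosed, ycols, drop = FALSE])
  plsr_out <- list()
  for (block in c("genera", "peaks")) {
    x <- as.matrix(study[[block]][dosed, , drop = FALSE])
    keep <- apply(x, 2, stats::sd) > 0
    x <- x[, keep, drop = FALSE]
    mc <- min(5L, nrow(x) - 1L, ncol(x))
    nc <- suppressWarnings(
      select_ncomp(x, yblock, threshold = ncomp_threshold, max_comp = mc))
    fit <- nipals_plsr(x, yblock, ncomp = nc)
    plsr_out[[block]] <- list(fit = fit, ncomp = nc, vip = vip(fit),
                              selected = screen_vip(fit, vip_threshold))
  }
  stages <- c(stages, "plsr")
  # stage 5: piecewise SEM on the dosed animals
  med_data <- scored[dosed, , drop = FALSE]
  vip_selected <- list()
  for (ycol in names(effect_models)) {
    sel <- character(0)
    for (block in c("genera", "peaks")) {
      s <- plsr_out[[block]]$selected
      for (v in s) med_data[[v]] <- study[[block]][dosed, v]
      sel <- c(sel, s)
    }
    vip_selected[[ycol]] <- sel
  }
  # one path model per outcome, mirroring the per-endpoint path diagrams;
  # term columns are attached on the standardized scale used by the SPRA
  nonempty <- Filter(function(em) length(em$terms) > 0, effect_models)
  psem_res <- NULL
  if (length(nonempty)) {
    tm <- expand_poly_terms(study$doses, scale_doses = TRUE,
                            scale_terms = TRUE)
    run_idx <- match(med_data$run, rownames(study$doses$doses))
    ok <- !is.na(run_idx)
    psem_data <- med_data[ok, , drop = FALSE]
    for (tc in colnames(tm)) psem_data[[tc]] <- tm[run_idx[ok], tc]
    psem_res <- lapply(nonempty, function(em) {
      dag <- build_initial_dag(list(em),
                               vip_selected[em$response])
      initial <- fit_psem(dag, psem_data)
      pruned <- prune_paths(initial, psem_data, alpha = alpha)
      list(initial = initial, pruned = pruned)
    })
  }
  stages <- c(stages, "psem")
  # stage 6: liver vs gastric Spearman matrix
  liver_vars <- intersect(c("ALT", "AST", "TBIL", "IL6_L", "TNFa_L"),
                          names(scored))
  gastric_vars <- intersect(c("UI", "HS", "EGF", "EGFR", "NO", "PGE2",
                              "COX2", "IL1b_G", "IL6_G", "TNFa_G"),
                            names(scored))
  correlations <- spearman_matrix(scored, rows = liver_vars,
                                  cols = gastric_vars)
  stages <- c(stages, "correlate")
  manifest <- list(
    stages = stages,
    seed = seed,
    config_seed = if (inherits(config, "study_config")) config$seed else NA,
    config_hash = config_hash(config),
    n_animals = nrow(scored),
    composites_scored = names(weights_used)
  )
  result <- list(study = study, scored = scored,
                 composite_weights = weights_used,
                 effect_models = effect_models, plsr = plsr_out,
                 psem = psem_res, correlations = correlations,
                 manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# stable content hash of the configuration (md5 of its serialization dump)
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(config, file = tf)
  unname(tools::md5sum(tf))
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$scored, file.path(out_dir, "scored.csv"),
                   row.names = FALSE)
  if (inherits(result$study, "study_dataset") &&
      inherits(result$study$doses, "dose_matrix")) {
    write_doses_csv(result$study$doses, file.path(out_dir, "doses.csv"))
  }
  em_tabs <- lapply(result$effect_models, effect_model_table)
  if (length(em_tabs)) {
    utils::write.csv(do.call(rbind, em_tabs),
                     file.path(out_dir, "spra_terms.csv"), row.names = FALSE)
  }
  for (block in names(result$plsr)) {
    v <- result$plsr[[block]]$vip
    utils::write.csv(data.frame(predictor = names(v), vip = unname(v)),
                     file.path(out_dir, paste0("vip_", block, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(result$psem)) {
    all_paths <- NULL
    fits <- list()
    for (nm in names(result$psem)) {
      pf <- result$psem[[nm]]$pruned
      if (!is.null(pf$paths) && nrow(pf$paths)) {
        all_paths <- rbind(all_paths, data.frame(outcome = nm, pf$paths))
      }
      fits[[nm]] <- list(c_stat = pf$c_stat, df = pf$df,
                         p_value = pf$p_value, aic = pf$aic,
                         k_params = pf$k_params)
    }
    if (!is.null(all_paths)) {
      utils::write.csv(all_paths, file.path(out_dir, "psem_paths.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(fits, file.path(out_dir, "psem_fits.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(cor_matrix_long(result$correlations),
                   file.path(out_dir, "correlations.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Validate a bundle of study tables
#'
#' Schema checks for the four study tables: required columns, recognised
#' group labels, numeric parsing, and compositional row sums for the genus
#' table.
#'
#' @param animals,doses,genera,peaks data.frames (any may be NULL to skip).
#' @param tol compositional tolerance for genus row sums (default 1e-6).
#' @return list with `ok` (logical) and `violations` (character vector).
#' @export
validate_tables <- function(animals = NULL, doses = NULL, genera = NULL,
                            peaks = NULL, tol = 1e-6) {
  v <- character(0)
  if (!is.null(animals)) {
    for (col in c("group", "run")) {
      if (!col %in% names(animals)) {
        v <- c(v, sprintf("animals: missing required column '%s'", col))
      }
    }
    if ("group" %in% names(animals)) {
      allowed <- c("control", "model", "MHWP")
      bad <- setdiff(unique(animals$group),
                     c(allowed, grep("^UD\\d+$", unique(animals$group),
                                     value = TRUE)))
      if (length(bad)) {
        v <- c(v, sprintf("animals: unrecognised group label(s): %s",
                          paste(bad, collapse = ", ")))
      }
    }
    non_num <- names(animals)[!vapply(animals, is.numeric, logical(1))]
    non_num <- setdiff(non_num, c("animal", "group", "run"))
    if (length(non_num)) {
      v <- c(v, sprintf("animals: non-numeric indicator column(s): %s",
                        paste(non_num, collapse = ", ")))
    }
  }
  if (!is.null(doses)) {
    d <- if (inherits(doses, "dose_matrix")) doses$doses else doses
    if (!all(vapply(as.data.frame(d), is.numeric, logical(1)))) {
      v <- c(v, "doses: non-numeric entries")
    }
  }
  if (!is.null(genera)) {
    rs <- rowSums(as.matrix(genera))
    bad <- which(abs(rs - 1) > tol)
    if (length(bad)) {
      v <- c(v, sprintf(
        "genera: row(s) not summing to 1 (compositional violation): %s",
        paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  if (!is.null(peaks)) {
    if (any(as.matrix(peaks) < 0)) {
      v <- c(v, "peaks: negative peak area(s)")
    }
  }
  list(ok = length(v) == 0, violations = v)
}
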