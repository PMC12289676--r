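#' Synthetic study configuration
#'
#' Describes a complete synthetic formulation study with the structure of the
#' rat experiment the pipeline targets: 10 groups (healthy control, injury
#' model, reference formulation, and seven uniform-design formulations) of 5
#' animals each, sparse polynomial dose effects on the endpoints, and known
#' mediation paths through liver markers, gut-microbiota genera and serum
#' metabolite peaks.
#'
#' Effect models are declared on the standardized term scale (doses Z-scored
#' across the design runs, term columns Z-scored again), so a declared
#' coefficient is directly comparable to the standardized coefficients the
#' SPRA stage estimates. Mediator latents are built to unit variance (path
#' contribution plus complementary noise), so declared path coefficients are
#' approximately standardized path coefficients.
#'
#' @param n_per_group animals per group (default 5).
#' @param n_runs design runs (default 7).
#' @param dose_ranges per-herb gram ranges (default [default_dose_ranges()]).
#' @param true_effects named list: endpoint -> list(intercept, terms =
#'   named coefficient vector over term labels such as `"ZR^2"`, `"ZR:PR"`).
#' @param baselines named list: endpoint -> c(control =, model =) values for
#'   the undosed groups; endpoints missing here reuse their intercept for
#'   both.
#' @param mediation data.frame(from, to, beta) of directed paths; sources
#'   may be term labels, endpoints or mediators, targets mediators or
#'   endpoints. Must be acyclic.
#' @param mediators data.frame(name, type) with type in liver/genus/peak;
#'   genus mediators occupy the first columns of the genus table, peak
#'   mediators the matching `P*` columns.
#' @param noise_sd endpoint measurement noise SD on the standardized effect
#'   scale (default 0.25; named vector to vary by endpoint).
#' @param n_genera,n_peaks table widths (defaults 10 and 18).
#' @param seed RNG seed.
#' @return object of class `"study_config"`.
#' @export
study_config <- function(n_per_group = 5,
                         n_runs = 7,
                         dose_ranges = default_dose_ranges(),
                         true_effects = default_true_effects(),
                         baselines = default_baselines(),
                         mediation = default_mediation(),
                         mediators = default_mediators(),
                         noise_sd = 0.25,
                         n_genera = 10,
                         n_peaks = 18,
                         seed = 1) {
  stopifnot(n_per_group >= 2, n_runs >= 2)
  endpoints <- union(names(true_effects), names(baselines))
  if (!length(endpoints)) stop("no endpoints declared")
  med_nodes <- if (nrow(mediation)) unique(c(mediation$from, mediation$to))
               else character(0)
  term_labels <- colnames(poly_columns(
    matrix(0, 2, length(dose_ranges),
           dimnames = list(NULL, names(dose_ranges)))))
  known <- c(endpoints, term_labels, mediators$name)
  unknown <- setdiff(med_nodes, known)
  if (length(unknown)) {
    stop(sprintf("mediation path references undeclared variable(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  if (any(noise_sd <= 0)) stop("noise_sd must be positive")
  structure(
    list(n_per_group = as.integer(n_per_group), n_runs = as.integer(n_runs),
         dose_ranges = dose_ranges, true_effects = true_effects,
         baselines = baselines, mediation = mediation, mediators = mediators,
         noise_sd = noise_sd, n_genera = as.integer(n_genera),
         n_peaks = as.integer(n_peaks), seed = as.integer(seed),
         groups = c("control", "model", "MHWP",
                    paste0("UD", seq_len(n_runs)))),
    class = "study_config"
  )
}

#' Default sparse dose-effect models
#'
#' Damage scores (UI, HS) fall with the key herb's quadratic and interaction
#' terms; regenerative factors rise with its linear term; cytokines fall;
#' liver markers fall. Standardized magnitudes sit around 1, squarely in the
#' recoverable regime for 7-run designs with 5 replicates.
#'
#' @return named list of effect models.
#' @export
default_true_effects <- function() {
  list(
    UI      = list(intercept = 10, terms = c("ZR^2" = -1.2, "ZR:PR" = -0.9)),
    HS      = list(intercept = 8,  terms = c("ZR^2" = -1.0, "ZR:GCR" = -0.8)),
    EGF     = list(intercept = 5,  terms = c("ZR" = 1.2)),
    EGFR    = list(intercept = 5,  terms = c("ZR" = 1.0)),
    IL1b_G  = list(intercept = 12, terms = c("ZR:LAR" = -1.0)),
    IL6_G   = list(intercept = 12, terms = c("ZR" = -0.9)),
    TNFa_G  = list(intercept = 12, terms = c("ZR" = -1.1)),
    IL1b_S  = list(intercept = 10, terms = c("ZR" = -1.0)),
    IL6_S   = list(intercept = 10, terms = c("ZR" = -0.9)),
    TNFa_S  = list(intercept = 10, terms = c("ZR" = -0.8)),
    ALT     = list(intercept = 40, terms = c("ZR" = -1.0)),
    AST     = list(intercept = 35, terms = c("ZR" = -0.9)),
    TBIL    = list(intercept = 6,  terms = c("ZR" = -0.8)),
    IL6_L   = list(intercept = 9,  terms = c("ZR" = -1.0)),
    TNFa_L  = list(intercept = 9,  terms = c("ZR:CR" = -0.9)),
    NO      = list(intercept = 4,  terms = c("ZR" = 1.0)),
    PGE2    = list(intercept = 6,  terms = c("ZR:PR" = 1.0)),
    COX2    = list(intercept = 7,  terms = c("ZR" = -0.9))
  )
}

#' Default control/model baselines
#'
#' Healthy controls sit at the favorable end of each endpoint, the untreated
#' injury model at the unfavorable end, bracketing the dosed groups.
#'
#' @return named list of c(control, model) values.
#' @export
default_baselines <- function() {
  eff <- default_true_effects()
  out <- lapply(names(eff), function(e) {
    ic <- eff[[e]]$intercept
    # damage/cytokine endpoints (negative dose effects): control low, model high
    sgn <- if (any(eff[[e]]$terms < 0)) 1 else -1
    c(control = ic - sgn * 3, model = ic + sgn * 1.5)
  })
  stats::setNames(out, names(eff))
}

#' Default mediation structure
#'
#' Three strong, known paths used by the recovery experiments: a liver
#' marker mediating a quadratic dose term's effect on the ulcer index, one
#' genus mediating a linear term's effect on a gastric cytokine, and one
#' metabolite peak mediating an interaction term's effect on PGE2.
#'
#' @return data.frame(from, to, beta).
#' @export
default_mediation <- function() {
  data.frame(
    from = c("ZR^2", "NFkB_L", "ZR", "genus_1", "ZR:PR", "P3"),
    to   = c("NFkB_L", "UI", "genus_1", "IL6_G", "P3", "PGE2"),
    beta = c(0.8, -0.6, 0.8, -0.6, 0.8, 0.6),
    stringsAsFactors = FALSE
  )
}

#' Default mediator roster
#' @return data.frame(name, type).
#' @export
default_mediators <- function() {
  data.frame(
    name = c("NFkB_L", "genus_1", "P3"),
    type = c("liver", "genus", "peak"),
    stringsAsFactors = FALSE
  )
}

# standardized term values for every animal: z-score doses and term columns
# over the design runs, then map each animal to its run's term row; the
# reference-formulation group is projected through the same scaling;
# undosed groups sit at zero (the design mean)
animal_term_matrix <- function(config, doses, animals) {
  d <- doses$doses
  dmu <- colMeans(d); dsd <- apply(d, 2, stats::sd)
  zd <- sweep(sweep(d, 2, dmu), 2, dsd, "/")
  traw <- poly_columns(zd)
  tmu <- colMeans(traw); tsd <- apply(traw, 2, stats::sd)
  tz <- sweep(sweep(traw, 2, tmu), 2, tsd, "/")
  ref <- mhwp_reference_doses()[colnames(d)]
  zref <- (ref - dmu) / dsd
  tref_raw <- poly_columns(rbind(zref, zref))[1, , drop = FALSE]
  tref <- (tref_raw - tmu) / tsd
  tm <- matrix(0, nrow(animals), ncol(tz),
               dimnames = list(NULL, colnames(tz)))
  for (i in seq_len(nrow(animals))) {
    if (!is.na(animals$run[i])) {
      tm[i, ] <- tz[animals$run[i], ]
    } else if (animals$group[i] == "MHWP") {
      tm[i, ] <- tref
    }
  }
  tm
}

#' Simulate per-animal pharmacological endpoints
#'
#' Uniform-design and reference-formulation animals receive
#' `intercept + sum(beta_t * t(doses)) + N(0, noise_sd^2)` with the terms
#' evaluated on the standardized term scale; control and model animals
#' receive their configured baselines plus the same noise. Deterministic
#' given the config seed.
#'
#' @param config a `"study_config"`.
#' @param doses optional `"dose_matrix"`; built from the config design when
#'   omitted.
#' @return data.frame: `animal`, `group`, `run`, one column per endpoint.
#' @export
simulate_endpoints <- function(config, doses = NULL) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  if (is.null(doses)) doses <- config_doses(config)
  animals <- animal_frame(config)
  tm <- animal_term_matrix(config, doses, animals)
  endpoints <- union(names(config$true_effects), names(config$baselines))
  n <- nrow(animals)
  for (e in endpoints) {
    eff <- config$true_effects[[e]]
    bl <- config$baselines[[e]]
    if (is.null(eff) && is.null(bl)) {
      stop(sprintf("endpoint %s has no effect model and no baseline", e))
    }
    mu <- numeric(n)
    dosed <- animals$group %in% c("MHWP", paste0("UD", seq_len(config$n_runs)))
    if (!is.null(eff)) {
      mu[dosed] <- eff$intercept +
        drop(tm[dosed, names(eff$terms), drop = FALSE] %*% eff$terms)
    } else {
      mu[dosed] <- bl[["model"]]
    }
    if (!is.null(bl)) {
      mu[animals$group == "control"] <- bl[["control"]]
      mu[animals$group == "model"] <- bl[["model"]]
    } else {
      mu[animals$group %in% c("control", "model")] <- eff$intercept
    }
    sd_e <- if (length(config$noise_sd) > 1 && e %in% names(config$noise_sd)) {
      config$noise_sd[[e]]
    } else {
      config$noise_sd[[1]]
    }
    animals[[e]] <- mu + stats::rnorm(n, 0, sd_e)
  }
  attr(animals, "term_matrix") <- tm
  animals
}

config_doses <- function(config) {
  des <- glp_design(config$n_runs, length(config$dose_ranges))
  dm <- scale_doses(des, config$dose_ranges)
  rownames(dm$doses) <- paste0("run", seq_len(config$n_runs))
  dm
}

animal_frame <- function(config) {
  groups <- rep(config$groups, each = config$n_per_group)
  run <- ifelse(grepl("^UD", groups),
                sub("^UD", "run", groups), NA_character_)
  data.frame(
    animal = sprintf("A%02d", seq_along(groups)),
    group = groups, run = run, stringsAsFactors = FALSE
  )
}

#' Simulate mediator blocks and apply mediation paths
#'
#' Mediator latents are generated in topological order of the mediation
#' graph: each latent is the sum of its declared upstream contributions
#' (sources standardized over the animals that carry them) plus complementary
#' Gaussian noise scaled so the latent is approximately unit-variance.
#' Liver-marker mediators join the animal table as observed columns;
#' genus latents pass through a per-row softmax so the genus table rows sum
#' to 1; peak latents are exponentiated so peak areas are positive.
#' Endpoints that receive mediator paths gain those contributions on top of
#' the values from [simulate_endpoints()] (no extra noise, so zero path
#' coefficients reproduce the endpoint table exactly).
#'
#' @param config a `"study_config"`.
#' @param endpoints the table from [simulate_endpoints()] (with its term
#'   matrix attribute).
#' @return list with `animals` (endpoint table with liver columns and
#'   mediated outcomes), `genera` (rows sum to 1), `peaks` (positive areas),
#'   `latents` (the mediator latent matrix, ground truth).
#' @export
simulate_mediators <- function(config, endpoints) {
  stopifnot(inherits(config, "study_config"))
  animals <- endpoints
  tm <- attr(endpoints, "term_matrix")
  n <- nrow(animals)
  spec <- config$mediation
  med_names <- config$mediators$name
  med_type <- stats::setNames(config$mediators$type, med_names)
  # order mediators topologically within the mediation graph
  med_edges <- spec[spec$to %in% med_names, , drop = FALSE]
  ord <- topo_sort(unique(c(med_edges$from, med_edges$to, med_names)),
                   med_edges[, c("from", "to")])
  if (is.null(ord)) stop("mediation paths form a cycle")
  ord <- ord[ord %in% med_names]
  latents <- matrix(0, n, length(med_names),
                    dimnames = list(NULL, med_names))
  source_value <- function(v) {
    if (v %in% colnames(tm)) return(tm[, v])
    if (v %in% colnames(latents) && v %in% ord) return(latents[, v])
    if (v %in% names(animals)) return(scale_safe(animals[[v]]))
    stop(sprintf("unknown mediation source: %s", v))
  }
  for (mname in ord) {
    inc <- spec[spec$to == mname, , drop = FALSE]
    contrib <- numeric(n)
    for (r in seq_len(nrow(inc))) {
      contrib <- contrib + inc$beta[r] * source_value(inc$from[r])
    }
    resid_sd <- sqrt(max(0.1, 1 - sum(inc$beta^2)))
    latents[, mname] <- contrib + stats::rnorm(n, 0, resid_sd)
  }
  # mediator -> endpoint contributions (deterministic additions)
  out_edges <- spec[spec$to %in% names(animals) & spec$from %in% med_names, ,
                    drop = FALSE]
  for (r in seq_len(nrow(out_edges))) {
    animals[[out_edges$to[r]]] <- animals[[out_edges$to[r]]] +
      out_edges$beta[r] * latents[, out_edges$from[r]]
  }
  # observed blocks
  genus_meds <- med_names[med_type == "genus"]
  genus_cols <- paste0("genus_", seq_len(config$n_genera))
  glat <- matrix(stats::rnorm(n * config$n_genera), n, config$n_genera,
                 dimnames = list(NULL, genus_cols))
  for (g in genus_meds) glat[, g] <- latents[, g]
  genera <- exp(glat) / rowSums(exp(glat))
  genera <- as.data.frame(genera)

  peak_cols <- paste0("P", seq_len(config$n_peaks))
  plat <- matrix(stats::rnorm(n * config$n_peaks), n, config$n_peaks,
                 dimnames = list(NULL, peak_cols))
  peak_meds <- med_names[med_type == "peak"]
  for (p_ in peak_meds) plat[, p_] <- latents[, p_]
  peaks <- as.data.frame(exp(plat))

  liver_meds <- med_names[med_type == "liver"]
  for (lv in liver_meds) animals[[lv]] <- latents[, lv]

  list(animals = animals, genera = genera, peaks = peaks, latents = latents)
}

scale_safe <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Simulate a complete synthetic study
#'
#' Composes the design construction, dose scaling, endpoint simulation and
#' mediator simulation into one dataset with its ground truth attached.
#'
#' @param config a `"study_config"`.
#' @return object of class `"study_dataset"`: list with `doses`
#'   (`"dose_matrix"`), `animals`, `genera`, `peaks`, `ground_truth` (list:
#'   `true_effects`, `mediation`, `mediators`, `seed`, `latents`).
#' @export
simulate_study <- function(config = study_config()) {
  doses <- config_doses(config)
  endpoints <- simulate_endpoints(config, doses)
  med <- simulate_mediators(config, endpoints)
  structure(
    list(doses = doses, animals = med$animals,
         genera = med$genera, peaks = med$peaks,
         ground_truth = list(
           true_effects = config$true_effects,
           mediation = config$mediation,
           mediators = config$mediators,
           noise_sd = config$noise_sd,
           seed = config$seed,
           latents = med$latents),
         config = config),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d animals in %d groups; %d genera, %d peaks\n",
    nrow(x$animals), length(unique(x$animals$group)),
    ncol(x$genera), ncol(x$peaks)))
  invisible(x)
}

#' Write a study dataset to a directory
#'
#' Writes `animals.csv`, `doses.csv`, `genera.csv`, `peaks.csv` and a
#' `ground_truth.json` sidecar.
#'
#' @param study a `"study_dataset"`.
#' @param dir output directory (created if absent).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$animals, file.path(dir, "animals.csv"),
                   row.names = FALSE)
  write_doses_csv(study$doses, file.path(dir, "doses.csv"))
  utils::write.csv(study$genera, file.path(dir, "genera.csv"),
                   row.names = FALSE)
  utils::write.csv(study$peaks, file.path(dir, "peaks.csv"),
                   row.names = FALSE)
  gt <- study$ground_truth
  gt$latents <- NULL                       # matrices stay in-memory only
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a ground-truth sidecar
#' @param dir study directory.
#' @return the ground-truth list.
#' @export
read_ground_truth <- function(dir) {
  jsonlite::read_json(file.path(dir, "ground_truth.json"),
                      simplifyVector = TRUE)
}
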