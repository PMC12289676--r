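#' SPRA parameter-recovery experiment
#'
#' Monte-Carlo check of the variable-selection machinery under the study's
#' conditions: a 7-run uniform design with `n_rep` animals per run, a
#' response driven by two sparse polynomial terms with standardized
#' magnitudes drawn from `beta_range`, and Gaussian replicate noise. Each
#' seed simulates a study, runs the full LASSO + stepwise pipeline on the
#' run means, and records whether the exact support and the coefficient
#' signs were recovered.
#'
#' @param n_seeds number of replicate studies (default 100).
#' @param true_terms the two causal term labels (default `ZR^2`, `ZR:PR`).
#' @param beta_range range of standardized effect magnitudes
#'   (default c(0.8, 1.5)).
#' @param noise_sd per-animal noise SD on the standardized response scale
#'   (default 0.25).
#' @param n_rep animals per run (default 5).
#' @param seed master seed.
#' @return list with `support_rate` (exact support recovery),
#'   `sign_rate` (sign agreement among runs where support was recovered),
#'   and the per-seed logical vectors.
#' @export
spra_recovery <- function(n_seeds = 100, true_terms = c("ZR^2", "ZR:PR"),
                          beta_range = c(0.8, 1.5), noise_sd = 0.25,
                          n_rep = 5, seed = 1) {
  support <- logical(n_seeds)
  signs <- rep(NA, n_seeds)
  for (i in seq_len(n_seeds)) {
    set.seed(seed + i)
    betas <- stats::runif(length(true_terms), beta_range[1], beta_range[2]) *
      sample(c(-1, 1), length(true_terms), replace = TRUE)
    names(betas) <- true_terms
    cfg <- study_config(
      n_per_group = n_rep,
      true_effects = list(Y = list(intercept = 0, terms = betas)),
      baselines = list(Y = c(control = -3, model = 2)),
      mediation = data.frame(from = character(0), to = character(0),
                             beta = numeric(0)),
      mediators = data.frame(name = character(0), type = character(0)),
      noise_sd = noise_sd, seed = seed + i
    )
    study <- simulate_study(cfg)
    em <- fit_spra(study$doses, study$animals, "Y", seed = seed + i)
    support[i] <- setequal(em$terms, true_terms)
    if (support[i]) {
      signs[i] <- all(sign(em$std_coefficients[true_terms]) == sign(betas))
    }
  }
  list(support_rate = mean(support),
       sign_rate = mean(signs[support]),
       support = support, signs = signs)
}

#' VIP mediator-screening experiment
#'
#' One genus latent carries a standardized effect on the response among
#' `n_noise` pure-noise genera; the observed block is the softmax-closed
#' relative-abundance table. Each seed fits a one-block PLSR and asks
#' whether the true genus passes the VIP > 1 screen.
#'
#' @param n_seeds replicates (default 100).
#' @param effect standardized effect of the true genus latent on the
#'   response (default 0.9).
#' @param n_noise noise genera (default 9).
#' @param n sample size (default 35, seven runs of five animals).
#' @param seed master seed.
#' @return list with `select_rate` and the per-seed logical vector.
#' @export
vip_recovery <- function(n_seeds = 100, effect = 0.9, n_noise = 9,
                         n = 35, seed = 1) {
  hits <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    set.seed(seed + i)
    k <- n_noise + 1
    lat <- matrix(stats::rnorm(n * k), n, k,
                  dimnames = list(NULL, paste0("genus_", seq_len(k))))
    genera <- exp(lat) / rowSums(exp(lat))
    y <- effect * scale_safe(lat[, 1]) +
      stats::rnorm(n, 0, sqrt(1 - effect^2))
    nc <- min(3, n - 1)
    fit <- nipals_plsr(genera, y, ncomp = nc)
    hits[i] <- "genus_1" %in% screen_vip(fit, 1.0)
  }
  list(select_rate = mean(hits), hits = hits)
}

#' pSEM adequacy and misspecification experiment
#'
#' Generates data exactly from a mediation DAG (term -> mediator -> outcome
#' with a direct path) and fits (a) the true DAG, recording the adequacy
#' p-value, and (b) a misspecified DAG omitting a direct edge of
#' standardized strength `beta_missing`, recording the detection p-value.
#'
#' @param n_seeds replicates (default 100).
#' @param n sample size per replicate (default 200).
#' @param beta_missing standardized strength of the omitted direct edge
#'   (default 0.6).
#' @param seed master seed.
#' @return list with `adequacy_rate` (p > 0.05 under the true DAG),
#'   `detection_rate` (p < 0.05 under the misspecified DAG), and the
#'   per-seed p-values.
#' @export
psem_calibration <- function(n_seeds = 100, n = 200, beta_missing = 0.6,
                             seed = 1) {
  p_true <- p_miss <- numeric(n_seeds)
  roles <- c(X = "exogenous", M = "mediator", Y = "outcome")
  dag_chain <- path_dag(
    data.frame(from = c("X", "M"), to = c("M", "Y")), roles)
  for (i in seq_len(n_seeds)) {
    set.seed(seed + i)
    x <- stats::rnorm(n)
    m <- 0.7 * x + stats::rnorm(n, 0, sqrt(1 - 0.49))
    # (a) data generated exactly from the chain DAG: one true claim X _||_ Y | M
    y0 <- 0.5 * m + stats::rnorm(n, 0, sqrt(0.75))
    p_true[i] <- fit_psem(dag_chain, data.frame(X = x, M = m, Y = y0))$p_value
    # (b) data with a direct X -> Y edge the chain DAG omits
    b <- beta_missing
    y1 <- 0.5 * m + b * x +
      stats::rnorm(n, 0, sqrt(max(0.1, 1 - 0.25 - b^2)))
    p_miss[i] <- fit_psem(dag_chain, data.frame(X = x, M = m, Y = y1))$p_value
  }
  list(adequacy_rate = mean(p_true > 0.05),
       detection_rate = mean(p_miss < 0.05),
       p_true = p_true, p_miss = p_miss)
}

#' Independence-claim test calibration
#'
#' Under the chain X -> M -> Y the claim X independent of Y given M is true;
#' its test p-value should be uniform, so the rejection rate at `alpha`
#' should match `alpha`.
#'
#' @param n_reps null replicates (default 500).
#' @param n sample size per replicate (default 500).
#' @param alpha nominal level (default 0.05).
#' @param seed master seed.
#' @return list with `rejection_rate` and the p-values.
#' @export
claim_calibration <- function(n_reps = 500, n = 500, alpha = 0.05, seed = 1) {
  claim <- list(x = "X", y = "Y", conditioning = "M")
  p <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(seed + i)
    x <- stats::rnorm(n)
    m <- 0.7 * x + stats::rnorm(n, 0, sqrt(0.51))
    y <- 0.6 * m + stats::rnorm(n, 0, sqrt(0.64))
    p[i] <- test_claim(claim, data.frame(X = x, M = m, Y = y))
  }
  list(rejection_rate = mean(p < alpha), p = p)
}
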