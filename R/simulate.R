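#' Configure the synthetic-cohort generator
#'
#' Builds a fully specified generative model for a memory-clinic style
#' cohort: two correlated latent life-course traits drive ordinal
#' social/lifestyle items through graded response models; three latent
#' pathology mediators and a latent cognition factor follow linear
#' structural equations in the traits and the covariates (age, sex,
#' APOE-e4); continuous indicators load on the latents; and modality
#' blocks (CSF panel, amyloid-PET, FDG-PET) go missing at random with
#' probabilities depending on age and sex.
#'
#' Defaults are calibrated to the reference cohort
#' ([reference_cohort_margins()], [reference_path_estimates()]): age ~
#' Normal(70.9, 8.7) truncated to (50, 95); 61.9% women; 28.3% APOE-e4
#' carriers; item-bank thresholds matched to the reference category
#' margins; structural coefficients equal to the reference standardized
#' direct effects; mediator residual correlations equal to the
#' reference residual correlations; CSF missing 82%, amyloid-PET 72%,
#' FDG-PET 43%; item-level missingness at the reference rates.
#' Latent residual variances are solved so every latent has unit total
#' variance, which makes the generative coefficients directly
#' comparable to endogenous-standardized estimates.
#'
#' @param n number of participants.
#' @param seed master seed; per-stage substreams are derived from it.
#' @param trait_corr correlation between the two life-course traits.
#' @param missing_rates named vector of modality missingness
#'   probabilities (`csf`, `amyloid`, `fdg`); set to 0 for complete
#'   data.
#' @param mar_strength log-odds slope of missingness per SD of age
#'   (half that per unit of female sex); 0 gives MCAR blocks.
#' @param item_missing named vector of item-level MCAR rates; `NULL`
#'   uses the reference rates, `0` disables.
#' @param structural optional list with `Gamma` (4x5 matrix of
#'   predictor effects on SVD/ADpath/Neuro/Cognition) and `b`
#'   (mediator effects on cognition); defaults to the reference
#'   estimates.
#' @param mediator_resid_corr 3x3 residual correlation among the
#'   mediators.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n, seed = 1, trait_corr = 0.3,
                       missing_rates = c(csf = 0.82, amyloid = 0.72,
                                         fdg = 0.43),
                       mar_strength = 0.4, item_missing = NULL,
                       structural = NULL, mediator_resid_corr = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != floor(n))
    stop("'n' must be a non-negative integer")
  if (abs(trait_corr) >= 1) stop("trait_corr must lie in (-1, 1)")
  if (any(missing_rates < 0 | missing_rates > 1))
    stop("missing_rates must lie in [0, 1]")
  ref <- reference_structural()
  structural <- structural %||% list(Gamma = ref$Gamma, b = ref$b)
  med_corr <- mediator_resid_corr %||% ref$med_corr
  if (any(eigen(med_corr, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("mediator residual correlation matrix is not positive definite")
  margins <- reference_cohort_margins()
  if (is.null(item_missing)) {
    im <- attr(margins, "item_missing") / attr(margins, "n_total")
  } else if (identical(item_missing, 0) || identical(item_missing, 0L)) {
    im <- c(apoe4 = 0, education = 0, occupation = 0, salary = 0,
            physical_activity = 0, leisure = 0, sni = 0)
  } else im <- item_missing

  obs_props <- function(var) {
    cnt <- margins$count[margins$variable == var]
    cnt / sum(cnt)
  }
  cum_from_props <- function(p) rev(cumsum(rev(p)))[-1]
  bank_item <- function(name, a, props)
    grm_item(a, calibrate_thresholds(a, cum_from_props(props)), name = name)
  si_bank <- list(
    bank_item("education", 1.6, obs_props("education")),
    bank_item("occupation", 1.4, obs_props("occupation")),
    bank_item("salary", 1.8, obs_props("salary")))
  li_bank <- list(
    bank_item("physical_activity", 1.3, obs_props("physical_activity")),
    bank_item("leisure_cat", 1.5, obs_props("leisure")))
  sni_bank <- list(
    bank_item("married", 1.1, c(0.35, 0.65)),
    bank_item("close_ties", 1.0, c(0.40, 0.60)),
    bank_item("membership", 1.2, c(0.58, 0.42)))

  age_mean <- attr(margins, "age_mean"); age_sd <- attr(margins, "age_sd")
  age_lim <- c(50, 95)
  p_female <- 1438 / 2323
  p_apoe <- 658 / 2323
  agem <- truncnorm_moments(age_mean, age_sd, age_lim[1], age_lim[2])

  preds <- c("si", "li", "age", "female", "apoe4")
  Sx <- diag(c(1, 1, agem$var, p_female * (1 - p_female),
               p_apoe * (1 - p_apoe)))
  dimnames(Sx) <- list(preds, preds)
  Sx["si", "li"] <- Sx["li", "si"] <- trait_corr
  mux <- c(si = 0, li = 0, age = agem$mean, female = p_female,
           apoe4 = p_apoe)

  G <- structural$Gamma; b <- structural$b
  med <- c("SVD", "ADpath", "Neuro")
  expl_med <- vapply(med, function(m)
    as.numeric(t(G[m, ]) %*% Sx %*% G[m, ]), numeric(1))
  psi_med <- 1 - expl_med
  if (any(psi_med <= 0))
    stop("structural coefficients imply non-positive mediator residual ",
         "variance; the implied covariance is not positive definite")
  Dm <- diag(sqrt(psi_med))
  Psi_med <- Dm %*% med_corr[med, med] %*% Dm
  dimnames(Psi_med) <- list(med, med)
  # reduced-form cognition coefficients: direct + Gamma' b
  c_red <- G["Cognition", ] + as.numeric(t(G[med, ]) %*% b[med])
  expl_C <- as.numeric(t(c_red) %*% Sx %*% c_red) +
    as.numeric(t(b[med]) %*% Psi_med %*% b[med])
  psi_C <- 1 - expl_C
  if (psi_C <= 0)
    stop("structural coefficients imply non-positive cognition residual ",
         "variance; the implied covariance is not positive definite")

  loadings <- list(
    SVD = c(wmh_t = 0.85, fazekas_peri = 0.80, fazekas_deep = 0.68),
    ADpath = c(ptau_t = 0.75, ab_ratio = -0.70, amyloid_t = 0.80),
    Neuro = c(hippo_nd = 0.80, thickness_nd = 0.75, bpf_nd = 0.70,
              fdg_nd = 0.65),
    Cognition = c(verbal_fluency = 0.70, fcsrt_free_recall = 0.75,
                  tmtb_t = 0.65, rey_score = 0.60))

  structure(list(
    n = as.integer(n), seed = as.integer(seed), trait_corr = trait_corr,
    si_bank = si_bank, li_bank = li_bank, sni_bank = sni_bank,
    Gamma = G, b = b, med_corr = med_corr, Psi_med = Psi_med,
    psi = c(SVD = psi_med[[1]], ADpath = psi_med[[2]],
            Neuro = psi_med[[3]], Cognition = psi_C),
    loadings = loadings, Sigma_x = Sx, mu_x = mux,
    age = list(mean = age_mean, sd = age_sd, lim = age_lim,
               trunc_mean = agem$mean, trunc_var = agem$var),
    p_female = p_female, p_apoe = p_apoe,
    missing_rates = missing_rates, mar_strength = mar_strength,
    item_missing = im), class = "sim_config")
}

analysis_indicators <- function(config) unlist(lapply(config$loadings, names))

# RAM matrices of the generative analysis-scale model (truth), sharing
# the implied-moment algebra of the SEM module.
true_matrices <- function(config) {
  inds <- analysis_indicators(config)
  preds <- c("si", "li", "age", "female", "apoe4")
  lat <- c("SVD", "ADpath", "Neuro", "Cognition")
  all <- c(inds, preds, lat)
  nv <- length(all)
  A <- matrix(0, nv, nv, dimnames = list(all, all))
  S <- matrix(0, nv, nv, dimnames = list(all, all))
  m <- stats::setNames(numeric(nv), all)
  for (L in lat) for (ind in names(config$loadings[[L]])) {
    lam <- config$loadings[[L]][[ind]]
    A[ind, L] <- lam
    S[ind, ind] <- 1 - lam^2
  }
  for (L in lat) A[L, preds] <- config$Gamma[L, preds]
  med <- c("SVD", "ADpath", "Neuro")
  A["Cognition", med] <- config$b[med]
  S[med, med] <- config$Psi_med
  S["Cognition", "Cognition"] <- config$psi[["Cognition"]]
  S[preds, preds] <- config$Sigma_x
  m[preds] <- config$mu_x
  # latent intercepts cancel the covariate means so latents have mean 0
  for (L in lat) m[L] <- -sum(config$Gamma[L, ] * config$mu_x)
  structure(list(A = A, S = S, m = m, obs = c(inds, preds), lat = lat,
                 obs_idx = stats::setNames(match(c(inds, preds), all),
                                           c(inds, preds)),
                 all = all), class = "sem_matrices")
}

#' Simulate a cohort
#'
#' Draws a full synthetic cohort from a [sim_config()]: covariates,
#' latent traits, GRM item responses, latent mediators/cognition,
#' continuous indicators, and (optionally) missingness.  Deterministic
#' given the config's seed.
#'
#' @param config a [sim_config()].
#' @param output `"raw"` returns the participant table on the natural
#'   measurement scales (volumes in mm3, CSF in pg/ml, test scores,
#'   ordinal items) ready for [preprocess_cohort()]; `"analysis"`
#'   returns the analysis-scale indicator set (the exact linear
#'   measurement model) with the true traits exposed as
#'   `si_score`/`li_score`, useful for estimator validation.
#' @param missingness apply the configured missingness? Default TRUE.
#' @return an object of class `"sim_cohort"`: list with `data` (the
#'   cohort table), `truth` (per-participant latent values), and
#'   `config`.
#' @export
simulate_cohort <- function(config, output = c("raw", "analysis"),
                            missingness = TRUE) {
  output <- match.arg(output)
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  inds <- analysis_indicators(config)
  if (n == 0L) {
    cols <- if (output == "analysis")
      c("participant_id", "si_score", "li_score", "age", "female", "apoe4",
        inds)
    else c("participant_id", "age", "sex", "apoe4", raw_column_names())
    empty <- as.data.frame(stats::setNames(
      replicate(length(cols), numeric(0), simplify = FALSE), cols))
    truth <- data.frame(participant_id = character(0),
                        theta_si = numeric(0), theta_li = numeric(0),
                        SVD = numeric(0), ADpath = numeric(0),
                        Neuro = numeric(0), Cognition = numeric(0))
    return(structure(list(data = empty, truth = truth, config = config),
                     class = "sim_cohort"))
  }
  pid <- sprintf("P%05d", seq_len(n))

  set.seed(sub_seed(config$seed, "covariates"))
  age <- rtruncnorm(n, config$age$mean, config$age$sd,
                    config$age$lim[1], config$age$lim[2])
  female <- stats::rbinom(n, 1, config$p_female)
  apoe4 <- stats::rbinom(n, 1, config$p_apoe)

  set.seed(sub_seed(config$seed, "traits"))
  Th <- rmvn(n, c(0, 0), matrix(c(1, config$trait_corr,
                                  config$trait_corr, 1), 2))
  theta_si <- Th[, 1]; theta_li <- Th[, 2]

  set.seed(sub_seed(config$seed, "items"))
  si_items <- sample_grm_responses(theta_si, config$si_bank)
  li_items <- sample_grm_responses(theta_li, config$li_bank)
  sni_items <- sample_grm_responses(theta_li, config$sni_bank) - 1L # 0/1
  # leisure category -> plausible 0-15 count within the category range,
  # with the two physical items as a sub-count
  leisure_cat <- li_items[, "leisure_cat"]
  lo <- c(0L, 6L, 8L, 10L)[leisure_cat]
  hi <- c(5L, 7L, 9L, 15L)[leisure_cat]
  leisure_count <- lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L)))
  leisure_physical_count <- pmin(stats::rbinom(n, 2L, 0.5), leisure_count)

  set.seed(sub_seed(config$seed, "latents"))
  X <- cbind(si = theta_si, li = theta_li, age = age, female = female,
             apoe4 = apoe4)
  Xc <- sweep(X, 2, config$mu_x[colnames(X)])
  med <- c("SVD", "ADpath", "Neuro")
  E_med <- rmvn(n, c(0, 0, 0), config$Psi_med)
  M <- Xc %*% t(config$Gamma[med, ]) + E_med
  colnames(M) <- med
  cog <- as.numeric(Xc %*% config$Gamma["Cognition", ]) +
    as.numeric(M %*% config$b[med]) +
    stats::rnorm(n, 0, sqrt(config$psi[["Cognition"]]))
  eta <- cbind(M, Cognition = cog)

  set.seed(sub_seed(config$seed, "indicators"))
  Y <- matrix(NA_real_, n, length(inds), dimnames = list(NULL, inds))
  for (L in names(config$loadings)) for (ind in names(config$loadings[[L]])) {
    lam <- config$loadings[[L]][[ind]]
    Y[, ind] <- lam * eta[, L] + stats::rnorm(n, 0, sqrt(1 - lam^2))
  }

  truth <- data.frame(participant_id = pid, theta_si = theta_si,
                      theta_li = theta_li, SVD = M[, "SVD"],
                      ADpath = M[, "ADpath"], Neuro = M[, "Neuro"],
                      Cognition = cog)

  if (output == "analysis") {
    dat <- data.frame(participant_id = pid, si_score = theta_si,
                      li_score = theta_li, age = age, female = female,
                      apoe4 = apoe4)
    dat <- cbind(dat, as.data.frame(Y))
  } else {
    set.seed(sub_seed(config$seed, "raw"))
    dat <- raw_scale_table(pid, age, female, apoe4, Y, si_items, li_items,
                           sni_items, leisure_count, leisure_physical_count)
  }
  if (missingness) {
    dat <- impose_missingness(dat, config$missing_rates,
                              config$mar_strength,
                              seed = sub_seed(config$seed, "missing"),
                              item_missing = config$item_missing)
  }
  structure(list(data = dat, truth = truth, config = config),
            class = "sim_cohort")
}

raw_column_names <- function() {
  c("education", "occupation", "salary", "physical_activity",
    "leisure_count", "leisure_physical_count", "married", "close_ties",
    "membership", "tiv", "wmh_volume", "fazekas_peri", "fazekas_deep",
    "csf_ab42", "csf_ab40", "csf_ptau", "amyloid_suvr", "radioligand",
    "hippocampus_volume", "cortical_thickness", "bpf", "fdg_suvr",
    "fcsrt_free_recall", "verbal_fluency", "tmtb_seconds", "rey_score")
}

# Map analysis-scale indicators to realistic raw measurement scales,
# inverting the transforms applied by preprocess_cohort().
raw_scale_table <- function(pid, age, female, apoe4, Y, si_items, li_items,
                            sni_items, leisure_count,
                            leisure_physical_count) {
  n <- length(pid)
  tiv <- stats::rnorm(n, 1.45e6, 1.2e5)
  ligand <- sample(c("florbetapir", "flutemetamol"), n, replace = TRUE)
  mu_l <- ifelse(ligand == "florbetapir", 0.20, 0.35)
  sd_l <- ifelse(ligand == "florbetapir", 0.15, 0.18)
  data.frame(
    participant_id = pid,
    age = age,
    sex = ifelse(female == 1, "F", "M"),
    apoe4 = apoe4,
    education = si_items[, "education"],
    occupation = si_items[, "occupation"],
    salary = si_items[, "salary"],
    physical_activity = li_items[, "physical_activity"],
    leisure_count = leisure_count,
    leisure_physical_count = leisure_physical_count,
    married = sni_items[, "married"],
    close_ties = sni_items[, "close_ties"],
    membership = sni_items[, "membership"],
    tiv = tiv,
    wmh_volume = tiv * exp(-6.6 + 0.8 * Y[, "wmh_t"]),
    fazekas_peri = 1.2 + 0.7 * Y[, "fazekas_peri"],
    fazekas_deep = 0.9 + 0.6 * Y[, "fazekas_deep"],
    csf_ab40 = exp(stats::rnorm(n, 9.4, 0.25)),
    csf_ptau = exp(3.6 + 0.5 * Y[, "ptau_t"]),
    amyloid_suvr = exp(mu_l + sd_l * Y[, "amyloid_t"]),
    radioligand = ligand,
    hippocampus_volume = tiv * exp(-6.03 + 0.14 * (-Y[, "hippo_nd"])),
    cortical_thickness = 2.4 + 0.12 * (-Y[, "thickness_nd"]),
    bpf = 0.76 + 0.03 * (-Y[, "bpf_nd"]),
    fdg_suvr = 1.25 + 0.12 * (-Y[, "fdg_nd"]),
    fcsrt_free_recall = pmin(pmax(round(29 + 7 * Y[, "fcsrt_free_recall"]), 0), 48),
    verbal_fluency = pmax(round(28 + 8 * Y[, "verbal_fluency"]), 0),
    tmtb_seconds = exp(4.6 - 0.45 * Y[, "tmtb_t"]),
    rey_score = pmin(pmax(round(26 + 4 * Y[, "rey_score"]), 0), 36)
  ) -> dat
  # ab42 defined through the ratio indicator (floored at a small
  # positive value; the floor binds with probability ~2e-5)
  ratio <- pmax(0.075 + 0.018 * Y[, "ab_ratio"], 0.005)
  dat$csf_ab42 <- ratio * dat$csf_ab40
  dat[, c("participant_id", "age", "sex", "apoe4", raw_column_names())]
}

#' Impose modality-block and item-level missingness
#'
#' Sets whole measurement blocks (the CSF panel jointly; each PET
#' modality) missing with probability depending only on fully observed
#' covariates (age, sex), which makes the mechanism missing-at-random
#' by construction, and applies item-level MCAR missingness to the
#' ordinal items and APOE status.  The block intercepts are calibrated
#' so the realized marginal missingness matches the requested rates.
#'
#' @param data cohort table (raw or analysis scale).
#' @param missing_rates named vector with any of `csf`, `amyloid`,
#'   `fdg`.
#' @param mar_strength log-odds slope per SD of age (and half per unit
#'   of female sex).
#' @param seed integer seed.
#' @param item_missing named vector of item-level rates (see
#'   [sim_config()]); `NULL` applies none.
#' @return the table with NAs inserted.
#' @export
impose_missingness <- function(data, missing_rates, mar_strength = 0,
                               seed = 1, item_missing = NULL) {
  set.seed(seed)
  n <- nrow(data)
  if (n == 0L) return(data)
  fem <- if ("female" %in% names(data)) data$female
         else as.integer(data$sex == "F")
  zage <- if (stats::sd(data$age) > 0) zstd(data$age) else rep(0, n)
  eta <- mar_strength * zage + 0.5 * mar_strength * fem
  blocks <- list(
    csf = c("csf_ab42", "csf_ab40", "csf_ptau", "ab_ratio", "ptau_t"),
    amyloid = c("amyloid_suvr", "radioligand", "amyloid_t"),
    fdg = c("fdg_suvr", "fdg_nd"))
  for (bk in names(blocks)) {
    rate <- unname(missing_rates[bk])
    if (is.null(rate) || is.na(rate) || rate <= 0) next
    cols <- intersect(blocks[[bk]], names(data))
    if (!length(cols)) next
    if (rate >= 1) { data[, cols] <- NA; next }
    alpha <- stats::uniroot(function(a)
      mean(stats::plogis(a + eta)) - rate, c(-40, 40), tol = 1e-10)$root
    drop <- stats::runif(n) < stats::plogis(alpha + eta)
    data[drop, cols] <- NA
  }
  if (!is.null(item_missing)) {
    item_cols <- list(
      apoe4 = "apoe4", education = "education", occupation = "occupation",
      salary = "salary", physical_activity = "physical_activity",
      leisure = c("leisure_count", "leisure_physical_count"),
      sni = c("married", "close_ties", "membership"))
    for (it in names(item_cols)) {
      rate <- unname(item_missing[it])
      if (is.null(rate) || is.na(rate) || rate <= 0) next
      cols <- intersect(item_cols[[it]], names(data))
      if (!length(cols)) next
      drop <- stats::runif(n) < rate
      data[drop, cols] <- NA
    }
  }
  data
}

#' Write a simulated cohort to disk
#'
#' Writes `data.csv` (one row per participant, empty cell = missing),
#' `truth.csv`, and `config.json` (the scalar generator settings plus
#' the item banks) into `dir`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("data.csv", "truth.csv", "config.json"))
  utils::write.csv(cohort$data, paths[1], row.names = FALSE, na = "")
  utils::write.csv(cohort$truth, paths[2], row.names = FALSE, na = "")
  cfg <- cohort$config
  bank_json <- function(bank) lapply(bank, function(it)
    list(name = it$name, a = it$a, b = it$b))
  jsonlite::write_json(list(
    n = cfg$n, seed = cfg$seed, trait_corr = cfg$trait_corr,
    missing_rates = as.list(cfg$missing_rates),
    mar_strength = cfg$mar_strength,
    item_missing = as.list(cfg$item_missing),
    Gamma = cfg$Gamma, b = as.list(cfg$b),
    psi = as.list(cfg$psi),
    loadings = lapply(cfg$loadings, as.list),
    si_bank = bank_json(cfg$si_bank), li_bank = bank_json(cfg$li_bank),
    sni_bank = bank_json(cfg$sni_bank)), paths[3],
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
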