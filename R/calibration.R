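#' Reference standardized path estimates
#'
#' Standardized direct, indirect, and total effect estimates from the
#' motivating clinic-based cohort analysis (N = 2323 memory-clinic
#' participants) of two life-course exposure scores (early-to-midlife
#' social indicator `si`, latelife lifestyle indicator `li`) and three
#' covariates (`female`, `age` in years, `apoe4`) acting on a latent
#' cognition factor directly and through three latent pathology
#' mediators (`SVD`, `ADpath`, `Neuro`).  These values serve two
#' purposes: they are the default structural coefficients of the
#' synthetic-cohort generator (so parameter-recovery tests target a
#' realistic regime), and their internal arithmetic (indirect = product
#' of paths, total = direct + sum of indirects) is used as a fast
#' consistency check of the effect-decomposition machinery.
#'
#' Exposure/covariate effects are standardized on the endogenous side
#' only (unit-variance latents; `age` per year, binary covariates as
#' group jumps), matching [standardize_solution()] mode
#' `"endogenous"`.
#'
#' @return data frame with columns `from`, `to`, `channel`
#'   (`"direct"`, a mediator name for indirect rows, or `"total"`),
#'   `type` (`direct`/`indirect`/`total`/`correlation`), and `beta`.
#' @export
reference_path_estimates <- function() {
  d <- function(from, to, beta)
    data.frame(from = from, to = to, channel = "direct", type = "direct",
               beta = beta, stringsAsFactors = FALSE)
  ind <- function(from, med, beta)
    data.frame(from = from, to = "Cognition", channel = med,
               type = "indirect", beta = beta, stringsAsFactors = FALSE)
  tot <- function(from, beta)
    data.frame(from = from, to = "Cognition", channel = "total",
               type = "total", beta = beta, stringsAsFactors = FALSE)
  corr <- function(a, b, beta)
    data.frame(from = a, to = b, channel = "correlation",
               type = "correlation", beta = beta, stringsAsFactors = FALSE)
  rbind(
    # exposures -> mediators and cognition
    d("si", "SVD", -0.001), d("si", "ADpath", -0.034),
    d("si", "Neuro", -0.030), d("si", "Cognition", 0.364),
    d("li", "SVD", -0.031), d("li", "ADpath", -0.036),
    d("li", "Neuro", -0.116), d("li", "Cognition", 0.076),
    # mediators -> cognition
    d("ADpath", "Cognition", -0.264),
    d("SVD", "Cognition", -0.039),
    d("Neuro", "Cognition", -0.574),
    # covariates -> mediators and cognition
    d("female", "SVD", 0.016), d("female", "ADpath", -0.129),
    d("female", "Neuro", -0.603), d("female", "Cognition", -0.193),
    d("age", "SVD", 0.053), d("age", "ADpath", 0.048),
    d("age", "Neuro", 0.075), d("age", "Cognition", 0.015),
    d("apoe4", "SVD", 0.085), d("apoe4", "ADpath", 0.835),
    d("apoe4", "Neuro", 0.199), d("apoe4", "Cognition", 0.023),
    # printed indirect effects (exposure/covariate -> cognition via mediator)
    ind("si", "ADpath", 0.009), ind("si", "SVD", 0.000),
    ind("si", "Neuro", 0.017),
    ind("li", "ADpath", 0.010), ind("li", "SVD", 0.001),
    ind("li", "Neuro", 0.066),
    ind("female", "ADpath", 0.034), ind("female", "SVD", -0.001),
    ind("female", "Neuro", 0.346),
    ind("age", "ADpath", -0.013), ind("age", "SVD", -0.002),
    ind("age", "Neuro", -0.043),
    ind("apoe4", "ADpath", -0.220), ind("apoe4", "SVD", -0.003),
    ind("apoe4", "Neuro", -0.114),
    # printed totals
    tot("si", 0.390), tot("li", 0.153), tot("female", 0.186),
    tot("age", -0.042),
    # mediator residual correlations
    corr("ADpath", "Neuro", 0.249), corr("ADpath", "SVD", 0.139),
    corr("SVD", "Neuro", 0.225))
}

#' Reference cohort margins
#'
#' Category counts of the ordinal social/lifestyle items and key
#' covariates in the motivating cohort (total N = 2323, of whom 885 men
#' and 1438 women), together with the percentages as printed in its
#' descriptive table (computed over the full N, missing included).
#' Used to calibrate the default item banks of the synthetic-cohort
#' generator and to check the descriptive-summary arithmetic.
#'
#' @return data frame with columns `variable`, `level`, `count`,
#'   `printed_pct`; attribute `n_total` = 2323 and `item_missing`
#'   (named missing counts per item).
#' @export
reference_cohort_margins <- function() {
  m <- function(variable, level, count, printed_pct)
    data.frame(variable = variable, level = level, count = count,
               printed_pct = printed_pct, stringsAsFactors = FALSE)
  out <- rbind(
    m("sex", "men", 885, 38.1), m("sex", "women", 1438, 61.9),
    m("apoe4", "non-carrier", 1538, 66.2), m("apoe4", "carrier", 658, 28.3),
    m("cdr", "0", 933, 40.2), m("cdr", "0.5", 1375, 59.2),
    m("education", "primary", 371, 16.0),
    m("education", "short secondary", 677, 29.1),
    m("education", "long secondary", 362, 15.6),
    m("education", "college+", 908, 39.1),
    m("occupation", "lower", 469, 20.2),
    m("occupation", "intermediate", 1093, 47.1),
    m("occupation", "higher", 735, 31.6),
    m("salary", "400-800", 46, 2.0), m("salary", "800-1200", 126, 5.4),
    m("salary", "1200-1800", 311, 13.4), m("salary", "1800-2500", 407, 17.5),
    m("salary", "2500-4000", 640, 27.6), m("salary", "4000-6000", 341, 14.7),
    m("salary", "6000+", 135, 5.8),
    m("physical_activity", "low", 350, 15.1),
    m("physical_activity", "moderate", 902, 38.8),
    m("physical_activity", "vigorous", 818, 35.2),
    m("leisure", "<6", 594, 25.6), m("leisure", "6-7", 782, 33.7),
    m("leisure", "8-9", 580, 25.0), m("leisure", ">9", 238, 10.2),
    m("sni", "0", 174, 7.5), m("sni", "1", 642, 27.6),
    m("sni", "2", 1085, 46.7), m("sni", "3", 280, 12.1))
  attr(out, "n_total") <- 2323L
  attr(out, "age_mean") <- 70.9
  attr(out, "age_sd") <- 8.7
  attr(out, "item_missing") <- c(apoe4 = 127L, education = 5L,
                                 occupation = 26L, salary = 317L,
                                 physical_activity = 253L, leisure = 129L,
                                 sni = 142L)
  out
}

# Structural coefficient matrices implied by the reference estimates:
# Gamma (4 outcomes x 5 predictors) and b (3 mediator -> cognition).
reference_structural <- function() {
  ref <- reference_path_estimates()
  dir <- ref[ref$type == "direct", ]
  get <- function(from, to) dir$beta[dir$from == from & dir$to == to]
  preds <- c("si", "li", "age", "female", "apoe4")
  outs <- c("SVD", "ADpath", "Neuro", "Cognition")
  G <- matrix(0, 4, 5, dimnames = list(outs, preds))
  for (o in outs) for (p in preds) G[o, p] <- get(p, o)
  b <- c(SVD = get("SVD", "Cognition"), ADpath = get("ADpath", "Cognition"),
         Neuro = get("Neuro", "Cognition"))
  med_corr <- matrix(c(1, 0.139, 0.225,
                       0.139, 1, 0.249,
                       0.225, 0.249, 1), 3, 3,
                     dimnames = list(c("SVD", "ADpath", "Neuro"),
                                     c("SVD", "ADpath", "Neuro")))
  list(Gamma = G, b = b, med_corr = med_corr)
}
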