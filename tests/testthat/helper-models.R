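# Shared fixtures: small item banks, small SEM models, and simulators
# used across test files.  Everything is generated in code.

toy_bank <- function() {
  list(grm_item(1.2, c(-1.2, 0.2, 1.1), name = "itemA"),
       grm_item(1.0, c(-0.8, 0.6), name = "itemB"),
       grm_item(1.3, c(-0.3, 0.4, 1.3), name = "itemC"))
}

# One-factor model with four indicators (used for chi-square
# calibration and fit-index behaviour).
onefac_model <- "
  F =~ y1 + y2 + y3 + y4
  F ~ x
"

onefac_truth <- list(lambda = c(1, 0.8, 0.7, 0.6), resid = c(0.5, 0.6, 0.7, 0.8),
                     gamma = 0.5, psi = 0.75)

sim_onefac <- function(n, seed) {
  set.seed(seed)
  tr <- onefac_truth
  x <- rnorm(n)
  f <- tr$gamma * x + rnorm(n, 0, sqrt(tr$psi))
  Y <- sapply(1:4, function(j) tr$lambda[j] * f + rnorm(n, 0, sqrt(tr$resid[j])))
  colnames(Y) <- paste0("y", 1:4)
  data.frame(x = x, Y)
}

# Observed-variable mediation path model x -> m -> y (plus direct).
path3_model <- "
  m ~ x
  y ~ x + m
"

path3_truth <- list(a = 0.45, b = 0.5, cp = 0.25, v_m = 0.8, v_y = 0.7)

sim_path3 <- function(n, seed) {
  set.seed(seed)
  tr <- path3_truth
  x <- rnorm(n)
  m <- tr$a * x + rnorm(n, 0, sqrt(tr$v_m))
  y <- tr$cp * x + tr$b * m + rnorm(n, 0, sqrt(tr$v_y))
  data.frame(x = x, m = m, y = y)
}

# Latent mediation model: exposure x, latent mediator M (3 indicators),
# latent outcome Y (3 indicators).
medlat_model <- "
  M =~ m1 + m2 + m3
  Y =~ w1 + w2 + w3
  M ~ x
  Y ~ x + M
"

medlat_truth <- list(a = 0.4, b = 0.5, cp = 0.2,
                     lam_m = c(1, 0.9, 0.8), lam_y = c(1, 0.85, 0.75),
                     resid_m = c(0.4, 0.5, 0.55), resid_y = c(0.45, 0.5, 0.6),
                     psi_m = 0.84, psi_y = 0.6)

sim_medlat <- function(n, seed) {
  set.seed(seed)
  tr <- medlat_truth
  x <- rnorm(n)
  M <- tr$a * x + rnorm(n, 0, sqrt(tr$psi_m))
  Y <- tr$cp * x + tr$b * M + rnorm(n, 0, sqrt(tr$psi_y))
  dm <- sapply(1:3, function(j) tr$lam_m[j] * M + rnorm(n, 0, sqrt(tr$resid_m[j])))
  dy <- sapply(1:3, function(j) tr$lam_y[j] * Y + rnorm(n, 0, sqrt(tr$resid_y[j])))
  colnames(dm) <- paste0("m", 1:3); colnames(dy) <- paste0("w", 1:3)
  data.frame(x = x, dm, dy)
}

# Quick fitted SEM reused by several effect tests (cached per session).
cached_medlat_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      dat <- sim_medlat(800, seed = 4242)
      fit <<- fit_sem(medlat_model, dat)
    }
    fit
  }
})
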