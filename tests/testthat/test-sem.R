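make_matrices <- function(A, S, m, obs, lat = character(0)) {
  all <- c(obs, lat)
  dimnames(A) <- dimnames(S) <- list(all, all)
  structure(list(A = A, S = S, m = setNames(m, all), obs = obs, lat = lat,
                 obs_idx = setNames(match(obs, all), obs), all = all),
            class = "sem_matrices")
}

test_that("implied moments reduce to F S F' and F m with no paths", {
  S <- matrix(c(2, 0.5, 0.5, 1.5), 2)
  mat <- make_matrices(matrix(0, 2, 2), S, c(1, -2), obs = c("a", "b"))
  imp <- implied_moments(mat)
  expect_equal(unname(imp$sigma), S)
  expect_equal(unname(imp$mu), c(1, -2))
})

test_that("implied moments match a generative-recursion simulation oracle", {
  # x -> m -> y with a direct x -> y path; moments simulated by the
  # explicit recursion, never through the RAM algebra
  A <- matrix(0, 3, 3); S <- matrix(0, 3, 3)
  a <- 0.7; b <- -0.6; cp <- 0.3
  A[2, 1] <- a; A[3, 1] <- cp; A[3, 2] <- b
  S[1, 1] <- 1.2; S[2, 2] <- 0.8; S[3, 3] <- 0.5
  mat <- make_matrices(A, S, c(0.3, -0.1, 0.2), obs = c("x", "m", "y"))
  imp <- implied_moments(mat)
  set.seed(11)
  n <- 2e5
  x <- 0.3 + rnorm(n, 0, sqrt(1.2))
  m <- -0.1 + a * x + rnorm(n, 0, sqrt(0.8))
  y <- 0.2 + cp * x + b * m + rnorm(n, 0, sqrt(0.5))
  D <- cbind(x = x, m = m, y = y)
  expect_equal(unname(imp$sigma), unname(cov(D)), tolerance = 0.02)
  expect_equal(unname(imp$mu), unname(colMeans(D)), tolerance = 0.02)
  # closed-form spot check: Var(y) by path arithmetic
  vy <- 0.5 + (cp + a * b)^2 * 1.2 + b^2 * 0.8
  expect_equal(imp$sigma["y", "y"], vy, tolerance = 1e-12)
})

test_that("a cyclic specification is rejected by name", {
  expect_error(sem_spec("a ~ b; b ~ a"), "cyclic")
})

test_that("FIML loglik equals the complete-data multivariate normal density", {
  skip_if_not_installed("mvtnorm")
  set.seed(21)
  mu <- c(x = 0.2, y = -0.4, z = 1)
  Sg <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  dimnames(Sg) <- list(names(mu), names(mu))
  D <- as.data.frame(pathsem:::rmvn(40, mu, Sg))
  names(D) <- names(mu)
  ours <- loglik_fiml(D, mu, Sg)
  oracle <- sum(mvtnorm::dmvnorm(as.matrix(D), mu, Sg, log = TRUE))
  expect_equal(ours, oracle, tolerance = 1e-8)
  # additivity across disjoint halves
  expect_equal(loglik_fiml(D[1:20, ], mu, Sg) +
                 loglik_fiml(D[21:40, ], mu, Sg), ours, tolerance = 1e-8)
})

test_that("a single standard-normal observation at zero scores -log(2pi)/2", {
  D <- data.frame(y = 0)
  expect_equal(loglik_fiml(D, c(y = 0), matrix(1, 1, 1)),
               -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("missing cells contribute their observed subvector only", {
  skip_if_not_installed("mvtnorm")
  set.seed(22)
  mu <- c(x = 0, y = 0.5)
  Sg <- matrix(c(1, 0.6, 0.6, 2), 2, dimnames = list(names(mu), names(mu)))
  D <- as.data.frame(pathsem:::rmvn(10, mu, Sg)); names(D) <- names(mu)
  D$y[1:3] <- NA
  ours <- loglik_fiml(D, mu, Sg)
  oracle <- sum(mvtnorm::dmvnorm(as.matrix(D[4:10, ]), mu, Sg, log = TRUE)) +
    sum(dnorm(D$x[1:3], 0, 1, log = TRUE))
  expect_equal(ours, oracle, tolerance = 1e-10)
})

test_that("the analytic FIML gradient matches numerical differentiation", {
  skip_if_not_installed("numDeriv")
  dat <- sim_medlat(120, seed = 31)
  dat$m2[1:30] <- NA; dat$w1[10:40] <- NA   # two extra patterns
  spec <- sem_spec(medlat_model)
  template <- pathsem:::build_ram(spec, dat)
  st <- pathsem:::ram_start(template, dat)
  theta <- st$start[template$par_table$free]
  patterns <- pathsem:::fiml_patterns(dat, template$vars$obs)
  f <- function(th) {
    imp <- implied_moments(pathsem:::theta_to_matrices(template, th))
    pathsem:::fiml_loglik_patterns(imp$mu, imp$sigma, patterns)
  }
  for (jit in c(0, 0.05)) {
    th <- theta * (1 + jit) + jit * 0.02
    g_num <- numDeriv::grad(f, th)
    g_ana <- pathsem:::fiml_theta_gradient(template, th, patterns)
    expect_equal(g_ana, g_num, tolerance = 1e-5)
  }
})

test_that("complete-data FIML matches a covariance-fitting ML oracle", {
  dat <- sim_medlat(500, seed = 41)
  fit <- fit_sem(medlat_model, dat, se = FALSE, standardize = FALSE)
  template <- fit$template
  # independent route: minimize the ML discrepancy computed from the
  # sample moments only (no casewise likelihood)
  n <- nrow(dat)
  Ybar <- colMeans(dat[template$vars$obs])
  Sml <- cov(dat[template$vars$obs]) * (n - 1) / n
  disc <- function(th) {
    imp <- tryCatch(implied_moments(pathsem:::theta_to_matrices(template, th)),
                    error = function(e) NULL)
    if (is.null(imp)) return(1e10)
    ch <- tryCatch(chol(imp$sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Kin <- chol2inv(ch)
    d <- Ybar - imp$mu
    2 * sum(log(diag(ch))) + sum(Kin * Sml) + as.numeric(t(d) %*% Kin %*% d)
  }
  st <- pathsem:::ram_start(template, dat)
  o <- optim(st$start[template$par_table$free], disc, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(max(abs(o$par - fit$theta)), 1e-4)
})

test_that("FIML-saturated moments equal sample moments on complete data", {
  dat <- sim_onefac(200, seed = 51)
  sat <- fiml_saturated(dat)
  expect_equal(sat$mu, colMeans(dat), tolerance = 1e-12)
  expect_equal(unname(sat$sigma),
               unname(cov(dat) * (nrow(dat) - 1) / nrow(dat)),
               tolerance = 1e-12)
  base <- fiml_baseline(dat)
  expect_lte(base$loglik, sat$loglik)
})

test_that("the saturated EM handles missingness and dominates the baseline", {
  dat <- sim_onefac(400, seed = 52)
  dat$y1[1:100] <- NA; dat$y3[50:200] <- NA
  sat <- fiml_saturated(dat)
  expect_true(sat$converged)
  base <- fiml_baseline(dat)
  expect_lte(base$loglik, sat$loglik)
  # EM solution is a stationary point: nearby moment perturbations
  # cannot improve the pattern likelihood
  pats <- pathsem:::fiml_patterns(dat, colnames(dat))
  ll0 <- pathsem:::fiml_loglik_patterns(sat$mu, sat$sigma, pats)
  set.seed(1)
  for (r in 1:5) {
    mu2 <- sat$mu + rnorm(5, 0, 0.01)
    P <- matrix(rnorm(25, 0, 0.005), 5); P <- (P + t(P)) / 2
    expect_lte(pathsem:::fiml_loglik_patterns(mu2, sat$sigma + P, pats),
               ll0 + 1e-6)
  }
})

test_that("model degrees of freedom count moments minus free parameters", {
  dat <- sim_onefac(150, seed = 53)
  fit <- fit_sem(onefac_model, dat, se = FALSE, standardize = FALSE)
  p <- 5
  expect_identical(fit$df, p * (p + 3) / 2 - length(fit$theta))
  expect_identical(fit$df_base, p * (p + 3) / 2 - 2 * p)
})

test_that("a just-identified model has chi-square zero and undefined indices", {
  dat <- sim_path3(200, seed = 54)
  fit <- fit_sem(path3_model, dat, se = FALSE, standardize = FALSE)
  expect_identical(fit$df, 0)
  expect_lt(fit$Tstat, 1e-4)
  expect_true(is.na(fit$indices$rmsea))
})

test_that("fit indices behave on correctly and incorrectly specified models", {
  dat <- sim_onefac(500, seed = 55)
  fit <- fit_sem(onefac_model, dat)
  expect_lt(fit$indices$rmsea, 0.05)
  expect_gt(fit$indices$cfi, 0.97)
  expect_lte(fit$indices$rmsea_ci[1], fit$indices$rmsea + 1e-12)
  expect_gte(fit$indices$rmsea_ci[2], fit$indices$rmsea - 1e-12)
  expect_lt(fit$indices$srmr, 0.05)
  # break the structure: y4 gets a large correlated twin of y1's error
  dat2 <- dat
  set.seed(56)
  e <- rnorm(500, 0, 0.4)
  dat2$y1 <- dat2$y1 + e
  dat2$y4 <- dat2$y4 + 1.4 * e
  fit2 <- fit_sem(onefac_model, dat2)
  expect_gt(fit2$indices$rmsea, fit$indices$rmsea)
  expect_lt(fit2$indices$cfi, fit$indices$cfi)
  expect_gt(fit2$indices$srmr, fit$indices$srmr)
})

test_that("the chi-square statistic is calibrated under the true model", {
  reps <- 150
  Ts <- numeric(reps)
  dfs <- NA
  for (r in seq_len(reps)) {
    dat <- sim_onefac(300, seed = 6000 + r)
    f <- suppressWarnings(fit_sem(onefac_model, dat, se = FALSE,
                                  standardize = FALSE))
    Ts[r] <- f$Tstat
    dfs <- f$df
  }
  expect_identical(dfs, 5)
  expect_lt(abs(mean(Ts) - dfs) / dfs, 0.10)
})

test_that("the standardized solution is invariant to indicator rescaling", {
  dat <- sim_medlat(600, seed = 61)
  fit1 <- fit_sem(medlat_model, dat)
  dat2 <- dat
  dat2$m1 <- dat2$m1 * 10
  fit2 <- fit_sem(medlat_model, dat2)
  # raw loading and residual rescale accordingly ...
  l1 <- fit1$par_table
  l2 <- fit2$par_table
  g <- function(tab, lab) tab$est[tab$label == lab]
  expect_equal(g(l2, "M=~m2") * 10, g(l1, "M=~m2"), tolerance = 1e-3)
  expect_equal(g(l2, "m1~~m1"), 100 * g(l1, "m1~~m1"), tolerance = 1e-3)
  # ... while the standardized solution and the fit indices do not move
  expect_equal(fit2$std$std, fit1$std$std, tolerance = 1e-4)
  expect_equal(fit2$indices$rmsea, fit1$indices$rmsea, tolerance = 1e-4)
  expect_equal(fit2$indices$srmr, fit1$indices$srmr, tolerance = 1e-4)
  expect_equal(fit2$indices$cfi, fit1$indices$cfi, tolerance = 1e-4)
  expect_equal(fit2$Tstat, fit1$Tstat, tolerance = 1e-3)
})

test_that("standardized variances partition and match raw estimates on a unit-scale system", {
  fit <- cached_medlat_fit()
  std <- fit$std
  # standardized residual variance of each indicator equals 1 minus its
  # squared standardized loading (single-factor indicators)
  for (ind in c("m2", "m3", "w2", "w3")) {
    lam <- std$std[std$label %in% paste0(c("M=~", "Y=~"), ind)]
    th <- std$std[std$label == paste0(ind, "~~", ind)]
    expect_equal(th, 1 - lam^2, tolerance = 1e-8)
  }
  # generative latents have near-unit variance, so standardized and raw
  # structural coefficients agree up to sampling scale
  a_raw <- fit$par_table$est[fit$par_table$label == "M~x"]
  a_std <- std$std[std$label == "M~x"]
  expect_equal(a_std, a_raw * 1 /
                 sqrt(implied_moments(fit$matrices)$sigma_all["M", "M"]),
               tolerance = 1e-10)
})

test_that("FIML remains unbiased under block MCAR where listwise deletion degrades", {
  dat <- sim_medlat(900, seed = 71)
  set.seed(72)
  for (cl in c("m1", "m2", "m3", "w1", "w2", "w3"))
    dat[[cl]][runif(900) < 0.3] <- NA
  fit <- suppressWarnings(fit_sem(medlat_model, dat))
  g <- function(lab) fit$par_table[fit$par_table$label == lab, ]
  expect_lt(abs(g("M~x")$est - medlat_truth$a), 3 * g("M~x")$se)
  expect_lt(abs(g("Y~M")$est - medlat_truth$b), 3 * g("Y~M")$se)
  # listwise deletion keeps ~0.7^6 of rows; its SEs must be clearly wider
  cc <- dat[complete.cases(dat), ]
  expect_lt(nrow(cc), 200)
  fit_cc <- suppressWarnings(fit_sem(medlat_model, cc))
  se_ratio <- fit_cc$par_table$se[fit_cc$par_table$label == "M~x"] /
    g("M~x")$se
  expect_gt(se_ratio, 1.5)
})

test_that("rows with every modelled variable missing are dropped with a warning", {
  dat <- sim_onefac(60, seed = 81)
  dat[1, ] <- NA
  expect_warning(f <- fit_sem(onefac_model, dat, se = FALSE,
                              standardize = FALSE), "dropped")
  expect_identical(f$n, 59L)
})
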