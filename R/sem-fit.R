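#' Fit a structural equation model by FIML
#'
#' Maximizes the full-information maximum likelihood of a [sem_spec()]
#' model by quasi-Newton iteration (with analytic gradients via the RAM
#' chain rule), starting from moment-based start values.  Standard
#' errors come from the inverse of the numerically differentiated
#' observed information.  Missing data are handled casewise under the
#' missing-at-random assumption; rows are grouped by missingness
#' pattern.
#'
#' @param spec a [sem_spec()] object or a model string.
#' @param data data frame containing every observed model variable.
#' @param se compute standard errors (numerical Hessian)?  Default TRUE.
#' @param standardize compute the standardized solution and its
#'   delta-method covariance?  Default TRUE.
#' @param std_mode standardization mode passed to
#'   [standardize_solution()].
#' @param ci_level confidence level for the RMSEA interval.
#' @param restarts number of jittered restarts attempted if the
#'   optimizer reports a poor solution.
#' @param control optimizer control: `iter_max` (default 1000),
#'   `grad_tol` (default 1e-5 on the max absolute gradient).
#' @return an object of class `"sem_fit"`; see [fit_indices()],
#'   [standardize_solution()], [effect_table()].
#' @export
fit_sem <- function(spec, data, se = TRUE, standardize = TRUE,
                    std_mode = c("endogenous", "all"), ci_level = 0.90,
                    restarts = 3, control = list()) {
  std_mode <- match.arg(std_mode)
  if (is.character(spec)) spec <- sem_spec(spec)
  template <- build_ram(spec, data)
  # drop rows with no observed modelled variable once, up front
  none <- rowSums(!is.na(data[template$vars$obs])) == 0L
  if (any(none)) {
    warning(sum(none), " row(s) with no observed modelled variable dropped")
    data <- data[!none, , drop = FALSE]
  }
  st <- ram_start(template, data)
  theta0 <- st$start[template$par_table$free]
  patterns <- fiml_patterns(data, template$vars$obs)
  n <- attr(patterns, "n")
  iter_max <- control$iter_max %||% 1000
  grad_tol <- control$grad_tol %||% 1e-5

  negll <- function(theta) {
    mat <- theta_to_matrices(template, theta)
    imp <- tryCatch(implied_moments(mat), error = function(e) NULL)
    if (is.null(imp)) return(1e10)
    ll <- fiml_loglik_patterns(imp$mu, imp$sigma, patterns)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  neggrad <- function(theta) -fiml_theta_gradient(template, theta, patterns)

  # BFGS with analytic gradients, then an nlminb polish: BFGS is robust
  # on the ridged surfaces that heavy block missingness produces, while
  # nlminb tightens the final gradient norm.
  run_opt <- function(start) {
    o <- stats::optim(start, negll, neggrad, method = "BFGS",
                      control = list(maxit = iter_max, reltol = 1e-14))
    p <- stats::nlminb(o$par, negll, gradient = neggrad,
                       control = list(iter.max = iter_max,
                                      eval.max = 3 * iter_max,
                                      rel.tol = 1e-12))
    if (p$objective <= o$value) list(par = p$par, objective = p$objective)
    else list(par = o$par, objective = o$value)
  }
  best <- run_opt(theta0)
  gnorm <- max(abs(neggrad(best$par)))
  # gradient tolerance on a scale commensurate with the log-likelihood
  gtol_eff <- function(obj) max(grad_tol, 1e-6 * (1 + abs(obj)))
  tries <- 0L
  while ((gnorm > gtol_eff(best$objective) || best$objective >= 1e9) &&
         tries < restarts) {
    tries <- tries + 1L
    start <- if (tries %% 2L == 1L && best$objective < 1e9) best$par
             else theta0 * (1 + stats::rnorm(length(theta0), 0, 0.1)) +
               stats::rnorm(length(theta0), 0, 0.02)
    cand <- run_opt(start)
    if (cand$objective < best$objective) best <- cand
    gnorm <- max(abs(neggrad(best$par)))
  }
  converged <- is.finite(best$objective) && best$objective < 1e9 &&
    gnorm <= gtol_eff(best$objective)
  if (!converged)
    warning("SEM optimization did not converge cleanly (max |gradient| = ",
            format(gnorm, digits = 3), ")")

  theta <- best$par
  ll <- -best$objective
  pt <- template$par_table
  free <- which(pt$free)
  pt$est <- pt$value
  pt$est[free] <- theta

  # Heywood check: negative residual variances
  var_rows <- free[pt$mat[free] == "S" & pt$i[free] == pt$j[free]]
  heywood <- any(pt$est[var_rows] < 0)
  if (heywood)
    warning("Heywood case: negative estimated residual variance(s): ",
            paste(pt$label[var_rows][pt$est[var_rows] < 0], collapse = ", "))

  vcov_free <- NULL
  pt$se <- NA_real_
  if (se) {
    H <- jacobian_cd(neggrad, theta)     # Hessian of -ll
    H <- (H + t(H)) / 2
    vcov_free <- tryCatch(solve(H), error = function(e) pinv(H))
    dv <- diag(vcov_free)
    if (any(dv < 0)) {
      warning("observed information not positive definite; ",
              "some standard errors unavailable")
      dv[dv < 0] <- NA_real_
    }
    pt$se[free] <- sqrt(dv)
    dimnames(vcov_free) <- list(pt$label[free], pt$label[free])
  }
  pt$z <- pt$est / pt$se
  pt$p <- 2 * stats::pnorm(-abs(pt$z))

  sat <- st$sat
  base <- fiml_baseline(data[template$vars$obs])
  p_obs <- length(template$vars$obs)
  df <- p_obs * (p_obs + 3) / 2 - length(free)
  df_base <- p_obs * (p_obs + 3) / 2 - base$df
  Tstat <- max(2 * (sat$loglik - ll), 0)
  T_base <- max(2 * (sat$loglik - base$loglik), 0)

  mat <- theta_to_matrices(template, theta)
  fit <- structure(list(
    spec = spec, template = template, theta = theta, par_table = pt,
    matrices = mat, vcov = vcov_free, loglik = ll,
    loglik_sat = sat$loglik, loglik_base = base$loglik,
    sigma_sat = sat$sigma, mu_sat = sat$mu,
    n = n, df = df, df_base = df_base, Tstat = Tstat, T_base = T_base,
    patterns = length(patterns), heywood = heywood,
    convergence = list(code = best$convergence, grad_norm = gnorm,
                       restarts = tries, converged = converged),
    ci_level = ci_level), class = "sem_fit")
  fit$indices <- fit_indices(fit, ci_level = ci_level)
  if (standardize && se) {
    std <- standardize_solution(fit, mode = std_mode)
    fit$std <- std$table
    fit$vcov_std <- std$vcov
    fit$std_mode <- std_mode
  }
  fit
}

#' Global fit indices
#'
#' Chi-square based indices relative to the FIML-saturated and baseline
#' (independence) models: `T = 2(ll_sat - ll_model)`,
#' `RMSEA = sqrt(max(0, (T - df) / (df n)))` with a confidence interval
#' from root-finding on the noncentral chi-square, `CFI`, `TLI`, and
#' `SRMR` computed from standardized residual moments between the
#' FIML-saturated and model-implied covariance matrices.
#'
#' @param fit a [fit_sem()] object.
#' @param ci_level RMSEA confidence level (default 0.90).
#' @return list with `chisq`, `df`, `pvalue`, `rmsea`, `rmsea_ci`,
#'   `srmr`, `cfi`, `tli`.
#' @export
fit_indices <- function(fit, ci_level = 0.90) {
  Tm <- fit$Tstat; df <- fit$df
  Tb <- fit$T_base; dfb <- fit$df_base
  n <- fit$n
  if (df <= 0) {
    rmsea <- NA_real_; ci <- c(NA_real_, NA_real_)
    cfi <- NA_real_; tli <- NA_real_
  } else {
    rmsea <- sqrt(max(0, (Tm - df) / (df * n)))
    alpha <- (1 - ci_level) / 2
    ncp_root <- function(target) {
      f <- function(l) stats::pchisq(Tm, df, ncp = l) - target
      if (f(0) < 0) return(0)
      upper <- max(Tm * 2, 10)
      while (f(upper) > 0 && upper < 1e7) upper <- upper * 2
      stats::uniroot(f, c(0, upper), tol = 1e-8)$root
    }
    lo <- ncp_root(1 - alpha)
    hi <- ncp_root(alpha)
    ci <- sqrt(pmax(0, c(lo, hi) / (df * n)))
    cfi <- 1 - max(Tm - df, 0) / max(Tb - dfb, Tm - df, 0)
    if (!is.finite(cfi)) cfi <- 1
    tli <- if (dfb > 0 && Tb / dfb > 1)
      ((Tb / dfb) - (Tm / df)) / ((Tb / dfb) - 1) else NA_real_
  }
  # SRMR against FIML-saturated moments (Bentler form, diagonal included)
  Ssat <- fit$sigma_sat
  imp <- implied_moments(fit$matrices)
  Smod <- imp$sigma
  dsd <- sqrt(diag(Ssat))
  p <- nrow(Ssat)
  acc <- 0; cnt <- 0
  for (i in seq_len(p)) for (j in seq_len(i)) {
    if (i == j) acc <- acc + ((Ssat[i, i] - Smod[i, i]) / Ssat[i, i])^2
    else acc <- acc + ((Ssat[i, j] - Smod[i, j]) / (dsd[i] * dsd[j]))^2
    cnt <- cnt + 1
  }
  srmr <- sqrt(acc / cnt)
  list(chisq = Tm, df = df,
       pvalue = if (df > 0) stats::pchisq(Tm, df, lower.tail = FALSE) else NA,
       rmsea = rmsea, rmsea_ci = ci, rmsea_ci_level = ci_level,
       srmr = srmr, cfi = cfi, tli = tli,
       chisq_base = Tb, df_base = dfb)
}

# Standardized value of every parameter row for a given theta.
std_values <- function(template, theta, mode) {
  mat <- theta_to_matrices(template, theta)
  imp <- implied_moments(mat)
  sdall <- sqrt(pmax(diag(imp$sigma_all), 0))
  if (any(sdall == 0))
    stop("zero implied variance for: ",
         paste(template$all[sdall == 0], collapse = ", "))
  v <- template$vars
  is_exo_obs <- template$all %in% v$exo_obs
  pt <- template$par_table
  vals <- pt$value
  vals[pt$free] <- theta
  out <- numeric(nrow(pt))
  for (r in seq_len(nrow(pt))) {
    i <- pt$i[r]; j <- pt$j[r]
    out[r] <- switch(pt$mat[r],
      A = {
        s_src <- if (mode == "endogenous" && is_exo_obs[j]) 1 else sdall[j]
        vals[r] * s_src / sdall[i]
      },
      S = if (i == j) vals[r] / sdall[i]^2
          else vals[r] / sqrt(mat$S[i, i] * mat$S[j, j]),
      m = {
        s_i <- if (mode == "endogenous" && is_exo_obs[i]) 1 else sdall[i]
        vals[r] / s_i
      })
  }
  out
}

#' Standardized solution with delta-method standard errors
#'
#' Rescales every estimate by model-implied standard deviations and
#' propagates the estimate covariance to the standardized scale by the
#' delta method (numerical Jacobian of the standardization map).
#'
#' Two modes are available.  `"endogenous"` (default) standardizes the
#' latent variables (and indicators) but leaves observed exogenous
#' predictors in their natural units, so a regression coefficient is
#' the change in SD units of the outcome per unit of the predictor --
#' the convention under which effects of age (per year) or binary
#' covariates (group jump) are reported alongside unit-variance
#' exposure scores.  `"all"` fully standardizes every variable.
#' Free covariances are always converted to residual correlations
#' (covariance over the product of the two residual SDs); residual
#' variances become proportions of the variable's total variance.
#'
#' @param fit a [fit_sem()] object (with standard errors).
#' @param mode `"endogenous"` or `"all"`.
#' @return list with `table` (parameter table plus `std`/`std_se`
#'   columns) and `vcov` (covariance of the standardized estimates).
#' @export
standardize_solution <- function(fit, mode = c("endogenous", "all")) {
  mode <- match.arg(mode)
  template <- fit$template
  f <- function(th) std_values(template, th, mode)
  std <- f(fit$theta)
  tab <- fit$par_table[, c("mat", "i", "j", "free", "label", "est", "se")]
  tab$std <- std
  tab$std_se <- NA_real_
  vc <- NULL
  if (!is.null(fit$vcov)) {
    J <- jacobian_cd(f, fit$theta)
    vc <- J %*% fit$vcov %*% t(J)
    vc <- (vc + t(vc)) / 2
    dimnames(vc) <- list(tab$label, tab$label)
    dv <- diag(vc)
    dv[dv < 0] <- NA_real_
    tab$std_se <- sqrt(dv)
  }
  list(table = tab, vcov = vc)
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("SEM fitted by FIML: ", length(x$theta), " free parameters, n = ",
      x$n, " (", x$patterns, " missingness pattern(s))\n", sep = "")
  cat("logLik ", format(x$loglik), ";  chi-square ",
      format(x$Tstat, digits = 5), " on ", x$df, " df\n", sep = "")
  ind <- x$indices
  cat(sprintf("RMSEA %.3f (%d%% CI %.3f-%.3f)  SRMR %.3f  CFI %.3f  TLI %.3f\n",
              ind$rmsea, round(100 * ind$rmsea_ci_level), ind$rmsea_ci[1],
              ind$rmsea_ci[2], ind$srmr, ind$cfi, ind$tli))
  if (!x$convergence$converged) cat("** convergence not clean **\n")
  invisible(x)
}

#' @export
coef.sem_fit <- function(object, ...) {
  stats::setNames(object$theta,
                  object$par_table$label[object$par_table$free])
}

#' @export
vcov.sem_fit <- function(object, ...) object$vcov

#' @export
logLik.sem_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}
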