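# Look up rows of the (standardized) solution and their covariance.
effect_basis <- function(fit, scale) {
  if (scale == "standardized") {
    if (is.null(fit$std))
      stop("fit has no standardized solution; refit with standardize = TRUE")
    list(est = stats::setNames(fit$std$std, fit$std$label),
         vcov = fit$vcov_std)
  } else {
    pt <- fit$par_table
    list(est = stats::setNames(pt$est, pt$label), vcov = fit$vcov)
  }
}

path_label <- function(outcome, predictor) paste0(outcome, "~", predictor)

get_path <- function(basis, outcome, predictor) {
  lab <- path_label(outcome, predictor)
  if (!lab %in% names(basis$est))
    stop("path '", predictor, " -> ", outcome,
         "' is not in the fitted model")
  lab
}

effect_row <- function(exposure, outcome, channel, beta, se,
                       ci_level = 0.95) {
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  data.frame(exposure = exposure, outcome = outcome, channel = channel,
             beta = beta, se = se,
             ci_lower = beta - zq * se, ci_upper = beta + zq * se,
             p = 2 * stats::pnorm(-abs(beta / se)),
             stringsAsFactors = FALSE)
}

quad_se <- function(basis, labels, grad) {
  V <- basis$vcov[labels, labels, drop = FALSE]
  sqrt(max(as.numeric(t(grad) %*% V %*% grad), 0))
}

#' Indirect, total, and tabulated mediation effects
#'
#' `indirect_effect()` computes the product-of-coefficients indirect
#' effect of `exposure` on `outcome` through `mediator`: `beta = a b`
#' with the delta-method standard error
#' `sqrt(b^2 Var(a) + a^2 Var(b) + 2 a b Cov(a, b))`.
#' `total_effect()` adds the direct path and every available
#' mediator's product, with the delta-method SE from the joint
#' estimate covariance.  `effect_table()` assembles the full report:
#' for each exposure and covariate, the direct effect on each mediator
#' and the outcome, each indirect channel, and the total, plus the
#' mediator residual correlations.
#'
#' Effects are computed on the standardized solution by default
#' (`scale = "raw"` uses the raw estimates).
#'
#' @param fit a [fit_sem()] object with standard errors.
#' @param exposure,mediator,outcome variable names as used in the
#'   model.
#' @param scale `"standardized"` or `"raw"`.
#' @param ci_level confidence level of the reported interval.
#' @return a one-row data frame (`indirect_effect`, `total_effect`) or
#'   an `effect_table` data frame.
#' @export
indirect_effect <- function(fit, exposure, mediator, outcome = "Cognition",
                            scale = c("standardized", "raw"),
                            ci_level = 0.95) {
  scale <- match.arg(scale)
  basis <- effect_basis(fit, scale)
  la <- get_path(basis, mediator, exposure)
  lb <- get_path(basis, outcome, mediator)
  a <- basis$est[[la]]; b <- basis$est[[lb]]
  se <- quad_se(basis, c(la, lb), c(b, a))
  effect_row(exposure, outcome, paste0("indirect:", mediator), a * b, se,
             ci_level)
}

#' @rdname indirect_effect
#' @param mediators mediator names; by default every variable with
#'   both an `exposure ->` path and a `-> outcome` path.
#' @export
total_effect <- function(fit, exposure, outcome = "Cognition",
                         mediators = NULL,
                         scale = c("standardized", "raw"),
                         ci_level = 0.95) {
  scale <- match.arg(scale)
  basis <- effect_basis(fit, scale)
  ld <- get_path(basis, outcome, exposure)
  if (is.null(mediators)) {
    cand <- unique(sub("~.*$", "", names(basis$est)[
      grepl(paste0("^[^~=]+~", exposure, "$"), names(basis$est))]))
    mediators <- cand[cand != outcome &
      path_label(outcome, cand) %in% names(basis$est)]
  }
  labels <- ld
  grad <- 1
  beta <- basis$est[[ld]]
  for (m in mediators) {
    la <- get_path(basis, m, exposure)
    lb <- get_path(basis, outcome, m)
    a <- basis$est[[la]]; b <- basis$est[[lb]]
    beta <- beta + a * b
    labels <- c(labels, la, lb)
    grad <- c(grad, b, a)
  }
  se <- quad_se(basis, labels, grad)
  effect_row(exposure, outcome, "total", beta, se, ci_level)
}

#' @rdname indirect_effect
#' @param exposures,covariates variables whose effects are tabulated.
#' @export
effect_table <- function(fit, exposures = c("si_score", "li_score"),
                         covariates = c("age", "female", "apoe4"),
                         mediators = c("SVD", "ADpath", "Neuro"),
                         outcome = "Cognition",
                         scale = c("standardized", "raw"),
                         ci_level = 0.95) {
  scale <- match.arg(scale)
  basis <- effect_basis(fit, scale)
  rows <- list()
  for (from in c(exposures, covariates)) {
    for (tg in c(mediators, outcome)) {
      lab <- get_path(basis, tg, from)
      rows[[length(rows) + 1L]] <- effect_row(
        from, tg, "direct", basis$est[[lab]],
        sqrt(basis$vcov[lab, lab]), ci_level)
    }
    for (m in mediators)
      rows[[length(rows) + 1L]] <- indirect_effect(fit, from, m, outcome,
                                                   scale, ci_level)
    rows[[length(rows) + 1L]] <- total_effect(fit, from, outcome, mediators,
                                              scale, ci_level)
  }
  # mediator -> outcome direct paths
  for (m in mediators) {
    lab <- get_path(basis, outcome, m)
    rows[[length(rows) + 1L]] <- effect_row(
      m, outcome, "direct", basis$est[[lab]], sqrt(basis$vcov[lab, lab]),
      ci_level)
  }
  # mediator residual correlations (standardized scale: correlations)
  if (length(mediators) > 1L) {
    for (i in seq_len(length(mediators) - 1L))
      for (j in (i + 1L):length(mediators)) {
        lab <- paste0(mediators[i], "~~", mediators[j])
        if (!lab %in% names(basis$est))
          lab <- paste0(mediators[j], "~~", mediators[i])
        if (lab %in% names(basis$est))
          rows[[length(rows) + 1L]] <- effect_row(
            mediators[i], mediators[j], "residual_correlation",
            basis$est[[lab]], sqrt(basis$vcov[lab, lab]), ci_level)
      }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("effect_table", "data.frame")
  attr(out, "scale") <- scale
  out
}

#' @export
print.effect_table <- function(x, digits = 3, ...) {
  cat("Effect decomposition (", attr(x, "scale"), " scale)\n", sep = "")
  y <- as.data.frame(x)
  y$beta <- round(y$beta, digits)
  y$se <- round(y$se, digits)
  y$ci_lower <- round(y$ci_lower, digits)
  y$ci_upper <- round(y$ci_upper, digits)
  y$p <- signif(y$p, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Parametric bootstrap SE for an indirect effect
#'
#' Simulates complete data from the fitted model's implied moments,
#' refits, and recomputes the indirect effect; the SD over replicates
#' is a reference against which the delta-method SE can be judged.
#' Raw-scale effects are bootstrapped (point estimates only, no SEs,
#' so refits are fast).
#'
#' @param fit a [fit_sem()] object.
#' @param exposure,mediator,outcome as in [indirect_effect()].
#' @param reps bootstrap replicates.
#' @param seed RNG seed.
#' @return list with `se` (bootstrap SE), `draws`, and `failures`.
#' @export
bootstrap_indirect_se <- function(fit, exposure, mediator,
                                  outcome = "Cognition", reps = 200,
                                  seed = 1) {
  imp <- implied_moments(fit$matrices)
  obs <- fit$template$vars$obs
  set.seed(seed)
  draws <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    Y <- as.data.frame(rmvn(fit$n, imp$mu, imp$sigma))
    names(Y) <- obs
    bf <- tryCatch(
      fit_sem(fit$spec, Y, se = FALSE, standardize = FALSE, restarts = 1),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(bf)) next
    a <- bf$par_table$est[bf$par_table$label == path_label(mediator, exposure)]
    b <- bf$par_table$est[bf$par_table$label == path_label(outcome, mediator)]
    draws[r] <- a * b
  }
  ok <- !is.na(draws)
  list(se = stats::sd(draws[ok]), draws = draws,
       failures = sum(!ok))
}
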