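#' Graded response model (GRM) tools
#'
#' The GRM links an ordered polytomous item response \eqn{Y_j \in \{1,
#' \dots, K_j\}} to a single latent trait \eqn{\theta} through cumulative
#' logistic curves \eqn{P(Y_j \ge k \mid \theta) = \mathrm{logit}^{-1}
#' (a_j(\theta - b_{j,k-1}))} with discrimination \eqn{a_j > 0} and
#' strictly increasing thresholds \eqn{b_{j,1} < \dots < b_{j,K_j-1}}.
#' Category probabilities are differences of adjacent cumulative curves.
#'
#' @param a positive discrimination.
#' @param b numeric vector of strictly increasing thresholds.
#' @param name optional item name.
#' @return `grm_item()` returns an object of class `"grm_item"`.
#' @examples
#' it <- grm_item(a = 1.5, b = c(-1, 0, 1))
#' category_probabilities(0, it)
#' @export
grm_item <- function(a, b, name = NULL) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("discrimination 'a' must be a positive scalar")
  if (!is.numeric(b) || length(b) < 1L || anyNA(b))
    stop("'b' must be a numeric threshold vector")
  if (is.unsorted(b, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  structure(list(a = a, b = as.numeric(b), K = length(b) + 1L,
                 name = name), class = "grm_item")
}

#' @rdname grm_item
#' @param theta latent trait value(s).
#' @param item a `grm_item`.
#' @return `category_probabilities()` returns a matrix with one row per
#'   `theta` and one column per category; rows sum to one.
#' @export
category_probabilities <- function(theta, item) {
  if (!inherits(item, "grm_item")) item <- do.call(grm_item, item)
  K <- item$K
  # cumulative P(Y >= k), k = 1..K (P(Y>=1) = 1)
  cum <- cbind(1, stats::plogis(outer(theta, item$b, function(t, b)
    item$a * (t - b))))
  p <- cum - cbind(cum[, -1, drop = FALSE], 0)
  colnames(p) <- paste0("cat", seq_len(K))
  p
}

# Category probability table over a set of quadrature nodes: K x Q.
grm_prob_table <- function(item, nodes) {
  t(category_probabilities(nodes, item))
}

#' Sample GRM responses
#'
#' Draws one ordinal response per participant and item from the graded
#' response model at the given trait values.
#'
#' @param theta numeric vector of trait values.
#' @param items list of [grm_item()] objects (an item bank).
#' @return integer matrix, `length(theta)` rows, one column per item,
#'   entries in `1..K_j`.
#' @export
sample_grm_responses <- function(theta, items) {
  items <- lapply(items, function(it)
    if (inherits(it, "grm_item")) it else do.call(grm_item, it))
  n <- length(theta)
  out <- matrix(NA_integer_, n, length(items))
  colnames(out) <- vapply(seq_along(items), function(j)
    items[[j]]$name %||% paste0("item", j), character(1))
  for (j in seq_along(items)) {
    it <- items[[j]]
    # P(Y >= k) is decreasing in k, so 1 + sum_k 1[u < P(Y>=k)] is an
    # inverse-CDF draw.
    cum <- stats::plogis(outer(theta, it$b, function(t, b) it$a * (t - b)))
    u <- stats::runif(n)
    out[, j] <- 1L + as.integer(rowSums(cum > u))
  }
  out
}

# Calibrate thresholds so that the marginal cumulative proportions
# P(Y >= k) under theta ~ N(0,1) equal `cum_props` (decreasing in k).
calibrate_thresholds <- function(a, cum_props, n_nodes = 101) {
  gh <- gh_rule(n_nodes)
  vapply(cum_props, function(p) {
    stats::uniroot(function(b)
      sum(gh$weights * stats::plogis(a * (gh$nodes - b))) - p,
      lower = -10, upper = 10, tol = 1e-10)$root
  }, numeric(1))
}

check_responses <- function(responses) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (ncol(responses) < 2L) stop("need at least 2 items")
  if (is.null(colnames(responses)))
    colnames(responses) <- paste0("item", seq_len(ncol(responses)))
  for (j in seq_len(ncol(responses))) {
    v <- responses[, j]
    obs <- sort(unique(v[!is.na(v)]))
    if (length(obs) < 2L)
      stop("item '", colnames(responses)[j], "' shows a single observed ",
           "category; collapse categories or drop the item")
    if (min(obs) < 1L)
      stop("responses must be coded 1..K (item '",
           colnames(responses)[j], "')")
  }
  responses
}

# Per-participant likelihood matrix over quadrature nodes: n x Q.
grm_lik_matrix <- function(items, responses, nodes) {
  n <- nrow(responses)
  L <- matrix(1, n, length(nodes))
  for (j in seq_along(items)) {
    P <- grm_prob_table(items[[j]], nodes)  # K x Q
    y <- responses[, j]
    ok <- !is.na(y)
    L[ok, ] <- L[ok, ] * P[y[ok], , drop = FALSE]
  }
  L
}

# M-step objective for one item: minus expected complete-data loglik
# given expected counts r (K x Q). Parameterized as (log a, b1,
# log-diffs) so the threshold order constraint is automatic.
item_par_pack <- function(a, b) c(log(a), b[1], if (length(b) > 1) log(diff(b)))
item_par_unpack <- function(par) {
  # clamp so extreme line-search steps cannot collapse the threshold
  # spacing to zero or overflow
  a <- exp(min(max(par[1], -10), 10))
  b1 <- min(max(par[2], -30), 30)
  gaps <- if (length(par) > 2) pmax(pmin(exp(pmin(par[-(1:2)], 4)), 60), 1e-6)
  b <- cumsum(c(b1, gaps))
  list(a = a, b = b)
}

item_mstep <- function(r, nodes, start) {
  negQ <- function(par) {
    p <- item_par_unpack(par)
    P <- grm_prob_table(grm_item(p$a, p$b), nodes)
    P <- pmax(P, 1e-300)
    -sum(r * log(P))
  }
  opt <- stats::optim(start, negQ, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  opt$par
}

#' Fit a graded response model by marginal maximum likelihood
#'
#' EM estimation with the latent trait fixed to N(0,1) (all
#' discriminations free), integrating the trait by fixed Gauss-Hermite
#' quadrature.  Missing responses are simply dropped from that
#' participant's likelihood contribution.
#'
#' @param responses matrix or data frame of ordinal responses coded
#'   `1..K` per item; `NA` allowed.
#' @param n_nodes number of Gauss-Hermite quadrature nodes (default 61).
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return an object of class `"grm_model"` with elements `items`
#'   (fitted [grm_item()]s), `loglik`, `n`, `iterations`, `converged`,
#'   and `grad_norm` (numerical gradient norm of the marginal
#'   log-likelihood at the solution).
#' @export
fit_grm <- function(responses, n_nodes = 61, max_iter = 500, tol = 1e-8) {
  responses <- check_responses(responses)
  n <- nrow(responses)
  J <- ncol(responses)
  gh <- gh_rule(n_nodes)
  Ks <- apply(responses, 2, max, na.rm = TRUE)

  # starts: a = 1, thresholds at marginal logit quantiles
  items <- lapply(seq_len(J), function(j) {
    y <- responses[, j]
    K <- Ks[j]
    tab <- tabulate(y[!is.na(y)], nbins = K)
    cum <- rev(cumsum(rev(tab / sum(tab))))[-1]    # P(Y >= k), k = 2..K
    cum <- pmin(pmax(cum, 1e-3), 1 - 1e-3)
    b0 <- -stats::qlogis(cum)
    b0 <- cummax(b0 + seq_along(b0) * 1e-6)       # enforce strict order
    grm_item(1, b0, name = colnames(responses)[j])
  })

  ll_old <- -Inf
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    L <- grm_lik_matrix(items, responses, gh$nodes)
    marg <- L %*% gh$weights
    ll <- sum(log(marg))
    W <- sweep(L, 2, gh$weights, `*`) / as.numeric(marg)  # n x Q posterior
    for (j in seq_len(J)) {
      y <- responses[, j]
      ok <- !is.na(y)
      K <- Ks[j]
      r <- matrix(0, K, n_nodes)
      for (k in seq_len(K)) {
        rows <- ok & y == k
        if (any(rows)) r[k, ] <- colSums(W[rows, , drop = FALSE])
      }
      par <- item_mstep(r, gh$nodes, item_par_pack(items[[j]]$a, items[[j]]$b))
      p <- item_par_unpack(par)
      items[[j]] <- grm_item(p$a, p$b, name = items[[j]]$name)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  # final marginal loglik and numerical gradient norm at the solution
  L <- grm_lik_matrix(items, responses, gh$nodes)
  ll <- sum(log(L %*% gh$weights))
  theta_hat <- unlist(lapply(items, function(it) item_par_pack(it$a, it$b)))
  mll <- function(par) {
    its <- list(); pos <- 1L
    for (j in seq_len(J)) {
      np <- Ks[j]
      p <- item_par_unpack(par[pos:(pos + np - 1L)])
      its[[j]] <- grm_item(p$a, p$b)
      pos <- pos + np
    }
    sum(log(grm_lik_matrix(its, responses, gh$nodes) %*% gh$weights))
  }
  g <- jacobian_cd(function(p) mll(p), theta_hat, h = rep(1e-5, length(theta_hat)))
  if (!converged)
    warning("GRM EM did not converge in ", max_iter, " iterations")
  structure(list(items = items, loglik = ll, n = n,
                 iterations = iter, converged = converged,
                 grad_norm = max(abs(g)), n_nodes = n_nodes),
            class = "grm_model")
}

#' @export
print.grm_model <- function(x, ...) {
  cat("Graded response model (", length(x$items), " items, n = ", x$n,
      ")\n", sep = "")
  cat("logLik ", format(x$loglik), ", EM iterations ", x$iterations,
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  for (it in x$items)
    cat(sprintf("  %-18s a = %6.3f  b = %s\n", it$name %||% "", it$a,
                paste(sprintf("%.3f", it$b), collapse = ", ")))
  invisible(x)
}

#' Expected a posteriori (EAP) trait scores
#'
#' Posterior mean and SD of the latent trait under the N(0,1) prior,
#' computed by Gauss-Hermite quadrature, plus scores standardized to
#' sample mean 0 and SD 1 over scored participants.  Participants with
#' all items missing receive `NA`.
#'
#' @param model a fitted [fit_grm()] model (or a list of `grm_item`s).
#' @param responses response matrix as in [fit_grm()].
#' @param n_nodes quadrature nodes (defaults to the model's).
#' @return data frame with columns `eap`, `psd`, `std`.
#' @export
eap_scores <- function(model, responses, n_nodes = NULL) {
  items <- if (inherits(model, "grm_model")) model$items else model
  responses <- as.matrix(responses)
  n_nodes <- n_nodes %||% (if (inherits(model, "grm_model")) model$n_nodes else 61)
  gh <- gh_rule(n_nodes)
  L <- grm_lik_matrix(items, responses, gh$nodes)
  Wl <- sweep(L, 2, gh$weights, `*`)
  marg <- rowSums(Wl)
  eap <- as.numeric(Wl %*% gh$nodes) / marg
  m2 <- as.numeric(Wl %*% gh$nodes^2) / marg
  psd <- sqrt(pmax(m2 - eap^2, 0))
  all_missing <- rowSums(!is.na(responses)) == 0L
  eap[all_missing] <- NA_real_
  psd[all_missing] <- NA_real_
  std <- if (sum(!all_missing) > 1L) zstd(eap) else eap * NA_real_
  data.frame(eap = eap, psd = psd, std = std)
}

#' Two-way margin fit diagnostics
#'
#' For every item pair and category pair, compares the observed
#' bivariate frequencies (over participants with both items observed)
#' with the model-expected frequencies obtained by integrating the
#' product of category probabilities over the N(0,1) trait, and reports
#' the chi-square-type residual \eqn{(O-E)^2/E}.  Residuals above
#' `flag_threshold` (default 4, the classical rule of thumb) are
#' flagged.
#'
#' @inheritParams eap_scores
#' @param flag_threshold residual magnitude above which a cell is
#'   flagged.
#' @return data frame with one row per (item pair, category pair).
#' @export
two_way_margins <- function(model, responses, flag_threshold = 4,
                            n_nodes = NULL) {
  items <- if (inherits(model, "grm_model")) model$items else model
  responses <- as.matrix(responses)
  n_nodes <- n_nodes %||% (if (inherits(model, "grm_model")) model$n_nodes else 61)
  gh <- gh_rule(n_nodes)
  J <- length(items)
  nm <- colnames(responses) %||% paste0("item", seq_len(J))
  out <- list()
  for (j in seq_len(J - 1L)) for (l in (j + 1L):J) {
    ok <- !is.na(responses[, j]) & !is.na(responses[, l])
    npair <- sum(ok)
    if (npair == 0L) next
    Kj <- items[[j]]$K; Kl <- items[[l]]$K
    O <- table(factor(responses[ok, j], levels = 1:Kj),
               factor(responses[ok, l], levels = 1:Kl))
    Pj <- grm_prob_table(items[[j]], gh$nodes)
    Pl <- grm_prob_table(items[[l]], gh$nodes)
    E <- npair * (sweep(Pj, 2, gh$weights, `*`) %*% t(Pl))
    res <- (O - E)^2 / pmax(E, .Machine$double.eps)
    grid <- expand.grid(cat1 = 1:Kj, cat2 = 1:Kl)
    out[[length(out) + 1L]] <- data.frame(
      item1 = nm[j], item2 = nm[l], grid,
      observed = as.numeric(O), expected = as.numeric(E),
      residual = as.numeric(res),
      flagged = as.numeric(res) > flag_threshold)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
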