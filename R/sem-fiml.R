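# --- Full-information maximum likelihood over missing-data patterns ---

# Group rows of `data[, obs]` by missingness pattern and precompute the
# sufficient statistics of each pattern: count, mean, and ML scatter.
fiml_patterns <- function(data, obs = colnames(data)) {
  Y <- as.matrix(data[, obs, drop = FALSE])
  storage.mode(Y) <- "double"
  miss <- is.na(Y)
  none <- rowSums(!miss) == 0L
  if (any(none)) {
    warning(sum(none), " row(s) with no observed modelled variable dropped")
    Y <- Y[!none, , drop = FALSE]
    miss <- miss[!none, , drop = FALSE]
  }
  key <- apply(miss, 1, function(r) paste(as.integer(r), collapse = ""))
  out <- lapply(split(seq_len(nrow(Y)), key), function(rows) {
    o <- which(!miss[rows[1], ])
    Yp <- Y[rows, o, drop = FALSE]
    n <- length(rows)
    ybar <- colMeans(Yp)
    Cc <- crossprod(sweep(Yp, 2, ybar)) / n
    list(o = o, n = n, ybar = ybar, C = Cc, rows = rows)
  })
  attr(out, "n") <- nrow(Y)
  attr(out, "obs") <- obs
  out
}

# Log-likelihood given observed-variable moments and precomputed
# patterns; -Inf if any pattern submatrix is not positive definite.
fiml_loglik_patterns <- function(mu, sigma, patterns) {
  ll <- 0
  for (p in patterns) {
    o <- p$o
    Sp <- sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(Sp), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    k <- length(o)
    d <- p$ybar - mu[o]
    Kin <- chol2inv(ch)
    W <- p$C + tcrossprod(d)
    ll <- ll - 0.5 * p$n * (k * log(2 * pi) + 2 * sum(log(diag(ch))) +
                              sum(Kin * W))
  }
  ll
}

#' FIML log-likelihood of data under given moments
#'
#' Casewise multivariate-normal log density: each participant
#' contributes the density of their observed subvector under the
#' corresponding subvector/submatrix of `mu` and `sigma`.  Rows are
#' grouped by missingness pattern for efficiency.
#'
#' @param data data frame; only the columns named in `mu` are used.
#' @param mu named mean vector.
#' @param sigma covariance matrix (dimnames matching `mu`).
#' @return scalar log-likelihood (`-Inf` if a pattern submatrix is not
#'   positive definite).
#' @export
loglik_fiml <- function(data, mu, sigma) {
  obs <- names(mu)
  if (is.null(obs)) stop("'mu' must be named")
  dimnames(sigma) <- list(obs, obs)
  pats <- fiml_patterns(data, obs)
  fiml_loglik_patterns(mu, sigma, pats)
}

# Gradient of the pattern log-likelihood with respect to the observed
# moments, accumulated into full-size matrices (G_sigma, g_mu).
fiml_moment_gradient <- function(mu, sigma, patterns) {
  p <- length(mu)
  G <- matrix(0, p, p)
  g <- numeric(p)
  for (pt in patterns) {
    o <- pt$o
    Sp <- sigma[o, o, drop = FALSE]
    Kin <- tryCatch(chol2inv(chol(Sp)), error = function(e) NULL)
    if (is.null(Kin)) return(NULL)
    d <- pt$ybar - mu[o]
    W <- pt$C + tcrossprod(d)
    G[o, o] <- G[o, o] - 0.5 * pt$n * (Kin - Kin %*% W %*% Kin)
    g[o] <- g[o] + pt$n * as.numeric(Kin %*% d)
  }
  list(G = G, g = g)
}

# Analytic gradient of the FIML log-likelihood with respect to the free
# parameters, by the RAM chain rule.
fiml_theta_gradient <- function(template, theta, patterns) {
  mat <- theta_to_matrices(template, theta)
  imp <- implied_moments(mat)
  mg <- fiml_moment_gradient(imp$mu, imp$sigma, patterns)
  if (is.null(mg)) return(rep(0, length(theta)))
  nv <- template$nv
  oi <- template$obs_idx
  Gt <- matrix(0, nv, nv); Gt[oi, oi] <- mg$G     # lifted to all variables
  gt <- numeric(nv); gt[oi] <- mg$g
  B <- imp$B
  sigma_all <- imp$sigma_all
  mu_all <- imp$mu_all
  Btg <- as.numeric(t(B) %*% gt)
  dA <- 2 * t(B) %*% Gt %*% sigma_all + outer(Btg, mu_all)
  MS <- t(B) %*% Gt %*% B
  pt <- template$par_table
  free <- which(pt$free)
  grad <- numeric(length(free))
  for (k in seq_along(free)) {
    r <- free[k]
    i <- pt$i[r]; j <- pt$j[r]
    grad[k] <- switch(pt$mat[r],
                      A = dA[i, j],
                      S = if (i == j) MS[i, i] else 2 * MS[i, j],
                      m = Btg[i])
  }
  grad
}

# --- FIML-saturated and baseline (independence) models ---

#' Saturated and baseline FIML solutions
#'
#' `fiml_saturated()` estimates an unstructured mean vector and
#' covariance matrix by FIML (EM algorithm for the multivariate normal
#' with missing data).  `fiml_baseline()` estimates the independence
#' model (means and variances only, zero covariances), whose FIML
#' solution factorizes per variable.  Both are needed as reference
#' points for chi-square based fit indices.
#'
#' @param data data frame of numeric columns (NAs allowed).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return `fiml_saturated()`: list with `mu`, `sigma`, `loglik`, `df`
#'   (number of free moments), `iterations`, `n`.  `fiml_baseline()`:
#'   list with `mu`, `var`, `loglik`, `df`.
#' @export
fiml_saturated <- function(data, max_iter = 500, tol = 1e-10) {
  obs <- colnames(data)
  pats <- fiml_patterns(data, obs)
  n <- attr(pats, "n")
  p <- length(obs)
  complete <- length(pats) == 1L && length(pats[[1]]$o) == p
  mu <- vapply(seq_len(p), function(j) {
    x <- data[[obs[j]]]; mean(x, na.rm = TRUE)
  }, numeric(1))
  names(mu) <- obs
  if (complete) {
    sigma <- pats[[1]]$C
    dimnames(sigma) <- list(obs, obs)
    mu <- pats[[1]]$ybar
    names(mu) <- obs
    ll <- fiml_loglik_patterns(mu, sigma, pats)
    return(list(mu = mu, sigma = sigma, loglik = ll, df = p * (p + 3) / 2,
                iterations = 0L, converged = TRUE, n = n))
  }
  v0 <- vapply(seq_len(p), function(j) {
    x <- data[[obs[j]]]
    v <- stats::var(x, na.rm = TRUE)
    if (!is.finite(v) || v <= 0) 1 else v
  }, numeric(1))
  sigma <- diag(v0, p)
  dimnames(sigma) <- list(obs, obs)
  ll_old <- -Inf
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (pt in pats) {
      o <- pt$o
      mis <- setdiff(seq_len(p), o)
      Soo_inv <- chol2inv(chol(sigma[o, o, drop = FALSE]))
      npat <- pt$n
      # observed contributions (second moments about zero)
      Yo_mean <- pt$ybar
      T1[o] <- T1[o] + npat * Yo_mean
      T2[o, o] <- T2[o, o] + npat * (pt$C + tcrossprod(Yo_mean))
      if (length(mis)) {
        Smo <- sigma[mis, o, drop = FALSE]
        Bhat <- Smo %*% Soo_inv
        Vm <- sigma[mis, mis, drop = FALSE] - Bhat %*% t(Smo)
        # grouped conditional expectations
        m_mean <- as.numeric(mu[mis] + Bhat %*% (Yo_mean - mu[o]))
        # E[sum y_m y_o'] = n (m_mean yo_bar' + Bhat C)
        cross <- npat * (tcrossprod(m_mean, Yo_mean) + Bhat %*% pt$C)
        T2[mis, o] <- T2[mis, o] + cross
        T2[o, mis] <- T2[o, mis] + t(cross)
        # E[sum y_m y_m'] = n (Vm + m_mean m_mean' + Bhat C Bhat')
        T2[mis, mis] <- T2[mis, mis] +
          npat * (Vm + tcrossprod(m_mean) + Bhat %*% pt$C %*% t(Bhat))
        T1[mis] <- T1[mis] + npat * m_mean
      }
    }
    mu <- T1 / n
    sigma <- T2 / n - tcrossprod(mu)
    sigma <- (sigma + t(sigma)) / 2
    names(mu) <- obs
    dimnames(sigma) <- list(obs, obs)
    ll <- fiml_loglik_patterns(mu, sigma, pats)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, loglik = ll, df = p * (p + 3) / 2,
       iterations = iter, converged = converged, n = n)
}

#' @rdname fiml_saturated
#' @export
fiml_baseline <- function(data) {
  obs <- colnames(data)
  ll <- 0
  mu <- numeric(length(obs)); v <- numeric(length(obs))
  for (j in seq_along(obs)) {
    x <- data[[obs[j]]]
    x <- x[!is.na(x)]
    mu[j] <- mean(x)
    v[j] <- mean((x - mu[j])^2)    # ML variance
    ll <- ll + sum(stats::dnorm(x, mu[j], sqrt(v[j]), log = TRUE))
  }
  names(mu) <- names(v) <- obs
  list(mu = mu, var = v, loglik = ll, df = 2 * length(obs))
}
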