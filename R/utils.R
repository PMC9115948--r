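#' @keywords internal
"_PACKAGE"

# Gauss-Hermite rule in probabilist form: nodes/weights such that
# sum(w * f(x)) approximates E[f(Z)] for Z ~ N(0,1).
gh_rule <- function(n) {
  q <- statmod::gauss.quad.prob(n, dist = "normal", mu = 0, sigma = 1)
  list(nodes = q$nodes, weights = q$weights)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage substream seed derived from a master seed.
# Keeps results < 2^31 so set.seed() accepts them.
sub_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(master)) * 48271 + h * 16807) %% 2147483399 + 1)
}

# z-score ignoring NAs; constant columns error by default (sd = 0).
zstd <- function(x, allow_constant = FALSE) {
  mu <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    if (allow_constant) return(x * NA_real_)
    stop("cannot standardize a constant (or all-missing) column")
  }
  (x - mu) / s
}

# Central-difference Jacobian of a vector-valued function.
jacobian_cd <- function(f, x, h = NULL) {
  if (is.null(h)) h <- pmax(1e-5, 1e-5 * abs(x))
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (k in seq_along(x)) {
    xp <- x; xm <- x
    xp[k] <- x[k] + h[k]
    xm[k] <- x[k] - h[k]
    J[, k] <- (f(xp) - f(xm)) / (2 * h[k])
  }
  J
}

# Moore-Penrose pseudo-inverse via SVD (fallback when a Hessian is
# numerically singular).
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Draws from N(mu, Sigma) via Cholesky.
rmvn <- function(n, mu, Sigma) {
  p <- length(mu)
  L <- chol(Sigma)
  Z <- matrix(stats::rnorm(n * p), n, p)
  sweep(Z %*% L, 2, mu, `+`)
}

# Truncated-normal draws by inverse-CDF, plus analytic mean/variance.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

truncnorm_moments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / Z
  v <- sd^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  list(mean = m, var = v)
}
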