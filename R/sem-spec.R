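#' Declare a structural equation model
#'
#' Parses a compact model syntax into a `sem_spec`:
#' \itemize{
#'   \item `latent =~ ind1 + ind2 + ...` measurement definition; the
#'     first indicator's loading is fixed to 1 (marker-variable
#'     identification), the remaining loadings are free.
#'   \item `outcome ~ pred1 + pred2 + ...` structural regression.
#'   \item `a ~~ b` free (residual) covariance.
#' }
#' Variables that only ever appear as predictors are treated as
#' exogenous and modelled jointly with free means, variances, and
#' pairwise covariances, so that full-information maximum likelihood
#' covers their missingness too.  A mean structure (indicator
#' intercepts, latent intercepts fixed at 0) is always included.
#'
#' @param model character scalar (or vector of lines) in the syntax
#'   above; `;` also separates statements.
#' @return an object of class `"sem_spec"`.
#' @examples
#' sem_spec("
#'   F =~ y1 + y2 + y3
#'   F ~ x
#' ")
#' @export
sem_spec <- function(model) {
  lines <- unlist(strsplit(paste(model, collapse = "\n"), "[\n;]"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  latents <- list()
  regressions <- list()
  covariances <- list()
  split_rhs <- function(x) trimws(unlist(strsplit(x, "\\+")))
  for (ln in lines) {
    if (grepl("=~", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "=~", fixed = TRUE)[[1]])
      latents[[parts[1]]] <- c(latents[[parts[1]]], split_rhs(parts[2]))
    } else if (grepl("~~", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "~~", fixed = TRUE)[[1]])
      covariances[[length(covariances) + 1L]] <- c(parts[1], parts[2])
    } else if (grepl("~", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "~", fixed = TRUE)[[1]])
      regressions[[parts[1]]] <- c(regressions[[parts[1]]], split_rhs(parts[2]))
    } else stop("cannot parse model line: '", ln, "'")
  }
  spec <- structure(list(latents = latents, regressions = regressions,
                         covariances = covariances), class = "sem_spec")
  validate_sem_spec(spec)
  spec
}

validate_sem_spec <- function(spec) {
  lat <- names(spec$latents)
  inds <- unlist(spec$latents)
  if (any(lat %in% inds))
    stop("a latent variable cannot also be an indicator: ",
         paste(intersect(lat, inds), collapse = ", "))
  if (anyDuplicated(inds))
    stop("indicator assigned to more than one latent: ",
         paste(unique(inds[duplicated(inds)]), collapse = ", "))
  # acyclicity of the directed (regression + loading) graph
  vars <- sem_spec_vars(spec)
  edges <- sem_spec_edges(spec)
  remaining <- vars$all
  repeat {
    # a variable with no outgoing edge into the remaining set can be peeled
    no_out <- remaining[vapply(remaining, function(v)
      !any(edges$from == v & edges$to %in% remaining), logical(1))]
    if (!length(no_out)) stop("directed part of the model is cyclic")
    remaining <- setdiff(remaining, no_out)
    if (!length(remaining)) break
  }
  invisible(spec)
}

sem_spec_edges <- function(spec) {
  ef <- character(0); et <- character(0)
  for (L in names(spec$latents)) {
    ef <- c(ef, rep(L, length(spec$latents[[L]])))
    et <- c(et, spec$latents[[L]])
  }
  for (out in names(spec$regressions)) {
    ef <- c(ef, spec$regressions[[out]])
    et <- c(et, rep(out, length(spec$regressions[[out]])))
  }
  data.frame(from = ef, to = et, stringsAsFactors = FALSE)
}

sem_spec_vars <- function(spec) {
  lat <- names(spec$latents)
  inds <- unlist(spec$latents, use.names = FALSE)
  reg_out <- names(spec$regressions)
  reg_pred <- unlist(spec$regressions, use.names = FALSE)
  cov_vars <- unlist(spec$covariances, use.names = FALSE)
  obs <- unique(c(inds, setdiff(c(reg_out, reg_pred, cov_vars), lat)))
  exo_obs <- setdiff(obs, c(inds, reg_out))       # never an outcome
  endo_obs <- setdiff(intersect(obs, reg_out), inds)
  list(obs = obs, lat = lat, exo_obs = exo_obs, endo_obs = endo_obs,
       indicators = inds, all = c(obs, lat))
}

# Build the RAM template (A, S, m skeletons plus a parameter table)
# from a spec and a data frame used for start values.
build_ram <- function(spec, data) {
  v <- sem_spec_vars(spec)
  missing_cols <- setdiff(v$obs, names(data))
  if (length(missing_cols))
    stop("model variables absent from data: ",
         paste(missing_cols, collapse = ", "))
  all <- v$all
  nv <- length(all)
  idx <- stats::setNames(seq_len(nv), all)
  obs_idx <- idx[v$obs]

  rows <- list()
  add <- function(mat, i, j, free, value, label)
    rows[[length(rows) + 1L]] <<- data.frame(
      mat = mat, i = idx[[i]], j = idx[[j]], free = free,
      value = value, label = label, stringsAsFactors = FALSE)

  # measurement part
  for (L in names(spec$latents)) {
    inds <- spec$latents[[L]]
    for (k in seq_along(inds))
      add("A", inds[k], L, free = k > 1L, value = if (k == 1L) 1 else NA,
          label = paste0(L, "=~", inds[k]))
  }
  # structural part
  for (out in names(spec$regressions))
    for (p in spec$regressions[[out]])
      add("A", out, p, free = TRUE, value = NA,
          label = paste0(out, "~", p))

  endo <- unique(c(names(spec$regressions), v$indicators))
  # variances: indicators, endogenous observed, latents
  for (y in v$indicators)
    add("S", y, y, TRUE, NA, paste0(y, "~~", y))
  for (y in v$endo_obs)
    add("S", y, y, TRUE, NA, paste0(y, "~~", y))
  for (L in v$lat)
    add("S", L, L, TRUE, NA, paste0(L, "~~", L))
  # stated residual covariances
  for (cv in spec$covariances)
    add("S", cv[1], cv[2], TRUE, NA, paste0(cv[1], "~~", cv[2]))
  # exogenous observed block: free means, variances, covariances
  ex <- v$exo_obs
  for (x in ex) add("S", x, x, TRUE, NA, paste0(x, "~~", x))
  if (length(ex) > 1L)
    for (a in seq_len(length(ex) - 1L)) for (b in (a + 1L):length(ex))
      add("S", ex[a], ex[b], TRUE, NA, paste0(ex[a], "~~", ex[b]))
  for (x in ex) add("m", x, x, TRUE, NA, paste0(x, "~1"))
  # intercepts for endogenous observed variables; latent intercepts 0
  for (y in c(v$indicators, v$endo_obs))
    add("m", y, y, TRUE, NA, paste0(y, "~1"))

  par_table <- do.call(rbind, rows)
  if (anyDuplicated(par_table$label))
    stop("duplicated parameter: ",
         paste(par_table$label[duplicated(par_table$label)], collapse = ", "))
  structure(list(spec = spec, vars = v, all = all, idx = idx,
                 obs_idx = obs_idx, nv = nv, par_table = par_table),
            class = "sem_template")
}

# Start values from FIML-saturated moments.
ram_start <- function(template, data) {
  v <- template$vars
  sat <- fiml_saturated(data[v$obs])
  mu <- sat$mu; Sg <- sat$sigma
  pt <- template$par_table
  start <- pt$value
  covg <- function(a, b) Sg[a, b]
  lat_var_guess <- stats::setNames(numeric(length(v$lat)), v$lat)
  for (L in v$lat) {
    inds <- spec_inds <- template$spec$latents[[L]]
    mk <- inds[1]
    vhat <- 0.5 * Sg[mk, mk]
    if (length(inds) >= 3) {
      c12 <- covg(mk, inds[2]); c13 <- covg(mk, inds[3]); c23 <- covg(inds[2], inds[3])
      if (abs(c23) > 1e-10) {
        tri <- c12 * c13 / c23
        if (is.finite(tri) && tri > 0.05 * Sg[mk, mk] && tri < Sg[mk, mk])
          vhat <- tri
      }
    }
    lat_var_guess[L] <- vhat
  }
  for (r in seq_len(nrow(pt))) {
    if (!pt$free[r]) next
    lab <- pt$label[r]
    i <- template$all[pt$i[r]]; j <- template$all[pt$j[r]]
    if (pt$mat[r] == "A" && grepl("=~", lab, fixed = TRUE)) {
      L <- j; ind <- i
      mk <- template$spec$latents[[L]][1]
      lam <- covg(ind, mk) / lat_var_guess[L]
      start[r] <- max(min(lam, 5), -5)
    } else if (pt$mat[r] == "A") {
      start[r] <- 0
    } else if (pt$mat[r] == "S" && i == j) {
      if (i %in% v$lat) {
        start[r] <- if (i %in% names(template$spec$regressions))
          0.5 * lat_var_guess[i] else lat_var_guess[i]
      } else if (i %in% v$exo_obs) {
        start[r] <- Sg[i, i]
      } else {
        # indicator / endogenous observed residual
        start[r] <- 0.5 * Sg[i, i]
      }
    } else if (pt$mat[r] == "S") {
      start[r] <- if (i %in% v$exo_obs && j %in% v$exo_obs) Sg[i, j] else 0
    } else if (pt$mat[r] == "m") {
      start[r] <- mu[i]
    }
  }
  list(start = start, sat = sat)
}

# Fill A, S, m from a parameter vector over the free rows.
theta_to_matrices <- function(template, theta) {
  pt <- template$par_table
  vals <- pt$value
  vals[pt$free] <- theta
  nv <- template$nv
  A <- matrix(0, nv, nv, dimnames = list(template$all, template$all))
  S <- matrix(0, nv, nv, dimnames = list(template$all, template$all))
  m <- stats::setNames(numeric(nv), template$all)
  for (r in seq_len(nrow(pt))) {
    i <- pt$i[r]; j <- pt$j[r]
    switch(pt$mat[r],
           A = { A[i, j] <- vals[r] },
           S = { S[i, j] <- vals[r]; S[j, i] <- vals[r] },
           m = { m[i] <- vals[r] })
  }
  structure(list(A = A, S = S, m = m, obs = template$vars$obs,
                 lat = template$vars$lat, obs_idx = template$obs_idx,
                 all = template$all),
            class = "sem_matrices")
}

#' Model-implied moments of a RAM-form SEM
#'
#' Computes the mean vector and covariance matrix of the observed
#' variables implied by the RAM matrices: with \eqn{B = (I-A)^{-1}},
#' \eqn{\Sigma = F B S B^\top F^\top} and \eqn{\mu = F B m}, where `F`
#' filters the observed rows.
#'
#' @param matrices a `sem_matrices` object (asymmetric path matrix `A`,
#'   symmetric covariance matrix `S`, mean vector `m`, observed index).
#' @return list with `mu` (named vector) and `sigma` (matrix) over the
#'   observed variables, plus `sigma_all`/`mu_all` over all variables
#'   (latents included).
#' @export
implied_moments <- function(matrices) {
  nv <- nrow(matrices$A)
  ImA <- diag(nv) - matrices$A
  B <- tryCatch(solve(ImA), error = function(e)
    stop("I - A is singular: the path specification is cyclic or ill-posed"))
  sigma_all <- B %*% matrices$S %*% t(B)
  mu_all <- as.numeric(B %*% matrices$m)
  names(mu_all) <- matrices$all
  oi <- matrices$obs_idx
  list(mu = mu_all[oi], sigma = sigma_all[oi, oi, drop = FALSE],
       mu_all = mu_all, sigma_all = sigma_all, B = B)
}
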