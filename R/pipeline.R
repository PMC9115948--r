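#' Default structural equation model
#'
#' The full pathway model: three latent pathology mediators (small
#' vessel disease, AD pathology, neurodegeneration) and a latent
#' cognition factor, each regressed on the two life-course exposure
#' scores and the covariates; cognition additionally regressed on the
#' mediators; free residual covariances among the mediators.  The AD
#' pathology latent is anchored on CSF p-tau so that the marker-variable
#' convention orients it with higher = more pathology (the Abeta42/40
#' ratio then loads negatively).
#'
#' @return model string accepted by [sem_spec()].
#' @export
default_sem_model <- function() {
  "
  SVD =~ wmh_t + fazekas_peri + fazekas_deep
  ADpath =~ ptau_t + ab_ratio + amyloid_t
  Neuro =~ hippo_nd + thickness_nd + bpf_nd + fdg_nd
  Cognition =~ verbal_fluency + fcsrt_free_recall + tmtb_t + rey_score
  SVD ~ si_score + li_score + age + female + apoe4
  ADpath ~ si_score + li_score + age + female + apoe4
  Neuro ~ si_score + li_score + age + female + apoe4
  Cognition ~ si_score + li_score + age + female + apoe4 + SVD + ADpath + Neuro
  SVD ~~ ADpath
  SVD ~~ Neuro
  ADpath ~~ Neuro
  "
}

#' Run the full pathway-analysis pipeline
#'
#' Orchestrates simulate/read -> preprocess -> GRM trait scoring ->
#' FIML SEM -> effect decomposition, with the two sensitivity variants
#' and reproducible seeding.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{data}{a raw cohort table (data frame) or a CSV path, OR}
#'     \item{sim}{a [sim_config()] to simulate from;}
#'     \item{variant}{`"main"` (default), `"no_sni"` (drop the social
#'       network index from the lifestyle trait), or
#'       `"no_physical_leisure"` (recompute the leisure score without
#'       its two physical items);}
#'     \item{dictionary}{optional data dictionary (see
#'       [apply_dictionary()]);}
#'     \item{n_nodes}{GRM quadrature nodes (default 61);}
#'     \item{ci_level}{RMSEA CI level (default 0.90);}
#'     \item{seed}{master seed (default 1);}
#'     \item{out_dir}{optional output directory for artifacts.}
#'   }
#' @return an object of class `"pathsem_run"` with the fitted stage
#'   objects (`grm_si`, `grm_li`, `fit`, `effects`, ...) and a run
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  variant <- config$variant %||% "main"
  if (!variant %in% c("main", "no_sni", "no_physical_leisure"))
    stop("unknown variant '", variant, "'")
  seed <- config$seed %||% 1L
  n_nodes <- config$n_nodes %||% 61
  ci_level <- config$ci_level %||% 0.90

  if (!is.null(config$sim)) {
    cohort <- simulate_cohort(config$sim)$data
  } else if (!is.null(config$data)) {
    cohort <- if (is.character(config$data))
      utils::read.csv(config$data, stringsAsFactors = FALSE)
    else config$data
    if (!is.null(config$dictionary))
      cohort <- apply_dictionary(cohort, config$dictionary)
  } else stop("config must contain either 'data' or 'sim'")

  proc <- preprocess_cohort(
    cohort, exclude_physical_leisure = variant == "no_physical_leisure")

  si_items <- as.matrix(proc[, c("education", "occupation", "salary")])
  li_cols <- c("physical_activity", "leisure_cat",
               if (variant != "no_sni") "sni")
  li_items <- as.matrix(proc[, li_cols, drop = FALSE])
  if ("sni" %in% colnames(li_items))
    li_items[, "sni"] <- li_items[, "sni"] + 1L   # 0-3 -> categories 1-4

  grm_si <- fit_grm(si_items, n_nodes = n_nodes)
  grm_li <- fit_grm(li_items, n_nodes = n_nodes)
  proc$si_score <- eap_scores(grm_si, si_items)$std
  proc$li_score <- eap_scores(grm_li, li_items)$std
  margins_si <- two_way_margins(grm_si, si_items)
  margins_li <- two_way_margins(grm_li, li_items)

  fit <- fit_sem(default_sem_model(), proc, ci_level = ci_level)
  eff <- effect_table(fit)

  manifest <- list(
    package = "pathsem",
    version = as.character(utils::packageVersion("pathsem")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, variant = variant, n = nrow(proc),
    n_nodes = n_nodes, ci_level = ci_level,
    li_items = li_cols,
    config_hash = sum(utf8ToInt(paste(
      variant, seed, n_nodes, ci_level, nrow(proc), collapse = "|"))))

  run <- structure(list(
    cohort = cohort, processed = proc, grm_si = grm_si, grm_li = grm_li,
    margins_si = margins_si, margins_li = margins_li, fit = fit,
    effects = eff, variant = variant, seed = seed, manifest = manifest),
    class = "pathsem_run")

  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$processed, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE, na = "")
  bank_json <- function(model) lapply(model$items, function(it)
    list(name = it$name, a = it$a, b = it$b))
  jsonlite::write_json(list(si = bank_json(run$grm_si),
                            li = bank_json(run$grm_li)),
                       file.path(out_dir, "grm_parameters.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(run$margins_si, file.path(out_dir, "margins_si.csv"),
                   row.names = FALSE)
  utils::write.csv(run$margins_li, file.path(out_dir, "margins_li.csv"),
                   row.names = FALSE)
  pt <- run$fit$par_table
  utils::write.csv(pt[, c("label", "free", "est", "se", "z", "p")],
                   file.path(out_dir, "sem_parameters.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$fit$indices,
                       file.path(out_dir, "fit_indices.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(run$effects),
                   file.path(out_dir, "effects.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pathsem_run <- function(x, ...) {
  cat("pathsem pipeline run (variant: ", x$variant, ", n = ",
      nrow(x$processed), ")\n\n", sep = "")
  print(x$grm_si); cat("\n")
  print(x$grm_li); cat("\n")
  print(x$fit); cat("\n")
  print(x$effects)
  invisible(x)
}

#' Describe a cohort table
#'
#' Per-variable counts and percentages (computed over all participants,
#' so that within a variable the percentages sum to 100 minus the
#' missing share), overall and by sex, with chi-square tests for
#' categorical variables; means/SDs with one-way ANOVA for continuous
#' variables.
#'
#' @param data cohort table with a `sex` (or `female`) column.
#' @param categorical,continuous variable names to summarize; defaults
#'   cover the standard cohort columns present in `data`.
#' @return data frame, one row per variable level (categorical) or per
#'   variable (continuous).
#' @export
describe_cohort <- function(data,
                            categorical = NULL, continuous = NULL) {
  if (!("sex" %in% names(data)) && "female" %in% names(data))
    data$sex <- ifelse(data$female == 1, "F", "M")
  if (!("sex" %in% names(data))) stop("need a 'sex' or 'female' column")
  categorical <- categorical %||% intersect(
    c("apoe4", "cdr", "education", "occupation", "salary",
      "physical_activity", "leisure_cat", "sni"), names(data))
  continuous <- continuous %||% intersect(c("age"), names(data))
  n <- nrow(data)
  men <- data$sex == "M"
  out <- list()
  pctf <- function(k, d) 100 * k / d
  for (v in categorical) {
    x <- data[[v]]
    lv <- sort(unique(x[!is.na(x)]))
    p <- if (length(lv) >= 2) {
      tb <- table(x, data$sex)
      tryCatch(suppressWarnings(stats::chisq.test(tb)$p.value),
               error = function(e) NA_real_)
    } else NA_real_
    for (l in lv) {
      out[[length(out) + 1L]] <- data.frame(
        variable = v, level = as.character(l), statistic = "count",
        total = sum(x == l, na.rm = TRUE),
        pct_total = pctf(sum(x == l, na.rm = TRUE), n),
        men = sum(x == l & men, na.rm = TRUE),
        pct_men = pctf(sum(x == l & men, na.rm = TRUE), sum(men)),
        women = sum(x == l & !men, na.rm = TRUE),
        pct_women = pctf(sum(x == l & !men, na.rm = TRUE), sum(!men)),
        missing = sum(is.na(x)), p_value = p, stringsAsFactors = FALSE)
    }
  }
  for (v in continuous) {
    x <- data[[v]]
    p <- if (stats::sd(x, na.rm = TRUE) > 0)
      stats::anova(stats::lm(x ~ data$sex))[["Pr(>F)"]][1]
    else NA_real_   # constant: ANOVA undefined
    out[[length(out) + 1L]] <- data.frame(
      variable = v, level = "", statistic = "mean (sd)",
      total = mean(x, na.rm = TRUE),
      pct_total = stats::sd(x, na.rm = TRUE),
      men = mean(x[men], na.rm = TRUE),
      pct_men = stats::sd(x[men], na.rm = TRUE),
      women = mean(x[!men], na.rm = TRUE),
      pct_women = stats::sd(x[!men], na.rm = TRUE),
      missing = sum(is.na(x)), p_value = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
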