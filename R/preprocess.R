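#' Derived-variable rules for the cohort table
#'
#' `derive_leisure_category()` codes the 0-15 weekly leisure-activity
#' count into its four reference categories (<6, 6-7, 8-9, >9).
#' `derive_sni()` builds the 0-3 social network index as the sum of
#' three binaries (married, more than two close relatives/friends,
#' membership in community organizations); any missing component makes
#' the index missing.
#'
#' @param leisure_count integer 0-15 (NA allowed).
#' @return `derive_leisure_category()`: ordinal 1-4.
#' @export
derive_leisure_category <- function(leisure_count) {
  leisure_count <- as.numeric(leisure_count)
  bad <- !is.na(leisure_count) &
    (leisure_count < 0 | leisure_count > 15 |
       leisure_count != floor(leisure_count))
  if (any(bad))
    stop("leisure_count out of range 0-15 at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  cut_points <- c(-Inf, 5, 7, 9, Inf)
  as.integer(cut(leisure_count, cut_points, labels = FALSE))
}

#' @rdname derive_leisure_category
#' @param married,close_ties,membership binary 0/1 components (NA
#'   allowed).
#' @return `derive_sni()`: ordinal 0-3.
#' @export
derive_sni <- function(married, close_ties, membership) {
  comp <- cbind(married, close_ties, membership)
  bad <- !is.na(comp) & !(comp %in% c(0, 1))
  if (any(bad)) stop("SNI components must be 0/1")
  as.integer(married + close_ties + membership)
}

check_positive <- function(x, col) {
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad))
    stop("non-positive value passed to log in column '", col,
         "' at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  x
}

#' Biomarker and cognition transforms
#'
#' `transform_biomarkers()` computes the analysis-scale biomarker
#' indicators: `wmh_t = log(wmh_volume / tiv)`, `hippo_t =
#' log(hippocampus_volume / tiv)`, `ptau_t = log(csf_ptau)`,
#' `ab_ratio = csf_ab42 / csf_ab40`, and `amyloid_t` as the z-score of
#' `log(amyloid_suvr)` computed within each radioligand group (which
#' makes the two tracers' scales commensurable).  `code_cognition()`
#' orients the cognitive tests so higher = better: `tmtb_t =
#' -log(tmtb_seconds)`; the other three tests pass through unchanged.
#' `reverse_code_neurodegeneration()` standardizes the four
#' neurodegeneration indicators (`hippo_t`, `cortical_thickness`,
#' `bpf`, `fdg_suvr`) and negates them so a higher score means more
#' neurodegeneration (`*_nd` columns).  Missingness always propagates
#' cellwise; no transform imputes.
#'
#' @param data cohort table with the raw measurement columns.
#' @return the table with the derived columns appended.
#' @export
transform_biomarkers <- function(data) {
  has <- function(cl) all(cl %in% names(data))
  if (has(c("wmh_volume", "tiv"))) {
    check_positive(data$wmh_volume, "wmh_volume")
    check_positive(data$tiv, "tiv")
    data$wmh_t <- log(data$wmh_volume / data$tiv)
  }
  if (has(c("hippocampus_volume", "tiv"))) {
    check_positive(data$hippocampus_volume, "hippocampus_volume")
    data$hippo_t <- log(data$hippocampus_volume / data$tiv)
  }
  if (has("csf_ptau")) {
    check_positive(data$csf_ptau, "csf_ptau")
    data$ptau_t <- log(data$csf_ptau)
  }
  if (has(c("csf_ab42", "csf_ab40"))) {
    check_positive(data$csf_ab40, "csf_ab40")
    data$ab_ratio <- data$csf_ab42 / data$csf_ab40
  }
  if (has(c("amyloid_suvr", "radioligand"))) {
    check_positive(data$amyloid_suvr, "amyloid_suvr")
    lg <- log(data$amyloid_suvr)
    data$amyloid_t <- NA_real_
    for (g in unique(stats::na.omit(data$radioligand))) {
      rows <- which(!is.na(data$radioligand) & data$radioligand == g)
      data$amyloid_t[rows] <- zstd(lg[rows])
    }
  }
  data
}

#' @rdname transform_biomarkers
#' @export
code_cognition <- function(data) {
  if ("tmtb_seconds" %in% names(data)) {
    check_positive(data$tmtb_seconds, "tmtb_seconds")
    data$tmtb_t <- -log(data$tmtb_seconds)
  }
  data
}

#' @rdname transform_biomarkers
#' @export
reverse_code_neurodegeneration <- function(data) {
  src <- c(hippo_nd = "hippo_t", thickness_nd = "cortical_thickness",
           bpf_nd = "bpf", fdg_nd = "fdg_suvr")
  for (out in names(src)) {
    if (src[[out]] %in% names(data))
      data[[out]] <- -zstd(data[[src[[out]]]])
  }
  data
}

#' Preprocess a raw cohort table
#'
#' Applies every derived-variable rule in sequence: leisure
#' categorization (optionally excluding the physical leisure items),
#' social network index, sex recoding (`female` 0/1), biomarker
#' transforms, cognition coding, and neurodegeneration reverse coding.
#'
#' @param data raw cohort table (see [simulate_cohort()] for the
#'   column set).
#' @param exclude_physical_leisure if TRUE, subtract
#'   `leisure_physical_count` from `leisure_count` before
#'   categorization and cut the reduced 0-13 score at its sample
#'   quartiles (used by the sensitivity variant).
#' @return the analysis-ready table.
#' @export
preprocess_cohort <- function(data, exclude_physical_leisure = FALSE) {
  if ("sex" %in% names(data) && !("female" %in% names(data)))
    data$female <- as.integer(data$sex == "F")
  if ("leisure_count" %in% names(data)) {
    if (exclude_physical_leisure) {
      if (!("leisure_physical_count" %in% names(data)))
        stop("exclude_physical_leisure requires a leisure_physical_count ",
             "column")
      reduced <- data$leisure_count - data$leisure_physical_count
      qs <- unique(stats::quantile(reduced, c(0.25, 0.5, 0.75),
                                   na.rm = TRUE, type = 1))
      data$leisure_cat <- as.integer(cut(reduced, c(-Inf, qs, Inf),
                                         labels = FALSE))
    } else {
      data$leisure_cat <- derive_leisure_category(data$leisure_count)
    }
  }
  if (all(c("married", "close_ties", "membership") %in% names(data)))
    data$sni <- derive_sni(data$married, data$close_ties, data$membership)
  data <- transform_biomarkers(data)
  data <- code_cognition(data)
  reverse_code_neurodegeneration(data)
}

#' Apply a data dictionary
#'
#' Renames user columns to the canonical names used throughout the
#' package, from a YAML file (or list) mapping `canonical: user_name`.
#'
#' @param data a data frame.
#' @param dictionary path to a YAML file or a named list.
#' @return the renamed data frame.
#' @export
apply_dictionary <- function(data, dictionary) {
  map <- if (is.character(dictionary)) yaml::read_yaml(dictionary)
         else dictionary
  for (canonical in names(map)) {
    user <- map[[canonical]]
    if (!user %in% names(data))
      stop("dictionary column '", user, "' not found in data")
    names(data)[names(data) == user] <- canonical
  }
  data
}
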