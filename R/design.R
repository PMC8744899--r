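#' Canonical child-survival variable specification
#'
#' Describes the covariates used throughout the package, mirroring the
#' DHS-style birth-record semantics: categorical variables with an explicit
#' reference level and two continuous maternal-age variables. The reference
#' levels are male child, urban residence, male household head, poorest
#' wealth quintile, no education and single birth.
#'
#' @return named list of variable descriptors (\code{type}, \code{levels},
#'   \code{reference}, per-effect column names and display labels).
#' @export
u5cm_variables <- function() {
  list(
    sex = list(
      type = "categorical", levels = c("male", "female"), reference = "male",
      effects = c(female = "sex_female"),
      labels = c(sex_female = "Sex of the child (Female)")),
    residence = list(
      type = "categorical", levels = c("urban", "rural"), reference = "urban",
      effects = c(rural = "residence_rural"),
      labels = c(residence_rural = "Type of place of residence (Rural)")),
    head_sex = list(
      type = "categorical", levels = c("male", "female"), reference = "male",
      effects = c(female = "head_female"),
      labels = c(head_female = "Sex of household head (Female)")),
    wealth = list(
      type = "categorical",
      levels = c("poorest", "poorer", "middle", "richer", "richest"),
      reference = "poorest",
      effects = c(poorer = "wealth_poorer", middle = "wealth_middle",
                  richer = "wealth_richer", richest = "wealth_richest"),
      labels = c(wealth_poorer = "Wealth Index (Poorer)",
                 wealth_middle = "Wealth Index (Middle)",
                 wealth_richer = "Wealth Index (Richer)",
                 wealth_richest = "Wealth Index (Richest)")),
    education = list(
      type = "categorical",
      levels = c("none", "primary", "secondary", "higher"),
      reference = "none",
      effects = c(primary = "edu_primary", secondary = "edu_secondary",
                  higher = "edu_higher"),
      labels = c(edu_primary = "Highest Level of Education (Primary)",
                 edu_secondary = "Highest Level of Education (Secondary)",
                 edu_higher = "Highest Level of Education (Higher)")),
    age_first_birth = list(
      type = "continuous",
      effects = c(value = "age_first_birth"),
      labels = c(age_first_birth = "Age of respondent at first birth")),
    maternal_age = list(
      type = "continuous",
      effects = c(value = "maternal_age"),
      labels = c(maternal_age = "Maternal age at birth")),
    twin = list(
      type = "categorical",
      levels = c("single", "first_multiple", "second_multiple"),
      reference = "single",
      effects = c(first_multiple = "twin_first_multiple",
                  second_multiple = "twin_second_multiple"),
      labels = c(twin_first_multiple = "Child is twin (1st Multiple)",
                 twin_second_multiple = "Child is twin (2nd Multiple)"))
  )
}

#' Display labels for the model effects
#' @param variable_spec a variable specification, see \code{\link{u5cm_variables}}.
#' @return named character vector mapping effect name to display label.
#' @export
effect_labels <- function(variable_spec = u5cm_variables()) {
  unlist(unname(lapply(variable_spec, `[[`, "labels")))
}

#' Reference effect sizes for under-five mortality
#'
#' Published posterior-mean log-hazard effects from a Bayesian spatial
#' survival analysis of KDHS-2014 under-five mortality, used as the default
#' ground truth of the synthetic-data generator and as the worked input of
#' \code{\link{hazard_ratio_report}}.
#'
#' @return named numeric vector of 14 log-hazard-ratio coefficients.
#' @export
u5cm_reference_effects <- function() {
  c(sex_female = -0.1304,
    residence_rural = 0.1424,
    head_female = -0.1550,
    wealth_poorer = 0.0851,
    wealth_middle = 0.1952,
    wealth_richer = 0.2017,
    wealth_richest = 0.2512,
    edu_primary = -0.1756,
    edu_secondary = -0.2982,
    edu_higher = -0.0460,
    age_first_birth = 0.0251,
    maternal_age = 0.0013,
    twin_first_multiple = 0.1642,
    twin_second_multiple = 0.4438)
}

#' Reference posterior summaries of the effects (coefficient scale)
#'
#' The full published posterior summary table (mean, sd, equal-tailed 95\%
#' interval) matching \code{\link{u5cm_reference_effects}}; input for the
#' hazard-ratio report when no fitted chains are at hand.
#'
#' @return data.frame with columns \code{effect}, \code{mean}, \code{sd},
#'   \code{lower}, \code{upper}.
#' @export
u5cm_reference_summary <- function() {
  data.frame(
    effect = names(u5cm_reference_effects()),
    mean = unname(u5cm_reference_effects()),
    sd = c(0.0636, 0.083, 0.0693, 0.0952, 0.102, 0.1188, 0.1533,
           0.1095, 0.1385, 0.2001, 0.0112, 0.0056, 0.1421, 0.1749),
    lower = c(-0.2535, -0.02, -0.2813, -0.0979, -0.0038, -0.0291, -0.0292,
              -0.3869, -0.5533, -0.4231, 0.0041, -0.0089, -0.1285, 0.0951),
    upper = c(-0.0079, 0.3102, -0.0159, 0.2751, 0.3824, 0.4229, 0.5688,
              0.0499, -0.0128, 0.3574, 0.0463, 0.0126, 0.4325, 0.7585),
    stringsAsFactors = FALSE
  )
}

#' Build the model design matrix
#'
#' Dummy-encodes the categorical covariates against their declared reference
#' levels and passes continuous covariates through, optionally centring them
#' (centring only shifts the baseline hazard; coefficients are unchanged).
#' Records with a missing value in any modelled field are dropped with a
#' message; an unseen categorical level is an error.
#'
#' @param records data.frame holding one column per variable in
#'   \code{variable_spec}.
#' @param variable_spec see \code{\link{u5cm_variables}}.
#' @param center centre continuous covariates at their sample mean
#'   (default \code{TRUE}).
#' @return object of class \code{design_matrix}: the numeric matrix with
#'   attributes \code{reference_levels}, \code{labels}, \code{centers} and
#'   \code{kept} (row indices of \code{records} retained).
#' @export
build_design <- function(records, variable_spec = u5cm_variables(),
                         center = TRUE) {
  vars <- names(variable_spec)
  missing_cols <- setdiff(vars, names(records))
  if (length(missing_cols))
    stop("records are missing variable column(s): ",
         paste(missing_cols, collapse = ", "))
  ## validate levels before dropping NAs so unseen levels always error
  for (v in vars) {
    sp <- variable_spec[[v]]
    if (sp$type == "categorical") {
      vals <- as.character(records[[v]])
      bad <- setdiff(unique(vals[!is.na(vals)]), sp$levels)
      if (length(bad))
        stop("unseen level(s) for '", v, "': ", paste(bad, collapse = ", "))
    }
  }
  keep <- rep(TRUE, nrow(records))
  for (v in vars) keep <- keep & !is.na(records[[v]])
  if (any(!keep))
    message("dropping ", sum(!keep), " record(s) with missing covariate values")
  recs <- records[keep, , drop = FALSE]

  cols <- list()
  refs <- list()
  centers <- c()
  for (v in vars) {
    sp <- variable_spec[[v]]
    if (sp$type == "categorical") {
      vals <- factor(as.character(recs[[v]]), levels = sp$levels)
      refs[[v]] <- sp$reference
      for (lev in names(sp$effects)) {
        cols[[sp$effects[[lev]]]] <- as.numeric(vals == lev)
      }
    } else {
      x <- as.numeric(recs[[v]])
      if (any(!is.finite(x))) stop("non-finite values in continuous variable '", v, "'")
      nm <- sp$effects[["value"]]
      if (center) {
        centers[nm] <- mean(x)
        x <- x - centers[nm]
      }
      cols[[nm]] <- x
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  structure(X,
            reference_levels = refs,
            labels = effect_labels(variable_spec),
            centers = centers,
            kept = which(keep),
            class = c("design_matrix", "matrix"))
}
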