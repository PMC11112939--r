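#' Printed study cohort specifications
#'
#' Per-stratum patient and outcome counts of the published NICS vs control
#' comparison, keyed by stratifier. `cohort_spec_age()` carries the female
#' age strata (< 35 / >= 35 years); `cohort_spec_miscarriage()` carries the
#' previous-early-spontaneous-miscarriage strata (0 / 1 / >= 2). The
#' marginal sums of either spec equal the overall two-group comparison
#' (90 NICS vs 161 control patients).
#'
#' @return An object of class `nics_cohort_spec`: list with `stratifier`
#'   and `strata` (data.frame `group`, `stratum`, `n`, `biochemical`,
#'   `clinical`, `ongoing`, `live_birth`).
#' @export
cohort_spec_age <- function() {
  strata <- data.frame(
    group = rep(c("NICS", "control"), each = 2),
    stratum = rep(c("<35", ">=35"), 2),
    n = c(28, 62, 105, 56),
    biochemical = c(24, 51, 81, 37),
    clinical = c(21, 42, 69, 18),
    ongoing = c(18, 35, 58, 14),
    live_birth = c(17, 34, 55, 14),
    stringsAsFactors = FALSE
  )
  structure(list(stratifier = "age", strata = strata),
            class = "nics_cohort_spec")
}

#' @rdname cohort_spec_age
#' @export
cohort_spec_miscarriage <- function() {
  strata <- data.frame(
    group = rep(c("NICS", "control"), each = 3),
    stratum = rep(c("0", "1", ">=2"), 2),
    n = c(59, 19, 12, 130, 23, 8),
    biochemical = c(52, 16, 7, 97, 16, 5),
    clinical = c(44, 14, 5, 75, 11, 1),
    ongoing = c(37, 12, 4, 64, 8, 0),
    live_birth = c(36, 11, 4, 61, 8, 0),
    stringsAsFactors = FALSE
  )
  structure(list(stratifier = "miscarriages", strata = strata),
            class = "nics_cohort_spec")
}

#' Reconstruct a patient-level table from printed stratum counts
#'
#' Expands per-stratum numerators into an exact patient-level binary table:
#' within each stratum the four outcomes are nested (live birth implies
#' ongoing implies clinical implies biochemical pregnancy), so the unique
#' patient-level table with the printed marginals assigns outcomes in sorted
#' order. Deterministic; covariates other than the stratifier are filled
#' with representative values (age 30 / 38 years for the age strata; the
#' miscarriage count itself for the miscarriage strata) and all others with
#' NA, since they are not printed at patient level.
#'
#' @param spec A `nics_cohort_spec` (see [cohort_spec_age()]).
#' @return A patient data.frame with the standard columns (`group`,
#'   `female_age`, `male_age`, `n_prior_miscarriages`, `indication`,
#'   `infertility_type`, `gn_dosage`, `gn_days`, `biochemical`, `clinical`,
#'   `ongoing`, `live_birth`).
#' @export
reconstruct_patient_table <- function(spec) {
  stopifnot(inherits(spec, "nics_cohort_spec"))
  st <- spec$strata
  bad <- !(st$live_birth <= st$ongoing & st$ongoing <= st$clinical &
             st$clinical <= st$biochemical & st$biochemical <= st$n)
  if (any(bad)) {
    k <- which(bad)[1]
    stop("inconsistent outcome nesting in stratum '", st$stratum[k],
         "' of group ", st$group[k],
         " (require live_birth <= ongoing <= clinical <= biochemical <= n)")
  }
  rows <- lapply(seq_len(nrow(st)), function(k) {
    n <- st$n[k]
    if (n == 0) return(NULL)
    i <- seq_len(n)
    df <- data.frame(
      group = st$group[k],
      female_age = NA_real_, male_age = NA_real_,
      n_prior_miscarriages = NA_integer_,
      indication = NA_character_, infertility_type = NA_character_,
      gn_dosage = NA_real_, gn_days = NA_real_,
      biochemical = as.integer(i <= st$biochemical[k]),
      clinical = as.integer(i <= st$clinical[k]),
      ongoing = as.integer(i <= st$ongoing[k]),
      live_birth = as.integer(i <= st$live_birth[k]),
      stringsAsFactors = FALSE
    )
    if (spec$stratifier == "age") {
      df$female_age <- if (st$stratum[k] == "<35") 30 else 38
    } else if (spec$stratifier == "miscarriages") {
      df$n_prior_miscarriages <-
        if (st$stratum[k] == ">=2") 2L else as.integer(st$stratum[k])
    }
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default cohort-simulation model
#'
#' Group sizes, covariate distributions (means/SDs matching the published
#' baseline table) and a true logistic outcome model for the primary
#' outcome. Covariate effects act on centred covariates, so `baseline_p` is
#' the control-group outcome probability at covariate means.
#'
#' @param n_nics,n_control Patients per arm.
#' @param group_or True odds ratio of the NICS group for the modelled
#'   outcome.
#' @param baseline_p Control-arm outcome probability at covariate means.
#' @param beta_female_age,beta_miscarriages Log-odds per year / per prior
#'   miscarriage (centred).
#' @return A list consumed by [simulate_patient_cohort()].
#' @export
cohort_model <- function(n_nics = 90, n_control = 161, group_or = 2.8,
                         baseline_p = 0.43, beta_female_age = -0.05,
                         beta_miscarriages = -0.2) {
  list(
    n = c(NICS = n_nics, control = n_control),
    covariates = list(
      female_age = list(NICS = c(35.1, 4.2), control = c(32.5, 4.9),
                        range = c(22, 40)),
      male_age = list(NICS = c(34.6, 4.2), control = c(33.1, 4.9),
                      range = c(20, 60)),
      gn_dosage = list(NICS = c(2077.5, 674.9), control = c(1856.0, 617.8),
                       range = c(300, 6000)),
      gn_days = list(NICS = c(10.0, 1.8), control = c(9.5, 1.8),
                     range = c(5, 20)),
      miscarriages = list(NICS = c(59, 19, 12) / 90,
                          control = c(130, 23, 8) / 161),
      indication = list(NICS = c(12, 69, 9) / 90,
                        control = c(61, 71, 29) / 161),
      infertility = list(NICS = c(20, 70) / 90, control = c(79, 82) / 161)
    ),
    model = list(
      outcome = "live_birth",
      baseline_p = baseline_p,
      log_or_group = log(group_or),
      beta_female_age = beta_female_age,
      beta_miscarriages = beta_miscarriages
    ),
    # conditional add-on probabilities that build the nested outcomes above
    # the modelled one: P(ongoing | not live), P(clinical | not ongoing),
    # P(biochemical | not clinical)
    nesting_up = c(ongoing = 0.04, clinical = 0.18, biochemical = 0.45)
  )
}

.rnorm_trunc <- function(n, mean, sd, range) {
  x <- rnorm(n, mean, sd)
  pmin(range[2], pmax(range[1], x))
}

#' Simulate a patient cohort from a stated logistic model
#'
#' Covariates are drawn per arm from the model's distributions; the primary
#' outcome is drawn from the logistic model (intercept at the control-arm
#' baseline, group log-OR, centred covariate effects); the remaining nested
#' outcomes are built upward with conditional add-on rates so the nesting
#' invariant holds by construction.
#'
#' @param spec Model from [cohort_model()].
#' @param seed Optional integer seed.
#' @return Patient data.frame in the standard schema.
#' @export
simulate_patient_cohort <- function(spec = cohort_model(), seed = NULL) {
  if (any(spec$n <= 0)) stop("group sizes must be positive")
  if (!is.null(seed)) set.seed(seed)
  cv <- spec$covariates
  arms <- lapply(c("NICS", "control"), function(g) {
    n <- spec$n[[g]]
    data.frame(
      group = g,
      female_age = .rnorm_trunc(n, cv$female_age[[g]][1],
                                cv$female_age[[g]][2], cv$female_age$range),
      male_age = .rnorm_trunc(n, cv$male_age[[g]][1], cv$male_age[[g]][2],
                              cv$male_age$range),
      n_prior_miscarriages = sample(0:2, n, TRUE, prob = cv$miscarriages[[g]]),
      indication = sample(c("male", "female", "both"), n, TRUE,
                          prob = cv$indication[[g]]),
      infertility_type = sample(c("primary", "secondary"), n, TRUE,
                                prob = cv$infertility[[g]]),
      gn_dosage = .rnorm_trunc(n, cv$gn_dosage[[g]][1], cv$gn_dosage[[g]][2],
                               cv$gn_dosage$range),
      gn_days = .rnorm_trunc(n, cv$gn_days[[g]][1], cv$gn_days[[g]][2],
                             cv$gn_days$range),
      stringsAsFactors = FALSE
    )
  })
  pat <- do.call(rbind, arms)
  md <- spec$model
  eta <- qlogis(md$baseline_p) +
    md$log_or_group * (pat$group == "NICS") +
    md$beta_female_age * (pat$female_age - mean(pat$female_age)) +
    md$beta_miscarriages * (pat$n_prior_miscarriages -
                              mean(pat$n_prior_miscarriages))
  primary <- rbinom(nrow(pat), 1, plogis(eta))

  up <- spec$nesting_up
  live <- primary
  ongoing <- pmax(live, rbinom(nrow(pat), 1, up[["ongoing"]]))
  clinical <- pmax(ongoing, rbinom(nrow(pat), 1, up[["clinical"]]))
  biochemical <- pmax(clinical, rbinom(nrow(pat), 1, up[["biochemical"]]))
  pat$biochemical <- biochemical
  pat$clinical <- clinical
  pat$ongoing <- ongoing
  pat$live_birth <- live
  rownames(pat) <- NULL
  pat
}

.patient_columns <- c("group", "female_age", "male_age",
                      "n_prior_miscarriages", "indication",
                      "infertility_type", "gn_dosage", "gn_days",
                      "biochemical", "clinical", "ongoing", "live_birth")

#' Write / read a patient table as CSV
#'
#' Reading validates the outcome-nesting invariant (live birth implies
#' ongoing implies clinical implies biochemical) and rejects violating
#' files naming the offending rows.
#'
#' @param patients Patient data.frame in the standard schema.
#' @param path CSV path.
#' @return `path` (write) or the validated data.frame (read).
#' @export
write_patients <- function(patients, path) {
  stopifnot(all(.patient_columns %in% names(patients)))
  write.csv(patients[, .patient_columns], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.patient_columns, names(df))
  if (length(missing)) {
    stop("patient CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  bad <- which(!(df$live_birth <= df$ongoing & df$ongoing <= df$clinical &
                   df$clinical <= df$biochemical))
  if (length(bad)) {
    stop("outcome nesting violated (live_birth <= ongoing <= clinical <= ",
         "biochemical) at row(s): ",
         paste(head(bad, 10), collapse = ", "))
  }
  df
}
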