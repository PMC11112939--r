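#' Percentage rate, printed-style rounding
#'
#' `100 * numerator / denominator`, rounded half-up to one decimal, the
#' convention used by the clinical tables.
#'
#' @param numerator,denominator Non-negative counts, numerator <= denominator.
#' @return Numeric percentage.
#' @export
rate <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0) || any(numerator > denominator)) {
    stop("numerator must lie in [0, denominator]")
  }
  .round_half_up(100 * numerator / denominator, 1)
}

#' Chi-square test on a 2x2 table
#'
#' Pearson statistic by default; Yates continuity correction or Fisher's
#' exact test by flag.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param method "pearson" (default), "yates" or "fisher".
#' @return List with `statistic` (NA for fisher), `p_value`, `df`,
#'   `expected`, `method`.
#' @export
chisq_2x2 <- function(table, method = c("pearson", "yates", "fisher")) {
  method <- match.arg(method)
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in 2x2 table")
  expected <- outer(rs, cs) / n
  if (method == "fisher") {
    p <- fisher.test(tab)$p.value
    return(list(statistic = NA_real_, p_value = p, df = NA_integer_,
                expected = expected, method = method))
  }
  dev <- abs(tab - expected)
  if (method == "yates") dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / expected)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, expected = expected, method = method)
}

# declared reference levels for the adjusted model
.reference_levels <- list(group = "control", indication = "male",
                          infertility_type = "primary")

#' Covariate-adjusted logistic regression
#'
#' Maximum-likelihood logistic fit (IRLS via `stats::glm`) of a binary
#' outcome on group and covariates, with Wald 95% confidence intervals.
#' Categorical covariates are dummy-coded against declared reference levels
#' (control group, male-factor indication, primary infertility). Separation
#' is flagged (huge coefficient or standard error), never silently dropped.
#'
#' @param patients Patient data.frame.
#' @param outcome Outcome column name (default "live_birth").
#' @param covariates Adjustment covariate names (default: the seven declared
#'   covariates); `character(0)` for an unadjusted fit.
#' @param include_group Include the group term (default TRUE); FALSE with no
#'   covariates gives the intercept-only model.
#' @return Data.frame per model term: `term`, `estimate` (log-odds), `se`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `separation`.
#' @export
fit_logistic <- function(patients, outcome = "live_birth",
                         covariates = c("female_age", "male_age",
                                        "n_prior_miscarriages", "indication",
                                        "infertility_type", "gn_dosage",
                                        "gn_days"),
                         include_group = TRUE) {
  stopifnot(outcome %in% names(patients))
  vars <- c(if (include_group) "group", covariates)
  vars <- vars[vars %in% names(patients)]
  use <- patients[, c(outcome, vars), drop = FALSE]
  bad <- which(!complete.cases(use))
  if (length(bad)) {
    stop("missing covariate values for patient row(s): ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  }
  for (v in names(.reference_levels)) {
    if (v %in% names(use)) {
      use[[v]] <- stats::relevel(factor(use[[v]]), .reference_levels[[v]])
    }
  }
  # drop constant covariates (e.g. in degenerate reconstructed tables)
  keep <- vapply(vars, function(v) length(unique(use[[v]])) > 1, TRUE)
  rhs <- if (any(keep)) paste(vars[keep], collapse = " + ") else "1"
  form <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- glm(form, family = binomial(), data = use)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    odds_ratio = unname(exp(est)),
    ci_low = unname(exp(est - qnorm(0.975) * se)),
    ci_high = unname(exp(est + qnorm(0.975) * se)),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    separation = unname(abs(est) > 10 | se > 10),
    stringsAsFactors = FALSE
  )
}

.outcome_names <- c("biochemical", "clinical", "ongoing", "live_birth")

# one group-vs-group comparison of one outcome; returns a one-row data.frame
.compare_outcome <- function(patients, outcome, method = "pearson") {
  g <- patients$group
  y <- patients[[outcome]]
  n1 <- sum(g == "NICS")
  n2 <- sum(g == "control")
  x1 <- sum(y[g == "NICS"])
  x2 <- sum(y[g == "control"])
  out <- data.frame(
    outcome = outcome,
    nics_n = n1, nics_events = x1,
    nics_rate = if (n1 > 0) rate(x1, n1) else NA_real_,
    control_n = n2, control_events = x2,
    control_rate = if (n2 > 0) rate(x2, n2) else NA_real_,
    chisq = NA_real_, p_value = NA_real_, p_fisher = NA_real_,
    stringsAsFactors = FALSE
  )
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE)
  if (n1 > 0 && n2 > 0 && all(colSums(tab) > 0)) {
    ch <- chisq_2x2(tab, method = method)
    out$chisq <- ch$statistic
    out$p_value <- ch$p_value
    out$p_fisher <- chisq_2x2(tab, method = "fisher")$p_value
  }
  out
}

#' Stratified outcome comparison
#'
#' Per-stratum, per-outcome rates and two-group chi-square comparisons,
#' mirroring the published age- and miscarriage-stratified tables. Empty
#' strata are emitted with zero denominators and no test.
#'
#' @param patients Patient data.frame.
#' @param stratifier "age" (female_age < 35 vs >= 35) or "miscarriages"
#'   (0 / 1 / >= 2 previous early spontaneous miscarriages).
#' @param method Chi-square variant for the test column; see [chisq_2x2()].
#' @return Data.frame with one row per stratum x outcome.
#' @export
stratified_outcomes <- function(patients,
                                stratifier = c("age", "miscarriages"),
                                method = "pearson") {
  stratifier <- match.arg(stratifier)
  if (stratifier == "age") {
    if (any(is.na(patients$female_age))) {
      stop("female_age missing; cannot stratify by age")
    }
    strat <- ifelse(patients$female_age < 35, "<35", ">=35")
    levels <- c("<35", ">=35")
  } else {
    if (any(is.na(patients$n_prior_miscarriages))) {
      stop("n_prior_miscarriages missing; cannot stratify by miscarriages")
    }
    strat <- ifelse(patients$n_prior_miscarriages >= 2, ">=2",
                    as.character(patients$n_prior_miscarriages))
    levels <- c("0", "1", ">=2")
  }
  out <- lapply(levels, function(s) {
    sub <- patients[strat == s, , drop = FALSE]
    rows <- do.call(rbind, lapply(.outcome_names, function(o) {
      if (nrow(sub) == 0) {
        data.frame(outcome = o, nics_n = 0L, nics_events = 0L,
                   nics_rate = NA_real_, control_n = 0L, control_events = 0L,
                   control_rate = NA_real_, chisq = NA_real_,
                   p_value = NA_real_, p_fisher = NA_real_,
                   stringsAsFactors = FALSE)
      } else {
        .compare_outcome(sub, o, method)
      }
    }))
    cbind(stratum = s, rows, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overall two-group outcome comparison
#'
#' All four outcome rates per group with unadjusted chi-square tests and,
#' when the adjustment covariates are complete, the covariate-adjusted
#' logistic odds ratio per outcome.
#'
#' @param patients Patient data.frame with both groups present.
#' @param adjust "auto" (adjust when covariates are complete), TRUE (error
#'   on missing covariates) or FALSE.
#' @param method Chi-square variant; see [chisq_2x2()].
#' @return List with `rates` (data.frame per outcome) and `adjusted`
#'   (data.frame of group odds ratios per outcome, or NULL), plus
#'   `adjusted_available`.
#' @export
compare_groups <- function(patients, adjust = "auto", method = "pearson") {
  if (!all(c("NICS", "control") %in% patients$group)) {
    stop("both groups must be present")
  }
  rates <- do.call(rbind, lapply(.outcome_names, function(o) {
    .compare_outcome(patients, o, method)
  }))
  covs <- c("female_age", "male_age", "n_prior_miscarriages", "indication",
            "infertility_type", "gn_dosage", "gn_days")
  complete <- all(covs %in% names(patients)) &&
    all(complete.cases(patients[, covs]))
  adjusted <- NULL
  if (isTRUE(adjust) && !complete) {
    bad <- which(!complete.cases(patients[, intersect(covs,
                                                      names(patients))]))
    stop("missing covariate values for patient row(s): ",
         paste(head(bad, 10), collapse = ", "))
  }
  if ((isTRUE(adjust) || identical(adjust, "auto")) && complete) {
    adjusted <- do.call(rbind, lapply(.outcome_names, function(o) {
      f <- fit_logistic(patients, outcome = o, covariates = covs)
      g <- f[grepl("^group", f$term), , drop = FALSE]
      cbind(outcome = o, g, stringsAsFactors = FALSE)
    }))
    rownames(adjusted) <- NULL
  }
  list(rates = rates, adjusted = adjusted, adjusted_available = complete)
}
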