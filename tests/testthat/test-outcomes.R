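test_that("rate uses printed-style half-up rounding", {
  expect_equal(rate(63, 90), 70.0)
  expect_equal(rate(0, 8), 0.0)
  expect_equal(rate(5, 5), 100.0)
  expect_equal(rate(51, 90), 56.7)
  expect_equal(rate(69, 161), 42.9)
  expect_error(rate(1, 0), "denominator")
  expect_error(rate(6, 5), "numerator")
})

test_that("chisq_2x2 matches the independent oracle on random tables", {
  expect_equal(chisq_2x2(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chisq_2x2(matrix(10, 2, 2))$p_value, 1)
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2)), "zero margin")

  set.seed(1)
  for (r in 1:1000) {
    tab <- matrix(rpois(4, 30) + 1, 2)
    ours <- chisq_2x2(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
    oursy <- chisq_2x2(tab, method = "yates")
    refy <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_equal(oursy$statistic, unname(refy$statistic), tolerance = 1e-10)
  }

  # overall clinical-pregnancy table; the uncorrected Pearson p is the one
  # compatible with the reported significance (p = 0.013)
  tab <- matrix(c(63, 27, 87, 74), 2, byrow = TRUE)
  p_pearson <- chisq_2x2(tab)$p_value
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(p_pearson, unname(ref$p.value), tolerance = 1e-12)

  # small-cell stratum (0/8 live births): both routes available
  tab2 <- matrix(c(4, 8, 0, 8), 2, byrow = TRUE)
  expect_true(is.finite(chisq_2x2(tab2)$p_value))
  expect_true(is.finite(chisq_2x2(tab2, method = "fisher")$p_value))
})

test_that("logistic fit matches closed forms", {
  # saturated 2x2: log OR equals log(ad/bc)
  a <- 63; b <- 27; c <- 87; d <- 74
  pat <- data.frame(
    group = rep(c("NICS", "control"), c(a + b, c + d)),
    live_birth = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  )
  fit <- fit_logistic(pat, "live_birth", covariates = character(0))
  logor <- fit$estimate[fit$term == "groupNICS"]
  expect_equal(logor, log(a * d / (b * c)), tolerance = 1e-8)

  # intercept-only model: fitted probability equals prevalence
  fit0 <- fit_logistic(pat, "live_birth", covariates = character(0),
                       include_group = FALSE)
  expect_equal(plogis(fit0$estimate[fit0$term == "(Intercept)"]),
               mean(pat$live_birth), tolerance = 1e-8)

  # null recovery at large n
  pat2 <- simulate_patient_cohort(
    cohort_model(n_nics = 5000, n_control = 5000, group_or = 1), seed = 2)
  fit2 <- fit_logistic(pat2, "live_birth")
  or <- fit2$odds_ratio[fit2$term == "groupNICS"]
  expect_gt(or, 0.8)
  expect_lt(or, 1.25)
  expect_false(any(fit2$separation))

  # missing covariates are rejected listing patients
  pat3 <- pat2[1:50, ]
  pat3$gn_days[7] <- NA
  expect_error(fit_logistic(pat3, "live_birth"), "row\\(s\\): 7")
})

test_that("group comparison reproduces printed overall rates", {
  pat <- reconstruct_patient_table(cohort_spec_age())
  rep <- compare_groups(pat)
  r <- rep$rates
  expect_equal(r$nics_rate[r$outcome == "biochemical"], 83.3)
  expect_equal(r$control_rate[r$outcome == "biochemical"], 73.3)
  expect_equal(r$nics_rate[r$outcome == "clinical"], 70.0)
  expect_equal(r$control_rate[r$outcome == "clinical"], 54.0)
  expect_equal(r$nics_rate[r$outcome == "ongoing"], 58.9)
  expect_equal(r$control_rate[r$outcome == "ongoing"], 44.7)
  expect_equal(r$nics_rate[r$outcome == "live_birth"], 56.7)
  expect_equal(r$control_rate[r$outcome == "live_birth"], 42.9)
  # reconstructed tables carry no full covariates: adjustment unavailable
  expect_false(rep$adjusted_available)
  expect_null(rep$adjusted)
  expect_error(compare_groups(pat, adjust = TRUE), "missing covariate")

  # symmetry: swapping group labels inverts the adjusted OR
  sim <- simulate_patient_cohort(cohort_model(), seed = 5)
  fwd <- compare_groups(sim)
  swapped <- sim
  swapped$group <- ifelse(sim$group == "NICS", "control", "NICS")
  bwd <- compare_groups(swapped)
  expect_equal(
    fwd$adjusted$odds_ratio[fwd$adjusted$outcome == "live_birth"],
    1 / bwd$adjusted$odds_ratio[bwd$adjusted$outcome == "live_birth"],
    tolerance = 1e-6)
})

test_that("stratified outcomes mirror the printed stratified tables", {
  age <- reconstruct_patient_table(cohort_spec_age())
  tab3 <- stratified_outcomes(age, "age")
  pick <- function(df, s, o, col) df[df$stratum == s & df$outcome == o, col]
  expect_equal(pick(tab3, ">=35", "live_birth", "nics_rate"), 54.8)
  expect_equal(pick(tab3, ">=35", "live_birth", "control_rate"), 25.0)
  expect_equal(pick(tab3, ">=35", "biochemical", "nics_rate"), 82.3)
  expect_equal(pick(tab3, ">=35", "clinical", "nics_rate"), 67.7)
  expect_equal(pick(tab3, ">=35", "ongoing", "nics_rate"), 56.5)
  expect_equal(pick(tab3, ">=35", "biochemical", "control_rate"), 66.1)
  expect_equal(pick(tab3, ">=35", "clinical", "control_rate"), 32.1)
  expect_equal(pick(tab3, ">=35", "ongoing", "control_rate"), 25.0)

  mis <- reconstruct_patient_table(cohort_spec_miscarriage())
  tab4 <- stratified_outcomes(mis, "miscarriages")
  expect_equal(pick(tab4, "0", "live_birth", "nics_rate"), 61.0)
  expect_equal(pick(tab4, "0", "live_birth", "control_rate"), 46.9)
  expect_equal(pick(tab4, "0", "live_birth", "nics_rate") -
                 pick(tab4, "0", "live_birth", "control_rate"), 14.1)
  expect_equal(pick(tab4, ">=2", "live_birth", "nics_rate"), 33.3)
  expect_equal(pick(tab4, ">=2", "live_birth", "control_rate"), 0.0)

  # degenerate partition: a constant stratifier equals the overall comparison
  const <- age
  const$female_age <- 30
  one <- stratified_outcomes(const, "age")
  overall <- compare_groups(age)$rates
  sub <- one[one$stratum == "<35", names(overall)]
  rownames(sub) <- NULL
  expect_equal(sub, overall)
})
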