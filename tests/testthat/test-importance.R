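fake_fit <- function(estimates, ses) {
  structure(list(
    coefficients = tibble::tibble(
      term = names(estimates), type = "mean",
      estimate = unname(estimates), std_error = unname(ses)
    ),
    beta_mean = estimates, converged = TRUE
  ), class = "mixlogit_fit")
}

test_that("coefficient ranges with the implicit reference zero give the published shares", {
  imp <- relative_importance(adsmart_beta_means(), study_attrs)
  shares <- setNames(imp$share_pct, imp$attribute)
  expect_identical(unname(shares["severe"]), 50.88)
  expect_identical(unname(shares["mild"]), 19.97)
  expect_identical(unname(shares["evidence"]), 19.21)
  expect_identical(round_half_up(unname(shares["frequency"]), 1), 8.0)
  expect_identical(unname(shares["monitoring"]), 1.95)
  # ranges: negative single coefficients count via the implicit 0
  expect_equal(imp$range[imp$attribute == "frequency"], 0.525)
  expect_equal(imp$range[imp$attribute == "severe"], 3.340)
})

test_that("importance shares normalise, are scale invariant, and sum to 100", {
  one <- dce_attributes(attribute("only", c("l1", "l2", "l3")))
  est <- c(only_l2 = 0.5, only_l3 = 1.2)
  imp <- relative_importance(est, one)
  expect_equal(imp$share, 100)

  two <- dce_attributes(attribute("a", c("a1", "a2")),
                        attribute("b", c("b1", "b2")))
  imp2 <- relative_importance(c(a_a2 = 0.7, b_b2 = -0.7), two)
  expect_equal(imp2$share, c(50, 50))

  withr::with_seed(61, {
    for (i in 1:10) {
      est <- setNames(rnorm(7), study_scheme$term)
      imp_a <- relative_importance(est, study_attrs)
      imp_b <- relative_importance(est * 7.3, study_attrs)
      expect_lte(abs(sum(imp_a$share_pct) - 100), 0.02)
      expect_equal(imp_a$share, imp_b$share, tolerance = 1e-10)
    }
  })

  expect_error(relative_importance(c(bogus = 1), study_attrs),
               class = "dcepref_missing_coefficient")
})

test_that("group comparisons follow the two-sample z statistic", {
  est <- setNames(rep(1, 7), study_scheme$term)
  fa <- fake_fit(replace(est, "severe_uncommon", 1.0), rep(0.1, 7))
  fb <- fake_fit(replace(est, "severe_uncommon", 0.5), rep(0.1, 7))
  cmp <- compare_groups(fa, fb, "severe_uncommon", labels = c("g1", "g2"))
  expect_equal(cmp$z, 0.5 / sqrt(0.02), tolerance = 1e-4)
  expect_equal(cmp$p_value, 2 * pnorm(-0.5 / sqrt(0.02)), tolerance = 1e-6)
  expect_equal(cmp$p_value, 4.07e-4, tolerance = 0.01)
  expect_identical(cmp$stars, "***")

  # antisymmetry: swapping groups negates z, keeps p
  rev_cmp <- compare_groups(fb, fa, "severe_uncommon", labels = c("g2", "g1"))
  expect_equal(rev_cmp$z, -cmp$z)
  expect_equal(rev_cmp$p_value, cmp$p_value)

  # identical fits: z = 0, p = 1
  same <- compare_groups(fa, fa, "severe_uncommon")
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  expect_identical(same$stars, "")

  expect_error(compare_groups(fa, fb, "not_a_term"),
               class = "dcepref_missing_coefficient")
})

test_that("stratified fits agree on a homogeneous cohort and split sizes add up", {
  cfg <- cohort_config(n_respondents = 800,
                       base_prefs = true_preferences(beta_sd = 0),
                       seed = 62)
  co <- simulate_cohort(cfg, study_design)
  est_data <- co$choices[!co$choices$is_attention, ]
  fits <- stratify_and_fit(est_data, co$respondents, "age65_gender",
                           engine = "mnl")
  expect_setequal(fits$stratum, c("female_under65", "female_65plus",
                                  "male_under65", "male_65plus"))
  n_stratifiable <- sum(co$respondents$gender %in% c("female", "male"))
  expect_identical(sum(fits$n_respondents), as.integer(n_stratifiable))

  # homogeneous generating preferences: estimates mutually within 3 SE
  for (tm in c("severe_rare_or_very_rare", "evidence_human_trials")) {
    cmp <- compare_all_groups(fits, terms = tm)
    expect_true(all(abs(cmp$z) < 3))
  }
})

test_that("a stratum-specific sign flip is recovered by the stratified fits", {
  flipped <- true_preferences(
    beta_mean = replace(adsmart_beta_means(), "monitoring_not_required", 1.5),
    beta_sd = 0)
  cfg <- cohort_config(
    n_respondents = 1200,
    base_prefs = true_preferences(
      beta_mean = replace(adsmart_beta_means(), "monitoring_not_required",
                          -1.5),
      beta_sd = 0),
    stratum_prefs = list(male_under65 = flipped),
    seed = 63)
  co <- simulate_cohort(cfg, study_design)
  est_data <- co$choices[!co$choices$is_attention, ]
  fits <- stratify_and_fit(est_data, co$respondents, "age65_gender",
                           engine = "mnl")
  get_mon <- function(s) {
    fits$fit[[which(fits$stratum == s)]]$beta_mean[["monitoring_not_required"]]
  }
  expect_gt(get_mon("male_under65"), 0)
  expect_lt(get_mon("female_under65"), 0)
  expect_lt(get_mon("female_65plus"), 0)
})

test_that("small strata are flagged exploratory", {
  cfg <- cohort_config(n_respondents = 400,
                       base_prefs = true_preferences(beta_sd = 0), seed = 64)
  co <- simulate_cohort(cfg, study_design)
  est_data <- co$choices[!co$choices$is_attention, ]
  fits <- suppressWarnings(
    stratify_and_fit(est_data, co$respondents, "experience",
                     engine = "mnl", min_size = 50))
  expect_gte(nrow(fits), 2L)
  expect_identical(fits$exploratory, fits$n_respondents < 50)
})

test_that("between-group p-values are uniform under the null", {
  # two strata drawn from one generating process; the z-test p-value for a
  # chosen coefficient should be U(0,1) across replicates
  attrs <- toy_attrs
  prof <- enumerate_full_factorial(attrs)
  tasks <- list(
    list(A = unlist(prof[1, ]), B = unlist(prof[4, ])),
    list(A = unlist(prof[2, ]), B = unlist(prof[3, ])),
    list(A = unlist(prof[3, ]), B = unlist(prof[2, ])),
    list(A = unlist(prof[4, ]), B = unlist(prof[1, ]))
  )
  des <- manual_design(tasks, attrs)
  prefs <- true_preferences(beta_mean = c(a_a1 = 0.4, b_b1 = -0.2),
                            beta_sd = 0,
                            drug_worths = adsmart_drug_worths())
  pvals <- vapply(1:200, function(rep) {
    ch <- simulate_choices(des, prefs, 160, seed = 7000 + rep,
                           opt_out = FALSE)
    ids <- unique(ch$respondent_id)
    fa <- fit_mnl(ch[ch$respondent_id %in% ids[1:80], ])
    fb <- fit_mnl(ch[ch$respondent_id %in% ids[81:160], ])
    compare_groups(fa, fb, "a_a1")$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
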