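test_that("choice shares follow the closed-form logit probability", {
  des <- one_attr_design()
  # utility(A) - utility(B) = 1, no opt-out: P(A) = e/(1+e)
  prefs <- true_preferences(beta_mean = c(x_alt = 1), beta_sd = 0,
                            drug_worths = adsmart_drug_worths())
  ch <- simulate_choices(des, prefs, 10000, seed = 3, opt_out = FALSE)
  share_a <- mean(ch$chosen[ch$alternative == "A"])
  p_true <- exp(1) / (1 + exp(1))
  mc_se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(share_a - p_true), 3 * mc_se)
})

test_that("a symmetric three-way Gumbel race gives equal shares", {
  des <- one_attr_design()
  prefs <- true_preferences(beta_mean = c(x_alt = 0), beta_sd = 0,
                            opt_out_constant = 0,
                            drug_worths = adsmart_drug_worths())
  ch <- simulate_choices(des, prefs, 10000, seed = 4)
  shares <- prop.table(table(ch$alternative[ch$chosen == 1]))
  expect_true(all(abs(shares - 1 / 3) < 0.02))
})

test_that("a dominant utility difference is almost always chosen", {
  des <- one_attr_design()
  prefs <- true_preferences(beta_mean = c(x_alt = 50), beta_sd = 0,
                            drug_worths = adsmart_drug_worths())
  ch <- simulate_choices(des, prefs, 1000, seed = 5, opt_out = FALSE)
  expect_gte(mean(ch$chosen[ch$alternative == "A"]), 0.99)
})

test_that("choice simulation is deterministic and panel-structured", {
  prefs <- true_preferences(beta_sd = 0.5)
  a <- simulate_choices(study_design, prefs, 50, seed = 9)
  b <- simulate_choices(study_design, prefs, 50, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, simulate_choices(study_design, prefs, 50,
                                             seed = 10)))
  # every respondent answers the three tasks of exactly one block
  per_resp <- tapply(a$task_id, a$respondent_id,
                     function(x) length(unique(x)))
  expect_true(all(per_resp == 3))
  expect_true(all(tapply(a$block, a$respondent_id,
                         function(x) length(unique(x))) == 1))
})

test_that("simulated rankings respect dominance and symmetry", {
  dom <- true_preferences(
    drug_worths = c(d1 = 50, d2 = 0, d3 = -50, d4 = -100))
  r <- simulate_rankings(dom, 1000, seed = 6)
  frac_sorted <- mean(r$rank1 == "d1" & r$rank2 == "d2" &
                        r$rank3 == "d3" & r$rank4 == "d4")
  expect_gte(frac_sorted, 0.99)

  flat <- true_preferences(drug_worths = c(d1 = 0, d2 = 0, d3 = 0, d4 = 0))
  r2 <- simulate_rankings(flat, 10000, seed = 7)
  first <- prop.table(table(r2$rank1))
  expect_true(all(abs(first - 0.25) < 0.03))
})

test_that("first-rank shares follow the Plackett-Luce closed form", {
  worths <- c(m = 0.8, a = 0.1, i = -0.2, l = -1.1)
  p_true <- exp(worths) / sum(exp(worths))
  prefs <- true_preferences(drug_worths = worths)
  r <- simulate_rankings(prefs, 20000, seed = 8)
  shares <- prop.table(table(factor(r$rank1, levels = names(worths))))
  mc_se <- sqrt(p_true * (1 - p_true) / 20000)
  expect_true(all(abs(shares - p_true) < 3 * mc_se))
})

test_that("default drug worths reproduce the published first-rank shares", {
  p <- exp(adsmart_drug_worths()) / sum(exp(adsmart_drug_worths()))
  printed <- c(metformin = 0.355, atomoxetine = 0.257,
               `isosorbide mononitrate` = 0.274, levetiracetam = 0.113)
  expect_equal(p, printed / sum(printed), tolerance = 1e-12)
})

test_that("cohort demographics track the configured margins", {
  co <- simulate_cohort(cohort_config(n_respondents = 3250, seed = 2),
                        study_design)
  g <- prop.table(table(co$respondents$gender))
  expect_lt(abs(g[["female"]] - 0.680), 0.02)
  expect_lt(abs(g[["male"]] - 0.313), 0.02)
  over55 <- mean(co$respondents$age_band %in% c("55-64", "65-74", "75-84",
                                                "85+"))
  expect_lt(abs(over55 - 0.712), 0.03)
  expect_identical(nrow(co$rankings), 3250L)
  # every respondent contributes 3 choice tasks plus the attention check
  n_tasks <- tapply(co$choices$task_id, co$choices$respondent_id,
                    function(x) length(unique(x)))
  expect_true(all(n_tasks == 4))
})

test_that("cohort generation is reproducible and files round-trip", {
  cfg <- cohort_config(n_respondents = 80, seed = 11)
  a <- simulate_cohort(cfg, study_design)
  b <- simulate_cohort(cfg, study_design)
  expect_identical(a$respondents, b$respondents)
  expect_identical(a$choices, b$choices)
  expect_identical(a$rankings, b$rankings)

  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_choice_file(a$choices, p1, seed = 11)
  write_choice_file(read_choice_file(p1), p2, seed = 11)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("invalid cohort proportions are rejected", {
  expect_error(cohort_config(age_probs = c(a = 0.5, b = 0.4)),
               class = "dcepref_invalid_config")
})

test_that("attention filter implements both policies", {
  cfg <- cohort_config(n_respondents = 100, attention_pass_prob = 0.9,
                       seed = 13)
  co <- simulate_cohort(cfg, study_design)
  n_fail <- sum(!co$respondents$attention_passed)
  expect_gt(n_fail, 0)

  strict <- apply_attention_filter(co$respondents, co$choices, "exclude-fail")
  expect_identical(nrow(strict$respondents), 100L - n_fail)
  expect_identical(strict$n_removed, n_fail)
  expect_false(any(strict$choices$respondent_id %in%
                     co$respondents$respondent_id[!co$respondents$attention_passed]))

  lax <- apply_attention_filter(co$respondents, co$choices, "keep-all")
  expect_identical(lax$n_removed, 0L)
  expect_identical(lax$choices, co$choices)

  all_pass <- simulate_cohort(cohort_config(n_respondents = 40, seed = 14),
                              study_design)
  same <- apply_attention_filter(all_pass$respondents, all_pass$choices,
                                 "exclude-fail")
  expect_identical(same$respondents, all_pass$respondents)

  expect_error(apply_attention_filter(co$respondents, co$choices, "drop"))
})
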