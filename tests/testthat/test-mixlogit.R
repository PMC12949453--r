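test_that("halton sequence returns the radical inverses of 1, 2, 3, ...", {
  h2 <- halton_sequence(3, 1, skip = 0)
  expect_equal(drop(h2), c(0.5, 0.25, 0.75), tolerance = 1e-15)
  h23 <- halton_sequence(2, 2, skip = 0)
  expect_equal(h23[, 2], c(1 / 3, 2 / 3), tolerance = 1e-15)
  # skipping drops the first points
  expect_equal(halton_sequence(1, 1, skip = 3)[1, 1], 0.125,
               tolerance = 1e-15)
  expect_error(halton_sequence(10, 8), class = "dcepref_invalid_spec")
  expect_error(halton_sequence(0, 1), class = "dcepref_invalid_spec")
})

test_that("halton points are close to uniform in every base", {
  h <- halton_sequence(1000, 7, skip = 10)
  for (d in 1:7) {
    ks <- suppressWarnings(stats::ks.test(h[, d], "punif"))
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("mnl_probability is the overflow-safe softmax", {
  expect_equal(mnl_probability(c(0, 0)), c(0.5, 0.5))
  expect_equal(mnl_probability(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(mnl_probability(c(1, 0)),
               c(exp(1) / (1 + exp(1)), 1 / (1 + exp(1))),
               tolerance = 1e-12)
  expect_error(mnl_probability(numeric(0)), class = "dcepref_invalid_spec")
  expect_error(mnl_probability(c(1, Inf)), class = "dcepref_invalid_spec")

  withr::with_seed(31, {
    for (i in 1:10) {
      u <- rnorm(sample(2:5, 1), sd = 10)
      p <- mnl_probability(u)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_equal(p, mnl_probability(u + 123.4), tolerance = 1e-12)
    }
  })
  # extreme utilities stay finite
  expect_equal(mnl_probability(c(1000, 0))[1], 1, tolerance = 1e-12)
})

test_that("MNL recovers generating coefficients on fixed-coefficient data", {
  prefs <- true_preferences(beta_sd = 0)
  ch <- simulate_choices(study_design, prefs, 5000, seed = 41)
  fit <- fit_mnl(ch)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$beta_mean - adsmart_beta_means())), 0.15)
  expect_lt(abs(fit$opt_out_constant - (-2)), 0.5)
  # fitted log-likelihood beats the null
  n_tasks <- fit$n_tasks
  expect_gte(fit$log_likelihood, n_tasks * log(1 / 3))
})

test_that("MNL null data yields coefficients within 3 SE of zero", {
  prefs <- true_preferences(beta_mean = setNames(rep(0, 7),
                                                 study_scheme$term),
                            beta_sd = 0, opt_out_constant = 0)
  ch <- simulate_choices(study_design, prefs, 2000, seed = 42)
  fit <- fit_mnl(ch)
  co <- fit$coefficients[fit$coefficients$type == "mean", ]
  expect_true(all(abs(co$estimate / co$std_error) < 3))
})

test_that("collinear coded columns are reported by name", {
  prefs <- true_preferences(beta_sd = 0)
  ch <- simulate_choices(study_design, prefs, 100, seed = 43)
  ch$dup_col <- ch$severe_uncommon
  expect_error(fit_mnl(ch), "dup_col|severe_uncommon",
               class = "dcepref_rank_deficient")
})

test_that("mixed logit with zero spreads reproduces the MNL log-likelihood", {
  prefs <- true_preferences(beta_sd = 0.4)
  ch <- simulate_choices(study_design, prefs, 300, seed = 44)
  mnl <- fit_mnl(ch)

  # sigma = 0 at the MNL optimum: simulated likelihood must equal MNL's for
  # any number of draws, including R = 1
  cd <- dcepref:::build_coded_data(ch)
  theta <- c(unname(mnl$beta_mean), rep(0, 7), mnl$opt_out_constant)
  for (R in c(1L, 25L)) {
    H <- halton_sequence(cd$n_resp * R, 7, skip = 10)
    Z <- qnorm(H)
    Z_list <- lapply(seq_len(R), function(r) {
      Z[(seq_len(cd$n_resp) - 1L) * R + r, , drop = FALSE]
    })
    ll <- dcepref:::sml_ll_grad(theta, cd, Z_list, 1:7)$ll
    expect_equal(ll, mnl$log_likelihood, tolerance = 1e-6)
  }

  # no-random-coefficient spec collapses to MNL entirely
  degenerate <- fit_mixed_logit(ch, mixlogit_spec(random = character(0)))
  expect_equal(degenerate$log_likelihood, mnl$log_likelihood,
               tolerance = 1e-6)
})

test_that("simulated likelihood at truth beats a shifted parameter vector", {
  prefs <- true_preferences(beta_sd = 0.5)
  ch <- simulate_choices(study_design, prefs, 800, seed = 45)
  cd <- dcepref:::build_coded_data(ch)
  R <- 50L
  H <- halton_sequence(cd$n_resp * R, 7, skip = 10)
  Z <- qnorm(H)
  Z_list <- lapply(seq_len(R), function(r) {
    Z[(seq_len(cd$n_resp) - 1L) * R + r, , drop = FALSE]
  })
  truth <- c(unname(adsmart_beta_means()), rep(0.5, 7), -2)
  shifted <- truth + c(rep(1, 7), rep(0, 7), 0)
  ll_truth <- dcepref:::sml_ll_grad(truth, cd, Z_list, 1:7)$ll
  ll_shift <- dcepref:::sml_ll_grad(shifted, cd, Z_list, 1:7)$ll
  expect_gt(ll_truth, ll_shift)
})

test_that("analytic score matches numerical differentiation", {
  prefs <- true_preferences(beta_sd = 0.5)
  ch <- simulate_choices(study_design, prefs, 40, seed = 46)
  cd <- dcepref:::build_coded_data(ch)
  R <- 5L
  H <- halton_sequence(cd$n_resp * R, 7, skip = 10)
  Z <- qnorm(H)
  Z_list <- lapply(seq_len(R), function(r) {
    Z[(seq_len(cd$n_resp) - 1L) * R + r, , drop = FALSE]
  })
  th <- c(unname(adsmart_beta_means()) * 0.8, seq(0.1, 0.7, length.out = 7),
          -1.4)
  res <- dcepref:::sml_ll_grad(th, cd, Z_list, 1:7)
  num <- vapply(seq_along(th), function(j) {
    h <- 1e-6
    up <- th; up[j] <- up[j] + h
    dn <- th; dn[j] <- dn[j] - h
    (dcepref:::sml_ll_grad(up, cd, Z_list, 1:7)$ll -
       dcepref:::sml_ll_grad(dn, cd, Z_list, 1:7)$ll) / (2 * h)
  }, numeric(1))
  expect_equal(unname(res$grad), num, tolerance = 1e-6)
})

test_that("mixed logit recovers parameters when tasks are informative", {
  # every respondent answers all 12 tasks: spreads are well identified
  des <- generate_defficient_design(study_attrs, 12, 1, seed = 1)
  prefs <- true_preferences(beta_sd = 0.5)
  ch <- simulate_choices(des, prefs, 1500, seed = 47)
  fit <- suppressWarnings(
    fit_mixed_logit(ch, mixlogit_spec(n_draws = 100), std_errors = FALSE))
  expect_lt(max(abs(fit$beta_mean - adsmart_beta_means())), 0.2)
  expect_lt(max(abs(fit$beta_sd - 0.5)), 0.25)
  imp <- relative_importance(fit, study_attrs)
  expect_identical(imp$attribute,
                   c("severe", "mild", "evidence", "frequency", "monitoring"))
})

test_that("stability: degenerate cut equals the full fit", {
  prefs <- true_preferences(beta_sd = 0)
  ch <- simulate_choices(study_design, prefs, 200, seed = 48)
  full <- fit_mnl(ch)
  st <- stability_curve(ch, cut_points = 200L, engine = "mnl")
  expect_identical(nrow(st$changes), 0L)
  expect_equal(st$fits[[1]]$coefficients$estimate,
               full$coefficients$estimate, tolerance = 1e-8)
})

test_that("stability changes shrink on a homogeneous cohort", {
  # widely spaced cuts make the consistency decay visible above noise
  prefs <- true_preferences(beta_sd = 0)
  ch <- simulate_choices(study_design, prefs, 7500, seed = 49)
  st <- stability_curve(ch, cut_points = c(60L, 300L, 1500L, 7500L),
                        engine = "mnl")
  expect_identical(nrow(st$changes), 3L)
  expect_true(all(diff(st$changes$max_abs_change) < 0))
})

test_that("stability fits are invariant to row order", {
  prefs <- true_preferences(beta_sd = 0)
  ch <- simulate_choices(study_design, prefs, 300, seed = 50)
  shuffled <- ch[withr::with_seed(2, sample(nrow(ch))), ]
  a <- stability_curve(ch, c(150L, 300L), engine = "mnl")
  b <- stability_curve(shuffled, c(150L, 300L), engine = "mnl")
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-8)
})

test_that("stability cut points are validated", {
  prefs <- true_preferences(beta_sd = 0)
  ch <- simulate_choices(study_design, prefs, 50, seed = 51)
  expect_error(stability_curve(ch, c(10L, 60L), engine = "mnl"),
               class = "dcepref_invalid_spec")
  expect_error(stability_curve(ch, c(30L, 20L), engine = "mnl"),
               class = "dcepref_invalid_spec")
})

test_that("fit objects expose tidy and glance views", {
  prefs <- true_preferences(beta_sd = 0)
  ch <- simulate_choices(study_design, prefs, 150, seed = 52)
  fit <- fit_mnl(ch)
  td <- tidy(fit)
  expect_true(all(c("term", "type", "estimate", "std_error") %in% names(td)))
  expect_identical(nrow(td), 8L)  # 7 means + opt-out constant
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_lte(gl$log_likelihood, 0)
  expect_true(all(td$std_error[td$type != "sd"] > 0))
})
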