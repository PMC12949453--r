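# Random-utility simulator: the generative reading of the mixed logit model.
# Each respondent i draws coefficients beta_mean + beta_sd * z_i once (panel
# structure), then every alternative's utility is coded-profile x coefficients
# plus independent standard Gumbel noise; the argmax is recorded.

#' The four anonymized candidate drugs of the ranking task
#' @return Character vector of drug labels.
#' @export
adsmart_drugs <- function() {
  c("metformin", "atomoxetine", "isosorbide mononitrate", "levetiracetam")
}

#' True preference parameters for the simulator
#'
#' @param beta_mean Named numeric vector of mean part-worths, one per coded
#'   column (see [coding_scheme()]). Defaults to the published mixed-logit
#'   mean utilities of the five-attribute study instance.
#' @param beta_sd Nonnegative vector (recycled) of random-deviation spreads.
#' @param opt_out_constant Utility intercept of the "neither" alternative.
#'   Default -2: the opt-out is rarely chosen, as in a survey where most
#'   respondents pick one of the drugs.
#' @param drug_worths Named numeric vector of 4 latent worths for the
#'   ranking task. Defaults to the log of the published first-rank shares so
#'   the implied Plackett-Luce first-choice probabilities equal those shares.
#' @param coef_dist `"normal"` (default) or `"lognormal"` for
#'   sign-constrained coefficients (`beta_mean` then acts on the log scale).
#' @return A list of class `true_preferences`.
#' @export
true_preferences <- function(beta_mean = adsmart_beta_means(),
                             beta_sd = 0.5,
                             opt_out_constant = -2,
                             drug_worths = adsmart_drug_worths(),
                             coef_dist = c("normal", "lognormal")) {
  coef_dist <- match.arg(coef_dist)
  beta_sd <- rep_len(beta_sd, length(beta_mean))
  if (any(beta_sd < 0)) abort_dce("beta_sd must be nonnegative", "invalid_prefs")
  structure(
    list(beta_mean = beta_mean, beta_sd = beta_sd,
         opt_out_constant = opt_out_constant,
         drug_worths = drug_worths, coef_dist = coef_dist),
    class = "true_preferences"
  )
}

#' @rdname true_preferences
#' @export
adsmart_beta_means <- function() {
  c(frequency_divided_daily = -0.525,
    monitoring_not_required = -0.128,
    evidence_human_trials = 1.261,
    mild_uncommon = 1.037,
    mild_rare_or_very_rare = 1.311,
    severe_uncommon = 3.247,
    severe_rare_or_very_rare = 3.340)
}

#' @rdname true_preferences
#' @export
adsmart_drug_worths <- function() {
  # log of the published first-rank shares; softmax of these reproduces them
  log(c(metformin = 0.355, atomoxetine = 0.257,
        `isosorbide mononitrate` = 0.274, levetiracetam = 0.113))
}

draw_respondent_coefs <- function(prefs, n) {
  K <- length(prefs$beta_mean)
  z <- matrix(stats::rnorm(n * K), n, K)
  raw <- matrix(prefs$beta_mean, n, K, byrow = TRUE) +
    z * matrix(prefs$beta_sd, n, K, byrow = TRUE)
  if (prefs$coef_dist == "lognormal") raw <- exp(raw)
  colnames(raw) <- names(prefs$beta_mean)
  raw
}

rgumbel <- function(n) -log(-log(stats::runif(n)))

#' Simulate discrete choices from a design
#'
#' Respondents are assigned design blocks round-robin and answer every
#' non-attention task of their block (plus any attention-check rows present
#' in the design). Each respondent draws one coefficient vector
#' `beta_mean + beta_sd * z_i` reused across all their tasks; utilities are
#' coded profile times coefficients for A and B and `opt_out_constant` for
#' the "neither" alternative, each plus independent standard Gumbel noise,
#' and the maximiser is chosen.
#'
#' @param design A `dce_design` (see [generate_defficient_design()]).
#' @param prefs A [true_preferences()] object.
#' @param n_respondents Number of respondents.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param opt_out Include the "neither" alternative (default TRUE).
#' @param respondent_ids Optional integer ids (default `1:n`).
#' @return A tibble in long format: one row per respondent x task x
#'   alternative with `respondent_id`, `block`, `task_id`, `alternative`
#'   (`"A"`, `"B"`, `"opt_out"`), `chosen` (0/1), `opt_out` indicator and
#'   one dummy-coded column per non-reference level.
#' @export
simulate_choices <- function(design, prefs, n_respondents, seed = 1L,
                             opt_out = TRUE, respondent_ids = NULL) {
  attrs <- attr(design, "attrs")
  scheme <- coding_scheme(attrs)
  if (length(prefs$beta_mean) != nrow(scheme)) {
    abort_dce(sprintf("prefs has %d coefficients but coding has %d columns",
                      length(prefs$beta_mean), nrow(scheme)),
              "dimension_mismatch")
  }
  n_blocks <- max(1L, attr(design, "n_blocks") %||% 1L)
  core <- design[!design$is_attention, ]
  core_a <- core[core$alternative == "A", ]
  core_a <- core_a[order(core_a$task_id), ]
  core_b <- core[core$alternative == "B", ]
  core_b <- core_b[order(core_b$task_id), ]
  XA <- dummy_code(core_a, attrs)
  XB <- dummy_code(core_b, attrs)
  ids <- respondent_ids %||% seq_len(n_respondents)
  blocks <- ((seq_len(n_respondents) - 1L) %% n_blocks) + 1L

  # respondent x task grid (each respondent answers the tasks of their block)
  task_rows_by_block <- lapply(seq_len(n_blocks),
                               function(b) which(core_a$block == b))
  task_row <- unlist(task_rows_by_block[blocks])
  i_row <- rep(seq_len(n_respondents),
               lengths(task_rows_by_block)[blocks])
  n_alts <- 2L + opt_out
  alts <- c("A", "B", if (opt_out) "opt_out")

  choice <- withr::with_seed(seed, {
    coefs <- draw_respondent_coefs(prefs, n_respondents)
    va <- rowSums(XA[task_row, , drop = FALSE] * coefs[i_row, , drop = FALSE])
    vb <- rowSums(XB[task_row, , drop = FALSE] * coefs[i_row, , drop = FALSE])
    u <- cbind(va, vb, if (opt_out) rep(prefs$opt_out_constant, length(va))) +
      matrix(rgumbel(length(va) * n_alts), length(va))
    alts[max.col(u)]
  })

  obs <- tibble::tibble(
    respondent_id = rep(ids[i_row], each = n_alts),
    block = rep(blocks[i_row], each = n_alts),
    task_id = rep(core_a$task_id[task_row], each = n_alts),
    alternative = rep(alts, length(task_row)),
    chosen = as.integer(rep(alts, length(task_row)) ==
                          rep(choice, each = n_alts)),
    opt_out = as.integer(rep(alts, length(task_row)) == "opt_out"),
    is_attention = FALSE
  )
  coded <- matrix(0, nrow(obs), ncol(XA), dimnames = list(NULL, colnames(XA)))
  is_a <- obs$alternative == "A"
  is_b <- obs$alternative == "B"
  coded[is_a, ] <- XA[rep(task_row, each = n_alts)[is_a], , drop = FALSE]
  coded[is_b, ] <- XB[rep(task_row, each = n_alts)[is_b], , drop = FALSE]
  dplyr::bind_cols(obs, tibble::as_tibble(coded))
}

#' Simulate drug rankings under a random-utility (exploded logit) model
#'
#' Each respondent's utility for drug d is `drug_worths[d]` plus independent
#' standard Gumbel noise; the reported ranking is the descending sort of
#' utilities (the Plackett-Luce scheme).
#'
#' @param prefs A [true_preferences()] object (its `drug_worths` are used).
#' @param n_respondents Number of respondents.
#' @param seed Integer seed.
#' @param respondent_ids Optional integer ids.
#' @return A tibble with `respondent_id` and `rank1` ... `rank4` (drug
#'   labels, rank 1 = most preferred).
#' @export
simulate_rankings <- function(prefs, n_respondents, seed = 1L,
                              respondent_ids = NULL) {
  worths <- prefs$drug_worths
  if (length(worths) != 4) abort_dce("drug_worths must have 4 entries", "invalid_prefs")
  drugs <- names(worths)
  ids <- respondent_ids %||% seq_len(n_respondents)
  ranks <- withr::with_seed(seed, {
    u <- matrix(worths, n_respondents, 4, byrow = TRUE) +
      matrix(rgumbel(n_respondents * 4), n_respondents, 4)
    t(apply(u, 1, function(r) drugs[order(r, decreasing = TRUE)]))
  })
  tibble::tibble(
    respondent_id = ids,
    rank1 = ranks[, 1], rank2 = ranks[, 2],
    rank3 = ranks[, 3], rank4 = ranks[, 4]
  )
}

#' Cohort configuration for the synthetic survey
#'
#' Default demographic margins mirror the published respondent table
#' (N = 3251): age bands, gender and dementia-experience categories are
#' sampled independently from those margins. Preferences may vary by
#' stratum: `stratum_prefs` maps age-65-by-gender stratum labels
#' (`"female_under65"`, `"female_65plus"`, `"male_under65"`,
#' `"male_65plus"`, `"other"`) to [true_preferences()] overrides; unlisted
#' strata use `base_prefs`.
#'
#' @param n_respondents Cohort size (default 3250, the study's headline n).
#' @param age_probs,gender_probs,experience_probs Named probability vectors
#'   (must each sum to 1 within 1e-9).
#' @param base_prefs A [true_preferences()] object.
#' @param stratum_prefs Optional named list of [true_preferences()].
#' @param attention_pass_prob Probability a respondent passes the attention
#'   check (default 1).
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_respondents = 3250L,
                          age_probs = adsmart_age_probs(),
                          gender_probs = adsmart_gender_probs(),
                          experience_probs = adsmart_experience_probs(),
                          base_prefs = true_preferences(),
                          stratum_prefs = NULL,
                          attention_pass_prob = 1,
                          seed = 1L) {
  for (p in list(age_probs, gender_probs, experience_probs)) {
    if (abs(sum(p) - 1) > 1e-9) {
      abort_dce("stratum proportions must sum to 1 (tolerance 1e-9)",
                "invalid_config")
    }
  }
  structure(
    list(n_respondents = as.integer(n_respondents), age_probs = age_probs,
         gender_probs = gender_probs, experience_probs = experience_probs,
         base_prefs = base_prefs, stratum_prefs = stratum_prefs,
         attention_pass_prob = attention_pass_prob, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
adsmart_age_probs <- function() {
  c(`18-24` = 175, `25-34` = 283, `35-44` = 171, `45-54` = 306,
    `55-64` = 808, `65-74` = 1017, `75-84` = 453, `85+` = 38) / 3251
}

#' @rdname cohort_config
#' @export
adsmart_gender_probs <- function() {
  c(female = 2209, male = 1018, another = 14, prefer_not = 10) / 3251
}

#' @rdname cohort_config
#' @export
adsmart_experience_probs <- function() {
  c(friend_family = 1507, carer = 544, work = 182, have_dementia = 90,
    none = 883, prefer_not = 45) / 3251
}

#' Age-65-by-gender stratum label for a respondent
#'
#' `"other"` collects the "another gender" / "prefer not to answer"
#' categories, which the age-by-gender stratifier excludes.
#'
#' @param age_band Age band label (bands at 55-64 and below are under 65).
#' @param gender Gender category.
#' @return Character vector of stratum labels.
#' @export
age65_gender_stratum <- function(age_band, gender) {
  under <- age_band %in% c("18-24", "25-34", "35-44", "45-54", "55-64")
  ifelse(gender %in% c("female", "male"),
         paste0(gender, ifelse(under, "_under65", "_65plus")),
         "other")
}

#' Simulate a full synthetic survey cohort
#'
#' Draws demographics from the configured margins, assigns each respondent
#' their stratum's preferences, and emits choices (including an
#' attention-check response), rankings and respondent records.
#'
#' @param config A [cohort_config()].
#' @param design A `dce_design`; default is the 12-task, 4-block study
#'   design generated from [adsmart_attributes()].
#' @return A list with tibbles `respondents` (`respondent_id`, `age_band`,
#'   `gender`, `experience`, `stratum`, `block`, `attention_passed`),
#'   `choices` (long format, attention task included with
#'   `is_attention = TRUE`) and `rankings`.
#' @export
simulate_cohort <- function(config, design = NULL) {
  if (!inherits(config, "cohort_config")) {
    abort_dce("config must be a cohort_config", "invalid_config")
  }
  if (is.null(design)) {
    design <- generate_defficient_design(adsmart_attributes(), 12L, 4L,
                                         seed = config$seed)
  }
  attrs <- attr(design, "attrs")
  n <- config$n_respondents
  n_blocks <- max(1L, attr(design, "n_blocks") %||% 1L)

  demo <- withr::with_seed(config$seed, {
    tibble::tibble(
      respondent_id = seq_len(n),
      age_band = sample(names(config$age_probs), n, TRUE, config$age_probs),
      gender = sample(names(config$gender_probs), n, TRUE, config$gender_probs),
      experience = sample(names(config$experience_probs), n, TRUE,
                          config$experience_probs),
      attention_passed = stats::runif(n) <= config$attention_pass_prob
    )
  })
  demo$stratum <- age65_gender_stratum(demo$age_band, demo$gender)
  demo$block <- ((demo$respondent_id - 1L) %% n_blocks) + 1L

  prefs_for <- function(s) config$stratum_prefs[[s]] %||% config$base_prefs
  strata <- unique(demo$stratum)
  choices <- dplyr::bind_rows(lapply(seq_along(strata), function(k) {
    idx <- which(demo$stratum == strata[k])
    simulate_choices(design, prefs_for(strata[k]), length(idx),
                     seed = config$seed + 1000L + k,
                     respondent_ids = demo$respondent_id[idx])
  }))
  # simulate_choices assigns blocks round-robin over its own ids; reattach
  # the cohort-level block assignment
  choices$block <- demo$block[match(choices$respondent_id, demo$respondent_id)]

  rankings <- dplyr::bind_rows(lapply(seq_along(strata), function(k) {
    idx <- which(demo$stratum == strata[k])
    simulate_rankings(prefs_for(strata[k]), length(idx),
                      seed = config$seed + 2000L + k,
                      respondent_ids = demo$respondent_id[idx])
  }))

  check <- make_attention_check(attrs, seed = config$seed)
  check_coded <- dummy_code(check, attrs)
  chosen_alt <- ifelse(demo$attention_passed, "A", "B")
  check_rows <- tibble::tibble(
    respondent_id = rep(demo$respondent_id, each = 2),
    block = rep(demo$block, each = 2),
    task_id = check$task_id[1],
    alternative = rep(c("A", "B"), n),
    chosen = as.integer(rep(c("A", "B"), n) == rep(chosen_alt, each = 2)),
    opt_out = 0L, is_attention = TRUE
  ) |>
    dplyr::bind_cols(tibble::as_tibble(
      check_coded[rep(1:2, n), , drop = FALSE]
    ))
  choices <- dplyr::bind_rows(choices, check_rows) |>
    dplyr::arrange(.data$respondent_id, .data$task_id, .data$alternative)

  list(
    respondents = demo[, c("respondent_id", "age_band", "gender",
                           "experience", "stratum", "block",
                           "attention_passed")],
    choices = choices,
    rankings = dplyr::arrange(rankings, .data$respondent_id),
    design = design
  )
}

#' Filter respondents by attention-check outcome
#'
#' @param respondents Respondent tibble with `attention_passed`.
#' @param choices Long-format choice tibble.
#' @param policy `"exclude-fail"` drops every record of respondents who
#'   failed the check; `"keep-all"` is the identity.
#' @return A list with filtered `respondents`, `choices` and `n_removed`.
#' @export
apply_attention_filter <- function(respondents, choices,
                                   policy = c("exclude-fail", "keep-all")) {
  policy <- match.arg(policy)
  if (is.null(respondents$attention_passed)) {
    abort_dce("respondents lack an attention_passed column", "invalid_config")
  }
  if (policy == "keep-all") {
    return(list(respondents = respondents, choices = choices, n_removed = 0L))
  }
  keep <- respondents$respondent_id[respondents$attention_passed]
  list(
    respondents = respondents[respondents$respondent_id %in% keep, ],
    choices = choices[choices$respondent_id %in% keep, ],
    n_removed = sum(!respondents$attention_passed)
  )
}
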