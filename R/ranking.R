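# Rank tabulation and the Borda-style weighted preference score
# (rank 1 = 4 points, rank 2 = 3, rank 3 = 2, rank 4 = 1).

rank_long <- function(rankings) {
  long <- tidyr::pivot_longer(rankings, dplyr::starts_with("rank"),
                              names_to = "position", values_to = "drug")
  long$position <- as.integer(sub("rank", "", long$position))
  long
}

#' Tabulate rank frequencies
#'
#' Counts, per drug, how often it was ranked 1st through 4th. Every record
#' must be a strict permutation of the same four drug labels.
#'
#' @param rankings Tibble with `respondent_id` and `rank1` ... `rank4`
#'   (drug labels), as produced by [simulate_rankings()].
#' @return A tibble with one row per drug: `drug`, `eta1` ... `eta4`
#'   (counts at each position) and `n_total`.
#' @export
tabulate_ranks <- function(rankings) {
  long <- rank_long(rankings)
  drugs <- sort(unique(long$drug))
  if (length(drugs) != 4) {
    abort_dce(sprintf("expected 4 distinct drug labels, found %d",
                      length(drugs)), "invalid_ranking")
  }
  per_resp <- tapply(long$drug, long$respondent_id,
                     function(d) anyDuplicated(d) > 0 || length(d) != 4)
  if (any(per_resp)) {
    abort_dce(paste("invalid ranking record(s) for respondent:",
                    paste(names(per_resp)[per_resp], collapse = ", ")),
              "invalid_ranking")
  }
  n <- nrow(rankings)
  counts <- table(factor(long$drug, levels = drugs), long$position)
  tibble::tibble(
    drug = drugs,
    eta1 = as.integer(counts[, "1"]), eta2 = as.integer(counts[, "2"]),
    eta3 = as.integer(counts[, "3"]), eta4 = as.integer(counts[, "4"]),
    n_total = n
  )
}

#' Weighted preference scores from rank tallies
#'
#' Applies the published scoring scheme: weighted score =
#' 4*eta1 + 3*eta2 + 2*eta3 + 1*eta4, where eta1..eta4 are the counts of
#' times a drug was ranked 1st through 4th. Also reports the percentage of
#' respondents placing the drug at each position (half-up, 1 decimal).
#'
#' @param tallies Output of [tabulate_ranks()], or a rankings tibble (which
#'   is tabulated first).
#' @return The tally tibble with `weighted_score` and `pct_rank1` ...
#'   `pct_rank4` columns, sorted by decreasing score.
#' @export
#' @examples
#' r <- simulate_rankings(true_preferences(), 200, seed = 7)
#' weighted_scores(r)
weighted_scores <- function(tallies) {
  if (!all(c("eta1", "eta2", "eta3", "eta4") %in% names(tallies))) {
    tallies <- tabulate_ranks(tallies)
  }
  eta <- as.matrix(tallies[, c("eta1", "eta2", "eta3", "eta4")])
  if (any(eta < 0)) abort_dce("negative rank counts", "invalid_ranking")
  tallies$weighted_score <- as.integer(eta %*% c(4, 3, 2, 1))
  for (k in 1:4) {
    tallies[[paste0("pct_rank", k)]] <-
      round_half_up(100 * eta[, k] / tallies$n_total, 1)
  }
  dplyr::arrange(tallies, dplyr::desc(.data$weighted_score))
}

#' Weighted-score tables by demographic subgroup
#'
#' Stratifies rankings by either age-65-by-gender (four strata: female and
#' male crossed with under/over 65; "another gender" and "prefer not to
#' answer" respondents are excluded from this stratifier) or by the four
#' dementia-experience roles (carer, person with dementia, friend/family,
#' dementia-related work; "none" and "prefer not" are excluded).
#'
#' @param rankings Rankings tibble (`respondent_id`, `rank1`..`rank4`).
#' @param respondents Respondent tibble with `age_band`, `gender`,
#'   `experience`.
#' @param stratifier `"age65_gender"` or `"experience"`.
#' @return A tibble of per-stratum weighted score tables with a `stratum`
#'   column.
#' @export
subgroup_rank_summary <- function(rankings, respondents,
                                  stratifier = c("age65_gender",
                                                 "experience")) {
  stratifier <- match.arg(stratifier)
  unmatched <- setdiff(rankings$respondent_id, respondents$respondent_id)
  if (length(unmatched)) {
    abort_dce(paste("rankings reference unknown respondent id(s):",
                    paste(utils::head(unmatched, 10), collapse = ", ")),
              "join_error")
  }
  resp <- add_stratum(respondents, stratifier)
  joined <- dplyr::inner_join(rankings, resp[, c("respondent_id", "stratum")],
                              by = "respondent_id")
  joined <- joined[!is.na(joined$stratum), ]
  joined |>
    dplyr::group_by(.data$stratum) |>
    dplyr::group_modify(~ weighted_scores(tabulate_ranks(.x))) |>
    dplyr::ungroup()
}

# Attach the stratum column used by both the ranking and the model-based
# subgroup analyses.
add_stratum <- function(respondents, stratifier) {
  if (stratifier == "age65_gender") {
    s <- age65_gender_stratum(respondents$age_band, respondents$gender)
    s[s == "other"] <- NA_character_
  } else {
    keep <- c("carer", "have_dementia", "friend_family", "work")
    s <- ifelse(respondents$experience %in% keep, respondents$experience,
                NA_character_)
  }
  respondents$stratum <- s
  respondents
}
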