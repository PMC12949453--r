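# Attribute relative importance from the range of level coefficients, and
# between-subgroup z tests on separately fitted models.

#' Relative importance of attributes from coefficient ranges
#'
#' For each attribute the range is the spread of its estimated level
#' coefficients including the implicit 0 of the reference level
#' (`max(0, coefs) - min(0, coefs)`); the importance share is the
#' attribute's range divided by the sum of ranges over all attributes,
#' in percent. Ranges use the mean coefficients only, not random-deviation
#' spreads, and are invariant to rescaling all coefficients by a positive
#' constant.
#'
#' @param fit A `mixlogit_fit`, or a named numeric vector / data frame
#'   (`term`, `estimate`) of mean coefficients named per [coding_scheme()].
#' @param attrs The [dce_attributes()] set mapping coefficients to
#'   attributes.
#' @return A tibble with one row per attribute: `attribute`, `range`,
#'   `share` (exact percent) and `share_pct` (rounded half-up to 2
#'   decimals), sorted by decreasing share.
#' @export
#' @examples
#' relative_importance(adsmart_beta_means(), adsmart_attributes())
relative_importance <- function(fit, attrs) {
  attrs <- validate_attributes(attrs)
  est <- extract_means(fit)
  scheme <- coding_scheme(attrs)
  missing_terms <- setdiff(scheme$term, names(est))
  if (length(missing_terms)) {
    abort_dce(paste("no coefficient for coded column(s):",
                    paste(missing_terms, collapse = ", ")),
              "missing_coefficient")
  }
  ranges <- vapply(attrs$name, function(a) {
    co <- est[scheme$term[scheme$attribute == a]]
    max(0, co) - min(0, co)   # reference level contributes 0
  }, numeric(1))
  share <- 100 * ranges / sum(ranges)
  tibble::tibble(
    attribute = attrs$name,
    range = unname(ranges),
    share = unname(share),
    share_pct = round_half_up(unname(share), 2)
  ) |>
    dplyr::arrange(dplyr::desc(.data$share))
}

extract_means <- function(fit) {
  if (inherits(fit, "mixlogit_fit")) {
    if (!fit$converged) {
      warning("relative importance computed from a non-converged fit",
              call. = FALSE)
    }
    return(fit$beta_mean)
  }
  if (is.data.frame(fit)) {
    return(stats::setNames(fit$estimate, fit$term))
  }
  if (is.numeric(fit) && !is.null(names(fit))) return(fit)
  abort_dce("fit must be a mixlogit_fit, a named vector, or a term/estimate data frame",
            "invalid_spec")
}

#' Fit the choice model separately within demographic strata
#'
#' Splits respondents by the age-65-by-gender or dementia-experience
#' stratifier (same definitions as [subgroup_rank_summary()]) and fits an
#' independent model per stratum. Strata below `min_size` respondents are
#' still fitted but flagged `exploratory`, mirroring the treatment of small
#' subgroups in underpowered preference surveys.
#'
#' @param data Long-format choice tibble.
#' @param respondents Respondent tibble with demographics.
#' @param stratifier `"age65_gender"` or `"experience"`.
#' @param spec A [mixlogit_spec()] (for `engine = "mixed"`).
#' @param engine `"mixed"` (default) or `"mnl"`.
#' @param min_size Minimum stratum size before the `exploratory` flag is
#'   raised (default 50).
#' @param terms Coded columns to use.
#' @return A tibble with one row per stratum: `stratum`, `n_respondents`,
#'   `exploratory`, and a `fit` list column of `mixlogit_fit` objects.
#' @export
stratify_and_fit <- function(data, respondents,
                             stratifier = c("age65_gender", "experience"),
                             spec = mixlogit_spec(),
                             engine = c("mixed", "mnl"),
                             min_size = 50L, terms = NULL) {
  stratifier <- match.arg(stratifier)
  engine <- match.arg(engine)
  resp <- add_stratum(respondents, stratifier)
  resp <- resp[!is.na(resp$stratum), ]
  strata <- sort(unique(resp$stratum))
  rows <- lapply(strata, function(s) {
    ids <- resp$respondent_id[resp$stratum == s]
    sub <- data[data$respondent_id %in% ids, ]
    if (nrow(sub) == 0) {
      warning(sprintf("stratum '%s' has no choice data; skipped", s),
              call. = FALSE)
      return(NULL)
    }
    fit <- tryCatch(
      if (engine == "mnl") fit_mnl(sub, terms = terms)
      else fit_mixed_logit(sub, spec, terms = terms),
      error = function(e) {
        warning(sprintf("stratum '%s' could not be fitted (%s); skipped",
                        s, conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(fit)) return(NULL)
    tibble::tibble(
      stratum = s, n_respondents = length(ids),
      exploratory = length(ids) < min_size, fit = list(fit)
    )
  })
  dplyr::bind_rows(rows)
}

#' Compare a coefficient between two independently fitted groups
#'
#' Two-sided z test on separately estimated models:
#' `z = (b_a - b_b) / sqrt(se_a^2 + se_b^2)`, with significance stars at
#' 0.05 / 0.01 / 0.001. Unadjusted by default; `adjust = "bonferroni"`
#' multiplies p by `n_comparisons`.
#'
#' @param fit_a,fit_b `mixlogit_fit` objects for the two groups.
#' @param term Coefficient name present in both fits (mean coefficients are
#'   compared).
#' @param labels Length-2 character vector of group labels.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @param n_comparisons Number of tests for the Bonferroni adjustment.
#' @return A one-row tibble: `term`, `group_a`, `group_b`, `estimate_a`,
#'   `estimate_b`, `se_a`, `se_b`, `z`, `p_value`, `stars`.
#' @export
compare_groups <- function(fit_a, fit_b, term,
                           labels = c("a", "b"),
                           adjust = c("none", "bonferroni"),
                           n_comparisons = 1L) {
  adjust <- match.arg(adjust)
  pick <- function(fit, which_group) {
    co <- fit$coefficients
    row <- co[co$term == term & co$type == "mean", ]
    if (nrow(row) != 1) {
      abort_dce(sprintf("coefficient '%s' not found in group %s fit",
                        term, which_group), "missing_coefficient")
    }
    if (is.na(row$std_error)) {
      abort_dce(sprintf("group %s fit has no standard error for '%s'",
                        which_group, term), "missing_se")
    }
    row
  }
  a <- pick(fit_a, labels[1])
  b <- pick(fit_b, labels[2])
  z <- (a$estimate - b$estimate) / sqrt(a$std_error^2 + b$std_error^2)
  p <- 2 * stats::pnorm(-abs(z))
  if (adjust == "bonferroni") p <- min(1, p * n_comparisons)
  tibble::tibble(
    term = term, group_a = labels[1], group_b = labels[2],
    estimate_a = a$estimate, estimate_b = b$estimate,
    se_a = a$std_error, se_b = b$std_error,
    z = z, p_value = p, stars = p_stars(p)
  )
}

p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}

#' All pairwise subgroup comparisons for a set of coefficients
#'
#' @param strata_fits Output of [stratify_and_fit()].
#' @param terms Coefficients to compare (default: all mean coefficients of
#'   the first fit).
#' @inheritParams compare_groups
#' @return A tibble of [compare_groups()] rows for every stratum pair and
#'   term.
#' @export
compare_all_groups <- function(strata_fits, terms = NULL,
                               adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  fits <- strata_fits$fit
  names(fits) <- strata_fits$stratum
  terms <- terms %||% names(fits[[1]]$beta_mean)
  pairs <- utils::combn(names(fits), 2, simplify = FALSE)
  n_comp <- length(pairs) * length(terms)
  dplyr::bind_rows(lapply(pairs, function(pr) {
    dplyr::bind_rows(lapply(terms, function(tm) {
      tryCatch(
        compare_groups(fits[[pr[1]]], fits[[pr[2]]], tm, labels = pr,
                       adjust = adjust, n_comparisons = n_comp),
        dcepref_missing_se = function(e) {
          warning(sprintf("comparison %s vs %s for '%s' skipped: %s",
                          pr[1], pr[2], tm, conditionMessage(e)),
                  call. = FALSE)
          NULL
        })
    }))
  }))
}
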