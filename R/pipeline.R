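# End-to-end workflow: design -> simulate (or load) -> attention filter ->
# rank summaries -> mixed logit -> importance -> subgroups -> stability,
# with every artifact written as seeded, hashed delimited text.

#' Configuration of a full pipeline run
#'
#' @param attrs A [dce_attributes()] set (default the five-attribute study
#'   instance).
#' @param n_tasks,n_blocks Design size (default 12 tasks in 4 blocks).
#' @param design_seed Seed for the design search.
#' @param prior Prior coefficient vector for the D-error (default zero).
#' @param cohort A [cohort_config()] describing the synthetic cohort; ignored
#'   when `input_files` is supplied.
#' @param input_files Optional named list with paths `respondents`,
#'   `choices`, `rankings` of real-format data to load instead of
#'   simulating.
#' @param spec A [mixlogit_spec()] for estimation.
#' @param engine `"mixed"` or `"mnl"` for the fits.
#' @param attention_policy `"exclude-fail"` or `"keep-all"`.
#' @param stratifiers Subgroup stratifiers to run (subset of
#'   `"age65_gender"`, `"experience"`).
#' @param stability_cuts Prefix sizes for the stability check; entries above
#'   the respondent count are truncated and the full sample is always
#'   included.
#' @param out_dir Output directory for artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(attrs = adsmart_attributes(),
                       n_tasks = 12L, n_blocks = 4L, design_seed = 1L,
                       prior = NULL,
                       cohort = cohort_config(),
                       input_files = NULL,
                       spec = mixlogit_spec(),
                       engine = c("mixed", "mnl"),
                       attention_policy = c("exclude-fail", "keep-all"),
                       stratifiers = c("age65_gender", "experience"),
                       stability_cuts = c(500L, 1000L, 1500L),
                       out_dir = tempfile("dcepref_run_")) {
  engine <- match.arg(engine)
  attention_policy <- match.arg(attention_policy)
  stratifiers <- match.arg(stratifiers, several.ok = TRUE)
  if (!is.null(input_files)) {
    missing_files <- unlist(input_files)[!file.exists(unlist(input_files))]
    if (length(missing_files)) {
      abort_dce(paste("input file(s) not found:",
                      paste(missing_files, collapse = ", ")), "invalid_config")
    }
  }
  structure(
    list(attrs = validate_attributes(attrs), n_tasks = as.integer(n_tasks),
         n_blocks = as.integer(n_blocks), design_seed = as.integer(design_seed),
         prior = prior, cohort = cohort, input_files = input_files,
         spec = spec, engine = engine, attention_policy = attention_policy,
         stratifiers = stratifiers,
         stability_cuts = as.integer(stability_cuts), out_dir = out_dir),
    class = "run_config"
  )
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s",
                         stage, conditionMessage(e)),
                 class = "dcepref_stage_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Executes design construction, cohort simulation (or loading of supplied
#' files), the attention filter, ranking summaries, the mixed logit fit,
#' relative importance, subgroup fits and comparisons, and the subsample
#' stability check, writing each artifact plus a JSON manifest to
#' `config$out_dir`. A rerun with the same configuration reproduces the
#' outputs byte for byte.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages on stderr.
#' @return Invisibly, a list with every intermediate object and the paths of
#'   the written artifacts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) {
    abort_dce("config must be a run_config", "invalid_config")
  }
  hash <- config_hash(config)
  seed <- config$cohort$seed
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[dcepref] ", fmt), ...))
  }
  t0 <- Sys.time()
  stage_time <- function(what) {
    say("%s (%.1fs elapsed)", what, as.numeric(Sys.time() - t0, units = "secs"))
  }

  design <- run_stage("design", generate_defficient_design(
    config$attrs, config$n_tasks, config$n_blocks,
    prior = config$prior, seed = config$design_seed))
  stage_time("design")

  if (is.null(config$input_files)) {
    cohort <- run_stage("simulate", simulate_cohort(config$cohort, design))
    respondents <- cohort$respondents
    choices <- cohort$choices
    rankings <- cohort$rankings
  } else {
    respondents <- run_stage("load", read_respondent_file(config$input_files$respondents))
    choices <- run_stage("load", read_choice_file(config$input_files$choices))
    rankings <- run_stage("load", read_ranking_file(config$input_files$rankings))
  }
  stage_time("data")

  filtered <- run_stage("attention_filter", apply_attention_filter(
    respondents, choices, config$attention_policy))
  # listwise exclusion: rankings follow the filtered respondent set
  rankings_f <- rankings[rankings$respondent_id %in%
                           filtered$respondents$respondent_id, ]

  rank_overall <- run_stage("rank", weighted_scores(tabulate_ranks(rankings_f)))
  rank_sub <- lapply(config$stratifiers, function(s) {
    run_stage("rank", subgroup_rank_summary(rankings_f,
                                            filtered$respondents, s))
  })
  names(rank_sub) <- config$stratifiers
  stage_time("rank summaries")

  est_data <- filtered$choices[!filtered$choices$is_attention, ]
  fit <- run_stage("fit", if (config$engine == "mnl") fit_mnl(est_data)
                   else fit_mixed_logit(est_data, config$spec))
  stage_time("model fit")

  importance <- run_stage("importance", relative_importance(fit, config$attrs))

  subgroups <- lapply(config$stratifiers, function(s) {
    fits <- run_stage("subgroups", stratify_and_fit(
      est_data, filtered$respondents, s, spec = config$spec,
      engine = config$engine))
    list(fits = fits,
         comparisons = run_stage("subgroups", compare_all_groups(fits)))
  })
  names(subgroups) <- config$stratifiers
  stage_time("subgroups")

  n_resp <- length(unique(est_data$respondent_id))
  cuts <- sort(unique(c(config$stability_cuts[config$stability_cuts < n_resp],
                        n_resp)))
  stability <- run_stage("stability", stability_curve(
    est_data, cuts, spec = config$spec, engine = config$engine))
  stage_time("stability")

  w <- function(tbl, name, kind) {
    write_dce_table(tbl, file.path(config$out_dir, name), kind, seed, hash)
  }
  paths <- c(
    design = write_design(design, file.path(config$out_dir, "design.csv")),
    respondents = w(filtered$respondents, "respondents.csv", "respondents"),
    choices = w(filtered$choices, "choices.csv", "choices"),
    rankings = w(rankings_f, "rankings.csv", "rankings"),
    rank_summary = w(dplyr::bind_rows(
      c(list(dplyr::mutate(rank_overall, stratum = "overall", .before = 1)),
        unname(rank_sub))), "rank_summary.csv", "rank_summary"),
    fit = w(fit$coefficients, "fit_coefficients.csv", "fit"),
    importance = w(importance, "importance.csv", "importance"),
    subgroup_comparisons = w(dplyr::bind_rows(
      lapply(names(subgroups), function(s) {
        dplyr::mutate(subgroups[[s]]$comparisons, stratifier = s, .before = 1)
      })), "subgroup_comparisons.csv", "subgroup_comparisons"),
    stability = w(stability$coefficients, "stability.csv", "stability")
  )

  manifest <- list(
    config_hash = hash,
    seeds = list(design = config$design_seed, cohort = seed,
                 estimation = config$spec$seed),
    package_version = as.character(utils::packageVersion("dcepref")),
    d_error = attr(design, "d_error"),
    n_respondents = nrow(filtered$respondents),
    n_removed_attention = filtered$n_removed,
    log_likelihood = fit$log_likelihood,
    converged = fit$converged,
    artifacts = as.list(basename(paths))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  stage_time("artifacts written")

  invisible(list(
    design = design, respondents = filtered$respondents,
    choices = filtered$choices, rankings = rankings_f,
    rank_overall = rank_overall, rank_subgroups = rank_sub,
    fit = fit, importance = importance, subgroups = subgroups,
    stability = stability, manifest = manifest,
    paths = c(paths, manifest = manifest_path)
  ))
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognised keys: `n_respondents`, `n_tasks`, `n_blocks`, `seed`,
#' `n_draws`, `engine`, `attention_policy`, `attention_pass_prob`,
#' `stratifiers`, `stability_cuts`, `out_dir`, and `attributes` (path to a
#' YAML attribute spec, see [read_attribute_spec()]).
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  attrs <- if (!is.null(y$attributes)) read_attribute_spec(y$attributes)
           else adsmart_attributes()
  seed <- as.integer(y$seed %||% 1L)
  run_config(
    attrs = attrs,
    n_tasks = y$n_tasks %||% 12L,
    n_blocks = y$n_blocks %||% 4L,
    design_seed = seed,
    cohort = cohort_config(
      n_respondents = y$n_respondents %||% 3250L,
      attention_pass_prob = y$attention_pass_prob %||% 1,
      seed = seed
    ),
    spec = mixlogit_spec(n_draws = y$n_draws %||% 500L, seed = seed),
    engine = y$engine %||% "mixed",
    attention_policy = y$attention_policy %||% "exclude-fail",
    stratifiers = unlist(y$stratifiers) %||% c("age65_gender", "experience"),
    stability_cuts = unlist(y$stability_cuts) %||% c(500L, 1000L, 1500L),
    out_dir = y$out_dir %||% "dcepref_out"
  )
}

#' Command-line entry point
#'
#' Thin dispatcher used by the `inst/cli/dcepref.R` script. Subcommands:
#' `run-all` (full pipeline), `design`, `simulate`, `validate`, `rank`,
#' `fit`, `importance`, `subgroups`, `stability`. All take
#' `--config <yaml>`; stage subcommands read their inputs from, and write
#' their outputs to, the configured `out_dir`.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the result of the dispatched stage.
#' @export
dcepref_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dcepref.R <run-all|design|simulate|validate|rank|fit|importance|subgroups|stability>",
    "--config <config.yaml> [--quiet]")
  if (length(args) < 1) {
    message(usage)
    return(invisible(NULL))
  }
  cmd <- args[1]
  quiet <- "--quiet" %in% args
  cfg_i <- which(args == "--config")
  cfg_path <- if (length(cfg_i)) args[cfg_i + 1] else NULL
  if (is.null(cfg_path)) {
    message(usage)
    abort_dce("--config is required", "invalid_config")
  }
  config <- load_run_config(cfg_path)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  out <- function(name) file.path(config$out_dir, name)

  result <- switch(
    cmd,
    "run-all" = run_pipeline(config, quiet = quiet),
    "design" = {
      d <- generate_defficient_design(config$attrs, config$n_tasks,
                                      config$n_blocks, prior = config$prior,
                                      seed = config$design_seed)
      write_design(d, out("design.csv"))
      d
    },
    "simulate" = {
      d <- read_design(out("design.csv"), config$attrs)
      co <- simulate_cohort(config$cohort, d)
      write_respondent_file(co$respondents, out("respondents.csv"),
                            config$cohort$seed, hash)
      write_choice_file(co$choices, out("choices.csv"),
                        config$cohort$seed, hash)
      write_ranking_file(co$rankings, out("rankings.csv"),
                         config$cohort$seed, hash)
      co
    },
    "validate" = {
      v <- validate_choice_file(out("choices.csv"), config$attrs,
                                read_respondent_file(out("respondents.csv")))
      if (nrow(v) == 0) message("choices.csv: valid")
      else print(v, n = nrow(v))
      v
    },
    "rank" = {
      r <- read_ranking_file(out("rankings.csv"))
      tbl <- weighted_scores(tabulate_ranks(r))
      write_dce_table(tbl, out("rank_summary.csv"), "rank_summary",
                      config$cohort$seed, hash)
      tbl
    },
    "fit" = {
      ch <- read_choice_file(out("choices.csv"))
      ch <- ch[!ch$is_attention, ]
      f <- if (config$engine == "mnl") fit_mnl(ch)
           else fit_mixed_logit(ch, config$spec)
      write_dce_table(f$coefficients, out("fit_coefficients.csv"), "fit",
                      config$spec$seed, hash)
      f
    },
    "importance" = {
      co <- read_dce_table(out("fit_coefficients.csv"))
      imp <- relative_importance(co[co$type == "mean", ], config$attrs)
      write_dce_table(imp, out("importance.csv"), "importance",
                      config$spec$seed, hash)
      imp
    },
    "subgroups" = {
      ch <- read_choice_file(out("choices.csv"))
      ch <- ch[!ch$is_attention, ]
      resp <- read_respondent_file(out("respondents.csv"))
      cmp <- dplyr::bind_rows(lapply(config$stratifiers, function(s) {
        fits <- stratify_and_fit(ch, resp, s, spec = config$spec,
                                 engine = config$engine)
        dplyr::mutate(compare_all_groups(fits), stratifier = s, .before = 1)
      }))
      write_dce_table(cmp, out("subgroup_comparisons.csv"),
                      "subgroup_comparisons", config$spec$seed, hash)
      cmp
    },
    "stability" = {
      ch <- read_choice_file(out("choices.csv"))
      ch <- ch[!ch$is_attention, ]
      n_resp <- length(unique(ch$respondent_id))
      cuts <- sort(unique(c(config$stability_cuts[config$stability_cuts <
                                                    n_resp], n_resp)))
      st <- stability_curve(ch, cuts, spec = config$spec,
                            engine = config$engine)
      write_dce_table(st$coefficients, out("stability.csv"), "stability",
                      config$spec$seed, hash)
      st
    },
    {
      message(usage)
      abort_dce(sprintf("unknown subcommand '%s'", cmd), "invalid_config")
    }
  )
  invisible(result)
}
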