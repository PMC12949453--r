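# Delimited-text readers and writers for the survey tables. Every emitted
# file starts with a single `#` comment header recording the kind of table,
# the seed and the configuration hash, so any artifact can be traced back to
# the run that produced it.

dce_header <- function(kind, seed = NA, config_hash = NA) {
  sprintf("# dcepref %s | seed: %s | config_hash: %s | package: %s",
          kind, seed, config_hash, as.character(utils::packageVersion("dcepref")))
}

write_dce_table <- function(tbl, path, kind, seed = NA, config_hash = NA) {
  writeLines(dce_header(kind, seed, config_hash), path)
  readr::write_csv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_dce_table <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read and write the survey tables as delimited text
#'
#' Choices are long format (one row per respondent x task x alternative
#' with `respondent_id`, `block`, `task_id`, `alternative`, `chosen`,
#' `opt_out`, `is_attention` and the dummy-coded level columns); rankings
#' are one row per respondent (`respondent_id`, `rank1` ... `rank4`);
#' respondents carry the demographics. Files begin with a `#` comment
#' header (seed, config hash) which readers skip.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @param seed,config_hash Optional provenance recorded in the header.
#' @return Writers return `path` invisibly; readers return a tibble.
#' @export
write_choice_file <- function(x, path, seed = NA, config_hash = NA) {
  write_dce_table(x, path, "choices", seed, config_hash)
}

#' @rdname write_choice_file
#' @export
read_choice_file <- function(path) read_dce_table(path)

#' @rdname write_choice_file
#' @export
write_ranking_file <- function(x, path, seed = NA, config_hash = NA) {
  write_dce_table(x, path, "rankings", seed, config_hash)
}

#' @rdname write_choice_file
#' @export
read_ranking_file <- function(path) read_dce_table(path)

#' @rdname write_choice_file
#' @export
write_respondent_file <- function(x, path, seed = NA, config_hash = NA) {
  write_dce_table(x, path, "respondents", seed, config_hash)
}

#' @rdname write_choice_file
#' @export
read_respondent_file <- function(path) read_dce_table(path)

#' Validate a long-format choice file
#'
#' Checks the header schema, that exactly one alternative is chosen per
#' respondent-task, that coded columns are 0/1 with at most one active level
#' per attribute, that opt-out rows carry no attribute levels, and (when a
#' respondent table is supplied) that every respondent id joins.
#'
#' @param path Path to a choices CSV (as written by [write_choice_file()]).
#' @param attrs Optional [dce_attributes()] set to check coded columns
#'   against.
#' @param respondents Optional respondent tibble for join checks.
#' @return A tibble of problems (`line`, `column`, `message`); zero rows
#'   means the file is valid. Line numbers refer to the file, counting the
#'   comment header.
#' @export
validate_choice_file <- function(path, attrs = NULL, respondents = NULL) {
  if (!file.exists(path)) {
    abort_dce(sprintf("cannot read '%s'", path), "io_error")
  }
  n_comment <- 0L
  con <- file(path, "r")
  on.exit(close(con))
  while (startsWith(readLines(con, 1), "#")) n_comment <- n_comment + 1L
  data <- read_dce_table(path)
  line_of <- function(row) row + n_comment + 1L
  problems <- list()
  note <- function(line, column, message) {
    problems[[length(problems) + 1]] <<-
      tibble::tibble(line = line, column = column, message = message)
  }

  required <- c("respondent_id", "task_id", "alternative", "chosen")
  miss <- setdiff(required, names(data))
  if (length(miss)) {
    note(n_comment + 1L, paste(miss, collapse = ", "),
         "missing required column(s)")
    return(dplyr::bind_rows(problems))
  }

  key <- paste(data$respondent_id, data$task_id)
  chosen_n <- tapply(data$chosen, key, sum)
  bad_tasks <- names(chosen_n)[chosen_n != 1]
  for (k in bad_tasks) {
    note(line_of(which(key == k)[1]), "chosen",
         sprintf("task %s has %d chosen alternatives (want 1)",
                 k, chosen_n[[k]]))
  }

  if (!is.null(attrs)) {
    attrs <- validate_attributes(attrs)
    scheme <- coding_scheme(attrs)
    miss_coded <- setdiff(scheme$term, names(data))
    if (length(miss_coded)) {
      note(n_comment + 1L, paste(miss_coded, collapse = ", "),
           "missing coded level column(s)")
    } else {
      for (tm in scheme$term) {
        bad <- which(!data[[tm]] %in% c(0, 1))
        if (length(bad)) {
          note(line_of(bad[1]), tm, "coded value not 0/1")
        }
      }
      for (a in unique(scheme$attribute)) {
        cols <- scheme$term[scheme$attribute == a]
        s <- rowSums(data[, cols, drop = FALSE])
        bad <- which(s > 1)
        if (length(bad)) {
          note(line_of(bad[1]), a,
               "more than one level active for attribute")
        }
      }
      if (!is.null(data$opt_out)) {
        s <- rowSums(data[, scheme$term, drop = FALSE])
        bad <- which(data$opt_out == 1 & s > 0)
        if (length(bad)) {
          note(line_of(bad[1]), "opt_out",
               "opt-out row carries attribute levels")
        }
      }
    }
  }

  if (!is.null(respondents)) {
    unknown <- which(!data$respondent_id %in% respondents$respondent_id)
    if (length(unknown)) {
      note(line_of(unknown[1]), "respondent_id",
           sprintf("%d row(s) reference unknown respondents",
                   length(unknown)))
    }
  }

  if (length(problems) == 0) {
    return(tibble::tibble(line = integer(), column = character(),
                          message = character()))
  }
  dplyr::bind_rows(problems)
}
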