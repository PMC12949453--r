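#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted choice model
#'
#' @param x A `mixlogit_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `type` (`"mean"`,
#'   `"sd"` or `"asc"`), `estimate`, `std_error`, `statistic`, `p_value`.
#' @export
tidy.mixlogit_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.mixlogit_fit
#' @export
glance.mixlogit_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    log_likelihood = x$log_likelihood,
    n_respondents = x$n_respondents,
    n_tasks = x$n_tasks,
    n_draws = x$n_draws,
    grad_norm = x$grad_norm,
    converged = x$converged
  )
}

#' @export
print.mixlogit_fit <- function(x, ...) {
  cat(sprintf("<%s logit fit> %d respondents, %d tasks%s\n",
              if (x$model == "mixed") "mixed" else "multinomial",
              x$n_respondents, x$n_tasks,
              if (x$model == "mixed")
                sprintf(", %d Halton draws", x$n_draws) else ""))
  cat(sprintf("log-likelihood: %.3f  (converged: %s, |grad| = %.2e)\n",
              x$log_likelihood, x$converged, x$grad_norm))
  print(x$coefficients, n = nrow(x$coefficients))
  invisible(x)
}

#' @export
print.stability_curve <- function(x, ...) {
  cat("<stability curve>\n")
  print(x$changes)
  invisible(x)
}

#' @rdname tidy.mixlogit_fit
#' @export
tidy.stability_curve <- function(x, ...) {
  x$coefficients
}
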