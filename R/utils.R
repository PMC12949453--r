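# Small shared helpers.

#' Round half away from zero
#'
#' Base `round()` rounds halves to even; published percentage tables are
#' conventionally rounded half-up, so tabulation functions use this variant.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Level label -> syntactic column suffix ("Rare or very rare" -> "rare_or_very_rare")
slugify <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

# Reserved (non-coded) column names in long-format choice data
.reserved_choice_cols <- c(
  "respondent_id", "block", "task_id", "alternative", "chosen",
  "opt_out", "is_attention"
)

coded_terms <- function(data) {
  setdiff(names(data), .reserved_choice_cols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_dce <- function(msg, class) {
  rlang::abort(msg, class = paste0("dcepref_", class))
}
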