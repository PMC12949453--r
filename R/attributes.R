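#' Define a set of treatment attributes
#'
#' An attribute set is a tibble with one row per attribute: its name, the
#' ordered level labels, the index of the reference level (the level coded as
#' the all-zero baseline), and a desirability ranking of the levels used to
#' construct dominated attention-check tasks.
#'
#' @param ... One or more attributes, each created by [attribute()].
#' @return A tibble of class `dce_attributes` with columns `name`,
#'   `levels` (list of character), `reference` (integer index) and
#'   `desirability` (list of integer ranks, larger = more desirable).
#' @seealso [adsmart_attributes()] for the five-attribute study instance.
#' @export
#' @examples
#' dce_attributes(
#'   attribute("dose", c("low", "high")),
#'   attribute("route", c("oral", "iv", "patch"), reference = 2)
#' )
dce_attributes <- function(...) {
  rows <- list(...)
  if (length(rows) == 0) {
    abort_dce("at least one attribute is required", "invalid_spec")
  }
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$name)) {
    abort_dce("attribute names must be unique", "invalid_spec")
  }
  structure(out, class = c("dce_attributes", class(out)))
}

#' @rdname dce_attributes
#' @param name Short attribute label (used as a column-name prefix).
#' @param levels Ordered character vector of level labels (at least 2).
#' @param reference Index of the reference level (default first).
#' @param desirability Integer ranks, one per level, larger = better;
#'   defaults to the level order.
#' @export
attribute <- function(name, levels, reference = 1L,
                      desirability = seq_along(levels)) {
  if (length(levels) < 2) {
    abort_dce(sprintf("attribute '%s' needs at least 2 levels", name),
              "invalid_spec")
  }
  if (anyDuplicated(levels)) {
    abort_dce(sprintf("attribute '%s' has duplicate level labels", name),
              "invalid_spec")
  }
  if (reference < 1 || reference > length(levels)) {
    abort_dce(sprintf("attribute '%s': reference index out of range", name),
              "invalid_spec")
  }
  if (length(desirability) != length(levels)) {
    abort_dce(sprintf("attribute '%s': desirability length mismatch", name),
              "invalid_spec")
  }
  tibble::tibble(
    name = name,
    levels = list(as.character(levels)),
    reference = as.integer(reference),
    desirability = list(as.integer(desirability))
  )
}

#' The five treatment attributes of the drug-preference survey
#'
#' The study instance: dosage frequency (2 levels), monitoring requirement
#' (2), type of evidence (2), probability of mild short-term side effects (3)
#' and probability of severe side effects (3), a 2 x 2 x 2 x 3 x 3 factorial
#' of 72 profiles. Reference levels are once-daily dosing, monitoring
#' required, pre-clinical animal evidence, and common-or-very-common side
#' effects. Desirability encodes that once-daily dosing, required monitoring,
#' human evidence and rarer side effects are the preferred levels (matching
#' the sign of the estimated marginal utilities).
#'
#' @return A `dce_attributes` tibble with five rows.
#' @export
adsmart_attributes <- function() {
  freq_levels <- c("Once daily", "Divided daily")
  se_levels <- c("Common or very common", "Uncommon", "Rare or very rare")
  dce_attributes(
    attribute("frequency", freq_levels, reference = 1L,
              desirability = c(2L, 1L)),
    attribute("monitoring", c("Required", "Not required"), reference = 1L,
              desirability = c(2L, 1L)),
    attribute("evidence", c("Pre-clinical animal trials", "Human trials"),
              reference = 1L, desirability = c(1L, 2L)),
    attribute("mild", se_levels, reference = 1L),
    attribute("severe", se_levels, reference = 1L)
  )
}

validate_attributes <- function(attrs) {
  if (!inherits(attrs, "dce_attributes")) {
    if (is.data.frame(attrs) &&
        all(c("name", "levels", "reference") %in% names(attrs))) {
      if (is.null(attrs$desirability)) {
        attrs$desirability <- lapply(attrs$levels, seq_along)
      }
      attrs <- structure(attrs, class = c("dce_attributes", class(attrs)))
    } else {
      abort_dce("not a dce_attributes object", "invalid_spec")
    }
  }
  if (nrow(attrs) == 0) abort_dce("empty attribute list", "invalid_spec")
  ok <- purrr::pmap_lgl(attrs, function(name, levels, reference, ...) {
    length(levels) >= 2 && !anyDuplicated(levels) &&
      reference >= 1 && reference <= length(levels)
  })
  if (!all(ok)) {
    abort_dce(paste("invalid attribute spec:",
                    paste(attrs$name[!ok], collapse = ", ")),
              "invalid_spec")
  }
  attrs
}

#' Enumerate the full factorial of profiles
#'
#' Returns the Cartesian product of all attribute levels in deterministic
#' lexicographic order: the last declared attribute varies fastest, matching
#' nested loops over attributes in declaration order.
#'
#' @param attrs A [dce_attributes()] set.
#' @return A tibble with one row per profile and one character column per
#'   attribute; `prod(lengths(attrs$levels))` rows.
#' @export
#' @examples
#' nrow(enumerate_full_factorial(adsmart_attributes()))  # 72
enumerate_full_factorial <- function(attrs) {
  attrs <- validate_attributes(attrs)
  grid <- rev(expand.grid(rev(stats::setNames(attrs$levels, attrs$name)),
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE))
  tibble::as_tibble(grid)
}

#' Dummy-coding scheme for an attribute set
#'
#' One coded column per non-reference level of every attribute; the reference
#' level of each attribute contributes the all-zero baseline. Column order is
#' attribute declaration order, then level order.
#'
#' @param attrs A [dce_attributes()] set.
#' @return A tibble with columns `term` (coded column name,
#'   `<attribute>_<level-slug>`), `attribute` and `level`.
#' @export
coding_scheme <- function(attrs) {
  attrs <- validate_attributes(attrs)
  purrr::pmap_dfr(attrs, function(name, levels, reference, ...) {
    lv <- levels[-reference]
    tibble::tibble(
      term = paste(name, slugify(lv), sep = "_"),
      attribute = name,
      level = lv
    )
  })
}

#' Dummy-code profiles against their attribute spec
#'
#' @param profiles A data frame with one character column per attribute
#'   (e.g. from [enumerate_full_factorial()]).
#' @param attrs A [dce_attributes()] set.
#' @return A numeric matrix, one row per profile and one 0/1 column per
#'   non-reference level (7 columns for the study instance).
#' @export
dummy_code <- function(profiles, attrs) {
  attrs <- validate_attributes(attrs)
  scheme <- coding_scheme(attrs)
  missing_attr <- setdiff(attrs$name, names(profiles))
  if (length(missing_attr)) {
    abort_dce(paste("profile missing attribute(s):",
                    paste(missing_attr, collapse = ", ")),
              "invalid_profile")
  }
  for (i in seq_len(nrow(attrs))) {
    bad <- !profiles[[attrs$name[i]]] %in% attrs$levels[[i]]
    if (any(bad)) {
      abort_dce(sprintf("unknown level '%s' for attribute '%s'",
                        profiles[[attrs$name[i]]][bad][1], attrs$name[i]),
                "invalid_profile")
    }
  }
  X <- vapply(seq_len(nrow(scheme)), function(j) {
    as.numeric(profiles[[scheme$attribute[j]]] == scheme$level[j])
  }, numeric(nrow(profiles)))
  X <- matrix(X, nrow = nrow(profiles),
              dimnames = list(NULL, scheme$term))
  X
}

#' Read and write attribute specs as YAML
#'
#' The plain-text config is a YAML list with one entry per attribute:
#' `name`, `levels` (in order), `reference` (level label), and optionally
#' `desirability` (integer ranks).
#'
#' @param path File path.
#' @return `read_attribute_spec()` returns a `dce_attributes` tibble;
#'   `write_attribute_spec()` returns `path` invisibly.
#' @export
read_attribute_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- lapply(raw, function(a) {
    ref <- match(a$reference %||% a$levels[[1]], unlist(a$levels))
    if (is.na(ref)) {
      abort_dce(sprintf("attribute '%s': reference level not among levels",
                        a$name), "invalid_spec")
    }
    attribute(a$name, unlist(a$levels), reference = ref,
              desirability = unlist(a$desirability) %||%
                seq_along(unlist(a$levels)))
  })
  do.call(dce_attributes, rows)
}

#' @rdname read_attribute_spec
#' @param attrs A [dce_attributes()] set.
#' @export
write_attribute_spec <- function(attrs, path) {
  attrs <- validate_attributes(attrs)
  out <- purrr::pmap(attrs, function(name, levels, reference, desirability) {
    list(name = name, levels = as.list(levels),
         reference = levels[reference],
         desirability = as.list(desirability))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
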