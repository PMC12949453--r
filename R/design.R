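#' Compute the D-error of a paired choice design
#'
#' The D-error is `det(I^-1)^(1/K)` where `I` is the multinomial-logit
#' information matrix of the design evaluated at a prior coefficient vector
#' and `K` is the number of dummy-coded columns. For a paired design the
#' per-task contribution reduces to `p(1-p) d d'` with `d` the coded
#' difference between the two alternatives and `p` the logit choice
#' probability at the prior. Smaller is better; a rank-deficient information
#' matrix yields `Inf`.
#'
#' The opt-out alternative carries no attribute information and is excluded
#' from design evaluation.
#'
#' @param design A `dce_design` tibble (see [generate_defficient_design()]),
#'   or any data frame with columns `task_id`, `alternative` and one column
#'   per attribute.
#' @param attrs A [dce_attributes()] set fixing the dummy coding.
#' @param prior Numeric prior coefficient vector, one entry per coded column.
#'   The default zero vector gives the utility-neutral design criterion.
#' @return A single nonnegative number, `Inf` when singular.
#' @export
d_error <- function(design, attrs, prior = NULL) {
  attrs <- validate_attributes(attrs)
  tasks <- design
  if (!is.null(tasks$is_attention)) tasks <- tasks[!tasks$is_attention, ]
  if (nrow(tasks) == 0) abort_dce("design has no non-attention tasks", "invalid_design")
  a_rows <- tasks[tasks$alternative == "A", ]
  b_rows <- tasks[tasks$alternative == "B", ]
  a_rows <- a_rows[order(a_rows$task_id), ]
  b_rows <- b_rows[order(b_rows$task_id), ]
  if (nrow(a_rows) != nrow(b_rows)) {
    abort_dce("each task needs exactly alternatives A and B", "invalid_design")
  }
  XA <- dummy_code(a_rows, attrs)
  XB <- dummy_code(b_rows, attrs)
  d_error_from_diff(XA - XB, prior)
}

# Core D-error on the coded difference matrix of a paired design.
d_error_from_diff <- function(D, prior = NULL) {
  K <- ncol(D)
  if (is.null(prior)) prior <- rep(0, K)
  if (length(prior) != K) {
    abort_dce(sprintf("prior has length %d but design has %d coded columns",
                      length(prior), K), "dimension_mismatch")
  }
  p <- stats::plogis(drop(D %*% prior))
  w <- p * (1 - p)
  info <- crossprod(D * sqrt(w))
  det_i <- det(info)
  if (!is.finite(det_i) || det_i <= .Machine$double.eps^0.9) return(Inf)
  det_i^(-1 / K)
}

new_dce_design <- function(task_tbl, attrs, n_blocks, d_err = NA_real_,
                           seed = NA_integer_) {
  structure(
    task_tbl,
    attrs = attrs,
    n_blocks = n_blocks,
    d_error = d_err,
    seed = seed,
    class = c("dce_design", class(task_tbl))
  )
}

profiles_to_task_tbl <- function(profiles, idx, block = NA_integer_) {
  n_tasks <- nrow(idx)
  tibble::tibble(
    task_id = rep(seq_len(n_tasks), each = 2),
    alternative = rep(c("A", "B"), n_tasks),
    block = rep(block, length.out = n_tasks)[rep(seq_len(n_tasks), each = 2)],
    is_attention = FALSE
  ) |>
    dplyr::bind_cols(profiles[as.vector(t(idx)), , drop = FALSE])
}

random_pair_idx <- function(n_profiles, n_tasks) {
  t(vapply(seq_len(n_tasks),
           function(i) sample.int(n_profiles, 2, replace = FALSE),
           integer(2)))
}

#' Generate a D-efficient blocked choice design
#'
#' Profile-swap coordinate exchange from a random start: for each task and
#' each of its two alternatives in turn, candidate replacement profiles from
#' the full factorial are scanned in order and the first strict D-error
#' improvement is accepted; passes repeat until a full pass yields no
#' improvement. Tasks never compare a profile with itself. Non-attention
#' tasks are then partitioned into `n_blocks` equal blocks by a greedy
#' level-balance heuristic (see [assign_blocks()]). The search is
#' deterministic given `seed`.
#'
#' @param attrs A [dce_attributes()] set.
#' @param n_tasks Number of paired tasks (must be a multiple of `n_blocks`
#'   and at least the number of coded columns).
#' @param n_blocks Number of blocks.
#' @param prior Prior coefficient vector for the D-error (default zero,
#'   utility-neutral).
#' @param seed Integer seed for the random start.
#' @param n_restarts Number of random restarts; the best design is kept.
#' @return A `dce_design` tibble: one row per task x alternative with
#'   `task_id`, `alternative`, `block`, `is_attention` and one column per
#'   attribute. The attained D-error is in `attr(, "d_error")`.
#' @export
#' @examples
#' des <- generate_defficient_design(adsmart_attributes(), 12, 4, seed = 1)
#' attr(des, "d_error")
generate_defficient_design <- function(attrs, n_tasks, n_blocks = 1L,
                                       prior = NULL, seed = 1L,
                                       n_restarts = 1L) {
  attrs <- validate_attributes(attrs)
  profiles <- enumerate_full_factorial(attrs)
  X <- dummy_code(profiles, attrs)
  K <- ncol(X)
  if (n_tasks < K) {
    abort_dce(sprintf("n_tasks (%d) below number of coded columns (%d): infeasible",
                      n_tasks, K), "infeasible_design")
  }
  if (n_tasks %% n_blocks != 0) {
    abort_dce("n_blocks must divide n_tasks", "infeasible_design")
  }
  if (is.null(prior)) prior <- rep(0, K)

  search_one <- function() {
    idx <- random_pair_idx(nrow(profiles), n_tasks)
    de <- function(ix) d_error_from_diff(X[ix[, 1], , drop = FALSE] -
                                           X[ix[, 2], , drop = FALSE], prior)
    cur <- de(idx)
    repeat {
      improved <- FALSE
      for (t in seq_len(n_tasks)) {
        for (a in 1:2) {
          other <- idx[t, 3 - a]
          for (cand in seq_len(nrow(profiles))) {
            if (cand == other || cand == idx[t, a]) next
            trial <- idx
            trial[t, a] <- cand
            val <- de(trial)
            if (val < cur - 1e-12) {
              idx <- trial
              cur <- val
              improved <- TRUE
              break
            }
          }
        }
      }
      if (!improved) break
    }
    list(idx = idx, d_error = cur)
  }

  best <- withr::with_seed(seed, {
    res <- search_one()
    for (r in seq_len(max(0L, n_restarts - 1L))) {
      alt <- search_one()
      if (alt$d_error < res$d_error) res <- alt
    }
    res
  })

  tasks <- profiles_to_task_tbl(profiles, best$idx)
  design <- new_dce_design(tasks, attrs, n_blocks, best$d_error, seed)
  assign_blocks(design, n_blocks)
}

#' Assign design tasks to blocks by greedy level balance
#'
#' Tasks are taken in `task_id` order and each is placed into the
#' non-full block that minimises the sum of squared attribute-level counts
#' after placement (spreading every level as evenly as possible across
#' blocks); ties are broken by the lowest block index. Attention-check tasks
#' are never assigned to a block.
#'
#' @param design A `dce_design` tibble.
#' @param n_blocks Number of blocks; must divide the number of
#'   non-attention tasks.
#' @return The design with its `block` column filled in.
#' @export
assign_blocks <- function(design, n_blocks) {
  attrs <- attr(design, "attrs")
  core <- design[!design$is_attention, ]
  task_ids <- unique(core$task_id)
  n_tasks <- length(task_ids)
  if (n_tasks %% n_blocks != 0) {
    abort_dce("n_blocks must divide the number of non-attention tasks",
              "infeasible_design")
  }
  capacity <- n_tasks / n_blocks
  # level-indicator matrix per task (both alternatives pooled)
  lvl_cols <- do.call(rbind, lapply(task_ids, function(tid) {
    rows <- core[core$task_id == tid, attrs$name, drop = FALSE]
    unlist(lapply(seq_len(nrow(attrs)), function(i) {
      tabulate(match(rows[[attrs$name[i]]], attrs$levels[[i]]),
               nbins = length(attrs$levels[[i]]))
    }))
  }))
  counts <- matrix(0, n_blocks, ncol(lvl_cols))
  sizes <- integer(n_blocks)
  assignment <- integer(n_tasks)
  for (t in seq_len(n_tasks)) {
    open <- which(sizes < capacity)
    scores <- vapply(open, function(b) {
      sum((counts[b, ] + lvl_cols[t, ])^2)
    }, numeric(1))
    b <- open[which.min(scores)]
    assignment[t] <- b
    counts[b, ] <- counts[b, ] + lvl_cols[t, ]
    sizes[b] <- sizes[b] + 1L
  }
  design$block[!design$is_attention] <-
    assignment[match(design$task_id[!design$is_attention], task_ids)]
  design$block[design$is_attention] <- NA_integer_
  attr(design, "n_blocks") <- n_blocks
  design
}

# Does profile a weakly dominate b, strictly in >= `strict` attributes,
# under the attrs desirability ordering?
dominates <- function(a, b, attrs, strict = 2L) {
  cmp <- vapply(seq_len(nrow(attrs)), function(i) {
    des <- attrs$desirability[[i]]
    lv <- attrs$levels[[i]]
    des[match(a[[attrs$name[i]]], lv)] - des[match(b[[attrs$name[i]]], lv)]
  }, numeric(1))
  all(cmp >= 0) && sum(cmp > 0) >= strict
}

#' Construct a dominated attention-check task
#'
#' Builds a task whose alternative A holds the most desirable level of every
#' attribute while B is strictly worse in at least two randomly chosen
#' attributes and never better, so any attentive respondent should choose A.
#' The task is flagged `is_attention` and carries no block.
#'
#' @param attrs A [dce_attributes()] set.
#' @param seed Integer seed choosing which attributes B degrades.
#' @param task_id Task identifier for the check (default `0L`, by convention
#'   distinct from design task ids).
#' @return A two-row `dce_design`-shaped tibble (alternatives A and B) with
#'   the expected answer `"A"` in `attr(, "expected_answer")`.
#' @export
make_attention_check <- function(attrs, seed = 1L, task_id = 0L) {
  attrs <- validate_attributes(attrs)
  best <- vapply(seq_len(nrow(attrs)), function(i) {
    attrs$levels[[i]][which.max(attrs$desirability[[i]])]
  }, character(1))
  worsenable <- which(vapply(seq_len(nrow(attrs)), function(i) {
    any(attrs$desirability[[i]] < max(attrs$desirability[[i]]))
  }, logical(1)))
  if (length(worsenable) < 2) {
    abort_dce("attention check needs >= 2 attributes with a strictly worse level",
              "invalid_spec")
  }
  worse <- withr::with_seed(seed, {
    k <- sample(2:length(worsenable), 1)
    chosen <- sort(sample(worsenable, k))
    vapply(chosen, function(i) {
      worse_lv <- attrs$levels[[i]][attrs$desirability[[i]] <
                                      max(attrs$desirability[[i]])]
      sample(worse_lv, 1)
    }, character(1)) |> stats::setNames(attrs$name[chosen])
  })
  b <- stats::setNames(as.list(best), attrs$name)
  b[names(worse)] <- worse
  task <- tibble::tibble(
    task_id = task_id,
    alternative = c("A", "B"),
    block = NA_integer_,
    is_attention = TRUE
  ) |>
    dplyr::bind_cols(dplyr::bind_rows(
      tibble::as_tibble(stats::setNames(as.list(best), attrs$name)),
      tibble::as_tibble(b)
    ))
  if (!dominates(task[1, ], task[2, ], attrs, strict = 2L)) {
    abort_dce("constructed attention check is not dominant", "invalid_design")
  }
  out <- new_dce_design(task, attrs, n_blocks = 0L)
  attr(out, "expected_answer") <- "A"
  out
}

#' Read and write designs as delimited text
#'
#' One row per task x alternative with `block`, `task_id`, `alternative`,
#' `is_attention`, and one 0/1 indicator column per attribute level
#' (including reference levels, named `<attribute>_<level-slug>`). Files
#' start with `#`-comment header lines recording the seed and D-error.
#'
#' @param design A `dce_design` tibble.
#' @param path Output file path.
#' @return `write_design()` returns `path` invisibly; `read_design()`
#'   returns a `dce_design` tibble.
#' @export
write_design <- function(design, path) {
  attrs <- attr(design, "attrs")
  lvl_tbl <- purrr::pmap_dfr(attrs, function(name, levels, ...) {
    tibble::tibble(attribute = name, level = levels,
                   col = paste(name, slugify(levels), sep = "_"))
  })
  ind <- vapply(seq_len(nrow(lvl_tbl)), function(j) {
    as.numeric(design[[lvl_tbl$attribute[j]]] == lvl_tbl$level[j])
  }, numeric(nrow(design)))
  out <- dplyr::bind_cols(
    design[, c("block", "task_id", "alternative", "is_attention")],
    tibble::as_tibble(matrix(ind, nrow = nrow(design),
                             dimnames = list(NULL, lvl_tbl$col)))
  )
  header <- c(
    sprintf("# dcepref design | seed: %s | d_error: %s | n_blocks: %s",
            attr(design, "seed"), format(attr(design, "d_error"), digits = 10),
            attr(design, "n_blocks"))
  )
  writeLines(header, path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_design
#' @param attrs The [dce_attributes()] set the design was coded against.
#' @export
read_design <- function(path, attrs) {
  attrs <- validate_attributes(attrs)
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  labels <- lapply(seq_len(nrow(attrs)), function(i) {
    cols <- paste(attrs$name[i], slugify(attrs$levels[[i]]), sep = "_")
    hit <- apply(as.matrix(raw[, cols]) == 1, 1, which.max)
    attrs$levels[[i]][hit]
  })
  names(labels) <- attrs$name
  tasks <- tibble::tibble(
    task_id = as.integer(raw$task_id),
    alternative = raw$alternative,
    block = as.integer(raw$block),
    is_attention = as.logical(raw$is_attention)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(labels))
  n_blocks <- length(unique(stats::na.omit(tasks$block)))
  new_dce_design(tasks, attrs, n_blocks)
}
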