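# Shared fixtures, built in code at load time.

study_attrs <- adsmart_attributes()
study_scheme <- coding_scheme(study_attrs)

toy_attrs <- dce_attributes(
  attribute("a", c("a0", "a1")),
  attribute("b", c("b0", "b1"))
)

# Small study design reused across files (fast, deterministic).
study_design <- generate_defficient_design(study_attrs, 12, 4, seed = 1)

# Build a design by hand from explicit profile rows (one list per task:
# list(A = c(attr = level, ...), B = ...)).
manual_design <- function(tasks, attrs, n_blocks = 1L) {
  rows <- dplyr::bind_rows(lapply(seq_along(tasks), function(t) {
    dplyr::bind_rows(
      tibble::as_tibble(as.list(tasks[[t]]$A)),
      tibble::as_tibble(as.list(tasks[[t]]$B))
    ) |>
      dplyr::mutate(task_id = t, alternative = c("A", "B"),
                    block = ((t - 1L) %% n_blocks) + 1L,
                    is_attention = FALSE, .before = 1)
  }))
  structure(rows, attrs = attrs, n_blocks = n_blocks,
            d_error = NA_real_, seed = NA_integer_,
            class = c("dce_design", class(rows)))
}

# One-binary-attribute instrument: task compares the non-reference level (A)
# against the reference (B); utility difference equals the single coefficient.
one_attr_design <- function() {
  attrs <- dce_attributes(attribute("x", c("ref", "alt")))
  manual_design(list(list(A = c(x = "alt"), B = c(x = "ref"))), attrs)
}

# Independent brute-force D-error oracle: generic MNL information matrix
# summed over tasks and alternatives (softmax at the prior), then
# det(I^-1)^(1/K). Deliberately written from the definition, not the
# pairwise shortcut used by d_error().
bruteforce_d_error <- function(design, attrs, prior = NULL) {
  tasks <- design[!design$is_attention, ]
  ids <- unique(tasks$task_id)
  X <- dummy_code(tasks, attrs)
  K <- ncol(X)
  if (is.null(prior)) prior <- rep(0, K)
  info <- matrix(0, K, K)
  for (tid in ids) {
    rows <- which(tasks$task_id == tid)
    Xt <- X[rows, , drop = FALSE]
    u <- drop(Xt %*% prior)
    p <- exp(u - max(u)); p <- p / sum(p)
    xbar <- colSums(p * Xt)
    for (j in seq_along(rows)) {
      d <- Xt[j, ] - xbar
      info <- info + p[j] * (d %o% d)
    }
  }
  det_i <- det(info)
  if (!is.finite(det_i) || det_i <= 1e-280) return(Inf)
  det_i^(-1 / K)
}

# All 4-task designs on the 2x2 toy factorial: every set of 4 distinct
# ordered profile pairs.
toy_pair_designs <- function() {
  profiles <- enumerate_full_factorial(toy_attrs)
  pairs <- expand.grid(a = 1:4, b = 1:4)
  pairs <- pairs[pairs$a != pairs$b, ]
  utils::combn(nrow(pairs), 4, simplify = FALSE) |>
    lapply(function(sel) {
      lapply(sel, function(s) {
        list(A = unlist(profiles[pairs$a[s], ]),
             B = unlist(profiles[pairs$b[s], ]))
      })
    })
}

expect_no_problem_rows <- function(report) {
  expect_identical(nrow(report), 0L)
}
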