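# Mixed logit estimation by simulated maximum likelihood.
#
# The utility of respondent i for alternative j in task t is
#   U_ijt = x_jt' (beta + sigma o z_i) + alpha * optout_j + e_ijt
# with e_ijt iid Type I extreme value (Gumbel), so conditional on z_i the
# choice probabilities are softmax. The simulated log-likelihood averages the
# panel product of task probabilities over quasi-random (Halton) normal draws
# z_ir, one block of R draws per respondent.

.halton_primes <- c(2L, 3L, 5L, 7L, 11L, 13L, 17L)

radical_inverse <- function(idx, base) {
  f <- numeric(length(idx))
  denom <- 1
  i <- idx
  while (any(i > 0)) {
    denom <- denom * base
    f <- f + (i %% base) / denom
    i <- i %/% base
  }
  f
}

#' Halton low-discrepancy sequence
#'
#' Radical-inverse Halton points with prime bases 2, 3, 5, 7, 11, 13, 17
#' assigned to dimensions in order; the first `skip` points of each
#' dimension are discarded (the leading points of a Halton sequence are
#' strongly correlated across bases).
#'
#' @param n Number of points.
#' @param dim Number of dimensions (at most 7).
#' @param skip Number of initial points to discard (default 10).
#' @return An `n` x `dim` matrix with entries in (0, 1).
#' @export
#' @examples
#' halton_sequence(3, 1, skip = 0)  # 0.5, 0.25, 0.75
halton_sequence <- function(n, dim, skip = 10L) {
  if (n < 1 || dim < 1) abort_dce("n and dim must be >= 1", "invalid_spec")
  if (dim > length(.halton_primes)) {
    abort_dce(sprintf("dim = %d exceeds the %d supported prime bases",
                      dim, length(.halton_primes)), "invalid_spec")
  }
  idx <- seq_len(n) + skip
  matrix(vapply(.halton_primes[seq_len(dim)],
                function(b) radical_inverse(idx, b), numeric(n)),
         nrow = n, ncol = dim)
}

#' Multinomial logit choice probabilities
#'
#' Softmax of a utility vector, computed with max-subtraction for overflow
#' safety. This is the choice rule implied by iid Type I extreme value
#' (Gumbel) utility errors.
#'
#' @param utilities Finite numeric vector.
#' @return Probability vector of the same length, summing to 1.
#' @export
#' @examples
#' mnl_probability(c(1, 0))  # e/(1+e), 1/(1+e)
mnl_probability <- function(utilities) {
  if (length(utilities) == 0) abort_dce("empty utility vector", "invalid_spec")
  if (any(!is.finite(utilities))) {
    abort_dce("utilities must be finite", "invalid_spec")
  }
  e <- exp(utilities - max(utilities))
  e / sum(e)
}

# ---- internal coded-data container -----------------------------------------

# Reshape long-format choice data (one row per respondent x task x
# alternative) into task-major slot matrices: slot s holds the s-th
# alternative of every task. Requires a constant alternative count per task,
# which all package-generated data satisfies.
build_coded_data <- function(data, terms = NULL) {
  if (!is.null(data$is_attention)) data <- data[!data$is_attention, ]
  terms <- terms %||% coded_terms(data)
  terms <- terms[vapply(data[terms], is.numeric, logical(1))]
  if (length(terms) == 0) abort_dce("no coded columns found", "invalid_data")
  ord <- order(data$respondent_id, data$task_id, data$alternative)
  data <- data[ord, ]
  key <- paste(data$respondent_id, data$task_id)
  task <- match(key, unique(key))
  counts <- tabulate(task)
  n_alts <- counts[1]
  if (any(counts != n_alts)) {
    abort_dce("all tasks must have the same number of alternatives",
              "invalid_data")
  }
  chosen_per_task <- rowsum(data$chosen, task)
  if (any(chosen_per_task != 1)) {
    bad <- which(chosen_per_task != 1)[1]
    abort_dce(sprintf("task %s of respondent %s has %d chosen alternatives",
                      data$task_id[task == bad][1],
                      data$respondent_id[task == bad][1],
                      chosen_per_task[bad]),
              "invalid_data")
  }
  n_task <- max(task)
  slot <- sequence(counts)
  X <- as.matrix(data[terms])
  opt <- if (is.null(data$opt_out)) numeric(nrow(data)) else
    as.numeric(data$opt_out)
  X_slots <- lapply(seq_len(n_alts), function(s) X[slot == s, , drop = FALSE])
  opt_slots <- lapply(seq_len(n_alts), function(s) opt[slot == s])
  chosen_slot <- slot[data$chosen == 1]
  resp_ids <- unique(data$respondent_id)
  resp_of_task <- match(data$respondent_id[slot == 1], resp_ids)
  list(
    terms = terms, n_alts = n_alts, n_task = n_task,
    X_slots = X_slots, opt_slots = opt_slots, chosen_slot = chosen_slot,
    resp_of_task = resp_of_task, resp_ids = resp_ids,
    n_resp = length(resp_ids),
    has_optout = any(opt > 0)
  )
}

# softmax across slots for a list of per-slot utility vectors; returns
# per-slot probabilities and log prob of the chosen slot
slot_softmax <- function(V, chosen_slot) {
  m <- Reduce(pmax, V)
  E <- lapply(V, function(v) exp(v - m))
  S <- Reduce(`+`, E)
  P <- lapply(E, function(e) e / S)
  idx <- cbind(seq_along(chosen_slot), chosen_slot)
  lp <- log(do.call(cbind, P)[idx])
  list(P = P, lp = lp)
}

# ---- multinomial logit ------------------------------------------------------

mnl_ll_grad <- function(theta, cd) {
  K <- length(cd$terms)
  beta <- theta[seq_len(K)]
  asc <- if (cd$has_optout) theta[K + 1] else 0
  V <- lapply(seq_len(cd$n_alts), function(s) {
    drop(cd$X_slots[[s]] %*% beta) + cd$opt_slots[[s]] * asc
  })
  sm <- slot_softmax(V, cd$chosen_slot)
  y <- lapply(seq_len(cd$n_alts), function(s) {
    as.numeric(cd$chosen_slot == s)
  })
  g_beta <- numeric(K)
  g_asc <- 0
  for (s in seq_len(cd$n_alts)) {
    e <- y[[s]] - sm$P[[s]]
    g_beta <- g_beta + drop(crossprod(cd$X_slots[[s]], e))
    g_asc <- g_asc + sum(e * cd$opt_slots[[s]])
  }
  list(ll = sum(sm$lp),
       grad = unname(c(g_beta, if (cd$has_optout) g_asc)),
       P = sm$P)
}

mnl_information <- function(theta, cd) {
  K <- length(cd$terms)
  npar <- K + cd$has_optout
  P <- mnl_ll_grad(theta, cd)$P
  xt <- lapply(seq_len(cd$n_alts), function(s) {
    if (cd$has_optout) cbind(cd$X_slots[[s]], optout = cd$opt_slots[[s]])
    else cd$X_slots[[s]]
  })
  info <- matrix(0, npar, npar)
  xbar <- matrix(0, cd$n_task, npar)
  for (s in seq_len(cd$n_alts)) {
    info <- info + crossprod(xt[[s]] * sqrt(P[[s]]), xt[[s]] * sqrt(P[[s]]))
    xbar <- xbar + P[[s]] * xt[[s]]
  }
  info - crossprod(xbar)
}

check_design_matrix <- function(cd) {
  Xall <- do.call(rbind, cd$X_slots)
  qr_x <- qr(Xall)
  if (qr_x$rank < ncol(Xall)) {
    dropped <- cd$terms[qr_x$pivot[(qr_x$rank + 1):ncol(Xall)]]
    abort_dce(paste("collinear coded column(s):",
                    paste(dropped, collapse = ", ")), "rank_deficient")
  }
  y <- unlist(lapply(seq_along(cd$X_slots), function(s) {
    as.numeric(cd$chosen_slot == s)
  }))
  for (j in seq_along(cd$terms)) {
    on <- Xall[, j] == 1
    if (any(on) && (all(y[on] == 1) || all(y[on] == 0))) {
      warning(sprintf("column '%s' is separation-degenerate (%s chosen)",
                      cd$terms[j], if (all(y[on] == 1)) "always" else "never"),
              call. = FALSE)
    }
  }
}

new_mixlogit_fit <- function(model, cd, theta, ll, grad, vcov_mat, spec,
                             converged) {
  K <- length(cd$terms)
  n_random <- if (model == "mixed") length(spec$random) else 0L
  types <- c(rep("mean", K), rep("sd", n_random),
             if (cd$has_optout) "asc")
  terms <- c(cd$terms,
             if (n_random) spec$random,
             if (cd$has_optout) "opt_out")
  est <- theta
  sd_idx <- which(types == "sd")
  est[sd_idx] <- abs(est[sd_idx])  # sign of sigma is unidentified
  se <- rep(NA_real_, length(theta))
  if (!is.null(vcov_mat)) se <- sqrt(pmax(diag(vcov_mat), 0))
  z <- est / se
  coefs <- tibble::tibble(
    term = terms, type = types, estimate = est, std_error = se,
    statistic = z, p_value = 2 * stats::pnorm(-abs(z))
  )
  structure(
    list(
      model = model,
      coefficients = coefs,
      beta_mean = stats::setNames(est[types == "mean"], cd$terms),
      beta_sd = if (n_random) stats::setNames(est[sd_idx], spec$random)
                else stats::setNames(rep(0, K), cd$terms),
      opt_out_constant = if (cd$has_optout) est[length(est)] else NA_real_,
      log_likelihood = ll,
      grad_norm = max(abs(grad)),
      converged = converged,
      n_respondents = cd$n_resp,
      n_tasks = cd$n_task,
      n_draws = if (model == "mixed") spec$n_draws else NA_integer_,
      vcov = vcov_mat,
      spec = spec
    ),
    class = "mixlogit_fit"
  )
}

#' Fit a multinomial logit model to choice data
#'
#' Conditional logit with fixed coefficients (the mixed logit special case
#' with all random spreads at zero), maximized by quasi-Newton iteration
#' with analytic gradients. Standard errors come from the inverse observed
#' information at the optimum.
#'
#' @param data Long-format choice tibble: one row per respondent x task x
#'   alternative with `respondent_id`, `task_id`, `alternative`, `chosen`
#'   (0/1), optional `opt_out` indicator, and dummy-coded attribute columns.
#'   Attention-check rows (`is_attention`) are dropped.
#' @param terms Coded columns to use (default: every non-reserved numeric
#'   column).
#' @param tol Convergence tolerance on the gradient infinity norm.
#' @param max_iterations Iteration cap for the optimizer.
#' @return A `mixlogit_fit` object; see [tidy.mixlogit_fit()].
#' @export
fit_mnl <- function(data, terms = NULL, tol = 1e-5, max_iterations = 500L) {
  cd <- build_coded_data(data, terms)
  check_design_matrix(cd)
  npar <- length(cd$terms) + cd$has_optout
  fn <- function(th) -mnl_ll_grad(th, cd)$ll
  gr <- function(th) -mnl_ll_grad(th, cd)$grad
  opt <- stats::optim(numeric(npar), fn, gr, method = "BFGS",
                      control = list(maxit = max_iterations, reltol = 1e-12))
  # Newton polish with the analytic information matrix: quadratic
  # convergence to the gradient tolerance from the BFGS solution
  theta <- opt$par
  res <- mnl_ll_grad(theta, cd)
  for (it in 1:25) {
    if (max(abs(res$grad)) < tol / 10) break
    info <- mnl_information(theta, cd)
    step <- tryCatch(solve(info, res$grad), error = function(e) NULL)
    if (is.null(step)) break
    cand <- theta + step
    res_cand <- mnl_ll_grad(cand, cd)
    halvings <- 0
    while (res_cand$ll < res$ll && halvings < 10) {
      step <- step / 2
      cand <- theta + step
      res_cand <- mnl_ll_grad(cand, cd)
      halvings <- halvings + 1
    }
    if (res_cand$ll < res$ll) break
    theta <- cand
    res <- res_cand
  }
  opt$par <- theta
  info <- mnl_information(opt$par, cd)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  converged <- max(abs(res$grad)) < tol
  if (!converged) {
    warning("MNL fit did not reach the gradient tolerance", call. = FALSE)
  }
  new_mixlogit_fit("mnl", cd, opt$par, res$ll, res$grad, vc,
                   spec = list(tol = tol), converged = converged)
}

#' Specification of a mixed logit model
#'
#' @param random Character vector of coefficients treated as random
#'   (normally distributed); `NULL` (default) makes every attribute
#'   coefficient random. The opt-out constant is always fixed.
#' @param n_draws Number of Halton draws per respondent (default 500).
#' @param seed Integer seed recorded with the fit.
#' @param max_iterations Optimizer iteration cap.
#' @param tol Gradient infinity-norm convergence tolerance.
#' @param halton_skip Initial Halton points to discard.
#' @return A list of class `mixlogit_spec`.
#' @export
mixlogit_spec <- function(random = NULL, n_draws = 500L, seed = 1L,
                          max_iterations = 200L, tol = 1e-5,
                          halton_skip = 10L) {
  if (n_draws < 1) abort_dce("n_draws must be >= 1", "invalid_spec")
  if (tol <= 0) abort_dce("tol must be positive", "invalid_spec")
  structure(
    list(random = random, n_draws = as.integer(n_draws),
         seed = as.integer(seed), max_iterations = as.integer(max_iterations),
         tol = tol, halton_skip = as.integer(halton_skip)),
    class = "mixlogit_spec"
  )
}

# simulated log-likelihood and analytic gradient; Z_list[[r]] is the
# (n_resp x n_random) normal draw matrix for draw r
sml_ll_grad <- function(theta, cd, Z_list, rand_idx) {
  K <- length(cd$terms)
  Kr <- length(rand_idx)
  R <- length(Z_list)
  beta <- theta[seq_len(K)]
  sigma <- theta[K + seq_len(Kr)]
  asc <- if (cd$has_optout) theta[K + Kr + 1] else 0
  npar <- K + Kr + cd$has_optout
  Vfix <- lapply(seq_len(cd$n_alts), function(s) {
    drop(cd$X_slots[[s]] %*% beta) + cd$opt_slots[[s]] * asc
  })
  Xr <- lapply(cd$X_slots, function(x) x[, rand_idx, drop = FALSE])
  y <- lapply(seq_len(cd$n_alts), function(s) {
    as.numeric(cd$chosen_slot == s)
  })
  rt <- cd$resp_of_task
  S <- numeric(cd$n_resp)
  NUM <- matrix(0, cd$n_resp, npar)
  for (r in seq_len(R)) {
    Zr <- Z_list[[r]]
    dev <- sweep(Zr, 2, sigma, `*`)   # n_resp x Kr deviations
    V <- lapply(seq_len(cd$n_alts), function(s) {
      Vfix[[s]] + rowSums(Xr[[s]] * dev[rt, , drop = FALSE])
    })
    sm <- slot_softmax(V, cd$chosen_slot)
    L_ir <- drop(rowsum(sm$lp, rt, reorder = TRUE))
    P_ir <- exp(L_ir)
    EX <- matrix(0, cd$n_task, K)
    e_opt <- numeric(cd$n_task)
    for (s in seq_len(cd$n_alts)) {
      e <- y[[s]] - sm$P[[s]]
      EX <- EX + e * cd$X_slots[[s]]
      e_opt <- e_opt + e * cd$opt_slots[[s]]
    }
    G_beta <- rowsum(EX, rt, reorder = TRUE)
    g <- cbind(G_beta, G_beta[, rand_idx, drop = FALSE] * Zr,
               if (cd$has_optout) drop(rowsum(e_opt, rt, reorder = TRUE)))
    S <- S + P_ir
    NUM <- NUM + P_ir * g
  }
  S <- pmax(S, 1e-300)
  list(ll = sum(log(S / R)), grad = unname(colSums(NUM / S)))
}

#' Fit a mixed logit model by simulated maximum likelihood
#'
#' Maximizes the simulated log-likelihood
#' `sum_i log( (1/R) sum_r prod_t P(choice_it | beta + sigma o z_ir) )`
#' over the mean coefficients, the normal random-deviation spreads and the
#' opt-out constant, with `z_ir` from per-respondent blocks of a Halton
#' sequence mapped through the standard normal quantile. Random-deviation
#' spreads are reported as absolute values (their sign is unidentified).
#' Standard errors come from the inverse observed information, computed by
#' central differences of the analytic score.
#'
#' @inheritParams fit_mnl
#' @param spec A [mixlogit_spec()].
#' @param start Optional named start values; defaults to the MNL estimates
#'   with small positive spreads.
#' @param std_errors Compute standard errors (default TRUE; skipping saves
#'   one Hessian evaluation).
#' @return A `mixlogit_fit` object.
#' @export
fit_mixed_logit <- function(data, spec = mixlogit_spec(), terms = NULL,
                            start = NULL, std_errors = TRUE) {
  cd <- build_coded_data(data, terms)
  check_design_matrix(cd)
  K <- length(cd$terms)
  random <- spec$random %||% cd$terms
  bad <- setdiff(random, cd$terms)
  if (length(bad)) {
    abort_dce(paste("unknown random coefficient(s):",
                    paste(bad, collapse = ", ")), "invalid_spec")
  }
  spec$random <- random
  rand_idx <- match(random, cd$terms)
  Kr <- length(rand_idx)
  npar <- K + Kr + cd$has_optout

  if (Kr == 0) {
    mnl <- fit_mnl(data, terms = terms, tol = spec$tol,
                   max_iterations = spec$max_iterations)
    mnl$model <- "mixed"
    mnl$spec <- spec
    mnl$n_draws <- spec$n_draws
    return(mnl)
  }

  R <- spec$n_draws
  H <- halton_sequence(cd$n_resp * R, Kr, skip = spec$halton_skip)
  Z <- stats::qnorm(H)
  # respondent i owns rows ((i-1)R+1):(iR); draw r takes row (i-1)R + r
  Z_list <- lapply(seq_len(R), function(r) {
    Z[(seq_len(cd$n_resp) - 1L) * R + r, , drop = FALSE]
  })

  if (is.null(start)) {
    mnl <- suppressWarnings(fit_mnl(data, terms = terms, tol = spec$tol))
    start <- c(unname(mnl$beta_mean), rep(0.1, Kr),
               if (cd$has_optout) mnl$opt_out_constant)
  }
  if (length(start) != npar) {
    abort_dce("start vector has the wrong length", "invalid_spec")
  }

  cache <- new.env(parent = emptyenv())
  eval_at <- function(th) {
    if (!is.null(cache$par) && identical(cache$par, th)) return(cache$res)
    res <- sml_ll_grad(th, cd, Z_list, rand_idx)
    cache$par <- th
    cache$res <- res
    res
  }
  fn <- function(th) -eval_at(th)$ll
  gr <- function(th) -eval_at(th)$grad
  # BFGS with cold restarts: a fresh Hessian approximation from the current
  # optimum often finishes the last stretch to the gradient tolerance
  opt <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(maxit = spec$max_iterations,
                                     reltol = 1e-12))
  res <- sml_ll_grad(opt$par, cd, Z_list, rand_idx)

  num_hessian <- function(par) {
    Hm <- matrix(0, npar, npar)
    h <- 1e-4 * pmax(abs(par), 1)
    for (j in seq_len(npar)) {
      up <- dn <- par
      up[j] <- up[j] + h[j]
      dn[j] <- dn[j] - h[j]
      Hm[, j] <- (sml_ll_grad(up, cd, Z_list, rand_idx)$grad -
                    sml_ll_grad(dn, cd, Z_list, rand_idx)$grad) / (2 * h[j])
    }
    (Hm + t(Hm)) / 2
  }

  for (restart in 1:2) {
    if (max(abs(res$grad)) < spec$tol) break
    opt2 <- stats::optim(opt$par, fn, gr, method = "BFGS",
                         control = list(maxit = spec$max_iterations,
                                        reltol = 1e-12))
    res2 <- sml_ll_grad(opt2$par, cd, Z_list, rand_idx)
    no_progress <- res2$ll - res$ll < 1e-9
    better_grad <- max(abs(res2$grad)) < max(abs(res$grad))
    if (res2$ll >= res$ll - 1e-9 && (better_grad || !no_progress)) {
      opt <- opt2
      res <- res2
    }
    if (no_progress && !better_grad) break
  }

  # Newton polish: the numerical Hessian of the simulated log-likelihood
  # finishes the last stretch to the gradient tolerance
  Hm <- NULL
  if (max(abs(res$grad)) >= spec$tol) {
    Hm <- num_hessian(opt$par)
    moved <- FALSE
    for (it in 1:20) {
      if (max(abs(res$grad)) < spec$tol / 10) break
      step <- tryCatch(solve(Hm, -res$grad), error = function(e) NULL)
      if (is.null(step)) break
      cand <- opt$par + step
      res_cand <- sml_ll_grad(cand, cd, Z_list, rand_idx)
      halvings <- 0
      while (res_cand$ll < res$ll && halvings < 10) {
        step <- step / 2
        cand <- opt$par + step
        res_cand <- sml_ll_grad(cand, cd, Z_list, rand_idx)
        halvings <- halvings + 1
      }
      if (res_cand$ll < res$ll) break
      moved <- TRUE
      opt$par <- cand
      res <- res_cand
    }
    if (moved) Hm <- NULL  # stale: recompute at the final point if needed
  }

  converged <- max(abs(res$grad)) < spec$tol
  if (!converged) {
    warning(sprintf(
      "mixed logit gradient norm %.2e above tolerance %.0e",
      max(abs(res$grad)), spec$tol), call. = FALSE)
  }
  vc <- NULL
  if (std_errors) {
    if (is.null(Hm)) Hm <- num_hessian(opt$par)
    vc <- tryCatch(solve(-Hm), error = function(e) NULL)
    if (!is.null(vc) && any(diag(vc) < 0)) {
      # keep the well-determined entries; flag only the flat directions
      bad <- diag(vc) < 0
      vc[bad, ] <- NA_real_
      vc[, bad] <- NA_real_
    }
  }
  new_mixlogit_fit("mixed", cd, opt$par, res$ll, res$grad, vc, spec,
                   converged)
}

#' Subsample stability of the model estimates
#'
#' Refits the model on progressively larger prefixes of the respondent list
#' ("first" = ascending respondent id) and reports the maximum absolute
#' coefficient change between successive cuts — a post hoc check that the
#' sample was large enough for stable estimation.
#'
#' @inheritParams fit_mnl
#' @param spec A [mixlogit_spec()] (used when `engine = "mixed"`).
#' @param cut_points Ascending integer vector of prefix sizes (e.g.
#'   `c(500, 1000, 1500, n)`); each must not exceed the number of
#'   respondents.
#' @param engine `"mixed"` (default) or `"mnl"` for a fast fixed-coefficient
#'   check.
#' @return An object of class `stability_curve`: a list with `coefficients`
#'   (tibble: cut, term, type, estimate, std_error), `changes` (tibble:
#'   cut_from, cut_to, max_abs_change) and `fits`.
#' @export
stability_curve <- function(data, cut_points, spec = mixlogit_spec(),
                            engine = c("mixed", "mnl"), terms = NULL) {
  engine <- match.arg(engine)
  ids <- sort(unique(data$respondent_id))
  if (is.unsorted(cut_points, strictly = TRUE)) {
    abort_dce("cut_points must be strictly ascending", "invalid_spec")
  }
  if (max(cut_points) > length(ids)) {
    abort_dce(sprintf("cut point %d exceeds the %d respondents",
                      max(cut_points), length(ids)), "invalid_spec")
  }
  fits <- lapply(cut_points, function(k) {
    sub <- data[data$respondent_id %in% ids[seq_len(k)], ]
    if (engine == "mnl") fit_mnl(sub, terms = terms)
    else fit_mixed_logit(sub, spec, terms = terms, std_errors = FALSE)
  })
  coefs <- dplyr::bind_rows(lapply(seq_along(cut_points), function(i) {
    dplyr::mutate(fits[[i]]$coefficients, cut = cut_points[i],
                  .before = 1)
  }))
  changes <- if (length(cut_points) > 1) {
    tibble::tibble(
      cut_from = cut_points[-length(cut_points)],
      cut_to = cut_points[-1],
      max_abs_change = vapply(seq_len(length(cut_points) - 1), function(i) {
        max(abs(fits[[i + 1]]$coefficients$estimate -
                  fits[[i]]$coefficients$estimate))
      }, numeric(1))
    )
  } else {
    tibble::tibble(cut_from = integer(), cut_to = integer(),
                   max_abs_change = numeric())
  }
  structure(list(coefficients = coefs, changes = changes, fits = fits),
            class = "stability_curve")
}
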