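#' Hyperbolic subjective value
#'
#' The subjective value of a reward of size `amount` delivered after
#' `delay` days under hyperbolic discounting with rate `k` per day:
#' `SV = A / (1 + k * D)`. At `delay = 0` or `k = 0` the reward is
#' undiscounted. All arguments are vectorized and recycled.
#'
#' @param amount Reward amount (> 0), in currency units (KRW here).
#' @param delay Delay in days (>= 0).
#' @param k Discount rate per day (>= 0); larger `k` means steeper
#'   devaluation of delayed rewards.
#' @return Subjective value on the scale of `amount`.
#' @examples
#' subjective_value(10000, 0, 0.017)        # 10000
#' subjective_value(45000, 62, 3.5 / 62)    # 10000: the indifference point
#' @export
subjective_value <- function(amount, delay, k) {
  if (any(amount <= 0) || any(delay < 0) || any(k < 0)) {
    stop("domain error: require amount > 0, delay >= 0, k >= 0", call. = FALSE)
  }
  amount / (1 + k * delay)
}

#' Logistic (softmax) choice probability
#'
#' Probability of choosing the delayed option given the two subjective
#' values: `P1 = 1 / (1 + exp(-beta * (sv_delayed - sv_immediate)))`.
#' `beta` is the inverse temperature: `beta = 0` gives indifferent (0.5)
#' choice regardless of the values; large `beta` makes choice nearly
#' deterministic in the sign of the value difference.
#'
#' @param sv_delayed,sv_immediate Subjective values of the two options.
#' @param beta Inverse-temperature scaling (>= 0).
#' @return Probability of choosing the delayed option, in (0, 1).
#' @export
choice_probability <- function(sv_delayed, sv_immediate, beta) {
  if (any(beta < 0)) stop("domain error: beta must be >= 0", call. = FALSE)
  stats::plogis(beta * (sv_delayed - sv_immediate))
}

#' Negative log-likelihood of a choice record
#'
#' Bernoulli negative log-likelihood of one subject's binary choices over a
#' trial set under the hyperbolic-value / logistic-choice model. Choice
#' probabilities are clamped to `[eps, 1 - eps]` inside the logs so that a
#' deterministic responder never produces an infinite likelihood.
#'
#' @param k Discount rate per day (>= 0).
#' @param beta Inverse temperature (>= 0).
#' @param choices 0/1 vector aligned to `trials` rows; 1 = delayed chosen.
#' @param trials A `trial_set` (see [generate_trial_set()]).
#' @param eps Probability floor inside the logs (default 1e-12).
#' @return The negative log-likelihood (>= 0).
#' @export
dd_negloglik <- function(k, beta, choices, trials, eps = 1e-12) {
  if (length(choices) != nrow(trials)) {
    stop(sprintf("choices (%d) and trials (%d) are misaligned",
                 length(choices), nrow(trials)), call. = FALSE)
  }
  if (anyNA(choices) || !all(choices %in% c(0, 1))) {
    stop("choices must be 0/1 with no missing entries", call. = FALSE)
  }
  sv1 <- subjective_value(trials$delayed_amount, trials$delay_days, k)
  p1 <- choice_probability(sv1, trials$immediate_amount, beta)
  p1 <- pmin(pmax(p1, eps), 1 - eps)
  -sum(choices * log(p1) + (1 - choices) * log1p(-p1))
}

#' Fitting configuration for the delay-discounting model
#'
#' Both parameters are optimized on the log10 scale for positivity and
#' conditioning. The search is a deterministic coarse grid of starting
#' points followed by bounded local refinement (L-BFGS-B) from the best
#' starts; no randomness enters the fit. `beta` multiplies KRW-scale value
#' differences, so plausible values are small — hence the default bounds.
#'
#' @param log10k_bounds Search bounds for log10(k) (default c(-5, 0)).
#' @param log10beta_bounds Search bounds for log10(beta) (default c(-6, 0)).
#' @param n_starts Grid starts per dimension (default c(7, 7)).
#' @param n_refine How many of the best grid starts get local refinement.
#' @param eps Probability floor passed to [dd_negloglik()].
#' @param boundary_tol Distance (log10 units) from a bound below which the
#'   optimum is flagged as a boundary solution.
#' @return A `dd_fit_config` list.
#' @export
dd_fit_config <- function(log10k_bounds = c(-5, 0), log10beta_bounds = c(-6, 0),
                          n_starts = c(7L, 7L), n_refine = 3L,
                          eps = 1e-12, boundary_tol = 1e-4) {
  stopifnot(length(log10k_bounds) == 2L, diff(log10k_bounds) > 0,
            length(log10beta_bounds) == 2L, diff(log10beta_bounds) > 0,
            all(n_starts >= 2L), n_refine >= 1L, eps > 0, boundary_tol > 0)
  structure(list(log10k_bounds = log10k_bounds,
                 log10beta_bounds = log10beta_bounds,
                 n_starts = as.integer(n_starts), n_refine = as.integer(n_refine),
                 eps = eps, boundary_tol = boundary_tol),
            class = "dd_fit_config")
}

#' Fit the hyperbolic model to one subject by maximum likelihood
#'
#' Minimizes [dd_negloglik()] jointly over (log10 k, log10 beta) with a
#' deterministic multistart: the likelihood is evaluated on a coarse grid of
#' starting points, and the best `n_refine` starts are refined with bounded
#' L-BFGS-B. Degenerate responders (e.g. a subject who always takes the
#' immediate option) have no interior optimum in `k`; such fits return the
#' bound value with `boundary_flag` set rather than erroring.
#'
#' @param choices 0/1 vector aligned to `trials`; 1 = delayed chosen.
#' @param trials A `trial_set`.
#' @param config A [dd_fit_config()].
#' @return A `dd_params` list: `k`, `beta`, `log10_k`, `log10_beta`, `nll`,
#'   `converged`, and `boundary_flag` (one of `"none"`, `"k_low"`,
#'   `"k_high"`, `"beta_low"`, `"beta_high"`).
#' @export
fit_dd_subject <- function(choices, trials, config = dd_fit_config()) {
  stopifnot(inherits(config, "dd_fit_config"))
  if (length(choices) != nrow(trials)) {
    stop("choices and trials are misaligned", call. = FALSE)
  }
  lo <- c(config$log10k_bounds[1], config$log10beta_bounds[1])
  hi <- c(config$log10k_bounds[2], config$log10beta_bounds[2])
  obj <- function(par) {
    dd_negloglik(10^par[1], 10^par[2], choices, trials, eps = config$eps)
  }

  starts <- expand.grid(
    lk = seq(lo[1], hi[1], length.out = config$n_starts[1]),
    lb = seq(lo[2], hi[2], length.out = config$n_starts[2]),
    KEEP.OUT.ATTRS = FALSE)
  grid_nll <- vapply(seq_len(nrow(starts)),
                     function(i) obj(c(starts$lk[i], starts$lb[i])), numeric(1))
  keep <- order(grid_nll)[seq_len(min(config$n_refine, nrow(starts)))]

  best <- NULL
  for (i in keep) {
    fit <- tryCatch(
      stats::optim(c(starts$lk[i], starts$lb[i]), obj, method = "L-BFGS-B",
                   lower = lo, upper = hi),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    # fall back to the best grid point; can happen only if every local
    # refinement failed numerically
    i <- keep[1]
    best <- list(par = c(starts$lk[i], starts$lb[i]),
                 value = grid_nll[i], convergence = 1L)
  }

  par <- pmin(pmax(best$par, lo), hi)
  # flat-likelihood tie-break: a separable (noiseless) responder saturates
  # the likelihood, whose supremum then lies at the beta bound; report the
  # bound rather than wherever the optimizer happened to stop
  if (par[2] < hi[2] && obj(c(par[1], hi[2])) <= best$value + 1e-8) {
    par[2] <- hi[2]
    best$value <- obj(par)
  }
  flag <- "none"
  tol <- config$boundary_tol
  if (par[1] - lo[1] <= tol) flag <- "k_low"
  else if (hi[1] - par[1] <= tol) flag <- "k_high"
  else if (par[2] - lo[2] <= tol) flag <- "beta_low"
  else if (hi[2] - par[2] <= tol) flag <- "beta_high"

  structure(list(
    k = 10^par[1], beta = 10^par[2],
    log10_k = par[1], log10_beta = par[2],
    nll = best$value,
    converged = identical(best$convergence, 0L),
    boundary_flag = flag,
    n_trials = nrow(trials)
  ), class = "dd_params")
}

#' Fit the delay-discounting model for every subject in a cohort
#'
#' @param choices_df Long-format choice records: columns `subject_id`,
#'   `trial_id`, `choice` (0/1, 1 = delayed chosen), one row per subject
#'   and trial.
#' @param trials A `trial_set`; every subject must cover exactly its trials.
#' @param config A [dd_fit_config()].
#' @return A data frame with one row per subject: `subject_id`, `k`,
#'   `log10_k`, `beta`, `nll`, `converged`, `boundary_flag`.
#' @export
fit_dd_cohort <- function(choices_df, trials, config = dd_fit_config()) {
  needed <- c("subject_id", "trial_id", "choice")
  if (!all(needed %in% names(choices_df))) {
    stop("choices_df needs columns subject_id, trial_id, choice", call. = FALSE)
  }
  ids <- unique(choices_df$subject_id)
  rows <- lapply(ids, function(sid) {
    sub <- choices_df[choices_df$subject_id == sid, , drop = FALSE]
    m <- match(trials$trial_id, sub$trial_id)
    if (anyNA(m) || nrow(sub) != nrow(trials)) {
      stop(sprintf("subject %s does not cover the trial set exactly", sid),
           call. = FALSE)
    }
    fit <- fit_dd_subject(sub$choice[m], trials, config)
    data.frame(subject_id = sid, k = fit$k, log10_k = fit$log10_k,
               beta = fit$beta, nll = fit$nll, converged = fit$converged,
               boundary_flag = fit$boundary_flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.dd_params <- function(x, ...) {
  cat("Hyperbolic delay-discounting fit\n")
  cat(sprintf("  k = %.5g per day (log10 k = %.3f), beta = %.3g\n",
              x$k, x$log10_k, x$beta))
  cat(sprintf("  nll = %.3f over %d trials; converged: %s; boundary: %s\n",
              x$nll, x$n_trials, x$converged, x$boundary_flag))
  invisible(x)
}
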