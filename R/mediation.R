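#' Specify a three-variable mediation model
#'
#' Names the independent variable X, mediator M, outcome Y and the
#' covariates that enter all three regressions identically. Entering the
#' covariates identically in every equation is what makes the linear
#' decomposition `c = c' + a*b` an exact algebraic identity of nested
#' least squares.
#'
#' @param x,m,y Column names of the independent variable, mediator and
#'   outcome in the cohort table.
#' @param covariates Character vector of covariate column names; must not
#'   include `x`, `m` or `y`.
#' @return A `mediation_design` list.
#' @export
mediation_design <- function(x = "reappraisal", m = "vs_gmv", y = "log10_k",
                             covariates = c("age", "sex", "handedness",
                                            "education_years", "tiv")) {
  vars <- c(x, m, y)
  if (anyDuplicated(vars)) stop("x, m and y must be distinct", call. = FALSE)
  if (length(intersect(covariates, vars))) {
    stop("covariates must exclude x, m and y", call. = FALSE)
  }
  structure(list(x = x, m = m, y = y, covariates = covariates),
            class = "mediation_design")
}

# complete-case model matrices shared by the point fit and the bootstrap.
# Covariate columns are centred and scaled once for conditioning (path
# coefficients on X and M are unaffected; only the intercept changes).
mediation_matrices <- function(table, design) {
  stopifnot(inherits(design, "mediation_design"))
  need <- c(design$x, design$m, design$y, design$covariates)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("columns not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- table[need]
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  n <- nrow(dat)
  x <- as.numeric(dat[[design$x]])
  m <- as.numeric(dat[[design$m]])
  y <- as.numeric(dat[[design$y]])
  cmat <- NULL
  if (length(design$covariates)) {
    cmat <- scale(as.matrix(dat[design$covariates]))
    if (any(!is.finite(cmat))) {
      stop("constant covariate column(s): ",
           paste(design$covariates[apply(!is.finite(cmat), 2, any)],
                 collapse = ", "), call. = FALSE)
    }
    attr(cmat, "scaled:center") <- NULL
    attr(cmat, "scaled:scale") <- NULL
  }
  xa <- cbind(`(intercept)` = 1, x = x, cmat)           # M ~ 1 + X + C; Y ~ 1 + X + C
  xb <- cbind(`(intercept)` = 1, x = x, m = m, cmat)    # Y ~ 1 + X + M + C
  if (n <= ncol(xb)) {
    stop(sprintf("too few complete cases (n = %d) for %d parameters",
                 n, ncol(xb)), call. = FALSE)
  }
  check_full_rank(xb)
  list(xa = xa, xb = xb, m = m, y = y, n = n, n_dropped = sum(!cc))
}

# all five path coefficients from a row subset; NULL if rank deficient
paths_from_index <- function(mm, idx) {
  qa <- qr(mm$xa[idx, , drop = FALSE])
  if (qa$rank < ncol(mm$xa)) return(NULL)
  qb <- qr(mm$xb[idx, , drop = FALSE])
  if (qb$rank < ncol(mm$xb)) return(NULL)
  ac <- qr.coef(qa, cbind(mm$m[idx], mm$y[idx]))  # columns: a-model, c-model
  bb <- qr.coef(qb, mm$y[idx])
  a <- unname(ac[2L, 1L]); cc <- unname(ac[2L, 2L])
  c_prime <- unname(bb[2L]); b <- unname(bb[3L])
  c(a = a, b = b, c = cc, c_prime = c_prime, ab = a * b)
}

#' Fit the mediation path coefficients by least squares
#'
#' Three OLS regressions sharing the covariate set: `M ~ 1 + X + C` gives
#' path `a`; `Y ~ 1 + X + M + C` gives the direct effect `c'` and path
#' `b`; `Y ~ 1 + X + C` gives the total effect `c`. The indirect effect is
#' `ab = a * b`, and `c = c' + a*b` holds exactly. Standard errors are the
#' usual analytic least-squares ones; the SE of `ab` is the first-order
#' (Sobel) delta-method value — bootstrap inference on `ab` is provided by
#' [bootstrap_mediation()].
#'
#' @param table Per-subject cohort table (complete cases are used).
#' @param design A [mediation_design()].
#' @return A `mediation_paths` list with elements `a`, `b`, `c`, `c_prime`,
#'   `ab`, their standard errors `se_*`, two-sided p-values `p_*` (t for
#'   the regression paths, Sobel normal approximation for `ab`), `n`,
#'   `n_dropped` and `covariate_names`.
#' @export
fit_mediation_paths <- function(table, design = mediation_design()) {
  mm <- mediation_matrices(table, design)
  fit_a <- stats::lm.fit(mm$xa, mm$m)
  fit_b <- stats::lm.fit(mm$xb, mm$y)
  fit_c <- stats::lm.fit(mm$xa, mm$y)

  coef_se <- function(fit, X) {
    rdf <- nrow(X) - ncol(X)
    s2 <- sum(fit$residuals^2) / rdf
    ord <- order(fit$qr$pivot)
    xtx_inv <- chol2inv(qr.R(fit$qr))[ord, ord, drop = FALSE]
    se <- sqrt(diag(xtx_inv) * s2)
    tval <- fit$coefficients / se
    list(se = se, p = 2 * stats::pt(abs(tval), rdf, lower.tail = FALSE))
  }
  sa <- coef_se(fit_a, mm$xa)
  sb <- coef_se(fit_b, mm$xb)
  sc <- coef_se(fit_c, mm$xa)

  a <- unname(fit_a$coefficients[2L])
  c_prime <- unname(fit_b$coefficients[2L])
  b <- unname(fit_b$coefficients[3L])
  cval <- unname(fit_c$coefficients[2L])
  ab <- a * b
  se_a <- sa$se[2L]; se_b <- sb$se[3L]
  se_ab <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)

  # exact property of nested OLS with a shared covariate set; a violation
  # beyond rounding indicates a broken design matrix
  scale_ref <- max(1, abs(cval), abs(c_prime) + abs(ab))
  stopifnot(abs(cval - (c_prime + ab)) <= 1e-8 * scale_ref)

  structure(list(
    a = a, b = b, c = cval, c_prime = c_prime, ab = ab,
    se_a = se_a, se_b = se_b, se_c = sc$se[2L], se_c_prime = sb$se[2L],
    se_ab = se_ab,
    p_a = sa$p[2L], p_b = sb$p[3L], p_c = sc$p[2L], p_c_prime = sb$p[2L],
    p_ab = 2 * stats::pnorm(abs(ab) / se_ab, lower.tail = FALSE),
    n = mm$n, n_dropped = mm$n_dropped,
    covariate_names = design$covariates
  ), class = "mediation_paths")
}

#' Bootstrap mediation analysis
#'
#' Case-resampling bootstrap for the covariate-adjusted mediation model:
#' whole subject rows are resampled with replacement `n_boot` times and all
#' five paths are recomputed per resample. The indirect-effect confidence
#' interval is the percentile interval by default (bias-corrected and
#' accelerated available via `ci_type = "bca"`). Two-sided bootstrap
#' p-values use the resample distribution's sign frequencies with the
#' small-sample (r+1)/(B+1) continuity correction:
#' `p = 2 * min((#{<=0}+1), (#{>=0}+1)) / (B+1)`, capped at 1.
#'
#' Rank-deficient resamples (possible when a binary covariate collapses to
#' one level) are redrawn; the redraw count is reported and more than 1% of
#' redraws triggers a warning. Given the same table, design and seed the
#' result is reproducible bit for bit.
#'
#' @param table Per-subject cohort table.
#' @param design A [mediation_design()].
#' @param n_boot Number of bootstrap resamples (>= 1000).
#' @param seed Integer RNG seed (required).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param ci_type `"percentile"` (default) or `"bca"`.
#' @return A `mediation_result` list: point estimates `a`, `b`, `c`,
#'   `c_prime`, `ab`; bootstrap standard errors `se_*`; `ci_ab`; bootstrap
#'   p-values `p_*`; `n`, `n_boot`, `seed`, `n_redraws`, `ci_type`,
#'   `conf_level`, `covariate_names`; and the resample draws in `boot`
#'   (an `n_boot` x 5 matrix).
#' @export
bootstrap_mediation <- function(table, design = mediation_design(),
                                n_boot = 10000L, seed,
                                conf_level = 0.95,
                                ci_type = c("percentile", "bca")) {
  ci_type <- match.arg(ci_type)
  if (missing(seed)) stop("a seed is required for the bootstrap", call. = FALSE)
  if (n_boot < 1000L) stop("n_boot must be at least 1000", call. = FALSE)

  mm <- mediation_matrices(table, design)
  point <- fit_mediation_paths(table, design)
  n <- mm$n

  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, nrow = n_boot, ncol = 5L,
                  dimnames = list(NULL, c("a", "b", "c", "c_prime", "ab")))
  n_redraws <- 0L
  for (i in seq_len(n_boot)) {
    repeat {
      est <- paths_from_index(mm, sample.int(n, n, replace = TRUE))
      if (!is.null(est)) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > 100L * n_boot) {
        stop("bootstrap cannot find full-rank resamples", call. = FALSE)
      }
    }
    draws[i, ] <- est
  }
  if (n_redraws > 0.01 * n_boot) {
    warning(sprintf("%d rank-deficient resamples redrawn (> 1%% of n_boot)",
                    n_redraws))
  }

  boot_p <- function(th) {
    min(1, 2 * min(sum(th <= 0) + 1, sum(th >= 0) + 1) / (length(th) + 1))
  }
  alpha2 <- (1 - conf_level) / 2
  if (ci_type == "percentile") {
    ci_ab <- unname(stats::quantile(draws[, "ab"], c(alpha2, 1 - alpha2)))
  } else {
    ci_ab <- bca_interval(draws[, "ab"], point$ab, conf_level,
                          function(idx) paths_from_index(mm, idx)[["ab"]], n)
  }

  structure(list(
    a = point$a, b = point$b, c = point$c, c_prime = point$c_prime,
    ab = point$ab,
    se_a = stats::sd(draws[, "a"]), se_b = stats::sd(draws[, "b"]),
    se_c = stats::sd(draws[, "c"]), se_c_prime = stats::sd(draws[, "c_prime"]),
    se_ab = stats::sd(draws[, "ab"]),
    ci_ab = ci_ab,
    p_a = boot_p(draws[, "a"]), p_b = boot_p(draws[, "b"]),
    p_c = boot_p(draws[, "c"]), p_c_prime = boot_p(draws[, "c_prime"]),
    p_ab = boot_p(draws[, "ab"]),
    n = n, n_dropped = mm$n_dropped, n_boot = as.integer(n_boot),
    seed = as.integer(seed), n_redraws = n_redraws,
    ci_type = ci_type, conf_level = conf_level,
    covariate_names = design$covariates,
    boot = draws
  ), class = "mediation_result")
}

# BCa interval: jackknife acceleration, bias correction from the resample
# distribution's position relative to the point estimate
bca_interval <- function(th_boot, th_hat, conf_level, stat_fn, n) {
  alpha2 <- (1 - conf_level) / 2
  prop <- mean(th_boot < th_hat)
  prop <- min(max(prop, 1 / (length(th_boot) + 1)),
              1 - 1 / (length(th_boot) + 1))
  z0 <- stats::qnorm(prop)
  jack <- vapply(seq_len(n), function(i) stat_fn(setdiff(seq_len(n), i)),
                 numeric(1))
  d <- mean(jack) - jack
  accel <- sum(d^3) / (6 * (sum(d^2))^1.5)
  if (!is.finite(accel)) accel <- 0
  adj <- function(a) {
    z <- z0 + stats::qnorm(a)
    stats::pnorm(z0 + z / (1 - accel * z))
  }
  unname(stats::quantile(th_boot, c(adj(alpha2), adj(1 - alpha2))))
}

#' Classify a mediation result
#'
#' Pattern classification of a fitted [bootstrap_mediation()] result at
#' level `alpha`: `"full-pattern"` when the indirect effect is significant,
#' the direct effect is not, and the total effect is; `"partial"` when both
#' the indirect and direct effects are significant; `"none"` otherwise.
#' The returned object always carries a non-causal framing note — with
#' cross-sectional data these labels describe a statistical pattern, not a
#' causal mechanism.
#'
#' @param result A `mediation_result` (or any list with `p_ab`,
#'   `p_c_prime`, `p_c`).
#' @param alpha Significance level (default 0.05).
#' @return A `mediation_class` list: `label`, `alpha`, `note`.
#' @export
classify_mediation <- function(result, alpha = 0.05) {
  label <- if (result$p_ab < alpha && result$p_c_prime >= alpha &&
               result$p_c < alpha) {
    "full-pattern"
  } else if (result$p_ab < alpha && result$p_c_prime < alpha) {
    "partial"
  } else {
    "none"
  }
  structure(list(
    label = label, alpha = alpha,
    note = "statistical pattern only; cross-sectional data cannot establish causal mediation"
  ), class = "mediation_class")
}

#' @export
print.mediation_class <- function(x, ...) {
  cat(sprintf("mediation pattern: %s (alpha = %g)\n  [%s]\n",
              x$label, x$alpha, x$note))
  invisible(x)
}

#' @export
print.mediation_paths <- function(x, ...) {
  cat(sprintf("Mediation path estimates (OLS, n = %d)\n", x$n))
  tab <- data.frame(
    estimate = c(x$a, x$b, x$c, x$c_prime, x$ab),
    se = c(x$se_a, x$se_b, x$se_c, x$se_c_prime, x$se_ab),
    p = c(x$p_a, x$p_b, x$p_c, x$p_c_prime, x$p_ab),
    row.names = c("a (X->M)", "b (M->Y|X)", "c (total)", "c' (direct)",
                  "a*b (indirect)"))
  print(round(tab, 5))
  invisible(x)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap mediation (case resampling, %d resamples, seed %d, n = %d)\n",
    x$n_boot, x$seed, x$n))
  tab <- data.frame(
    estimate = c(x$a, x$b, x$c, x$c_prime, x$ab),
    boot_se = c(x$se_a, x$se_b, x$se_c, x$se_c_prime, x$se_ab),
    boot_p = c(x$p_a, x$p_b, x$p_c, x$p_c_prime, x$p_ab),
    row.names = c("a (X->M)", "b (M->Y|X)", "c (total)", "c' (direct)",
                  "a*b (indirect)"))
  print(round(tab, 5))
  cat(sprintf("  %g%% %s CI for a*b: [%.5g, %.5g]\n", 100 * x$conf_level,
              x$ci_type, x$ci_ab[1], x$ci_ab[2]))
  if (x$n_redraws > 0) cat(sprintf("  rank-deficient resamples redrawn: %d\n",
                                   x$n_redraws))
  invisible(x)
}
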