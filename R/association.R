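#' Covariate-adjusted (partial) Spearman correlation
#'
#' Operationalizes "Spearman correlation controlling for covariates" as:
#' rank-transform `x` and `y` (average ranks for ties), residualize each
#' rank vector on an intercept plus the covariates by least squares, and
#' return the Pearson correlation of the residuals. The two-sided p-value
#' uses the t approximation with `df = n - 2 - q` where `q` is the number
#' of covariate columns. With no covariates this reduces exactly to the
#' plain Spearman rank correlation.
#'
#' The alternative convention — residualize the raw values first, then
#' Spearman-correlate the residuals — is available via
#' `method = "residual-rank"` for sensitivity analysis.
#'
#' An optional permutation p-value (`n_perm > 0`) permutes the residualized
#' `y` ranks under a caller-supplied seed and reports the proportion of
#' permuted |rho| at least as large as observed, with the (r+1)/(B+1)
#' correction; it serves as a cross-check on the t approximation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional numeric matrix/data frame of covariates (one
#'   row per observation); must be full rank together with an intercept.
#' @param method `"rank-residual"` (default, partial Spearman) or
#'   `"residual-rank"`.
#' @param n_perm Number of permutations for the optional permutation
#'   p-value (0 = skip).
#' @param perm_seed Seed used when `n_perm > 0`.
#' @return A `partial_spearman` list: `rho`, `p`, `statistic` (t), `df`,
#'   `n`, `n_covariates`, `method`, and `p_perm` (NA unless requested).
#' @export
partial_spearman <- function(x, y, covariates = NULL,
                             method = c("rank-residual", "residual-rank"),
                             n_perm = 0L, perm_seed = 1L) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y", call. = FALSE)

  cmat <- NULL
  if (!is.null(covariates) && NCOL(covariates) > 0L) {
    cmat <- as.matrix(covariates)
    if (nrow(cmat) != n) stop("covariates must have one row per observation",
                              call. = FALSE)
    if (is.null(colnames(cmat))) colnames(cmat) <- paste0("covar_", seq_len(ncol(cmat)))
    check_full_rank(cbind(`(intercept)` = 1, cmat))
  }
  q <- if (is.null(cmat)) 0L else ncol(cmat)
  if (n < 4L + q) stop("too few observations for the requested adjustment",
                       call. = FALSE)

  resid_pair <- function(a, b) {
    if (is.null(cmat)) return(list(a = a - mean(a), b = b - mean(b)))
    xx <- cbind(1, cmat)
    fit <- stats::lm.fit(xx, cbind(a, b))
    list(a = fit$residuals[, 1L], b = fit$residuals[, 2L])
  }

  if (method == "rank-residual") {
    res <- resid_pair(rank(x), rank(y))
  } else {
    raw <- resid_pair(x, y)
    res <- list(a = rank(raw$a), b = rank(raw$b))
    res$a <- res$a - mean(res$a); res$b <- res$b - mean(res$b)
  }
  rho <- stats::cor(res$a, res$b)
  df <- n - 2L - q
  tval <- if (abs(rho) >= 1) sign(rho) * Inf else rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)

  p_perm <- NA_real_
  if (n_perm > 0L) {
    set.seed(perm_seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      r_perm <- stats::cor(res$a, res$b[sample.int(n)])
      if (abs(r_perm) >= abs(rho)) hits <- hits + 1L
    }
    p_perm <- (hits + 1) / (n_perm + 1)
  }

  structure(list(rho = rho, p = p, statistic = tval, df = df, n = n,
                 n_covariates = q, method = method, p_perm = p_perm),
            class = "partial_spearman")
}

# error names the collinear columns, via pivoted QR
check_full_rank <- function(m) {
  qr_m <- qr(m)
  if (qr_m$rank < ncol(m)) {
    dropped <- colnames(m)[qr_m$pivot[(qr_m$rank + 1L):ncol(m)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(qr_m$rank)
}

#' @export
print.partial_spearman <- function(x, ...) {
  lab <- if (x$n_covariates > 0)
    sprintf("partial Spearman (adjusting for %d covariate(s))", x$n_covariates)
  else "Spearman rank correlation"
  cat(sprintf("%s\n  rho = %.4f, t = %.3f, df = %d, p = %.4g, n = %d\n",
              lab, x$rho, x$statistic, x$df, x$p, x$n))
  if (!is.na(x$p_perm)) cat(sprintf("  permutation p = %.4g\n", x$p_perm))
  invisible(x)
}

#' Cohort descriptive statistics
#'
#' Means and standard deviations (n-1 denominator) of the analysis columns
#' of a per-subject cohort table. Defaults to the discounting, score and
#' covariate columns when present.
#'
#' @param table Per-subject data frame.
#' @param columns Columns to summarize; defaults to the intersection of the
#'   standard analysis columns with `names(table)`.
#' @return A data frame: `variable`, `mean`, `sd`, `n`.
#' @export
describe_cohort <- function(table, columns = NULL) {
  if (!nrow(table)) stop("empty cohort table", call. = FALSE)
  if (is.null(columns)) {
    columns <- intersect(
      c("k", "log10_k", "reappraisal", "suppression", "vs_gmv",
        "age", "sex", "handedness", "education_years", "tiv"),
      names(table))
  }
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols)) {
    stop("columns not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    variable = columns,
    mean = vapply(columns, function(cl) mean(table[[cl]]), numeric(1)),
    sd = vapply(columns, function(cl) stats::sd(table[[cl]]), numeric(1)),
    n = nrow(table),
    row.names = NULL, stringsAsFactors = FALSE)
}
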