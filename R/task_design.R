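#' Generate the fixed intertemporal-choice trial menu
#'
#' Builds the factorial amount-by-delay grid of binary intertemporal choices
#' that every subject faces: a fixed immediate reward of 10,000 KRW against a
#' larger delayed reward. Delayed amounts are evenly spaced (rounded to whole
#' KRW) over `amount_range`; delays are approximately log-spaced integer days
#' over `delay_range` (rounded, deduplicated, then re-padded so the requested
#' number of distinct delays is preserved). Log spacing is used because the
#' hyperbolic discount curve is better constrained by delays that are dense
#' near zero and sparse at the horizon.
#'
#' Generation is a pure function of its arguments: two calls with identical
#' arguments return identical trial sets.
#'
#' @param n_amounts Number of distinct delayed amounts (default 12).
#' @param n_delays Number of distinct delays (default 10).
#' @param amount_range Length-2 numeric, inclusive bounds for the delayed
#'   amount in KRW; must lie within \[11000, 48000\].
#' @param delay_range Length-2 numeric, inclusive bounds for the delay in
#'   days; must lie within \[2, 180\].
#' @param n_trials Required total trial count; `n_amounts * n_delays` must
#'   equal it (default 120).
#' @return A `trial_set`: a data frame with integer columns `trial_id`,
#'   `immediate_amount`, `delayed_amount`, `delay_days`, ordered by delay then
#'   amount, with contiguous ids starting at 1.
#' @examples
#' ts <- generate_trial_set()
#' nrow(ts)              # 120
#' range(ts$delay_days)  # 2 180
#' @export
generate_trial_set <- function(n_amounts = 12L, n_delays = 10L,
                               amount_range = c(11000, 48000),
                               delay_range = c(2, 180),
                               n_trials = 120L) {
  if (length(n_amounts) != 1L || length(n_delays) != 1L ||
      n_amounts < 1 || n_delays < 1 ||
      n_amounts != round(n_amounts) || n_delays != round(n_delays)) {
    stop("'n_amounts' and 'n_delays' must be positive integers", call. = FALSE)
  }
  if (n_amounts * n_delays != n_trials) {
    stop(sprintf(
      "configuration error: n_amounts * n_delays = %d does not equal the requested trial count %d",
      as.integer(n_amounts * n_delays), as.integer(n_trials)), call. = FALSE)
  }
  check_range(amount_range, c(11000, 48000), "amount_range")
  check_range(delay_range, c(2, 180), "delay_range")

  amounts <- unique(as.integer(floor(
    seq(amount_range[1], amount_range[2], length.out = n_amounts) + 0.5)))
  if (length(amounts) != n_amounts) {
    stop("amount_range too narrow for the requested number of distinct amounts",
         call. = FALSE)
  }
  delays <- log_spaced_days(delay_range[1], delay_range[2], as.integer(n_delays))

  grid <- expand.grid(delayed_amount = amounts, delay_days = delays,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$delay_days, grid$delayed_amount), , drop = FALSE]
  ts <- data.frame(
    trial_id = seq_len(nrow(grid)),
    immediate_amount = 10000L,
    delayed_amount = as.integer(grid$delayed_amount),
    delay_days = as.integer(grid$delay_days)
  )
  class(ts) <- c("trial_set", "data.frame")
  validate_trial_set(ts, n_expected = as.integer(n_trials))
  ts
}

# log-spaced integer days; escalates grid resolution until rounding leaves
# at least n distinct values, then picks n of them evenly (endpoints kept)
log_spaced_days <- function(lo, hi, n) {
  if (n == 1L) return(as.integer(lo))
  m <- n
  repeat {
    cand <- floor(exp(seq(log(lo), log(hi), length.out = m)) + 0.5)
    cand <- sort(unique(pmin(pmax(cand, lo), hi)))
    if (length(cand) >= n) break
    m <- m + 1L
  }
  idx <- floor(seq(1, length(cand), length.out = n) + 0.5)
  as.integer(cand[idx])
}

check_range <- function(x, bounds, name) {
  if (length(x) != 2L || !is.numeric(x) || any(!is.finite(x)) || x[1] > x[2]) {
    stop(sprintf("'%s' must be an increasing numeric pair", name), call. = FALSE)
  }
  if (x[1] < bounds[1] || x[2] > bounds[2]) {
    stop(sprintf("validation error: '%s' must lie within [%g, %g]",
                 name, bounds[1], bounds[2]), call. = FALSE)
  }
  invisible(x)
}

#' Validate a trial set
#'
#' Checks the per-trial invariants (immediate amount fixed at 10,000 KRW,
#' delayed amount in \[11000, 48000\] and strictly larger than the immediate
#' amount, integer delays in \[2, 180\]) and the set-level invariants
#' (unique, contiguous trial ids; expected count when declared). Errors name
#' the first offending row.
#'
#' @param ts A data frame with columns `trial_id`, `immediate_amount`,
#'   `delayed_amount`, `delay_days`.
#' @param n_expected Optional declared trial count.
#' @return `ts`, invisibly reclassed as a `trial_set`, if valid.
#' @export
validate_trial_set <- function(ts, n_expected = NULL) {
  needed <- c("trial_id", "immediate_amount", "delayed_amount", "delay_days")
  missing_cols <- setdiff(needed, names(ts))
  if (length(missing_cols)) {
    stop("parse error: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in needed) {
    if (!is.numeric(ts[[col]]) || anyNA(ts[[col]])) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(ts[[col]]))))[1]
      stop(sprintf("parse error: non-numeric or missing value in column '%s' (row %s)",
                   col, ifelse(is.na(bad), "?", bad)), call. = FALSE)
    }
  }
  if (!is.null(n_expected) && nrow(ts) != n_expected) {
    stop(sprintf("parse error: %d trials found but %d declared",
                 nrow(ts), as.integer(n_expected)), call. = FALSE)
  }
  if (anyDuplicated(ts$trial_id)) {
    stop(sprintf("parse error: duplicate trial_id at row %d",
                 anyDuplicated(ts$trial_id)), call. = FALSE)
  }
  if (!identical(as.integer(sort(ts$trial_id)), seq_len(nrow(ts)))) {
    stop("validation error: trial_id must be contiguous 1..n", call. = FALSE)
  }
  fail <- function(cond, msg) {
    if (any(cond)) {
      stop(sprintf("validation error: %s (row %d)", msg, which(cond)[1]),
           call. = FALSE)
    }
  }
  fail(ts$immediate_amount != 10000, "immediate_amount must be 10000 KRW")
  fail(ts$delayed_amount < 11000 | ts$delayed_amount > 48000,
       "delayed_amount outside [11000, 48000]")
  fail(ts$delayed_amount <= ts$immediate_amount,
       "delayed_amount must exceed immediate_amount")
  fail(ts$delay_days < 2 | ts$delay_days > 180, "delay_days outside [2, 180]")
  fail(ts$delay_days != round(ts$delay_days), "delay_days must be whole days")
  if (!inherits(ts, "trial_set")) class(ts) <- c("trial_set", class(ts))
  invisible(ts)
}

#' Read or write a trial-set CSV
#'
#' The on-disk format is a plain CSV with header
#' `trial_id,immediate_amount,delayed_amount,delay_days`. Writing then
#' reading reproduces the trial set exactly (all columns are integer KRW /
#' integer days).
#'
#' @param path Path to the CSV file.
#' @param n_expected Optional declared trial count checked on read.
#' @return `read_trials()` returns a validated `trial_set`;
#'   `write_trials()` returns `path` invisibly.
#' @export
read_trials <- function(path, n_expected = NULL) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  needed <- c("trial_id", "immediate_amount", "delayed_amount", "delay_days")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("parse error: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- raw[needed]
  for (col in needed) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    if (anyNA(vals)) {
      stop(sprintf("parse error: non-numeric value '%s' in column '%s' (row %d)",
                   out[[col]][which(is.na(vals))[1]], col, which(is.na(vals))[1]),
           call. = FALSE)
    }
    out[[col]] <- as.integer(vals)
  }
  class(out) <- c("trial_set", "data.frame")
  validate_trial_set(out, n_expected = n_expected)
  out
}

#' @param ts A `trial_set`.
#' @rdname read_trials
#' @export
write_trials <- function(ts, path) {
  validate_trial_set(ts)
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Intertemporal-choice trial set: %d trials\n", nrow(x)))
  cat(sprintf("  immediate: %d KRW; delayed: %d-%d KRW; delay: %d-%d days\n",
              x$immediate_amount[1], min(x$delayed_amount), max(x$delayed_amount),
              min(x$delay_days), max(x$delay_days)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more trials\n", nrow(x) - 6L))
  invisible(x)
}
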