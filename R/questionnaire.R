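#' Standard ERQ item-to-subscale assignment
#'
#' The Emotion Regulation Questionnaire has ten items on 7-point Likert
#' scales; six load on cognitive reappraisal and four on expressive
#' suppression. This default is the standard assignment (reappraisal items
#' 1, 3, 5, 7, 8, 10; suppression items 2, 4, 6, 9) and can be overridden
#' when a translated administration orders items differently.
#'
#' @param reappraisal Integer indices of the six reappraisal items.
#' @param suppression Integer indices of the four suppression items.
#' @return A validated list with elements `reappraisal` and `suppression`.
#' @export
erq_item_map <- function(reappraisal = c(1L, 3L, 5L, 7L, 8L, 10L),
                         suppression = c(2L, 4L, 6L, 9L)) {
  reappraisal <- as.integer(reappraisal)
  suppression <- as.integer(suppression)
  if (length(reappraisal) != 6L || length(suppression) != 4L ||
      !setequal(c(reappraisal, suppression), 1:10)) {
    stop("item map must partition items 1..10 into 6 reappraisal + 4 suppression",
         call. = FALSE)
  }
  list(reappraisal = reappraisal, suppression = suppression)
}

#' Score ERQ subscales
#'
#' Sum scoring: each subscale is the sum of its mapped items, giving
#' reappraisal scores in \[6, 42\] and suppression scores in \[4, 28\].
#' Higher scores mean greater habitual use of that regulation strategy.
#' Missing items are an error — no imputation is attempted.
#'
#' @param items A data frame with a `subject_id` column plus item columns
#'   `item_1` .. `item_10`, or a bare 10-column matrix/data frame of item
#'   responses (integers 1-7).
#' @param item_map Item-to-subscale assignment, see [erq_item_map()].
#' @return A data frame: `subject_id`, `reappraisal`, `suppression`.
#' @examples
#' it <- data.frame(subject_id = 1,
#'                  t(c(4, 3, 5, 4, 4, 3, 5, 4, 4, 5)))
#' names(it)[-1] <- paste0("item_", 1:10)
#' score_erq(it)
#' @export
score_erq <- function(items, item_map = erq_item_map()) {
  if ("subject_id" %in% names(items)) {
    ids <- items$subject_id
    mat <- items[paste0("item_", 1:10)]
    if (anyNA(match(paste0("item_", 1:10), names(items)))) {
      stop("expected item columns item_1 .. item_10", call. = FALSE)
    }
  } else {
    if (ncol(items) != 10L) stop("expected exactly 10 item columns", call. = FALSE)
    ids <- seq_len(nrow(items))
    mat <- items
  }
  mat <- as.matrix(mat)
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("missing item response (subject %s, item %d); no imputation is performed",
                 ids[bad[1]], bad[2]), call. = FALSE)
  }
  if (any(mat < 1 | mat > 7) || any(mat != round(mat))) {
    bad <- which(mat < 1 | mat > 7 | mat != round(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("item responses must be integers in 1..7 (subject %s, item %d)",
                 ids[bad[1]], bad[2]), call. = FALSE)
  }
  data.frame(subject_id = ids,
             reappraisal = as.integer(rowSums(mat[, item_map$reappraisal, drop = FALSE])),
             suppression = as.integer(rowSums(mat[, item_map$suppression, drop = FALSE])),
             stringsAsFactors = FALSE)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' `alpha = K/(K-1) * (1 - sum(var(item_i)) / var(total))`, with sample
#' variances (n-1 denominator) throughout. With perfectly correlated items
#' this is exactly 1; with independent items it converges to 0 as the
#' number of subjects grows.
#'
#' @param item_matrix Subjects-by-items numeric matrix or data frame of a
#'   single subscale (>= 2 items, >= 3 subjects).
#' @return The alpha coefficient (a scalar; can be negative for scales
#'   worse than uncorrelated).
#' @export
cronbach_alpha <- function(item_matrix) {
  x <- as.matrix(item_matrix)
  if (ncol(x) < 2L) stop("alpha needs at least 2 items", call. = FALSE)
  if (nrow(x) < 3L) stop("alpha needs at least 3 subjects", call. = FALSE)
  if (anyNA(x)) stop("missing responses in item matrix", call. = FALSE)
  k <- ncol(x)
  total_var <- stats::var(rowSums(x))
  if (total_var == 0) {
    stop("alpha is undefined: total-score variance is zero", call. = FALSE)
  }
  item_vars <- apply(x, 2L, stats::var)
  k / (k - 1) * (1 - sum(item_vars) / total_var)
}
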