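#' Pairwise Pearson correlation table
#'
#' Pairwise-complete Pearson correlations with two-sided p-values from the
#' t distribution on n - 2 degrees of freedom. No multiple-testing
#' correction is applied (these are exploratory associations).
#'
#' @param data data frame of numeric columns.
#' @param rows,cols column names; default all numeric columns for both.
#' @return A `correlation_table` list with matrices `r`, `p`, `n`
#'   (pairwise-complete counts). Constant columns yield `NA` entries.
#' @export
correlation_table <- function(data, rows = NULL, cols = NULL) {
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  rows <- rows %||% num
  cols <- cols %||% num
  miss <- setdiff(c(rows, cols), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  r <- matrix(NA_real_, length(rows), length(cols), dimnames = list(rows, cols))
  p <- r
  nmat <- matrix(NA_integer_, length(rows), length(cols), dimnames = list(rows, cols))
  for (i in seq_along(rows)) {
    for (j in seq_along(cols)) {
      x <- data[[rows[i]]]
      y <- data[[cols[j]]]
      ok <- stats::complete.cases(x, y)
      n <- sum(ok)
      nmat[i, j] <- n
      if (n < 4L) next
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next # constant: flagged NA
      rij <- stats::cor(x[ok], y[ok])
      r[i, j] <- rij
      tstat <- rij * sqrt((n - 2) / max(1e-300, 1 - rij^2))
      p[i, j] <- if (abs(rij) >= 1) 0 else 2 * stats::pt(-abs(tstat), n - 2)
    }
  }
  structure(list(r = r, p = p, n = nmat), class = "correlation_table")
}

#' Two-predictor commonality analysis
#'
#' Partitions the R-squared of the OLS regression of `y` on `{x1, x2}`
#' (with intercept) into the variance unique to each predictor and the
#' variance they share: `unique_x1 = R2_full - R2_x2_only`,
#' `unique_x2 = R2_full - R2_x1_only`,
#' `common = R2_x1_only + R2_x2_only - R2_full`. The three components sum
#' to the full R-squared exactly. Negative common variance (suppression) is
#' reported, not clipped. Percentages are components over the full
#' R-squared.
#'
#' @param y,x1,x2 numeric vectors of equal length (n > 3, finite).
#' @return A `commonality_result` list: `r2_full`, `r2_x1_only`,
#'   `r2_x2_only`, `unique_x1`, `unique_x2`, `common`, `percent_unique_x1`,
#'   `percent_unique_x2`, `percent_common` (NA with
#'   `percents_defined = FALSE` when `r2_full` is 0), `n`.
#' @export
commonality_two_predictors <- function(y, x1, x2) {
  ok <- stats::complete.cases(y, x1, x2)
  y <- y[ok]; x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(y)
  if (n <= 3L) stop("need more than 3 complete observations", call. = FALSE)
  if (!all(is.finite(c(y, x1, x2)))) stop("non-finite values", call. = FALSE)
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0) {
    stop("constant predictor", call. = FALSE)
  }
  if (abs(stats::cor(x1, x2)) > 1 - 1e-12) {
    stop("x1 and x2 are perfectly collinear; commonality is undefined", call. = FALSE)
  }
  r2 <- function(fit) summary(fit)$r.squared
  r2_full <- r2(stats::lm(y ~ x1 + x2))
  r2_x1 <- r2(stats::lm(y ~ x1))
  r2_x2 <- r2(stats::lm(y ~ x2))
  unique_x1 <- r2_full - r2_x2
  unique_x2 <- r2_full - r2_x1
  common <- r2_x1 + r2_x2 - r2_full
  defined <- r2_full > 0
  pct <- function(v) if (defined) 100 * v / r2_full else NA_real_
  structure(
    list(
      r2_full = r2_full, r2_x1_only = r2_x1, r2_x2_only = r2_x2,
      unique_x1 = unique_x1, unique_x2 = unique_x2, common = common,
      percent_unique_x1 = pct(unique_x1), percent_unique_x2 = pct(unique_x2),
      percent_common = pct(common), percents_defined = defined, n = n
    ),
    class = "commonality_result"
  )
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of `k` repeated measurements
#' ("items": here, recording segments) over subjects:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of item sums)`,
#' with sample (n-1) variances. Adding a constant to any one item leaves
#' alpha unchanged.
#'
#' @param items numeric matrix, segments (items) x subjects.
#' @return scalar alpha; `NA` (with a warning) when total variance is zero.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- nrow(items)
  if (k < 2L) stop("need at least 2 segments", call. = FALSE)
  if (ncol(items) < 3L) stop("need at least 3 subjects", call. = FALSE)
  var_items <- apply(items, 1, stats::var)
  var_total <- stats::var(colSums(items))
  if (var_total == 0) {
    warning("zero total variance; alpha undefined", call. = FALSE)
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(var_items) / var_total)
}

#' Tidy a commonality result
#' @param x a `commonality_result`.
#' @return one-row tibble.
#' @export
commonality_tidy <- function(x) {
  tibble::tibble(
    r2_full = x$r2_full, r2_x1_only = x$r2_x1_only, r2_x2_only = x$r2_x2_only,
    unique_x1 = x$unique_x1, unique_x2 = x$unique_x2, common = x$common,
    percent_unique_x1 = x$percent_unique_x1,
    percent_unique_x2 = x$percent_unique_x2,
    percent_common = x$percent_common, n = x$n
  )
}
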