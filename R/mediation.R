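# Closed-form OLS pieces for the three mediation regressions. Slopes are
# computed from sums of squares / cross-products so the bootstrap can be
# fully vectorized; lm() reproduces these to machine precision (tested).
mediation_paths <- function(x, m, y) {
  vx <- stats::var(x)
  a <- stats::cov(x, m) / vx
  c_total <- stats::cov(x, y) / vx
  # y ~ m + x: 2x2 normal equations
  smm <- stats::var(m); sxm <- stats::cov(x, m)
  smy <- stats::cov(m, y); sxy <- stats::cov(x, y)
  det <- smm * vx - sxm^2
  b <- (smy * vx - sxm * sxy) / det
  c_prime <- (sxy * smm - sxm * smy) / det
  c(a = a, b = b, c = c_total, c_prime = c_prime)
}

# vectorized paths over bootstrap resamples: X, M, Y are n x B matrices
mediation_paths_boot <- function(X, M, Y) {
  n <- nrow(X)
  cm <- function(A) colMeans(A)
  mx <- cm(X); mm <- cm(M); my <- cm(Y)
  sxx <- (colSums(X * X) - n * mx^2)
  smm <- (colSums(M * M) - n * mm^2)
  sxm <- (colSums(X * M) - n * mx * mm)
  sxy <- (colSums(X * Y) - n * mx * my)
  smy <- (colSums(M * Y) - n * mm * my)
  a <- sxm / sxx
  det <- smm * sxx - sxm^2
  b <- (smy * sxx - sxm * sxy) / det
  list(a = a, b = b, indirect = a * b, bad = sxx <= 0 | smm <= 0 | det <= 0)
}

#' Single-mediator model with percentile-bootstrap CI
#'
#' The simple mediation model X -> M -> Y: OLS fits with intercepts give
#' `a` (M ~ X), `b` and `c_prime` (Y ~ M + X) and `c` (Y ~ X); the indirect
#' effect is `a * b`, satisfying the identity `a*b + c_prime = c` exactly.
#' Its confidence interval comes from case resampling: subject (x, m, y)
#' triples are resampled with replacement, `a * b` is recomputed for each
#' resample, and the CI is the 2.5th/97.5th percentile of the bootstrap
#' distribution (no bias correction, no homoskedasticity assumption).
#' Resamples with a degenerate (constant) column are redrawn and counted.
#' Both unstandardized and standardized (z-scored x, m, y) coefficients are
#' produced in one call, sharing the same resamples.
#'
#' @param x,m,y numeric vectors: predictor, mediator, outcome.
#' @param n_bootstrap number of bootstrap resamples (default 10000).
#' @param seed optional integer seed.
#' @param conf_level CI level (default 0.95).
#' @return A `mediation_result` list: `a`, `b`, `c`, `c_prime`, `indirect`,
#'   `se`, `ci_low`, `ci_high`, a `standardized` sublist with the same
#'   fields on z-scored data, `n`, `n_bootstrap`, `seed`, `n_redrawn`,
#'   `ci_excludes_estimate` (resampling-pathology flag).
#' @export
mediate <- function(x, m, y, n_bootstrap = 10000, seed = NULL,
                    conf_level = 0.95) {
  ok <- stats::complete.cases(x, m, y)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10L) stop("need at least 10 complete observations", call. = FALSE)
  if (any(!is.finite(c(x, m, y)))) stop("non-finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(m) == 0 || stats::sd(y) == 0) {
    stop("constant variable", call. = FALSE)
  }
  if (abs(stats::cor(x, m)) > 1 - 1e-12) {
    stop("mediator perfectly collinear with predictor; b path unidentifiable",
         call. = FALSE)
  }
  paths <- mediation_paths(x, m, y)
  zx <- as.numeric(scale(x)); zm <- as.numeric(scale(m)); zy <- as.numeric(scale(y))
  paths_std <- mediation_paths(zx, zm, zy)

  if (!is.null(seed)) set.seed(seed)
  B <- n_bootstrap
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  boot <- mediation_paths_boot(
    matrix(x[idx], n, B), matrix(m[idx], n, B), matrix(y[idx], n, B)
  )
  n_redrawn <- 0L
  while (any(boot$bad)) {
    bad <- which(boot$bad)
    n_redrawn <- n_redrawn + length(bad)
    idx[, bad] <- sample.int(n, n * length(bad), replace = TRUE)
    redo <- mediation_paths_boot(
      matrix(x[idx[, bad]], n, length(bad)),
      matrix(m[idx[, bad]], n, length(bad)),
      matrix(y[idx[, bad]], n, length(bad))
    )
    boot$indirect[bad] <- redo$indirect
    boot$bad[bad] <- redo$bad
  }
  boot_std <- mediation_paths_boot(
    matrix(zx[idx], n, B), matrix(zm[idx], n, B), matrix(zy[idx], n, B)
  )
  qs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci <- stats::quantile(boot$indirect, qs, names = FALSE)
  ci_std <- stats::quantile(boot_std$indirect, qs, names = FALSE)
  indirect <- unname(paths["a"] * paths["b"])
  structure(
    list(
      a = unname(paths["a"]), b = unname(paths["b"]),
      c = unname(paths["c"]), c_prime = unname(paths["c_prime"]),
      indirect = indirect,
      se = stats::sd(boot$indirect),
      ci_low = ci[1], ci_high = ci[2],
      standardized = list(
        a = unname(paths_std["a"]), b = unname(paths_std["b"]),
        c = unname(paths_std["c"]), c_prime = unname(paths_std["c_prime"]),
        indirect = unname(paths_std["a"] * paths_std["b"]),
        se = stats::sd(boot_std$indirect),
        ci_low = ci_std[1], ci_high = ci_std[2]
      ),
      n = n, n_bootstrap = B, seed = seed, conf_level = conf_level,
      n_redrawn = n_redrawn,
      ci_excludes_estimate = indirect < ci[1] || indirect > ci[2]
    ),
    class = "mediation_result"
  )
}

#' Run one mediation model per predictor
#'
#' Fits [mediate()] for each named predictor column against a shared
#' mediator and outcome. Per-model seeds are derived from the master seed
#' (`seed + model index`) so each model is individually reproducible.
#'
#' @param traits data frame (trait table with behavioural and ROI columns).
#' @param x_names character vector of predictor columns.
#' @param m_name mediator column.
#' @param y_name outcome column.
#' @param n_bootstrap resamples per model.
#' @param seed master seed.
#' @return A tibble, one row per predictor: paths, indirect effect, SE,
#'   percentile CI, standardized indirect and CI, `n_boot`, `seed`.
#' @export
mediation_table <- function(traits, x_names, m_name, y_name,
                            n_bootstrap = 10000, seed = 1L) {
  miss <- setdiff(c(x_names, m_name, y_name), names(traits))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_along(x_names), function(i) {
    fit <- mediate(traits[[x_names[i]]], traits[[m_name]], traits[[y_name]],
                   n_bootstrap = n_bootstrap, seed = seed + i - 1L)
    tibble::tibble(
      x = x_names[i], m = m_name, y = y_name,
      a = fit$a, b = fit$b, c = fit$c, c_prime = fit$c_prime,
      indirect = fit$indirect, se = fit$se,
      ci_low = fit$ci_low, ci_high = fit$ci_high,
      indirect_std = fit$standardized$indirect,
      ci_low_std = fit$standardized$ci_low,
      ci_high_std = fit$standardized$ci_high,
      n = fit$n, n_boot = fit$n_bootstrap, seed = seed + i - 1L
    )
  })
  do.call(rbind, rows)
}
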