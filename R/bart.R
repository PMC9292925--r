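#' Construct a BART session
#'
#' A session is one subject's ordered sequence of balloon trials. Pumps are
#' the pumps actually recorded on each trial (up to the explosion, when one
#' occurred); `exploded` marks trials that ended in an explosion.
#'
#' @param subject_id scalar identifier.
#' @param pumps integer vector of recorded pumps per trial (>= 1).
#' @param exploded logical (or 0/1) vector, same length as `pumps`.
#' @return A tibble of class `bart_session` with columns `subject_id`,
#'   `trial`, `pumps`, `exploded`.
#' @export
bart_session <- function(subject_id, pumps, exploded) {
  pumps <- as.integer(pumps)
  exploded <- as.logical(exploded)
  if (length(pumps) != length(exploded)) {
    stop("pumps and exploded must have equal length", call. = FALSE)
  }
  if (length(pumps) == 0L) stop("session must contain at least one trial", call. = FALSE)
  if (any(is.na(pumps)) || any(pumps < 1L)) {
    stop("pumps must be positive integers", call. = FALSE)
  }
  out <- tibble::tibble(
    subject_id = rep(as.character(subject_id), length(pumps)),
    trial = seq_along(pumps),
    pumps = pumps,
    exploded = exploded
  )
  class(out) <- c("bart_session", class(out))
  out
}

as_session_df <- function(session) {
  stopifnot(is.data.frame(session), all(c("pumps", "exploded") %in% names(session)))
  if (nrow(session) == 0L) stop("empty session", call. = FALSE)
  session
}

#' Risk-taking score (RT)
#'
#' RT = mean pumps over all trials (exploded trials included, with pumps
#' recorded up to the explosion) times (number of explosions + 1), divided
#' by the number of trials. Explosions enter the numerator because they are
#' themselves risky outcomes; restricting to safe trials would understate
#' risk appetite.
#'
#' @param session a `bart_session` or data frame with `pumps`, `exploded`.
#' @return scalar RT score.
#' @seealso [coefficient_of_variability()], [bart_scores()]
#' @export
#' @examples
#' s <- bart_session("s1", rep(10, 20), rep(FALSE, 20))
#' risk_taking(s) # 10 * 1 / 20 = 0.5
risk_taking <- function(session) {
  session <- as_session_df(session)
  n <- nrow(session)
  mean(session$pumps) * (sum(session$exploded) + 1) / n
}

#' Alternative risk-taking indices
#'
#' Simpler conventions in the BART literature: the total number of pumps
#' across the session, and the plain average pumps per trial. They rank
#' subjects very similarly to [risk_taking()] on realistic cohorts.
#'
#' @param session a `bart_session` or compatible data frame.
#' @return scalar.
#' @export
risk_taking_total_pumps <- function(session) {
  sum(as_session_df(session)$pumps)
}

#' @rdname risk_taking_total_pumps
#' @export
risk_taking_mean_pumps <- function(session) {
  mean(as_session_df(session)$pumps)
}

#' Coefficient of variability (COV)
#'
#' COV = standard deviation of pumps across trials divided by average pumps:
#' an inverse index of strategic consistency. A consistent pumper (small
#' trial-to-trial adjustments) has a low COV; erratic pumping yields a high
#' COV. The sample (n-1) standard deviation is the default convention.
#'
#' @param session a `bart_session` or data frame with a `pumps` column.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return scalar COV.
#' @export
#' @examples
#' coefficient_of_variability(bart_session("s1", c(5, 15, 2, 18), rep(FALSE, 4)))
coefficient_of_variability <- function(session, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  session <- as_session_df(session)
  p <- session$pumps
  if (length(p) < 2L) stop("COV requires at least 2 trials", call. = FALSE)
  m <- mean(p)
  if (m <= 0) stop("COV undefined for zero mean pumps", call. = FALSE)
  s <- stats::sd(p)
  if (sd_type == "population") s <- s * sqrt((length(p) - 1) / length(p))
  s / m
}

#' Score one BART session
#'
#' @param session a `bart_session` or compatible data frame.
#' @param sd_type passed to [coefficient_of_variability()].
#' @return One-row tibble: `subject_id`, `rt`, `cov`, `mean_pumps`,
#'   `sd_pumps`, `n_explosions`, `n_trials`, `total_pumps`.
#' @export
bart_scores <- function(session, sd_type = "sample") {
  session <- as_session_df(session)
  sid <- if ("subject_id" %in% names(session)) as.character(session$subject_id[1]) else NA_character_
  tibble::tibble(
    subject_id = sid,
    rt = risk_taking(session),
    cov = coefficient_of_variability(session, sd_type),
    mean_pumps = mean(session$pumps),
    sd_pumps = stats::sd(session$pumps),
    n_explosions = sum(session$exploded),
    n_trials = nrow(session),
    total_pumps = sum(session$pumps)
  )
}

#' Score a cohort of BART sessions
#'
#' @param sessions either a list of `bart_session` objects or one long data
#'   frame with columns `subject_id`, `trial`, `pumps`, `exploded`.
#' @param sd_type passed to [coefficient_of_variability()].
#' @return A list with `scores` (one row per subject, includes the
#'   alternative indices `total_pumps` and `mean_pumps`) and `summary`
#'   (mean, SD, min, max of `rt` and `cov` over subjects; SD reported as 0
#'   with `single_subject = TRUE` for a one-subject cohort).
#' @export
score_cohort <- function(sessions, sd_type = "sample") {
  if (is.data.frame(sessions)) {
    stopifnot(all(c("subject_id", "pumps", "exploded") %in% names(sessions)))
    sessions <- split(sessions, sessions$subject_id)
    # split() sorts keys; keep first-appearance subject order
  }
  ids <- vapply(sessions, function(s) as.character(s$subject_id[1]), character(1))
  if (anyDuplicated(ids)) stop("duplicate subject_id in cohort", call. = FALSE)
  scores <- do.call(rbind, lapply(sessions, bart_scores, sd_type = sd_type))
  single <- nrow(scores) == 1L
  summarise_one <- function(x) {
    tibble::tibble(
      mean = mean(x),
      sd = if (single) 0 else stats::sd(x),
      min = min(x), max = max(x)
    )
  }
  summary <- cbind(
    measure = c("rt", "cov"),
    rbind(summarise_one(scores$rt), summarise_one(scores$cov))
  )
  summary <- tibble::as_tibble(summary)
  summary$single_subject <- single
  list(scores = tibble::as_tibble(scores), summary = summary)
}
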