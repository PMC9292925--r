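#' Canonical resting-EEG frequency bands
#'
#' The seven-band partition used throughout the pipeline: delta 1.5-6 Hz,
#' theta 6.5-8 Hz, alpha1 8.5-10 Hz, alpha2 10.5-12 Hz, beta1 12.5-18 Hz,
#' beta2 18.5-21 Hz, beta3 21.5-30 Hz. The half-integer edges make band
#' membership of 0.5-Hz-resolution spectral bins (2-s epochs) unambiguous:
#' a bin belongs to a band iff its centre frequency lies in `[low, high]`
#' inclusive.
#'
#' @return A tibble with columns `band`, `low`, `high` (Hz).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha1", "alpha2", "beta1", "beta2", "beta3"),
    low  = c(1.5, 6.5, 8.5, 10.5, 12.5, 18.5, 21.5),
    high = c(6.0, 8.0, 10.0, 12.0, 18.0, 21.0, 30.0)
  )
}

#' Validate a band-definition table
#'
#' @param bands data frame with columns `band`, `low`, `high`.
#' @return The validated table, invisibly usable downstream.
#' @keywords internal
validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("band", "low", "high") %in% names(bands)))
  if (any(bands$low <= 0) || any(bands$high <= bands$low)) {
    stop("band definitions must satisfy 0 < low < high", call. = FALSE)
  }
  if (anyDuplicated(bands$band)) stop("duplicate band names", call. = FALSE)
  bands
}

#' Read band definitions from a YAML file
#'
#' YAML layout: a `bands` mapping of name to `[low, high]` pairs in Hz.
#'
#' @param path YAML file path.
#' @return Band tibble as from [eeg_bands()].
#' @export
read_bands_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$bands)) stop("YAML must contain a 'bands' mapping", call. = FALSE)
  out <- tibble::tibble(
    band = names(raw$bands),
    low  = unname(vapply(raw$bands, function(b) as.numeric(b[[1]]), numeric(1))),
    high = unname(vapply(raw$bands, function(b) as.numeric(b[[2]]), numeric(1)))
  )
  validate_bands(out)
}
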