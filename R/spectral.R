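#' Construct an EEG recording
#'
#' In-memory container for a continuous multichannel recording in microvolts.
#' Segment annotations mark eyes-open / eyes-closed periods.
#'
#' @param samples numeric matrix, channels x time (µV).
#' @param sampling_rate Hz.
#' @param channel_labels character vector, one per channel row.
#' @param segments optional data frame with `onset_s`, `duration_s`, `label`
#'   (labels `"eyes_closed"` / `"eyes_open"`); `NULL` means the whole
#'   recording is usable.
#' @return An `eeg_recording` list.
#' @export
eeg_recording <- function(samples, sampling_rate, channel_labels = NULL,
                          segments = NULL) {
  samples <- as.matrix(samples)
  stopifnot(sampling_rate > 0)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(samples)))
  stopifnot(length(channel_labels) == nrow(samples))
  if (!is.null(segments)) {
    stopifnot(all(c("onset_s", "duration_s", "label") %in% names(segments)))
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_labels = as.character(channel_labels), segments = segments),
    class = "eeg_recording"
  )
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return scalar seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$sampling_rate

#' Preprocess a resting EEG recording
#'
#' Standard resting-state cleaning contract: re-reference to the average of
#' the two mastoid channels, resample to 256 Hz, zero-phase band-pass filter
#' 0.1-30 Hz plus a 60-Hz notch, and retain only eyes-closed segments
#' (concatenated). Ocular correction is assumed to have been applied
#' upstream; residual artifacts are handled per epoch by
#' [reject_artifact_epochs()].
#'
#' @param rec an `eeg_recording`.
#' @param mastoids labels of the two mastoid reference channels.
#' @param band band-pass edges in Hz.
#' @param notch notch centre in Hz (`NULL` to skip); a 2-Hz-wide stop band.
#' @param resample_to target rate in Hz.
#' @param keep_eyes_closed drop all but eyes-closed segments (requires
#'   annotations when `TRUE` and annotations exist; a recording without
#'   annotations is taken as all eyes-closed).
#' @param filter_order Butterworth half-order for the band edges.
#' @return A cleaned `eeg_recording` at `resample_to` Hz.
#' @export
preprocess_eeg <- function(rec, mastoids = c("TP9", "TP10"), band = c(0.1, 30),
                           notch = 60, resample_to = 256,
                           keep_eyes_closed = TRUE, filter_order = 2) {
  mi <- match(mastoids, rec$channel_labels)
  if (any(is.na(mi))) {
    stop("mastoid channels missing: ", paste(mastoids[is.na(mi)], collapse = ", "),
         call. = FALSE)
  }
  x <- rec$samples
  ref <- colMeans(x[mi, , drop = FALSE])
  x <- sweep(x, 2, ref)
  fs <- rec$sampling_rate
  segments <- rec$segments
  if (fs != resample_to) {
    fac <- fs / resample_to
    if (abs(fac - round(fac)) < 1e-9) {
      x <- t(apply(x, 1, function(ch) signal::decimate(ch, round(fac))))
    } else {
      x <- t(apply(x, 1, function(ch) signal::resample(ch, resample_to, fs)))
    }
    fs <- resample_to
  }
  ny <- fs / 2
  hp <- signal::butter(filter_order, band[1] / ny, type = "high")
  lp <- signal::butter(2 * filter_order, band[2] / ny, type = "low")
  filt <- function(ch) {
    ch <- signal::filtfilt(hp, ch)
    signal::filtfilt(lp, ch)
  }
  x <- t(apply(x, 1, filt))
  if (!is.null(notch)) {
    bs <- signal::butter(filter_order, c(notch - 1, notch + 1) / ny, type = "stop")
    x <- t(apply(x, 1, function(ch) signal::filtfilt(bs, ch)))
  }
  if (keep_eyes_closed && !is.null(segments)) {
    ec <- segments[segments$label == "eyes_closed", , drop = FALSE]
    if (nrow(ec) == 0L) stop("no eyes-closed annotation in recording", call. = FALSE)
    cols <- unlist(lapply(seq_len(nrow(ec)), function(i) {
      a <- floor(ec$onset_s[i] * fs) + 1
      b <- min(ncol(x), floor((ec$onset_s[i] + ec$duration_s[i]) * fs))
      seq(a, b)
    }))
    x <- x[, cols, drop = FALSE]
    segments <- NULL
  }
  eeg_recording(x, fs, rec$channel_labels, segments)
}

#' Segment a recording into overlapping epochs
#'
#' Epochs start every `epoch_seconds * (1 - overlap_fraction)` seconds;
#' a partial tail is dropped. 60 s at 2-s epochs with 75% overlap yields
#' 117 epochs.
#'
#' @param rec an `eeg_recording`, or a channels x time matrix with
#'   `sampling_rate` given.
#' @param epoch_seconds epoch length (default 2 s).
#' @param overlap_fraction in `[0, 1)` (default 0.75).
#' @param sampling_rate required when `rec` is a bare matrix.
#' @return List of channels x samples matrices, each with an `offset_s`
#'   attribute; the list carries `sampling_rate`/`epoch_seconds` attributes.
#' @export
segment_epochs <- function(rec, epoch_seconds = 2, overlap_fraction = 0.75,
                           sampling_rate = NULL) {
  if (inherits(rec, "eeg_recording")) {
    x <- rec$samples
    fs <- rec$sampling_rate
  } else {
    x <- as.matrix(rec)
    fs <- sampling_rate
    if (is.null(fs)) stop("sampling_rate required for matrix input", call. = FALSE)
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)", call. = FALSE)
  }
  nper <- round(epoch_seconds * fs)
  if (ncol(x) < nper) stop("recording shorter than one epoch", call. = FALSE)
  step <- round(nper * (1 - overlap_fraction))
  starts <- seq(1, ncol(x) - nper + 1, by = step)
  out <- lapply(starts, function(a) {
    e <- x[, a:(a + nper - 1), drop = FALSE]
    attr(e, "offset_s") <- (a - 1) / fs
    e
  })
  attr(out, "sampling_rate") <- fs
  attr(out, "epoch_seconds") <- epoch_seconds
  out
}

#' Reject artifact epochs
#'
#' An epoch is rejected if on any channel (a) any sample exceeds the min/max
#' amplitude window, (b) any adjacent-sample voltage step exceeds
#' `max_step_uv`, or (c) any sliding 100-ms interval is nearly flat
#' (max - min below `min_range_uv`, a dead-channel signature).
#'
#' @param epochs list from [segment_epochs()] (µV).
#' @param sampling_rate Hz; defaults to the list's attribute.
#' @param amplitude_uv min/max threshold (default c(-100, 100)).
#' @param max_step_uv maximum adjacent-sample step (default 50).
#' @param min_range_uv lowest allowed max-min per interval (default 0.5).
#' @param range_window_ms flatness interval length (default 100 ms).
#' @return List with `kept` (epoch list, possibly empty) and `mask`, a
#'   tibble per epoch: `kept`, `reason` (`"minmax"`, `"step"`,
#'   `"low_activity"` or `NA`).
#' @export
reject_artifact_epochs <- function(epochs, sampling_rate = NULL,
                                   amplitude_uv = c(-100, 100),
                                   max_step_uv = 50, min_range_uv = 0.5,
                                   range_window_ms = 100) {
  fs <- sampling_rate %||% attr(epochs, "sampling_rate")
  if (is.null(fs)) stop("sampling_rate unknown", call. = FALSE)
  w <- max(2L, round(range_window_ms / 1000 * fs))
  classify <- function(e) {
    if (any(e < amplitude_uv[1]) || any(e > amplitude_uv[2])) return("minmax")
    if (ncol(e) > 1 && any(abs(e[, -1, drop = FALSE] - e[, -ncol(e), drop = FALSE]) > max_step_uv)) {
      return("step")
    }
    n <- ncol(e)
    starts <- seq(1, max(1, n - w + 1))
    for (ch in seq_len(nrow(e))) {
      run_max <- run_window_max(e[ch, ], w)
      run_min <- run_window_min(e[ch, ], w)
      if (any((run_max - run_min)[starts] < min_range_uv)) return("low_activity")
    }
    NA_character_
  }
  reasons <- vapply(epochs, classify, character(1))
  kept_idx <- which(is.na(reasons))
  kept <- epochs[kept_idx]
  attr(kept, "sampling_rate") <- fs
  attr(kept, "epoch_seconds") <- attr(epochs, "epoch_seconds")
  if (length(kept_idx) == 0L) {
    warning("all epochs rejected", call. = FALSE)
  }
  list(
    kept = kept,
    mask = tibble::tibble(
      epoch = seq_along(epochs),
      kept = is.na(reasons),
      reason = reasons
    )
  )
}

# running max/min over trailing windows of width w, aligned to window start
run_window_max <- function(x, w) {
  n <- length(x)
  if (n <= w) return(max(x))
  vapply(seq_len(n - w + 1), function(a) max(x[a:(a + w - 1)]), numeric(1))
}
run_window_min <- function(x, w) {
  n <- length(x)
  if (n <= w) return(min(x))
  vapply(seq_len(n - w + 1), function(a) min(x[a:(a + w - 1)]), numeric(1))
}

#' One-sided Hamming-windowed periodogram
#'
#' Power per frequency bin from a Hamming-windowed DFT, scaled so that the
#' sum over all bins equals the windowed time-domain energy (Parseval);
#' bins strictly between DC and Nyquist are doubled to fold negative
#' frequencies. No window amplitude correction is applied: only relative
#' comparisons across subjects are used downstream.
#'
#' @param x numeric vector (one channel, one epoch).
#' @param sampling_rate Hz.
#' @return List with `freq` (Hz, DC..Nyquist) and `power`.
#' @export
periodogram_hamming <- function(x, sampling_rate) {
  n <- length(x)
  xw <- x * signal::hamming(n)
  X <- stats::fft(xw)
  p_full <- Mod(X)^2 / n
  half <- floor(n / 2) + 1
  p <- p_full[seq_len(half)]
  inner <- 2:(half - 1)
  if (n %% 2 == 0) p[inner] <- 2 * p[inner] else p[2:half] <- 2 * p[2:half]
  list(freq = (seq_len(half) - 1) * sampling_rate / n, power = p)
}

#' Band power from epochs
#'
#' Per epoch and channel, the Hamming-windowed power spectrum is computed;
#' per band, the power of the bins whose centre frequencies fall inside
#' `[low, high]` (inclusive) is aggregated (mean by default); the final
#' table is the mean over epochs. Frequency resolution is
#' `1 / epoch_seconds` (0.5 Hz for 2-s epochs).
#'
#' @param epochs list from [segment_epochs()] (ideally artifact-free).
#' @param bands band tibble, default [eeg_bands()].
#' @param sampling_rate Hz; defaults to the epoch list attribute.
#' @param aggregate `"mean"` (default) or `"sum"` over member bins.
#' @return A `band_power_table`: channels x bands matrix with attributes
#'   `epoch_count` and `bands`.
#' @export
band_power <- function(epochs, bands = eeg_bands(), sampling_rate = NULL,
                       aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  bands <- validate_bands(bands)
  fs <- sampling_rate %||% attr(epochs, "sampling_rate")
  if (is.null(fs)) stop("sampling_rate unknown", call. = FALSE)
  if (length(epochs) == 0L) stop("no epochs supplied", call. = FALSE)
  if (any(bands$high > fs / 2)) stop("band exceeds Nyquist frequency", call. = FALSE)
  n <- ncol(epochs[[1]])
  freq <- (seq_len(floor(n / 2) + 1) - 1) * fs / n
  bin_sets <- lapply(seq_len(nrow(bands)), function(b) {
    which(freq >= bands$low[b] - 1e-9 & freq <= bands$high[b] + 1e-9)
  })
  if (any(lengths(bin_sets) == 0L)) stop("a band contains no frequency bin", call. = FALSE)
  nch <- nrow(epochs[[1]])
  acc <- matrix(0, nch, nrow(bands))
  for (e in epochs) {
    for (ch in seq_len(nch)) {
      p <- periodogram_hamming(e[ch, ], fs)$power
      acc[ch, ] <- acc[ch, ] + vapply(bin_sets, function(ix) {
        if (aggregate == "mean") mean(p[ix]) else sum(p[ix])
      }, numeric(1))
    }
  }
  out <- acc / length(epochs)
  dimnames(out) <- list(NULL, bands$band)
  attr(out, "epoch_count") <- length(epochs)
  attr(out, "bands") <- bands
  class(out) <- c("band_power_table", class(out))
  out
}

#' Normalize and log-transform a density map
#'
#' Per subject (and band), values are divided by their total so the sum
#' becomes exactly 1, then natural-log transformed. Scale invariant:
#' multiplying all raw values by a constant leaves the output unchanged.
#'
#' @param x positive numeric matrix (subjects x features), 3-d array
#'   (subjects x voxels x bands), or a `voxel_map` of raw densities.
#' @return Same shape, log fractions; a `voxel_map` gains
#'   `normalized = TRUE`.
#' @export
normalize_log_map <- function(x) {
  norm_mat <- function(m) {
    if (any(m <= 0)) stop("all values must be positive", call. = FALSE)
    log(m / rowSums(m))
  }
  if (inherits(x, "voxel_map")) {
    v <- x$values
    for (b in seq_len(dim(v)[3])) v[, , b] <- norm_mat(v[, , b, drop = TRUE])
    x$values <- v
    x$normalized <- TRUE
    return(x)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    for (b in seq_len(dim(x)[3])) x[, , b] <- norm_mat(x[, , b, drop = TRUE])
    return(x)
  }
  if (is.matrix(x)) return(norm_mat(x))
  if (is.numeric(x)) {
    if (any(x <= 0)) stop("all values must be positive", call. = FALSE)
    return(log(x / sum(x)))
  }
  stop("unsupported input", call. = FALSE)
}

#' Split a recording for split-half reliability
#'
#' Cuts the first `n_segments * segment_seconds` seconds into contiguous
#' non-overlapping segments and runs each through [segment_epochs()],
#' [reject_artifact_epochs()] and [band_power()] independently. The
#' per-segment tables feed [cronbach_alpha()] across subjects.
#'
#' @param rec cleaned `eeg_recording`.
#' @param n_segments number of segments (default 4).
#' @param segment_seconds seconds per segment (default 30).
#' @param epoch_seconds,overlap_fraction epoching parameters.
#' @param bands band tibble.
#' @param reject apply artifact rejection inside each segment.
#' @return List of `band_power_table`s, one per segment.
#' @export
split_segments_for_reliability <- function(rec, n_segments = 4,
                                           segment_seconds = 30,
                                           epoch_seconds = 2,
                                           overlap_fraction = 0.75,
                                           bands = eeg_bands(),
                                           reject = TRUE) {
  need <- n_segments * segment_seconds
  if (recording_duration(rec) < need) {
    stop("recording too short: need ", need, " s, have ",
         round(recording_duration(rec), 2), " s", call. = FALSE)
  }
  fs <- rec$sampling_rate
  nper <- round(segment_seconds * fs)
  lapply(seq_len(n_segments), function(i) {
    cols <- ((i - 1) * nper + 1):(i * nper)
    seg <- eeg_recording(rec$samples[, cols, drop = FALSE], fs, rec$channel_labels)
    ep <- segment_epochs(seg, epoch_seconds, overlap_fraction)
    if (reject) ep <- reject_artifact_epochs(ep)$kept
    band_power(ep, bands)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
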