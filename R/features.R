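# EEG band decomposition, windowing and differential-entropy extraction,
# plus facial-frame preprocessing.
#
# The per-window, per-channel, per-band feature is the differential entropy
# h(X) = -\int f(x) ln f(x) dx of the band-limited signal.  Band-filtered
# EEG is modelled as Gaussian N(mu, sigma^2), for which the integral has
# the closed form h = 1/2 ln(2*pi*e*sigma^2) (natural log, nats).  The
# variance estimate is the maximum-likelihood (1/n) sample variance, so the
# amplitude-scaling law h(c*X) = h(X) + ln|c| holds exactly.

#' Construct an EEG recording object
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param sample_rate Sampling rate in Hz.
#' @param channel_names Character vector, one per row of `data`.
#' @param subject_id,clip_id Identifiers.
#' @param emotion Emotion label, one of happy/sad/fear/calm (or NA).
#' @return An `eeg_recording`.
#' @export
eeg_recording <- function(data, sample_rate, channel_names,
                          subject_id = NA, clip_id = NA, emotion = NA) {
  data <- as.matrix(data)
  abort_if(nrow(data) != length(channel_names),
           "channel_names length must match rows of data")
  abort_if(!is.na(emotion) && !emotion %in% EMOTIONS,
           "unknown emotion label: ", emotion)
  structure(list(data = data, sample_rate = sample_rate,
                 channel_names = as.character(channel_names),
                 subject_id = subject_id, clip_id = clip_id,
                 emotion = emotion),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s)",
              nrow(x$data), ncol(x$data), x$sample_rate,
              ncol(x$data) / x$sample_rate))
  if (!is.na(x$subject_id)) cat(sprintf("  subject=%s clip=%s emotion=%s",
                                        x$subject_id, x$clip_id, x$emotion))
  cat("\n")
  invisible(x)
}

# Zero-phase 4th-order Butterworth band-pass of a channels x samples matrix.
bandpass_matrix <- function(m, lo, hi, fs) {
  ny <- fs / 2
  bf <- signal::butter(4, c(lo, hi) / ny, type = "pass")
  t(apply(m, 1, function(ch) as.numeric(signal::filtfilt(bf, ch))))
}

#' Decompose a recording into band-limited copies
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth band-pass
#' per band; each output has the same length as the input.
#'
#' @param rec An `eeg_recording`.
#' @param bands Band table as from [default_bands()].
#' @return Named list of `eeg_recording`, one per band.
#' @export
decompose_bands <- function(rec, bands = default_bands()) {
  validate_bands(bands, rec$sample_rate)
  out <- lapply(seq_len(nrow(bands)), function(i) {
    r <- rec
    r$data <- bandpass_matrix(rec$data, bands$lo[i], bands$hi[i], rec$sample_rate)
    attr(r, "band") <- bands$name[i]
    r
  })
  names(out) <- bands$name
  out
}

#' Cut a recording into fixed-length windows
#'
#' @param rec An `eeg_recording`.
#' @param length Window length in seconds (default 1).
#' @param overlap Window overlap in seconds (default 0, the analysis
#'   protocol); trailing partial samples are dropped.
#' @return Array channels x samples_per_window x n_windows (possibly 0
#'   windows when the recording is shorter than one window).
#' @export
window_signal <- function(rec, length = 1, overlap = 0) {
  abort_if(length <= 0, "window length must be positive")
  abort_if(overlap < 0 || overlap >= length, "overlap must be in [0, length)")
  spw <- as.integer(round(length * rec$sample_rate))
  step <- as.integer(round((length - overlap) * rec$sample_rate))
  n <- ncol(rec$data)
  n_win <- if (n < spw) 0L else (n - spw) %/% step + 1L
  out <- array(0, c(nrow(rec$data), spw, n_win))
  for (w in seq_len(n_win)) {
    out[, , w] <- rec$data[, ((w - 1L) * step + 1L):((w - 1L) * step + spw)]
  }
  out
}

#' Differential entropy of a signal window under the Gaussian model
#'
#' Returns `0.5 * log(2 * pi * e * v)` nats with `v` the 1/n sample
#' variance.  A zero-variance window returns `-Inf` (flagged sentinel; the
#' topographic stage clamps to a configurable floor).
#'
#' @param x Numeric vector with at least 2 finite samples.
#' @return Differential entropy in nats.
#' @export
differential_entropy <- function(x) {
  abort_if(length(x) < 2, "need at least 2 samples")
  abort_if(any(!is.finite(x)), "non-finite samples")
  v <- mean((x - mean(x))^2)
  if (v == 0) return(-Inf)
  0.5 * log(2 * pi * exp(1) * v)
}

#' Extract the windows x channels x bands differential-entropy tensor
#'
#' Composes band decomposition, 1-second windowing and per-window
#' differential entropy.
#'
#' @param rec An `eeg_recording`.
#' @param bands Band table (default the five canonical bands).
#' @param window_length Window length in seconds (default 1).
#' @return Array windows x channels x bands (nats), class `de_features`,
#'   with the band table, window map and channel names as attributes.
#' @export
extract_de_features <- function(rec, bands = default_bands(), window_length = 1) {
  per_band <- decompose_bands(rec, bands)
  n_win <- ncol(rec$data) %/% as.integer(round(window_length * rec$sample_rate))
  out <- array(NA_real_, c(n_win, nrow(rec$data), nrow(bands)))
  for (b in seq_along(per_band)) {
    w <- window_signal(per_band[[b]], length = window_length) # ch x spw x W
    if (dim(w)[3] == 0) next
    mu <- apply(w, c(1, 3), mean)
    m2 <- apply(w^2, c(1, 3), mean)
    v <- pmax(m2 - mu^2, 0)
    de <- ifelse(v > 0, 0.5 * log(2 * pi * exp(1) * v), -Inf)
    out[, , b] <- t(de)
  }
  structure(out, class = "de_features",
            bands = bands, channel_names = rec$channel_names,
            window_length = window_length,
            subject_id = rec$subject_id, clip_id = rec$clip_id,
            emotion = rec$emotion)
}

# ---------------------------------------------------------------------------
# Facial frames

#' Construct a face frame object
#'
#' @param pixels Array H x W x 3, values in normalized units.
#' @param subject_id,clip_id,window Identifiers tying the frame to its
#'   1-second EEG window.
#' @return A `face_frame`.
#' @export
face_frame <- function(pixels, subject_id = NA, clip_id = NA, window = NA) {
  abort_if(length(dim(pixels)) != 3 || dim(pixels)[3] != 3,
           "pixels must be an H x W x 3 RGB array")
  structure(list(pixels = pixels, subject_id = subject_id,
                 clip_id = clip_id, window = window),
            class = "face_frame")
}

#' Per-subject min-max normalization of face frames
#'
#' Every pixel/channel feature is rescaled over the given subject's frames
#' as `(F - min) / (max - min)`, mapping each non-constant feature onto
#' `[0, 1]`; constant features map to 0.  Frames of other subjects are
#' returned untouched.
#'
#' @param frames List of `face_frame`.
#' @param subject_id Subject whose frames to normalize; default (`NULL`)
#'   normalizes every subject present, each over its own frames.
#' @param rescale_signed If TRUE, apply `2x - 1` after min-max scaling so
#'   non-constant features span `[-1, 1]` instead of the default `[0, 1]`.
#' @return List of `face_frame` with normalized pixels.
#' @export
normalize_faces <- function(frames, subject_id = NULL, rescale_signed = FALSE) {
  abort_if(length(frames) == 0, "empty frame set")
  subs <- vapply(frames, function(f) as.character(f$subject_id), "")
  targets <- if (is.null(subject_id)) unique(subs) else as.character(subject_id)
  out <- frames
  for (s in targets) {
    idx <- which(subs == s)
    abort_if(length(idx) == 0, "no frames for subject ", s)
    lo <- Reduce(pmin, lapply(frames[idx], function(f) f$pixels))
    hi <- Reduce(pmax, lapply(frames[idx], function(f) f$pixels))
    rng <- hi - lo
    const <- rng == 0
    rng[const] <- 1
    for (i in idx) {
      p <- (frames[[i]]$pixels - lo) / rng
      p[const] <- 0
      if (rescale_signed) p <- 2 * p - 1
      out[[i]]$pixels <- p
    }
  }
  out
}

#' Center-crop an RGB image to a square and resize
#'
#' Crops the central square of the shorter side, then resizes with
#' bilinear resampling.
#'
#' @param image Array H x W x 3.
#' @param size Output side length (default 256).
#' @return Array `size` x `size` x 3.
#' @export
center_crop_resize <- function(image, size = 256) {
  d <- dim(image)
  abort_if(length(d) != 3 || d[3] != 3, "input must be an H x W x 3 RGB image")
  h <- d[1]; w <- d[2]
  side <- min(h, w)
  r0 <- (h - side) %/% 2
  c0 <- (w - side) %/% 2
  crop <- image[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side), , drop = FALSE]
  if (side == size) return(crop)
  # bilinear resample at output pixel centers
  src <- (seq_len(size) - 0.5) * side / size + 0.5
  i0 <- pmin(pmax(floor(src - 1e-12), 1), side)
  i1 <- pmin(i0 + 1, side)
  fr <- pmin(pmax(src - i0, 0), 1)
  out <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    m <- crop[, , ch]
    a <- m[i0, i0]; b <- m[i0, i1]; cc <- m[i1, i0]; dd <- m[i1, i1]
    fx <- matrix(fr, size, size, byrow = TRUE) # column fraction
    fy <- matrix(fr, size, size)               # row fraction
    out[, , ch] <- a * (1 - fy) * (1 - fx) + b * (1 - fy) * fx +
      cc * fy * (1 - fx) + dd * fy * fx
  }
  out
}
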