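#' Construct an EEG signal object
#'
#' A `Signal` is one channel of EEG samples together with its sampling rate,
#' an optional class label, and an identifier. Amplitudes are in arbitrary
#' units; the pipeline is scale-invariant because every epoch is min-max
#' rescaled before encoding.
#'
#' @param samples numeric vector of finite samples (length >= 1).
#' @param fs sampling rate in Hz (> 0); the reference setting is 512 Hz.
#' @param label optional class tag, `"normal"` or `"focal"`.
#' @param id string identifier.
#' @return an object of class `eeg_signal`.
#' @export
eeg_signal <- function(samples, fs, label = NULL, id = "signal") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop_gasfeeg("gasfeeg_config_error", "signal must contain at least one sample")
  }
  if (!all(is.finite(samples))) {
    stop_gasfeeg("gasfeeg_parse_error", "signal contains non-finite samples")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_gasfeeg("gasfeeg_config_error", "fs must be a positive scalar (Hz)")
  }
  if (!is.null(label)) label <- match.arg(label, c("normal", "focal"))
  structure(
    list(samples = samples, fs = fs, label = label, id = as.character(id)),
    class = "eeg_signal"
  )
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf("<eeg_signal '%s'> %d samples @ %g Hz (%.2f s)%s\n",
              x$id, length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

#' @export
length.eeg_signal <- function(x) length(x$samples)

#' Read a single-channel signal from delimited text
#'
#' Accepts one sample per line or multiple comma/whitespace-separated columns
#' per line (the paired-channel dialect used by common focal-EEG archives);
#' `channel` selects the column. Blank lines are skipped.
#'
#' @param path path to a `.txt`/`.csv` file.
#' @param fs sampling rate in Hz (supplied out of band; the file has none).
#' @param channel 1-based column index to read.
#' @param label,id passed to [eeg_signal()]; `id` defaults to the file name.
#' @return an `eeg_signal`.
#' @export
read_signal <- function(path, fs, channel = 1L, label = NULL, id = NULL) {
  if (!file.exists(path)) {
    stop_gasfeeg("gasfeeg_io_error", "file not found: %s", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    stop_gasfeeg("gasfeeg_parse_error", "no data lines in %s", path)
  }
  fields <- strsplit(trimws(lines), "[,[:space:]]+")
  ncol <- lengths(fields)
  if (any(ncol < channel)) {
    bad <- lineno[which(ncol < channel)[1L]]
    stop_gasfeeg("gasfeeg_channel_error",
                 "line %d of %s has %d column(s); channel %d requested",
                 bad, path, ncol[which(ncol < channel)[1L]], channel)
  }
  vals <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", channel)))
  if (anyNA(vals)) {
    bad <- lineno[which(is.na(vals))[1L]]
    stop_gasfeeg("gasfeeg_parse_error",
                 "malformed numeric field at line %d of %s", bad, path)
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  eeg_signal(vals, fs = fs, label = label, id = id)
}

#' Write a signal as delimited text (one sample per line)
#'
#' @param signal an `eeg_signal`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "eeg_signal"))
  writeLines(format(signal$samples, digits = 15, trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}

#' Configuration for the two-class synthetic EEG generator
#'
#' The generator emulates the study setting: two balanced classes of 20-s,
#' 512-Hz single-channel signals. The "normal" class is dominated by an
#' alpha-band (8-13 Hz) rhythm over a 1/f (pink) background; the "focal"
#' class has a slower 2-6 Hz dominant rhythm plus Poisson-timed
#' spike-wave transients 3-5 times the background amplitude, mirroring the
#' qualitative contrast between non-focal and focal recordings without any
#' claim of clinical realism.
#'
#' @param n_per_class signals per class (reference setting: 50).
#' @param duration_s duration in seconds (default 20).
#' @param fs sampling rate in Hz (default 512).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param normal_band,focal_band dominant-rhythm frequency band (Hz) per class.
#' @param normal_amp,focal_amp dominant-rhythm amplitude (arbitrary units).
#' @param transient_rate expected focal transients per second.
#' @param transient_amp_range transient peak amplitude as a multiple of the
#'   background amplitude.
#' @param noise_floor standard deviation of the white component of the
#'   background noise.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_class = 50L, duration_s = 20, fs = 512,
                             seed = 1L,
                             normal_band = c(8, 13), focal_band = c(2, 6),
                             normal_amp = 1.0, focal_amp = 1.0,
                             transient_rate = 0.8,
                             transient_amp_range = c(3, 5),
                             noise_floor = 0.35) {
  if (n_per_class < 1L) {
    stop_gasfeeg("gasfeeg_config_error", "n_per_class must be >= 1")
  }
  if (duration_s <= 0 || fs <= 0) {
    stop_gasfeeg("gasfeeg_config_error", "duration_s and fs must be positive")
  }
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-9) {
    stop_gasfeeg("gasfeeg_config_error",
                 "duration_s * fs must be an integer sample count")
  }
  structure(list(
    n_per_class = as.integer(n_per_class), duration_s = duration_s, fs = fs,
    seed = as.integer(seed),
    normal_band = normal_band, focal_band = focal_band,
    normal_amp = normal_amp, focal_amp = focal_amp,
    transient_rate = transient_rate,
    transient_amp_range = transient_amp_range,
    noise_floor = noise_floor
  ), class = "synthetic_config")
}

# 1/f ("pink") noise by spectral shaping of white Gaussian noise.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # two-sided frequency index
  shaped <- spec / sqrt(f)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Stereotyped spike-and-wave transient: sharp biphasic spike followed by a
# slow half-wave, ~0.3 s at 512 Hz.
spike_wave <- function(fs) {
  t <- seq(0, 0.3, by = 1 / fs)
  spike <- exp(-((t - 0.04) / 0.012)^2) - 0.6 * exp(-((t - 0.07) / 0.02)^2)
  wave <- 0.5 * sin(pi * pmax(0, pmin(1, (t - 0.1) / 0.2)))
  spike + wave
}

simulate_one <- function(cfg, label, seed) {
  with_seed(seed, {
    n <- as.integer(round(cfg$duration_s * cfg$fs))
    t <- seq_len(n) / cfg$fs
    band <- if (label == "normal") cfg$normal_band else cfg$focal_band
    amp <- if (label == "normal") cfg$normal_amp else cfg$focal_amp
    f0 <- stats::runif(1, band[1], band[2])
    phase <- stats::runif(1, 0, 2 * pi)
    # slow amplitude modulation so the rhythm waxes and wanes
    am <- 1 + 0.25 * sin(2 * pi * stats::runif(1, 0.05, 0.2) * t +
                           stats::runif(1, 0, 2 * pi))
    x <- amp * am * sin(2 * pi * f0 * t + phase)
    x <- x + cfg$noise_floor * (0.7 * pink_noise(n) + 0.3 * stats::rnorm(n))
    if (label == "focal") {
      n_tr <- stats::rpois(1, cfg$transient_rate * cfg$duration_s)
      if (n_tr > 0) {
        proto <- spike_wave(cfg$fs)
        onsets <- sort(stats::runif(n_tr, 0, cfg$duration_s - 0.35))
        amps <- stats::runif(n_tr, cfg$transient_amp_range[1],
                             cfg$transient_amp_range[2]) * amp
        for (k in seq_len(n_tr)) {
          i0 <- as.integer(round(onsets[k] * cfg$fs)) + 1L
          idx <- i0:(i0 + length(proto) - 1L)
          idx <- idx[idx <= n]
          x[idx] <- x[idx] + amps[k] * proto[seq_along(idx)]
        }
      }
    }
    x
  })
}

#' Generate a balanced two-class synthetic EEG dataset
#'
#' Produces `2 * n_per_class` signals ("normal" then "focal"), each simulated
#' from a per-signal child seed derived from `cfg$seed` (see [child_seed()]),
#' so any subset is reproducible regardless of batch size.
#'
#' @param cfg a [synthetic_config()].
#' @return a list of `eeg_signal` objects with labels and ids
#'   `normal_001 ... focal_<n>`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  out <- vector("list", 2L * cfg$n_per_class)
  idx <- 1L
  for (label in c("normal", "focal")) {
    for (i in seq_len(cfg$n_per_class)) {
      sd_i <- child_seed(cfg$seed, idx)
      out[[idx]] <- eeg_signal(
        simulate_one(cfg, label, sd_i), fs = cfg$fs, label = label,
        id = sprintf("%s_%03d", label, i)
      )
      idx <- idx + 1L
    }
  }
  out
}

#' Write a dataset manifest (id, label, path, fs, seed) as CSV
#'
#' Also writes each signal as one-sample-per-line text under `dir`.
#'
#' @param signals list of `eeg_signal`s.
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the manifest (provenance only).
#' @return path to the manifest CSV, invisibly.
#' @export
write_dataset <- function(signals, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(signals, function(s) {
    p <- file.path(dir, paste0(s$id, ".txt"))
    write_signal(s, p)
    data.frame(id = s$id, label = s$label %||% NA_character_,
               path = p, fs = s$fs, seed = seed, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal power (mean of squared samples)
#'
#' The SNR convention used throughout: power is the mean square, not the
#' variance, so a DC offset counts as signal.
#'
#' @param signal an `eeg_signal` or numeric vector.
#' @return scalar power.
#' @export
signal_power <- function(signal) {
  x <- if (inherits(signal, "eeg_signal")) signal$samples else as.numeric(signal)
  mean(x^2)
}

#' Corrupt a signal with additive Gaussian noise at a requested SNR
#'
#' Noise power is `Ps / 10^(snr_db / 10)` with `Ps = mean(x^2)`. The input is
#' not modified; `snr_db = Inf` is the no-noise sentinel and returns the
#' signal unchanged.
#'
#' @param signal an `eeg_signal`.
#' @param snr_db target signal-to-noise ratio in dB (finite, or `Inf`).
#' @param seed integer seed for the noise draw.
#' @return a new `eeg_signal` with the same length, fs, label and id.
#' @export
add_noise <- function(signal, snr_db, seed = 1L) {
  stopifnot(inherits(signal, "eeg_signal"))
  if (is.infinite(snr_db) && snr_db > 0) return(signal)
  if (!is.finite(snr_db)) {
    stop_gasfeeg("gasfeeg_config_error", "snr_db must be finite (or +Inf)")
  }
  ps <- signal_power(signal)
  if (ps == 0) {
    stop_gasfeeg("gasfeeg_degenerate_signal",
                 "signal '%s' has zero power; SNR is undefined", signal$id)
  }
  pn <- ps / 10^(snr_db / 10)
  noisy <- with_seed(seed, {
    signal$samples + stats::rnorm(length(signal$samples), sd = sqrt(pn))
  })
  eeg_signal(noisy, fs = signal$fs, label = signal$label, id = signal$id)
}
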