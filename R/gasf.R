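#' Epoching configuration
#'
#' @param epoch_len epoch length in samples (default 256, giving 256 x 256
#'   images; 40 non-overlapping epochs from a 20-s, 512-Hz signal).
#' @param overlap overlap between consecutive epochs in samples
#'   (default 0; must satisfy `0 <= overlap < epoch_len`).
#' @return an `epoching_config` list.
#' @export
epoching_config <- function(epoch_len = 256L, overlap = 0L) {
  epoch_len <- as.integer(epoch_len); overlap <- as.integer(overlap)
  if (epoch_len < 2L) {
    stop_gasfeeg("gasfeeg_config_error", "epoch_len must be >= 2")
  }
  if (overlap < 0L || overlap >= epoch_len) {
    stop_gasfeeg("gasfeeg_config_error", "need 0 <= overlap < epoch_len")
  }
  structure(list(epoch_len = epoch_len, overlap = overlap),
            class = "epoching_config")
}

#' Segment a signal into fixed-length epochs
#'
#' Consecutive windows with the configured overlap; a trailing partial window
#' is dropped, so a signal shorter than one epoch yields an empty list.
#'
#' @param signal an `eeg_signal`.
#' @param cfg an [epoching_config()].
#' @return list of numeric vectors of length `epoch_len`.
#' @export
segment_epochs <- function(signal, cfg = epoching_config()) {
  stopifnot(inherits(signal, "eeg_signal"), inherits(cfg, "epoching_config"))
  n <- length(signal$samples)
  l <- cfg$epoch_len
  step <- l - cfg$overlap
  if (n < l) return(list())
  starts <- seq.int(1L, n - l + 1L, by = step)
  lapply(starts, function(s) signal$samples[s:(s + l - 1L)])
}

#' Min-max rescale an epoch for angular encoding
#'
#' Two modes are supported. `"symmetric"` (the default) maps the epoch
#' linearly onto `[-1, 1]`, the range the angular-field construction calls
#' for. `"unit"` maps onto `[0, 1]`, i.e. the plain min-max form
#' `(t - min) / (max - min)`; the two conventions disagree in parts of the
#' literature, so both are implemented (see the methods vignette). Values are
#' clipped to the closed target range to absorb floating-point excess before
#' `acos`.
#'
#' @param epoch numeric vector with `max > min`.
#' @param mode `"symmetric"` or `"unit"`.
#' @return a `normalized_series` list with `values`, `phases = acos(values)`,
#'   and `rescale_mode`.
#' @export
gasf_rescale <- function(epoch, mode = c("symmetric", "unit")) {
  mode <- match.arg(mode)
  epoch <- as.numeric(epoch)
  lo <- min(epoch); hi <- max(epoch)
  if (hi <= lo) {
    stop_gasfeeg("gasfeeg_degenerate_signal",
                 "constant epoch: min-max rescaling is undefined")
  }
  u <- (epoch - lo) / (hi - lo)
  v <- if (mode == "symmetric") 2 * u - 1 else u
  rng <- if (mode == "symmetric") c(-1, 1) else c(0, 1)
  v <- pmin(pmax(v, rng[1]), rng[2])
  structure(list(values = v, phases = acos(pmin(pmax(v, -1), 1)),
                 rescale_mode = mode),
            class = "normalized_series")
}

#' Polar phase of a rescaled series
#'
#' `phi_i = acos(x_i)`, each in `[0, pi]`. [gasf_rescale()] already fills
#' phases; this is the standalone form for values produced elsewhere.
#'
#' @param values numeric vector in `[-1, 1]` (tolerance 1e-12, then clipped).
#' @return phases in radians.
#' @export
gasf_phase <- function(values) {
  if (any(values < -1 - 1e-12 | values > 1 + 1e-12)) {
    stop_gasfeeg("gasfeeg_internal_error",
                 "rescaled values outside [-1, 1] beyond tolerance")
  }
  acos(pmin(pmax(values, -1), 1))
}

#' Gramian angular summation field of a rescaled epoch
#'
#' `G[i, j] = cos(phi_i + phi_j)`, evaluated through the algebraic identity
#' `x_i x_j - sqrt(1 - x_i^2) sqrt(1 - x_j^2)` so the whole matrix is two
#' outer products. The result is symmetric with diagonal `2 x_i^2 - 1` and
#' entries in `[-1, 1]`.
#'
#' @param series a `normalized_series` from [gasf_rescale()].
#' @param epoch_index,source_id provenance carried on the result.
#' @return a `gasf_matrix`: numeric `l x l` matrix with attributes.
#' @export
gasf_matrix <- function(series, epoch_index = NA_integer_, source_id = NA_character_) {
  stopifnot(inherits(series, "normalized_series"))
  x <- series$values
  s <- sqrt(pmax(0, 1 - x^2))
  g <- outer(x, x) - outer(s, s)
  g <- pmin(pmax(g, -1), 1)
  structure(g, class = c("gasf_matrix", class(g)),
            epoch_index = epoch_index, source_id = source_id,
            rescale_mode = series$rescale_mode)
}

#' Quantize a GASF matrix to an 8-bit grayscale image
#'
#' `pixel = round(255 * (v + 1) / 2)` with round-half-up, so -1 maps to 0,
#' 0 to 128, and +1 to 255. Deterministic and bit-exact, suitable for golden
#' images.
#'
#' @param matrix a `gasf_matrix` (entries in `[-1, 1]`).
#' @return a `gasf_image`: integer matrix in `[0, 255]` with the matrix's
#'   provenance attributes.
#' @export
gasf_quantize <- function(matrix) {
  px <- as.integer(floor(255 * (unclass(matrix) + 1) / 2 + 0.5))
  dim(px) <- dim(matrix)
  structure(px, class = c("gasf_image", "matrix"),
            epoch_index = attr(matrix, "epoch_index"),
            source_id = attr(matrix, "source_id"),
            rescale_mode = attr(matrix, "rescale_mode"))
}

#' @export
print.gasf_image <- function(x, ...) {
  cat(sprintf("<gasf_image> %d x %d, source=%s epoch=%s\n",
              nrow(x), ncol(x), attr(x, "source_id"), attr(x, "epoch_index")))
  invisible(x)
}

#' Encode a whole signal as GASF images
#'
#' Composition of [segment_epochs()], [gasf_rescale()] (per epoch, inside the
#' epoch loop), [gasf_matrix()] and [gasf_quantize()]. A 10,240-sample signal
#' yields 40 images of 256 x 256 under the defaults.
#'
#' @param signal an `eeg_signal`.
#' @param cfg an [epoching_config()].
#' @param rescale_mode passed to [gasf_rescale()].
#' @return list of `gasf_image`s tagged with the signal id and epoch index.
#' @export
signal_to_images <- function(signal, cfg = epoching_config(),
                             rescale_mode = "symmetric") {
  epochs <- segment_epochs(signal, cfg)
  lapply(seq_along(epochs), function(k) {
    ns <- tryCatch(gasf_rescale(epochs[[k]], rescale_mode),
      gasfeeg_degenerate_signal = function(e) {
        stop_gasfeeg("gasfeeg_degenerate_signal",
                     "constant epoch %d of signal '%s'", k, signal$id)
      })
    gasf_quantize(gasf_matrix(ns, epoch_index = k, source_id = signal$id))
  })
}

#' Write a GASF image as an 8-bit grayscale PNG
#'
#' Files are named `<source_id>_e<epoch_index>.png` when `path` is a
#' directory.
#'
#' @param image a `gasf_image`.
#' @param path output file, or an existing directory.
#' @return the file path, invisibly.
#' @export
write_gasf_png <- function(image, path) {
  stopifnot(inherits(image, "gasf_image"))
  if (dir.exists(path)) {
    path <- file.path(path, sprintf("%s_e%d.png", attr(image, "source_id"),
                                    attr(image, "epoch_index")))
  }
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}
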