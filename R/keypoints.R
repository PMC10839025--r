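#' Keypoint extractor configuration
#'
#' Thresholds follow the standard published algorithm definitions; none are
#' tuned to any particular dataset. `contrast_thresh` and `edge_thresh`
#' control the DoG (SIFT) detector's low-contrast and edge-response
#' rejection; `fast_thresh` (on the 0-255 intensity scale) and
#' `pyramid_levels` control the FAST detector behind ORB. `orb_bits` is the
#' binary descriptor length and may be 128, 256 or 512 (default 128, i.e.
#' 16-byte descriptors). `max_keypoints = 0` means no cap.
#'
#' @param method `"sift"` or `"orb"`.
#' @param orb_bits BRIEF string length in bits.
#' @param contrast_thresh DoG contrast threshold on \[0,1\] intensities.
#' @param edge_thresh principal-curvature ratio for edge rejection.
#' @param fast_thresh FAST segment-test threshold (0-255 scale).
#' @param pyramid_levels ORB scale-pyramid depth (factor 1.2 per level).
#' @param max_keypoints keep at most this many strongest keypoints (0 = all).
#' @return an `extractor_config` list.
#' @export
extractor_config <- function(method = c("sift", "orb"), orb_bits = 128L,
                             contrast_thresh = 0.03, edge_thresh = 10,
                             fast_thresh = 20, pyramid_levels = 4L,
                             max_keypoints = 500L) {
  if (!is.character(method) || !all(method %in% c("sift", "orb"))) {
    stop_gasfeeg("gasfeeg_config_error",
                 "unsupported extractor method: %s", paste(method, collapse = ","))
  }
  method <- match.arg(method)
  if (!orb_bits %in% c(128L, 256L, 512L)) {
    stop_gasfeeg("gasfeeg_config_error", "orb_bits must be 128, 256 or 512")
  }
  structure(list(method = method, orb_bits = as.integer(orb_bits),
                 contrast_thresh = contrast_thresh, edge_thresh = edge_thresh,
                 fast_thresh = fast_thresh,
                 pyramid_levels = as.integer(pyramid_levels),
                 max_keypoints = as.integer(max_keypoints)),
            class = "extractor_config")
}

as_intensity <- function(image) {
  if (inherits(image, "gasf_image")) return(unclass(image) / 255)
  m <- as.matrix(image)
  if (max(m) > 1) m / 255 else m
}

#' Extract keypoints and descriptors from a GASF image
#'
#' SIFT descriptors are rows of 128 reals (4x4 spatial bins x 8 orientation
#' bins, normalised). ORB descriptors are binary strings packed as raw bytes,
#' `orb_bits / 8` bytes per row (16 bytes for the 128-bit default); use
#' [orb_unpack()] to expand them to 0/1 columns. Extraction is deterministic:
#' the same bytes always yield the same keypoints and descriptors. An image
#' with no detectable structure yields an empty set.
#'
#' @param image a `gasf_image` (or any 8-bit / \[0,1\] grayscale matrix).
#' @param cfg an [extractor_config()].
#' @return a `descriptor_set`: list with `image_id`, `method`, `keypoints`
#'   (data.frame: x, y, scale, orientation, response; x = 0-based column) and
#'   `descriptors` (numeric matrix for SIFT, raw matrix for ORB).
#' @export
extract_keypoints <- function(image, cfg = extractor_config()) {
  stopifnot(inherits(cfg, "extractor_config"))
  m <- as_intensity(image)
  id <- if (inherits(image, "gasf_image")) {
    sprintf("%s_e%s", attr(image, "source_id"), attr(image, "epoch_index"))
  } else "image"
  res <- if (cfg$method == "sift") {
    .sift_extract(m, cfg$contrast_thresh, cfg$edge_thresh, cfg$max_keypoints)
  } else {
    .orb_extract(m, cfg$fast_thresh / 255, cfg$pyramid_levels, 1.2,
                 cfg$max_keypoints, cfg$orb_bits)
  }
  kp <- data.frame(x = res$x, y = res$y, scale = res$scale,
                   orientation = res$orientation, response = res$response)
  desc <- res$descriptors
  if (cfg$method == "orb") desc <- orb_pack(desc)
  structure(list(image_id = id, method = cfg$method,
                 keypoints = kp, descriptors = desc),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set> %s: %d %s keypoint(s)\n",
              x$image_id, nrow(x$keypoints), toupper(x$method)))
  invisible(x)
}

#' Pack a 0/1 bit matrix into raw bytes (one row per descriptor)
#'
#' Bits fill bytes most-significant-bit first; column count must be a
#' multiple of 8.
#'
#' @param bits integer/logical matrix of 0s and 1s.
#' @return raw matrix with `ncol(bits) / 8` columns.
#' @export
orb_pack <- function(bits) {
  bits <- as.matrix(bits)
  stopifnot(ncol(bits) %% 8 == 0)
  nb <- ncol(bits) %/% 8
  out <- matrix(as.raw(0), nrow(bits), nb)
  if (nrow(bits) == 0) return(out)
  w <- 2^(7:0)
  for (j in seq_len(nb)) {
    block <- bits[, ((j - 1) * 8 + 1):(j * 8), drop = FALSE]
    out[, j] <- as.raw(block %*% w)
  }
  out
}

#' Unpack raw descriptor bytes into a 0/1 numeric matrix
#'
#' Inverse of [orb_pack()]; used to place binary descriptors in a real vector
#' space for k-means clustering.
#'
#' @param bytes raw matrix, one descriptor per row.
#' @return numeric matrix of 0/1 with `8 * ncol(bytes)` columns.
#' @export
orb_unpack <- function(bytes) {
  stopifnot(is.raw(bytes))
  if (is.null(dim(bytes))) bytes <- matrix(bytes, nrow = 1)
  n <- nrow(bytes); nb <- ncol(bytes)
  out <- matrix(0, n, nb * 8)
  if (n == 0) return(out)
  for (j in seq_len(nb)) {
    ints <- as.integer(bytes[, j])
    for (b in 0:7) {
      out[, (j - 1) * 8 + b + 1] <- (ints %/% 2^(7 - b)) %% 2
    }
  }
  out
}

#' Extract descriptors from a batch of images
#'
#' Order-preserving and per-image independent: the result for each image is
#' exactly what [extract_keypoints()] returns for it alone. Errors are
#' re-raised with the offending image's id.
#'
#' @param images list of `gasf_image`s.
#' @param cfg an [extractor_config()].
#' @return list of `descriptor_set`s.
#' @export
extract_batch <- function(images, cfg = extractor_config()) {
  if (length(images) == 0L) {
    stop_gasfeeg("gasfeeg_config_error", "empty image batch")
  }
  lapply(seq_along(images), function(i) {
    tryCatch(extract_keypoints(images[[i]], cfg), error = function(e) {
      id <- if (inherits(images[[i]], "gasf_image")) {
        sprintf("%s_e%s", attr(images[[i]], "source_id"),
                attr(images[[i]], "epoch_index"))
      } else sprintf("image %d", i)
      stop_gasfeeg("gasfeeg_batch_error", "[%s] %s", id, conditionMessage(e))
    })
  })
}

#' Number of descriptors in a descriptor set
#' @param dset a `descriptor_set`.
#' @return integer count.
#' @export
n_descriptors <- function(dset) nrow(dset$keypoints)

# Descriptors of a set as a real-valued matrix (ORB bytes unpacked to bits).
descriptor_matrix <- function(dset) {
  if (dset$method == "orb") orb_unpack(dset$descriptors) else dset$descriptors
}
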