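#' Multi-coil k-t dataset
#'
#' Container for dynamic Cartesian multi-coil k-space data. The k-space
#' array is stored `[k_y, k_x, frame, coil]` (phase-encode, frequency-encode,
#' time, coil), DC-centered along both k-space axes.
#'
#' @param kspace complex 4-D array `[n_pe, n_fe, n_frames, n_coils]`.
#' @param reference optional fully sampled complex k-space of the same
#'   shape, used for metric computation.
#' @param plan optional [sampling_plan()] the data was masked with.
#' @return an object of class `kt_dataset`.
#' @export
kt_dataset <- function(kspace, reference = NULL, plan = NULL) {
  if (length(dim(kspace)) != 4L) {
    stop("kspace must be a 4-D array [k_y, k_x, frame, coil]")
  }
  if (!is.complex(kspace)) kspace <- kspace + 0i
  if (!is.null(reference) && !identical(dim(reference), dim(kspace))) {
    stop("reference must have the same shape as kspace")
  }
  structure(list(kspace = kspace, reference = reference, plan = plan),
            class = "kt_dataset")
}

#' @export
print.kt_dataset <- function(x, ...) {
  d <- dim(x$kspace)
  cat(sprintf("<kt_dataset> %d PE x %d FE x %d frames x %d coils%s\n",
              d[1], d[2], d[3], d[4],
              if (is.null(x$reference)) "" else " (+reference)"))
  invisible(x)
}

# accept a kt_dataset or a bare 4-D array
as_kspace <- function(data) {
  if (inherits(data, "kt_dataset")) data$kspace else data
}

#' Apply a sampling mask to k-t data
#'
#' Zero-fills every phase-encode line not present in the mask; acquired
#' lines are passed through bit-identically. Idempotent.
#'
#' @param data a [kt_dataset()] or complex array `[k_y, k_x, frame, coil]`
#'   (a 3-D single-coil array `[k_y, k_x, frame]` is also accepted).
#' @param mask logical frame x phase-encode matrix.
#' @return same type as `data`, with unacquired lines exactly zero.
#' @export
apply_mask <- function(data, mask) {
  k <- as_kspace(data)
  d <- dim(k)
  single <- length(d) == 3L
  if (single) {
    dim(k) <- c(d, 1L)
    d <- dim(k)
  }
  if (nrow(mask) != d[3] || ncol(mask) != d[1]) {
    stop("mask shape must be n_frames x n_pe")
  }
  for (f in seq_len(d[3])) {
    k[!mask[f, ], , f, ] <- 0i
  }
  if (single) dim(k) <- d[1:3]
  if (inherits(data, "kt_dataset")) {
    data$kspace <- k
    data
  } else {
    k
  }
}

#' Reconstruct per-coil complex images from k-space
#'
#' Centered unitary 2-D inverse DFT of each frame and coil.
#'
#' @param data a [kt_dataset()] or complex `[k_y, k_x, frame, coil]` array.
#' @return complex array `[y, x, frame, coil]`.
#' @export
coil_images <- function(data) {
  kspace_to_image(as_kspace(data))
}

#' Magnitude image series
#'
#' @param magnitude nonnegative real array `[y, x, frame]`.
#' @param provenance character tag naming the pipeline that produced it.
#' @return an object of class `image_series`.
#' @export
image_series <- function(magnitude, provenance = "unknown") {
  if (length(dim(magnitude)) != 3L) stop("magnitude must be [y, x, frame]")
  if (any(magnitude < 0)) stop("magnitude must be nonnegative")
  structure(list(magnitude = magnitude, provenance = provenance),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf("<image_series> %d x %d x %d frames (%s)\n",
              d[1], d[2], d[3], x$provenance))
  invisible(x)
}
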