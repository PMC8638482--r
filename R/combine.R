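#' @title Coil combination and evaluation metrics
#' @name ktjoint-combine
NULL

#' Root-sum-of-squares coil combination
#'
#' Per voxel, the square root of the sum over coils of squared magnitudes —
#' the standard sensitivity-map-free magnitude combination. Invariant to
#' per-coil phase.
#'
#' @param coil_imgs complex array `[y, x, frame, coil]` of per-coil images.
#' @param provenance tag passed to [image_series()].
#' @return an [image_series()].
#' @export
rss_combine <- function(coil_imgs, provenance = "rss") {
  d <- dim(coil_imgs)
  stopifnot(length(d) == 4L)
  mag <- sqrt(rowSums(Mod(coil_imgs)^2, dims = 3L))
  image_series(mag, provenance)
}

#' Normalized mean-square error per frame
#'
#' `||ref - recon||^2 / ||ref||^2` over the region-of-interest voxels,
#' computed frame by frame on unnormalized magnitudes.
#'
#' @param ref reference [image_series()] (or magnitude array).
#' @param recon reconstructed [image_series()] (or magnitude array).
#' @param roi optional logical `y` x `x` matrix; `NULL` uses the full frame.
#' @return numeric vector of per-frame NMSE values.
#' @export
nmse <- function(ref, recon, roi = NULL) {
  a <- if (inherits(ref, "image_series")) ref$magnitude else ref
  b <- if (inherits(recon, "image_series")) recon$magnitude else recon
  if (!identical(dim(a), dim(b))) stop("ref and recon shapes disagree")
  if (is.null(roi)) roi <- matrix(TRUE, dim(a)[1], dim(a)[2])
  vapply(seq_len(dim(a)[3]), function(f) {
    rf <- a[, , f][roi]
    rc <- b[, , f][roi]
    e <- sum(rf^2)
    if (e == 0) stop("zero reference energy in ROI at frame ", f)
    sum((rf - rc)^2) / e
  }, numeric(1))
}

#' Temporal profile along one spatial column
#'
#' Extracts the magnitude of a single x-column across all frames — the x-t
#' plane plot used to judge how well a reconstruction preserves temporal
#' variation.
#'
#' @param series an [image_series()] (or magnitude array `[y, x, frame]`).
#' @param x_column 1-based column index.
#' @return real matrix `frame` x `y`.
#' @export
temporal_profile <- function(series, x_column) {
  m <- if (inherits(series, "image_series")) series$magnitude else series
  if (x_column < 1L || x_column > dim(m)[2]) stop("x_column out of bounds")
  t(m[, x_column, ])
}
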