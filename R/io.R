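#' @title On-disk formats
#' @description Serialization of datasets and results: RDS for the k-t
#' container and sampling plans, NIfTI-1 for magnitude image series (frame
#' as the temporal dimension), CSV for metric tables.
#' @name ktjoint-io
NULL

#' Save / load a k-t dataset or sampling plan
#'
#' Single-file RDS serialization of the container (complex k-space,
#' optional reference, attached plan).
#'
#' @param x a [kt_dataset()] or [sampling_plan()].
#' @param path file path.
#' @return `save_ktdata` returns `path` invisibly; `load_ktdata` returns
#'   the restored object.
#' @export
save_ktdata <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_ktdata
#' @export
load_ktdata <- function(path) {
  readRDS(path)
}

#' Export a magnitude image series to NIfTI-1
#'
#' Writes `[x, y, 1, frame]` so viewers treat the frame axis as time.
#'
#' @param series an [image_series()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path` invisibly.
#' @export
write_nifti_series <- function(series, path) {
  m <- series$magnitude
  d <- dim(m)
  vol <- aperm(m, c(2L, 1L, 3L))
  dim(vol) <- c(d[2], d[1], 1L, d[3])
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' Export per-frame NMSE values to CSV
#'
#' @param nmse_values numeric vector (per frame) or a sweep table from
#'   [sweep_acceleration()] / [sweep_acs()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_nmse_csv <- function(nmse_values, path) {
  tab <- if (is.data.frame(nmse_values)) nmse_values else
    data.frame(frame = seq_along(nmse_values), nmse = nmse_values)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
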