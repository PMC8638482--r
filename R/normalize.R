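#' @title Inter-stage scaling normalization
#' @description The FOCUSS stage can return k-space whose scale (and global
#' phase) differs from the acquisition; the two are modeled as differing by
#' a complex scalar, `d_recon = beta * d_acq`, and the reconstruction is
#' divided by the least-squares `beta` estimated on the k-space locations
#' where reconstructed and acquired data overlap, per frame and per coil.
#' @name ktjoint-normalize
NULL

#' Estimate the complex scaling factor between reconstruction and acquisition
#'
#' Least-squares fit of the scaling model `recon = beta * acq` over the
#' overlap locations: `beta = <acq, recon> / ||acq||^2`.
#'
#' @param recon complex vector/array of reconstructed samples.
#' @param acq complex vector/array of acquired samples, same shape.
#' @param overlap_mask logical, same shape: where both are observed.
#' @return an object of class `scale_estimate`: `beta` (complex scalar),
#'   `n_overlap`, and `residual_rel` (relative LS residual on the overlap).
#' @export
estimate_beta <- function(recon, acq, overlap_mask = NULL) {
  if (is.null(overlap_mask)) overlap_mask <- rep(TRUE, length(recon))
  r <- recon[overlap_mask]
  a <- acq[overlap_mask]
  if (length(a) < 1L) stop("overlap is empty")
  aa <- sum(Mod(a)^2)
  if (aa == 0) stop("acquired overlap energy is zero")
  beta <- sum(Conj(a) * r) / aa
  rr <- sqrt(sum(Mod(r)^2))
  residual_rel <- if (rr > 0) sqrt(sum(Mod(r - beta * a)^2)) / rr else 0
  structure(list(beta = beta, n_overlap = length(a),
                 residual_rel = residual_rel),
            class = "scale_estimate")
}

#' @export
print.scale_estimate <- function(x, ...) {
  cat(sprintf("<scale_estimate> |beta|=%.6g arg=%.4g rad (n=%d, resid=%.3g)\n",
              Mod(x$beta), Arg(x$beta), x$n_overlap, x$residual_rel))
  invisible(x)
}

# per (frame, coil) beta over the acquired-line overlap
estimate_betas <- function(recon4, acq4, overlap_mask) {
  d <- dim(recon4)
  betas <- matrix(0i, d[3], d[4])
  resid <- matrix(0, d[3], d[4])
  for (f in seq_len(d[3])) {
    rows <- overlap_mask[f, ]
    for (cc in seq_len(d[4])) {
      est <- estimate_beta(recon4[rows, , f, cc], acq4[rows, , f, cc])
      betas[f, cc] <- est$beta
      resid[f, cc] <- est$residual_rel
    }
  }
  list(beta = betas, residual_rel = resid)
}

#' Apply the scaling normalization
#'
#' Divides the reconstructed samples of each frame and coil by its
#' estimated `beta` so the reconstruction matches the acquired scale.
#' Locations flagged as acquired (already carrying measured data) are left
#' untouched.
#'
#' @param recon complex array `[n_pe, n_fe, n_frames, n_coils]` of stage-1
#'   output.
#' @param beta complex matrix `[n_frames, n_coils]` (or a scalar, recycled).
#' @param acquired_mask optional logical frame x phase-encode matrix of
#'   measured lines to leave untouched; `NULL` (default) rescales
#'   everything.
#' @return the normalized array.
#' @export
apply_normalization <- function(recon, beta, acquired_mask = NULL) {
  d <- dim(recon)
  if (length(beta) == 1L) beta <- matrix(beta, d[3], d[4])
  if (any(Mod(beta) < 1e-12)) stop("degenerate scale: |beta| below 1e-12")
  out <- recon
  for (f in seq_len(d[3])) {
    keep <- if (is.null(acquired_mask)) rep(FALSE, d[1]) else acquired_mask[f, ]
    for (cc in seq_len(d[4])) {
      scaled <- recon[, , f, cc] / beta[f, cc]
      if (any(keep)) scaled[keep, ] <- recon[keep, , f, cc]
      out[, , f, cc] <- scaled
    }
  }
  out
}
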