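#' @title Two-stage reconstruction pipeline and experiment harnesses
#' @description Orchestrates the proposed reconstruction (per-coil FOCUSS,
#' scaling normalization, nonlinear GRAPPA lattice completion,
#' root-sum-of-squares combination), the coil-wise CS-only baseline, the
#' zero-filled baseline, and the two parameter-sweep experiments
#' (acceleration splits and ACS counts at a fixed net reduction factor).
#' @name ktjoint-pipeline
NULL

#' Reconstruction configuration
#'
#' @param method `"proposed"` (two-stage), `"cs_only"` (coil-wise FOCUSS on
#'   the full acquired mask, no lattice completion), or `"zero_filled"`.
#' @param focuss a [focuss_state()].
#' @param nlg_b1,nlg_b2,nlg_h1,nlg_h2 nonlinear GRAPPA geometry.
#' @param nlg_reg_rel calibration Tikhonov parameter, see
#'   [nlg_calibrate()].
#' @param nlg_second_order include second-order feature groups.
#' @param nlg_edge_mode `"zero"` or `"strict"`.
#' @param roi optional logical ROI matrix for metrics.
#' @return an object of class `recon_config`.
#' @export
recon_config <- function(method = c("proposed", "cs_only", "zero_filled"),
                         focuss = focuss_state(),
                         nlg_b1 = -1L, nlg_b2 = 2L, nlg_h1 = -2L, nlg_h2 = 2L,
                         nlg_reg_rel = 1e-6, nlg_second_order = TRUE,
                         nlg_edge_mode = "zero", roi = NULL) {
  structure(list(method = match.arg(method), focuss = focuss,
                 nlg_b1 = nlg_b1, nlg_b2 = nlg_b2,
                 nlg_h1 = nlg_h1, nlg_h2 = nlg_h2,
                 nlg_reg_rel = nlg_reg_rel,
                 nlg_second_order = nlg_second_order,
                 nlg_edge_mode = nlg_edge_mode, roi = roi),
            class = "recon_config")
}

# stage 1 over all coils; data_consistency as in focuss_reconstruct
stage1_all_coils <- function(kspace, plan, state, lattice, data_consistency) {
  d <- dim(kspace)
  out <- array(0i, d)
  for (cc in seq_len(d[4])) {
    out[, , , cc] <- focuss_reconstruct(kspace[, , , cc, drop = TRUE], plan,
                                        state, lattice = lattice,
                                        data_consistency = data_consistency)
  }
  out
}

#' Complete the k-space of a dataset with the selected method
#'
#' Runs the reconstruction up to (but not including) coil combination,
#' returning completed multi-coil k-space. Useful for stage isolation and
#' for serializing stage-1 output.
#'
#' @param data a [kt_dataset()] masked consistently with `plan`.
#' @param plan a [sampling_plan()].
#' @param cfg a [recon_config()].
#' @return complex array `[n_pe, n_fe, n_frames, n_coils]`.
#' @export
reconstruct_kspace <- function(data, plan, cfg = recon_config()) {
  k <- as_kspace(data)
  switch(cfg$method,
    zero_filled = k,
    cs_only = {
      # treat the whole acquired set as the CS mask; FOCUSS fills all lines
      stage1_all_coils(k, plan, cfg$focuss, lattice = "full",
                       data_consistency = TRUE)
    },
    proposed = {
      s1 <- stage1_all_coils(k, plan, cfg$focuss, lattice = "uniform",
                             data_consistency = FALSE)
      s1n <- normalize_stage1(s1, k, plan)
      if (plan$r1 > 1L) {
        geom <- kernel_geometry(dim(k)[4], plan$r1, cfg$nlg_b1, cfg$nlg_b2,
                                cfg$nlg_h1, cfg$nlg_h2, cfg$nlg_second_order)
        kern <- nlg_calibrate(k, plan$acs_mask, geom, cfg$nlg_reg_rel)
        nlg_apply(s1n, kern, plan, measured = k,
                  edge_mode = cfg$nlg_edge_mode)
      } else {
        s1n
      }
    }
  )
}

#' Normalize stage-1 output against the acquisition
#'
#' Estimates the per-frame, per-coil complex scaling factor on the overlap
#' of reconstructed and acquired lines, divides the reconstruction by it,
#' and reinstates the measured samples at acquired locations.
#'
#' @param s1 raw stage-1 k-space (no data-consistency override),
#'   `[n_pe, n_fe, n_frames, n_coils]`.
#' @param acq the masked acquired k-space, same shape.
#' @param plan a [sampling_plan()].
#' @return normalized, measurement-consistent k-space; attribute
#'   `"betas"` holds the estimate table.
#' @export
normalize_stage1 <- function(s1, acq, plan) {
  # overlap: acquired lines within the uniform lattice — the only locations
  # where stage-1 reconstruction and acquisition both exist
  est <- estimate_betas(s1, acq, plan$acquired_mask & plan$uniform_mask)
  out <- apply_normalization(s1, est$beta, acquired_mask = NULL)
  # measured samples take precedence over rescaled reconstruction
  for (f in seq_len(dim(acq)[3])) {
    rows <- plan$acquired_mask[f, ]
    out[rows, , f, ] <- acq[rows, , f, ]
  }
  attr(out, "betas") <- est
  out
}

#' Run a full reconstruction to a magnitude image series
#'
#' `"proposed"`: per-coil FOCUSS on the random subset, scaling
#' normalization, nonlinear GRAPPA lattice completion, RSS combination.
#' `"cs_only"`: per-coil FOCUSS treating the full acquired mask as the CS
#' mask (no lattice completion), RSS — the coil-wise CS baseline.
#' `"zero_filled"`: inverse DFT of the zero-filled data, RSS.
#'
#' @inheritParams reconstruct_kspace
#' @return an [image_series()] tagged with the method.
#' @export
run_reconstruction <- function(data, plan, cfg = recon_config()) {
  kfull <- reconstruct_kspace(data, plan, cfg)
  rss_combine(coil_images(kfull), provenance = cfg$method)
}

#' Reference image series of a dataset
#'
#' RSS combination of the fully sampled reference k-space.
#'
#' @param data a [kt_dataset()] carrying a `reference`.
#' @return an [image_series()].
#' @export
reference_images <- function(data) {
  if (is.null(data$reference)) stop("dataset carries no fully sampled reference")
  rss_combine(coil_images(data$reference), provenance = "reference")
}

sweep_one <- function(kfull, n_pe, n_fe, n_frames, r1, r2, n_acs, cfg, seed,
                      ref_imgs, label) {
  plan <- sampling_plan(n_pe, n_fe, n_frames, r1 = r1, r2 = r2, n_acs = n_acs,
                        seed = seed)
  masked <- kt_dataset(apply_mask(kfull, plan$acquired_mask), plan = plan)
  rec <- run_reconstruction(masked, plan, cfg)
  err <- nmse(ref_imgs, rec, cfg$roi)
  data.frame(label = label, r1 = r1, r2 = r2, n_acs = n_acs,
             net_r = net_reduction_factor(n_pe, r1, r2, n_acs),
             frame = seq_along(err), nmse = err)
}

#' Sweep acceleration splits at a fixed net reduction factor
#'
#' Retrospectively undersamples a fully sampled dataset with each
#' `(r1, r2)` split (fixed ACS count), runs the proposed reconstruction,
#' and tabulates frame-wise NMSE against the dataset's reference. All
#' splits must yield the same net reduction factor within `tol`.
#' Orderings across splits are reported, not asserted: which split wins is
#' data-dependent.
#'
#' @param data a [kt_dataset()] whose `reference` (or `kspace`) is fully
#'   sampled.
#' @param net_r the common net reduction factor of all splits.
#' @param splits list of `c(r1, r2)` pairs.
#' @param n_acs ACS count shared by all splits.
#' @param cfg a [recon_config()] (method forced to `"proposed"`).
#' @param seed sampling seed.
#' @param tol allowed net-R deviation per split (default 0.05).
#' @return long data frame with columns label, r1, r2, n_acs, net_r,
#'   frame, nmse.
#' @export
sweep_acceleration <- function(data, net_r, splits, n_acs,
                               cfg = recon_config(), seed = 1L, tol = 0.05) {
  kfull <- if (!is.null(data$reference)) data$reference else as_kspace(data)
  d <- dim(kfull)
  for (s in splits) {
    r <- net_reduction_factor(d[1], s[1], s[2], n_acs)
    if (abs(r - net_r) > tol) {
      stop(sprintf("split %dx%g has net R = %.3f, not %.3f within %.2f",
                   s[1], s[2], r, net_r, tol))
    }
  }
  cfg$method <- "proposed"
  ref_imgs <- rss_combine(coil_images(kfull))
  out <- lapply(splits, function(s) {
    sweep_one(kfull, d[1], d[2], d[3], s[1], s[2], n_acs, cfg, seed,
              ref_imgs, sprintf("%dx%g", s[1], s[2]))
  })
  do.call(rbind, out)
}

#' Sweep ACS counts at a fixed net reduction factor
#'
#' As [sweep_acceleration()], but each combination supplies its own
#' `(r1, r2, n_acs)` triple; all must match `net_r` within `tol`.
#'
#' @inheritParams sweep_acceleration
#' @param combos list of `c(r1, r2, n_acs)` triples.
#' @return long data frame as in [sweep_acceleration()].
#' @export
sweep_acs <- function(data, net_r, combos, cfg = recon_config(), seed = 1L,
                      tol = 0.05) {
  kfull <- if (!is.null(data$reference)) data$reference else as_kspace(data)
  d <- dim(kfull)
  for (s in combos) {
    r <- net_reduction_factor(d[1], s[1], s[2], s[3])
    if (abs(r - net_r) > tol) {
      stop(sprintf("combo %dx%g ACS=%d has net R = %.3f, not %.3f within %.2f",
                   s[1], s[2], s[3], r, net_r, tol))
    }
  }
  cfg$method <- "proposed"
  ref_imgs <- rss_combine(coil_images(kfull))
  out <- lapply(combos, function(s) {
    sweep_one(kfull, d[1], d[2], d[3], s[1], s[2], s[3], cfg, seed,
              ref_imgs, sprintf("%dx%g/ACS%d", s[1], s[2], s[3]))
  })
  do.call(rbind, out)
}
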