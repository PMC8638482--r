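#' @title Stage 2: nonlinear GRAPPA lattice completion
#' @description Fills the phase-encode lines missing from the uniform
#' lattice by a truncated second-order polynomial interpolation of the
#' acquired/reconstructed lattice lines across all coils. Each missing
#' sample at offset `r` above a lattice line is predicted from a
#' neighborhood of `B = b2-b1+1` lattice lines and `H = h2-h1+1` read-out
#' columns in every coil, using (in fixed order) a constant term, the
#' first-order source values, their squares, adjacent-column products, and
#' skip-one-column products. Kernel coefficients are calibrated on the
#' fully sampled ACS block, jointly over all frames, by Tikhonov-regularized
#' least squares.
#' @name ktjoint-nlgrappa
NULL

#' Nonlinear GRAPPA kernel geometry
#'
#' @param n_coils number of coils L.
#' @param orf outer reduction factor R: the uniform lattice spacing
#'   (must equal the sampling plan's `r1`).
#' @param b1,b2 source block range along phase-encode, in units of
#'   `R * dky`; defaults `-1..2` give 4 source lines bracketing the target.
#' @param h1,h2 source column range along read-out, in units of `dkx`;
#'   defaults `-2..2` give 5 columns.
#' @param second_order include the second-order feature groups (squares and
#'   cross products). With `FALSE`, the kernel reduces to conventional
#'   linear GRAPPA (plus the constant term) on the same geometry.
#' @return an object of class `kernel_geometry`.
#' @export
kernel_geometry <- function(n_coils, orf, b1 = -1L, b2 = 2L,
                            h1 = -2L, h2 = 2L, second_order = TRUE) {
  stopifnot(n_coils >= 1, orf >= 1, b1 <= b2, h1 <= h2)
  if (!(b1 <= 0 && b2 >= 0)) {
    stop("source blocks must surround the target line (b1 <= 0 <= b2)")
  }
  structure(list(n_coils = as.integer(n_coils), orf = as.integer(orf),
                 b1 = as.integer(b1), b2 = as.integer(b2),
                 h1 = as.integer(h1), h2 = as.integer(h2),
                 offsets = if (orf > 1) seq_len(orf - 1L) else integer(0),
                 second_order = isTRUE(second_order)),
            class = "kernel_geometry")
}

#' Number of features of a nonlinear GRAPPA kernel
#'
#' `1 + L*B*H` (constant + first order) plus, if second order is enabled,
#' `L*B*H + L*B*max(H-1,0) + L*B*max(H-2,0)` (squares, adjacent products,
#' skip-one products), with `B = b2-b1+1`, `H = h2-h1+1`.
#'
#' @param geom a [kernel_geometry()].
#' @return integer feature count.
#' @export
n_features <- function(geom) {
  L <- geom$n_coils
  B <- geom$b2 - geom$b1 + 1L
  H <- geom$h2 - geom$h1 + 1L
  n <- 1L + L * B * H
  if (geom$second_order) {
    n <- n + L * B * H + L * B * max(H - 1L, 0L) + L * B * max(H - 2L, 0L)
  }
  n
}

# gather source values S_l(ky0 + b*R, kx + h) for a vector of kx positions.
# slab: [n_pe, n_fe, n_coils] (one frame); ky0 0-based reference lattice
# line; returns list of matrices src[[l]][[b]][[h]] -> complex vector
# over kx, with out-of-bounds sources zero-filled or rejected.
gather_sources <- function(slab, ky0, kx, geom, edge_mode = c("zero", "strict")) {
  edge_mode <- match.arg(edge_mode)
  d <- dim(slab)
  n_pe <- d[1]; n_fe <- d[2]
  out <- vector("list", geom$n_coils)
  for (l in seq_len(geom$n_coils)) {
    bl <- vector("list", geom$b2 - geom$b1 + 1L)
    for (bi in seq_along(geom$b1:geom$b2)) {
      b <- (geom$b1:geom$b2)[bi]
      row0 <- ky0 + b * geom$orf
      hl <- vector("list", geom$h2 - geom$h1 + 1L)
      for (hi in seq_along(geom$h1:geom$h2)) {
        h <- (geom$h1:geom$h2)[hi]
        col <- kx + h
        ok <- row0 >= 0L && row0 < n_pe
        inb <- col >= 1L & col <= n_fe
        if (edge_mode == "strict" && (!ok || any(!inb))) {
          stop("source location outside k-space (edge_mode = \"strict\")")
        }
        v <- complex(length.out = length(kx))
        if (ok && any(inb)) v[inb] <- slab[row0 + 1L, col[inb], l]
        hl[[hi]] <- v
      }
      bl[[bi]] <- hl
    }
    out[[l]] <- bl
  }
  out
}

#' Build the nonlinear GRAPPA feature matrix
#'
#' Feature vector(s) for predicting the missing samples at
#' `(ky0 + r, kx)` from the lattice neighborhood of reference line `ky0`.
#' Column order is fixed: constant; first-order sources (coil-major, then
#' block, then column); squares in the same order; adjacent-column products
#' `S(h) * S(h+1)`; skip-one products `S(h) * S(h+2)`.
#'
#' @param slab complex array `[n_pe, n_fe, n_coils]`, one frame of k-space.
#' @param ky0 0-based reference lattice line (the target sits at
#'   `ky0 + r`).
#' @param kx 1-based read-out column(s).
#' @param geom a [kernel_geometry()].
#' @param edge_mode `"zero"` (default) zero-fills sources clipped outside
#'   k-space; `"strict"` raises an error instead.
#' @return complex matrix `length(kx)` x [n_features()].
#' @export
build_features <- function(slab, ky0, kx, geom, edge_mode = "zero") {
  src <- gather_sources(slab, ky0, kx, geom, edge_mode)
  nk <- length(kx)
  H <- geom$h2 - geom$h1 + 1L
  cols <- vector("list", n_features(geom))
  j <- 1L
  cols[[j]] <- rep(1 + 0i, nk); j <- j + 1L
  for (l in seq_len(geom$n_coils)) for (bi in seq_len(geom$b2 - geom$b1 + 1L))
    for (hi in seq_len(H)) {
      cols[[j]] <- src[[l]][[bi]][[hi]]; j <- j + 1L
    }
  if (geom$second_order) {
    for (l in seq_len(geom$n_coils)) for (bi in seq_len(geom$b2 - geom$b1 + 1L))
      for (hi in seq_len(H)) {
        cols[[j]] <- src[[l]][[bi]][[hi]]^2; j <- j + 1L
      }
    if (H >= 2L) {
      for (l in seq_len(geom$n_coils)) for (bi in seq_len(geom$b2 - geom$b1 + 1L))
        for (hi in seq_len(H - 1L)) {
          cols[[j]] <- src[[l]][[bi]][[hi]] * src[[l]][[bi]][[hi + 1L]]
          j <- j + 1L
        }
    }
    if (H >= 3L) {
      for (l in seq_len(geom$n_coils)) for (bi in seq_len(geom$b2 - geom$b1 + 1L))
        for (hi in seq_len(H - 2L)) {
          cols[[j]] <- src[[l]][[bi]][[hi]] * src[[l]][[bi]][[hi + 2L]]
          j <- j + 1L
        }
    }
  }
  matrix(unlist(cols), nrow = nk)
}

#' Calibrate a nonlinear GRAPPA kernel on the ACS block
#'
#' Slides the kernel geometry over the fully sampled ACS lines of every
#' frame (sources and targets strictly inside the ACS block and the
#' interior read-out columns), stacks the resulting equations, and solves
#' one Tikhonov-regularized least-squares system per target offset `r`,
#' jointly for all target coils. Feature columns are scaled to unit RMS
#' before solving (the scaling is folded back into the returned weights),
#' which conditions the mixed first/second-order system.
#'
#' @param kspace complex array `[n_pe, n_fe, n_frames, n_coils]` containing
#'   measured ACS data (other lines may be anything; only ACS rows are
#'   read).
#' @param acs_mask logical phase-encode vector of ACS lines.
#' @param geom a [kernel_geometry()].
#' @param reg_rel Tikhonov parameter relative to the mean diagonal of the
#'   (column-scaled) normal matrix; `0` requests an unregularized solve and
#'   errors if the system is rank-deficient.
#' @return an object of class `nlg_kernel`: geometry, list of weight
#'   matrices (features x target coils, one per offset), `reg_rel` and the
#'   overall `calib_residual_rel`.
#' @export
nlg_calibrate <- function(kspace, acs_mask, geom, reg_rel = 1e-6) {
  d <- dim(kspace)
  stopifnot(length(d) == 4L, d[4] == geom$n_coils)
  R <- geom$orf
  acs0 <- which(acs_mask) - 1L            # 0-based ACS line indices
  if (length(acs0) == 0L) stop("empty ACS block")
  a_lo <- min(acs0); a_hi <- max(acs0)
  span_lo <- geom$b1 * R; span_hi <- geom$b2 * R
  if ((a_hi - a_lo) < (span_hi - span_lo)) {
    stop("ACS block too short for the kernel geometry: needs at least ",
         span_hi - span_lo + 1L, " lines")
  }
  # only lattice-aligned source positions: calibration equations must have
  # the same geometry the kernel is applied with (sources on the lattice)
  ky0s <- (a_lo - span_lo):(a_hi - span_hi)
  ky0s <- ky0s[ky0s %% R == 0L]
  if (length(ky0s) == 0L) {
    stop("ACS block too short for a lattice-aligned calibration position")
  }
  kx <- seq.int(max(1L, 1L - geom$h1), min(d[2], d[2] - geom$h2))
  if (length(kx) == 0L) stop("no interior read-out columns for calibration")
  if (length(geom$offsets) == 0L) {
    kern <- structure(list(geometry = geom, weights = list(),
                           reg_rel = reg_rel, calib_residual_rel = 0),
                      class = "nlg_kernel")
    return(kern)
  }
  weights <- vector("list", length(geom$offsets))
  ss_res <- 0; ss_tot <- 0
  for (ri in seq_along(geom$offsets)) {
    r <- geom$offsets[ri]
    xs <- list(); ys <- list(); n <- 0L
    for (f in seq_len(d[3])) {
      slab <- kspace[, , f, , drop = FALSE]
      dim(slab) <- d[c(1, 2, 4)]
      for (ky0 in ky0s) {
        tgt0 <- ky0 + r
        if (tgt0 < a_lo || tgt0 > a_hi) next
        n <- n + 1L
        xs[[n]] <- build_features(slab, ky0, kx, geom, edge_mode = "strict")
        ys[[n]] <- slab[tgt0 + 1L, kx, , drop = TRUE]
      }
    }
    if (n == 0L) stop("no calibration targets for offset ", r)
    x <- do.call(rbind, xs)
    y <- do.call(rbind, ys)
    if (!is.matrix(y)) y <- matrix(y, ncol = geom$n_coils)
    nf <- ncol(x)
    if (nrow(x) < nf && reg_rel <= 0) {
      stop("fewer calibration equations (", nrow(x), ") than features (",
           nf, "); increase ACS or set reg_rel > 0")
    }
    scale <- sqrt(colMeans(Mod(x)^2))
    scale[scale == 0] <- 1
    xs_ <- sweep(x, 2L, scale, `/`)
    xtx <- crossprod(Conj(xs_), xs_)
    reg <- reg_rel * mean(Re(diag(xtx)))
    rhs <- crossprod(Conj(xs_), y)
    w <- tryCatch(
      solve(xtx + diag(reg, nf), rhs),
      error = function(e) {
        stop("calibration system is rank-deficient; set reg_rel > 0 ",
             "(solver reported: ", conditionMessage(e), ")")
      }
    )
    ss_res <- ss_res + sum(Mod(xs_ %*% w - y)^2)
    ss_tot <- ss_tot + sum(Mod(y)^2)
    weights[[ri]] <- sweep(w, 1L, scale, `/`)  # fold scaling into weights
  }
  structure(list(geometry = geom, weights = weights, reg_rel = reg_rel,
                 calib_residual_rel = sqrt(ss_res / max(ss_tot, .Machine$double.xmin))),
            class = "nlg_kernel")
}

#' @export
print.nlg_kernel <- function(x, ...) {
  g <- x$geometry
  cat(sprintf(
    "<nlg_kernel> L=%d R=%d blocks %d..%d cols %d..%d | %d features, resid=%.3g\n",
    g$n_coils, g$orf, g$b1, g$b2, g$h1, g$h2, n_features(g),
    x$calib_residual_rel))
  invisible(x)
}

#' Apply a nonlinear GRAPPA kernel to complete the uniform lattice
#'
#' Predicts, per frame and coil, every phase-encode line not on the uniform
#' lattice from the lattice lines of all coils, then reinstates the
#' measured ACS lines. Lattice and acquired lines pass through
#' bit-identically. Sources clipped outside k-space follow the kernel's
#' edge mode (zero-filled by default).
#'
#' @param uniform_kt a [kt_dataset()] or complex array
#'   `[n_pe, n_fe, n_frames, n_coils]`, complete on the uniform lattice
#'   (stage-1 output after normalization).
#' @param kernel an [nlg_kernel][nlg_calibrate()].
#' @param plan a [sampling_plan()] (must use the fixed-offset lattice with
#'   `r1 == kernel$geometry$orf`).
#' @param measured optional array of the originally acquired (masked)
#'   k-space whose ACS lines overwrite the output; defaults to
#'   `uniform_kt` itself.
#' @param edge_mode `"zero"` or `"strict"`, see [build_features()].
#' @return completed complex array `[n_pe, n_fe, n_frames, n_coils]`.
#' @export
nlg_apply <- function(uniform_kt, kernel, plan, measured = NULL,
                      edge_mode = "zero") {
  k <- as_kspace(uniform_kt)
  d <- dim(k)
  geom <- kernel$geometry
  if (geom$orf != plan$r1) {
    stop("kernel geometry orf (", geom$orf, ") inconsistent with plan r1 (",
         plan$r1, ")")
  }
  if (plan$offset_mode != "fixed") {
    stop("nonlinear GRAPPA requires the fixed-offset uniform lattice")
  }
  R <- geom$orf
  if (R == 1L) return(k)                  # no lattice gaps
  out <- k
  missing0 <- setdiff(0:(d[1] - 1L), seq.int(0L, d[1] - 1L, by = R))
  kx <- seq_len(d[2])
  for (f in seq_len(d[3])) {
    slab <- k[, , f, , drop = FALSE]
    dim(slab) <- d[c(1, 2, 4)]
    for (m in missing0) {
      ky0 <- (m %/% R) * R
      r <- m - ky0
      feat <- build_features(slab, ky0, kx, geom, edge_mode = edge_mode)
      out[m + 1L, , f, ] <- feat %*% kernel$weights[[which(geom$offsets == r)]]
    }
  }
  # measured ACS lines (and any acquired line) take precedence
  src <- if (is.null(measured)) k else measured
  for (f in seq_len(d[3])) {
    rows <- plan$acs_mask | plan$acquired_mask[f, ]
    out[rows, , f, ] <- src[rows, , f, ]
  }
  out
}
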