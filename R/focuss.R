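#' @title Stage 1: FOCUSS compressed-sensing reconstruction
#' @description Recovers each coil's uniformly undersampled k-t data from
#' the Gaussian-tapered random acquisition by approximating the truncated
#' l1 problem
#' \deqn{\min \|\rho\|_1 \; s.t. \; \|d - F\rho\|_2 \le \epsilon}
#' with FOCUSS iteratively reweighted l2 minimization in the x-f domain:
#' each outer iteration solves the ridge system
#' \deqn{\min_q \|d - FWq\|_2^2 + \lambda \|q\|_2^2}
#' by conjugate gradients on its dual normal equations and then updates the
#' diagonal weights to \eqn{|\rho|^{0.5}} of the current solution. The
#' read-out axis is inverse-DFT'd first so the problem decouples into
#' independent (phase-encode x frame) subproblems per read-out column,
#' which are solved in one batched CG.
#' @name ktjoint-focuss
NULL

#' FOCUSS solver settings
#'
#' @param outer_iters number of reweighting rounds after the initial solve
#'   (so `outer_iters + 1` CG solves in total).
#' @param cg_max_iters conjugate-gradient iteration cap per solve.
#' @param cg_tol relative residual tolerance for CG, `||r|| <= cg_tol ||d||`.
#' @param lambda_rel Tikhonov weight lambda as a fraction of the mean power
#'   of the acquired samples.
#' @param weight_power exponent in the weight update `w = |rho|^p`
#'   (0.5 approximates l1 sparsity).
#' @param weight_floor_rel weights are floored at
#'   `weight_floor_rel * max(w)` so no x-f coefficient is permanently
#'   zeroed out.
#' @param baseline_subtract if `TRUE`, the temporal-average k-space
#'   (estimated from the acquired samples) is subtracted before solving and
#'   added back afterwards — the classic dynamic-FOCUSS variant that
#'   sparsifies the residual rather than the full signal.
#' @return an object of class `focuss_state`.
#' @export
focuss_state <- function(outer_iters = 2L, cg_max_iters = 40L, cg_tol = 1e-6,
                         lambda_rel = 0.01, weight_power = 0.5,
                         weight_floor_rel = 1e-4, baseline_subtract = FALSE) {
  stopifnot(outer_iters >= 0, cg_max_iters >= 1, cg_tol > 0,
            lambda_rel >= 0, weight_power > 0, weight_floor_rel >= 0)
  structure(list(outer_iters = as.integer(outer_iters),
                 cg_max_iters = as.integer(cg_max_iters),
                 cg_tol = cg_tol, lambda_rel = lambda_rel,
                 weight_power = weight_power,
                 weight_floor_rel = weight_floor_rel,
                 baseline_subtract = isTRUE(baseline_subtract),
                 weights = NULL, lam = NULL),
            class = "focuss_state")
}

# multiply each dim-3 slab of x by the corresponding scalar in a
scale_cols3 <- function(x, a) {
  x * rep(a, each = prod(dim(x)[1:2]))
}

# sum of a real quantity over dims 1:2, per dim-3 slab
slab_sums <- function(x) {
  colSums(matrix(x, ncol = dim(x)[3]))
}

# Batched CG for (M F W^2 F^H M^H + lam I) y = d over independent dim-3
# problems. d and the returned rho are [n_pe, n_frames, n_prob]; mask3 is
# logical of the same shape; w2 holds the squared FOCUSS weights in x-f.
focuss_cg_batch <- function(d, mask3, w2, lam, cg_tol, cg_max_iters) {
  stopifnot(identical(dim(d), dim(mask3)), identical(dim(d), dim(w2)))
  if (any(!is.finite(Re(d))) || any(!is.finite(Im(d)))) {
    stop("non-finite values in acquired data")
  }
  amul <- function(y) {
    mask3 * xf_to_kt(w2 * kt_to_xf(mask3 * y)) + lam * y
  }
  y <- array(0i, dim(d))
  r <- d
  p <- r
  rs <- slab_sums(Re(r * Conj(r)))
  d2 <- pmax(rs, .Machine$double.xmin)
  iters <- 0L
  for (i in seq_len(cg_max_iters)) {
    if (all(sqrt(rs / d2) <= cg_tol)) break
    ap <- amul(p)
    pap <- slab_sums(Re(Conj(p) * ap))
    alpha <- ifelse(pap > 0, rs / pap, 0)
    y <- y + scale_cols3(p, alpha)
    r <- r - scale_cols3(ap, alpha)
    rs_new <- slab_sums(Re(r * Conj(r)))
    beta <- ifelse(rs > 0, rs_new / rs, 0)
    p <- r + scale_cols3(p, beta)
    rs <- rs_new
    iters <- i
  }
  xfy <- kt_to_xf(mask3 * y)
  rho <- w2 * xfy
  list(rho = rho, y = y, xfy = xfy, iters = iters,
       resid_rel = sqrt(rs / d2),
       converged = sqrt(rs / d2) <= cg_tol)
}

#' Solve one reweighted-l2 subproblem by conjugate gradients
#'
#' Solves the dual normal system `(F W W^H F^H + lambda I) y = d` restricted
#' to the acquired k-t locations by CG (avoiding the dense inversion of the
#' closed form) and returns `rho = W W^H F^H y`, the x-f solution of the
#' weighted ridge problem.
#'
#' @param d complex matrix `[n_pe, n_frames]` of acquired k-t samples
#'   (zero at unacquired locations).
#' @param mask logical matrix `[n_pe, n_frames]`, `TRUE` where acquired.
#' @param weights nonnegative real matrix `[n_pe, n_frames]`, the diagonal
#'   of W in x-f coordinates.
#' @param lam ridge parameter lambda, `>= 0`.
#' @param cg_tol,cg_max_iters CG stopping rule (relative residual / cap).
#' @return a list with `rho` (complex x-f solution), `iters`,
#'   `resid_rel` (relative residual of the normal system) and `converged`.
#' @export
cg_solve <- function(d, mask, weights, lam, cg_tol = 1e-6, cg_max_iters = 200L) {
  stopifnot(lam >= 0, all(weights >= 0))
  d3 <- array(d * mask, c(dim(d), 1L))
  m3 <- array(as.logical(mask), c(dim(d), 1L))
  w3 <- array(weights^2, c(dim(d), 1L))
  out <- focuss_cg_batch(d3, m3, w3, lam, cg_tol, cg_max_iters)
  list(rho = array(out$rho, dim(d)), iters = out$iters,
       resid_rel = out$resid_rel[1], converged = out$converged[1])
}

# w = |rho|^power floored at floor_rel * max, slab-wise over dim 3
update_weights <- function(rho, power, floor_rel) {
  w <- Mod(rho)^power
  mx <- apply(w, 3L, max)
  pmax(w, rep(floor_rel * mx, each = prod(dim(w)[1:2])))
}

#' Initialize FOCUSS weights from the ACS block
#'
#' Zero-fills everything outside the fully sampled center (ACS) lines,
#' transforms the low-resolution data to x-f, and sets the initial weights
#' to `|rho_lowres|^weight_power`, floored at `weight_floor_rel * max`.
#' The resulting weights are invariant to a global phase rotation of the
#' data.
#'
#' @param kt complex array `[n_pe, n_frames]` or `[n_pe, n_frames, n_cols]`
#'   of (hybrid) k-t data with ACS lines present in all frames.
#' @param acs_mask logical phase-encode vector marking the ACS lines.
#' @param state a [focuss_state()].
#' @return the state with `weights` filled in (same shape as `kt`).
#' @export
init_weights <- function(kt, acs_mask, state = focuss_state()) {
  if (!any(acs_mask)) {
    stop("empty ACS block: initialize weights uniformly instead ",
         "(state$weights <- array(1, dim(kt)))")
  }
  x <- kt
  was_mat <- length(dim(x)) == 2L
  if (was_mat) dim(x) <- c(dim(x), 1L)
  x[!acs_mask, , ] <- 0i
  rho <- kt_to_xf(x)
  w <- update_weights(rho, state$weight_power, state$weight_floor_rel)
  if (was_mat) dim(w) <- dim(kt)
  state$weights <- w
  state
}

# temporal-average k-t baseline per (pe, column) from acquired samples
kt_baseline <- function(d, mask2) {
  # d: [n_pe, n_frames, n_cols]; mask2: [n_pe, n_frames]
  cnt <- rowSums(mask2)
  num <- apply(d, 3L, function(s) rowSums(s * mask2))
  b <- sweep(num, 1L, pmax(cnt, 1L), `/`)
  b[cnt == 0L, ] <- 0i
  b # [n_pe, n_cols]
}

#' FOCUSS reconstruction of one coil
#'
#' Recovers the uniformly undersampled k-t data of a single coil from its
#' randomly subsetted acquisition. The read-out axis is inverse-transformed
#' first; each read-out column's (phase-encode x frame) problem is solved
#' by `outer_iters + 1` CG solves with FOCUSS weight updates in between,
#' all columns batched in one CG.
#'
#' With `lattice = "uniform"` the compressed-sensing problem is posed on
#' the uniform lattice itself: the unknown x-f image is the aliased
#' (reduced field-of-view) series whose k-t representation lives on the
#' lattice lines, and only the acquired lattice samples (random subset
#' plus any ACS line on the lattice) enter the data term. The recovered
#' lattice lines are embedded back into the full grid; lines outside the
#' lattice and outside ACS are the parallel-imaging stage's job and stay
#' zero. With `lattice = "full"` the problem is posed on the full grid and
#' every line is reconstructed (the coil-wise CS-only baseline). In both
#' cases the measured samples are reinstated where acquired when
#' `data_consistency = TRUE`.
#'
#' @param d_ur complex array `[n_pe, n_fe, n_frames]`: one coil's k-space,
#'   zero-filled at unacquired locations (consistent with `plan`).
#' @param plan a [sampling_plan()].
#' @param state a [focuss_state()].
#' @param lattice `"uniform"` (default) restricts the output support to the
#'   uniform lattice plus ACS; `"full"` keeps every line — used when FOCUSS
#'   alone performs the whole reconstruction (the coil-wise CS-only
#'   baseline).
#' @param data_consistency replace reconstructed values with the measured
#'   ones at acquired locations (default `TRUE`). The two-stage pipeline
#'   sets this to `FALSE` so the scaling normalization can compare raw
#'   reconstruction against acquisition on their overlap first.
#' @return complex array `[n_pe, n_fe, n_frames]` with attribute
#'   `"history"`: per outer iteration, the ridge objective and CG iteration
#'   count.
#' @export
focuss_reconstruct <- function(d_ur, plan, state = focuss_state(),
                               lattice = c("uniform", "full"),
                               data_consistency = TRUE) {
  lattice <- match.arg(lattice)
  d <- dim(d_ur)
  stopifnot(length(d) == 3L, d[1] == plan$n_pe, d[3] == plan$n_frames)
  acq <- t(plan$acquired_mask)            # [n_pe, n_frames]
  # hybrid space: inverse DFT along read-out, then [n_pe, n_frames, n_x]
  h <- aperm(cdft_dim(d_ur, 2L, inverse = TRUE), c(1L, 3L, 2L))
  n_x <- d[2]
  h <- h * array(acq, dim(h))             # enforce the masking contract
  if (lattice == "uniform") {
    if (plan$offset_mode != "fixed") {
      stop("lattice = \"uniform\" requires the fixed-offset lattice")
    }
    rows <- which(plan$uniform_mask[1L, ])       # frame-invariant lattice
    solved <- focuss_solve_grid(h[rows, , , drop = FALSE],
                                acq[rows, , drop = FALSE],
                                plan$acs_mask[rows], state, data_consistency)
    kt <- array(0i, dim(h))
    kt[rows, , ] <- solved$kt
  } else {
    solved <- focuss_solve_grid(h, acq, plan$acs_mask, state, data_consistency)
    kt <- solved$kt
  }
  if (data_consistency) {
    m3 <- array(acq, dim(h))
    kt[m3] <- h[m3]                       # ACS lines off the lattice included
  }
  out <- cdft_dim(aperm(kt, c(1L, 3L, 2L)), 2L, inverse = FALSE)
  attr(out, "history") <- solved$history
  out
}

# FOCUSS on one (possibly reduced) phase-encode grid.
# h: [n_rows, n_frames, n_x] hybrid data (zero off mask); mask2: [n_rows,
# n_frames] acquired; acs_rows: logical over rows for weight init.
focuss_solve_grid <- function(h, mask2, acs_rows, state, data_consistency) {
  dh <- dim(h)
  mask3 <- array(mask2, dh)
  lam <- state$lambda_rel * mean(Mod(h[mask3])^2)
  if (!is.finite(lam) || lam < 0) lam <- 0
  baseline <- NULL
  expand_baseline <- function(b) {
    aperm(array(b, c(dh[1], dh[3], dh[2])), c(1L, 3L, 2L))
  }
  if (state$baseline_subtract) {
    baseline <- kt_baseline(h, mask2)     # [n_rows, n_x]
    h <- (h - expand_baseline(baseline)) * mask3
  }
  st <- if (any(acs_rows)) {
    init_weights(h, acs_rows, state)
  } else {
    s <- state
    s$weights <- array(1, dh)
    s
  }
  w2 <- st$weights^2
  history <- data.frame(iter = integer(0), objective = numeric(0),
                        resid_rel = numeric(0), cg_iters = integer(0))
  d_energy <- max(sum(Mod(h)^2), .Machine$double.xmin)
  sol <- NULL
  best <- NULL
  for (l in seq_len(state$outer_iters + 1L)) {
    sol <- focuss_cg_batch(h, mask3, w2, lam, state$cg_tol, state$cg_max_iters)
    # Eq. 5 objective (for the current W) and the data-fit residual that is
    # comparable across reweightings
    obj <- sum(Mod(h - mask3 * xf_to_kt(sol$rho))^2) +
      lam * sum(w2 * Mod(sol$xfy)^2)
    res <- sqrt(sum(Mod(h - mask3 * xf_to_kt(sol$rho))^2) / d_energy)
    history <- rbind(history,
                     data.frame(iter = l, objective = obj, resid_rel = res,
                                cg_iters = sol$iters))
    if (is.null(best) || res <= best$res) {
      best <- list(res = res, rho = sol$rho)
    } else if (res > 1.5 * best$res + state$cg_tol) {
      warning("FOCUSS residual increased across outer iterations; ",
              "returning best iterate")
      sol$rho <- best$rho
      break
    }
    if (l <= state$outer_iters) {
      w2 <- update_weights(sol$rho, state$weight_power,
                           state$weight_floor_rel)^2
    }
  }
  kt <- xf_to_kt(sol$rho)                 # [n_rows, n_frames, n_x]
  if (!is.null(baseline)) kt <- kt + expand_baseline(baseline)
  if (data_consistency) {
    h_meas <- h + if (!is.null(baseline)) expand_baseline(baseline) * mask3 else 0i
    kt[mask3] <- h_meas[mask3]
  }
  list(kt = kt, history = history)
}
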