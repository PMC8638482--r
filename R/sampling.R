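#' @title k-t sampling design
#' @description Construction and composition of the decoupled undersampling
#' operators: a uniform phase-encode lattice (reduction factor R1, the
#' parallel-imaging stage's outer reduction factor), a Gaussian-tapered
#' random subset of the lattice (reduction factor R2, the compressed-sensing
#' stage's mask), and a fully sampled auto-calibration (ACS) block at the
#' k-space center, present in every frame.
#' @name ktjoint-sampling
NULL

# round half away from zero (base round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

# run code under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(code)
}

# 0-based index of the phase-encode center line (DC after centering)
pe_center <- function(n_pe) floor(n_pe / 2)

#' Uniform phase-encode undersampling mask
#'
#' Samples every `r1`-th phase-encode line in every frame. In `"fixed"` mode
#' every frame uses offset 0 (line 0, r1, 2*r1, ...); in `"interleaved"`
#' mode the offset advances by one line per frame modulo `r1`.
#'
#' @param n_pe number of phase-encode lines.
#' @param n_frames number of time frames.
#' @param r1 integer uniform reduction factor, `1 <= r1 <= n_pe`.
#' @param offset_mode `"fixed"` (default) or `"interleaved"`. The nonlinear
#'   GRAPPA stage calibrates and applies one kernel on a frame-invariant
#'   lattice, so the pipeline requires `"fixed"`.
#' @return logical matrix `n_frames` x `n_pe` (frame by phase-encode line).
#' @export
make_uniform_mask <- function(n_pe, n_frames, r1,
                              offset_mode = c("fixed", "interleaved")) {
  offset_mode <- match.arg(offset_mode)
  if (r1 < 1 || r1 > n_pe || r1 != round(r1)) {
    stop("r1 must be an integer in [1, n_pe]")
  }
  line0 <- seq_len(n_pe) - 1L
  m <- matrix(FALSE, nrow = n_frames, ncol = n_pe)
  for (f in seq_len(n_frames)) {
    off <- if (offset_mode == "fixed") 0L else (f - 1L) %% r1
    m[f, ] <- (line0 %% r1) == off
  }
  m
}

#' ACS (auto-calibration) line mask
#'
#' `n_acs` contiguous phase-encode lines centered on the DC line
#' `floor(n_pe/2)` (0-based), acquired in full in every frame.
#'
#' @param n_pe number of phase-encode lines.
#' @param n_acs number of ACS lines (0 allowed).
#' @return logical vector of length `n_pe`.
#' @export
make_acs_mask <- function(n_pe, n_acs) {
  if (n_acs < 0 || n_acs > n_pe) stop("n_acs must be in [0, n_pe]")
  m <- rep(FALSE, n_pe)
  if (n_acs > 0) {
    start0 <- pe_center(n_pe) - floor(n_acs / 2)
    idx0 <- start0 + seq_len(n_acs) - 1L
    if (any(idx0 < 0L) || any(idx0 >= n_pe)) {
      stop("ACS block does not fit inside the phase-encode range")
    }
    m[idx0 + 1L] <- TRUE
  }
  m
}

# systematic probability-proportional-to-size sampling of k distinct items.
# Inclusion probability of item i is k * p_i (items with k*p_i >= 1 are
# force-included and the rest renormalized). Assumes p >= 0, sum(p) > 0.
pps_systematic <- function(p, k) {
  n <- length(p)
  if (k <= 0L) return(integer(0))
  if (k >= n) return(seq_len(n))
  forced <- integer(0)
  remaining <- which(p > 0)
  if (length(remaining) < k) {
    # top up with zero-probability items only if unavoidable
    remaining <- seq_len(n)
  }
  repeat {
    m <- k - length(forced)
    if (m == 0L) break
    pr <- p[remaining] / sum(p[remaining])
    over <- remaining[m * pr >= 1]
    if (length(over) == 0L) break
    take <- utils::head(over, m)
    forced <- c(forced, take)
    remaining <- setdiff(remaining, take)
  }
  m <- k - length(forced)
  if (m > 0L) {
    pr <- p[remaining] / sum(p[remaining])
    cum <- cumsum(pr)
    pts <- stats::runif(1) / m + (seq_len(m) - 1L) / m
    sel <- remaining[pmin(findInterval(pts, cum, left.open = TRUE) + 1L,
                          length(remaining))]
    forced <- c(forced, sel)
  }
  sort(unique(forced))
}

#' Gaussian-tapered random subset of a uniform mask
#'
#' For each frame independently, keeps `round(U / r2)` of that frame's `U`
#' uniformly sampled lines, drawn without replacement with probability
#' proportional to a zero-mean Gaussian in (line index - center line) with
#' standard deviation `density_sigma * n_pe`, renormalized over the frame's
#' uniform lines — variable-density sampling whose density tapers off toward
#' outer k-space. The uniform line closest to the center is always kept so
#' the x-f DC component is observed. Frame `f` uses RNG seed `seed + f - 1`;
#' the draw is systematic probability-proportional-to-size sampling, so line
#' inclusion frequencies match the stated density.
#'
#' @param uniform_mask logical frame x phase-encode matrix from
#'   [make_uniform_mask()].
#' @param r2 real random-subset reduction factor, `>= 1`.
#' @param density_sigma Gaussian density std as a fraction of `n_pe`
#'   (default 0.25).
#' @param seed integer RNG seed.
#' @return logical frame x phase-encode matrix, a subset of `uniform_mask`.
#' @export
make_random_subset <- function(uniform_mask, r2, density_sigma = 0.25, seed = 1L) {
  if (r2 < 1) stop("r2 must be >= 1")
  if (density_sigma <= 0) stop("density_sigma must be > 0")
  n_frames <- nrow(uniform_mask)
  n_pe <- ncol(uniform_mask)
  c0 <- pe_center(n_pe)
  out <- matrix(FALSE, n_frames, n_pe)
  for (f in seq_len(n_frames)) {
    cand <- which(uniform_mask[f, ])        # 1-based
    u <- length(cand)
    k <- round_half_up(u / r2)
    if (k > u) stop("requested random-subset count exceeds available uniform lines")
    if (k == 0L) next
    p <- stats::dnorm(cand - 1L, mean = c0, sd = density_sigma * n_pe)
    p <- p / sum(p)
    # force the center-most uniform line
    ic <- which.min(abs(cand - 1L - c0))
    sel <- with_seed(seed + f - 1L, {
      rest <- setdiff(seq_len(u), ic)
      picked <- if (k > 1L) rest[pps_systematic(p[rest] / sum(p[rest]), k - 1L)] else integer(0)
      c(ic, picked)
    })
    out[f, cand[sel]] <- TRUE
  }
  out
}

#' Compose the acquired mask from random subset and ACS block
#'
#' Logical OR of the per-frame random-subset mask with the ACS line mask
#' broadcast to all frames: ACS lines are acquired in every frame.
#'
#' @param random_mask logical frame x phase-encode matrix.
#' @param acs_mask logical phase-encode vector.
#' @return logical frame x phase-encode matrix.
#' @export
compose_acquired <- function(random_mask, acs_mask) {
  if (length(acs_mask) != ncol(random_mask)) {
    stop("acs_mask length must equal the phase-encode dimension of random_mask")
  }
  sweep(random_mask, 2L, acs_mask, `|`)
}

#' Net reduction factor
#'
#' Total acceleration of the tailored sampling scheme, accounting for the
#' lattice-times-random acquisition and the fully sampled ACS overhead:
#' `R = n_pe / (n_pe / (r1 * r2) + n_acs)`. No overlap deduction is made
#' between ACS lines and the random subset.
#'
#' @param n_pe number of phase-encode lines.
#' @param r1 uniform (parallel-imaging) reduction factor.
#' @param r2 random-subset (compressed-sensing) reduction factor.
#' @param n_acs number of fully sampled center lines.
#' @return the net reduction factor (a real scalar).
#' @examples
#' net_reduction_factor(165, 6, 2, 32)  # 3.6 to one decimal
#' @export
net_reduction_factor <- function(n_pe, r1, r2, n_acs) {
  if (n_pe < 1) stop("n_pe must be >= 1")
  if (r1 * r2 < 1) stop("r1 * r2 must be >= 1")
  if (n_acs < 0) stop("n_acs must be >= 0")
  denom <- n_pe / (r1 * r2) + n_acs
  if (denom <= 0) stop("invalid parameters: non-positive denominator")
  n_pe / denom
}

#' Sampling plan
#'
#' Bundles the three masks of the acquisition design (uniform lattice,
#' Gaussian-tapered random subset, ACS block) with their parameters and the
#' composed per-frame acquired mask.
#'
#' @param n_pe,n_fe,n_frames grid size: phase-encode lines, frequency-encode
#'   points, time frames.
#' @param r1 integer uniform reduction factor (outer reduction factor of the
#'   parallel-imaging stage).
#' @param r2 real random-subset reduction factor (compressed-sensing stage).
#' @param n_acs number of fully sampled center lines.
#' @param seed RNG seed for the random subset.
#' @param density_sigma Gaussian density std as a fraction of `n_pe`.
#' @param offset_mode lattice offset mode, see [make_uniform_mask()].
#' @return an object of class `sampling_plan`: a list with the parameters,
#'   `uniform_mask`, `random_mask`, `acs_mask` and `acquired_mask`.
#' @export
sampling_plan <- function(n_pe, n_fe, n_frames, r1, r2 = 1, n_acs = 0,
                          seed = 1L, density_sigma = 0.25,
                          offset_mode = "fixed") {
  um <- make_uniform_mask(n_pe, n_frames, r1, offset_mode)
  rm_ <- make_random_subset(um, r2, density_sigma, seed)
  am <- make_acs_mask(n_pe, n_acs)
  plan <- list(
    n_pe = n_pe, n_fe = n_fe, n_frames = n_frames,
    r1 = as.integer(r1), r2 = r2, n_acs = as.integer(n_acs),
    seed = as.integer(seed), density_sigma = density_sigma,
    offset_mode = offset_mode,
    uniform_mask = um, random_mask = rm_, acs_mask = am,
    acquired_mask = compose_acquired(rm_, am)
  )
  class(plan) <- "sampling_plan"
  plan
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf(
    "<sampling_plan> %d PE x %d FE x %d frames | R1=%d R2=%.3g ACS=%d (net R=%.2f)\n",
    x$n_pe, x$n_fe, x$n_frames, x$r1, x$r2, x$n_acs,
    net_reduction_factor(x$n_pe, x$r1, x$r2, x$n_acs)
  ))
  cat(sprintf("  acquired lines/frame: %s\n",
              paste(range(rowSums(x$acquired_mask)), collapse = "-")))
  invisible(x)
}
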