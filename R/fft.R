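#' @title Centered unitary Fourier transforms
#' @description Internal DFT conventions used throughout the package.
#' All arrays are stored DC-centered: the zero-frequency (and zero-position)
#' index sits at `floor(n/2)` (0-based). Transforms are unitary (1/sqrt(n)
#' scaling in both directions), so Parseval holds exactly and round trips
#' are identities to machine precision. Shift bookkeeping lives only here.
#' @name ktjoint-fft
#' @keywords internal
NULL

# circular shift by k along one dimension: y[i] = x[i - k]
roll_dim <- function(x, along, k) {
  d <- dim(x)
  n <- d[along]
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(x)
  idx <- ((seq_len(n) - 1L - k) %% n) + 1L
  args <- rep(list(quote(expr = )), length(d))
  args[[along]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

# unitary (uncentered) DFT along one dimension of an array
dft_dim <- function(x, along, inverse = FALSE) {
  d <- dim(x)
  nd <- length(d)
  n <- d[along]
  perm <- c(along, setdiff(seq_len(nd), along))
  y <- aperm(x, perm)
  dim(y) <- c(n, prod(d) / n)
  y <- stats::mvfft(y, inverse = inverse) / sqrt(n)
  dim(y) <- d[perm]
  aperm(y, order(perm))
}

# centered unitary DFT along one dimension (ifftshift -> DFT -> fftshift)
cdft_dim <- function(x, along, inverse = FALSE) {
  if (is.null(dim(x))) dim(x) <- length(x)
  n <- dim(x)[along]
  x <- roll_dim(x, along, -floor(n / 2))
  y <- dft_dim(x, along, inverse = inverse)
  roll_dim(y, along, floor(n / 2))
}

#' Transform k-t data to the x-f domain
#'
#' Maps Cartesian k-t data for one read-out column (or a stack of columns)
#' into the x-f (spatial position by temporal frequency) domain, where
#' quasi-periodic cardiac motion is sparse. The forward model maps x-f to
#' k-t with a DFT along space (x to k_y) and an inverse DFT along temporal
#' frequency (f to t); this function applies the exact inverse of that map.
#' Both directions are unitary and DC-centered.
#'
#' @param kt complex matrix or array with phase-encode (k_y) as dimension 1
#'   and time frame as dimension 2; further dimensions (e.g. read-out
#'   position) are carried along unchanged.
#' @return complex array of the same shape in (x, f) coordinates.
#' @seealso [xf_to_kt()] for the forward (x-f to k-t) direction.
#' @examples
#' kt <- array(complex(real = rnorm(32), imaginary = rnorm(32)), c(8, 4))
#' max(Mod(xf_to_kt(kt_to_xf(kt)) - kt)) < 1e-12
#' @export
kt_to_xf <- function(kt) {
  cdft_dim(cdft_dim(kt, 1L, inverse = TRUE), 2L, inverse = FALSE)
}

#' Transform x-f data to the k-t domain
#'
#' Forward encoding operator: DFT along the spatial axis (dimension 1,
#' x to k_y) and inverse DFT along the temporal-frequency axis
#' (dimension 2, f to t). Exact inverse of [kt_to_xf()].
#'
#' @param xf complex matrix or array, space as dimension 1, temporal
#'   frequency as dimension 2.
#' @return complex array of the same shape in (k_y, t) coordinates.
#' @export
xf_to_kt <- function(xf) {
  cdft_dim(cdft_dim(xf, 2L, inverse = TRUE), 1L, inverse = FALSE)
}

# centered unitary 2-D image <-> k-space transforms (dims 1 and 2)
kspace_to_image <- function(k) {
  cdft_dim(cdft_dim(k, 1L, inverse = TRUE), 2L, inverse = TRUE)
}

image_to_kspace <- function(im) {
  cdft_dim(cdft_dim(im, 1L, inverse = FALSE), 2L, inverse = FALSE)
}
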