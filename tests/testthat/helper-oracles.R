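# Independent oracles and small fixtures, built in code at test time.

# dense centered unitary DFT matrix (x -> k), the closed form the package's
# transforms must match
centered_dft_matrix <- function(n) {
  k0 <- (0:(n - 1)) - floor(n / 2)
  exp(-2i * pi * outer(k0, k0) / n) / sqrt(n)
}

# bind 4-D arrays along the coil (4th) dimension
abind_c <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(0i, c(d[1:3], sum(sapply(xs, function(x) dim(x)[4]))))
  at <- 0L
  for (x in xs) {
    nc <- dim(x)[4]
    out[, , , at + seq_len(nc)] <- x
    at <- at + nc
  }
  out
}

rcomplex <- function(n, sd = 1) {
  complex(real = stats::rnorm(n, sd = sd), imaginary = stats::rnorm(n, sd = sd))
}

# small noiseless multi-coil cine acquisition for fast pipeline tests
tiny_dataset <- function(n = 32, nf = 6, coils = 2, r1 = 2, r2 = 2,
                         n_acs = 8, noise = 0, seed = 5) {
  spec <- phantom_spec(nx = n, ny = n, n_frames = nf, n_coils = coils,
                       noise_sigma_rel = noise, seed = seed)
  plan <- sampling_plan(n, n, nf, r1 = r1, r2 = r2, n_acs = n_acs, seed = seed)
  list(spec = spec, plan = plan, ds = simulate_phantom_acquisition(spec, plan))
}

# Independent plain (linear) GRAPPA with a bias term on the same geometry:
# explicit per-equation loops and qr.solve, no shared code with the package.
linear_grappa_oracle <- function(kspace, acs_mask, orf, b1, b2, h1, h2, plan) {
  d <- dim(kspace)
  L <- d[4]
  acs0 <- which(acs_mask) - 1L
  a_lo <- min(acs0); a_hi <- max(acs0)
  kx_in <- seq.int(1L - h1, d[2] - h2)
  out <- kspace
  for (r in seq_len(orf - 1L)) {
    rows <- list(); ys <- list(); n_eq <- 0L
    ky0s <- (a_lo - b1 * orf):(a_hi - b2 * orf)
    ky0s <- ky0s[ky0s %% orf == 0]         # lattice-aligned, as applied
    for (f in seq_len(d[3])) {
      for (ky0 in ky0s) {
        if (ky0 + r < a_lo || ky0 + r > a_hi) next
        for (kx in kx_in) {
          feat <- c(1 + 0i)
          for (l in seq_len(L)) for (b in b1:b2) for (h in h1:h2) {
            feat <- c(feat, kspace[ky0 + b * orf + 1L, kx + h, f, l])
          }
          n_eq <- n_eq + 1L
          rows[[n_eq]] <- feat
          ys[[n_eq]] <- kspace[ky0 + r + 1L, kx, f, ]
        }
      }
    }
    x <- do.call(rbind, rows)
    y <- do.call(rbind, ys)
    w <- qr.solve(x, y)
    lattice0 <- seq.int(0L, d[1] - 1L, by = orf)
    for (f in seq_len(d[3])) {
      for (m in setdiff(0:(d[1] - 1L), lattice0)) {
        ky0 <- (m %/% orf) * orf
        if (m - ky0 != r) next
        for (kx in seq_len(d[2])) {
          feat <- c(1 + 0i)
          for (l in seq_len(L)) for (b in b1:b2) for (h in h1:h2) {
            row <- ky0 + b * orf
            col <- kx + h
            v <- if (row >= 0L && row < d[1] && col >= 1L && col <= d[2]) {
              kspace[row + 1L, col, f, l]
            } else 0i
            feat <- c(feat, v)
          }
          out[m + 1L, kx, f, ] <- as.vector(t(w) %*% feat)
        }
      }
    }
  }
  for (f in seq_len(d[3])) {
    rows <- acs_mask | plan$acquired_mask[f, ]
    out[rows, , f, ] <- kspace[rows, , f, ]
  }
  out
}

# exact truncated second-order synthetic k-space: lattice lines random, all
# off-lattice lines generated from a known coefficient set via the package's
# feature layout (the known weights are the oracle; the estimates are not)
exact_nlg_instance <- function(n_pe = 48, n_fe = 40, nf = 3, L = 2,
                               orf = 2, n_acs = 24, seed = 9) {
  set.seed(seed)
  geom <- kernel_geometry(L, orf, b1 = -1L, b2 = 2L, h1 = -1L, h2 = 1L)
  k <- array(0i, c(n_pe, n_fe, nf, L))
  lattice0 <- seq.int(0L, n_pe - 1L, by = orf)
  k[lattice0 + 1L, , , ] <- rcomplex(length(lattice0) * n_fe * nf * L, sd = 0.7)
  w_true <- matrix(rcomplex(n_features(geom) * L, sd = 0.3), ncol = L)
  for (f in seq_len(nf)) {
    slab <- k[, , f, , drop = FALSE]
    dim(slab) <- c(n_pe, n_fe, L)
    for (m in setdiff(0:(n_pe - 1L), lattice0)) {
      ky0 <- (m %/% orf) * orf
      feat <- build_features(slab, ky0, seq_len(n_fe), geom, edge_mode = "zero")
      k[m + 1L, , f, ] <- feat %*% w_true
    }
  }
  plan <- sampling_plan(n_pe, n_fe, nf, r1 = orf, r2 = 1, n_acs = n_acs,
                        seed = seed)
  list(kspace = k, geom = geom, w_true = w_true, plan = plan)
}
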