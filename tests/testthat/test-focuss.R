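test_that("cg_solve reduces to the ridge closed form on a full mask", {
  set.seed(2)
  n <- 16; nf <- 4
  d <- matrix(rcomplex(n * nf), n, nf)
  mask <- matrix(TRUE, n, nf)
  w <- matrix(1, n, nf)
  for (lam in c(0, 0.5, 3)) {
    s <- cg_solve(d, mask, w, lam, 1e-12, 100)
    expect_lt(max(Mod(s$rho - kt_to_xf(d) / (1 + lam))), 1e-10)
  }
})

test_that("cg_solve matches explicit dense inversion on a 32-point problem", {
  set.seed(12)
  n <- 32
  D <- centered_dft_matrix(n)
  mask <- rep(FALSE, n); mask[sample(n, 12)] <- TRUE
  w <- runif(n, 0.05, 1)
  d_full <- rcomplex(n)
  d <- d_full * mask
  lam <- 0.3
  # dense closed form: rho = W W^H F^H M^H (M F W^2 F^H M^H + lam I)^-1 d
  A <- D[mask, ] %*% diag(w)
  y <- solve(A %*% Conj(t(A)) + lam * diag(sum(mask)), d_full[mask])
  rho_dense <- diag(w^2) %*% Conj(t(D[mask, ])) %*% y
  s <- cg_solve(matrix(d, n, 1), matrix(mask, n, 1), matrix(w, n, 1),
                lam, 1e-12, 500)
  expect_lt(sqrt(sum(Mod(s$rho[, 1] - rho_dense)^2) / sum(Mod(rho_dense)^2)),
            1e-6)
})

test_that("the ridge limit shrinks the solution to zero monotonically", {
  set.seed(3)
  n <- 24
  d <- matrix(rcomplex(n), n, 1)
  mask <- matrix(runif(n) < 0.6, n, 1)
  w <- matrix(1, n, 1)
  norms <- sapply(c(0.01, 1, 100, 1e4), function(lam) {
    sqrt(sum(Mod(cg_solve(d * mask, mask, w, lam, 1e-12, 200)$rho)^2))
  })
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[length(norms)], 1e-3 * norms[1])
})

test_that("the ridge objective is non-increasing across CG iterations", {
  for (seed in c(3, 17, 29)) {
    set.seed(seed)
    n <- 32; nf <- 4
    rho_t <- matrix(0i, n, nf)
    rho_t[sample(n * nf, 12)] <- rcomplex(12)
    mask <- matrix(runif(n * nf) < 0.5, n, nf)
    d3 <- array(xf_to_kt(rho_t) * mask, c(n, nf, 1))
    m3 <- array(mask, c(n, nf, 1))
    w3 <- array(runif(n * nf, 0.2, 1)^2, c(n, nf, 1))
    lam <- 0.05
    J <- sapply(1:20, function(k) {
      s <- ktjoint:::focuss_cg_batch(d3, m3, w3, lam, 1e-14, k)
      sum(Mod(d3 - m3 * xf_to_kt(s$rho))^2) + lam * sum(w3 * Mod(s$xfy)^2)
    })
    expect_true(all(diff(J) <= 1e-8 * J[1]))
  }
})

test_that("weight initialization uses the low-resolution ACS image", {
  n <- 32; nf <- 4
  acs <- make_acs_mask(n, 8)
  st <- focuss_state()
  # all-zero data: every weight equals the (zero) floor
  w0 <- init_weights(matrix(0i, n, nf), acs, st)$weights
  expect_true(all(w0 == w0[1]))
  # global phase invariance
  set.seed(8)
  kt <- matrix(rcomplex(n * nf), n, nf)
  w1 <- init_weights(kt, acs, st)$weights
  w2 <- init_weights(kt * exp(1i * 0.77), acs, st)$weights
  expect_lt(max(abs(w1 - w2)), 1e-12)
  # signal band-limited to the ACS block: low-res init = full-data init
  ktb <- matrix(0i, n, nf)
  ktb[acs, ] <- rcomplex(sum(acs) * nf)
  wb <- init_weights(ktb, acs, st)$weights
  wfull <- pmax(Mod(kt_to_xf(ktb))^st$weight_power,
                st$weight_floor_rel * max(Mod(kt_to_xf(ktb))^st$weight_power))
  expect_lt(max(abs(wb - wfull)), 1e-12)
  expect_error(init_weights(kt, rep(FALSE, n), st), "uniform")
})

test_that("fully sampled data passes through focuss_reconstruct exactly", {
  dat <- tiny_dataset(n = 24, nf = 4, coils = 1, r1 = 1, r2 = 1, n_acs = 6)
  k <- dat$ds$kspace[, , , 1]
  for (lat in c("uniform", "full")) {
    out <- focuss_reconstruct(k, dat$plan, focuss_state(), lattice = lat)
    expect_lt(max(Mod(out - k)), 1e-10)
  }
})

test_that("stage-1 output lives on the lattice plus ACS only", {
  dat <- tiny_dataset(n = 32, nf = 4, coils = 1, r1 = 2, r2 = 2, n_acs = 8)
  k <- dat$ds$kspace[, , , 1]
  out <- focuss_reconstruct(k, dat$plan, focuss_state())
  supp <- dat$plan$uniform_mask[1, ] | dat$plan$acs_mask
  expect_lt(max(Mod(out[!supp, , ])), 1e-14)
  # acquired samples reinstated bit-exactly under data consistency
  for (f in seq_len(dat$plan$n_frames)) {
    rows <- dat$plan$acquired_mask[f, ]
    expect_lt(max(Mod(out[rows, , f] - k[rows, , f])), 1e-10)
  }
})

test_that("focuss_reconstruct is phase-equivariant and deterministic", {
  dat <- tiny_dataset(n = 32, nf = 4, coils = 1, r1 = 2, r2 = 2, n_acs = 8)
  k <- dat$ds$kspace[, , , 1]
  st <- focuss_state()
  a <- focuss_reconstruct(k, dat$plan, st)
  b <- focuss_reconstruct(k * exp(1i * 1.2), dat$plan, st)
  # equivariance is exact in exact arithmetic; rounding differences are
  # amplified by the conditioning of the small-lambda ridge systems
  expect_lt(max(Mod(b - a * exp(1i * 1.2))), 1e-5 * max(Mod(a)))
  expect_identical(as.vector(focuss_reconstruct(k, dat$plan, st)), as.vector(a))
})

test_that("coils reconstruct independently of ordering", {
  dat <- tiny_dataset(n = 24, nf = 4, coils = 3, r1 = 2, r2 = 2, n_acs = 6)
  k <- dat$ds$kspace
  st <- focuss_state()
  direct <- ktjoint:::stage1_all_coils(k, dat$plan, st, "uniform", TRUE)
  perm <- c(3, 1, 2)
  permuted <- ktjoint:::stage1_all_coils(k[, , , perm], dat$plan, st,
                                         "uniform", TRUE)
  expect_identical(as.vector(permuted), as.vector(direct[, , , perm]))
})

test_that("baseline subtraction round-trips on temporally static data", {
  n <- 24; nf <- 6
  plan <- sampling_plan(n, 8, nf, r1 = 1, r2 = 2, n_acs = 6, seed = 3)
  set.seed(3)
  line <- rcomplex(n)
  k <- array(0i, c(n, 8, nf))
  for (f in seq_len(nf)) k[, , f] <- matrix(line, n, 8)  # static series
  km <- apply_mask(k, plan$acquired_mask)
  st <- focuss_state(baseline_subtract = TRUE)
  out <- focuss_reconstruct(km, plan, st, lattice = "full")
  # every line sampled in at least one frame is recovered by the temporal
  # average; restrict to those
  seen <- colSums(plan$acquired_mask) > 0
  expect_lt(max(Mod(out[seen, , ] - k[seen, , ])), 1e-8 * max(Mod(k)))
})
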