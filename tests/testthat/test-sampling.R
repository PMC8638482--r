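test_that("uniform lattice masks follow the every-r1-th-line rule", {
  expect_true(all(make_uniform_mask(8, 1, 1)))
  m <- make_uniform_mask(8, 1, 2)
  expect_identical(which(m[1, ]) - 1L, c(0L, 2L, 4L, 6L))
  # brute-force count over the lattice
  m <- make_uniform_mask(130, 15, 2)
  expect_true(all(rowSums(m) == sum((0:129) %% 2 == 0)))
  expect_true(all(rowSums(m) == 65))
  # interleaved mode shifts the offset per frame
  mi <- make_uniform_mask(12, 4, 3, offset_mode = "interleaved")
  for (f in 1:4) {
    expect_identical(which(mi[f, ]) - 1L,
                     which(((0:11) %% 3) == ((f - 1) %% 3)) - 1L)
  }
  expect_error(make_uniform_mask(8, 1, 0), "r1")
  expect_error(make_uniform_mask(8, 1, 9), "r1")
})

test_that("ACS mask is contiguous and centered on the PE center line", {
  am <- make_acs_mask(16, 4)
  expect_identical(which(am) - 1L, 6:9)   # center line floor(16/2) = 8
  expect_true(all(diff(which(am)) == 1))
  expect_identical(sum(make_acs_mask(17, 5)), 5L)
  expect_true(make_acs_mask(17, 5)[floor(17 / 2) + 1])
  expect_error(make_acs_mask(8, 9), "n_acs")
})

test_that("random subset selects the right counts from uniform lines only", {
  um <- make_uniform_mask(128, 4, 2)
  expect_identical(make_random_subset(um, 1, 0.25, 1), um)
  rs <- make_random_subset(um, 4, 0.25, 7)
  expect_true(all(rowSums(rs) == 16))            # round(64 / 4)
  expect_true(all(rs <= um))                     # subset of the lattice
  # the center-most uniform line is always kept
  c0 <- floor(128 / 2)
  for (f in 1:4) {
    cand <- which(um[f, ]) - 1L
    ic <- cand[which.min(abs(cand - c0))]
    expect_true(rs[f, ic + 1L])
  }
  expect_error(make_random_subset(um, 0.5, 0.25, 1), "r2")
})

test_that("random subsets are seed-reproducible and frame-varying", {
  um <- make_uniform_mask(64, 6, 2)
  a <- make_random_subset(um, 3, 0.25, 42)
  b <- make_random_subset(um, 3, 0.25, 42)
  expect_identical(a, b)
  expect_false(identical(a, make_random_subset(um, 3, 0.25, 43)))
  expect_true(any(a[1, ] != a[2, ]))             # frames drawn independently
})

test_that("selection frequencies follow the tapered Gaussian density", {
  n_pe <- 128
  um <- make_uniform_mask(n_pe, 1, 2)
  cand <- which(um[1, ]) - 1L
  u <- length(cand)
  k <- round(u / 4)
  c0 <- floor(n_pe / 2)
  ic <- which.min(abs(cand - c0))
  p <- stats::dnorm(cand, mean = c0, sd = 0.25 * n_pe)
  p_rest <- p[-ic] / sum(p[-ic])
  draws <- 10000L
  counts <- numeric(u)
  for (s in seq_len(draws)) {
    sel <- which(make_random_subset(um, 4, 0.25, s)[1, ]) - 1L
    counts[match(sel, cand)] <- counts[match(sel, cand)] + 1
  }
  expect_equal(counts[ic], draws)                # forced center line
  # expected inclusion probability of the systematic PPS draw is (k-1) p_i
  pi_i <- (k - 1) * p_rest
  se <- sqrt(draws * pi_i * (1 - pi_i))
  expect_true(all(abs(counts[-ic] - draws * pi_i) <= 3 * se + 1))
})

test_that("acquired mask composes random subset with broadcast ACS", {
  empty <- matrix(FALSE, 3, 32)
  acq <- compose_acquired(empty, make_acs_mask(32, 4))
  expect_true(all(rowSums(acq) == 4))
  # disjoint union
  rnd <- matrix(FALSE, 2, 64)
  rnd[, 1:10] <- TRUE
  acs <- rep(FALSE, 64); acs[20:51] <- TRUE
  expect_true(all(rowSums(compose_acquired(rnd, acs)) == 42))
  expect_error(compose_acquired(rnd, rep(TRUE, 8)), "length")
})

test_that("Data-4-like plan acquires the brute-force per-frame line count", {
  plan <- sampling_plan(165, 304, 5, r1 = 6, r2 = 2, n_acs = 32, seed = 2)
  u <- ceiling(165 / 6)
  k <- floor(u / 2 + 0.5)
  for (f in 1:5) {
    overlap <- sum(plan$random_mask[f, ] & plan$acs_mask)
    expect_equal(sum(plan$acquired_mask[f, ]), k + 32 - overlap)
  }
})

test_that("net reduction factor follows the ACS-corrected formula", {
  expect_equal(round(net_reduction_factor(165, 6, 2, 32), 1), 3.6)
  expect_equal(net_reduction_factor(99, 1, 1, 0), 1.0)
  expect_equal(net_reduction_factor(128, 2, 2, 16), 128 / 48)
  expect_error(net_reduction_factor(128, 0.5, 1, 0), "r1")
  # monotonicity
  r <- sapply(1:6, function(a) net_reduction_factor(128, a, 1.5, 20))
  expect_true(all(diff(r) > 0))
  r <- sapply(c(0, 8, 16, 32), function(a) net_reduction_factor(128, 2, 2, a))
  expect_true(all(diff(r) < 0))
})

test_that("apply_mask zero-fills exactly and is idempotent", {
  set.seed(4)
  k <- array(rcomplex(16 * 8 * 3 * 2), c(16, 8, 3, 2))
  plan <- sampling_plan(16, 8, 3, r1 = 2, r2 = 2, n_acs = 4, seed = 1)
  m <- plan$acquired_mask
  km <- apply_mask(k, m)
  expect_identical(apply_mask(km, m), km)
  expect_identical(apply_mask(k, matrix(TRUE, 3, 16)), k)
  expect_true(all(apply_mask(k, matrix(FALSE, 3, 16)) == 0i))
  # energy restricted to the mask (direct summation oracle)
  e <- 0
  for (f in 1:3) e <- e + sum(Mod(k[m[f, ], , f, ])^2)
  expect_equal(sum(Mod(km)^2), e)
  # acquired lines bit-identical
  for (f in 1:3) expect_identical(km[m[f, ], , f, ], k[m[f, ], , f, ])
  expect_error(apply_mask(k, matrix(TRUE, 2, 16)), "mask")
})

test_that("acquired line counts are monotone in the plan parameters", {
  cnt <- function(r1, r2, acs) {
    sum(sampling_plan(96, 64, 4, r1, r2, acs, seed = 3)$acquired_mask)
  }
  expect_true(cnt(2, 2, 8) >= cnt(4, 2, 8))
  expect_true(cnt(2, 2, 8) >= cnt(2, 4, 8))
  expect_true(cnt(2, 2, 16) >= cnt(2, 2, 8))
})
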