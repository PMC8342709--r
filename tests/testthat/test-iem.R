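test_that("channel responses follow the rectified raised-cosine filter", {
  b <- channel_basis()
  # unit response at a channel's own center, both precedence modes
  bs <- channel_basis(mode = "power_on_sum")
  for (basis in list(b, bs)) {
    for (i in seq_along(basis$centers)) {
      expect_equal(channel_response(basis$centers[i], basis)[i], 1)
    }
  }
  # hand evaluation at 90 deg from a center with s = 180, exponent 8
  expect_equal(channel_response(90, b)[1], 0.5 + 0.5 * cos(pi / 4)^8)
  expect_equal(channel_response(90, b)[1], 0.53125)
  # support boundary: wrapped distance 180 with s = 180 gives 0
  expect_equal(channel_response(180, b)[1], 0)
  # angles are treated modulo 360
  expect_equal(channel_response(370, b), channel_response(10, b))
  expect_error(channel_basis(centers = c(0, 360)), "distinct")
})

test_that("the predicted channel matrix has the documented structure", {
  b <- channel_basis()
  C <- channel_matrix(b$centers, b)
  expect_equal(diag(C), rep(1, 8))
  C32 <- channel_matrix(seq(0, 360 - 11.25, by = 11.25), b)
  expect_equal(qr(C32)$rank, 8)
  expect_equal(channel_matrix(33, b)[1, ], channel_response(33, b))
})

test_that("weight estimation equals OLS and matches a pseudo-inverse oracle", {
  skip_if_not_installed("MASS")
  b <- channel_basis()
  set.seed(21)
  angles <- runif(50, 0, 360)
  C <- channel_matrix(angles, b)
  W_true <- matrix(rnorm(8 * 200), 8, 200)
  # consistent system: exact recovery
  m0 <- estimate_weights(C, C %*% W_true, b)
  expect_lt(max(abs(m0$weights - W_true)), 1e-8)
  # noisy system: agreement with an independent pseudo-inverse solver
  B <- C %*% W_true + matrix(rnorm(50 * 200, 0, 0.3), 50, 200)
  m1 <- estimate_weights(C, B, b)
  expect_lt(max(abs(m1$weights - MASS::ginv(C) %*% B)), 1e-8)
  # underdetermined and rank-deficient designs fail loudly
  expect_error(estimate_weights(C[1:5, ], B[1:5, ], b), "underdetermined")
  C_bad <- channel_matrix(rep(13, 20), b)
  expect_error(estimate_weights(C_bad, B[1:20, ], b), "ill-conditioned")
})

test_that("inversion is the exact right-inverse of the forward map", {
  b <- channel_basis()
  set.seed(22)
  C <- channel_matrix(runif(40, 0, 360), b)
  W <- matrix(rnorm(8 * 100), 8, 100)
  model <- estimate_weights(C, C %*% W, b)
  # round trip invert(C W) = C
  expect_lt(max(abs(invert_channels(C %*% model$weights, model) - C)), 1e-8)
  # single-row inversion matches a row-wise oracle
  brow <- matrix(rnorm(100), 1, 100)
  oracle <- drop(brow %*% t(W) %*% solve(W %*% t(W)))
  expect_equal(drop(invert_channels(brow, model)), oracle, tolerance = 1e-8)
  # fewer voxels than channels is an error
  m_small <- model
  m_small$weights <- model$weights[, 1:5]
  expect_error(invert_channels(matrix(rnorm(5), 1, 5), m_small),
               "at least as many voxels")
})

test_that("reconstruction equals the brute-force channel sum", {
  b <- channel_basis()
  set.seed(23)
  ch <- rnorm(8)
  rec <- reconstruct(ch, b)
  # independent loop oracle
  oracle <- vapply(rec$grid, function(g) {
    sum(ch * channel_response(g, b))
  }, numeric(1))
  expect_equal(rec$activation, oracle, tolerance = 1e-12)
  expect_equal(reconstruct(rep(0, 8), b)$activation, rep(0, 360))
  e1 <- reconstruct(c(1, rep(0, 7)), b)
  expect_equal(e1$activation, channel_matrix(e1$grid, b)[, 1])
})

test_that("alignment shifts the reference to zero and preserves mass", {
  b <- channel_basis()
  rec <- reconstruct(channel_response(37, b), b)
  expect_equal(rec$grid[which.max(rec$activation)], 37)
  al <- align_recon(rec, 37)
  expect_equal(al$grid[which.max(al$activation)], 0)
  expect_equal(sum(al$activation), sum(rec$activation))
  # reference 0 is the identity
  expect_equal(align_recon(rec, 0)$activation, rec$activation)
  # composition: align by a then b == align by a + b
  ab <- align_recon(align_recon(rec, 20), 17)
  expect_equal(ab$activation, al$activation)
  expect_equal(ab$aligned_to, 37)
})
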