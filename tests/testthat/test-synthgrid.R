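test_that("generated layers honour the requested cross-correlation", {
  st <- make_climate_stack(pair_spec(rho = 1))
  r <- cor(as.vector(st$layers$a), as.vector(st$layers$b))
  expect_gte(r, 0.99)

  st6 <- make_climate_stack(pair_spec(rho = 0.6, n = 120))
  r6 <- cor(as.vector(st6$layers$a), as.vector(st6$layers$b))
  expect_lt(abs(r6 - 0.6), 0.05)
})

test_that("stack generation is deterministic and degenerate scales work", {
  spec <- pair_spec(rho = 0.3, n = 30, smoothness = 1)
  expect_identical(make_climate_stack(spec), make_climate_stack(spec))

  flat <- synthetic_climate_spec(
    data.frame(name = c("a", "b"), mean = c(5, -2), sd = c(0, 1)),
    n_rows = 20, n_cols = 20, seed = 3)
  st <- make_climate_stack(flat)
  expect_true(all(st$layers$a == 5))
})

test_that("invalid correlation matrices are rejected by name", {
  bad <- matrix(c(1, 2, 2, 1), 2, 2)  # eigenvalues 3, -1
  expect_error(
    synthetic_climate_spec(data.frame(name = c("a", "b"), mean = 0, sd = 1),
                           10, 10, correlation = bad),
    "correlation.*positive semidefinite")
  asym <- matrix(c(1, 0.2, 0.4, 1), 2, 2)
  expect_error(
    synthetic_climate_spec(data.frame(name = c("a", "b"), mean = 0, sd = 1),
                           10, 10, correlation = asym),
    "correlation.*symmetric")
})

test_that("marginal mean and sd are calibrated on unsmoothed grids", {
  spec <- synthetic_climate_spec(
    data.frame(name = c("a", "b"), mean = c(-1.7, 1113.2), sd = c(4, 369.4)),
    n_rows = 100, n_cols = 100, smoothness = 0, seed = 11)
  st <- make_climate_stack(spec)
  for (k in 1:2) {
    v <- as.vector(st$layers[[k]])
    tol <- 4 * spec$variables$sd[k] / sqrt(length(v))
    expect_lt(abs(mean(v) - spec$variables$mean[k]), tol)
  }
})

test_that("smoothing preserves marginal calibration via rescaling", {
  spec <- synthetic_climate_spec(
    data.frame(name = "a", mean = 10, sd = 3),
    n_rows = 100, n_cols = 100, smoothness = 3, seed = 5)
  v <- as.vector(make_climate_stack(spec)$layers$a)
  expect_lt(abs(sd(v) - 3), 1e-8)  # rescaled exactly to spec sd
  # smoothing induces positive spatial autocorrelation between row neighbours
  m <- make_climate_stack(spec)$layers$a
  expect_gt(cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ])), 0.5)
})

test_that("future stacks are additive and preserve georeference and nodata", {
  m <- matrix(rnorm(20), 4, 5)
  m[2, 3] <- NA
  st <- tiny_stack(bio1 = m, bio12 = m * 10)
  same <- make_future_stack(st, c(bio1 = 0, bio12 = 0))
  expect_identical(same$layers, st$layers)

  fut <- make_future_stack(st, c(bio1 = 2))
  expect_equal(fut$layers$bio1 - st$layers$bio1,
               matrix(c(2, NA)[1 + is.na(m)], 4, 5))
  expect_identical(fut$layers$bio12, st$layers$bio12)
  expect_true(is.na(fut$layers$bio1[2, 3]))
  expect_identical(dim(fut), dim(st))

  expect_error(make_future_stack(st, c(bioX = 1)), "bioX.*bio1, bio12")
})

test_that("occurrence sampling respects the envelope support", {
  st <- make_climate_stack(pair_spec(rho = 0, n = 40))
  # envelope spanning the full observed range: every cell eligible
  full <- true_envelope_spec(
    lower = c(a = min(st$layers$a), b = min(st$layers$b)),
    upper = c(a = max(st$layers$a), b = max(st$layers$b)))
  occ <- sample_occurrences(st, full, 300, seed = 9)
  expect_true(all(occ$a >= full$lower["a"] & occ$a <= full$upper["a"]))

  # a bound excluding half the grid: no samples in the excluded half
  half <- true_envelope_spec(
    lower = c(a = median(st$layers$a), b = min(st$layers$b)),
    upper = c(a = max(st$layers$a), b = max(st$layers$b)))
  occ2 <- sample_occurrences(st, half, 100, seed = 9)
  expect_true(all(occ2$a >= median(st$layers$a)))

  # impossible envelope
  none <- true_envelope_spec(lower = c(a = 1e6), upper = c(a = 2e6))
  expect_error(sample_occurrences(st, none, 5), "no habitable cells")

  # determinism and distinct cells
  occ3 <- sample_occurrences(st, full, 300, seed = 9)
  expect_identical(as_tibble(occ), as_tibble(occ3))
  expect_false(any(duplicated(paste(occ$lon, occ$lat))))
})

test_that("sampled records carry their generating cell values exactly", {
  st <- make_climate_stack(default_climate_spec(n_rows = 50, n_cols = 50))
  occ <- sample_occurrences(st, default_envelope(), 150, seed = 2)
  env <- extract_at_points(st, occ)
  for (v in stack_vars(st)) {
    expect_identical(env[[v]], occ[[v]])
  }
})
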