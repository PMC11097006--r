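test_that("extraction reads the containing cell and handles nodata", {
  st <- const_stack(7)
  occ <- occ_table(lon = c(100.5, 103.2), lat = c(39.5, 36.8))
  env <- extract_at_points(st, occ)
  expect_equal(env$bio1, c(7, 7))
  expect_equal(attr(env, "dropped_nodata"), 0L)

  m <- matrix(1:20 + 0, 4, 5)
  m[2, 2] <- NA
  st2 <- tiny_stack(bio1 = m)
  occ2 <- occ_table(lon = c(101.5, 100.5), lat = c(38.5, 39.5))  # cell (2,2), (1,1)
  env2 <- extract_at_points(st2, occ2)
  expect_equal(nrow(env2), 1)
  expect_equal(attr(env2, "dropped_nodata"), 1L)
  expect_equal(env2$bio1, m[1, 1])

  far <- occ_table(lon = 130, lat = 35, id = "outlier")
  expect_error(extract_at_points(st, far), "outlier")
})

test_that("descriptive statistics reproduce printed summary arithmetic", {
  # reconstruct an annual-precipitation sample with the published moments
  bio12 <- vector_with_moments(604, mean = 1113.2, sd = 369.4)
  s <- descriptive_stats(tibble::tibble(bio12 = bio12))
  expect_equal(s$mean, 1113.2)
  expect_equal(s$sd, 369.4)
  expect_equal(s$cv, 33.2)
  expect_equal(s$ci95_low, 1083.7)
  expect_equal(s$ci95_high, 1142.7)

  const <- descriptive_stats(data.frame(x = rep(4.2, 10)))
  expect_equal(const$sd, 0)
  expect_equal(const$cv, 0)
  expect_equal(const$ci95_low, const$ci95_high)

  centered <- descriptive_stats(data.frame(x = c(-1, 1)), digits = NULL)
  expect_true(is.na(centered$cv))  # undefined cv at zero mean
})

test_that("confidence interval width shrinks as 1/sqrt(n)", {
  widths <- vapply(c(100, 400, 1600), function(n) {
    x <- vector_with_moments(n, mean = 50, sd = 10, seed = n)
    s <- descriptive_stats(data.frame(x = x), digits = NULL)
    s$ci95_high - s$ci95_low
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 1e-10)
  expect_equal(widths[2] / widths[3], 2, tolerance = 1e-10)
})

test_that("stepwise VIF prunes collinear variables and reports rounds", {
  # orthogonal design: nothing dropped, all VIFs exactly 1
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1), c = c(1, -1, -1, 1))
  X <- rbind(X, X)  # 8 rows > 3 variables
  rep0 <- vif_stepwise(as.data.frame(X), threshold = 5)
  expect_equal(rep0$kept, c("a", "b", "c"))
  expect_equal(rep0$rounds$vif, rep(1, 3), tolerance = 1e-12)

  # duplicated column: exactly one of the pair goes in round 1
  dup <- withr::with_seed(8, data.frame(x1 = rnorm(30), x2 = rnorm(30)))
  dup$x3 <- dup$x1
  rep1 <- vif_stepwise(dup, threshold = 5)
  expect_equal(nrow(rep1$dropped), 1)
  expect_equal(rep1$dropped$variable, "x3")  # tie broken toward later column
  expect_setequal(rep1$kept, c("x1", "x2"))

  # every kept variable satisfies the threshold on exit
  corr <- withr::with_seed(12, {
    z <- rnorm(100)
    data.frame(a = z + rnorm(100, sd = 0.3), b = z + rnorm(100, sd = 0.3),
               c = z + rnorm(100, sd = 0.3), d = rnorm(100))
  })
  rep2 <- vif_stepwise(corr, threshold = 5)
  final <- dplyr::filter(tidy(rep2), round == max(round))
  expect_true(all(final$vif < 5))
  expect_setequal(final$variable, rep2$kept)
})

test_that("VIF matches a direct normal-equations regression oracle", {
  df <- withr::with_seed(21, {
    x1 <- rnorm(60)
    x2 <- rnorm(60)
    data.frame(x1 = x1, x2 = x2, x3 = x1 + x2 + rnorm(60, sd = 0.05))
  })
  rounds <- tidy(vif_stepwise(df, threshold = Inf))
  # oracle: solve the normal equations by hand for x3 ~ x1 + x2
  y <- df$x3
  X <- cbind(1, df$x1, df$x2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  r2 <- 1 - sum((y - X %*% beta)^2) / sum((y - mean(y))^2)
  expect_equal(rounds$vif[rounds$variable == "x3"], 1 / (1 - r2),
               tolerance = 1e-6)
})

test_that("PCA of the correlation matrix has the closed-form 2x2 solution", {
  df <- withr::with_seed(14, {
    z <- rnorm(200)
    data.frame(u = z + rnorm(200), v = z + rnorm(200))
  })
  rho <- cor(df$u, df$v)
  p <- pca_env(df)
  expect_equal(p$eigenvalues, c(1 + rho, 1 - rho), tolerance = 1e-12)
  expect_equal(p$proportion, 100 * c(1 + rho, 1 - rho) / 2, tolerance = 1e-12)
})

test_that("PCA conserves trace, reconstructs the correlation matrix, and fixes signs", {
  df <- withr::with_seed(15, as.data.frame(matrix(rnorm(300), 60, 5)))
  p <- pca_env(df)
  expect_equal(sum(p$eigenvalues), 5, tolerance = 1e-10)
  expect_equal(sum(p$proportion), 100, tolerance = 1e-8)
  recon <- p$loadings %*% diag(p$eigenvalues) %*% t(p$loadings)
  expect_lt(max(abs(recon - cor(as.matrix(df)))), 1e-8)
  # unit-length loading columns, largest-magnitude entry positive
  expect_equal(colSums(p$loadings^2), rep(1, 5), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (k in 1:5) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  }

  df$flat <- 1
  expect_error(pca_env(df), "flat")
})

test_that("independent large-n data give near-isotropic components", {
  df <- withr::with_seed(16, as.data.frame(matrix(rnorm(4000), 1000, 4)))
  p <- pca_env(df)
  expect_true(all(abs(p$eigenvalues - 1) < 0.15))
})
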