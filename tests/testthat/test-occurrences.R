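test_that("reading validates coordinates and counts rejections", {
  clean <- read_occurrences(data.frame(lon = c(110, 115, 98), lat = c(30, 35, 25)))
  expect_equal(nrow(clean), 3)
  expect_equal(provenance(clean)$rejected, 0L)

  dirty <- read_occurrences(data.frame(lon = c(110, 115), lat = c(30, 95)))
  expect_equal(nrow(dirty), 1)
  expect_equal(provenance(dirty)$rejected, 1L)

  expect_error(read_occurrences(data.frame(x = 1, y = 2)), "lon, lat")
  expect_error(
    read_occurrences(data.frame(lon = c(1, 2), lat = c(1, 2),
                                id = c("a", "a"))),
    "Duplicated occurrence id\\(s\\): a")
})

test_that("delimited files round-trip through write/read", {
  occ <- occ_table(lon = c(110.25, 115.5), lat = c(30.1, 35.9),
                   elevation = c(120, NA), label = c("X", NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, path)
  back <- read_occurrences(path)
  expect_equal(back$lon, occ$lon)
  expect_equal(back$lat, occ$lat)
  expect_equal(back$elevation, occ$elevation)
})

test_that("thinning keeps the first record per cell and is idempotent", {
  grid <- const_stack(nr = 10, nc = 10)
  # two points in the same 1-degree cell
  occ <- occ_table(lon = c(100.2, 100.7, 103.5), lat = c(39.2, 39.7, 35.5))
  thin <- thin_to_cells(occ, grid)
  expect_equal(nrow(thin), 2)
  expect_equal(thin$id[1], occ$id[1])  # first in input order wins
  expect_equal(provenance(thin)$thinned, 1L)

  # all in distinct cells: identity
  sparse <- occ_table(lon = c(100.5, 102.5, 104.5), lat = c(39.5, 37.5, 35.5))
  expect_equal(nrow(thin_to_cells(sparse, grid)), 3)

  # fixture of 10 points; expected count = distinct floor-indexed cells
  withr::with_seed(31, {
    lon <- runif(10, 100, 105)
    lat <- runif(10, 33, 38)
  })
  occ10 <- occ_table(lon = lon, lat = lat)
  expected <- nrow(unique(cbind(floor(lon - 100), floor(40 - lat))))
  thinned <- thin_to_cells(occ10, grid)
  expect_equal(nrow(thinned), expected)
  expect_identical(as_tibble(thin_to_cells(thinned, grid)),
                   as_tibble(thinned))

  outside <- occ_table(lon = 150, lat = 10, id = "far_away")
  expect_error(thin_to_cells(outside, grid), "far_away")
})

test_that("altitude classes partition elevations with lower-inclusive bounds", {
  base <- occ_table(lon = rep(110, 4), lat = rep(30, 4),
                    elevation = c(100, 900, 1700, 2500))
  s <- altitude_class_summary(base)
  expect_equal(s$percent, c(25, 25, 25, 25))
  expect_equal(sum(s$percent), 100, tolerance = 0.002)

  zero <- occ_table(lon = c(1, 2), lat = c(1, 2), elevation = c(0, 0))
  expect_equal(altitude_class_summary(zero)$percent, c(100, 0, 0, 0))

  # boundary values land in the upper class (lower-inclusive)
  edge <- occ_table(lon = 1:3, lat = 1:3, elevation = c(800, 1600, 2400))
  se <- altitude_class_summary(edge)
  expect_equal(se$n, c(0L, 1L, 1L, 1L))

  # every elevation maps to exactly one class
  any_elev <- occ_table(lon = rep(1, 50), lat = rep(1, 50),
                        elevation = withr::with_seed(4, runif(50, 0, 4000)))
  expect_equal(sum(altitude_class_summary(any_elev)$n), 50L)

  no_elev <- occ_table(lon = 1, lat = 1)
  expect_error(altitude_class_summary(no_elev), "no elevation data")
})

test_that("train/test split is a seeded 70/30 partition", {
  occ <- occ_table(lon = 1:10, lat = 1:10)
  parts <- split_train_test(occ, 0.7, seed = 5)
  expect_equal(nrow(parts$train), 7)
  expect_equal(nrow(parts$test), 3)
  expect_setequal(c(parts$train$id, parts$test$id), occ$id)
  expect_length(intersect(parts$train$id, parts$test$id), 0)

  again <- split_train_test(occ, 0.7, seed = 5)
  expect_identical(parts$train$id, again$train$id)

  expect_error(split_train_test(occ_table(lon = 1, lat = 1)),
               "too few records")
})

test_that("each record lands in train with frequency near the train fraction", {
  occ <- occ_table(lon = 1:10, lat = 1:10)
  hits <- numeric(10)
  n_seeds <- 1000
  for (s in seq_len(n_seeds)) {
    tr <- split_train_test(occ, 0.7, seed = s)$train$id
    hits <- hits + occ$id %in% tr
  }
  freq <- hits / n_seeds
  expect_true(all(abs(freq - 0.7) <= 0.05 + 1e-9))
})

test_that("extent summary returns the tight bounding box", {
  one <- occ_table(lon = 110, lat = 30)
  expect_equal(unlist(extent_summary(one)),
               c(lon_min = 110, lon_max = 110, lat_min = 30, lat_max = 30))

  # the published occurrence range of the compiled national data set
  two <- occ_table(lon = c(98.5, 123.6), lat = c(24.5, 40.4))
  expect_equal(unlist(extent_summary(two)),
               c(lon_min = 98.5, lon_max = 123.6, lat_min = 24.5,
                 lat_max = 40.4))

  three <- occ_table(lon = c(98.5, 123.6, 110), lat = c(24.5, 40.4, 30))
  expect_equal(extent_summary(three), extent_summary(two))

  expect_error(extent_summary(occ_table(lon = numeric(), lat = numeric())),
               "empty")
})
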