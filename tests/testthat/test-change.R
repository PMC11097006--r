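make_cat <- function(codes_matrix, origin_lat = 0 + nrow(codes_matrix) / 2 *
                       (2.5 / 60), cell_size = 2.5 / 60, model = "bioclim") {
  nichebox:::new_category_grid(
    codes_matrix,
    list(origin_lon = 100, origin_lat = origin_lat, cell_size = cell_size),
    model
  )
}

test_that("spherical-band cell areas match the closed form and cosine scaling", {
  a_eq <- cell_area_km2(0, 2.5 / 60)
  expect_equal(a_eq, 21.47, tolerance = 0.01 / 21.47)

  ratio <- cell_area_km2(60, 2.5 / 60) / a_eq
  expect_equal(ratio, cos(60 * pi / 180), tolerance = 0.002)

  lats <- seq(0, 89, by = 1)
  areas <- cell_area_km2(lats, 2.5 / 60)
  expect_true(all(diff(areas) < 0))

  expect_error(cell_area_km2(90, 1), "pole")
  expect_error(cell_area_km2(95, 0.1), "within")
})

test_that("per-class areas partition the total grid area", {
  # 10x10 equatorial grid, 25 cells 'excellent', rest unsuitable
  codes <- matrix(0L, 10, 10)
  codes[1:5, 1:5] <- 5L
  cat <- make_cat(codes)
  areas <- class_areas(cat)
  expect_equal(areas$area_1e4_km2[areas$class == "excellent"],
               0.0537, tolerance = 0.0005 / 0.0537)
  expect_equal(round(areas$area_1e4_km2[areas$class == "excellent"], 1), 0.1)

  total_cells <- sum(cell_area_km2(
    cat$origin_lat - (seq_len(10) - 0.5) * cat$cell_size, cat$cell_size) * 10)
  expect_equal(sum(areas$area_1e4_km2), total_cells / 1e4, tolerance = 1e-10)

  uniform <- make_cat(matrix(3L, 6, 6))
  ua <- class_areas(uniform)
  expect_equal(sum(ua$area_1e4_km2[ua$class != "high"]), 0)
})

test_that("areas are invariant under longitude translation", {
  codes <- matrix(sample(0:5, 64, replace = TRUE), 8, 8)
  a <- class_areas(make_cat(codes))
  b <- class_areas(nichebox:::new_category_grid(
    codes, list(origin_lon = 30, origin_lat = 4 * 2.5 / 60,
                cell_size = 2.5 / 60), "bioclim"))
  expect_equal(a$area_1e4_km2, b$area_1e4_km2)
})

test_that("percent change reproduces published scenario arithmetic", {
  expect_equal(percent_change(16.5, 15.5), -6.1)
  expect_equal(percent_change(27.5, 32.3), 17.5)
  expect_equal(percent_change(4.2, 4.2), 0)
  expect_true(is.na(percent_change(0, 3)))
  # rounding is half away from zero
  expect_equal(percent_change(100, 100.25), 0.3)
  expect_equal(percent_change(100, 99.75), -0.3)
})

test_that("transition maps obey the retained/lost/new accounting identities", {
  withr::with_seed(30, {
    cur <- make_cat(matrix(sample(0:5, 100, replace = TRUE), 10, 10))
    fut <- make_cat(matrix(sample(0:5, 100, replace = TRUE), 10, 10))
  })
  tr <- transition_map(cur, fut, focal = "excellent")
  s <- tr$summary
  get <- function(cat) s$cells[s$category == cat]
  expect_equal(get("retained") + get("lost"), sum(cur$codes == 5))
  expect_equal(get("retained") + get("new"), sum(fut$codes == 5))

  # antisymmetry: swapping scenarios swaps lost and new
  rev <- transition_map(fut, cur, focal = "excellent")$summary
  expect_equal(rev$cells[rev$category == "lost"], get("new"))
  expect_equal(rev$cells[rev$category == "new"], get("lost"))
  expect_equal(rev$cells[rev$category == "retained"], get("retained"))

  same <- transition_map(cur, cur)
  expect_equal(same$summary$cells[same$summary$category == "lost"], 0)
  expect_equal(same$summary$cells[same$summary$category == "new"], 0)
  expect_equal(same$summary$cells[same$summary$category == "retained"],
               sum(cur$codes == 5))

  off <- nichebox:::new_category_grid(
    fut$codes, list(origin_lon = 101, origin_lat = fut$origin_lat,
                    cell_size = fut$cell_size), "bioclim")
  expect_error(transition_map(cur, off), "Georeference mismatch")
})

test_that("identical scenarios report zero change for every occupied class", {
  withr::with_seed(33, {
    cur <- make_cat(matrix(sample(0:5, 144, replace = TRUE), 12, 12))
  })
  ct <- change_table(cur, cur)
  occupied <- ct$current_area > 0
  expect_true(all(ct$change_percent[occupied] == 0))
})

test_that("patch statistics count 4-connected components", {
  solid <- matrix(0L, 6, 6)
  solid[2:4, 2:5] <- 5L
  expect_equal(patch_stats(make_cat(solid))$n_patches, 1)

  diag2 <- matrix(0L, 4, 4)
  diag2[1, 1] <- 5L
  diag2[2, 2] <- 5L
  expect_equal(patch_stats(make_cat(diag2))$n_patches, 2)
  expect_equal(patch_stats(make_cat(diag2), connectivity = 8)$n_patches, 1)

  three <- matrix(0L, 5, 5)
  three[1, 1] <- 5L
  three[3, 3] <- 5L
  three[5, 5] <- 5L
  ps <- patch_stats(make_cat(three))
  expect_equal(unlist(ps), c(n_patches = 3, mean_patch_cells = 1,
                             max_patch_cells = 1))

  empty <- patch_stats(make_cat(matrix(0L, 3, 3)))
  expect_equal(unlist(empty), c(n_patches = 0, mean_patch_cells = 0,
                                max_patch_cells = 0))
})
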