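test_that("distance matrix matches brute-force Euclidean distances", {
  land <- landscape(data.frame(
    id = 1:4, area_ha = 1, depth_cm = 1,
    x_m = c(0, 3, -2, 10), y_m = c(0, 4, 7, -1)
  ))
  d <- patch_distances(land)
  expect_equal(dim(d), c(4, 4))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(d[i, j],
                 sqrt((land$x_m[i] - land$x_m[j])^2 +
                      (land$y_m[i] - land$y_m[j])^2))
  }
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
})

test_that("hand-computed distance examples hold", {
  one <- landscape(data.frame(id = 1, area_ha = 1, depth_cm = 1,
                              x_m = 0, y_m = 0))
  expect_equal(unname(patch_distances(one)), matrix(0, 1, 1))

  two <- landscape(data.frame(id = 1:2, area_ha = 1, depth_cm = 1,
                              x_m = c(0, 3), y_m = c(0, 4)))
  expect_equal(patch_distances(two)[1, 2], 5)

  coll <- landscape(data.frame(id = 1:3, area_ha = 1, depth_cm = 1,
                               x_m = c(0, 100, 250), y_m = 0))
  expect_equal(unname(patch_distances(coll)),
               matrix(c(0, 100, 250, 100, 0, 150, 250, 150, 0), 3,
                      byrow = TRUE))
})

test_that("landscape validation rejects bad inputs by name", {
  base <- data.frame(id = 1:2, area_ha = 1, depth_cm = 1,
                     x_m = 0:1, y_m = 0)
  expect_error(landscape(base[, -2]), "area_ha")
  bad_area <- base; bad_area$area_ha[1] <- -1
  expect_error(landscape(bad_area), "area_ha")
  bad_depth <- base; bad_depth$depth_cm[2] <- -0.1
  expect_error(landscape(bad_depth), "depth_cm")
  dup <- base; dup$id <- c(1, 1)
  expect_error(landscape(dup), "id")
})

test_that("carrying capacity is depth x area x density, bilinear, zero-absorbing", {
  expect_equal(unname(carrying_capacity(
    data.frame(area_ha = 3, depth_cm = 2), 17)), 102)
  expect_equal(unname(carrying_capacity(
    data.frame(area_ha = 3, depth_cm = 0), 17)), 0)
  expect_equal(unname(carrying_capacity(
    data.frame(area_ha = 0, depth_cm = 2), 17)), 0)
  df <- data.frame(area_ha = runif(5, 0.1, 2), depth_cm = runif(5, 1, 9))
  k1 <- carrying_capacity(df, 17)
  expect_equal(carrying_capacity(transform(df, area_ha = 2 * area_ha), 17),
               2 * k1)
  expect_equal(carrying_capacity(transform(df, depth_cm = 2 * depth_cm), 17),
               2 * k1)
  expect_error(carrying_capacity(df, -1), "k_volume")
})

test_that("landscape CSV round-trips patches exactly", {
  land <- synthetic_landscape(seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landscape(land, path)
  back <- read_landscape(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(land))
})

test_that("synthetic generator is seed-reproducible with the preset shape", {
  a <- synthetic_landscape(seed = 42)
  b <- synthetic_landscape(seed = 42)
  expect_identical(a, b)
  c <- synthetic_landscape(seed = 43)
  expect_false(identical(a, c))

  expect_equal(nrow(a), 36)
  expect_setequal(unique(a$group), c("north", "central", "south"))
  K <- carrying_capacity(a, 17)
  # right-skewed K span emulating observed subpopulation sizes (~1-120)
  expect_lt(min(K), 5)
  expect_gt(max(K), 60)
  expect_lt(max(K), 250)
})

test_that("generator rejects inconsistent cluster counts", {
  cl <- default_clusters()
  expect_error(synthetic_landscape(n_patches = 35, clusters = cl),
               "sum")
})
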