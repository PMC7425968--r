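test_that("isolate_patch zeroes all other depths, keeps geometry, is idempotent", {
  land <- landscape(data.frame(id = c(4, 7, 9), area_ha = c(1, 2, 3),
                               depth_cm = c(2, 3, 4),
                               x_m = c(0, 100, 200), y_m = 0))
  iso <- isolate_patch(land, 7)
  expect_equal(unname(carrying_capacity(iso)), c(0, 2 * 3 * 17, 0))
  expect_equal(iso$x_m, land$x_m)
  expect_equal(iso$area_ha, land$area_ha)
  expect_identical(isolate_patch(iso, 7), iso)
  # input is untouched
  expect_equal(land$depth_cm, c(2, 3, 4))
  expect_error(isolate_patch(land, 99), "unknown")

  one <- single_patch_landscape()
  expect_identical(isolate_patch(one, 1), one)
})

test_that("sink classes follow the persistence thresholds", {
  expect_equal(sink_class(30), "I")
  expect_equal(sink_class(15), "II")
  expect_equal(sink_class(5), "III")
  # boundary placement: 25 and 10 both fall in class II
  expect_equal(sink_class(c(25, 10)), c("II", "II"))
  expect_equal(sink_class(c(25.01, 9.99)), c("I", "III"))
  expect_error(sink_class(-1), ">= 0")
})

test_that("classification partitions patches into exactly one class each", {
  land <- grouped_landscape()
  cls <- classify_patches(land, demography_params(), migration_params(),
                          sim_config(tmax = 40, trials = 30, seed = 5),
                          persist_years = 25)
  expect_equal(nrow(cls), nrow(land))
  expect_true(all(cls$class %in% c("Context-independent Source",
                                   "Rescued Sink",
                                   "Context-independent Sink",
                                   "Converted Sink")))
  expect_true(all(cls$sink_class %in% c("I", "II", "III")))
  # each patch appears once
  expect_setequal(cls$id, land$id)
})

test_that("a zero-habitat patch is a Context-independent Sink", {
  land <- landscape(rbind(patch_with_K(102, id = 1, x = 0),
                          data.frame(id = 2, area_ha = 1, depth_cm = 0,
                                     x_m = 100, y_m = 0)))
  cls <- classify_patches(land, demography_params(v_r = 0),
                          migration_params(beta = 0),
                          sim_config(tmax = 30, trials = 5, seed = 2))
  expect_equal(cls$class[cls$id == 2], "Context-independent Sink")
  expect_equal(cls$te_isolated[cls$id == 2], 1)
  expect_equal(cls$sink_class[cls$id == 2], "III")
})

test_that("a far-away strong patch gets the same class isolated or in context", {
  land <- landscape(rbind(patch_with_K(102, id = 1, x = 0),
                          patch_with_K(102, id = 2, x = 1e6)))
  demo <- demography_params(r_d = 0.01, v_r = 0)
  cls <- classify_patches(land, demo, migration_params(),
                          sim_config(tmax = 30, trials = 5, seed = 3))
  expect_true(all(cls$class == "Context-independent Source"))
})

test_that("classification of a symmetric two-patch fixture is label-invariant", {
  mk <- function(ids) landscape(rbind(patch_with_K(60, id = ids[1], x = 0),
                                      patch_with_K(60, id = ids[2], x = 80)))
  cfg <- sim_config(tmax = 40, trials = 60, seed = 11)
  a <- classify_patches(mk(c(1, 2)), config = cfg)
  b <- classify_patches(mk(c(2, 1)), config = cfg)
  expect_setequal(a$class, b$class)
})
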