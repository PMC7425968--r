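test_that("deterministic single patch sits at its fixed point forever", {
  land <- single_patch_landscape(K = 102)  # depth 6, area 1
  demo <- demography_params(r_d = 0.01, v_r = 0)
  cfg <- sim_config(tmax = 101, trials = 1, seed = 1)
  tr <- run_trial(land, demo, migration_params(beta = 0), cfg)
  expect_equal(unname(tr$N[, 1]), rep(102, 102))
  expect_true(is.na(tr$extinct_year))
})

test_that("a landscape with no habitat is extinct at year one", {
  land <- landscape(data.frame(id = 1:3, area_ha = 1, depth_cm = 0,
                               x_m = c(0, 50, 100), y_m = 0))
  tr <- run_trial(land, demography_params(), migration_params(),
                  sim_config(trials = 1, seed = 4))
  expect_equal(tr$extinct_year, 1L)
  expect_true(all(tr$N == 0))
})

test_that("an empty patch next to a strong source is recolonized quickly", {
  land <- two_patch_landscape(K1 = 102, K2 = 102, d = 100)
  demo <- demography_params(r_d = 0.01, v_r = 0)
  mig <- migration_params(alpha = 0.01, beta = 0.1)
  # lambda onto the empty patch = 0.1 * 102 * exp(-1) ~ 3.75/yr, so
  # P(no migrant in 5 yr) = exp(-5 * 3.75) ~ 7e-9
  hits <- 0L
  for (i in 1:1000) {
    cfg <- sim_config(tmax = 5, trials = 1, seed = 1000 + i,
                      n0 = c(102, 0))
    tr <- run_trial(land, demo, mig, cfg, trial_seed = cfg$seed)
    if (any(tr$N[-1, 2] >= 1)) hits <- hits + 1L
  }
  expect_gte(hits / 1000, 0.99)
})

test_that("metapopulation extinction is absorbing", {
  land <- two_patch_landscape(K1 = 3, K2 = 2, d = 200)
  cfg <- sim_config(tmax = 60, trials = 40, seed = 21)
  for (i in 1:40) {
    tr <- run_trial(land, demography_params(v_r = 2), migration_params(),
                    cfg, trial_seed = cfg$seed + i - 1)
    if (!is.na(tr$extinct_year)) {
      after <- tr$N[(tr$extinct_year + 1):nrow(tr$N), , drop = FALSE]
      expect_true(all(after == 0))
    }
  }
})

test_that("trial populations never go negative and migrants are integer", {
  land <- synthetic_landscape(seed = 3)
  tr <- run_trial(land, demography_params(), migration_params(),
                  sim_config(tmax = 50, trials = 1, seed = 9))
  expect_true(all(tr$N >= 0))
  expect_true(all(tr$migrants >= 0))
  expect_true(all(tr$migrants == floor(tr$migrants)))
})

test_that("estimate_te averages with censoring at tmax", {
  expect_equal(estimate_te(c(1, 1, 1), 101), 1)
  expect_equal(estimate_te(c(5, 10, NA), 101), (5 + 10 + 101) / 3)
  expect_equal(estimate_te(c(NA, NA), 101), 101)
  expect_error(estimate_te(numeric(0), 101), "nonempty")
  expect_error(estimate_te(c(0, 5), 101), "1..tmax")
})

test_that("single-trial aggregation equals that trial's history", {
  land <- two_patch_landscape()
  cfg <- sim_config(tmax = 30, trials = 1, seed = 77)
  sim <- run_simulation(land, demography_params(), migration_params(), cfg)
  tr <- run_trial(land, demography_params(), migration_params(), cfg,
                  trial_seed = cfg$seed)
  expect_equal(sim$mean_N, tr$N)
  expect_equal(unname(sim$trial_total_N[1, ]), unname(rowSums(tr$N)))
  expect_equal(sim$te, estimate_te(tr$extinct_year, 30))
})

test_that("deterministic persistent setup yields censored T_e and full occupancy", {
  land <- single_patch_landscape(K = 50)
  demo <- demography_params(r_d = 0.01, v_r = 0, k_volume = 17)
  cfg <- sim_config(tmax = 101, trials = 5, seed = 2)
  sim <- run_simulation(land, demo, migration_params(beta = 0), cfg)
  expect_equal(sim$te, 101)
  expect_true(all(sim$occupancy == 1))
  rv <- response_variables(sim, t = 25)
  expect_equal(rv$mN, 50)
  expect_equal(rv$mvp, 1)
  expect_equal(rv$mcol, 0)
})

test_that("mean migrants at t matches the Poisson mean on a deterministic fixture", {
  land <- two_patch_landscape(K1 = 102, K2 = 102, d = 100)
  demo <- demography_params(r_d = 0.01, v_r = 0)
  mig <- migration_params(alpha = 0.01, beta = 0.01)
  lam <- 0.01 * 102 * exp(-1)     # pressure on each patch from the other
  cfg <- sim_config(tmax = 30, trials = 500, seed = 5)
  sim <- run_simulation(land, demo, mig, cfg)
  rv <- response_variables(sim, t = 25)
  se <- sqrt(2 * lam / 500)
  expect_lt(abs(rv$mcol - 2 * lam), 3 * se)
})

test_that("year-by-year trajectory matches a spreadsheet-style recursion", {
  # 2 patches, v_r = 0: the only randomness is the Poisson migrant draw,
  # replayed here with the same seed and draw order.
  land <- two_patch_landscape(K1 = 102, K2 = 51, d = 150)
  demo <- demography_params(r_d = 0.3, v_r = 0)
  mig <- migration_params(alpha = 0.01, beta = 0.05)
  cfg <- sim_config(tmax = 20, trials = 1, seed = 31)
  tr <- run_trial(land, demo, mig, cfg, trial_seed = 31)

  k <- c(102, 51)
  kern <- exp(-0.01 * patch_distances(land)); diag(kern) <- 0
  set.seed(31)
  n <- k
  expected <- matrix(0, 21, 2); expected[1, ] <- n
  for (t in 1:20) {
    n <- n * exp(0.3 * (1 - n / k))
    n <- pmin(n, k)
    n <- ifelse(n < 1, 0, n)
    n <- n + rpois(2, 0.05 * drop(kern %*% n))
    expected[t + 1, ] <- n
  }
  expect_equal(tr$N, expected)
})

test_that("response_variables rejects an out-of-range year", {
  land <- single_patch_landscape()
  sim <- run_simulation(land, config = sim_config(tmax = 10, trials = 2,
                                                  seed = 1))
  expect_error(response_variables(sim, t = 11), "tmax")
})

test_that("tidy and glance return well-formed tables", {
  land <- two_patch_landscape()
  sim <- run_simulation(land, config = sim_config(tmax = 30, trials = 10,
                                                  seed = 3))
  td <- tidy(sim)
  expect_equal(nrow(td), 31 * 2)
  expect_named(td, c("year", "id", "mean_N", "var_N", "occupancy"))
  expect_true(all(td$occupancy >= 0 & td$occupancy <= 1))
  gl <- glance(sim)
  expect_equal(gl$trials, 10L)
  expect_lte(gl$te, 30)
})
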