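test_that("single-state constant-speed rupture forces match the analytic ramp CDF", {
  cfg <- constant_speed_config(1600, 0.1, replicates = 500, seed = 3)
  sim <- simulate_constant_speed(slip_model(), cfg)
  expect_false(any(sim$censored))
  expect_true(all(sim$pathway == "P0"))
  oracle <- bell_ramp_cdf(cfg, 0.1, 0.5)
  D <- max(abs(stats::ecdf(sim$rupture_force)(oracle$force) - oracle$cdf))
  expect_lt(D, 1.628 / sqrt(500))  # KS critical value at alpha = 0.01
})

test_that("median rupture force grows with pulling speed and tracks the Bell-Evans prediction", {
  meds <- preds <- numeric(0)
  for (v in c(800, 1600, 3200, 6400)) {
    cfg <- constant_speed_config(v, 0.1, replicates = 500, seed = 11)
    sim <- simulate_constant_speed(slip_model(), cfg)
    meds <- c(meds, stats::median(sim$rupture_force))
    preds <- c(preds, be_force(be_ref, stats::median(sim$loading_rate)))
  }
  expect_true(all(diff(meds) > 0))
  expect_true(all(abs(meds - preds) / preds < 0.10))
})

test_that("clamp lifetimes of a single barrier are exponential with mean 1/k(F)", {
  cfg <- force_clamp_config(20, replicates = 1000, seed = 7)
  sim <- simulate_force_clamp(slip_model(), cfg)
  k <- bell_rate(be_ref, 20)
  mu <- 1 / k
  life <- sim$records$lifetime
  expect_equal(mu, 0.881, tolerance = 1e-3)
  se <- stats::sd(life) / sqrt(length(life))
  expect_lt(abs(mean(life) - mu), 3 * se)
  # exponential shape (KS at alpha = 0.01)
  ks <- suppressWarnings(stats::ks.test(life, stats::pexp, rate = k))
  expect_lt(unname(ks$statistic), 1.628 / sqrt(1000))
  # F = 0 limit: mean ~ 1/k0
  cfg0 <- force_clamp_config(1e-9, replicates = 800, seed = 9, max_time = 200)
  sim0 <- simulate_force_clamp(slip_model(), cfg0)
  expect_lt(abs(mean(sim0$records$lifetime) - 10) / 10, 0.15)
})

test_that("state-machine legality: pathways only from their states", {
  # all transition rates negligible -> every rupture is P0
  cfg <- constant_speed_config(1600, replicates = 200, seed = 5)
  sim <- simulate_constant_speed(slip_model(), cfg)
  expect_true(all(sim$pathway == "P0"))
  expect_true(all(sim$n_transitions == 0))
  # a three-state model with mechanically strong I2: P2 > P1 > P0 medians
  m <- threestate_fixture()
  med <- sapply(1:10, function(s) {
    sim <- simulate_constant_speed(
      m, constant_speed_config(3200, replicates = 300, seed = 100 + s))
    tapply(sim$rupture_force, sim$pathway, stats::median)
  })
  expect_true(all(med["P2", ] > med["P1", ], na.rm = TRUE))
  expect_true(all(med["P1", ] > med["P0", ], na.rm = TRUE))
})

test_that("no ruptures when all rates vanish: replicates are censored", {
  dead <- single_state_model(be_params(1e-300, 1e-6))
  dead$rupture$P0 <- be_params(1e-300, 1e-6)
  cfg <- constant_speed_config(1600, replicates = 20, seed = 2)
  sim <- simulate_constant_speed(dead, cfg)
  expect_true(all(sim$censored))
  expect_true(all(is.na(sim$rupture_force)))
})

test_that("simulations are bitwise reproducible under a fixed seed", {
  cfg <- constant_speed_config(1600, replicates = 50, seed = 42)
  a <- simulate_constant_speed(default_state_model(), cfg)
  b <- simulate_constant_speed(default_state_model(), cfg)
  expect_identical(a, b)
  fcfg <- force_clamp_config(c(30, 60), replicates = 50, seed = 42)
  x <- suppressWarnings(simulate_force_clamp(default_state_model(), fcfg))
  y <- suppressWarnings(simulate_force_clamp(default_state_model(), fcfg))
  expect_identical(x$records, y$records)
})

test_that("reversible catch-bond model shows an interior lifetime maximum", {
  cfg <- force_clamp_config(seq(10, 110, by = 20), replicates = 200,
                            seed = 13)
  sim <- suppressWarnings(simulate_force_clamp(default_state_model(), cfg))
  ml <- sim$summary$mean_lifetime
  peak <- which.max(ml)
  expect_gt(peak, 1)
  expect_lt(peak, length(ml))
  expect_gt(max(ml), 2 * ml[1])
  expect_gt(max(ml), 2 * ml[length(ml)])
})

test_that("analytic pathway lifetime is 1/k(F) and decreases with force", {
  expect_equal(analytic_pathway_lifetime(be_ref, 0), 1 / 0.1)
  expect_equal(analytic_pathway_lifetime(be_ref, 20), 0.881,
               tolerance = 1e-3)
  f <- seq(0, 100, 5)
  expect_true(all(diff(analytic_pathway_lifetime(be_ref, f)) < 0))
})
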