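synthetic_hist <- function(k0 = 0.5, dx = 0.3, dG = 8, nu = 0.5,
                           noise = 0, seed = 1,
                           forces = seq(15, 95, by = 10)) {
  set.seed(seed)
  k <- dhs_rate(forces, k0, dx, dG, nu, ctx0)
  k <- k * exp(stats::rnorm(length(forces), 0, noise))
  structure(
    data.frame(bin_lo = forces - 5, bin_hi = forces + 5, width = 10,
               count = 50, height = 1 / (10 * length(forces)),
               force_median = forces, loading_rate_median = 1e4,
               k_off = k),
    class = c("off_rate_histogram", "data.frame"))
}

test_that("histogram transform matches hand-evaluated cases", {
  # single bin: k = 2 r / dF
  one <- off_rate_histogram(data.frame(rupture_force = rep(25, 50),
                                       loading_rate = 1000), 10)
  expect_equal(one$k_off, 200)
  # two equal bins with equal loading rate: ratio 1/3
  two <- off_rate_histogram(
    data.frame(rupture_force = c(rep(25, 50), rep(35, 50)),
               loading_rate = 1000), 10)
  expect_equal(two$k_off[1] / two$k_off[2], 1 / 3)
  # normalisation: sum h_k width_k = 1, even after sparse-bin merging
  set.seed(3)
  rec <- data.frame(rupture_force = stats::rgamma(400, 8, 0.2),
                    loading_rate = stats::runif(400, 5e3, 2e4))
  h <- off_rate_histogram(rec, 10)
  expect_equal(sum(h$height * h$width), 1, tolerance = 1e-12)
  expect_true(all(h$count >= 3))
  expect_true(all(h$k_off > 0))
  expect_error(off_rate_histogram(data.frame(rupture_force = numeric(),
                                             loading_rate = numeric())),
               "at least one")
})

test_that("histogram transform on Bell-simulated data recovers the slope beta*dx", {
  rec <- generate_rupture_dataset(slip_model(), speeds = 1600,
                                  n_per_speed = 5000, seed = 41)
  h <- off_rate_histogram(rec, 10)
  fit <- stats::lm(log(k_off) ~ force_median, data = h,
                   weights = h$count)
  slope <- stats::coef(fit)[[2]]
  expect_lt(abs(slope - ctx0$beta * 0.5) / (ctx0$beta * 0.5), 0.10)
})

test_that("DHS fit recovers generating parameters within 25% under 5% noise", {
  errs <- sapply(1:10, function(s) {
    h <- synthetic_hist(noise = 0.05, seed = s)
    fit <- fit_dhs(h, nu = 0.5, n_starts = 300, n_seed_runs = 2,
                   optimize_top = 30, seed = s)
    abs(c(fit$k0, fit$delta_x, fit$deltaG) / c(0.5, 0.3, 8) - 1)
  })
  expect_true(all(errs <= 0.25))
})

test_that("DHS fit refuses underdetermined input and reduces to Bell at nu = 1", {
  small <- synthetic_hist(forces = c(20, 40))
  expect_error(fit_dhs(small), "refused")
  # nu = 1: exact Bell for all forces, machine precision
  f <- seq(0, 200, 5)
  expect_equal(dhs_rate(f, 0.2, 0.4, 7, 1, ctx0),
               bell_rate(be_params(0.2, 0.4), f, ctx0))
  # fitted on Bell data at nu = 1, deltaG reported unidentifiable
  hb <- synthetic_hist(k0 = 0.2, dx = 0.4, dG = 10, nu = 1, noise = 0)
  fit1 <- fit_dhs(hb, nu = 1)
  expect_true(is.na(fit1$deltaG))
  expect_equal(fit1$k0, 0.2, tolerance = 1e-6)
  expect_equal(fit1$delta_x, 0.4, tolerance = 1e-6)
  # physical-region guard: rates undefined where nu*beta*F*dx >= dG
  expect_true(is.na(dhs_rate(1000, 0.5, 0.3, 8, 0.5, ctx0)))
})

test_that("DHS force vs loading rate behaves per the closed form", {
  p <- list(k0 = 0.5, delta_x = 0.3, deltaG = 8, nu = 0.5)
  # bracket-zero point: the critical force dG/(nu beta dx) where the
  # barrier disappears
  l0 <- p$k0 * exp(p$deltaG) / (ctx0$beta * p$delta_x)
  expect_equal(dhs_force_vs_loading_rate(p, l0),
               p$deltaG / (p$nu * ctx0$beta * p$delta_x), tolerance = 1e-9)
  # frozen spot value from independent hand evaluation of the formula at
  # l = 1e4: inner = ln(0.5 e^8 / (0.2430 * 0.3 * 1e4)) / 8,
  # F = 8/(0.5 * 0.2430 * 0.3) * (1 - sqrt(inner))
  inner <- log(p$k0 * exp(8) / (ctx0$beta * 0.3 * 1e4)) / 8
  f_hand <- 8 / (0.5 * ctx0$beta * 0.3) * (1 - sqrt(inner))
  expect_equal(dhs_force_vs_loading_rate(p, 1e4), f_hand,
               tolerance = 1e-12)
  expect_equal(f_hand, 153.891, tolerance = 1e-4)
  # monotone increasing over the physical range
  l <- 10^seq(2, log10(l0 * 0.99), length.out = 40)
  f <- dhs_force_vs_loading_rate(p, l)
  ok <- !is.na(f)
  expect_gt(sum(ok), 20)
  expect_true(all(diff(f[ok]) > 0))
  # cross-check against the mode of the rupture-force distribution,
  # found numerically from the DHS hazard, in the moderate-force regime
  # where the leading-order formula applies
  l1 <- 1e3
  fg <- seq(0.01, 219, by = 0.002)
  kk <- dhs_rate(fg, p$k0, p$delta_x, p$deltaG, p$nu, ctx0)
  dens <- (kk / l1) * exp(-cumsum(kk / l1 * 0.002))
  mode_num <- fg[which.max(dens)]
  expect_equal(dhs_force_vs_loading_rate(p, l1), mode_num,
               tolerance = 0.10)
})

test_that("Bell-Evans fitting recovers parameters from exact and simulated data", {
  # two exact points from the closed form: exact recovery
  r <- c(1e3, 1e5)
  f <- be_force(be_ref, r)
  rec <- data.frame(rupture_force = rep(f, each = 3),
                    loading_rate = rep(r, each = 3),
                    pulling_speed = rep(c(800, 6400), each = 3))
  fit <- fit_be(rec)
  expect_equal(fit$delta_x, 0.5, tolerance = 1e-9)
  expect_equal(fit$k0, 0.1, tolerance = 1e-9)
  # closed-form spot value
  expect_equal(be_force(be_ref, 1000), 58.4, tolerance = 1e-2)
  # end-to-end: 4-speed Monte Carlo data recovers delta_x within 15%
  sim <- generate_rupture_dataset(slip_model(), n_per_speed = 500,
                                  seed = 9)
  fit2 <- fit_be(sim)
  expect_lt(abs(fit2$delta_x - 0.5) / 0.5, 0.15)
  expect_error(fit_be(sim[sim$pulling_speed == 800, ]), "refused")
})

test_that("k_of_F dispatches by model and locates crossings", {
  expect_equal(k_of_F(be_ref, 0), 0.1)
  expect_equal(k_of_F(be_ref, 20), 1.135, tolerance = 1e-3)
  dp <- structure(list(k0 = 0.3, delta_x = 0.4, deltaG = 9, nu = 0.5),
                  class = "dhs_params")
  expect_equal(k_of_F(dp, 0), 0.3, tolerance = 1e-12)
  # a weak-but-soft barrier crosses a strong-but-stiff one exactly once
  a <- be_params(0.02, 0.9)
  b <- be_params(0.5, 0.2)
  fx <- k_crossing(a, b)
  expect_gt(fx, 0)
  expect_equal(k_of_F(a, fx), k_of_F(b, fx), tolerance = 1e-6)
  grid <- seq(0.1, 1000, length.out = 5000)
  sgn <- sign(log(k_of_F(a, grid)) - log(k_of_F(b, grid)))
  expect_equal(sum(diff(sgn) != 0), 1)
})

test_that("full pipeline recovery: generate, classify, fit per-pathway Bell-Evans", {
  rec <- generate_rupture_dataset(threestate_fixture(), n_per_speed = 400,
                                  seed = 77)
  rec <- rec[!rec$censored, ]
  g <- fit_pathway_gmm(rec$rupture_force, seed = 1)
  g <- reclassify_fourth_component(g)
  asn <- pathway_assignments(g)
  rec$pathway <- asn$pathway
  expect_gte(mean(as.character(rec$pathway) == rec$pathway_truth), 0.95)
  fits <- lapply(c("P0", "P1", "P2"), function(p)
    fit_be(rec[rec$pathway == p, ]))
  dx_true <- c(1.2, 0.3, 0.1)
  dx_fit <- vapply(fits, `[[`, numeric(1), "delta_x")
  expect_true(all(abs(dx_fit - dx_true) / dx_true < 0.20))
})
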