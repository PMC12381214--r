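strong_model <- function() single_state_model(be_params(0.01, 0.12))

test_that("zero-noise curves are exactly recoverable by the pipeline", {
  gen <- generate_constant_speed_curve(
    strong_model(), handle_model(), noise_model(0, 0, 0), 1600, 0.1,
    seed = 42)
  truth <- gen$truth
  expect_equal(nrow(truth$events), 5)  # 4 fingerprint peaks + rupture
  expect_true(all(diff(truth$events$extension) > 0))
  expect_equal(sum(truth$events$kind == "rupture"), 1)
  cv <- baseline_subtract(gen$curve)
  pk <- detect_peaks(cv)
  expect_equal(nrow(pk), 5)
  expect_equal(pk$peak_force, truth$events$force, tolerance = 1e-9)
  expect_equal(pk$extension, truth$events$extension, tolerance = 1e-9)
  fp <- identify_fingerprint(cv, pk)
  expect_identical(fp$classification, "criterion2")
  # fingerprint increments sum to the configured 32 nm exactly
  expect_equal(fp$fp_increment_sum, 32, tolerance = 1e-6)
  expect_equal(fp$rupture_contour, 190, tolerance = 1e-6)
  rec <- extract_rupture(cv, fp)
  expect_equal(rec$rupture_force_pN, truth$rupture_force, tolerance = 0.1)
})

test_that("generation is a pure function of (config, seed)", {
  a <- generate_constant_speed_curve(strong_model(), seed = 7)
  b <- generate_constant_speed_curve(strong_model(), seed = 7)
  expect_identical(a, b)
  c2 <- generate_constant_speed_curve(strong_model(), seed = 8)
  expect_false(identical(a$curve$force, c2$curve$force))
})

test_that("nonspecific adhesion artifacts always fail the prefilter", {
  curves <- lapply(1:10, function(s) generate_constant_speed_curve(
    strong_model(), noise = noise_model(nonspecific_adhesion_rate = 1),
    seed = s)$curve)
  curves <- lapply(curves, baseline_subtract)
  pf <- prefilter(curves)
  expect_length(pf$kept, 0)
  expect_true(all(pf$rejected$reason == "early_peak"))
})

test_that("clean fingerprint curves almost always pass the prefilter at default noise", {
  curves <- lapply(1:40, function(s) generate_constant_speed_curve(
    strong_model(), noise = noise_model(nonspecific_adhesion_rate = 0),
    seed = 1000 + s)$curve)
  curves <- lapply(curves, baseline_subtract)
  pf <- prefilter(curves)
  expect_gte(length(pf$kept), 39)
})

test_that("clamp traces carry truth lifetimes and respect the detection floor", {
  dm <- default_state_model()
  # the default model's fast forward edges trip the (intended)
  # discretisation warning at this setpoint
  tr <- suppressWarnings(generate_force_clamp_trace(dm, 40, seed = 5))
  expect_s3_class(tr$trace, "clamp_trace")
  expect_true(all(diff(tr$trace$time) > 0))
  est <- estimate_setpoint_and_lifetime(tr$trace)
  expect_equal(est$lifetime_s, tr$truth$lifetime, tolerance = 2e-3)
  expect_lt(abs(est$setpoint_estimate_pN - 40), 5)
  # jitter-free plateau sits exactly at the setpoint
  quiet <- suppressWarnings(generate_force_clamp_trace(
    dm, 40, noise_model(setpoint_jitter_sd = 0), seed = 5))
  seg <- quiet$trace$force[quiet$trace$force > 39.9]
  expect_true(all(abs(seg - 40) < 1e-9))
  # short-lived bonds are flagged below the 15 ms floor
  fast <- single_state_model(be_params(50, 0.5))
  trf <- suppressWarnings(generate_force_clamp_trace(fast, 40, seed = 3))
  expect_lt(trf$truth$lifetime, 0.015)
  expect_true(trf$truth$below_detection_floor)
})

test_that("clamp mean truth lifetime matches the Bell oracle over seeds", {
  k <- bell_rate(be_ref, 30)
  lives <- vapply(1:300, function(s) generate_force_clamp_trace(
    slip_model(), 30, seed = s)$truth$lifetime, numeric(1))
  mu <- 1 / k
  expect_lt(abs(mean(lives) - mu), 3 * stats::sd(lives) / sqrt(length(lives)))
})

test_that("rupture datasets have the advertised shape and kinetics", {
  expect_equal(nrow(generate_rupture_dataset(slip_model(),
                                             n_per_speed = 0)), 0)
  rec <- generate_rupture_dataset(slip_model(), n_per_speed = 300, seed = 9)
  expect_true(all(rec$pathway_truth == "P0"))
  med <- tapply(rec$rupture_force, rec$pulling_speed, stats::median)
  expect_true(all(diff(med[order(as.numeric(names(med)))]) > 0))
  # three well-separated pathways give a trimodal dataset
  rec3 <- generate_rupture_dataset(threestate_fixture(), speeds = 3200,
                                   n_per_speed = 600, seed = 17)
  expect_setequal(unique(rec3$pathway_truth[!rec3$censored]),
                  c("P0", "P1", "P2"))
  meds <- tapply(rec3$rupture_force, rec3$pathway_truth, stats::median)
  expect_true(meds["P0"] < meds["P1"] && meds["P1"] < meds["P2"])
})

test_that("Hill titration tables follow the binding isotherm", {
  tt <- generate_hill_titration(45, noise_sd = 0, replicates = 1)
  # default design: 7 five-fold dilutions from 100 x kd
  expect_equal(sort(unique(tt$concentration_nM)),
               100 * 45 / 5^(6:0))
  sig_at <- function(c0) tt$signal[abs(tt$concentration_nM - c0) < 1e-9]
  expect_equal(sig_at(100 * 45), 100 / 101, tolerance = 1e-12)
  tt_kd <- generate_hill_titration(45, concentrations = 45, noise_sd = 0,
                                   replicates = 1)
  expect_equal(tt_kd$signal, 0.5)
  expect_error(generate_hill_titration(-1), "kd")
})
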