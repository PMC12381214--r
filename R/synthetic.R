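# Seed derivation for reproducible, order-independent substreams: each
# curve/trace gets its own seed from (master seed, index), kept inside
# the 32-bit signed range R requires.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 30269) %%
               2147483647)
}

#' Tether and fingerprint geometry of the synthetic construct
#'
#' Defaults encode the experimental construct: two elastin-like
#' polypeptide handles of ~65 nm each (tether contour 130 nm), a folded
#' protein offset bringing the pre-unfolding contour to 158 nm, and two
#' fingerprint domains whose four unfolding events (50-80 pN) add
#' 4 x 8 = 32 nm, for a final contour of ~190 nm at rupture.
#' Intermediate unfolding events add a median ~15 nm.
#'
#' @param tether_contour_length Contour of both handles combined, nm.
#' @param folded_offset Folded-protein contribution to the initial
#'   contour, nm (one free parameter; the decomposition of the final
#'   ~190 nm is not knowable from the curves).
#' @param fingerprint_domains Number of fingerprint domains.
#' @param events_per_domain Unfolding events per domain.
#' @param increment_per_event Contour increment per fingerprint event, nm.
#' @param force_range Fingerprint unfolding force window, pN.
#' @param intermediate_increment_median Median contour increment of an
#'   intermediate unfolding event, nm.
#' @param intermediate_sdlog Log-scale spread of intermediate increments.
#' @param intermediate_prob Probability that a P1/P2 rupture is preceded
#'   by an intermediate unfolding event.
#' @param frc [frc_params()] used to render the tether elasticity.
#' @return An object of class `handle_model`.
#' @export
handle_model <- function(tether_contour_length = 130, folded_offset = 28,
                         fingerprint_domains = 2, events_per_domain = 2,
                         increment_per_event = 8, force_range = c(50, 80),
                         intermediate_increment_median = 15,
                         intermediate_sdlog = 0.3,
                         intermediate_prob = 0.5,
                         frc = frc_params()) {
  stopifnot(tether_contour_length > 0, folded_offset >= 0,
            fingerprint_domains >= 0, events_per_domain >= 1,
            increment_per_event > 0, length(force_range) == 2,
            force_range[1] < force_range[2])
  structure(
    list(tether_contour_length = tether_contour_length,
         folded_offset = folded_offset,
         fingerprint_domains = fingerprint_domains,
         events_per_domain = events_per_domain,
         increment_per_event = increment_per_event,
         force_range = force_range,
         intermediate_increment_median = intermediate_increment_median,
         intermediate_sdlog = intermediate_sdlog,
         intermediate_prob = intermediate_prob,
         frc = frc),
    class = "handle_model"
  )
}

#' Measurement noise and artifact model for synthetic curves
#'
#' @param force_noise_sd Gaussian force noise, pN (default 2).
#' @param baseline_drift Linear baseline tilt, pN/nm (default 0).
#' @param nonspecific_adhesion_rate Probability per curve of injecting a
#'   non-specific adhesion artifact (spurious peaks within the first
#'   100 nm of extension). Default 0.05.
#' @param setpoint_jitter_sd Force jitter around a clamp setpoint, pN
#'   (default 1.5; the instrument holds the setpoint to within ~5 pN).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(force_noise_sd = 2, baseline_drift = 0,
                        nonspecific_adhesion_rate = 0.05,
                        setpoint_jitter_sd = 1.5) {
  stopifnot(force_noise_sd >= 0, nonspecific_adhesion_rate >= 0,
            nonspecific_adhesion_rate <= 1, setpoint_jitter_sd >= 0)
  structure(
    list(force_noise_sd = force_noise_sd, baseline_drift = baseline_drift,
         nonspecific_adhesion_rate = nonspecific_adhesion_rate,
         setpoint_jitter_sd = setpoint_jitter_sd),
    class = "noise_model"
  )
}

#' Generate one synthetic constant-speed force-extension curve
#'
#' Renders a retraction trace of the tethered complex: FRC elasticity of
#' the handles, fingerprint unfolding events at threshold forces drawn in
#' the configured window (each adding its contour increment and dropping
#' the force), optionally one intermediate unfolding event, and a
#' terminal rupture whose force and pathway are drawn from the
#' multi-state kinetic Monte Carlo driver on the fully extended tether.
#' The returned ground truth logs every event as rendered, so a
#' zero-noise curve is exactly recoverable by the analysis pipeline.
#'
#' @param model A [state_model()] supplying rupture kinetics.
#' @param handle A [handle_model()].
#' @param noise A [noise_model()].
#' @param pulling_speed Retraction speed, nm/s.
#' @param spring_constant Cantilever spring constant, N/m.
#' @param seed Seed for this curve.
#' @param grid_step Extension sampling step, nm (default 0.2).
#' @param curve_id,experiment_id Identifiers carried in the curve.
#' @return A list with `curve` (a [force_curve()]) and `truth` (class
#'   `ground_truth`: event data.frame plus `pathway`, `rupture_force`,
#'   `final_contour`, `has_adhesion_artifact`).
#' @export
generate_constant_speed_curve <- function(model, handle = handle_model(),
                                          noise = noise_model(),
                                          pulling_speed = 1600,
                                          spring_constant = 0.1,
                                          seed = 1, grid_step = 0.2,
                                          curve_id = "curve_1",
                                          experiment_id = "exp_1") {
  stopifnot(inherits(model, "state_model"), inherits(handle, "handle_model"),
            inherits(noise, "noise_model"))
  if (pulling_speed <= 0) stop("pulling_speed must be > 0 nm/s")
  if (spring_constant <= 0) stop("spring_constant must be > 0 N/m")
  set.seed(seed)
  frc <- handle$frc
  ctx <- thermal_context(frc$temperature)

  n_fp <- handle$fingerprint_domains * handle$events_per_domain
  L0 <- handle$tether_contour_length + handle$folded_offset
  L_final <- L0 + n_fp * handle$increment_per_event

  # terminal rupture (force, pathway) from the kinetic driver on the
  # fully extended tether
  cs <- constant_speed_config(pulling_speed, spring_constant,
                              tether = wlc_params(L_final, 0.4),
                              replicates = 1,
                              seed = derive_seed(seed, 1), ctx = ctx)
  draw <- simulate_constant_speed(model, cs)
  f_rup <- draw$rupture_force[1]
  pathway <- as.character(draw$pathway[1])
  if (is.na(f_rup)) {  # censored draw: pin to a high rupture force
    f_rup <- 2 * handle$force_range[2]
    pathway <- NA_character_
  }

  thr_fp <- sort(stats::runif(n_fp, handle$force_range[1],
                              handle$force_range[2]))
  events <- data.frame(kind = rep("fingerprint", n_fp),
                       threshold = thr_fp,
                       increment = rep(handle$increment_per_event, n_fp))
  if (pathway %in% c("P1", "P2") &&
      stats::runif(1) < handle$intermediate_prob) {
    thr_int <- f_rup * stats::runif(1, 0.85, 0.95)
    inc_int <- stats::rlnorm(1, log(handle$intermediate_increment_median),
                             handle$intermediate_sdlog)
    events <- rbind(events, data.frame(kind = "intermediate",
                                       threshold = thr_int,
                                       increment = inc_int))
  }
  events <- events[order(events$threshold), ]

  # march the extension axis; trigger events as their thresholds are crossed
  x_max <- L_final * 0.995
  x <- seq(grid_step, x_max, by = grid_step)
  force <- numeric(length(x))
  L_c <- L0
  ev_log <- list()
  next_ev <- 1L
  rupture_i <- NA_integer_
  for (i in seq_along(x)) {
    f_i <- frc_force(min(x[i] / L_c, 0.995), frc, ctx)
    if (next_ev <= nrow(events) && f_i >= events$threshold[next_ev]) {
      # render the apex sample at the event force; the post-drop force
      # appears from the next sample on
      ev_log[[length(ev_log) + 1L]] <- data.frame(
        kind = events$kind[next_ev], extension = x[i], force = f_i,
        increment = events$increment[next_ev],
        contour_before = L_c, contour_after = L_c + events$increment[next_ev])
      L_c <- L_c + events$increment[next_ev]
      next_ev <- next_ev + 1L
      force[i] <- f_i
      next
    }
    if (f_i >= f_rup) {
      ev_log[[length(ev_log) + 1L]] <- data.frame(
        kind = "rupture", extension = x[i], force = f_i, increment = 0,
        contour_before = L_c, contour_after = L_c)
      force[i] <- f_i
      rupture_i <- i
      break
    }
    force[i] <- f_i
  }
  if (is.na(rupture_i)) rupture_i <- length(x)
  # post-rupture zero-force tail (~50 nm)
  n_tail <- ceiling(50 / grid_step)
  x_all <- c(x[seq_len(rupture_i)],
             x[rupture_i] + grid_step * seq_len(n_tail))
  f_all <- c(force[seq_len(rupture_i)], rep(0, n_tail))

  if (noise$nonspecific_adhesion_rate > 0 &&
      stats::runif(1) < noise$nonspecific_adhesion_rate) {
    # spurious adhesion: sawtooth spikes within the first 100 nm
    has_artifact <- TRUE
    for (centre in stats::runif(2, 15, 85)) {
      idx <- which(x_all > centre - 5 & x_all <= centre)
      amp <- stats::runif(1, 30, 90)
      f_all[idx] <- f_all[idx] + amp * seq_along(idx) / length(idx)
    }
  } else {
    has_artifact <- FALSE
  }
  if (noise$force_noise_sd > 0)
    f_all <- f_all + stats::rnorm(length(f_all), 0, noise$force_noise_sd)
  if (noise$baseline_drift != 0)
    f_all <- f_all + noise$baseline_drift * x_all

  truth_events <- if (length(ev_log)) do.call(rbind, ev_log) else
    data.frame(kind = character(), extension = numeric(), force = numeric(),
               increment = numeric(), contour_before = numeric(),
               contour_after = numeric())
  truth <- structure(
    list(events = truth_events, pathway = pathway,
         rupture_force = truth_events$force[truth_events$kind == "rupture"][1],
         final_contour = L_c,
         has_adhesion_artifact = has_artifact),
    class = "ground_truth"
  )
  curve <- force_curve(x_all, f_all, pulling_speed, spring_constant,
                       curve_id, experiment_id)
  list(curve = curve, truth = truth)
}

#' Generate one synthetic force-clamp trace
#'
#' Renders a force versus time trace with head-height channel: a loading
#' ramp at the retraction speed, a clamp plateau at the setpoint with
#' feedback jitter, rupture after a lifetime drawn from the kinetic
#' Monte Carlo clamp driver, and a post-rupture retraction. Artifacts
#' (discrete head-height steps, short/long retraction) can be injected
#' to exercise the trace filter. Truth lifetimes below the 15 ms
#' detection floor are flagged.
#'
#' @param model A [state_model()].
#' @param setpoint Clamp force, pN (> 0).
#' @param noise A [noise_model()].
#' @param seed Seed for this trace.
#' @param sampling_rate Samples per second (default 2000).
#' @param retraction_speed Loading/retraction speed, nm/s (default 4000).
#' @param retraction_distance Head travel from clamp to free baseline, nm
#'   (default 120).
#' @param head_steps Number of discrete head-height steps to inject
#'   during the clamp (artifact; default 0).
#' @param dt,max_time Clamp Monte Carlo interval and cap, s.
#' @return A list with `trace` (class `clamp_trace`: `time`, `force`,
#'   `head_height`, `target_setpoint`) and `truth` (list: `lifetime`,
#'   `pathway`, `below_detection_floor`, `censored`).
#' @export
generate_force_clamp_trace <- function(model, setpoint,
                                       noise = noise_model(), seed = 1,
                                       sampling_rate = 2000,
                                       retraction_speed = 4000,
                                       retraction_distance = 120,
                                       head_steps = 0,
                                       dt = 1e-4, max_time = 10) {
  stopifnot(inherits(model, "state_model"))
  if (setpoint <= 0) stop("setpoint must be > 0 pN")
  set.seed(seed)
  ctx <- thermal_context()
  cfg <- force_clamp_config(setpoint, dt = dt, max_time = max_time,
                            replicates = 1, seed = derive_seed(seed, 1),
                            ctx = ctx)
  sim <- simulate_force_clamp(model, cfg)
  lifetime <- sim$records$lifetime[1]
  pathway <- as.character(sim$records$pathway[1])
  censored <- sim$records$censored[1]

  dt_s <- 1 / sampling_rate
  # loading ramp: effective stiffness ~5 pN/nm at the retraction speed
  ramp_rate <- 5 * retraction_speed
  t_ramp <- setpoint / ramp_rate
  n_ramp <- max(2L, ceiling(t_ramp / dt_s))
  n_clamp <- max(1L, round(lifetime / dt_s))
  n_retract <- max(2L, ceiling((retraction_distance / retraction_speed) /
                                 dt_s))
  n_tail <- ceiling(0.05 / dt_s)

  f_ramp <- seq(0, setpoint, length.out = n_ramp)
  f_clamp <- rep(setpoint, n_clamp)
  if (noise$setpoint_jitter_sd > 0)
    f_clamp <- f_clamp + stats::rnorm(n_clamp, 0, noise$setpoint_jitter_sd)
  f_post <- rep(0, n_retract + n_tail)

  h_clamp0 <- 40 + setpoint / 5
  h_ramp <- seq(0, h_clamp0, length.out = n_ramp)
  h_clamp <- rep(h_clamp0, n_clamp)
  if (head_steps > 0) {
    at <- sort(sample.int(n_clamp, min(head_steps, n_clamp)))
    for (a in at) h_clamp[a:n_clamp] <- h_clamp[a:n_clamp] + 8
  }
  h_post <- c(seq(h_clamp[n_clamp],
                  h_clamp[n_clamp] + retraction_distance,
                  length.out = n_retract),
              rep(h_clamp[n_clamp] + retraction_distance, n_tail))

  force <- c(f_ramp, f_clamp, f_post)
  head <- c(h_ramp, h_clamp, h_post)
  tim <- seq_along(force) * dt_s
  trace <- structure(
    list(time = tim, force = force, head_height = head,
         target_setpoint = setpoint, clamp_start = n_ramp * dt_s),
    class = "clamp_trace"
  )
  truth <- list(lifetime = lifetime, pathway = pathway,
                below_detection_floor = lifetime < 0.015,
                censored = censored)
  list(trace = trace, truth = truth)
}

#' Generate a rupture-force dataset directly from the kinetic driver
#'
#' Bypasses curve rendering: draws rupture records (force, loading rate,
#' pathway truth) from the constant-speed Monte Carlo at each pulling
#' speed. This is the fast route into mixture classification and energy
#' landscape fitting.
#'
#' @param model A [state_model()].
#' @param speeds Pulling speeds in nm/s (default the experimental ramp
#'   800, 1600, 3200, 6400).
#' @param n_per_speed Records per speed (0 gives an empty table).
#' @param seed Master seed.
#' @param spring_constant Spring constant, N/m.
#' @param tether A [wlc_params()] for the pulled construct.
#' @param experiment_id Identifier column value.
#' @param ctx A [thermal_context()].
#' @return Data.frame: `rupture_force`, `loading_rate`, `pulling_speed`,
#'   `pathway_truth`, `experiment`, `censored`.
#' @export
generate_rupture_dataset <- function(model,
                                     speeds = c(800, 1600, 3200, 6400),
                                     n_per_speed = 500, seed = 1,
                                     spring_constant = 0.1,
                                     tether = wlc_params(190, 0.4),
                                     experiment_id = "exp_1",
                                     ctx = thermal_context()) {
  stopifnot(inherits(model, "state_model"), n_per_speed >= 0)
  if (n_per_speed == 0)
    return(data.frame(rupture_force = numeric(), loading_rate = numeric(),
                      pulling_speed = numeric(), pathway_truth = character(),
                      experiment = character(), censored = logical()))
  out <- lapply(seq_along(speeds), function(i) {
    cfg <- constant_speed_config(speeds[i], spring_constant, tether,
                                 replicates = n_per_speed,
                                 seed = derive_seed(seed, i), ctx = ctx)
    sim <- simulate_constant_speed(model, cfg)
    data.frame(rupture_force = sim$rupture_force,
               loading_rate = sim$loading_rate,
               pulling_speed = speeds[i],
               pathway_truth = as.character(sim$pathway),
               experiment = experiment_id,
               censored = sim$censored)
  })
  do.call(rbind, out)
}

#' Generate a synthetic equilibrium titration table
#'
#' Signal follows the Hill binding isotherm
#' S(c) = baseline + bmax c^n / (kd^n + c^n) plus Gaussian noise. The
#' default concentration series mirrors the experimental design: seven
#' five-fold dilutions starting at 100 x kd.
#'
#' @param kd Dissociation constant, nM (> 0).
#' @param hill_n Hill coefficient (default 1).
#' @param bmax Saturating signal (default 1).
#' @param baseline Baseline signal (default 0).
#' @param concentrations Concentrations in nM; default
#'   `100 * kd / 5^(6:0)`.
#' @param noise_sd Gaussian noise standard deviation on the signal
#'   (absolute units; default 0).
#' @param replicates Measurements per concentration (default 3).
#' @param seed Seed.
#' @return Data.frame: `concentration_nM`, `replicate`, `signal`.
#' @export
generate_hill_titration <- function(kd, hill_n = 1, bmax = 1, baseline = 0,
                                    concentrations = 100 * kd / 5^(6:0),
                                    noise_sd = 0, replicates = 3, seed = 1) {
  if (kd <= 0) stop("kd must be > 0")
  set.seed(seed)
  grid <- expand.grid(concentration_nM = concentrations,
                      replicate = seq_len(replicates))
  mu <- baseline + bmax * grid$concentration_nM^hill_n /
    (kd^hill_n + grid$concentration_nM^hill_n)
  grid$signal <- mu + if (noise_sd > 0)
    stats::rnorm(nrow(grid), 0, noise_sd) else 0
  grid[order(grid$concentration_nM, grid$replicate), ]
}
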