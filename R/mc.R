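#' Configuration for constant-speed pulling simulations
#'
#' @param pulling_speed Retraction speed V in nm/s (> 0).
#' @param spring_constant Cantilever spring constant in N/m (> 0);
#'   1 N/m corresponds to 1000 pN/nm.
#' @param tether A [wlc_params()] describing the stretched construct
#'   (default contour 190 nm, persistence 0.4 nm, the fully unfolded
#'   fingerprint-certified tether).
#' @param grid_step Extension grid resolution in nm (default 0.1).
#' @param replicates Number of replicates (default 500).
#' @param seed Master seed for the replicate substreams.
#' @param ctx A [thermal_context()].
#' @return An object of class `constant_speed_config`.
#' @export
constant_speed_config <- function(pulling_speed, spring_constant = 0.1,
                                  tether = wlc_params(190, 0.4),
                                  grid_step = 0.1, replicates = 500,
                                  seed = 1, ctx = thermal_context()) {
  if (pulling_speed <= 0) stop("pulling_speed must be > 0 nm/s")
  if (spring_constant <= 0) stop("spring_constant must be > 0 N/m")
  if (replicates < 1) stop("replicates must be >= 1")
  stopifnot(inherits(tether, "wlc_params"))
  structure(
    list(pulling_speed = pulling_speed, spring_constant = spring_constant,
         tether = tether, grid_step = grid_step, replicates = replicates,
         seed = seed, ctx = ctx),
    class = "constant_speed_config"
  )
}

# Force/time grid for a constant-speed protocol: WLC force across an evenly
# spaced molecular extension axis, head height H = X + F/k (spring in
# pN/nm), step times dt = dH / V. Also returns the local loading rate
# dF/dt set by the WLC + cantilever series compliance.
constant_speed_grid <- function(cfg) {
  L <- cfg$tether$L
  x <- seq(cfg$grid_step, L * 0.999, by = cfg$grid_step)
  f <- wlc_force(x, cfg$tether, cfg$ctx)
  k_pn_nm <- cfg$spring_constant * 1000
  h <- x + f / k_pn_nm
  dh <- diff(c(0, h))
  dt <- dh / cfg$pulling_speed
  df <- diff(c(0, f))
  list(extension = x, force = f, head_height = h, dt = dt,
       loading_rate = df / dt)
}

#' Simulate constant-speed pulling of a multi-state bond
#'
#' Kinetic Monte Carlo along the pulling grid: at each extension step the
#' off-rate of every edge leaving the current state is converted into a
#' per-interval event probability P = 1 - exp(-k dt); eligible events are
#' shuffled and the first whose independent uniform draw succeeds is
#' executed. Rupture records the current force and the pathway of the
#' rupture edge; transitions move the replicate to the next interval in
#' the new state. Replicates whose tether reaches full extension without
#' rupturing are flagged censored.
#'
#' @param model A [state_model()].
#' @param cfg A [constant_speed_config()].
#' @return A data.frame with one row per replicate: `replicate`,
#'   `rupture_force` (pN), `loading_rate` (pN/s, local rate at rupture),
#'   `time` (s), `pathway` (factor P0/P1/P2, NA if censored),
#'   `n_transitions`, `censored`.
#' @export
simulate_constant_speed <- function(model, cfg) {
  stopifnot(inherits(model, "state_model"),
            inherits(cfg, "constant_speed_config"))
  grid <- constant_speed_grid(cfg)
  ed <- model_edges(model)
  res <- mc_constant_speed_cpp(grid$force, grid$dt, ed$from, ed$to,
                               ed$pathway, ed$k0, ed$dx, cfg$ctx$beta,
                               cfg$replicates, cfg$seed)
  lr <- rep(NA_real_, cfg$replicates)
  ok <- !is.na(res$step)
  lr[ok] <- grid$loading_rate[res$step[ok]]
  data.frame(
    replicate = seq_len(cfg$replicates),
    rupture_force = res$rupture_force,
    loading_rate = lr,
    time = res$time,
    pathway = factor(paste0("P", res$pathway), levels = c("P0", "P1", "P2")),
    n_transitions = res$n_transitions,
    censored = is.na(res$step)
  )
}

#' Configuration for force-clamp simulations
#'
#' @param setpoints Clamp forces in pN (all > 0).
#' @param dt Time interval in s (default 1e-4).
#' @param max_time Maximum clamp time in s before censoring (default 10,
#'   the experimental cap).
#' @param replicates Replicates per setpoint (default 100).
#' @param seed Master seed.
#' @param ctx A [thermal_context()].
#' @return An object of class `force_clamp_config`.
#' @export
force_clamp_config <- function(setpoints, dt = 1e-4, max_time = 10,
                               replicates = 100, seed = 1,
                               ctx = thermal_context()) {
  if (any(setpoints <= 0)) stop("setpoints must be > 0 pN")
  if (dt <= 0) stop("dt must be > 0 s")
  structure(
    list(setpoints = setpoints, dt = dt, max_time = max_time,
         replicates = replicates, seed = seed, ctx = ctx),
    class = "force_clamp_config"
  )
}

#' Simulate force-clamp lifetimes of a multi-state bond
#'
#' Holds the force constant at each setpoint and runs the same
#' shuffle-and-execute kinetic Monte Carlo with a fixed interval `dt`.
#' Lifetimes are the elapsed time at rupture; runs reaching `max_time`
#' are censored at that value. A warning is raised if `dt * max(k)` for
#' any eligible edge exceeds 0.1 (per-interval discretisation error).
#'
#' @param model A [state_model()].
#' @param cfg A [force_clamp_config()].
#' @return A list with `records` (data.frame: setpoint, replicate,
#'   lifetime, pathway, n_transitions, censored) and `summary`
#'   (data.frame per setpoint: mean/median lifetime and the relative
#'   frequency of each unbinding pathway, computed as the number of
#'   ruptures through that pathway over the number of simulations).
#' @export
simulate_force_clamp <- function(model, cfg) {
  stopifnot(inherits(model, "state_model"),
            inherits(cfg, "force_clamp_config"))
  ed <- model_edges(model)
  recs <- vector("list", length(cfg$setpoints))
  for (i in seq_along(cfg$setpoints)) {
    fset <- cfg$setpoints[i]
    kmax <- max(ed$k0 * exp(cfg$ctx$beta * fset * ed$dx))
    if (kmax * cfg$dt > 0.1)
      warning(sprintf(paste0("dt * max(k_off) = %.2g at setpoint %g pN: ",
                             "per-interval probabilities are coarse"),
                      kmax * cfg$dt, fset))
    res <- mc_clamp_cpp(fset, cfg$dt, cfg$max_time, ed$from, ed$to,
                        ed$pathway, ed$k0, ed$dx, cfg$ctx$beta,
                        cfg$replicates, cfg$seed + i - 1)
    recs[[i]] <- data.frame(
      setpoint = fset,
      replicate = seq_len(cfg$replicates),
      lifetime = res$lifetime,
      pathway = factor(paste0("P", res$pathway), levels = c("P0", "P1", "P2")),
      n_transitions = res$n_transitions,
      censored = res$censored
    )
  }
  records <- do.call(rbind, recs)
  summ <- do.call(rbind, lapply(split(records, records$setpoint), function(d) {
    n <- nrow(d)
    data.frame(
      setpoint = d$setpoint[1],
      mean_lifetime = mean(d$lifetime),
      median_lifetime = stats::median(d$lifetime),
      freq_P0 = sum(d$pathway == "P0", na.rm = TRUE) / n,
      freq_P1 = sum(d$pathway == "P1", na.rm = TRUE) / n,
      freq_P2 = sum(d$pathway == "P2", na.rm = TRUE) / n,
      prop_censored = mean(d$censored)
    )
  }))
  rownames(summ) <- NULL
  list(records = records, summary = summ[order(summ$setpoint), ])
}

#' Analytic single-pathway bond lifetime under constant force
#'
#' 1 / k(F) with k(F) the Bell-Evans off-rate: the mean lifetime a bond
#' clamped at force F would show if it could only rupture through this
#' one barrier.
#'
#' @param params A [be_params()].
#' @param force Force in pN (vectorised, >= 0).
#' @param ctx A [thermal_context()].
#' @return Lifetime in s.
#' @examples
#' analytic_pathway_lifetime(be_params(0.1, 0.5), 20)
#' @export
analytic_pathway_lifetime <- function(params, force, ctx = thermal_context()) {
  if (any(force < 0)) stop("force must be >= 0 pN")
  1 / bell_rate(params, force, ctx)
}
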