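# Shared fixtures: reference kinetic parameters and small generators.

ctx0 <- thermal_context()

be_ref <- be_params(0.1, 0.5)

slip_model <- function(k0 = 0.1, dx = 0.5) single_state_model(be_params(k0, dx))

# irreversible three-state fixture with well-separated pathway
# rupture-force distributions (~25 / ~95 / ~410 pN at the default
# speeds) and balanced populations; each transition edge shares its
# source state's rupture delta_x so censoring is proportional and the
# per-pathway Bell kinetics stay identifiable
threestate_fixture <- function() {
  state_model(
    rupture = list(P0 = be_params(0.1, 1.2), P1 = be_params(0.3, 0.3),
                   P2 = be_params(0.05, 0.1)),
    forward = list(N_I1 = be_params(0.2, 1.2), I1_I2 = be_params(0.15, 0.3))
  )
}

# brute-force evaluation of all three FRC branches plus their validity
# conditions, independent of the package's branch dispatch
frc_branches_oracle <- function(force, b, gamma, cc = 2, kBT = ctx0$kBT) {
  cg <- cos(gamma)
  a <- b * (1 + cg) / ((1 - cg) * cos(gamma / 2))
  p <- b * cos(gamma / 2) / abs(log(cg))
  f <- force * b / kBT
  list(
    a = a, p = p, f = f,
    low = force * a / (3 * kBT),
    mid = 1 - (4 * force * p / kBT)^(-1 / 2),
    high = 1 - (cc * force * b / kBT)^(-1),
    in_low = f < b / p, in_mid = f >= b / p & f <= p / b, in_high = f > p / b
  )
}

# analytic survival of a single Bell barrier along the package's pulling
# grid (deterministic quadrature; only the stochastic sampling is under
# test)
bell_ramp_cdf <- function(cfg, k0, dx) {
  L <- cfg$tether$L
  x <- seq(cfg$grid_step, L * 0.999, by = cfg$grid_step)
  f <- wlc_force(x, cfg$tether, cfg$ctx)
  h <- x + f / (cfg$spring_constant * 1000)
  dt <- diff(c(0, h)) / cfg$pulling_speed
  k <- k0 * exp(cfg$ctx$beta * f * dx)
  list(force = f, cdf = 1 - exp(-cumsum(k * dt)))
}
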