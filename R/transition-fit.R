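#' Configuration for the random-search transition-barrier fit
#'
#' The barriers separating the bound states are experimentally invisible:
#' they leave no pause or unfolding signature in the curves. Their Bell
#' parameters are estimated by randomly sampling candidate sets within
#' bounds, simulating constant-speed rupture-force distributions, and
#' scoring them against target histograms by the sum of squared residuals.
#'
#' @param k0_bounds Bounds for transition k0 in 1/s (default `c(1e-5, 100)`).
#' @param dx_bounds Bounds for transition delta_x in nm (default
#'   `c(0.01, 10)`).
#' @param n_starts Number of random starting parameter sets (default 10000).
#' @param replicates Simulation replicates per speed per evaluation
#'   (default 500).
#' @param bin_width Histogram bin width in pN (default 20).
#' @param f_max Upper edge of the common histogram support in pN
#'   (default 700, the upper end of observed rupture forces).
#' @param refine_frac Fraction of best starts polished by coordinate-wise
#'   log-space line search (default 0.01).
#' @param refine_iter Polish sweeps per refined start (default 2).
#' @param seed Master seed; start draws and simulation substreams both
#'   derive from it.
#' @return An object of class `transition_search_config`.
#' @export
transition_search_config <- function(k0_bounds = c(1e-5, 100),
                                     dx_bounds = c(0.01, 10),
                                     n_starts = 10000, replicates = 500,
                                     bin_width = 20, f_max = 700,
                                     refine_frac = 0.01, refine_iter = 2,
                                     seed = 1) {
  stopifnot(length(k0_bounds) == 2, k0_bounds[1] > 0,
            diff(k0_bounds) >= 0,
            length(dx_bounds) == 2, dx_bounds[1] > 0,
            diff(dx_bounds) >= 0,
            n_starts >= 1, replicates >= 1)
  structure(
    list(k0_bounds = k0_bounds, dx_bounds = dx_bounds,
         n_starts = n_starts, replicates = replicates,
         bin_width = bin_width, f_max = f_max,
         refine_frac = refine_frac, refine_iter = refine_iter, seed = seed),
    class = "transition_search_config"
  )
}

#' Probability-normalised rupture-force histogram on a fixed support
#'
#' @param forces Rupture forces in pN.
#' @param bin_width Bin width in pN.
#' @param f_max Upper support edge in pN; forces above it fall in the
#'   last bin.
#' @return Numeric vector of per-bin probabilities (sums to 1).
#' @export
rupture_histogram <- function(forces, bin_width = 20, f_max = 700) {
  forces <- forces[!is.na(forces)]
  breaks <- seq(0, f_max, by = bin_width)
  idx <- pmin(pmax(findInterval(forces, breaks, left.open = TRUE), 1L),
              length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  if (sum(counts) == 0) return(counts)
  counts / sum(counts)
}

# SSR between simulated and target per-speed histograms for one
# transition-parameter vector. Simulation seed fixed per evaluation id so
# refinement sees a deterministic objective.
transition_ssr <- function(theta, skeleton, grids, targets, search, sim_seed) {
  model <- set_transition_params(skeleton, theta)
  ed <- model_edges(model)
  ssr <- 0
  for (i in seq_along(grids)) {
    g <- grids[[i]]
    res <- mc_constant_speed_cpp(g$force, g$dt, ed$from, ed$to, ed$pathway,
                                 ed$k0, ed$dx, g$beta, search$replicates,
                                 sim_seed + (i - 1) * 1000003)
    p_sim <- rupture_histogram(res$rupture_force, search$bin_width,
                               search$f_max)
    ssr <- ssr + sum((p_sim - targets[[i]])^2)
  }
  ssr
}

#' Fit hidden inter-state transition barriers by random search
#'
#' Rupture edges are held at their (experimentally fitted) Bell
#' parameters; the transition-edge parameters are drawn uniformly within
#' the configured bounds, each candidate is scored by simulating the
#' constant-speed protocol at every target speed and summing squared
#' residuals between the simulated and target probability-normalised
#' rupture-force histograms, and the best starts are polished by a
#' coordinate-wise multiplicative line search in log space. Start draws
#' and simulation substreams are both re-randomised per start.
#'
#' @param skeleton A [state_model()] whose rupture edges are fixed; its
#'   transition edges define the topology (reversible or not) and are
#'   overwritten by the search.
#' @param targets Either a data.frame with columns `pulling_speed` and
#'   `rupture_force` (experimental records; histograms are built
#'   internally), or a named list mapping speed to a probability vector
#'   from [rupture_histogram()].
#' @param search A [transition_search_config()].
#' @param spring_constant,tether,grid_step,ctx Pulling-protocol settings,
#'   as in [constant_speed_config()].
#' @return A list of class `transition_fit`: `model` (best-fit
#'   [state_model()]), `ssr`, `theta`, `trace` (monotone non-increasing
#'   best-SSR trace over starts), `log` (per-start SSR table), and the
#'   budget (`n_starts`, `replicates`) and `seed` used.
#' @export
fit_transition_parameters <- function(skeleton, targets, search,
                                      spring_constant = 0.1,
                                      tether = wlc_params(190, 0.4),
                                      grid_step = 0.1,
                                      ctx = thermal_context()) {
  stopifnot(inherits(skeleton, "state_model"),
            inherits(search, "transition_search_config"))
  if (is.data.frame(targets)) {
    sp <- split(targets$rupture_force, targets$pulling_speed)
    speeds <- as.numeric(names(sp))
    targets <- lapply(sp, rupture_histogram, bin_width = search$bin_width,
                      f_max = search$f_max)
  } else {
    speeds <- as.numeric(names(targets))
    if (anyNA(speeds)) stop("list targets must be named by pulling speed")
  }
  grids <- lapply(speeds, function(v) {
    cfg <- constant_speed_config(v, spring_constant, tether, grid_step,
                                 replicates = search$replicates, ctx = ctx)
    g <- constant_speed_grid(cfg)
    g$beta <- ctx$beta
    g
  })

  n_par <- if (skeleton$reversible) 8L else 4L
  is_k0 <- seq_len(n_par) %% 2L == 1L
  lower <- ifelse(is_k0, search$k0_bounds[1], search$dx_bounds[1])
  upper <- ifelse(is_k0, search$k0_bounds[2], search$dx_bounds[2])

  set.seed(search$seed)
  starts <- matrix(stats::runif(search$n_starts * n_par,
                                rep(lower, each = search$n_starts),
                                rep(upper, each = search$n_starts)),
                   nrow = search$n_starts)
  sim_seeds <- sample.int(.Machine$integer.max, search$n_starts)

  ssr <- numeric(search$n_starts)
  for (s in seq_len(search$n_starts))
    ssr[s] <- transition_ssr(starts[s, ], skeleton, grids, targets, search,
                             sim_seeds[s])

  n_refine <- max(1L, ceiling(search$refine_frac * search$n_starts))
  top <- order(ssr)[seq_len(n_refine)]
  best_theta <- starts[top[1], ]
  best_ssr <- ssr[top[1]]
  for (s in top) {
    th <- starts[s, ]
    val <- ssr[s]
    fac <- 2
    for (it in seq_len(search$refine_iter)) {
      for (j in seq_len(n_par)) {
        for (cand in c(th[j] * fac, th[j] / fac)) {
          cand <- min(max(cand, lower[j]), upper[j])
          th_try <- th
          th_try[j] <- cand
          v <- transition_ssr(th_try, skeleton, grids, targets, search,
                              sim_seeds[s])
          if (v < val) {
            val <- v
            th <- th_try
          }
        }
      }
      fac <- 1 + (fac - 1) / 1.618  # shrink the step golden-ratio style
    }
    if (val < best_ssr) {
      best_ssr <- val
      best_theta <- th
    }
  }

  structure(
    list(model = set_transition_params(skeleton, best_theta),
         ssr = best_ssr, theta = best_theta,
         trace = cummin(ssr),
         log = data.frame(start = seq_len(search$n_starts), ssr = ssr),
         n_starts = search$n_starts, replicates = search$replicates,
         seed = search$seed, speeds = speeds),
    class = "transition_fit"
  )
}

#' Compare reversible and irreversible transition models
#'
#' Fits both topologies with equal search budgets against the same target
#' histograms and reports per-speed and total SSR; the lower-SSR model is
#' declared preferred. Budgets must match or the comparison is refused.
#'
#' @param reversible,irreversible [state_model()] skeletons of the two
#'   topologies (rupture edges fixed).
#' @param targets As in [fit_transition_parameters()].
#' @param search A [transition_search_config()] applied to the reversible
#'   fit.
#' @param search_irr Search configuration for the irreversible fit;
#'   defaults to `search`. `n_starts` and `replicates` must equal those
#'   of `search`.
#' @param ... Passed to [fit_transition_parameters()] (pulling-protocol
#'   settings).
#' @return A list of class `model_comparison`: the two `transition_fit`
#'   objects, a per-model SSR table, and `preferred` ("reversible" or
#'   "irreversible").
#' @export
compare_transition_models <- function(reversible, irreversible, targets,
                                      search, search_irr = search, ...) {
  stopifnot(reversible$reversible, !irreversible$reversible)
  if (search$n_starts != search_irr$n_starts ||
      search$replicates != search_irr$replicates)
    stop("unequal search budgets: comparison refused")
  fit_rev <- fit_transition_parameters(reversible, targets, search, ...)
  fit_irr <- fit_transition_parameters(irreversible, targets, search_irr, ...)
  tab <- data.frame(
    model = c("reversible", "irreversible"),
    ssr = c(fit_rev$ssr, fit_irr$ssr),
    n_starts = search$n_starts,
    replicates = search$replicates,
    seed = c(search$seed, search_irr$seed)
  )
  structure(
    list(reversible = fit_rev, irreversible = fit_irr, table = tab,
         preferred = tab$model[which.min(tab$ssr)]),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table)
  cat("preferred:", x$preferred, "\n")
  invisible(x)
}
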