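#' Force-dependent off-rates by the histogram transformation method
#'
#' Pools rupture forces from one unbinding pathway (all pulling speeds
#' combined), bins them with equal width `bin_width`, and converts each
#' bin into an off-rate estimate at the bin's median rupture force:
#' k_off(F_k) = h_k r(F_k) / ((h_k/2 + sum_{i>k} h_i) dF),
#' with bin heights h_k = C_k / (C_tot dF) so that sum h_k dF = 1, and
#' r(F_k) the median loading rate of the records in bin k. Bins with
#' fewer than `min_bin_count` records are merged into their
#' larger-population neighbour before the transform (the widths then
#' enter the formula per bin).
#'
#' @param records Data.frame with columns `rupture_force` (pN) and
#'   `loading_rate` (pN/s).
#' @param bin_width Histogram bin width in pN (default 10).
#' @param min_bin_count Minimum records per bin before merging (default 3).
#' @return An object of class `off_rate_histogram`: a data.frame with
#'   `bin_lo`, `bin_hi`, `width`, `count`, `height` (1/pN),
#'   `force_median` (pN), `loading_rate_median` (pN/s), `k_off` (1/s).
#' @examples
#' rec <- data.frame(rupture_force = runif(200, 20, 120),
#'                   loading_rate = 1e4)
#' off_rate_histogram(rec)
#' @export
off_rate_histogram <- function(records, bin_width = 10, min_bin_count = 3) {
  stopifnot(is.data.frame(records),
            all(c("rupture_force", "loading_rate") %in% names(records)))
  f <- records$rupture_force
  r <- records$loading_rate
  keep <- !is.na(f) & !is.na(r)
  f <- f[keep]
  r <- r[keep]
  if (length(f) < 1) stop("at least one rupture record is required")
  lo <- floor(min(f) / bin_width) * bin_width
  hi <- ceiling(max(f) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  idx <- pmin(pmax(findInterval(f, edges, left.open = TRUE), 1L),
              length(edges) - 1L)
  bins <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1])
  bins$count <- tabulate(idx, nbins = nrow(bins))
  bins <- bins[bins$count > 0, , drop = FALSE]
  # merge sparse bins into the adjacent bin with the larger count
  while (nrow(bins) > 1 && any(bins$count < min_bin_count)) {
    k <- which(bins$count < min_bin_count)[1]
    nb <- if (k == 1) 2L
          else if (k == nrow(bins)) k - 1L
          else if (bins$count[k + 1] >= bins$count[k - 1]) k + 1L else k - 1L
    j <- min(k, nb)
    bins$bin_hi[j] <- bins$bin_hi[max(k, nb)]
    bins$count[j] <- bins$count[k] + bins$count[nb]
    bins <- bins[-max(k, nb), , drop = FALSE]
  }
  ctot <- sum(bins$count)
  bins$width <- bins$bin_hi - bins$bin_lo
  bins$height <- bins$count / (ctot * bins$width)
  in_bin <- lapply(seq_len(nrow(bins)), function(k)
    which(f > bins$bin_lo[k] & f <= bins$bin_hi[k] |
            (k == 1 & f <= bins$bin_hi[1])))
  bins$force_median <- vapply(in_bin, function(i) stats::median(f[i]),
                              numeric(1))
  bins$loading_rate_median <- vapply(in_bin, function(i) stats::median(r[i]),
                                     numeric(1))
  n <- nrow(bins)
  tail_mass <- rev(cumsum(rev(bins$height * bins$width)))  # sum_{i>=k} h w
  denom <- bins$height * bins$width / 2 +
    (tail_mass - bins$height * bins$width)
  bins$k_off <- bins$height * bins$loading_rate_median / denom
  rownames(bins) <- NULL
  structure(bins[, c("bin_lo", "bin_hi", "width", "count", "height",
                     "force_median", "loading_rate_median", "k_off")],
            class = c("off_rate_histogram", "data.frame"),
            bin_width = bin_width, C_tot = ctot)
}

#' Dudko-Hummer-Szabo off-rate
#'
#' k_off(F) = k0 (1 - nu beta F dx / dG)^(1/nu - 1)
#'            exp(dG (1 - (1 - nu beta F dx / dG)^(1/nu)))
#' with the activation free energy dG carried in kBT units (so beta*dG
#' is the plain number dG). nu = 1/2 is the cusp-like barrier, nu = 1/3
#' the linear-cubic one; at nu = 1 the expression reduces exactly to the
#' Bell-Evans rate k0 exp(beta F dx). Outside the physical region
#' (nu beta F dx >= dG) the model is undefined and NA is returned.
#'
#' @param force Force in pN (vectorised).
#' @param k0 Intrinsic rate, 1/s.
#' @param delta_x Distance to the transition state, nm.
#' @param deltaG Activation free energy in kBT units.
#' @param nu Barrier-shape parameter (1/2, 1/3, or 1).
#' @param ctx A [thermal_context()].
#' @return Off-rate in 1/s; NA outside the physical force range.
#' @export
dhs_rate <- function(force, k0, delta_x, deltaG, nu = 1 / 2,
                     ctx = thermal_context()) {
  if (identical(nu, 1) || isTRUE(all.equal(nu, 1))) {
    # the shape factor cancels algebraically at nu = 1: exact Bell limit
    return(k0 * exp(ctx$beta * force * delta_x))
  }
  eps <- 1 - nu * ctx$beta * force * delta_x / deltaG
  out <- rep(NA_real_, length(eps))
  ok <- !is.na(eps) & eps > 0
  out[ok] <- k0 * eps[ok]^(1 / nu - 1) * exp(deltaG * (1 - eps[ok]^(1 / nu)))
  out
}

#' Fit the Dudko-Hummer-Szabo model to a transformed off-rate histogram
#'
#' Least squares on ln k_off(F_k) versus the bin median forces, by
#' Levenberg-Marquardt (minpack.lm) started from parameter sets drawn
#' uniformly within the search bounds. All starts are first scored by
#' their initial residual sum of squares and the best `optimize_top` are
#' optimised; the whole procedure is repeated `n_seed_runs` times with
#' different seeds and a warning is raised if the best SSRs across runs
#' disagree by more than 1%.
#'
#' @param hist An [off_rate_histogram()] with at least 3 populated bins.
#' @param nu Barrier-shape parameter: 1/2 (cusp) or 1/3 (linear-cubic).
#'   At nu = 1 the model is Bell and deltaG is unidentifiable; the fit is
#'   then performed on (k0, delta_x) only and deltaG reported NA.
#' @param bounds Named list of length-2 ranges for `k0` (1/s), `delta_x`
#'   (nm) and `deltaG` (kBT). Defaults `[0.001, 20]`, `[0.001, 2]`,
#'   `[0.01, 20]`.
#' @param n_starts Random starting sets per run (default 10000).
#' @param n_seed_runs Independent restart batches (default 3).
#' @param optimize_top Number of best-scoring starts sent to the
#'   optimiser per run (default 200).
#' @param seed Base seed.
#' @param ctx A [thermal_context()].
#' @return An object of class `dhs_params`: `k0`, `delta_x`, `deltaG`
#'   (kBT), `nu`, `ssr`, `run_ssr` (per seed run), `consistent` (best
#'   SSRs within 1%), `n_starts`.
#' @export
fit_dhs <- function(hist, nu = 1 / 2,
                    bounds = list(k0 = c(0.001, 20), delta_x = c(0.001, 2),
                                  deltaG = c(0.01, 20)),
                    n_starts = 10000, n_seed_runs = 3, optimize_top = 200,
                    seed = 1, ctx = thermal_context()) {
  stopifnot(inherits(hist, "off_rate_histogram"))
  if (nrow(hist) < 3)
    stop("fit refused: fewer populated bins (", nrow(hist),
         ") than parameters (3)")
  fk <- hist$force_median
  y <- log(hist$k_off)
  beta <- ctx$beta

  if (identical(nu, 1)) {
    # Bell reduction: ln k = ln k0 + beta F dx, deltaG drops out
    co <- stats::coef(stats::lm(y ~ fk))
    res <- y - (co[1] + co[2] * fk)
    out <- list(k0 = exp(unname(co[1])), delta_x = unname(co[2]) / beta,
                deltaG = NA_real_, nu = 1, ssr = sum(res^2),
                run_ssr = sum(res^2), consistent = TRUE, n_starts = 0L,
                note = "deltaG unidentifiable at nu = 1 (Bell limit)")
    return(structure(out, class = "dhs_params"))
  }

  ln_model <- function(par) {
    eps <- pmax(1 - nu * beta * fk * par[2] / par[3], 1e-12)
    log(par[1]) + (1 / nu - 1) * log(eps) + par[3] * (1 - eps^(1 / nu))
  }
  ssr_of <- function(par) sum((y - ln_model(par))^2)
  lower <- c(bounds$k0[1], bounds$delta_x[1], bounds$deltaG[1])
  upper <- c(bounds$k0[2], bounds$delta_x[2], bounds$deltaG[2])

  run_best <- function(run_seed) {
    set.seed(run_seed)
    starts <- cbind(stats::runif(n_starts, lower[1], upper[1]),
                    stats::runif(n_starts, lower[2], upper[2]),
                    stats::runif(n_starts, lower[3], upper[3]))
    score <- apply(starts, 1, ssr_of)
    top <- order(score)[seq_len(min(optimize_top, n_starts))]
    best <- list(par = starts[top[1], ], ssr = score[top[1]])
    for (s in top) {
      st <- starts[s, ]
      fit <- try(minpack.lm::nlsLM(
        y ~ log(k0) + (1 / nu - 1) * log(pmax(1 - nu * beta * fk * dx / dG,
                                              1e-12)) +
          dG * (1 - pmax(1 - nu * beta * fk * dx / dG, 1e-12)^(1 / nu)),
        start = list(k0 = st[1], dx = st[2], dG = st[3]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 100)),
        silent = TRUE)
      if (!inherits(fit, "try-error")) {
        par <- stats::coef(fit)
        v <- ssr_of(par)
        if (v < best$ssr) best <- list(par = par, ssr = v)
      }
    }
    best
  }

  runs <- lapply(seq_len(n_seed_runs), function(i) run_best(seed + i - 1))
  run_ssr <- vapply(runs, `[[`, numeric(1), "ssr")
  best <- runs[[which.min(run_ssr)]]
  consistent <- diff(range(run_ssr)) <= 0.01 * min(run_ssr)
  if (!consistent)
    warning("multi-seed DHS fits disagree by more than 1% in SSR")
  structure(
    list(k0 = unname(best$par[1]), delta_x = unname(best$par[2]),
         deltaG = unname(best$par[3]), nu = nu, ssr = best$ssr,
         run_ssr = run_ssr, consistent = consistent, n_starts = n_starts),
    class = "dhs_params"
  )
}

#' @export
print.dhs_params <- function(x, ...) {
  cat(sprintf(
    "<dhs_params> nu = %s: k0 = %.4g 1/s, dx = %.4g nm, dG = %.4g kBT (SSR %.4g)\n",
    format(x$nu), x$k0, x$delta_x, if (is.na(x$deltaG)) NA else x$deltaG,
    x$ssr))
  invisible(x)
}

#' Typical rupture force versus loading rate under the DHS model
#'
#' F(l) = dG/(nu beta dx) * (1 - ((1/dG) ln(k0 exp(dG) / (beta dx l)))^nu),
#' with dG carried in kBT units (dG/beta is the activation energy in
#' pN nm). Used to draw model lines through force versus log loading
#' rate data. The bracketed term vanishes where the inner logarithm is
#' zero, giving the critical force dG/(nu beta dx) at which the barrier
#' disappears; outside the range where the logarithm's argument and the
#' resulting force are physical, NA is returned.
#'
#' @param params A `dhs_params` object (or any list with `k0`, `delta_x`,
#'   `deltaG`, `nu`).
#' @param loading_rate Loading rate l in pN/s (vectorised, > 0).
#' @param ctx A [thermal_context()].
#' @return Force in pN; NA where the expression is undefined.
#' @export
dhs_force_vs_loading_rate <- function(params, loading_rate,
                                      ctx = thermal_context()) {
  if (any(loading_rate <= 0)) stop("loading_rate must be > 0 pN/s")
  k0 <- params$k0
  dx <- params$delta_x
  dG <- params$deltaG
  nu <- params$nu
  arg <- k0 * exp(dG) / (ctx$beta * dx * loading_rate)
  inner <- rep(NA_real_, length(arg))
  ok <- arg > 0
  inner[ok] <- log(arg[ok]) / dG
  out <- rep(NA_real_, length(arg))
  good <- !is.na(inner) & inner >= 0 & inner <= 1
  out[good] <- dG / (nu * ctx$beta * dx) * (1 - inner[good]^nu)
  out
}

#' Fit the Bell-Evans model to per-speed median rupture data
#'
#' F = (kBT/dx) ln(r dx / (k0 kBT)): linear in the logarithm of the
#' loading rate. The median rupture force and median loading rate are
#' computed per pulling-speed group and fitted by unweighted least
#' squares; the slope gives kBT/dx and the intercept the intrinsic rate.
#'
#' @param records Data.frame with columns `rupture_force`, `loading_rate`
#'   and a grouping column named by `speed_col`.
#' @param speed_col Name of the pulling-speed column (default
#'   `"pulling_speed"`).
#' @param ctx A [thermal_context()].
#' @return A [be_params()] with extra fields `medians` (per-speed table),
#'   `r_squared`, and `n_groups`.
#' @export
fit_be <- function(records, speed_col = "pulling_speed",
                   ctx = thermal_context()) {
  stopifnot(is.data.frame(records),
            all(c("rupture_force", "loading_rate", speed_col) %in%
                  names(records)))
  grp <- split(records, records[[speed_col]])
  if (length(grp) < 2)
    stop("fit refused: at least 2 pulling-speed groups are required")
  med <- do.call(rbind, lapply(grp, function(d) data.frame(
    speed = d[[speed_col]][1],
    force_median = stats::median(d$rupture_force, na.rm = TRUE),
    loading_rate_median = stats::median(d$loading_rate, na.rm = TRUE)
  )))
  fit <- stats::lm(force_median ~ log(loading_rate_median), data = med)
  m <- stats::coef(fit)[[2]]
  c0 <- stats::coef(fit)[[1]]
  if (m <= 0) stop("non-positive slope: median force does not grow with ",
                   "loading rate, Bell-Evans fit is meaningless")
  dx <- ctx$kBT / m
  k0 <- dx / (ctx$kBT * exp(c0 / m))
  out <- be_params(k0, dx)
  out$medians <- med
  out$r_squared <- summary(fit)$r.squared
  out$n_groups <- length(grp)
  out
}

#' Bell-Evans most-probable rupture force at a loading rate
#'
#' @param params A [be_params()].
#' @param loading_rate Loading rate in pN/s (vectorised, > 0).
#' @param ctx A [thermal_context()].
#' @return Force in pN.
#' @export
be_force <- function(params, loading_rate, ctx = thermal_context()) {
  stopifnot(inherits(params, "be_params"))
  if (any(loading_rate <= 0)) stop("loading_rate must be > 0 pN/s")
  (ctx$kBT / params$delta_x) *
    log(loading_rate * params$delta_x / (params$k0 * ctx$kBT))
}

#' Off-rate at a given force for either landscape model
#'
#' Dispatches on the parameter class: [be_params()] gives the Bell rate,
#' `dhs_params` the DHS rate (NA outside its physical region).
#'
#' @param params A [be_params()] or `dhs_params` object.
#' @param force Force in pN (vectorised).
#' @param ctx A [thermal_context()].
#' @return Off-rate in 1/s.
#' @export
k_of_F <- function(params, force, ctx = thermal_context()) {
  if (inherits(params, "be_params")) {
    bell_rate(params, force, ctx)
  } else if (inherits(params, "dhs_params")) {
    dhs_rate(force, params$k0, params$delta_x, params$deltaG, params$nu, ctx)
  } else {
    stop("params must be be_params or dhs_params")
  }
}

#' Force at which two off-rate curves cross
#'
#' Finds the positive force where k1(F) = k2(F), e.g. where a weaker
#' pathway's off-rate overtakes a stronger one's.
#'
#' @param params1,params2 Parameter objects accepted by [k_of_F()].
#' @param interval Search interval in pN (default `c(1e-3, 1000)`).
#' @param ctx A [thermal_context()].
#' @return Crossing force in pN.
#' @export
k_crossing <- function(params1, params2, interval = c(1e-3, 1000),
                       ctx = thermal_context()) {
  g <- function(f) log(k_of_F(params1, f, ctx)) - log(k_of_F(params2, f, ctx))
  stats::uniroot(g, interval = interval, tol = 1e-9)$root
}
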