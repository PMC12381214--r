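#' A single retraction force-extension curve
#'
#' @param extension Extension in nm (non-decreasing, length >= 2).
#' @param force Force in pN (same length).
#' @param pulling_speed Retraction speed in nm/s.
#' @param spring_constant Cantilever spring constant in N/m.
#' @param curve_id,experiment_id Identifiers.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(extension, force, pulling_speed, spring_constant,
                        curve_id = "curve_1", experiment_id = "exp_1") {
  if (length(extension) != length(force) || length(extension) < 2)
    stop("extension and force must have equal length >= 2")
  if (is.unsorted(extension))
    stop("extension must be non-decreasing")
  structure(
    list(extension = as.numeric(extension), force = as.numeric(force),
         pulling_speed = pulling_speed, spring_constant = spring_constant,
         curve_id = curve_id, experiment_id = experiment_id,
         baseline_subtracted = FALSE, baseline_flag = NA_character_),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %s: %d samples, %.0f nm/s, k = %g N/m\n",
              x$curve_id, length(x$force), x$pulling_speed,
              x$spring_constant))
  invisible(x)
}

# Locate the post-rupture zero-force tail: samples after the last index
# where |force| exceeds a threshold set by the terminal noise level.
find_tail <- function(curve, min_tail = 20, max_tail_slope = 0.2) {
  f <- curve$force
  n <- length(f)
  tail_guess <- f[max(1, n - 49):n]
  thr <- max(5, 5 * stats::mad(tail_guess))
  last_sig <- max(which(abs(f - stats::median(tail_guess)) > thr), 0)
  if (n - last_sig < min_tail) return(NULL)
  idx <- (last_sig + 1):n
  # a credible baseline is nearly flat; a still-loaded segment is not
  slope <- stats::coef(stats::lm(f[idx] ~ curve$extension[idx]))[[2]]
  if (!is.finite(slope) || abs(slope) > max_tail_slope) return(NULL)
  idx
}

#' Subtract the baseline from a force-extension curve
#'
#' Fits a line to the post-rupture zero-force tail and subtracts it from
#' the whole curve, so the tail median is zero and any linear tilt is
#' removed. Curves without an identifiable tail are passed through
#' unchanged with a flag.
#'
#' @param curve A [force_curve()].
#' @return The corrected `force_curve` (fields `baseline_subtracted`,
#'   `baseline_flag` updated).
#' @export
baseline_subtract <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  idx <- find_tail(curve)
  if (is.null(idx)) {
    curve$baseline_flag <- "no_tail"
    return(curve)
  }
  d <- data.frame(x = curve$extension[idx], f = curve$force[idx])
  fit <- stats::lm(f ~ x, data = d)
  pred <- stats::coef(fit)[[1]] + stats::coef(fit)[[2]] * curve$extension
  # align the tail median exactly to zero after the tilt removal
  resid_med <- stats::median(curve$force[idx] - pred[idx])
  curve$force <- curve$force - pred - resid_med
  curve$baseline_subtracted <- TRUE
  curve$baseline_flag <- "ok"
  curve
}

#' Detect sawtooth peaks in a force-extension curve
#'
#' The force channel is smoothed by a short running median, local maxima
#' are screened by topographic prominence and by the depth of the force
#' drop that follows, and the peak force is read from the raw samples
#' around the smoothed maximum.
#'
#' @param curve A baseline-subtracted [force_curve()].
#' @param min_prominence Minimum peak prominence, pN (default 10).
#' @param min_drop Minimum force drop after the peak, pN (default 10).
#' @param smooth_k Running-median window in samples (odd; default 5).
#' @return Data.frame of class `peak_events`: `index`, `extension`,
#'   `peak_force`, `prominence`, `drop`, `kind` (initially "unknown"),
#'   ordered by extension. Possibly zero rows.
#' @export
detect_peaks <- function(curve, min_prominence = 10, min_drop = 10,
                         smooth_k = 5) {
  stopifnot(inherits(curve, "force_curve"))
  f_raw <- curve$force
  n <- length(f_raw)
  f <- if (smooth_k >= 3 && n > smooth_k)
    as.numeric(stats::runmed(f_raw, smooth_k)) else f_raw
  # candidate local maxima, plateau-aware: a down-run of the force
  # difference preceded (ignoring flats) by an up-run marks an apex at
  # the last sample before the descent
  d <- sign(diff(f))
  r <- rle(d)
  ends <- cumsum(r$lengths)
  cand <- integer()
  lastnz <- 0
  for (k in seq_along(r$values)) {
    if (r$values[k] == -1 && lastnz == 1)
      cand <- c(cand, ends[k] - r$lengths[k] + 1L)
    if (r$values[k] != 0) lastnz <- r$values[k]
  }
  cand <- cand[f[cand] > 0]
  if (!length(cand))
    return(empty_peaks())
  keep <- logical(length(cand))
  prom <- drop <- numeric(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    # prominence: descend each side until a higher point; key saddle is
    # the higher of the two valley minima
    left_higher <- which(f[seq_len(i - 1)] > f[i])
    lo_l <- if (length(left_higher)) min(f[(max(left_higher) + 1):(i - 1)])
            else min(f[seq_len(max(i - 1, 1))])
    right_higher <- which(f[(i + 1):n] > f[i])
    if (length(right_higher)) {
      r_end <- i + min(right_higher) - 1
      lo_r <- min(f[(i + 1):r_end])
    } else {
      lo_r <- min(f[(i + 1):n])
      r_end <- n
    }
    prom[j] <- f[i] - max(lo_l, lo_r)
    drop[j] <- f[i] - lo_r
    keep[j] <- prom[j] >= min_prominence && drop[j] >= min_drop
  }
  cand <- cand[keep]
  if (!length(cand))
    return(empty_peaks())
  # peak force from raw samples near the smoothed maximum
  half <- max(1L, (smooth_k - 1L) %/% 2L)
  idx_raw <- vapply(cand, function(i) {
    w <- max(1, i - half):min(n, i + half)
    w[which.max(f_raw[w])]
  }, integer(1))
  out <- data.frame(index = idx_raw,
                    extension = curve$extension[idx_raw],
                    peak_force = f_raw[idx_raw],
                    prominence = prom[keep],
                    drop = drop[keep],
                    kind = "unknown",
                    stringsAsFactors = FALSE)
  out <- out[order(out$extension), ]
  rownames(out) <- NULL
  class(out) <- c("peak_events", "data.frame")
  out
}

empty_peaks <- function() {
  out <- data.frame(index = integer(), extension = numeric(),
                    peak_force = numeric(), prominence = numeric(),
                    drop = numeric(), kind = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_events", "data.frame")
  out
}

#' Prefilter curves on their sawtooth-peak pattern
#'
#' Excludes curves indicative of non-specific surface adhesion, absent
#' interactions, or multiple simultaneous tethers: any peak within the
#' first ~100 nm of extension, no peaks at all, or more than 9 peaks.
#' Each rejection carries exactly one reason (checked in that order).
#'
#' @param curves List of [force_curve()] objects.
#' @param peaks List of peak tables from [detect_peaks()], parallel to
#'   `curves`; computed internally when NULL.
#' @param early_limit Extension limit for the early-peak rule, nm
#'   (default 100).
#' @param max_peaks Maximum peak count (default 9).
#' @param ... Passed to [detect_peaks()] when `peaks` is NULL.
#' @return List with `kept` (indices), `rejected` (data.frame: index,
#'   reason in early_peak / no_peaks / too_many_peaks), and `peaks`.
#' @export
prefilter <- function(curves, peaks = NULL, early_limit = 100,
                      max_peaks = 9, ...) {
  if (inherits(curves, "force_curve")) curves <- list(curves)
  if (is.null(peaks)) peaks <- lapply(curves, detect_peaks, ...)
  reasons <- vapply(peaks, function(p) {
    if (nrow(p) > 0 && any(p$extension < early_limit)) "early_peak"
    else if (nrow(p) == 0) "no_peaks"
    else if (nrow(p) > max_peaks) "too_many_peaks"
    else ""
  }, character(1))
  list(kept = which(reasons == ""),
       rejected = data.frame(index = which(reasons != ""),
                             reason = reasons[reasons != ""]),
       peaks = peaks)
}

#' Transform a force-extension curve into contour-length space
#'
#' Applies the FRC inversion sample by sample: L_i = x_i / (x/L)(F_i).
#' Within one unfolding plateau the contour length is constant up to
#' noise, so unfolding events appear as a staircase. Samples below the
#' force noise floor are undefined (NA).
#'
#' @param curve A baseline-subtracted [force_curve()].
#' @param frc [frc_params()].
#' @param noise_floor_pN Force floor below which the inversion is not
#'   trusted (default 10).
#' @return Numeric vector of contour lengths (nm), NA below the floor.
#' @export
to_contour_length <- function(curve, frc = frc_params(),
                              noise_floor_pN = 10) {
  stopifnot(inherits(curve, "force_curve"))
  ok <- curve$extension > 0
  out <- rep(NA_real_, length(curve$force))
  out[ok] <- frc_contour_length(curve$force[ok], curve$extension[ok], frc,
                                noise_floor_pN = noise_floor_pN)
  out
}

#' Fingerprint classification tolerances
#'
#' The published selection rules quote approximate values; these
#' tolerances make the tildes explicit and are all configurable.
#'
#' @param c1_force_max Criterion-1 maximum rupture force, pN (100).
#' @param c1_contour,c1_contour_tol Criterion-1 rupture contour length
#'   target and tolerance, nm (135 +/- 10).
#' @param c2_contour,c2_contour_tol Criterion-2 rupture contour length
#'   target and tolerance, nm (190 +/- 15).
#' @param fp_force_range Fingerprint force window, pN (50-80, hard).
#' @param fp_count Required fingerprint peak count (4).
#' @param fp_increment_sum,fp_increment_tol Total fingerprint contour
#'   increment and tolerance, nm (32 +/- 4).
#' @return A list of tolerances.
#' @export
fingerprint_criteria <- function(c1_force_max = 100,
                                 c1_contour = 135, c1_contour_tol = 10,
                                 c2_contour = 190, c2_contour_tol = 15,
                                 fp_force_range = c(50, 80), fp_count = 4,
                                 fp_increment_sum = 32,
                                 fp_increment_tol = 4) {
  list(c1_force_max = c1_force_max, c1_contour = c1_contour,
       c1_contour_tol = c1_contour_tol, c2_contour = c2_contour,
       c2_contour_tol = c2_contour_tol, fp_force_range = fp_force_range,
       fp_count = fp_count, fp_increment_sum = fp_increment_sum,
       fp_increment_tol = fp_increment_tol)
}

# Per-peak contour lengths and increments. The contour before peak j is
# the FRC inversion at the peak's (force, extension); the contour after
# is the contour before the next peak (or, for the last peak, itself).
peak_contours <- function(curve, peaks, frc) {
  if (nrow(peaks) == 0) return(peaks)
  L <- frc_contour_length(peaks$peak_force, peaks$extension, frc,
                          noise_floor_pN = 0)
  peaks$contour_before <- L
  peaks$contour_after <- c(L[-1], L[length(L)])
  peaks$increment <- peaks$contour_after - peaks$contour_before
  peaks
}

#' Classify a curve by its single-molecule fingerprint
#'
#' Criterion 1: a terminal rupture below `c1_force_max` at a contour
#' length near the pre-unfolding construct length, with no fingerprint
#' unfolding peaks. Criterion 2: the full fingerprint - `fp_count` peaks
#' inside the force window whose contour increments sum to the expected
#' total - followed by rupture at the fully unfolded contour length.
#' Anything else is rejected as not certifiably single-molecule.
#'
#' @param curve A baseline-subtracted [force_curve()].
#' @param peaks Peak table from [detect_peaks()]; computed when NULL.
#' @param frc [frc_params()].
#' @param criteria A [fingerprint_criteria()] list.
#' @return A list of class `fingerprint_class`: `classification`
#'   ("criterion1", "criterion2" or "reject"), `peaks` (annotated with
#'   contours, increments, kinds), `rupture_contour`, `fp_increment_sum`.
#' @export
identify_fingerprint <- function(curve, peaks = NULL, frc = frc_params(),
                                 criteria = fingerprint_criteria()) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(peaks)) peaks <- detect_peaks(curve)
  if (nrow(peaks) == 0)
    return(structure(list(classification = "reject", peaks = peaks,
                          rupture_contour = NA_real_,
                          fp_increment_sum = NA_real_),
                     class = "fingerprint_class"))
  peaks <- peak_contours(curve, peaks, frc)
  n <- nrow(peaks)
  terminal <- n
  peaks$kind[terminal] <- "rupture"
  in_window <- which(seq_len(n) != terminal &
                       peaks$peak_force >= criteria$fp_force_range[1] &
                       peaks$peak_force <= criteria$fp_force_range[2])
  peaks$kind[in_window] <- "fingerprint"
  peaks$kind[setdiff(seq_len(n - 1), in_window)] <- "intermediate"
  rupture_contour <- peaks$contour_before[terminal]
  fp_sum <- sum(peaks$increment[in_window])
  cls <- "reject"
  if (length(in_window) == 0 &&
      peaks$peak_force[terminal] < criteria$c1_force_max &&
      abs(rupture_contour - criteria$c1_contour) <= criteria$c1_contour_tol) {
    cls <- "criterion1"
  } else if (length(in_window) == criteria$fp_count &&
             abs(fp_sum - criteria$fp_increment_sum) <=
               criteria$fp_increment_tol &&
             abs(rupture_contour - criteria$c2_contour) <=
               criteria$c2_contour_tol) {
    cls <- "criterion2"
  }
  structure(list(classification = cls, peaks = peaks,
                 rupture_contour = rupture_contour,
                 fp_increment_sum = fp_sum),
            class = "fingerprint_class")
}

#' Extract the rupture record from a classified curve
#'
#' Rupture force is the force at the terminal peak; the loading rate is
#' the slope of a linear force-versus-time fit over the final rise
#' segment - from the last local force minimum before the terminal peak,
#' restricted to forces above `rise_floor_frac` of the rupture force.
#' Time is recovered from extension and pulling speed. Intermediate
#' unfolding increments are recorded and set the subtype:
#' a = criterion-1 rupture, b = full fingerprint without intermediates,
#' c = with intermediates.
#'
#' @param curve A baseline-subtracted [force_curve()].
#' @param fp A `fingerprint_class` from [identify_fingerprint()];
#'   computed when NULL.
#' @param rise_floor_frac Lower force bound of the loading-rate window
#'   as a fraction of the rupture force (default 0.3).
#' @param min_rise_samples Minimum samples in the rise segment; fewer
#'   flags the record and leaves the loading rate NA (default 5).
#' @param ... Passed to [identify_fingerprint()] when `fp` is NULL.
#' @return A one-row data.frame of class `rupture_record`:
#'   `rupture_force_pN`, `loading_rate_pN_s`, `final_contour_nm`,
#'   `pathway` ("unassigned"), `subtype`, `n_intermediates`,
#'   `intermediate_increments_nm` (list column), `pulling_speed_nm_s`,
#'   `experiment`, `curve_id`, `classification`, `flag`.
#' @export
extract_rupture <- function(curve, fp = NULL, rise_floor_frac = 0.3,
                            min_rise_samples = 5, ...) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(fp)) fp <- identify_fingerprint(curve, ...)
  if (fp$classification == "reject")
    stop("cannot extract a rupture record from a rejected curve")
  peaks <- fp$peaks
  terminal <- nrow(peaks)
  i_rup <- peaks$index[terminal]
  f_rup <- peaks$peak_force[terminal]
  tim <- curve$extension / curve$pulling_speed

  # rise segment: last local minimum before the terminal peak
  prev_end <- if (terminal > 1) peaks$index[terminal - 1] else 1L
  seg <- prev_end:i_rup
  i_min <- seg[which.min(curve$force[seg])]
  rise <- i_min:i_rup
  rise <- rise[curve$force[rise] >= rise_floor_frac * f_rup]
  flag <- ""
  lr <- NA_real_
  if (length(rise) < min_rise_samples) {
    flag <- "degenerate_rise"
  } else {
    lr <- stats::coef(stats::lm(curve$force[rise] ~ tim[rise]))[[2]]
  }
  ints <- peaks$increment[peaks$kind == "intermediate"]
  subtype <- if (fp$classification == "criterion1") "a"
             else if (length(ints) == 0) "b" else "c"
  out <- data.frame(
    rupture_force_pN = f_rup,
    loading_rate_pN_s = lr,
    final_contour_nm = fp$rupture_contour,
    pathway = "unassigned",
    subtype = subtype,
    n_intermediates = length(ints),
    pulling_speed_nm_s = curve$pulling_speed,
    experiment = curve$experiment_id,
    curve_id = curve$curve_id,
    classification = fp$classification,
    flag = flag,
    stringsAsFactors = FALSE
  )
  out$intermediate_increments_nm <- list(ints)
  class(out) <- c("rupture_record", "data.frame")
  out
}
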