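# Clamp segment of a trace: the contiguous run of samples whose force
# stays above a fraction of the target setpoint, beginning at the end of
# the loading ramp.
clamp_segment <- function(trace, frac = 0.6) {
  above <- trace$force >= frac * trace$target_setpoint
  if (!any(above)) return(NULL)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  runs_true <- which(runs$values)
  best <- runs_true[which.max(runs$lengths[runs_true])]
  starts[best]:ends[best]
}

#' Filter force-clamp traces for non-specific events
#'
#' Excludes the signatures of non-specific clamping identified from
#' no-receptor control surfaces: more than `max_head_steps` discrete
#' head-height steps during the clamp, post-rupture retraction distances
#' below `min_retraction` or above `max_retraction` nm, and bond
#' lifetimes under the `lifetime_floor` (feedback regularisation
#' artifacts). Each rejection carries exactly one reason, checked in the
#' order head_steps, retraction_short, retraction_long, lifetime_floor.
#'
#' @param traces List of `clamp_trace` objects (or one).
#' @param max_head_steps Maximum discrete head-height steps (default 3).
#' @param head_step_nm Jump size that counts as a discrete step, nm
#'   (default 5).
#' @param min_retraction,max_retraction Allowed retraction distance
#'   range, nm (default 40-200).
#' @param lifetime_floor Minimum bond lifetime, s (default 0.015).
#' @return List with `accepted` (data.frame of [estimate_setpoint_and_lifetime()]
#'   records), `rejected` (data.frame: index, reason).
#' @export
filter_clamp_traces <- function(traces, max_head_steps = 3,
                                head_step_nm = 5, min_retraction = 40,
                                max_retraction = 200,
                                lifetime_floor = 0.015) {
  if (inherits(traces, "clamp_trace")) traces <- list(traces)
  recs <- list()
  rej <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    seg <- clamp_segment(tr)
    if (is.null(seg)) {
      rej[[length(rej) + 1]] <- data.frame(index = i, reason = "no_clamp")
      next
    }
    h <- tr$head_height[seg]
    h_sm <- if (length(h) > 9) as.numeric(stats::runmed(h, 9)) else h
    n_steps <- sum(abs(diff(h_sm)) > head_step_nm)
    post <- tr$head_height[seg[length(seg)]:length(tr$head_height)]
    retraction <- max(post) - stats::median(h)
    lifetime <- tr$time[seg[length(seg)]] - tr$time[seg[1]]
    reason <- if (n_steps > max_head_steps) "head_steps"
      else if (retraction < min_retraction) "retraction_short"
      else if (retraction > max_retraction) "retraction_long"
      else if (lifetime < lifetime_floor) "lifetime_floor"
      else ""
    if (reason != "") {
      rej[[length(rej) + 1]] <- data.frame(index = i, reason = reason)
    } else {
      r <- estimate_setpoint_and_lifetime(tr)
      r$index <- i
      recs[[length(recs) + 1]] <- r
    }
  }
  list(
    accepted = if (length(recs)) do.call(rbind, recs) else NULL,
    rejected = if (length(rej)) do.call(rbind, rej) else
      data.frame(index = integer(), reason = character())
  )
}

#' Estimate the realised setpoint and bond lifetime of a clamp trace
#'
#' The setpoint is identified as the highest mean force over any sliding
#' ~5 ms window during the clamp (so brief spikes are averaged down);
#' the lifetime runs from the start of the clamp to the resumption of
#' retraction (end of the clamped segment). The record carries the 10 pN
#' force bin used for lifetime statistics.
#'
#' @param trace A `clamp_trace`.
#' @param window Setpoint window length in s (default 0.005).
#' @param bin_width Force bin width in pN (default 10).
#' @return One-row data.frame of class `lifetime_record`:
#'   `setpoint_estimate_pN`, `lifetime_s`, `force_bin_pN` (lower bin
#'   edge), `accepted`, `flag`.
#' @export
estimate_setpoint_and_lifetime <- function(trace, window = 0.005,
                                           bin_width = 10) {
  stopifnot(inherits(trace, "clamp_trace"))
  seg <- clamp_segment(trace)
  if (is.null(seg)) stop("no clamp segment identified in trace")
  f <- trace$force[seg]
  dt <- stats::median(diff(trace$time))
  w <- max(1L, round(window / dt))
  flag <- ""
  if (length(f) < w) {
    flag <- "clamp_shorter_than_window"
    setp <- mean(f)
  } else {
    cs <- cumsum(c(0, f))
    setp <- max((cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w)
  }
  lifetime <- trace$time[seg[length(seg)]] - trace$time[seg[1]]
  out <- data.frame(
    setpoint_estimate_pN = setp,
    lifetime_s = lifetime,
    force_bin_pN = floor(setp / bin_width) * bin_width,
    accepted = flag == "",
    flag = flag,
    stringsAsFactors = FALSE
  )
  class(out) <- c("lifetime_record", "data.frame")
  out
}
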