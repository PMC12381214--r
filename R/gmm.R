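#' Square-root transform and standardise rupture forces
#'
#' The pooled rupture-force distribution is square-root transformed (to
#' tame the right skew of the strong-pathway tail) and z-standardised
#' before mixture fitting. The transform parameters are kept so the
#' component means can be mapped back to pN.
#'
#' @param forces Rupture forces in pN (> 0).
#' @return An object of class `force_transform`: `z` (transformed
#'   values), `center`, `scale`.
#' @export
preprocess_forces <- function(forces) {
  if (length(forces) == 0) stop("empty force vector")
  if (any(forces <= 0, na.rm = TRUE)) stop("forces must be > 0 pN")
  s <- sqrt(forces)
  center <- mean(s)
  scale <- stats::sd(s)
  if (length(s) < 2 || !is.finite(scale) || scale == 0) scale <- 1
  structure(list(z = (s - center) / scale, center = center, scale = scale),
            class = "force_transform")
}

#' Invert the rupture-force preprocessing
#'
#' @param z Values in transformed space.
#' @param transform A `force_transform` from [preprocess_forces()].
#' @return Forces in pN.
#' @export
invert_forces <- function(z, transform) {
  stopifnot(inherits(transform, "force_transform"))
  (z * transform$scale + transform$center)^2
}

#' Fit a Gaussian mixture to pooled rupture forces
#'
#' Candidate mixtures with 1 to 4 unequal-variance univariate components
#' are fitted to the transformed forces and the component count is
#' selected by BIC (mclust's model-based clustering; its hierarchical
#' initialisation makes the fit deterministic). Components are relabelled
#' in ascending order of mean so that labels map canonically onto the
#' unbinding pathways P0 < P1 < P2.
#'
#' @param forces Rupture forces in pN pooled over speeds for one
#'   experiment.
#' @param G Candidate component counts (default 1:4).
#' @param min_records Minimum number of records (default 30).
#' @param seed Seed set before fitting (the fit is deterministic; the
#'   seed guards any stochastic fallback inside mclust).
#' @return An object of class `gmm_result`: `n_components`, `weights`,
#'   `means`, `variances` (transformed space), `means_pN`,
#'   `responsibilities` (n x G matrix), `bic` (per candidate G),
#'   `transform`, `forces`.
#' @export
fit_pathway_gmm <- function(forces, G = 1:4, min_records = 30, seed = 1) {
  forces <- forces[!is.na(forces)]
  if (length(forces) < min_records)
    stop("at least ", min_records, " rupture records are required")
  pp <- preprocess_forces(forces)
  set.seed(seed)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  fit <- mclust::Mclust(pp$z, G = G, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed to converge for all G")
  ord <- order(fit$parameters$mean)
  resp <- fit$z[, ord, drop = FALSE]
  vars <- fit$parameters$variance$sigmasq
  if (length(vars) == 1) vars <- rep(vars, fit$G)
  means <- fit$parameters$mean[ord]
  structure(
    list(n_components = fit$G,
         weights = unname(fit$parameters$pro[ord]),
         means = unname(means),
         variances = unname(vars[ord]),
         means_pN = unname(invert_forces(means, pp)),
         responsibilities = unname(resp),
         bic = fit$BIC[, 1],
         loglik = fit$loglik,
         transform = pp,
         forces = forces),
    class = "gmm_result"
  )
}

#' @export
print.gmm_result <- function(x, ...) {
  cat(sprintf("<gmm_result> %d components (n = %d)\n",
              x$n_components, length(x$forces)))
  print(data.frame(weight = round(x$weights, 3),
                   mean_pN = round(x$means_pN, 1),
                   variance = round(x$variances, 4)))
  invisible(x)
}

# Bhattacharyya coefficient between two univariate Gaussians.
bhattacharyya_gaussian <- function(m1, v1, m2, v2) {
  sqrt(2 * sqrt(v1 * v2) / (v1 + v2)) * exp(-(m1 - m2)^2 / (4 * (v1 + v2)))
}

#' Reclassify a spurious fourth mixture component
#'
#' When four components are selected, the minor (smallest-weight)
#' component is taken as experimental variance rather than a distinct
#' pathway: its records are reassigned to the remaining components by
#' maximum responsibility among them, leaving three effective pathways.
#' "Overlapping parents" are components whose Bhattacharyya coefficient
#' with the minor component exceeds `bc_threshold`; if none overlaps the
#' result is flagged ambiguous but the reassignment (still by maximum
#' remaining responsibility) proceeds.
#'
#' @param result A `gmm_result`.
#' @param bc_threshold Overlap criterion on the Bhattacharyya coefficient
#'   (default 0.1).
#' @return A `gmm_result` with three components; unchanged if the input
#'   has three or fewer. Carries `reclassified = TRUE` and
#'   `ambiguous_parent` flags.
#' @export
reclassify_fourth_component <- function(result, bc_threshold = 0.1) {
  stopifnot(inherits(result, "gmm_result"))
  if (result$n_components < 4) return(result)
  # candidate = the minor component among those that overlap another one;
  # a non-overlapping component is a genuine mode, not the artifact
  k <- result$n_components
  max_bc <- vapply(seq_len(k), function(i) max(vapply(
    setdiff(seq_len(k), i), function(j) bhattacharyya_gaussian(
      result$means[i], result$variances[i],
      result$means[j], result$variances[j]), numeric(1))), numeric(1))
  overlapping <- which(max_bc > bc_threshold)
  ambiguous <- length(overlapping) == 0
  pool <- if (ambiguous) seq_len(k) else overlapping
  minor <- pool[which.min(result$weights[pool])]
  others <- setdiff(seq_len(k), minor)
  resp <- result$responsibilities[, others, drop = FALSE]
  resp <- resp / pmax(rowSums(resp), .Machine$double.eps)
  out <- result
  out$n_components <- length(others)
  out$weights <- colMeans(resp)
  out$means <- result$means[others]
  out$variances <- result$variances[others]
  out$means_pN <- result$means_pN[others]
  out$responsibilities <- resp
  out$reclassified <- TRUE
  out$ambiguous_parent <- ambiguous
  if (ambiguous)
    warning("no component overlaps the minor component at the configured ",
            "Bhattacharyya threshold; reassignment by maximum remaining ",
            "responsibility")
  out
}

#' Per-record pathway assignments from a mixture result
#'
#' Records are assigned to the component of maximum responsibility, ties
#' broken toward the lower-mean component (conservative toward P0).
#' Component order is canonical (ascending mean), so component 1 is P0.
#'
#' @param result A `gmm_result` with at most 3 components.
#' @return Data.frame: `record`, `rupture_force`, `pathway` (factor
#'   P0/P1/P2), `posterior`.
#' @export
pathway_assignments <- function(result) {
  stopifnot(inherits(result, "gmm_result"))
  if (result$n_components > 3)
    stop("apply reclassify_fourth_component() before assignment")
  resp <- result$responsibilities
  comp <- apply(resp, 1, function(p) which(p >= max(p) - 1e-12)[1])
  data.frame(
    record = seq_along(result$forces),
    rupture_force = result$forces,
    pathway = factor(paste0("P", comp - 1),
                     levels = c("P0", "P1", "P2")),
    posterior = resp[cbind(seq_len(nrow(resp)), comp)]
  )
}

#' Pathway proportions per pulling speed with SEM across experiments
#'
#' @param assignments Data.frame with columns `pathway`,
#'   `pulling_speed`, `experiment`.
#' @return Data.frame: `pulling_speed`, `pathway`, `proportion` (mean
#'   across experiments), `sem` (NA with a single experiment),
#'   `n_experiments`. Within each experiment and speed the proportions
#'   sum to 1.
#' @export
pathway_proportions <- function(assignments) {
  stopifnot(all(c("pathway", "pulling_speed", "experiment") %in%
                  names(assignments)))
  lv <- c("P0", "P1", "P2")
  per_exp <- do.call(rbind, lapply(
    split(assignments,
          list(assignments$pulling_speed, assignments$experiment),
          drop = TRUE),
    function(d) {
      tab <- table(factor(d$pathway, levels = lv))
      data.frame(pulling_speed = d$pulling_speed[1],
                 experiment = d$experiment[1],
                 pathway = lv,
                 prop = as.numeric(tab) / sum(tab))
    }))
  out <- do.call(rbind, lapply(
    split(per_exp, list(per_exp$pulling_speed, per_exp$pathway), drop = TRUE),
    function(d) {
      n <- nrow(d)
      data.frame(pulling_speed = d$pulling_speed[1],
                 pathway = d$pathway[1],
                 proportion = mean(d$prop),
                 sem = if (n >= 2) stats::sd(d$prop) / sqrt(n) else NA_real_,
                 n_experiments = n)
    }))
  out <- out[order(out$pulling_speed, out$pathway), ]
  rownames(out) <- NULL
  out
}
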