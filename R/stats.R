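#' Shapiro-Wilk normality screen across groups
#'
#' Because multi-pathway unbinding mixes lifetime distributions, binned
#' lifetimes are not expected to be normal; this screens each group
#' before falling back to nonparametric tests.
#'
#' @param groups Named list of numeric vectors (e.g. lifetimes per 10 pN
#'   force bin).
#' @param alpha Significance level for the non-normal flag (default
#'   0.05).
#' @return Data.frame: `group`, `n`, `W`, `p`, `non_normal`, `skipped`
#'   (reason, empty when tested). Groups with n < 3 are skipped; groups
#'   beyond the test's 5000-sample limit are thinned to evenly spaced
#'   order statistics.
#' @export
normality_screen <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups))
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  out <- lapply(names(groups), function(g) {
    x <- groups[[g]][!is.na(groups[[g]])]
    n <- length(x)
    if (n < 3)
      return(data.frame(group = g, n = n, W = NA_real_, p = NA_real_,
                        non_normal = NA, skipped = "fewer_than_3"))
    if (length(unique(x)) == 1)
      return(data.frame(group = g, n = n, W = NA_real_, p = NA_real_,
                        non_normal = NA, skipped = "constant"))
    if (n > 5000) x <- sort(x)[round(seq(1, n, length.out = 5000))]
    sw <- stats::shapiro.test(x)
    data.frame(group = g, n = n, W = unname(sw$statistic), p = sw$p.value,
               non_normal = sw$p.value < alpha, skipped = "")
  })
  do.call(rbind, out)
}

# Dunn's post-hoc z statistics on pooled mid-ranks with tie-corrected
# variance. No pre-installed package provides Dunn's test, so the
# standard formulas are implemented here.
dunn_pairwise <- function(groups) {
  k <- length(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  r <- rank(x)
  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- as.numeric(lengths(groups))
  p <- z <- matrix(NA_real_, k, k, dimnames = list(names(groups),
                                                   names(groups)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
      zij <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
      z[i, j] <- z[j, i] <- zij
      p[i, j] <- p[j, i] <- 2 * stats::pnorm(-abs(zij))
    }
  }
  list(z = z, p = p)
}

#' Sidak adjustment of p-values
#'
#' p_adj = 1 - (1 - p)^m, monotone in p.
#'
#' @param p P-values.
#' @param m Number of comparisons (default `length(p)`).
#' @return Adjusted p-values, capped at 1.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  pmin(1 - (1 - p)^m, 1)
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb over the groups ordered by their summary statistic:
#' two groups share a letter iff their adjusted p-value exceeds alpha.
#'
#' @param p_matrix Symmetric matrix of (adjusted) pairwise p-values with
#'   group names.
#' @param order_stat Named numeric used to order groups (e.g. mean
#'   ranks); defaults to the column order.
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter codes.
#' @export
letter_display <- function(p_matrix, order_stat = NULL, alpha = 0.05) {
  gn <- colnames(p_matrix)
  k <- length(gn)
  if (is.null(order_stat)) order_stat <- stats::setNames(seq_len(k), gn)
  ord <- names(sort(order_stat))
  sig <- function(a, b) !is.na(p_matrix[a, b]) && p_matrix[a, b] <= alpha
  cols <- list(ord)  # start: one column holding every group
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- ord[i]; b <- ord[j]
      if (!sig(a, b)) next
      for (ci in seq_along(cols)) {
        if (all(c(a, b) %in% cols[[ci]])) {
          cols[[length(cols) + 1]] <- setdiff(cols[[ci]], a)
          cols[[ci]] <- setdiff(cols[[ci]], b)
        }
      }
      # absorb columns that are subsets of others
      keep <- rep(TRUE, length(cols))
      for (ci in seq_along(cols)) {
        for (cj in seq_along(cols)) {
          if (ci != cj && keep[ci] && keep[cj] &&
              all(cols[[ci]] %in% cols[[cj]])) keep[ci] <- FALSE
        }
      }
      cols <- cols[keep]
    }
  }
  # order columns by first member, assign letters
  first_pos <- vapply(cols, function(cl) min(match(cl, ord)), numeric(1))
  cols <- cols[order(first_pos)]
  letters_out <- stats::setNames(rep("", k), gn)
  for (ci in seq_along(cols)) {
    for (g in cols[[ci]]) {
      letters_out[g] <- paste0(letters_out[g], letters[ci])
    }
  }
  letters_out
}

#' Kruskal-Wallis omnibus with Dunn's Sidak-adjusted post hoc
#'
#' Two-sided throughout. All-identical data across groups yields an
#' omnibus p of 1 by convention (the rank statistic is degenerate).
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List of class `kruskal_dunn`: `omnibus_p`, `omnibus_stat`,
#'   `pairwise` (symmetric Sidak-adjusted p matrix), `pairwise_raw`,
#'   `z`, `letters` (shared letters mark the absence of significant
#'   differences), `m` (number of comparisons).
#' @export
kruskal_dunn <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1) {
    k <- length(groups)
    pmat <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
    diag(pmat) <- NA
    return(structure(list(omnibus_p = 1, omnibus_stat = 0, pairwise = pmat,
                          pairwise_raw = pmat, z = pmat * 0,
                          letters = letter_display(pmat, alpha = alpha),
                          m = choose(k, 2)),
                     class = "kruskal_dunn"))
  }
  kw <- stats::kruskal.test(groups)
  dn <- dunn_pairwise(groups)
  m <- choose(length(groups), 2)
  padj <- sidak_adjust(dn$p, m)
  # mean pooled ranks, used to order groups in the letter display
  g <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(rank(x), g, mean)
  names(rbar) <- names(groups)
  structure(
    list(omnibus_p = kw$p.value, omnibus_stat = unname(kw$statistic),
         pairwise = padj, pairwise_raw = dn$p, z = dn$z,
         letters = letter_display(padj, order_stat = rbar, alpha = alpha),
         m = m),
    class = "kruskal_dunn"
  )
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis p = %.4g; Dunn pairwise (Sidak, m = %d)\n",
              x$omnibus_p, x$m))
  print(round(x$pairwise, 4))
  cat("letters:", paste(names(x$letters), x$letters, sep = ":",
                        collapse = "  "), "\n")
  invisible(x)
}

#' Kruskal-Wallis omnibus with pairwise Wilcoxon rank-sum tests
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @param p_adjust Adjustment method passed to [stats::p.adjust()]
#'   (default "none": the pairwise tests are reported raw).
#' @return List: `omnibus_p`, `pairwise` (symmetric p matrix).
#' @export
kruskal_wilcoxon_pairwise <- function(groups, p_adjust = "none") {
  stopifnot(is.list(groups))
  if (length(groups) < 2) stop("at least 2 groups are required")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  k <- length(groups)
  p <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      w <- suppressWarnings(stats::wilcox.test(groups[[i]], groups[[j]]))
      p[i, j] <- p[j, i] <- w$p.value
    }
  }
  p[] <- stats::p.adjust(p, method = p_adjust)
  list(omnibus_p = kw$p.value, pairwise = p)
}

#' Fit the Hill equation to titration data
#'
#' signal = baseline + bmax c^n / (kd^n + c^n), fitted by
#' Levenberg-Marquardt least squares with the Hill coefficient bounded
#' to 0.5-4 and initialised over a log grid. Standard errors come
#' from the fit covariance.
#'
#' @param titration Data.frame with columns `concentration_nM` and
#'   `signal` (replicates as extra rows).
#' @param hill_bounds Bounds on the Hill coefficient (default
#'   `c(0.5, 4)`).
#' @param n_grid Number of log-spaced initial Hill coefficients
#'   (default 7).
#' @return List of class `hill_fit`: `kd` (nM), `hill_n`, `bmax`,
#'   `baseline`, `se` (named vector), `ssr`, `fitted`.
#' @export
fit_hill <- function(titration, hill_bounds = c(0.5, 4), n_grid = 7) {
  stopifnot(is.data.frame(titration),
            all(c("concentration_nM", "signal") %in% names(titration)))
  conc <- titration$concentration_nM
  sig <- titration$signal
  if (length(unique(conc)) < 5)
    stop("at least 5 distinct concentrations are required")
  if (stats::sd(sig) == 0 || all(sig == 0))
    stop("signal carries no information: Hill fit unidentifiable")
  span <- max(sig) - min(sig)
  half <- min(sig) + span / 2
  kd0 <- conc[which.min(abs(sig - half))]
  if (kd0 <= 0) kd0 <- stats::median(conc)
  best <- NULL
  for (n0 in exp(seq(log(hill_bounds[1]), log(hill_bounds[2]),
                     length.out = n_grid))) {
    fit <- try(minpack.lm::nlsLM(
      sig ~ baseline + bmax * conc^n / (kd^n + conc^n),
      start = list(baseline = min(sig), bmax = span, kd = kd0, n = n0),
      lower = c(-Inf, 0, min(conc) / 1e3, hill_bounds[1]),
      upper = c(Inf, Inf, max(conc) * 1e3, hill_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      ssr <- sum(stats::resid(fit)^2)
      if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
    }
  }
  if (is.null(best))
    stop("Hill fit failed to converge over the initialisation grid")
  co <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  structure(
    list(kd = unname(co["kd"]), hill_n = unname(co["n"]),
         bmax = unname(co["bmax"]), baseline = unname(co["baseline"]),
         se = se, ssr = best$ssr, fitted = stats::fitted(best$fit)),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> KD = %.4g nM, n = %.3g, bmax = %.4g, baseline = %.4g\n",
              x$kd, x$hill_n, x$bmax, x$baseline))
  invisible(x)
}
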