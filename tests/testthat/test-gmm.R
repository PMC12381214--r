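trimodal <- function(n = 600, seed = 1) {
  set.seed(seed)
  c(stats::rnorm(round(0.40 * n), 35, 6),
    stats::rnorm(round(0.35 * n), 110, 15),
    stats::rnorm(round(0.25 * n), 420, 40))
}

test_that("force preprocessing is a standardised sqrt transform with exact inverse", {
  pp <- preprocess_forces(c(4))
  expect_equal(pp$z, 0)
  f <- trimodal(400, 3)
  pp <- preprocess_forces(f)
  expect_equal(mean(pp$z), 0, tolerance = 1e-12)
  expect_equal(stats::var(pp$z), 1, tolerance = 1e-12)
  expect_equal(invert_forces(pp$z, pp), f, tolerance = 1e-9)
  expect_error(preprocess_forces(numeric(0)), "empty")
  expect_error(preprocess_forces(c(1, -2)), "> 0")
})

test_that("mixture selection recovers the generating component count and weights", {
  g <- fit_pathway_gmm(trimodal(600, 1))
  expect_equal(g$n_components, 3)
  expect_true(all(abs(g$weights - c(0.40, 0.35, 0.25)) <= 0.05))
  expect_true(all(diff(g$means) > 0))  # canonical ascending order
  expect_equal(rowSums(g$responsibilities), rep(1, 600), tolerance = 1e-9)
  # weights recovered across seeds
  ws <- sapply(1:10, function(s) {
    gg <- fit_pathway_gmm(trimodal(600, s))
    if (gg$n_components == 3) gg$weights else rep(NA, 3)
  })
  expect_gte(sum(!is.na(ws[1, ])), 8)
  expect_true(all(abs(ws[, !is.na(ws[1, ])] - c(0.40, 0.35, 0.25)) <= 0.05))
  # unimodal data selects one component
  set.seed(2)
  expect_equal(fit_pathway_gmm(stats::rnorm(300, 60, 5))$n_components, 1)
  # two well-separated modes: two components, means within 5%
  set.seed(4)
  f2 <- c(stats::rnorm(300, 40, 5), stats::rnorm(300, 300, 30))
  g2 <- fit_pathway_gmm(f2)
  expect_equal(g2$n_components, 2)
  expect_true(all(abs(g2$means_pN / c(40, 300) - 1) < 0.05))
  expect_error(fit_pathway_gmm(stats::rnorm(10, 50)), "30")
})

test_that("classification accuracy exceeds 95% for separated pathways", {
  n <- c(240, 210, 150)
  truth <- rep(c("P0", "P1", "P2"), n)
  g <- fit_pathway_gmm(trimodal(600, 6))
  g <- reclassify_fourth_component(g)
  asn <- pathway_assignments(g)
  expect_gte(mean(asn$pathway == truth), 0.95)
})

test_that("fourth-component reclassification folds the minor mode into its parent", {
  g3 <- fit_pathway_gmm(trimodal(600, 1))
  expect_identical(reclassify_fourth_component(g3), g3)  # no-op at 3
  # force a 4-component fit on 3-mode data: reclassification keeps accuracy
  g4 <- fit_pathway_gmm(trimodal(900, 9), G = 4)
  expect_equal(g4$n_components, 4)
  r <- reclassify_fourth_component(g4)
  expect_equal(r$n_components, 3)
  expect_true(r$reclassified)
  expect_equal(rowSums(r$responsibilities), rep(1, 900), tolerance = 1e-9)
  truth <- rep(c("P0", "P1", "P2"), round(c(0.40, 0.35, 0.25) * 900))
  asn <- pathway_assignments(r)
  expect_gte(mean(asn$pathway == truth), 0.95)
})

test_that("pathway proportions aggregate with SEM across experiments", {
  asn <- data.frame(
    pathway = c(rep("P0", 6), rep("P1", 4), rep("P0", 8), rep("P1", 2)),
    pulling_speed = 1600,
    experiment = rep(c("e1", "e2"), each = 10))
  pp <- pathway_proportions(asn)
  p0 <- pp[pp$pathway == "P0", ]
  expect_equal(p0$proportion, 0.7)
  expect_equal(p0$sem, 0.1)
  # proportions sum to one within experiment and speed
  expect_equal(sum(pp$proportion), 1, tolerance = 1e-12)
  # single experiment: SEM undefined
  one <- pathway_proportions(asn[asn$experiment == "e1", ])
  expect_true(all(is.na(one$sem)))
  expect_equal(one$proportion[one$pathway == "P0"], 0.6)
  # all-P0 experiment
  all0 <- pathway_proportions(data.frame(pathway = "P0",
                                         pulling_speed = 800,
                                         experiment = "e1"))
  expect_equal(all0$proportion[all0$pathway == "P0"], 1)
})

test_that("speed-dependent mixtures yield a monotone recovered trend", {
  speeds <- c(800, 1600, 3200, 6400)
  w0 <- seq(0.7, 0.25, length.out = 4)  # P0 weight falls with log speed
  asn <- do.call(rbind, lapply(1:2, function(e) {
    do.call(rbind, lapply(seq_along(speeds), function(i) {
      set.seed(100 * e + i)
      n <- 200
      n0 <- round(w0[i] * n)
      data.frame(pathway = c(rep("P0", n0), rep("P1", n - n0)),
                 pulling_speed = speeds[i],
                 experiment = paste0("e", e))
    }))
  }))
  pp <- pathway_proportions(asn)
  p0 <- pp[pp$pathway == "P0", ]
  p0 <- p0[order(p0$pulling_speed), ]
  expect_true(all(diff(p0$proportion) < 0))
})
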