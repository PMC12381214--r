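test_that("normality screen has the right size and power", {
  # size: standard-normal groups flagged normal in >= 93% of runs
  flags <- vapply(1:100, function(s) {
    set.seed(s)
    normality_screen(list(g = stats::rnorm(1000)))$non_normal
  }, logical(1))
  expect_gte(mean(!flags), 0.93)
  # power: well-separated bimodal mixture flagged in >= 99%
  flags2 <- vapply(1:100, function(s) {
    set.seed(s)
    x <- c(stats::rnorm(500, -2, 1), stats::rnorm(500, 2, 1))
    normality_screen(list(g = x))$non_normal
  }, logical(1))
  expect_gte(mean(flags2), 0.99)
  # tiny groups are skipped with a reason
  out <- normality_screen(list(a = c(1, 2), b = stats::rnorm(10)))
  expect_identical(out$skipped[out$group == "a"], "fewer_than_3")
  expect_identical(out$skipped[out$group == "b"], "")
})

test_that("Kruskal-Wallis + Dunn controls size and detects shifts", {
  # type-I error of the omnibus near 5% under the null
  rej <- vapply(1:400, function(s) {
    set.seed(s)
    g <- list(a = stats::rnorm(30), b = stats::rnorm(30),
              c = stats::rnorm(30))
    kruskal_dunn(g)$omnibus_p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
  # strong shifts: all pairs significant, all letters distinct
  set.seed(1)
  g <- list(a = stats::rnorm(40), b = stats::rnorm(40) + 3,
            c = stats::rnorm(40) + 6)
  kd <- kruskal_dunn(g)
  expect_lt(kd$omnibus_p, 1e-6)
  off_diag <- kd$pairwise[upper.tri(kd$pairwise)]
  expect_true(all(off_diag < 0.05))
  expect_equal(length(unique(kd$letters)), 3)
  expect_true(isSymmetric(kd$pairwise))
  # identical groups share a letter; all-identical data gives p = 1
  same <- kruskal_dunn(list(a = rep(2, 10), b = rep(2, 10)))
  expect_equal(same$omnibus_p, 1)
  expect_identical(unname(same$letters["a"]), unname(same$letters["b"]))
})

test_that("Sidak adjustment follows its closed form and stays monotone", {
  p <- c(0.01, 0.04, 0.2)
  expect_equal(sidak_adjust(p, 3), 1 - (1 - p)^3)
  expect_true(all(diff(sidak_adjust(sort(stats::runif(20)), 20)) >= 0))
  expect_lte(max(sidak_adjust(0.9, 50)), 1)
})

test_that("pairwise Wilcoxon protocol reports raw rank-sum p-values", {
  expect_error(kruskal_wilcoxon_pairwise(list(a = 1:5)), "2 groups")
  # identical distributions: pairwise p > 0.05 in most seeded runs
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    kw <- kruskal_wilcoxon_pairwise(list(a = stats::rnorm(30),
                                         b = stats::rnorm(30)))
    kw$pairwise["a", "b"] > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  # a 1.5 sd shift at n = 50 is detected with >= 80% power
  power <- vapply(1:100, function(s) {
    set.seed(s)
    kw <- kruskal_wilcoxon_pairwise(list(a = stats::rnorm(50),
                                         b = stats::rnorm(50) + 1.5))
    kw$pairwise["a", "b"] < 0.05
  }, logical(1))
  expect_gte(mean(power), 0.80)
})

test_that("letter display marks exactly the non-significant pairs as shared", {
  p <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p["a", "c"] <- p["c", "a"] <- 0.01
  diag(p) <- NA
  lt <- letter_display(p, order_stat = c(a = 1, b = 2, c = 3))
  share <- function(x, y) length(intersect(strsplit(lt[[x]], "")[[1]],
                                           strsplit(lt[[y]], "")[[1]])) > 0
  expect_true(share("a", "b"))
  expect_true(share("b", "c"))
  expect_false(share("a", "c"))
})

test_that("Hill fitting recovers the dissociation constant", {
  # noiseless: exact recovery
  tt <- generate_hill_titration(45, noise_sd = 0, replicates = 1)
  fit <- fit_hill(tt)
  expect_lt(abs(fit$kd - 45) / 45, 1e-6)
  expect_equal(fit$hill_n, 1, tolerance = 1e-4)
  # 5% noise on the 7-point 5-fold design: within 20% over seeds
  errs <- vapply(1:100, function(s) {
    tt <- generate_hill_titration(45, noise_sd = 0.05, seed = s)
    abs(fit_hill(tt)$kd - 45) / 45
  }, numeric(1))
  expect_lt(stats::median(errs), 0.20)
  expect_gte(mean(errs <= 0.20), 0.8)
  # degenerate input is refused
  flat <- data.frame(concentration_nM = c(1, 5, 25, 125, 625),
                     signal = rep(0, 5))
  expect_error(fit_hill(flat), "unidentifiable")
  expect_error(fit_hill(data.frame(concentration_nM = c(1, 2, 4),
                                   signal = c(0, 1, 2))), "5 distinct")
})
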