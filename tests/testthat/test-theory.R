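test_that("one-species error rates match the incomplete-gamma closed form", {
  r <- one_species_error(1, 5, e = 3)
  # Gamma(2,1): F(x) = 1 - (1+x) exp(-x); alpha = 2 log 5 / 4
  a <- 2 * log(5) / 4
  expect_equal(r$alpha, a)
  expect_equal(r$p01, (1 + 5 * a) * exp(-5 * a), tolerance = 1e-12)
  expect_equal(r$p10, 1 - (1 + a) * exp(-a), tolerance = 1e-12)
  expect_equal(round(100 * r$p01), 9)
  expect_equal(round(100 * r$p10), 19)
  expect_equal(r$gen_error, (r$p01 + r$p10) / 2)

  # dropping the (e-1) factor in alpha would instead give ~40% and ~6%,
  # far from the reference rates: the factor is load-bearing
  a0 <- log(5) / 4
  expect_equal(round(100 * (1 + 5 * a0) * exp(-5 * a0)), 40)
  expect_equal(round(100 * (1 - (1 + a0) * exp(-a0))), 6)
})

test_that("equal scales give a coin-flip classifier", {
  r <- one_species_error(2, 2, e = 3)
  expect_identical(r$gen_error, 0.5)
  expect_error(one_species_error(5, 1, e = 3), "swap")
})

test_that("estimation error widens the intervals around the point rates", {
  r0 <- one_species_error(1, 5, e = 3, epsilon = 0)
  r5 <- one_species_error(1, 5, e = 3, epsilon = 0.5)
  expect_equal(r0$interval01, rep(r0$p01, 2))
  expect_gte(r0$p01, r5$interval01[1]); expect_lte(r0$p01, r5$interval01[2])
  expect_gte(r0$p10, r5$interval10[1]); expect_lte(r0$p10, r5$interval10[2])
  expect_gt(diff(r5$interval01), diff(r0$interval01))
  expect_gt(diff(r5$interval10), diff(r0$interval10))
})

test_that("the more dispersed class is misclassified more often", {
  for (e in c(3, 5, 9))
    for (s1 in c(1.5, 3, 8)) {
      r <- one_species_error(1, s1, e = e)
      expect_lt(r$p01, r$p10)
    }
})

test_that("empirical error of the exact classifier matches the formula", {
  r <- one_species_error(1, 5, e = 3)
  cc <- (3 - 1) * log(5 / 1) / (1 - 1 / 5)       # threshold from the link
  set.seed(104)
  n <- 20000
  d0 <- apply(rtroplap(n, e = 3, sigma = 1), 1, trop_dist, w = c(0, 0, 0))
  d1 <- apply(rtroplap(n, e = 3, sigma = 5), 1, trop_dist, w = c(0, 0, 0))
  p01_hat <- mean(d0 >= cc)
  p10_hat <- mean(d1 < cc)
  expect_lt(abs(p01_hat - r$p01), 3 * sqrt(r$p01 * (1 - r$p01) / n))
  expect_lt(abs(p10_hat - r$p10), 3 * sqrt(r$p10 * (1 - r$p10) / n))
})

test_that("two-species bound: closed form, limits, monotonicity", {
  expect_equal(as.numeric(two_species_error_bound(0.5, 3, separation = 0)),
               0.5)
  # Gamma(2, 3)/2 = (1+3) e^{-3} / 2
  expect_equal(two_species_error_bound(0.5, 3, separation = 3),
               2 * exp(-3), tolerance = 1e-12, ignore_attr = TRUE)
  seps <- seq(0, 6, by = 0.5)
  vals <- sapply(seps, function(s) two_species_error_bound(0.5, 3, s))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals >= 0 & vals <= 0.5))
  expect_warning(v <- two_species_error_bound(0.5, 3, 1, epsilon = 2),
                 "vacuous")
  expect_equal(as.numeric(v), 0.5)
  expect_warning(two_species_error_bound(0.5, 3, 3, epsilon = 0.5),
                 "partial")
})

test_that("distance-law fits recover scale and prefer the true family", {
  expect_equal(fit_distance_law(rep(2, 10), e = 3)$sigma_hat, 1)

  set.seed(105)
  d <- apply(rtroplap(2000, e = 3, sigma = 2), 1, trop_dist, w = c(0, 0, 0))
  lap <- fit_distance_law(d, e = 3, geometry = "tropical", family = "laplace")
  expect_equal(lap$sigma_hat, 2, tolerance = 0.1)
  gau <- fit_distance_law(d, e = 3, geometry = "tropical", family = "gaussian")
  expect_lt(lap$ks_stat, gau$ks_stat)
  expect_equal(lap$dof, 2)
  expect_equal(fit_distance_law(d, e = 3, geometry = "euclidean")$dof, 3)
  expect_error(fit_distance_law(c(1, -1), e = 3), "positive")
})

test_that("AUC equals the brute-force Mann-Whitney probability", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 1, 0, 0))$auc, 0)
  s <- c(1, 2, 2, 3); y <- c(0, 1, 0, 1)
  expect_equal(roc_auc(s, y)$auc, brute_auc(s, y))

  set.seed(106)
  for (rep in 1:10) {
    sc <- sample(1:6, 30, replace = TRUE)   # heavy ties
    yy <- rbinom(30, 1, 0.5)
    if (length(unique(yy)) < 2) next
    expect_equal(roc_auc(sc, yy)$auc, brute_auc(sc, yy))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC equals the trapezoidal area under its own ROC curve", {
  set.seed(107)
  sc <- sample(1:8, 60, replace = TRUE)
  yy <- rbinom(60, 1, 0.4)
  r <- roc_auc(sc, yy)
  trap <- sum(diff(r$roc$fpr) * (head(r$roc$tpr, -1) + tail(r$roc$tpr, -1)) / 2)
  expect_equal(r$auc, trap, tolerance = 1e-12)
})

test_that("AUC agrees with the independent pROC implementation", {
  set.seed(108)
  sc <- rnorm(80); yy <- rbinom(80, 1, 0.5)
  expect_equal(roc_auc(sc, yy)$auc,
               as.numeric(pROC::auc(yy, sc, direction = "<",
                                    levels = c(0, 1), quiet = TRUE)),
               tolerance = 1e-12)
})
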