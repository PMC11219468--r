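test_that("general link reduces to the one- and two-species forms", {
  set.seed(12)
  for (rep in 1:10) {
    e <- sample(3:6, 1)
    x <- rnorm(e); w0 <- rnorm(e); w1 <- rnorm(e)
    s0 <- runif(1, 0.2, 2); s1 <- runif(1, 0.2, 2)
    # same centers, same scales: indistinguishable classes
    expect_equal(trop_h(x, w0, w0, s0, s0), 0)
    # shared scale: two-species form
    expect_equal(trop_h(x, w0, w1, s0, s0),
                 (trop_dist(x, w0) - trop_dist(x, w1)) / s0,
                 tolerance = 1e-12)
    # shared center: one-species form with the (e-1)-bearing threshold
    lambda <- 1 / s0 - 1 / s1
    cc <- (e - 1) * log(s1 / s0) / lambda
    expect_equal(trop_h(x, w0, w0, s0, s1),
                 lambda * (trop_dist(x, w0) - cc), tolerance = 1e-12)
  }
})

test_that("the one-species boundary solves h = 0 at the tropical circle", {
  # sigma0 = 1, sigma1 = 5, e = 3: threshold 2 log(5) / 0.8
  cc <- 2 * log(5) / (1 - 1 / 5)
  w <- c(0, 0, 0)
  x_on <- c(cc, 0, 0)            # d_tr(x, w) = cc exactly
  expect_equal(trop_h(x_on, w, w, 1, 5), 0, tolerance = 1e-12)
  expect_equal(cc, 4.0236, tolerance = 1e-4)
})

test_that("predicted probabilities follow the logistic link", {
  w0 <- c(0, 0, 0); w1 <- c(3, 2, 0)
  fit <- list(model = "two-species", center0 = w0, center1 = w1,
              sigma = 0.5, e = 3L, n = 0L, fitted = NULL)
  class(fit) <- "tlr"
  # at x = w0: h = (0 - d(w0, w1))/sigma = -3/0.5 = -6
  expect_equal(predict(fit, rbind(w0), type = "response"), plogis(-6))
  expect_equal(plogis(-6), 0.00247, tolerance = 5e-3)
  # at x = w1 the own-center pull wins
  expect_gt(predict(fit, rbind(w1), type = "response"), 0.5)
  # h = 0 maps to probability 1/2 and (by the tie rule) class 1
  mid <- rbind(c(1.5, 1.5, 0))   # d to both centers equal? verify via link
  h <- predict(fit, mid, type = "link")
  expect_equal(predict(fit, mid, type = "response"), plogis(h))
  expect_equal(predict(fit, rbind(w0), type = "class"), 0L)
  expect_equal(predict(fit, rbind(w1), type = "class"), 1L)
})

test_that("two-species fit recovers the generating parameters", {
  s <- toy_dataset("two-species", n_per_class = 500, seed = 91)
  fit <- tlr(s$x, s$y)
  expect_lt(trop_dist(fit$center0, c(0, 0, 0)), 0.5)
  expect_lt(trop_dist(fit$center1, c(3, 2, 0)), 0.5)
  expect_lt(abs(fit$sigma - 0.5), 0.2)

  # swapping the labels swaps the centers and keeps sigma
  fit2 <- tlr(s$x, 1L - s$y)
  expect_equal(fit2$center0, fit$center1)
  expect_equal(fit2$center1, fit$center0)
  expect_equal(fit2$sigma, fit$sigma, tolerance = 1e-6)
  expect_equal(fit2$fitted, -fit$fitted, tolerance = 1e-6)
})

test_that("mean log-likelihood is coherent with the predictions", {
  s <- toy_dataset("two-species", n_per_class = 40, seed = 92)
  fit <- tlr(s$x, s$y)
  p <- predict(fit, s$x, type = "response")
  expect_equal(fit$logLik,
               mean(s$y * log(p) + (1 - s$y) * log(1 - p)),
               tolerance = 1e-9)
  expect_lt(fit$logLik, 0)
  expect_equal(as.numeric(logLik(fit)), fit$logLik * fit$n)
  # an uninformative model scores log(1/2) per point
  expect_equal(mean(0.5 * log(0.5) + 0.5 * log(0.5)), log(0.5))
})

test_that("joint MLE fit runs and is no better than its own likelihood bound", {
  s <- toy_dataset("two-species", n_per_class = 50, seed = 93)
  fw_fit <- tlr(s$x, s$y, method = "fw")
  mle_fit <- tlr(s$x, s$y, method = "mle", mle_starts = 3, seed = 94)
  expect_s3_class(mle_fit, "tlr")
  # the joint MLE maximizes the same objective the fw pipeline evaluates
  expect_gte(mle_fit$logLik, fw_fit$logLik - 1e-6)
})

test_that("one-species fit recovers the decision radius", {
  s <- toy_dataset("one-species", n_per_class = 1000, seed = 95)
  fit <- tlr(s$x, s$y, model = "one-species")
  expect_gt(fit$rate, 0)
  expect_gt(fit$threshold, 3.0)    # population value ~4.02
  expect_lt(fit$threshold, 5.0)
  expect_lt(trop_dist(fit$center, c(0, 0, 0)), 0.6)

  # a point exactly at the fitted radius has probability 1/2
  x_on <- fit$center + c(fit$threshold, 0, 0)
  expect_equal(predict(fit, rbind(x_on), type = "response"), 0.5,
               tolerance = 1e-9)

  # inverted labels trigger the documented swap and flip predictions
  expect_warning(fit_sw <- tlr(s$x, 1L - s$y, model = "one-species"),
                 "swapped")
  expect_true(fit_sw$label_swap)
  expect_equal(predict(fit_sw, s$x[1:10, ], type = "response"),
               1 - predict(fit, s$x[1:10, ], type = "response"),
               tolerance = 0.05)
})

test_that("classical baseline cannot see concentric tropical classes", {
  s <- toy_dataset("one-species", n_per_class = 300, seed = 96)
  trop <- tlr(s$x, s$y, model = "one-species")
  classical <- tlr(s$x, s$y, model = "classical")
  auc_t <- roc_auc(predict(trop), s$y)$auc
  auc_c <- roc_auc(predict(classical), s$y)$auc
  expect_gt(auc_t, 0.8)
  expect_lt(abs(auc_c - 0.5), 0.12)
  # deterministic given the data
  expect_identical(coef(tlr(s$x, s$y, model = "classical")), coef(classical))
})

test_that("classical baseline flags separation with a bounded fallback", {
  x <- rbind(matrix(c(0, 0, 0), 5, 3, byrow = TRUE) + runif(15, 0, 0.1),
             matrix(c(9, 0, 0), 5, 3, byrow = TRUE) + runif(15, 0, 0.1))
  y <- rep(0:1, each = 5)
  expect_warning(fit <- tlr(x, y, model = "classical"), "separation")
  expect_lte(max(abs(predict(fit, x))), 30 + 1e-6)
})

test_that("model serialization round-trips predictions", {
  s <- toy_dataset("two-species", n_per_class = 30, seed = 97)
  for (model in c("two-species", "one-species", "classical")) {
    fit <- suppressWarnings(tlr(s$x, s$y, model = model))
    fn <- tempfile(fileext = ".json")
    write_tlr(fit, fn)
    back <- read_tlr(fn)
    expect_equal(predict(back, s$x), predict(fit, s$x), tolerance = 1e-12)
  }
})

test_that("simulate() regenerates data matching the fitted law", {
  s <- toy_dataset("two-species", n_per_class = 400, seed = 98)
  fit <- tlr(s$x, s$y)
  sim <- simulate(fit, nsim = 2000, seed = 99)
  d0 <- apply(sim$x[sim$y == 0, ], 1, trop_dist, w = fit$center0)
  expect_equal(mean(d0), 2 * fit$sigma, tolerance = 0.1)
  # one-species inversion lambda, c -> sigma0, sigma1 (vignette identity)
  fit1 <- tlr(s$x, s$y, model = "one-species")
  expect_s3_class(fit1, "tlr")
  r <- residuals(fit)
  expect_length(r, fit$n)
  expect_true(all(is.finite(r)))
})
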