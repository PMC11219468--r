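#' @export
print.tlr <- function(x, ...) {
  cat("Tropical logistic regression (", x$model, ", ", x$method, " fit)\n",
      sep = "")
  cat("  n = ", x$n, ", e = ", x$e, "\n", sep = "")
  if (x$model == "two-species") {
    cat("  sigma:", format(x$sigma, digits = 4), "\n")
    cat("  center separation d_tr(w0, w1):",
        format(trop_dist(x$center0, x$center1), digits = 4), "\n")
  } else if (x$model == "one-species") {
    cat("  rate lambda:", format(x$rate, digits = 4),
        " threshold c:", format(x$threshold, digits = 4), "\n")
    if (x$label_swap) cat("  (labels swapped internally: class 0 is the ",
                          "more dispersed class)\n", sep = "")
  } else {
    cat("  coefficients (canonical coordinates):\n")
    print(round(x$coefficients, 4))
  }
  cat("  mean log-likelihood:", format(x$logLik, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.tlr <- function(object, ...) {
  cls <- as.integer(object$fitted >= 0)
  out <- list(fit = object,
              confusion = table(observed = object$y, predicted = cls),
              accuracy = mean(cls == object$y),
              auc = roc_auc(object$fitted, object$y)$auc)
  class(out) <- "summary.tlr"
  out
}

#' @export
print.summary.tlr <- function(x, ...) {
  print(x$fit)
  cat("\nTraining confusion matrix (h >= 0 -> class 1):\n")
  print(x$confusion)
  cat("accuracy:", format(x$accuracy, digits = 4),
      "  AUC:", format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.tlr <- function(object, ...) {
  switch(object$model,
    "two-species" = c(sigma = object$sigma,
                      stats::setNames(object$center0,
                        paste0("center0.", seq_along(object$center0))),
                      stats::setNames(object$center1,
                        paste0("center1.", seq_along(object$center1)))),
    "one-species" = c(rate = object$rate, threshold = object$threshold,
                      stats::setNames(object$center,
                        paste0("center.", seq_along(object$center)))),
    "classical" = object$coefficients)
}

#' Predict from a tropical logistic regression fit
#'
#' @param object A fitted [tlr()] model.
#' @param newdata Matrix of row points or trees; defaults to the training
#'   log-odds.
#' @param type \code{"link"} (log-odds h), \code{"response"}
#'   (probability of class 1), or \code{"class"} (0/1; the tie h = 0 is
#'   assigned to class 1).
#' @param ... Unused.
#' @return Numeric (or integer for \code{"class"}) vector.
#' @export
predict.tlr <- function(object, newdata = NULL,
                        type = c("link", "response", "class"), ...) {
  type <- match.arg(type)
  h <- if (is.null(newdata)) object$fitted else {
    X <- .point_matrix(newdata)
    if (ncol(X) != object$e)
      stop("newdata has e = ", ncol(X), " but model expects e = ", object$e)
    switch(object$model,
      "two-species" = trop_h(X, object$center0, object$center1,
                             object$sigma, object$sigma),
      "one-species" = {
        hs <- object$rate * (.trop_dist_rows(X, object$center) -
                               object$threshold)
        if (object$label_swap) -hs else hs
      },
      "classical" = {
        Z <- X[, -ncol(X), drop = FALSE] - X[, ncol(X)]
        drop(cbind(1, Z) %*% object$coefficients)
      })
  }
  switch(type,
         link = h,
         response = stats::plogis(h),
         class = as.integer(h >= 0))
}

#' @export
logLik.tlr <- function(object, ...) {
  # Eq.-style mean Bernoulli log-likelihood times n, standard logLik scale
  structure(object$logLik * object$n,
            df = switch(object$model,
                        "two-species" = 2 * (object$e - 1) + 1,
                        "one-species" = (object$e - 1) + 2,
                        "classical" = object$e),
            nobs = object$n, class = "logLik")
}

#' @export
residuals.tlr <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  p <- stats::plogis(object$fitted)
  if (type == "response") return(object$y - p)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sign(object$y - p) *
    sqrt(-2 * (object$y * log(p) + (1 - object$y) * log1p(-p)))
}

#' Simulate labeled samples from a fitted tropical model
#'
#' Draws balanced class labels and covariates from the generative model
#' implied by the fit (tropical Laplace class conditionals). Not available
#' for the classical baseline.
#'
#' @param object A fitted [tlr()] model (one- or two-species).
#' @param nsim Number of points to draw (split evenly between classes).
#' @param seed Optional seed, passed to [set.seed()].
#' @param ... Unused.
#' @return List with matrix \code{x} and labels \code{y}.
#' @export
simulate.tlr <- function(object, nsim = object$n, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n1 <- nsim %/% 2L
  n0 <- nsim - n1
  if (object$model == "two-species") {
    x <- rbind(rtroplap(n0, object$center0, object$sigma),
               rtroplap(n1, object$center1, object$sigma))
  } else if (object$model == "one-species") {
    # rate/threshold encode the scale ratio; recover sigma0, sigma1 from
    # lambda = 1/s0 - 1/s1 and lambda*c = (e-1) log(s1/s0)
    ss <- .sigmas_from_rate(object$rate, object$threshold, object$e)
    if (object$label_swap) ss <- rev(ss)
    x <- rbind(rtroplap(n0, object$center, ss[1L]),
               rtroplap(n1, object$center, ss[2L]))
  } else stop("simulate() is not defined for the classical baseline")
  list(x = x, y = rep(c(0L, 1L), c(n0, n1)))
}

# invert (lambda, c) -> (sigma0, sigma1) for the one-species model
.sigmas_from_rate <- function(rate, threshold, e) {
  ratio_log <- rate * threshold / (e - 1)      # log(s1/s0)
  rho <- exp(ratio_log)
  # rate = 1/s0 - 1/s1 = (rho - 1) / (rho * s0)
  s0 <- (rho - 1) / (rho * rate)
  c(s0, rho * s0)
}

#' Plot a tropical logistic regression fit
#'
#' For 3-leaf-scale data (\eqn{e = 3}) plots the training points in
#' canonical coordinates with the decision boundary \eqn{h = 0} as a
#' contour; for larger \eqn{e} plots per-class histograms of the fitted
#' log-odds.
#'
#' @param x A fitted [tlr()] model.
#' @param data Optional list with elements \code{x} and \code{y} to plot
#'   instead of the training data (the training covariates are not stored).
#' @param grid_n Grid resolution for the boundary contour.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tlr <- function(x, data = NULL, grid_n = 120L, ...) {
  object <- x
  if (object$e == 3L && !is.null(data)) {
    P <- .point_matrix(data$x)
    z1 <- P[, 1L] - P[, 3L]; z2 <- P[, 2L] - P[, 3L]
    graphics::plot(z1, z2, col = data$y + 1L, pch = c(1, 4)[data$y + 1L],
                   xlab = "x1 - x3", ylab = "x2 - x3", ...)
    g1 <- seq(min(z1), max(z1), length.out = grid_n)
    g2 <- seq(min(z2), max(z2), length.out = grid_n)
    gg <- as.matrix(expand.grid(g1, g2))
    H <- matrix(predict(object, cbind(gg, 0), type = "link"),
                grid_n, grid_n)
    graphics::contour(g1, g2, H, levels = 0, add = TRUE, lwd = 2,
                      drawlabels = FALSE)
  } else {
    h <- object$fitted
    br <- pretty(h, 30)
    h0 <- graphics::hist(h[object$y == 0L], breaks = br, plot = FALSE)
    h1 <- graphics::hist(h[object$y == 1L], breaks = br, plot = FALSE)
    graphics::plot(h0, col = grDevices::adjustcolor(1, 0.4),
                   xlab = "fitted log-odds h", main = "tlr fit", ...)
    graphics::plot(h1, col = grDevices::adjustcolor(2, 0.4), add = TRUE)
  }
  invisible(object)
}
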