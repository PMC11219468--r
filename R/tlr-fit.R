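#' General tropical logistic link
#'
#' The log-odds of class membership under tropical-Laplace class-conditional
#' distributions with centers \eqn{\omega_0, \omega_1} and scales
#' \eqn{\sigma_0, \sigma_1}:
#' \deqn{h(x) = d_{tr}(x,\omega_0)/\sigma_0 - d_{tr}(x,\omega_1)/\sigma_1
#'       + (e-1)\log(\sigma_0/\sigma_1).}
#' With \eqn{\omega_0 = \omega_1} this reduces to the one-species form
#' \eqn{\lambda(d_{tr}(x,\omega) - c)} with
#' \eqn{\lambda = \sigma_0^{-1} - \sigma_1^{-1}} and
#' \eqn{\lambda c = (e-1)\log(\sigma_1/\sigma_0)}; with
#' \eqn{\sigma_0 = \sigma_1 = \sigma} it reduces to the two-species form
#' \eqn{(d_{tr}(x,\omega_0) - d_{tr}(x,\omega_1))/\sigma}. The \eqn{(e-1)}
#' factor comes from the tropical Laplace normalizer \eqn{e!\sigma^{e-1}}
#' and is kept throughout (see the package vignette).
#'
#' @param x Point(s): vector or matrix of row points.
#' @param center0,center1 Class centers.
#' @param sigma0,sigma1 Positive class scales.
#' @return Numeric vector of log-odds.
#' @export
trop_h <- function(x, center0, center1, sigma0, sigma1) {
  if (sigma0 <= 0 || sigma1 <= 0) stop("scales must be positive")
  X <- .point_matrix(x)
  e <- ncol(X)
  c0 <- trop_canonical(as.numeric(center0))
  c1 <- trop_canonical(as.numeric(center1))
  if (length(c0) != e || length(c1) != e) stop("dimension mismatch")
  .trop_dist_rows(X, c0) / sigma0 - .trop_dist_rows(X, c1) / sigma1 +
    (e - 1) * log(sigma0 / sigma1)
}

# mean Bernoulli log-likelihood (negative cross-entropy) of log-odds h
.mean_loglik <- function(h, y, clamp = 1e-12, warn = FALSE) {
  p <- stats::plogis(h)
  if (any(p < clamp | p > 1 - clamp) && warn)
    warning("fitted probabilities numerically 0 or 1; clamped", call. = FALSE)
  p <- pmin(pmax(p, clamp), 1 - clamp)
  mean(y * log(p) + (1 - y) * log1p(-p))
}

#' Fit a tropical logistic regression model
#'
#' Fits a classifier for points of the tropical projective torus (typically
#' cophenetic vectors of phylogenetic trees) with binary labels. Three model
#' forms are available:
#' \describe{
#'   \item{\code{"two-species"}}{distinct centers \eqn{\omega_0, \omega_1},
#'     shared scale \eqn{\sigma}; decision boundary is the tropical bisector
#'     of the centers. Appropriate when the two classes of gene trees come
#'     from different species trees.}
#'   \item{\code{"one-species"}}{shared center \eqn{\omega}, different
#'     scales; decision boundary is a tropical circle
#'     \eqn{d_{tr}(x,\omega) = c}. Appropriate when both classes surround
#'     the same species tree with different dispersion.}
#'   \item{\code{"classical"}}{ordinary logistic regression on canonical
#'     coordinates (\eqn{e-1} features plus intercept), the Euclidean
#'     baseline.}
#' }
#'
#' With \code{method = "fw"} (default) the centers are tropical Fermat-Weber
#' points of the per-class (or pooled) samples and the remaining scalar
#' parameters maximize the mean Bernoulli log-likelihood, a concave
#' one-dimensional problem in \eqn{1/\sigma} solved by bracketed search on
#' \eqn{\log\sigma \in [-10, 10]}. With \code{method = "mle"} all parameters
#' of the two-species model are optimized jointly by seeded multi-start
#' Nelder-Mead (the likelihood is only piecewise smooth in the centers).
#'
#' @param x Covariates: an \code{n} by \code{e} matrix of dissimilarity
#'   vectors (rows are torus points), or a \code{multiPhylo}/list of trees
#'   which are vectorized with [cophenetic_vector()].
#' @param y Binary labels (0/1, logical, or 2-level factor); both classes
#'   must be present.
#' @param model Model form, see Details.
#' @param method Center estimation for the two-species model: \code{"fw"}
#'   or \code{"mle"}.
#' @param max_iter Iteration cap for the Fermat-Weber solver.
#' @param mle_starts Number of Nelder-Mead starts for \code{method = "mle"}.
#' @param seed Optional integer seed for the multi-start perturbations.
#' @return An object of class \code{"tlr"} with components depending on the
#'   model form (\code{center0}, \code{center1}, \code{sigma};
#'   \code{center}, \code{rate}, \code{threshold}; or
#'   \code{coefficients}), plus \code{logLik}, fitted log-odds
#'   \code{fitted}, and fit metadata.
#' @examples
#' set.seed(7)
#' s <- toy_dataset("two-species", n_per_class = 60)
#' fit <- tlr(s$x, s$y)
#' mean((predict(fit, type = "class")) == s$y)
#' @export
tlr <- function(x, y, model = c("two-species", "one-species", "classical"),
                method = c("fw", "mle"), max_iter = 1000L, mle_starts = 5L,
                seed = NULL) {
  model <- match.arg(model)
  method <- match.arg(method)
  X <- .point_matrix(x)
  y <- .binary_labels(y)
  if (length(y) != nrow(X)) stop("'x' and 'y' lengths differ")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (!is.null(seed)) set.seed(seed)

  fit <- switch(model,
    "two-species" = if (method == "mle")
        .fit_two_species_mle(X, y, mle_starts) else
        .fit_two_species_fw(X, y, max_iter),
    "one-species" = .fit_one_species(X, y, max_iter),
    "classical"   = .fit_classical(X, y))

  fit$call <- match.call()
  fit$model <- model
  fit$method <- if (model == "two-species") method else "fw"
  fit$n <- nrow(X); fit$e <- ncol(X)
  fit$pair_names <- colnames(X)
  fit$y <- y
  fit$logLik <- .mean_loglik(fit$fitted, y)
  class(fit) <- "tlr"
  fit
}

.binary_labels <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("'y' must be binary (0/1)")
  y
}

.fit_two_species_fw <- function(X, y, max_iter) {
  if (min(table(y)) < 2L) stop("need at least 2 points per class")
  fw0 <- fermat_weber(X[y == 0L, , drop = FALSE], max_iter = max_iter)
  fw1 <- fermat_weber(X[y == 1L, , drop = FALSE], max_iter = max_iter)
  .finish_two_species(X, y, fw0$point, fw1$point, fw = list(fw0, fw1))
}

.finish_two_species <- function(X, y, c0, c1, fw = NULL) {
  if (trop_dist(c0, c1) < 1e-9)
    warning("fitted centers are (nearly) identical; classes may be ",
            "indistinguishable under the two-species model", call. = FALSE)
  dd <- .trop_dist_rows(X, c0) - .trop_dist_rows(X, c1)
  # h = dd / sigma: concave in 1/sigma, single interior max or a boundary
  obj <- function(ls) .mean_loglik(dd / exp(ls), y)
  op <- stats::optimize(obj, c(-10, 10), maximum = TRUE, tol = 1e-9)
  separation <- op$maximum < -9.99
  if (separation)
    warning("classes are (almost) perfectly separated; sigma at search ",
            "bracket boundary", call. = FALSE)
  sigma <- exp(op$maximum)
  list(center0 = c0, center1 = c1, sigma = sigma, fw = fw,
       separation = separation, fitted = dd / sigma)
}

.fit_two_species_mle <- function(X, y, mle_starts) {
  e <- ncol(X); k <- e - 1L
  start_fit <- .fit_two_species_fw(X, y, max_iter = 1000L)
  th0 <- c(start_fit$center0[seq_len(k)], start_fit$center1[seq_len(k)],
           log(start_fit$sigma))
  negll <- function(th) {
    h <- trop_h(X, c(th[seq_len(k)], 0), c(th[k + seq_len(k)], 0),
                exp(th[2L * k + 1L]), exp(th[2L * k + 1L]))
    -.mean_loglik(h, y)
  }
  scale0 <- max(stats::sd(as.numeric(X)), 0.1)
  best <- NULL
  for (s in seq_len(max(1L, mle_starts))) {
    th <- if (s == 1L) th0 else
      th0 + c(stats::rnorm(2L * k, 0, 0.5 * scale0), stats::rnorm(1L, 0, 0.3))
    op <- stats::optim(th, negll, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || op$value < best$value) best <- op
  }
  th <- best$par
  c0 <- trop_canonical(c(th[seq_len(k)], 0))
  c1 <- trop_canonical(c(th[k + seq_len(k)], 0))
  sigma <- exp(th[2L * k + 1L])
  h <- trop_h(X, c0, c1, sigma, sigma)
  list(center0 = stats::setNames(c0, colnames(X)),
       center1 = stats::setNames(c1, colnames(X)),
       sigma = sigma, fw = NULL, separation = FALSE, fitted = h)
}

.fit_one_species <- function(X, y, max_iter) {
  fw <- fermat_weber(X, max_iter = max_iter)   # pooled: classes share center
  d <- .trop_dist_rows(X, fw$point)
  glm_fit <- suppressWarnings(
    stats::glm(y ~ d, family = stats::binomial()))
  label_swap <- FALSE
  if (coef(glm_fit)[2L] <= 0) {
    # class 1 is the less dispersed class: relabel so sigma1 > sigma0 holds
    label_swap <- TRUE
    warning("class 1 appears less dispersed than class 0; labels swapped ",
            "internally so that the rate is positive (predictions still ",
            "refer to the input labels)", call. = FALSE)
    glm_fit <- suppressWarnings(
      stats::glm(I(1L - y) ~ d, family = stats::binomial()))
  }
  beta <- coef(glm_fit)
  rate <- unname(beta[2L])
  threshold <- unname(-beta[1L] / beta[2L])
  h_swapped <- rate * (d - threshold)
  fitted <- if (label_swap) -h_swapped else h_swapped
  list(center = fw$point, rate = rate, threshold = threshold, fw = list(fw),
       label_swap = label_swap, separation = FALSE, fitted = fitted)
}

.fit_classical <- function(X, y) {
  Z <- X[, -ncol(X), drop = FALSE] - X[, ncol(X)]   # canonical coordinates
  colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  df <- data.frame(.y = y, Z)
  w <- NULL
  glm_fit <- withCallingHandlers(
    stats::glm(.y ~ ., family = stats::binomial(), data = df),
    warning = function(cond) { w <<- conditionMessage(cond)
                               invokeRestart("muffleWarning") })
  beta <- coef(glm_fit)
  beta[is.na(beta)] <- 0
  eta <- drop(cbind(1, Z) %*% beta)
  separation <- (!is.null(w) && grepl("0 or 1", w)) ||
    glm_fit$deviance < 1e-6 || max(abs(eta)) > 30
  if (separation) {
    # bounded-norm fallback: rescale so the largest |log-odds| is at most 30
    sc <- min(1, 30 / max(abs(eta)))
    beta <- beta * sc
    eta <- eta * sc
    warning("perfect separation in classical baseline; coefficients ",
            "rescaled to bounded norm", call. = FALSE)
  }
  list(coefficients = beta, separation = separation, fitted = eta)
}
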