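#' Tropical Laplace density
#'
#' Density of the tropical Laplace distribution on the projective torus,
#' \deqn{f(x) = \Lambda^{-1} \exp(-d_{tr}(x, \omega)/\sigma),
#'       \qquad \Lambda = e!\,\sigma^{e-1},}
#' the tropical analogue of an isotropic Gaussian: probability decays
#' exponentially in the tropical distance from the center. The density is
#' constant along the all-ones direction, so it is evaluated per torus point
#' (equivalently, on canonical coordinates \eqn{R^{e-1}}).
#'
#' @param x Numeric vector (one point) or matrix of row points.
#' @param center Center \eqn{\omega}, a point of the same torus.
#' @param sigma Scale \eqn{\sigma > 0} (evolutionary-time units).
#' @param log Return the log density?
#' @return Numeric vector of (log) density values.
#' @seealso [rtroplap()] for sampling.
#' @export
dtroplap <- function(x, center, sigma = 1, log = FALSE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive number")
  X <- .point_matrix(x)
  center <- as.numeric(center)
  if (length(center) != ncol(X))
    stop("'center' must have the same length as the points")
  e <- ncol(X)
  d <- .trop_dist_rows(X, trop_canonical(center))
  lp <- -d / sigma - lfactorial(e) - (e - 1) * log(sigma)
  if (log) lp else exp(lp)
}

#' Sample from the tropical Laplace distribution
#'
#' Exact rejection sampler. Working in canonical coordinates
#' \eqn{z \in R^{e-1}}, proposals are independent classical Laplace draws
#' with per-coordinate scale \eqn{(e-1)\sigma}, accepted with probability
#' \eqn{\exp(-d_{tr}(z,0)/\sigma + \sum_i |z_i| / ((e-1)\sigma))}. This is a
#' valid envelope because
#' \eqn{d_{tr}(z, 0) \ge \max_i |z_i| \ge \sum_i |z_i|/(e-1)}, so the
#' acceptance ratio never exceeds one. Accepted draws are translated by the
#' center. The tropical distance of a draw to the center follows
#' \eqn{\sigma\,\mathrm{Gamma}(e-1, 1)}.
#'
#' @param n Number of draws.
#' @param center Center of the distribution; a numeric vector of length
#'   \eqn{e \ge 2}. Defaults to the origin of a torus of dimension \code{e}.
#' @param sigma Scale \eqn{\sigma > 0}.
#' @param e Torus ambient dimension, only needed when \code{center} is
#'   omitted.
#' @return An \code{n} by \code{e} matrix of canonical points (last column 0
#'   when the center is canonical).
#' @examples
#' set.seed(1)
#' x <- rtroplap(1000, e = 3)
#' mean(apply(x, 1, trop_dist, w = c(0, 0, 0))) # close to e - 1 = 2
#' @export
rtroplap <- function(n, center = NULL, sigma = 1, e = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive number")
  if (is.null(center)) {
    if (is.null(e)) stop("supply either 'center' or 'e'")
    center <- numeric(e)
  }
  center <- trop_canonical(as.numeric(center))
  e <- length(center)
  if (e < 2L) stop("torus dimension e must be at least 2")
  k <- e - 1L
  n <- as.integer(n)
  out <- matrix(NA_real_, n, k)
  got <- 0L
  while (got < n) {
    m <- max(64L, (n - got) * 3L)
    u <- matrix(stats::runif(m * k) - 0.5, m, k)
    z <- -(k * sigma) * sign(u) * log1p(-2 * abs(u))
    zfull <- cbind(z, 0)
    dtr <- .row_max(zfull) - .row_min(zfull)
    acc <- stats::runif(m) < exp(-dtr / sigma + rowSums(abs(z)) / (k * sigma))
    zacc <- z[acc, , drop = FALSE]
    take <- min(nrow(zacc), n - got)
    if (take > 0L) {
      out[got + seq_len(take), ] <- zacc[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  trop_canonical(cbind(out, 0) + rep(center, each = n))
}
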