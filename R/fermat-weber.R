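#' Fermat-Weber objective
#'
#' Sum of tropical distances from a candidate center to a sample of torus
#' points, \eqn{f(\omega) = \sum_i d_{tr}(X_i, \omega)}. The function is
#' piecewise linear and convex in canonical coordinates.
#'
#' @param x Sample: matrix of row points (or trees, which are vectorized).
#' @param omega Candidate center.
#' @return Nonnegative number.
#' @export
fw_objective <- function(x, omega) {
  X <- .point_matrix(x)
  if (nrow(X) == 0L) stop("empty point list")
  omega <- trop_canonical(as.numeric(omega))
  if (length(omega) != ncol(X)) stop("dimension mismatch")
  sum(.trop_dist_rows(X, omega))
}

#' Integer subgradient of the Fermat-Weber objective
#'
#' Each sample contributes +1 at the argmax and -1 at the argmin coordinate
#' of \eqn{\omega - X_i} (lowest index on ties). The gradient proper is
#' defined only when every sample has a unique maximum and minimum; at such a
#' point a zero gradient certifies a global Fermat-Weber optimum.
#'
#' @inheritParams fw_objective
#' @return List with \code{gradient} (integer vector summing to zero) and
#'   \code{defined} (\code{FALSE} when any sample has a tied max or min).
#' @export
fw_subgradient <- function(x, omega) {
  X <- .point_matrix(x)
  omega <- trop_canonical(as.numeric(omega))
  if (length(omega) != ncol(X)) stop("dimension mismatch")
  D <- rep(omega, each = nrow(X)) - X
  amx <- max.col(D, ties.method = "first")
  amn <- max.col(-D, ties.method = "first")
  e <- ncol(X)
  g <- tabulate(amx, e) - tabulate(amn, e)
  idx <- cbind(seq_len(nrow(D)), amx)
  idn <- cbind(seq_len(nrow(D)), amn)
  tie <- any(rowSums(D == D[idx]) > 1L) || any(rowSums(D == D[idn]) > 1L)
  list(gradient = as.integer(g), defined = !tie)
}

#' Tropical Fermat-Weber point (geometric median)
#'
#' Minimizes \eqn{\sum_i d_{tr}(X_i, \omega)} over the tropical projective
#' torus. The default solver is projected subgradient descent in canonical
#' coordinates, started at the coordinatewise median with diminishing steps
#' \eqn{\eta_t = d_0/\sqrt{t}} (\eqn{d_0} = initial mean distance) on the
#' mean subgradient, tracking the best iterate. Iteration stops early when
#' the integer gradient is well defined and exactly zero, which certifies a
#' global optimum; Fermat-Weber sets are rarely single points for finite
#' samples, and landing in the interior of the optimal cell is common.
#'
#' \code{method = "lp"} solves the equivalent linear program
#' \eqn{\min \sum_i (u_i - l_i)} subject to
#' \eqn{l_i \le \omega_j - X_{ij} \le u_i} exactly (simplex via
#' \pkg{pracma}); it is intended as an oracle for small instances
#' (\eqn{n \cdot e \le 10^4}).
#'
#' Fermat-Weber points of ultrametric samples may leave ultrametric space;
#' no projection back is performed (the classifier operates on the torus).
#'
#' @param x Sample matrix (rows are points) or trees.
#' @param method \code{"subgradient"} (default) or \code{"lp"}.
#' @param max_iter Iteration cap for the subgradient solver. On exhaustion
#'   the best iterate is returned with \code{certified = FALSE} and a
#'   warning, never an error.
#' @param check_ultrametric Also report whether the solution is an
#'   ultrametric (only meaningful for tree-derived samples).
#' @return Object of class \code{"trop_fw"}: a list with \code{point},
#'   \code{objective}, \code{certified}, \code{iterations},
#'   \code{gradient_norm} and \code{method}.
#' @examples
#' set.seed(1)
#' x <- rtroplap(50, e = 3)
#' fw <- fermat_weber(x)
#' fw$objective - fermat_weber(x, method = "lp")$objective # ~0
#' @export
fermat_weber <- function(x, method = c("subgradient", "lp"),
                         max_iter = 1000L, check_ultrametric = FALSE) {
  method <- match.arg(method)
  X <- .point_matrix(x)
  n <- nrow(X); e <- ncol(X)
  if (n == 0L) stop("empty point list")

  if (method == "lp") {
    if (n * e > 1e4)
      stop("LP oracle is limited to n * e <= 10^4; use method = 'subgradient'")
    res <- .fw_lp(X)
  } else {
    res <- .fw_subgradient_descent(X, max_iter = max_iter)
    if (!res$certified && n > 1L)
      warning("subgradient solver stopped without the zero-gradient certificate; ",
              "returning best iterate", call. = FALSE)
  }
  if (check_ultrametric)
    res$ultrametric <- !is.na(.m_from_e(e)) && is_ultrametric_map(res$point)
  res$n <- n; res$e <- e
  class(res) <- "trop_fw"
  res
}

.fw_subgradient_descent <- function(X, max_iter = 1000L) {
  n <- nrow(X); e <- ncol(X)
  w <- trop_canonical(apply(X, 2L, stats::median))
  f0 <- fw_objective(X, w)
  best <- w; fbest <- f0
  d0 <- f0 / n
  certified <- FALSE
  g <- integer(e); defined <- FALSE
  t <- 0L
  while (t < max_iter) {
    t <- t + 1L
    s <- fw_subgradient(X, w)
    g <- s$gradient; defined <- s$defined
    if (defined && all(g == 0L)) {
      best <- w; fbest <- fw_objective(X, w); certified <- TRUE
      break
    }
    if (all(g == 0L) || d0 == 0) break   # tied flat point: no direction to move

    w <- trop_canonical(w - (d0 / sqrt(t)) * g / n)
    f <- fw_objective(X, w)
    if (f < fbest) { fbest <- f; best <- w }
  }
  if (!certified) {
    pol <- .fw_polish(X, best, fbest)
    best <- pol$point; fbest <- pol$objective
    certified <- pol$certified
  }
  sb <- fw_subgradient(X, best)
  list(point = stats::setNames(best, colnames(X)), objective = fbest,
       certified = certified && sb$defined && all(sb$gradient == 0L),
       iterations = t,
       gradient_norm = sqrt(sum(as.numeric(sb$gradient)^2)),
       start_objective = f0, method = "subgradient")
}

# descent polish for uncertified iterates: exact line searches along the
# negative mean subgradient, falling back to coordinate directions when the
# (tie-broken) subgradient direction stalls at a nondifferentiable ridge
.fw_polish <- function(X, w, fcur, rounds = 60L, search_budget = 200L) {
  n <- nrow(X); e <- ncol(X)
  searches <- 0L
  line_min <- function(w, d) {
    searches <<- searches + 1L
    ft <- function(t) fw_objective(X, w + t * d)
    T <- 1
    k <- 0L
    while (ft(2 * T) < ft(T) && k < 40L) { T <- 2 * T; k <- k + 1L }
    op <- stats::optimize(ft, c(0, 2 * T), tol = 1e-12)
    list(t = op$minimum, f = op$objective)
  }
  for (r in seq_len(rounds)) {
    if (searches >= search_budget) break
    s <- fw_subgradient(X, w)
    if (s$defined && all(s$gradient == 0L))
      return(list(point = w, objective = fw_objective(X, w),
                  certified = TRUE))
    improved <- FALSE
    if (any(s$gradient != 0L)) {
      ls <- line_min(w, -s$gradient / n)
      if (ls$f < fcur - 1e-12 * max(1, fcur)) {
        w <- trop_canonical(w - ls$t * s$gradient / n)
        fcur <- ls$f; improved <- TRUE
      }
    }
    if (!improved) {
      for (j in seq_len(e - 1L)) {
        if (searches >= search_budget) break
        for (sgn in c(1, -1)) {
          d <- numeric(e); d[j] <- sgn
          ls <- line_min(w, d)
          if (ls$f < fcur - 1e-12 * max(1, fcur)) {
            w <- trop_canonical(w + ls$t * d)
            fcur <- ls$f; improved <- TRUE
            break
          }
        }
        if (improved) break
      }
    }
    if (!improved) break
  }
  s <- fw_subgradient(X, w)
  list(point = w, objective = fcur,
       certified = s$defined && all(s$gradient == 0L))
}

# exact LP: variables (omega[1..e-1], u[1..n], l[1..n]), all free, each split
# into nonnegative parts for the simplex solver
.fw_lp <- function(X) {
  n <- nrow(X); e <- ncol(X); k <- e - 1L
  nf <- k + 2L * n
  cc0 <- c(rep(0, k), rep(1, n), rep(-1, n))
  A0 <- matrix(0, 2L * n * e, nf)
  b <- numeric(2L * n * e)
  r <- 0L
  for (i in seq_len(n)) for (j in seq_len(e)) {
    r <- r + 1L
    if (j <= k) A0[r, j] <- 1
    A0[r, k + i] <- -1
    b[r] <- X[i, j]
    r <- r + 1L
    if (j <= k) A0[r, j] <- -1
    A0[r, k + n + i] <- 1
    b[r] <- -X[i, j]
  }
  sol <- pracma::linprog(c(cc0, -cc0), A = cbind(A0, -A0), b = b,
                         maxiter = 50000)
  wpart <- sol$x[seq_len(k)] - sol$x[nf + seq_len(k)]
  w <- trop_canonical(c(wpart, 0))
  sb <- fw_subgradient(X, w)
  list(point = stats::setNames(w, colnames(X)), objective = sol$fval,
       certified = TRUE, iterations = NA_integer_,
       gradient_norm = sqrt(sum(as.numeric(sb$gradient)^2)),
       start_objective = NA_real_, method = "lp")
}

#' @export
print.trop_fw <- function(x, ...) {
  cat("Tropical Fermat-Weber point (", x$method, ")\n", sep = "")
  cat("  n = ", x$n, ", e = ", x$e, "\n", sep = "")
  cat("  objective: ", format(x$objective), "\n", sep = "")
  cat("  certified optimum (zero integer gradient): ", x$certified, "\n",
      sep = "")
  if (!is.na(x$iterations)) cat("  iterations: ", x$iterations, "\n", sep = "")
  if (!is.null(x$ultrametric))
    cat("  ultrametric: ", x$ultrametric, "\n", sep = "")
  invisible(x)
}
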