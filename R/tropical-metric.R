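#' Tropical distance between two points of the projective torus
#'
#' Computes the tropical metric (Generalized Hilbert projective metric)
#' between two points of the tropical projective torus \eqn{R^e/R\mathbf{1}},
#' \deqn{d_{tr}(v, w) = \max_i (v_i - w_i) - \min_i (v_i - w_i).}
#' The distance is invariant under adding a constant to every coordinate of
#' either argument, which is exactly the equivalence defining the torus.
#'
#' @param v,w Numeric vectors of equal length \eqn{e \ge 2} with finite
#'   entries. For tree-derived points, \eqn{e = m(m-1)/2} for \eqn{m} leaves.
#' @return A single nonnegative number; zero if and only if \code{v} and
#'   \code{w} differ by a constant vector.
#' @examples
#' trop_dist(c(2, 2, 2, 1.4, 1.4, 1), c(1.6, 2, 0.6, 2, 1.6, 2)) # 2.4
#' trop_dist(c(1, 0, 0), c(0, 0, 0))                             # 1
#' @export
trop_dist <- function(v, w) {
  v <- as.numeric(v); w <- as.numeric(w)
  if (length(v) != length(w))
    stop("'v' and 'w' must have the same length (points of the same torus)")
  if (length(v) < 2L)
    stop("points of the tropical projective torus need length e >= 2")
  d <- v - w
  if (any(!is.finite(d)))
    stop("all entries must be finite")
  max(d) - min(d)
}

#' Canonical torus representative
#'
#' Maps a point (or a matrix of row points) of \eqn{R^e/R\mathbf{1}} to its
#' canonical representative with last coordinate zero, i.e.
#' \eqn{x \mapsto x - x_e \mathbf{1}}. Canonicalization does not move the
#' point: \code{trop_dist(x, trop_canonical(x)) == 0}.
#'
#' @param x Numeric vector, or matrix with one point per row.
#' @return Object of the same shape with last coordinate(s) exactly 0.
#' @export
trop_canonical <- function(x) {
  if (is.matrix(x)) {
    if (any(!is.finite(x))) stop("all entries must be finite")
    return(x - x[, ncol(x)])
  }
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("all entries must be finite")
  x - x[length(x)]
}

#' Leaf-pair labels for dissimilarity vectors
#'
#' The fixed vectorization order of a distance matrix is row-major over the
#' strictly upper triangle: (1,2), (1,3), ..., (1,m), (2,3), ..., (m-1,m).
#' This helper names the \eqn{e = m(m-1)/2} positions as \code{"i|j"} from a
#' set of (lexicographically sorted) leaf labels.
#'
#' @param labels Character vector of leaf labels (sorted internally).
#' @return Character vector of length \code{choose(m, 2)}.
#' @export
leaf_pairs <- function(labels) {
  labels <- sort(as.character(labels))
  if (length(labels) < 2L) stop("need at least two leaf labels")
  apply(utils::combn(labels, 2L), 2L, paste, collapse = "|")
}

# number of leaves encoded by a dissimilarity vector of length e, or NA
.m_from_e <- function(e) {
  m <- (1 + sqrt(1 + 8 * e)) / 2
  if (abs(m - round(m)) > 1e-9) return(NA_integer_)
  as.integer(round(m))
}

# coerce points input (vector, matrix, data.frame, list of trees) to a
# canonical n x e matrix
.point_matrix <- function(x) {
  if (inherits(x, "phylo")) x <- structure(list(x), class = "multiPhylo")
  if (inherits(x, "multiPhylo") || (is.list(x) && length(x) &&
                                    inherits(x[[1]], "phylo"))) {
    labs <- sort(x[[1]]$tip.label)
    rows <- lapply(x, function(tr) {
      if (!setequal(tr$tip.label, labs))
        stop("all trees must share the same leaf label set")
      suppressWarnings(cophenetic_vector(tr))
    })
    x <- do.call(rbind, rows)
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = 1L)
  storage.mode(x) <- "double"
  if (ncol(x) < 2L) stop("points need length e >= 2")
  if (any(!is.finite(x))) stop("all entries must be finite")
  trop_canonical(x)
}

# rowwise tropical distance from each row of X to a single point w
.trop_dist_rows <- function(X, w) {
  D <- X - rep(w, each = nrow(X))
  .row_max(D) - .row_min(D)
}

.row_max <- function(D) D[cbind(seq_len(nrow(D)), max.col(D, ties.method = "first"))]
.row_min <- function(D) -.row_max(-D)
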