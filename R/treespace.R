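#' Cophenetic (dissimilarity) vector of a rooted tree
#'
#' Vectorizes the pairwise leaf-to-leaf path distances of a tree in the fixed
#' row-major order (1,2), (1,3), ..., (1,m), (2,3), ..., (m-1,m) over
#' lexicographically sorted leaf labels, giving a point of the tropical
#' projective torus of dimension \eqn{e = m(m-1)/2}. For an equidistant
#' (molecular-clock) tree each entry equals twice the height of the most
#' recent common ancestor of the pair, and the resulting vector is an
#' ultrametric.
#'
#' Non-equidistant trees (for instance non-clock MCMC samples) are accepted
#' with a warning: the tropical metric is defined on general dissimilarity
#' maps, and equidistance is only needed where the tree/ultrametric
#' correspondence is invoked.
#'
#' @param tree A rooted \code{phylo} tree with branch lengths and at least 3
#'   leaves.
#' @param warn_nonclock Warn when the tree is not equidistant.
#' @return Named numeric vector of length \code{choose(m, 2)}; names are
#'   \code{"i|j"} leaf pairs.
#' @export
cophenetic_vector <- function(tree, warn_nonclock = TRUE) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  labs <- tree$tip.label
  if (anyDuplicated(labs)) stop("duplicate leaf labels")
  if (length(labs) < 3L) stop("need at least 3 leaves")
  labs <- sort(labs)
  M <- ape::cophenetic.phylo(tree)[labs, labs]
  if (warn_nonclock) {
    depth <- ape::node.depth.edgelength(tree)[seq_along(labs)]
    if (diff(range(depth)) > 1e-9 * max(1, max(depth)))
      warning("tree is not equidistant (leaves at unequal root-to-leaf depth)",
              call. = FALSE)
  }
  u <- t(M)[lower.tri(M)]
  names(u) <- leaf_pairs(labs)
  u
}

#' Test a dissimilarity vector for ultrametricity
#'
#' A dissimilarity map is ultrametric when for every leaf triple (i, j, k)
#' the maximum of the three pairwise values is attained at least twice
#' (the three-point condition). By the classical correspondence, this holds
#' exactly when the map is the cophenetic vector of an equidistant tree.
#'
#' @param u Numeric dissimilarity vector of length \code{choose(m, 2)} in the
#'   row-major pair order.
#' @param tol Absolute tolerance for the two largest values to be equal.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
is_ultrametric_map <- function(u, tol = 1e-8) {
  is.null(.ultrametric_violation(u, tol))
}

# first violating triple (indices i < j < k) or NULL
.ultrametric_violation <- function(u, tol = 1e-8) {
  D <- .vec_to_matrix(u)
  m <- nrow(D)
  trip <- utils::combn(m, 3L)
  for (t in seq_len(ncol(trip))) {
    i <- trip[1L, t]; j <- trip[2L, t]; k <- trip[3L, t]
    v <- sort(c(D[i, j], D[i, k], D[j, k]), decreasing = TRUE)
    if (v[1L] - v[2L] > tol) return(c(i, j, k))
  }
  NULL
}

.vec_to_matrix <- function(u) {
  u <- as.numeric(u)
  m <- .m_from_e(length(u))
  if (is.na(m) || m < 3L)
    stop("length of 'u' must be choose(m, 2) for some m >= 3")
  D <- matrix(0, m, m)
  D[lower.tri(D)] <- u     # row-major upper triangle = column-major lower of t
  D <- t(D)
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

#' Reconstruct an equidistant tree from an ultrametric vector
#'
#' Single-linkage agglomeration: clusters are merged in nondecreasing order
#' of dissimilarity, at height \eqn{D_{ij}/2} (ties broken towards the pair
#' containing the smallest leaf index, so the topology is reproducible). The
#' cophenetic vector of the result equals the input within tolerance; the
#' round trip with [cophenetic_vector()] is the identity on ultrametrics.
#'
#' @param u Ultrametric vector (row-major pair order). If named with
#'   \code{"i|j"} pairs the leaf labels are taken from the names.
#' @param labels Optional leaf labels (sorted internally); defaults to names
#'   parsed from \code{u}, else \code{t1..tm}.
#' @param tol Ultrametricity tolerance; violations raise an error naming a
#'   violating triple.
#' @return A rooted equidistant \code{phylo} tree.
#' @export
tree_from_ultrametric <- function(u, labels = NULL, tol = 1e-8) {
  u <- stats::setNames(as.numeric(u), names(u))
  D <- .vec_to_matrix(u)
  m <- nrow(D)
  if (is.null(labels)) {
    labels <- if (!is.null(names(u)))
      sort(unique(unlist(strsplit(names(u), "|", fixed = TRUE))))
    else paste0("t", seq_len(m))
  }
  labels <- sort(as.character(labels))
  if (length(labels) != m) stop("'labels' must name the ", m, " leaves")
  bad <- .ultrametric_violation(u, tol)
  if (!is.null(bad))
    stop(sprintf("not ultrametric: triple (%s, %s, %s) attains its maximum only once",
                 labels[bad[1]], labels[bad[2]], labels[bad[3]]))
  if (any(u < 0)) stop("dissimilarities must be nonnegative")

  frag <- labels                     # newick fragment per active cluster
  hgt <- numeric(m)                  # cluster heights
  lead <- seq_len(m)                 # smallest leaf index, for tie-breaks
  active <- seq_len(m)
  Dc <- D
  while (length(active) > 2L) {
    best <- NULL
    for (a in seq_along(active)[-length(active)])
      for (b in seq.int(a + 1L, length(active))) {
        key <- c(Dc[active[a], active[b]],
                 min(lead[active[a]], lead[active[b]]),
                 max(lead[active[a]], lead[active[b]]))
        if (is.null(best) || key[1] < best$key[1] - 1e-15 ||
            (abs(key[1] - best$key[1]) <= 1e-15 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3]))))
          best <- list(key = key, a = active[a], b = active[b])
      }
    a <- best$a; b <- best$b
    h <- Dc[a, b] / 2
    frag[a] <- sprintf("(%s:%.12g,%s:%.12g)", frag[a], h - hgt[a],
                       frag[b], h - hgt[b])
    hgt[a] <- h
    lead[a] <- min(lead[a], lead[b])
    rest <- setdiff(active, c(a, b))
    Dc[a, rest] <- Dc[rest, a] <- pmin(Dc[a, rest], Dc[b, rest])
    active <- sort(c(rest, a))
  }
  a <- active[1L]; b <- active[2L]
  h <- Dc[a, b] / 2
  nwk <- sprintf("(%s:%.12g,%s:%.12g);", frag[a], h - hgt[a],
                 frag[b], h - hgt[b])
  ape::read.tree(text = nwk)
}

#' Read rooted trees with branch lengths
#'
#' Reads an ordered list of trees from a Newick file (one tree per line) or a
#' NEXUS trees block (MrBayes dialect; translate tables are honored).
#'
#' @param path File path.
#' @param format \code{"auto"} detects NEXUS by a leading \code{#NEXUS};
#'   otherwise \code{"newick"} or \code{"nexus"}.
#' @return A \code{multiPhylo} list preserving file order.
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) "nexus"
              else "newick"
  }
  trees <- if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path)
  if (inherits(trees, "phylo"))
    trees <- structure(list(trees), class = "multiPhylo")
  if (length(trees) == 0L) stop("no trees found in ", path)
  for (tr in trees)
    if (is.null(tr$edge.length))
      stop("trees in ", path, " are missing branch lengths")
  trees
}

#' Write trees to Newick or NEXUS
#'
#' @param trees A \code{phylo} or \code{multiPhylo} object.
#' @param path Output file path.
#' @param format \code{"newick"} (one tree per line) or \code{"nexus"}
#'   (trees block with translate table).
#' @return \code{path}, invisibly.
#' @export
write_trees <- function(trees, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (inherits(trees, "phylo"))
    trees <- structure(list(trees), class = "multiPhylo")
  if (format == "nexus") ape::write.nexus(trees, file = path, translate = TRUE)
  else ape::write.tree(trees, file = path)
  invisible(path)
}

# root-to-leaf height of an (assumed clock-like) rooted tree
.tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree))
}
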