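#' Labeled toy datasets from the tropical Laplace distribution
#'
#' Generates balanced two-class samples on the 3-leaf torus (\eqn{e = 3} by
#' default), matching the package's reference toy settings: the one-species
#' setting has a common center at the origin with scales
#' \eqn{\sigma_0 = 1, \sigma_1 = 5}; the two-species setting has centers
#' \eqn{\omega_0 = (0,0,0)}, \eqn{\omega_1 = (3,2,0)} and common scale
#' \eqn{\sigma = 0.5}.
#'
#' @param model \code{"one-species"} or \code{"two-species"}.
#' @param n_per_class Points per class.
#' @param center Common center (one-species).
#' @param sigma0,sigma1 Class scales (one-species); must satisfy
#'   \code{sigma0 < sigma1}.
#' @param center0,center1 Class centers (two-species).
#' @param sigma Common scale (two-species).
#' @param seed Optional seed, passed to [set.seed()].
#' @return List with matrix \code{x} (canonical points, class-0 rows first),
#'   labels \code{y}, and the generating \code{params}.
#' @export
toy_dataset <- function(model = c("one-species", "two-species"),
                        n_per_class = 100L,
                        center = c(0, 0, 0), sigma0 = 1, sigma1 = 5,
                        center0 = c(0, 0, 0), center1 = c(3, 2, 0),
                        sigma = 0.5, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_per_class)
  if (n < 1L) stop("'n_per_class' must be positive")
  if (model == "one-species") {
    if (sigma0 >= sigma1)
      stop("one-species generation requires sigma0 < sigma1")
    x <- rbind(rtroplap(n, center, sigma0), rtroplap(n, center, sigma1))
    params <- list(center = trop_canonical(center), sigma0 = sigma0,
                   sigma1 = sigma1)
  } else {
    x <- rbind(rtroplap(n, center0, sigma), rtroplap(n, center1, sigma))
    params <- list(center0 = trop_canonical(center0),
                   center1 = trop_canonical(center1), sigma = sigma)
  }
  list(x = x, y = rep(c(0L, 1L), each = n), model = model, params = params)
}

#' Simulate a Yule species tree
#'
#' Pure-birth topology with exponential waiting times (constant birth rate,
#' zero death rate), rescaled so the root-to-leaf height equals
#' \code{species_depth}. The result is equidistant.
#'
#' @param m Number of species (leaves), at least 3.
#' @param birth_rate Speciation rate of the Yule process.
#' @param species_depth Root height after rescaling (time units).
#' @param seed Optional seed.
#' @return A rooted equidistant \code{phylo} tree with tips
#'   \code{s1..sm}.
#' @export
sim_yule_tree <- function(m, birth_rate = 1, species_depth = 1, seed = NULL) {
  if (m < 3L) stop("'m' must be at least 3")
  if (birth_rate <= 0 || species_depth <= 0)
    stop("'birth_rate' and 'species_depth' must be positive")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(as.integer(m), birth = birth_rate, death = 0)
  tr$edge.length <- tr$edge.length * (species_depth / .tree_height(tr))
  tr$tip.label <- paste0("s", seq_len(m))
  tr
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Censored coalescent within the branches of an equidistant species tree:
#' one gene lineage is sampled per species; within each population the k
#' active lineages coalesce pairwise at rate \eqn{k(k-1)/2 / N}
#' (haploid convention, time in branch-length units); lineages surviving a
#' branch enter the parent population, and all remaining lineages coalesce
#' above the root. Gene trees are equidistant, with pair divergence at least
#' the species divergence of the pair.
#'
#' @param species_tree Equidistant rooted \code{phylo} tree.
#' @param pop_size Effective population size \eqn{N > 0}; the
#'   classification difficulty is governed by the ratio
#'   \eqn{R = \mathrm{species\ depth}/N}.
#' @param n_genes Number of independent gene trees.
#' @param seed Optional seed.
#' @return A \code{multiPhylo} list of \code{n_genes} gene trees with the
#'   species tips as leaf labels.
#' @export
sim_msc_gene_trees <- function(species_tree, pop_size = 1, n_genes = 1L,
                               seed = NULL) {
  if (!inherits(species_tree, "phylo")) stop("'species_tree' must be phylo")
  if (pop_size <= 0) stop("'pop_size' must be positive")
  if (!is.null(seed)) set.seed(seed)
  m <- length(species_tree$tip.label)
  depth <- ape::node.depth.edgelength(species_tree)
  height <- max(depth) - depth          # node heights above leaf level
  if (max(abs(height[seq_len(m)])) > 1e-8)
    stop("'species_tree' must be equidistant (all leaves at height 0)")
  root <- m + 1L
  ids <- m + seq_len(species_tree$Nnode)
  internal <- ids[order(height[ids])]   # ascending height; root comes last
  children <- function(v) species_tree$edge[species_tree$edge[, 1L] == v, 2L]

  trees <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    lin <- vector("list", max(species_tree$edge))
    for (tip in seq_len(m))
      lin[[tip]] <- list(list(lab = species_tree$tip.label[tip], h = 0))
    for (v in internal) {
      pool <- list()
      for (ch in children(v)) {
        evolved <- .coalesce(lin[[ch]], height[ch], height[v], pop_size)
        pool <- c(pool, evolved)
      }
      lin[[v]] <- pool
    }
    final <- .coalesce(lin[[root]], height[root], Inf, pop_size)
    trees[[g]] <- ape::read.tree(text = paste0(final[[1L]]$lab, ";"))
  }
  structure(trees, class = "multiPhylo")
}

# coalesce lineages within one population from time 'from' up to 'to'
.coalesce <- function(lins, from, to, N) {
  t <- from
  while (length(lins) >= 2L) {
    k <- length(lins)
    dt <- stats::rexp(1L, rate = k * (k - 1) / 2 / N)
    if (t + dt > to) break
    t <- t + dt
    pick <- sample.int(k, 2L)
    a <- lins[[pick[1L]]]; b <- lins[[pick[2L]]]
    merged <- list(lab = sprintf("(%s:%.12g,%s:%.12g)", a$lab, t - a$h,
                                 b$lab, t - b$h),
                   h = t)
    lins <- c(lins[-pick], list(merged))
  }
  lins
}
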