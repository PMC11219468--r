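# independent oracles used across tests (deliberately naive implementations)

# tropical distance by exhaustive scan of the difference vector
brute_trop_dist <- function(v, w) {
  best_max <- -Inf; best_min <- Inf
  for (i in seq_along(v)) {
    d <- v[i] - w[i]
    if (d > best_max) best_max <- d
    if (d < best_min) best_min <- d
  }
  best_max - best_min
}

# Mann-Whitney AUC by looping over all class pairs, ties counted 1/2
brute_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(s1) * length(s0))
}

# three-point condition by explicit triple enumeration on the full matrix
brute_is_ultrametric <- function(u, tol = 1e-8) {
  e <- length(u)
  m <- (1 + sqrt(1 + 8 * e)) / 2
  D <- matrix(0, m, m)
  idx <- 1
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    D[i, j] <- D[j, i] <- u[idx]; idx <- idx + 1
  }
  for (i in 1:(m - 2)) for (j in (i + 1):(m - 1)) for (k in (j + 1):m) {
    v <- sort(c(D[i, j], D[i, k], D[j, k]), decreasing = TRUE)
    if (v[1] - v[2] > tol) return(FALSE)
  }
  TRUE
}

# midpoint-rule mass of the tropical Laplace density over canonical
# coordinates (e = 3: 2-D grid; e = 4: 3-D grid)
laplace_mass_quadrature <- function(e, sigma, L = 20 * sigma, h = 0.05 * sigma) {
  g <- seq(-L + h / 2, L - h / 2, by = h)
  if (e == 3) {
    z1 <- rep(g, times = length(g)); z2 <- rep(g, each = length(g))
    dtr <- pmax(z1, z2, 0) - pmin(z1, z2, 0)
    sum(exp(-dtr / sigma)) * h^2 / (factorial(e) * sigma^(e - 1))
  } else if (e == 4) {
    total <- 0
    for (z3 in g) {
      z1 <- rep(g, times = length(g)); z2 <- rep(g, each = length(g))
      dtr <- pmax(z1, z2, z3, 0) - pmin(z1, z2, z3, 0)
      total <- total + sum(exp(-dtr / sigma))
    }
    total * h^3 / (factorial(e) * sigma^(e - 1))
  } else stop("oracle supports e in {3, 4}")
}

# newick text -> phylo
nwk <- function(text) ape::read.tree(text = text)

# n copies of the trees in 'x' (recycled), as a multiPhylo chain
tree_chain <- function(x, n) {
  if (inherits(x, "phylo")) x <- list(x)
  structure(rep(x, length.out = n), class = "multiPhylo")
}

# scale every branch length of a chain by a constant factor
scale_chain <- function(chain, factor) {
  structure(lapply(chain, function(tr) {
    tr$edge.length <- tr$edge.length * factor
    tr
  }), class = "multiPhylo")
}

run_cli <- function(args) {
  script <- system.file("cli", "troplr.R", package = "troplr")
  out <- suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"), c(script, args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
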