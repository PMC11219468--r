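# Convergence diagnostics for paired Bayesian MCMC tree chains.
#
# Two complementary metrics: the topology-only ASDSF (average standard
# deviation of split frequencies, as popularized by MrBayes) and a
# branch-length-sensitive AUC obtained by asking tropical logistic
# regression to tell the two chains apart. Chains drawn from the same
# stationary distribution are indistinguishable (AUC near 1/2); a high AUC
# flags non-convergence even when split frequencies already agree.

# coerce a chain (multiPhylo, list of phylo, file path, or point matrix)
# to a canonical point matrix
.chain_matrix <- function(chain) {
  if (is.character(chain) && length(chain) == 1L) chain <- read_trees(chain)
  .point_matrix(chain)
}

# retained suffix window of a chain matrix
.retain <- function(X, keep_fraction) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("'keep_fraction' must be in (0, 1]")
  n <- nrow(X)
  keep <- ceiling(keep_fraction * n)
  X[seq.int(n - keep + 1L, n), , drop = FALSE]
}

#' Cross-validated AUC between two MCMC tree chains
#'
#' Labels the retained trees of each chain by chain membership, fits the
#' two-species tropical logistic model on training folds and scores held-out
#' trees, pooling held-out log-odds into a single ROC. An AUC near 1/2 means
#' the chains are statistically indistinguishable; a high AUC means the
#' chains sample visibly different distributions (not converged). Held-out
#' scoring is used because the in-sample AUC of a flexible fit is
#' optimistically biased.
#'
#' @param chain0,chain1 Chains: \code{multiPhylo}, list of trees, a tree
#'   file path, or a matrix of dissimilarity vectors (one tree per row, in
#'   sampling order).
#' @param keep_fraction Fraction of each chain retained as a suffix window
#'   (burn-in removal); the reference protocol keeps the last 30 percent.
#' @param folds Number of stratified cross-validation folds.
#' @param seed Optional seed for the fold assignment.
#' @param max_iter Fermat-Weber iteration cap (the fits are refreshed once
#'   per fold).
#' @return List with \code{auc}, the pooled held-out \code{scores} and
#'   \code{labels}, and \code{model}, a final fit on all retained trees.
#' @export
chain_auc <- function(chain0, chain1, keep_fraction = 0.3, folds = 5L,
                      seed = NULL, max_iter = 400L) {
  X0 <- .retain(.chain_matrix(chain0), keep_fraction)
  X1 <- .retain(.chain_matrix(chain1), keep_fraction)
  if (ncol(X0) != ncol(X1))
    stop("chains have different leaf sets (e = ", ncol(X0), " vs ",
         ncol(X1), ")")
  if (nrow(X0) < 2L * folds || nrow(X1) < 2L * folds)
    stop("each retained window needs at least 2 * folds trees")
  if (!is.null(seed)) set.seed(seed)
  X <- rbind(X0, X1)
  y <- rep(c(0L, 1L), c(nrow(X0), nrow(X1)))
  fold <- integer(length(y))
  for (cls in 0:1) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- suppressWarnings(tlr(X[tr, , drop = FALSE], y[tr],
                                model = "two-species", max_iter = max_iter))
    scores[!tr] <- predict(fit, X[!tr, , drop = FALSE], type = "link")
  }
  full <- suppressWarnings(tlr(X, y, model = "two-species",
                               max_iter = max_iter))
  list(auc = roc_auc(scores, y)$auc, scores = scores, labels = y,
       model = full)
}

# clade frequency table of one chain: named vector of relative frequencies,
# keys are sorted tip-label sets of nontrivial clades
.split_freqs <- function(trees) {
  n <- length(trees)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (tr in trees) {
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    m <- length(labs)
    for (cl in pp) {
      if (length(cl) <= 1L || length(cl) >= m) next
      key <- paste(sort(labs[cl]), collapse = "|")
      assign(key, get0(key, envir = counts, ifnotfound = 0L) + 1L,
             envir = counts)
    }
  }
  keys <- ls(counts)
  stats::setNames(vapply(keys, function(k) get(k, envir = counts), 0L) / n,
                  keys)
}

#' Average standard deviation of split frequencies
#'
#' For every nontrivial clade (leaf bipartition of the rooted trees) whose
#' relative frequency reaches \code{min_freq} in at least one chain, the
#' sample standard deviation of its two per-chain frequencies is
#' \eqn{|f_0 - f_1|/\sqrt{2}}; the ASDSF is the mean over qualifying
#' splits. The statistic depends on topologies only - branch lengths are
#' invisible to it, which is exactly the blind spot the AUC diagnostic
#' covers. This is a dialect reimplementation of the MrBayes convention
#' (default \code{min_freq = 0.1}), compared qualitatively only.
#'
#' @param chain0,chain1 Chains of trees (\code{multiPhylo}, list, or file
#'   path).
#' @param min_freq Minimum relative frequency for a split to qualify.
#' @param keep_fraction Suffix window retained per chain.
#' @return The ASDSF (nonnegative number); an error if no split qualifies.
#' @export
asdsf <- function(chain0, chain1, min_freq = 0.1, keep_fraction = 1) {
  if (min_freq < 0 || min_freq >= 1) stop("'min_freq' must be in [0, 1)")
  t0 <- .chain_trees(chain0); t1 <- .chain_trees(chain1)
  t0 <- .retain_trees(t0, keep_fraction)
  t1 <- .retain_trees(t1, keep_fraction)
  if (!setequal(t0[[1L]]$tip.label, t1[[1L]]$tip.label))
    stop("chains have different leaf sets")
  f0 <- .split_freqs(t0); f1 <- .split_freqs(t1)
  keys <- union(names(f0)[f0 >= min_freq], names(f1)[f1 >= min_freq])
  if (length(keys) == 0L) stop("no splits above min_freq")
  g0 <- ifelse(is.na(f0[keys]), 0, f0[keys])
  g1 <- ifelse(is.na(f1[keys]), 0, f1[keys])
  mean(abs(g0 - g1) / sqrt(2))
}

.chain_trees <- function(chain) {
  if (is.character(chain) && length(chain) == 1L) chain <- read_trees(chain)
  if (inherits(chain, "phylo")) chain <- structure(list(chain),
                                                   class = "multiPhylo")
  if (!length(chain) || !inherits(chain[[1L]], "phylo"))
    stop("expected trees (multiPhylo, list of phylo, or a tree file path)")
  chain
}

.retain_trees <- function(trees, keep_fraction) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("'keep_fraction' must be in (0, 1]")
  n <- length(trees)
  keep <- ceiling(keep_fraction * n)
  trees[seq.int(n - keep + 1L, n)]
}

#' ASDSF / AUC convergence trace over checkpoints
#'
#' Replays two chains and evaluates both diagnostics at every multiple of
#' \code{diagnfreq}: the chain prefix up to the checkpoint is truncated to
#' its suffix window (\code{keep_fraction}), then [asdsf()] and
#' [chain_auc()] are computed on the retained trees. The final verdict is
#' "converged" when, at the last checkpoint, the AUC is below
#' \code{auc_threshold} and the ASDSF is below \code{asdsf_threshold}.
#'
#' @param chain0,chain1 Chains (tree files or \code{multiPhylo}); unequal
#'   lengths are truncated to the shorter with a warning.
#' @param diagnfreq Checkpoint spacing, in sampled trees.
#' @param keep_fraction Suffix window per checkpoint.
#' @param auc_threshold,asdsf_threshold Convergence thresholds (defaults
#'   0.8 and 0.01).
#' @param folds,seed,max_iter Passed to [chain_auc()].
#' @return Object of class \code{"tlr_trace"}: list with data frame
#'   \code{trace} (checkpoint, auc, asdsf), \code{converged}, and the
#'   thresholds.
#' @export
convergence_trace <- function(chain0, chain1, diagnfreq,
                              keep_fraction = 0.3, auc_threshold = 0.8,
                              asdsf_threshold = 0.01, folds = 5L,
                              seed = NULL, max_iter = 400L) {
  t0 <- .chain_trees(chain0); t1 <- .chain_trees(chain1)
  if (length(t0) != length(t1)) {
    warning("chains have unequal length; truncating to the shorter",
            call. = FALSE)
    n <- min(length(t0), length(t1))
    t0 <- t0[seq_len(n)]; t1 <- t1[seq_len(n)]
  }
  n <- length(t0)
  checkpoints <- seq.int(diagnfreq, n, by = diagnfreq)
  if (length(checkpoints) == 0L)
    stop("'diagnfreq' exceeds the chain length")
  if (!is.null(seed)) set.seed(seed)
  auc <- numeric(length(checkpoints))
  asd <- numeric(length(checkpoints))
  for (i in seq_along(checkpoints)) {
    k <- checkpoints[i]
    p0 <- t0[seq_len(k)]; p1 <- t1[seq_len(k)]
    asd[i] <- asdsf(p0, p1, keep_fraction = keep_fraction)
    auc[i] <- chain_auc(p0, p1, keep_fraction = keep_fraction,
                        folds = folds, max_iter = max_iter)$auc
  }
  out <- list(trace = data.frame(checkpoint = checkpoints, auc = auc,
                                 asdsf = asd),
              converged = auc[length(auc)] < auc_threshold &&
                asd[length(asd)] < asdsf_threshold,
              auc_threshold = auc_threshold,
              asdsf_threshold = asdsf_threshold)
  class(out) <- "tlr_trace"
  out
}

#' @export
print.tlr_trace <- function(x, ...) {
  cat("MCMC convergence trace (", nrow(x$trace), " checkpoints)\n", sep = "")
  print(x$trace, row.names = FALSE)
  cat(sprintf("verdict: %s (AUC %s %.2f, ASDSF %s %.3g at final checkpoint)\n",
              if (x$converged) "converged" else "NOT converged",
              if (x$trace$auc[nrow(x$trace)] < x$auc_threshold) "<" else ">=",
              x$auc_threshold,
              if (x$trace$asdsf[nrow(x$trace)] < x$asdsf_threshold) "<" else ">=",
              x$asdsf_threshold))
  invisible(x)
}
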