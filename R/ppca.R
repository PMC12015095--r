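# Phylogenetic PCA: eigen-decomposition of the evolutionary (GLS-estimated)
# covariance of per-motif counts, with scores centered on the phylogenetic
# mean. With C the (lambda-transformed) phylogenetic covariance and X the
# n x m trait matrix:
#   a = (1' C^-1 1)^-1 1' C^-1 X        (phylogenetic mean, 1 x m)
#   R = (X - 1a)' C^-1 (X - 1a)/(n - 1) (evolutionary covariance)
# Scores are (X - 1a) times the eigenvectors of R.

#' Phylogenetic principal component analysis
#'
#' Counts are log10-transformed by default (so all counts must be positive),
#' centered on the GLS phylogenetic mean, and decomposed along the
#' eigenvectors of the evolutionary covariance. Brownian motion
#' (`lambda = 1`) is the default correlation structure; a smaller fixed
#' lambda may be supplied. Eigenvector signs are fixed so each component's
#' largest-magnitude loading is positive.
#'
#' @param X Numeric species-by-motif count matrix with species rownames.
#' @param tree Phylogeny containing all row species as tips.
#' @param transform `"log10"` (default) or `"none"`.
#' @param lambda Fixed lambda in \[0, 1\] for the correlation structure.
#' @return A `phylo_pca` list: `scores` (species x PC), `loadings`
#'   (motif x PC), `eigenvalues` (descending), `mean` (phylogenetic mean per
#'   motif), `lambda`.
#' @export
phylo_pca <- function(X, tree, transform = c("log10", "none"), lambda = 1) {
  transform <- match.arg(transform)
  X <- as.matrix(X)
  if (is.null(rownames(X))) stop("X must have species rownames", call. = FALSE)
  if (transform == "log10") {
    if (any(X <= 0)) stop("all counts must be positive to log-transform", call. = FALSE)
    X <- log10(X)
  }
  n <- nrow(X)
  tree <- prune_tree(tree, rownames(X))
  C <- pagel_transform(phylo_vcv(tree)[rownames(X), rownames(X)], lambda)
  U <- chol(C)
  Xw <- backsolve(U, X, transpose = TRUE)
  onew <- backsolve(U, rep(1, n), transpose = TRUE)
  a <- drop(crossprod(onew, Xw) / sum(onew^2))      # phylogenetic mean
  centered <- sweep(X, 2L, a, "-")
  Cw <- backsolve(U, centered, transpose = TRUE)
  R <- crossprod(Cw) / (n - 1)
  eig <- eigen(R, symmetric = TRUE)
  vec <- eig$vectors
  for (k in seq_len(ncol(vec))) {
    j <- which.max(abs(vec[, k]))
    if (vec[j, k] < 0) vec[, k] <- -vec[, k]
  }
  colnames(vec) <- paste0("PC", seq_len(ncol(vec)))
  rownames(vec) <- colnames(X)
  scores <- centered %*% vec
  structure(list(scores = scores, loadings = vec,
                 eigenvalues = eig$values, mean = a, lambda = lambda),
            class = "phylo_pca")
}

#' @export
print.phylo_pca <- function(x, ...) {
  cat(sprintf("<phylo_pca: %d species, %d traits, lambda = %g>\n",
              nrow(x$scores), nrow(x$loadings), x$lambda))
  ev <- x$eigenvalues
  cat("eigenvalues:", paste(signif(ev, 4), collapse = ", "), "\n")
  cat("proportion of variance:",
      paste(signif(ev / sum(ev), 3), collapse = ", "), "\n")
  invisible(x)
}
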