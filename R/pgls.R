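# Phylogenetic generalized least squares with Pagel's lambda estimated by
# maximum likelihood on the profile log-likelihood, plus the headline model
# SSD ~ ln(HRE count) + ln(body size) and the contig-N50 quality check.
#
# Given a phylogenetic covariance C and lambda in [0,1], the residual
# covariance is V = pagel_transform(C, lambda). At fixed lambda the GLS
# estimates are analytic:
#   beta  = (X' V^-1 X)^-1 X' V^-1 y
#   s2    = r' V^-1 r / n                     (ML scale estimate)
#   logL  = -(n log(2 pi s2) + log|V| + n)/2
# Lambda is profiled out by bounded 1-D optimization. Standard errors use the
# small-sample correction n/(n-p) and p-values a t distribution on n-p df.

#' Read and validate a Newick phylogeny
#'
#' Requires branch lengths, no negative branches, no zero-length terminal
#' branches (a tip at zero distance from its parent makes the phylogenetic
#' covariance singular), and unique tip labels.
#'
#' @param path Newick file path.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  stopifnot(file.exists(path))
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file", call. = FALSE)
  validate_tree(tree)
}

#' @rdname read_newick
#' @param tree An `ape::phylo` object to validate in-memory.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels", call. = FALSE)
  tip_edges <- tree$edge[, 2] <= length(tree$tip.label)
  if (any(tree$edge.length[tip_edges] == 0)) {
    stop("tree has zero-length terminal branches", call. = FALSE)
  }
  tree
}

#' Prune a phylogeny to a species set
#'
#' Drops all other tips; `ape` collapses the resulting unifurcations, summing
#' the collapsed branch lengths so path lengths between retained tips are
#' preserved.
#'
#' @param tree An `ape::phylo`.
#' @param species Tip labels to retain.
#' @export
prune_tree <- function(tree, species) {
  missing_sp <- setdiff(species, tree$tip.label)
  if (length(missing_sp) > 0L) {
    stop(sprintf("species not in tree: %s", paste(missing_sp, collapse = ", ")),
         call. = FALSE)
  }
  ape::keep.tip(tree, species)
}

#' Phylogenetic variance-covariance matrix
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j;
#' `C[i, i]` is the root-to-tip depth.
#'
#' @param tree A rooted `ape::phylo` with branch lengths.
#' @return Square symmetric matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_tree(tree)
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: `lambda = 1` is Brownian motion, `lambda = 0` erases
#' phylogenetic signal (a star phylogeny).
#'
#' @param C Phylogenetic covariance matrix.
#' @param lambda Value in \[0, 1\].
#' @export
pagel_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

.gls_at_lambda <- function(y, X, C, lambda, jitter = FALSE) {
  V <- pagel_transform(C, lambda)
  if (jitter) diag(V) <- diag(V) + 1e-10 * mean(diag(V))
  U <- tryCatch(chol(V), error = function(e) {
    stop("lambda-transformed covariance is not positive definite; ",
         "check the tree (or use jitter = TRUE)", call. = FALSE)
  })
  # whiten: V = U'U so solve(t(U)) maps GLS to OLS
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, y, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  if (fit$rank < ncol(X)) stop("design matrix is singular", call. = FALSE)
  r <- fit$residuals
  rss <- sum(r^2)                        # = r' V^-1 r
  n <- length(y)
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(U)))
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdetV + n)
  onew <- backsolve(U, rep(1, n), transpose = TRUE)
  mu <- sum(onew * yw) / sum(onew^2)     # GLS intercept-only fit
  rss0 <- sum((yw - mu * onew)^2)
  list(beta = fit$coefficients, rss = rss, rss0 = rss0, sigma2 = sigma2,
       logLik = ll, Xw = Xw, U = U)
}

#' Fit phylogenetic GLS with Pagel's lambda
#'
#' With `lambda = "ML"` the profile log-likelihood is maximized over
#' \[0, 1\] by bounded one-dimensional optimization (tolerance 1e-8), with the
#' two endpoints checked explicitly so boundary optima are never missed. With
#' a fixed numeric lambda the analytic GLS solution is used directly; at
#' `lambda = 0` (or on a star tree) the estimates coincide with ordinary
#' least squares.
#'
#' The reported R-squared is the GLS deviance ratio
#' `1 - (r' V^-1 r) / (r0' V^-1 r0)` where `r0` are residuals from the GLS
#' intercept-only fit; it reduces to the usual OLS R-squared when lambda = 0.
#'
#' @param y Numeric response vector.
#' @param X Design matrix (include the intercept column yourself; see
#'   [model_ssd()] for the standard construction). Rows must be in the same
#'   species order as `C`.
#' @param C Phylogenetic covariance matrix from [phylo_vcv()].
#' @param lambda `"ML"` or a fixed value in \[0, 1\].
#' @param jitter Add `1e-10 * mean(diag(V))` to the diagonal; off by default —
#'   near-singular covariances raise an error rather than being silently
#'   ridged.
#' @return A `pgls_fit`: coefficient table (estimate, se, t, p), `lambda`,
#'   `sigma2`, `logLik`, `r.squared`, `n`, `p`.
#' @export
fit_pgls <- function(y, X, C, lambda = "ML", jitter = FALSE) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, nrow(C) == n, ncol(C) == n)
  if (n < p + 2L) stop(sprintf("need at least %d species for %d coefficients", p + 2L, p),
                       call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p) - 1L)

  if (identical(lambda, "ML")) {
    prof <- function(l) .gls_at_lambda(y, X, C, l, jitter = jitter)$logLik
    opt <- stats::optimize(prof, interval = c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(0, opt$maximum, 1)
    ll <- vapply(cand, prof, numeric(1L))
    lambda_hat <- cand[which.max(ll)]
    lambda_method <- "ML"
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop("lambda must be \"ML\" or a value in [0, 1]", call. = FALSE)
    }
    lambda_hat <- lambda
    lambda_method <- "fixed"
  }

  g <- .gls_at_lambda(y, X, C, lambda_hat, jitter = jitter)
  XtX_inv <- chol2inv(chol(crossprod(g$Xw)))
  se <- sqrt(diag(XtX_inv) * g$sigma2 * n / (n - p))
  tval <- g$beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  coefs <- data.frame(estimate = g$beta, se = se, t = tval, p = pval,
                      row.names = colnames(X))
  r2 <- 1 - g$rss / g$rss0
  structure(
    list(coefficients = coefs, lambda = lambda_hat, lambda_method = lambda_method,
         sigma2 = g$sigma2, logLik = g$logLik, r.squared = r2, n = n, p = p),
    class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic GLS fit (n = %d, lambda = %.4f [%s])\n",
              x$n, x$lambda, x$lambda_method))
  print(round(x$coefficients, 6))
  cat(sprintf("sigma2 = %.6g, logLik = %.4f, R2 = %.4f\n",
              x$sigma2, x$logLik, x$r.squared))
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, rownames(object$coefficients))
}

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$logLik, df = object$p + 2, class = "logLik")
}

.align_table_tree <- function(table, tree) {
  tree <- prune_tree(tree, table$species)
  C <- phylo_vcv(tree)
  C[table$species, table$species, drop = FALSE]
}

#' The headline species-level model: SSD ~ ln(HRE count) + ln(body size)
#'
#' Fits sexual size dimorphism on the natural-log HRE count of the requested
#' class with natural-log mean body mass as a covariate (body size enters
#' because of Rensch's Rule), by phylogenetic GLS with ML Pagel's lambda. Can
#' be restricted to one taxonomic order; per-order analyses are run as
#' independent fits on the subset, never with order as a covariate.
#'
#' @param table Species analysis table from [build_species_table()].
#' @param tree Phylogeny containing all table species as tips.
#' @param hre_class `"ARE"` or `"ERE"`.
#' @param order Optional order name to subset on (requires an `order` column).
#' @param min_n Minimum species count required to fit (default 20).
#' @param lambda `"ML"` or fixed value, passed to [fit_pgls()].
#' @return A `pgls_fit` with attributes `hre_class` and `order`.
#' @export
model_ssd <- function(table, tree, hre_class = c("ARE", "ERE"), order = NULL,
                      min_n = 20, lambda = "ML") {
  hre_class <- match.arg(hre_class)
  if (!is.null(order)) {
    if (!"order" %in% names(table)) stop("table has no 'order' column", call. = FALSE)
    table <- table[!is.na(table$order) & table$order == order, , drop = FALSE]
  }
  if (nrow(table) < min_n) {
    stop(sprintf("only %d species%s; at least %d required", nrow(table),
                 if (is.null(order)) "" else sprintf(" in order %s", order), min_n),
         call. = FALSE)
  }
  ln_count <- if (hre_class == "ARE") table$ln_are else table$ln_ere
  X <- cbind("(Intercept)" = 1, ln_hre = ln_count, ln_body = table$ln_body)
  C <- .align_table_tree(table, tree)
  fit <- fit_pgls(table$ssd, X, C, lambda = lambda)
  attr(fit, "hre_class") <- hre_class
  attr(fit, "order") <- if (is.null(order)) "All" else order
  fit
}

#' Genome-quality check: ln(HRE count) ~ ln(contig N50)
#'
#' Fits the natural-log HRE count on natural-log contig N50 with the same
#' phylogenetic GLS machinery, so the direction of any quality confounding
#' can be read off the slope's sign.
#'
#' @inheritParams model_ssd
#' @export
qc_n50 <- function(table, tree, hre_class = c("ARE", "ERE"), lambda = "ML") {
  hre_class <- match.arg(hre_class)
  if (!"contig_n50" %in% names(table)) {
    stop("table has no 'contig_n50' column", call. = FALSE)
  }
  if (any(!is.finite(table$contig_n50)) || any(table$contig_n50 <= 0)) {
    stop("contig_n50 must be finite and positive", call. = FALSE)
  }
  ln_count <- if (hre_class == "ARE") table$ln_are else table$ln_ere
  X <- cbind("(Intercept)" = 1, ln_n50 = log(table$contig_n50))
  C <- .align_table_tree(table, tree)
  fit <- fit_pgls(ln_count, X, C, lambda = lambda)
  attr(fit, "hre_class") <- hre_class
  fit
}

#' One-row summary of a model fit, Table-style
#'
#' @param fit A `pgls_fit` from [model_ssd()].
#' @param flank Optional flank size to record.
#' @return Data frame with order, hre_class, flank, n, effect and p for the
#'   HRE slope, body-size effect and p, lambda and r_squared.
#' @export
summarize_fit <- function(fit, flank = NA_real_) {
  stopifnot(inherits(fit, "pgls_fit"))
  cf <- fit$coefficients
  data.frame(order = attr(fit, "order") %||% NA_character_,
             hre_class = attr(fit, "hre_class") %||% NA_character_,
             flank = flank, n = fit$n,
             hre_effect = cf["ln_hre", "estimate"],
             hre_p = cf["ln_hre", "p"],
             body_effect = if ("ln_body" %in% rownames(cf)) cf["ln_body", "estimate"] else NA_real_,
             body_p = if ("ln_body" %in% rownames(cf)) cf["ln_body", "p"] else NA_real_,
             lambda = fit$lambda, r_squared = fit$r.squared,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
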