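# Path-enumeration oracle for the phylogenetic covariance: shared branch
# length of the two root-to-tip paths.
vcv_oracle <- function(tree) {
  n <- length(tree$tip.label)
  nmax <- max(tree$edge)
  parent <- integer(nmax)
  elen <- numeric(nmax)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- n + 1L
  paths <- lapply(seq_len(n), function(tip) {
    p <- integer(0)
    node <- tip
    while (node != root) {
      p <- c(p, node)
      node <- parent[node]
    }
    p
  })
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in i:n) {
      C[i, j] <- C[j, i] <- sum(elen[intersect(paths[[i]], paths[[j]])])
    }
  }
  C
}

star_tree <- function(n) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

test_that("Newick reading and pruning preserve tip path lengths", {
  path <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tree <- read_newick(path)
  pruned <- prune_tree(tree, c("A", "C"))
  expect_setequal(pruned$tip.label, c("A", "C"))
  d <- ape::cophenetic.phylo(pruned)
  expect_equal(d["A", "C"], 4)  # depths 2 + 2, unifurcation collapsed

  expect_error(prune_tree(tree, c("A", "Z")), "Z")

  big <- sim_tree(50, 1, 21)
  d_full <- ape::cophenetic.phylo(big)
  keep <- sample(big$tip.label, 17)
  d_sub <- ape::cophenetic.phylo(prune_tree(big, keep))
  expect_equal(d_sub[keep, keep], d_full[keep, keep])
  # prune to all tips changes nothing
  expect_equal(ape::cophenetic.phylo(prune_tree(big, big$tip.label)), d_full)
})

test_that("degenerate trees are rejected at load", {
  p1 <- tempfile(fileext = ".nwk")
  writeLines("((A:0,B:1):1,C:2);", p1)
  expect_error(read_newick(p1), "zero-length terminal")
  p3 <- tempfile(fileext = ".nwk")
  writeLines("((A,B),C);", p3)
  expect_error(read_newick(p3), "branch lengths")
})

test_that("phylogenetic covariance matches the path-enumeration oracle", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_vcv(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "A"], 2)
  expect_equal(C["A", "C"], 0)
  two <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(phylo_vcv(two)), diag(2))
  for (seed in c(2, 9)) {
    tree <- sim_tree(25, 1, seed)
    expect_equal(phylo_vcv(tree), vcv_oracle(tree))
  }
})

test_that("Pagel transform scales off-diagonals only and checks bounds", {
  C <- phylo_vcv(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  expect_equal(pagel_transform(C, 1), C)
  expect_equal(pagel_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  half <- pagel_transform(C, 0.5)
  expect_equal(half["A", "B"], 0.5)
  expect_equal(diag(half), diag(C))
  expect_error(pagel_transform(C, 1.2), "lambda")
  expect_error(pagel_transform(C, -0.1), "lambda")
})

test_that("PGLS reduces to OLS on a star tree and at lambda = 0", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 25
    X <- cbind(1, rnorm(n), rnorm(n))
    colnames(X) <- c("(Intercept)", "x1", "x2")
    y <- drop(X %*% c(0.5, 1, -2)) + rnorm(n)
    beta_ols <- ols_oracle(y, X)

    fit_star <- fit_pgls(y, X, phylo_vcv(star_tree(n)), lambda = "ML")
    expect_equal(unname(coef(fit_star)), beta_ols, tolerance = 1e-8)

    tree <- sim_tree(n, 1, rep)
    fit0 <- fit_pgls(y, X, phylo_vcv(tree), lambda = 0)
    expect_equal(unname(coef(fit0)), beta_ols, tolerance = 1e-8)
    # lambda = 0 R2 equals the OLS R2
    expect_equal(fit0$r.squared, summary(lm(y ~ X[, -1]))$r.squared,
                 tolerance = 1e-8)
  }
})

test_that("PGLS matches an independent GLS implementation (nlme + corPagel)", {
  skip_if_not_installed("nlme")
  tree <- sim_tree(48, 1, 4)
  cfg <- simulation_config(seed = 4, n_species = 48, lambda = 0.6, beta_are = 0.4)
  rc <- sim_rates_and_counts(tree, cfg)
  tr <- sim_traits(tree, setNames(rc$totals$are_count, rc$totals$species), cfg)
  tab <- build_species_table(tr$traits, rc$totals, tree$tip.label, quiet = TRUE)
  fit <- model_ssd(tab, tree, "ARE")

  dat <- data.frame(species = tab$species, ssd = tab$ssd,
                    ln_hre = tab$ln_are, ln_body = tab$ln_body)
  g <- nlme::gls(ssd ~ ln_hre + ln_body, data = dat,
                 correlation = ape::corPagel(0.5, tree, form = ~species),
                 method = "ML")
  expect_equal(unname(coef(fit)), unname(coef(g)), tolerance = 1e-5)
  expect_equal(fit$lambda,
               unname(coef(g$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-5)
  expect_equal(fit$logLik, as.numeric(stats::logLik(g)), tolerance = 1e-5)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(stats::vcov(g)))),
               tolerance = 1e-5)
})

test_that("profile likelihood at the ML lambda dominates the endpoints", {
  set.seed(12)
  for (rep in 1:5) {
    tree <- sim_tree(40, 1, rep + 100)
    C <- phylo_vcv(tree)
    X <- cbind(1, rnorm(40))
    y <- drop(t(chol(pagel_transform(C, 0.5))) %*% rnorm(40)) + X %*% c(0, 0.5)
    fit <- fit_pgls(y, X, C, lambda = "ML")
    ll0 <- fit_pgls(y, X, C, lambda = 0)$logLik
    ll1 <- fit_pgls(y, X, C, lambda = 1)$logLik
    expect_gte(fit$logLik, ll0 - 1e-9)
    expect_gte(fit$logLik, ll1 - 1e-9)
  }
})

test_that("branch-length rescaling is absorbed by sigma2", {
  tree <- sim_tree(30, 1, 77)
  set.seed(77)
  X <- cbind(1, rnorm(30))
  colnames(X) <- c("(Intercept)", "x")
  y <- rnorm(30)
  f1 <- fit_pgls(y, X, phylo_vcv(tree), lambda = "ML")
  tree2 <- tree
  tree2$edge.length <- tree$edge.length * 13.7
  f2 <- fit_pgls(y, X, phylo_vcv(tree2), lambda = "ML")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(f1$coefficients$t, f2$coefficients$t, tolerance = 1e-6)
  expect_equal(f1$coefficients$p, f2$coefficients$p, tolerance = 1e-6)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-6)
  expect_equal(f1$r.squared, f2$r.squared, tolerance = 1e-6)
  expect_equal(f2$sigma2, f1$sigma2 / 13.7, tolerance = 1e-6)

  # adding a constant to the response moves only the intercept
  f3 <- fit_pgls(y + 5, X, phylo_vcv(tree), lambda = f1$lambda)
  f1b <- fit_pgls(y, X, phylo_vcv(tree), lambda = f1$lambda)
  expect_equal(coef(f3)[["(Intercept)"]], coef(f1b)[["(Intercept)"]] + 5,
               tolerance = 1e-8)
  expect_equal(coef(f3)[["x"]], coef(f1b)[["x"]], tolerance = 1e-8)
})

test_that("singular designs and tiny samples are refused", {
  tree <- sim_tree(20, 1, 3)
  C <- phylo_vcv(tree)
  X <- cbind(1, rep(2, 20))  # constant predictor aliases the intercept
  expect_error(fit_pgls(rnorm(20), X, C), "singular")
  expect_error(fit_pgls(rnorm(3), cbind(1, rnorm(3), rnorm(3)), diag(3)),
               "at least")
})

test_that("the species-level model enforces the minimum sample size", {
  tree <- sim_tree(12, 1, 8)
  cfg <- simulation_config(seed = 8, n_species = 12)
  rc <- sim_rates_and_counts(tree, cfg)
  tr <- sim_traits(tree, setNames(rc$totals$are_count, rc$totals$species), cfg)
  tab <- build_species_table(tr$traits, rc$totals, tree$tip.label, quiet = TRUE)
  expect_error(model_ssd(tab, tree, "ARE"), "at least 20")
  fit <- model_ssd(tab, tree, "ARE", min_n = 5)
  expect_s3_class(fit, "pgls_fit")
  expect_equal(attr(fit, "order"), "All")
  # an all-equal count column gives a singular design
  tab2 <- tab
  tab2$ln_are <- 3
  expect_error(model_ssd(tab2, tree, "ARE", min_n = 5), "singular")
})

test_that("N50 quality check recovers a planted quality confounder", {
  tree <- sim_tree(40, 1, 15)
  cfg <- simulation_config(seed = 15, n_species = 40)
  rc <- sim_rates_and_counts(tree, cfg)
  tr <- sim_traits(tree, setNames(rc$totals$are_count, rc$totals$species), cfg)
  tab <- build_species_table(tr$traits, rc$totals, tree$tip.label, quiet = TRUE)
  expect_error(qc_n50(tab[, setdiff(names(tab), "contig_n50")], tree, "ARE"),
               "contig_n50")

  # counts constructed to decrease with N50 (lower quality -> more HREs)
  tabq <- tab
  set.seed(15)
  tabq$ln_are <- 10 - 0.5 * log(tabq$contig_n50) + rnorm(40, sd = 0.05)
  fitq <- qc_n50(tabq, tree, "ARE")
  expect_lt(coef(fitq)[["ln_n50"]], 0)
  expect_lt(fitq$coefficients["ln_n50", "p"], 1e-4)

  # counts independent of N50: mostly non-significant slopes
  nonsig <- 0L
  for (s in 1:20) {
    tree_s <- sim_tree(40, 1, s + 400)
    cfg_s <- simulation_config(seed = s + 400, n_species = 40)
    rc_s <- sim_rates_and_counts(tree_s, cfg_s)
    tr_s <- sim_traits(tree_s, setNames(rc_s$totals$are_count, rc_s$totals$species), cfg_s)
    tab_s <- build_species_table(tr_s$traits, rc_s$totals, tree_s$tip.label,
                                 quiet = TRUE)
    if (qc_n50(tab_s, tree_s, "ARE")$coefficients["ln_n50", "p"] > 0.05) {
      nonsig <- nonsig + 1L
    }
  }
  expect_gte(nonsig, 17L)
})
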