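# Independent oracles and fixture builders shared across test files.

# Random DNA string; optionally with assembly Ns sprinkled in.
random_dna <- function(n, n_frac = 0) {
  alphabet <- c("A", "C", "G", "T")
  s <- sample(alphabet, n, replace = TRUE)
  if (n_frac > 0) {
    k <- rbinom(1, n, n_frac)
    if (k > 0) s[sample.int(n, k)] <- "N"
  }
  paste(s, collapse = "")
}

# Regex oracle for motif scanning: lookahead so overlapping matches are all
# reported; motif N matches an unambiguous base only. 0-based starts.
regex_scan <- function(sequence, iupac) {
  pat <- gsub("N", "[ACGT]", iupac, fixed = TRUE)
  m <- gregexpr(paste0("(?=", pat, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# OLS by direct normal equations.
ols_oracle <- function(y, X) unname(drop(solve(t(X) %*% X, t(X) %*% y)))

# Boolean-mask oracle for interval union over [0, limit).
mask_union_bp <- function(starts, ends, limit) {
  mask <- logical(limit)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) mask[(starts[i] + 1):ends[i]] <- TRUE
  }
  sum(mask)
}

# Simulate a full dataset at the count level and fit the species model.
sim_and_fit <- function(seed, n_species, lambda, beta_are, beta_body = 0.3,
                        burst = FALSE, burst_multiplier = 4, lambda_fit = "ML") {
  tree <- sim_tree(n_species, 1, seed)
  bt <- if (burst) pick_burst_clade(tree, 0.5) else NULL
  cfg <- simulation_config(seed = seed, n_species = n_species, lambda = lambda,
                           beta_are = beta_are, beta_body = beta_body,
                           burst_tips = bt, burst_multiplier = burst_multiplier)
  rc <- sim_rates_and_counts(tree, cfg)
  tr <- sim_traits(tree, setNames(rc$totals$are_count, rc$totals$species), cfg)
  # rare replicates draw a zero ERE total; the documented exclusion applies
  tab <- suppressWarnings(
    build_species_table(tr$traits, rc$totals, tree$tip.label, quiet = TRUE))
  suppressWarnings(model_ssd(tab, tree, "ARE", lambda = lambda_fit))
}

# A small random fixture of hits and genes on one contig.
random_hits_fixture <- function(n_hits = 60, n_genes = 8, contig_len = 100000) {
  hits <- data.frame(
    contig = "c1",
    start = sample.int(contig_len - 20, n_hits) - 1L,
    strand = sample(c("+", "-"), n_hits, replace = TRUE),
    motif_name = sample(c("ARE_canonical", "ERE_canonical"), n_hits, replace = TRUE),
    stringsAsFactors = FALSE)
  hits$hre_class <- ifelse(hits$motif_name == "ARE_canonical", "ARE", "ERE")
  hits$width <- ifelse(hits$hre_class == "ARE", 15L, 13L)
  hits <- hits[order(hits$contig, hits$start, hits$motif_name), ]
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n_genes)), contig = "c1",
                      strand = "+", tss = sort(sample.int(contig_len - 1, n_genes)) - 1L,
                      category = "Intact", stringsAsFactors = FALSE)
  list(hits = hits, genes = genes, contig_lengths = c(c1 = contig_len))
}
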