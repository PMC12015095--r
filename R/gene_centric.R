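# Gene-centric scan: per-gene phylogenetic regressions of SSD on that gene's
# HRE count (body size as covariate), with eligibility filtering, direction
# summaries and the significant-gene export for enrichment tools.
#
# Species where a gene is not annotated (Lost/Missing in that species) are
# missing data for that gene, not zero counts: an absent annotation is not
# evidence of zero regulatory elements. Observed zero counts, in contrast,
# are real data, so the per-gene model uses ln(count + 1).

#' Select genes eligible for the per-gene scan
#'
#' A gene is testable when at least `min_species` species carry it (non-NA
#' counts) and those counts take at least two distinct values.
#'
#' @param count_matrix Genes-by-species numeric matrix; `NA` marks species
#'   where the gene is not annotated.
#' @param min_species Minimum species carrying the gene (default 10).
#' @return Character vector of eligible gene ids.
#' @export
select_testable <- function(count_matrix, min_species = 10) {
  stopifnot(is.matrix(count_matrix), !is.null(rownames(count_matrix)))
  n_sp <- rowSums(!is.na(count_matrix))
  variable <- apply(count_matrix, 1L, function(x) {
    length(unique(x[!is.na(x)])) >= 2L
  })
  rownames(count_matrix)[n_sp >= min_species & variable]
}

#' Fit the per-gene model for one gene
#'
#' Fits `SSD ~ ln(count + 1) + ln(body_size)` by phylogenetic GLS on the
#' species subset carrying the gene, pruning the tree accordingly. Lambda is
#' re-estimated by ML per gene unless fixed.
#'
#' @param gene_id Gene label for the record.
#' @param counts Named numeric vector of per-species counts for this gene
#'   (`NA` = gene absent in that species).
#' @param traits Data frame with `species`, `ssd` and `ln_body` (e.g. a
#'   [build_species_table()] result).
#' @param tree Phylogeny containing the carrying species.
#' @param lambda `"ML"` or fixed value.
#' @return One-row data frame: `gene_id`, `n_species`, `effect` (slope on the
#'   ln count), `se`, `p_value`, `direction` (sign of the effect) and
#'   `status` (`"ok"` or `"failed"`).
#' @export
fit_gene <- function(gene_id, counts, traits, tree, lambda = "ML") {
  stopifnot(!is.null(names(counts)))
  sp <- names(counts)[!is.na(counts)]
  sp <- intersect(sp, traits$species)
  rec <- data.frame(gene_id = gene_id, n_species = length(sp),
                    effect = NA_real_, se = NA_real_, p_value = NA_real_,
                    direction = NA_real_, status = "failed",
                    stringsAsFactors = FALSE)
  fit <- tryCatch({
    tr <- traits[match(sp, traits$species), , drop = FALSE]
    X <- cbind("(Intercept)" = 1,
               ln_count1 = log(counts[sp] + 1),
               ln_body = tr$ln_body)
    C <- phylo_vcv(prune_tree(tree, sp))[sp, sp]
    fit_pgls(tr$ssd, X, C, lambda = lambda)
  }, error = function(e) NULL)
  if (is.null(fit)) return(rec)
  cf <- fit$coefficients
  rec$effect <- cf["ln_count1", "estimate"]
  rec$se <- cf["ln_count1", "se"]
  rec$p_value <- cf["ln_count1", "p"]
  rec$direction <- sign(rec$effect)
  rec$status <- "ok"
  rec
}

#' Run the gene-centric scan over a count matrix
#'
#' Applies [select_testable()] then [fit_gene()] to every eligible gene. Genes
#' whose fit fails (e.g. a singular design) are kept in the output with
#' `status = "failed"` and excluded from summaries. A Benjamini-Hochberg
#' `q_value` column is added over the successful fits.
#'
#' @inheritParams select_testable
#' @inheritParams fit_gene
#' @param hre_class,flank Labels recorded in the output.
#' @return Data frame of gene records.
#' @export
gene_scan <- function(count_matrix, traits, tree, hre_class = "ARE",
                      flank = NA_real_, min_species = 10, lambda = "ML") {
  eligible <- select_testable(count_matrix, min_species = min_species)
  if (length(eligible) == 0L) {
    message("no eligible genes")
    return(data.frame(gene_id = character(0), hre_class = character(0),
                      flank = numeric(0), n_species = integer(0),
                      effect = numeric(0), se = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      direction = numeric(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  recs <- do.call(rbind, lapply(eligible, function(g) {
    fit_gene(g, count_matrix[g, ], traits, tree, lambda = lambda)
  }))
  n_failed <- sum(recs$status != "ok")
  if (n_failed > 0L) message(sprintf("%d gene fit(s) failed", n_failed))
  recs$hre_class <- hre_class
  recs$flank <- flank
  recs$q_value <- NA_real_
  ok <- recs$status == "ok"
  recs$q_value[ok] <- stats::p.adjust(recs$p_value[ok], method = "BH")
  recs[, c("gene_id", "hre_class", "flank", "n_species", "effect", "se",
           "p_value", "q_value", "direction", "status")]
}

#' Proportion of genes with a positive effect on SSD
#'
#' Computed over all successfully fitted genes, significant or not, per
#' (hre_class, flank) group.
#'
#' @param records Gene records from [gene_scan()] (several scans may be
#'   row-bound).
#' @return Data frame: `hre_class`, `flank`, `n_genes`, `n_positive`,
#'   `prop_positive`.
#' @export
direction_summary <- function(records) {
  ok <- records[records$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) stop("no successful gene fits to summarize", call. = FALSE)
  groups <- split(ok, list(ok$hre_class, ok$flank), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(hre_class = g$hre_class[1L], flank = g$flank[1L],
               n_genes = nrow(g), n_positive = sum(g$effect > 0),
               prop_positive = mean(g$effect > 0), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Export genes with a significantly positive SSD effect
#'
#' Writes genes with `effect > 0` and uncorrected `p < alpha`, one id per
#' line — the input list for external Gene Ontology enrichment tools.
#' (No multiple-testing correction is applied here by design; the
#' [gene_scan()] output carries a BH q-value column for users who want one.)
#'
#' @param records Gene records from [gene_scan()].
#' @param path Output text file.
#' @param alpha Uncorrected significance threshold (default 0.05).
#' @return Invisibly, the exported gene ids.
#' @export
export_significant <- function(records, path, alpha = 0.05) {
  ok <- records$status == "ok"
  sel <- ok & records$effect > 0 & records$p_value < alpha
  genes <- records$gene_id[sel]
  writeLines(genes, path)
  message(sprintf("exported %d significant positive gene(s) at p < %g",
                  length(genes), alpha))
  invisible(genes)
}
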