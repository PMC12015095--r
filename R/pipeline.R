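# End-to-end orchestration: scan -> window counting -> species table -> PGLS
# fits (all species and per order) -> gene-centric scan -> phylogenetic PCA,
# from a single validated config, with a JSON run manifest.

#' Validate a pipeline run configuration
#'
#' @param genomes_dir Directory of per-species FASTA files (`<species>.fa`).
#' @param annotations_dir Directory of per-species annotation TSVs
#'   (`<species>.tsv`).
#' @param traits_file Traits CSV (see [read_traits()]).
#' @param tree_file Newick tree.
#' @param outdir Output directory (created if needed).
#' @param motifs_file Motif TSV; defaults to the canonical two-motif file
#'   shipped with the package.
#' @param flanks Positive, strictly increasing flank sizes in bases.
#' @param keep_categories Annotation categories to analyze.
#' @param hre_classes Classes to fit (`"ARE"`, `"ERE"` or both).
#' @param min_order_n Minimum species for a per-order fit (smaller orders are
#'   skipped with a logged reason, not failed).
#' @param min_all_n Minimum species for the all-species fit.
#' @param min_species_gene Gene-centric eligibility minimum.
#' @param lambda `"ML"` or fixed value for all fits.
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A validated `run_config` list.
#' @export
run_config <- function(genomes_dir, annotations_dir, traits_file, tree_file,
                       outdir, motifs_file = NULL,
                       flanks = c(10000, 50000, 100000, 1000000),
                       keep_categories = c("Intact", "ParalogousProjection"),
                       hre_classes = c("ARE", "ERE"),
                       min_order_n = 20, min_all_n = 20,
                       min_species_gene = 10, lambda = "ML", seed = 1) {
  if (is.null(motifs_file)) {
    motifs_file <- system.file("extdata", "hre_motifs.tsv", package = "hrescan")
  }
  cfg <- list(genomes_dir = genomes_dir, annotations_dir = annotations_dir,
              traits_file = traits_file, tree_file = tree_file, outdir = outdir,
              motifs_file = motifs_file, flanks = flanks,
              keep_categories = keep_categories, hre_classes = hre_classes,
              min_order_n = min_order_n, min_all_n = min_all_n,
              min_species_gene = min_species_gene, lambda = lambda, seed = seed)
  for (p in c(genomes_dir, annotations_dir)) {
    if (!dir.exists(p)) stop(sprintf("directory not found: %s", p), call. = FALSE)
  }
  for (p in c(traits_file, tree_file, motifs_file)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  if (any(flanks <= 0) || is.unsorted(flanks, strictly = TRUE)) {
    stop("flanks must be positive and strictly increasing", call. = FALSE)
  }
  bad_class <- setdiff(hre_classes, HRE_CLASSES)
  if (length(bad_class) > 0L) {
    stop(sprintf("unknown hre class: %s", paste(bad_class, collapse = ", ")),
         call. = FALSE)
  }
  bad_cat <- setdiff(keep_categories, TOGA_CATEGORIES)
  if (length(bad_cat) > 0L) {
    stop(sprintf("unknown annotation category: %s", paste(bad_cat, collapse = ", ")),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

.tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis
#'
#' Per species: read the genome and annotations, scan for all motifs, and for
#' every flank compute once-only (merged-window) class counts, interrogated
#' bp, per-motif counts and per-gene counts. Then, per flank: assemble the
#' species table, fit the species-level model for each class (all species and
#' per order where an `order` column is present and large enough), run the
#' gene-centric scan, and run the phylogenetic PCA on per-motif counts.
#' Everything is written under `config$outdir` along with a JSON manifest.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `counts`, `model_summary`, `gene_records`,
#'   `direction_summary`, `pca` and `manifest`.
#' @export
run_full_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  motifs <- parse_motif_file(config$motifs_file)
  tree <- read_newick(config$tree_file)
  traits <- read_traits(config$traits_file)

  fasta <- list.files(config$genomes_dir, pattern = "\\.(fa|fasta)(\\.gz)?$",
                      full.names = TRUE)
  if (length(fasta) == 0L) stop("no FASTA files in genomes_dir", call. = FALSE)
  species <- sub("\\.(fa|fasta)(\\.gz)?$", "", basename(fasta))

  count_rows <- list()
  motif_counts <- list()   # per flank: species x motif
  gene_counts <- list()    # per flank/class: gene x species
  timings <- list()
  for (i in seq_along(species)) {
    sp <- species[i]
    t_sp <- Sys.time()
    genome <- read_genome_fasta(fasta[i])
    contig_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
    ann_path <- file.path(config$annotations_dir, paste0(sp, ".tsv"))
    if (!file.exists(ann_path)) {
      stop(sprintf("stage annotate, species %s: no annotation file %s", sp, ann_path),
           call. = FALSE)
    }
    ann <- read_annotations(ann_path, keep_categories = config$keep_categories,
                            quiet = TRUE)
    hits <- scan_genome(genome, motifs, quiet = TRUE)
    for (flank in config$flanks) {
      win <- merge_windows(build_gene_windows(ann, flank, contig_lengths), flank)
      ded <- count_hits_dedup(hits, win, quiet = TRUE)
      count_rows[[length(count_rows) + 1L]] <- data.frame(
        species = sp, flank = flank,
        are_count = unname(ded$by_class["ARE"]),
        ere_count = unname(ded$by_class["ERE"]),
        interrogated_bp = ded$interrogated_bp, stringsAsFactors = FALSE)
      fk <- as.character(flank)
      mv <- stats::setNames(rep(0L, length(motifs)), names(motifs))
      mv[names(ded$by_motif)] <- ded$by_motif
      motif_counts[[fk]] <- rbind(motif_counts[[fk]],
                                  matrix(mv, nrow = 1L,
                                         dimnames = list(sp, names(mv))))
      pg <- count_hits_per_gene(hits, ann, flank, contig_lengths)
      for (cls in config$hre_classes) {
        key <- paste(cls, fk, sep = "_")
        v <- stats::setNames(pg[[cls]], pg$gene_id)
        gene_counts[[key]][[sp]] <- v
      }
    }
    timings[[sp]] <- as.numeric(difftime(Sys.time(), t_sp, units = "secs"))
    say("scanned %s (%d/%d): %d hits", sp, i, length(species), nrow(hits))
  }
  counts <- do.call(rbind, count_rows)
  .tsv(counts, file.path(config$outdir, "species_counts.tsv"))

  model_rows <- list()
  gene_records <- list()
  pca_results <- list()
  for (flank in config$flanks) {
    fk <- as.character(flank)
    tab <- build_species_table(traits, counts[counts$flank == flank, ],
                               tree$tip.label, quiet = TRUE)
    .tsv(tab, file.path(config$outdir, sprintf("species_table_%s.tsv", fk)))
    orders <- if ("order" %in% names(tab)) {
      names(which(table(tab$order) >= config$min_order_n))
    } else character(0)
    for (cls in config$hre_classes) {
      if (nrow(tab) >= config$min_all_n) {
        fit <- model_ssd(tab, tree, cls, min_n = config$min_all_n,
                         lambda = config$lambda)
        model_rows[[length(model_rows) + 1L]] <- summarize_fit(fit, flank)
      } else {
        say("skipping all-species %s fit at flank %s: only %d species",
            cls, fk, nrow(tab))
      }
      for (ord in orders) {
        fit <- model_ssd(tab, tree, cls, order = ord,
                         min_n = config$min_order_n, lambda = config$lambda)
        model_rows[[length(model_rows) + 1L]] <- summarize_fit(fit, flank)
      }
      # gene-centric scan
      gmat_list <- gene_counts[[paste(cls, fk, sep = "_")]]
      gmat_list <- gmat_list[intersect(names(gmat_list), tab$species)]
      if (length(gmat_list) > 0L) {
        genes <- sort(unique(unlist(lapply(gmat_list, names))))
        gmat <- matrix(NA_real_, nrow = length(genes), ncol = length(gmat_list),
                       dimnames = list(genes, names(gmat_list)))
        for (sp in names(gmat_list)) gmat[names(gmat_list[[sp]]), sp] <- gmat_list[[sp]]
        recs <- gene_scan(gmat, tab, tree, hre_class = cls, flank = flank,
                          min_species = config$min_species_gene,
                          lambda = config$lambda)
        if (nrow(recs) > 0L) {
          gene_records[[length(gene_records) + 1L]] <- recs
          .tsv(recs, file.path(config$outdir,
                               sprintf("gene_records_%s_%s.tsv", cls, fk)))
          export_significant(recs, file.path(config$outdir,
                                             sprintf("significant_%s_%s.txt", cls, fk)))
        }
      }
    }
    # phylogenetic PCA on per-motif counts
    mm <- motif_counts[[fk]][tab$species, , drop = FALSE]
    pos <- apply(mm, 2L, function(x) all(x > 0))
    if (sum(pos) >= 2L && nrow(mm) >= 3L) {
      pca <- phylo_pca(mm[, pos, drop = FALSE], tree)
      pca_results[[fk]] <- pca
      .tsv(data.frame(species = rownames(pca$scores), pca$scores),
           file.path(config$outdir, sprintf("pca_scores_%s.tsv", fk)))
      .tsv(data.frame(motif = rownames(pca$loadings), pca$loadings,
                      check.names = FALSE),
           file.path(config$outdir, sprintf("pca_loadings_%s.tsv", fk)))
    } else {
      say("skipping PCA at flank %s: need >= 2 all-positive motif columns", fk)
    }
  }
  model_summary <- if (length(model_rows) > 0L) do.call(rbind, model_rows) else NULL
  if (!is.null(model_summary)) {
    .tsv(model_summary, file.path(config$outdir, "model_summary.tsv"))
  }
  gene_records <- if (length(gene_records) > 0L) do.call(rbind, gene_records) else NULL
  dir_summary <- if (!is.null(gene_records) && any(gene_records$status == "ok")) {
    ds <- direction_summary(gene_records)
    .tsv(ds, file.path(config$outdir, "direction_summary.tsv"))
    ds
  } else NULL

  cfg <- unclass(config)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hrescan")),
    config = cfg,
    config_hash = sum(utf8ToInt(paste(
      vapply(cfg, function(x) paste(format(x), collapse = ","), character(1L)),
      collapse = ";"))),
    seed = config$seed,
    n_species = length(species),
    stage_seconds = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(counts = counts, model_summary = model_summary,
                 gene_records = gene_records, direction_summary = dir_summary,
                 pca = pca_results, manifest = manifest))
}
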