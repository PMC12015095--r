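# Synthetic-data generator: Yule trees, per-species motif rates evolving by
# Brownian motion (with an optional clade burst emulating a lineage-specific
# explosion of AREs), genomes with planted motif instances on clean
# background, and traits generated from the inverse of the analysis model
#   SSD = intercept + beta_are * ln(ARE total) + beta_body * ln(body)
#         + MVN(0, sigma^2 * pagel_transform(C, lambda)).
# All randomness flows from the config seed (plus fixed small offsets per
# stage), so every output is reproducible.

#' Simulation configuration
#'
#' Defaults describe the study conditions the statistical checks run under:
#' 128 species on a unit-depth Yule tree; per-gene planted ARE rates around 50
#' whose natural log evolves by Brownian motion with variance 0.25 (giving a
#' tip spread of ln counts comparable to real mammal ARE tables); rarer EREs;
#' SSD generated with a positive ARE effect of 0.3, body-size effect 0.3,
#' intermediate phylogenetic signal (lambda 0.5) and residual sd 0.2; ln body
#' mass a Brownian motion with variance 1 from a 1 kg root.
#'
#' @param seed Integer seed; every stage derives its stream from it.
#' @param n_species Number of tips (>= 3).
#' @param birth_rate Yule speciation rate.
#' @param n_genes Genes per genome.
#' @param flank Planting half-window around each TSS, bases.
#' @param contig_length Optional fixed contig length (error if too short).
#' @param gc_fraction Background GC content in (0, 1).
#' @param root_log_rate Root value of the per-gene ln planted-ARE rate.
#' @param rate_bm_var Brownian variance of the ARE ln rate over unit depth.
#' @param ere_root_log_rate,ere_rate_bm_var Same for EREs.
#' @param burst_tips Optional tip labels whose ARE ln rate is shifted by
#'   `log(burst_multiplier)` (see [pick_burst_clade()]).
#' @param burst_multiplier Fold increase in the burst clade (>= 1).
#' @param beta_are,beta_body,intercept,lambda,resid_sd Trait-model parameters.
#' @param body_bm_var,body_root_log_mass Brownian variance and root of ln body
#'   mass (kg).
#' @param n50_meanlog,n50_sdlog Log-normal contig N50 distribution.
#' @param clean_background Scrub spurious motif matches from background
#'   sequence (default TRUE; turn off for statistical realism studies).
#' @param dispersion Negative-binomial size for realized counts; `Inf`
#'   (default) gives Poisson.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1, n_species = 128, birth_rate = 1,
                              n_genes = 20, flank = 10000, contig_length = NULL,
                              gc_fraction = 0.42,
                              root_log_rate = log(50), rate_bm_var = 0.25,
                              ere_root_log_rate = log(2), ere_rate_bm_var = 0.25,
                              burst_tips = NULL, burst_multiplier = 4,
                              beta_are = 0.3, beta_body = 0.3, intercept = 0,
                              lambda = 0.5, resid_sd = 0.2,
                              body_bm_var = 1, body_root_log_mass = 0,
                              n50_meanlog = log(5e6), n50_sdlog = 1,
                              clean_background = TRUE, dispersion = Inf) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_species >= 3, cfg$birth_rate > 0, cfg$n_genes >= 1,
            cfg$flank > 0, cfg$gc_fraction > 0, cfg$gc_fraction < 1,
            cfg$rate_bm_var >= 0, cfg$ere_rate_bm_var >= 0,
            cfg$burst_multiplier >= 1, cfg$lambda >= 0, cfg$lambda <= 1,
            cfg$resid_sd >= 0, cfg$body_bm_var >= 0, cfg$dispersion > 0)
  structure(cfg, class = "simulation_config")
}

#' Simulate a Yule tree rescaled to unit depth
#'
#' @param n_species Number of tips.
#' @param birth_rate Speciation rate.
#' @param seed Integer seed (deterministic output).
#' @return Ultrametric `ape::phylo` with tips `sp001`, `sp002`, ...
#' @export
sim_tree <- function(n_species, birth_rate = 1, seed = 1) {
  stopifnot(n_species >= 3)
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

#' Pick a monophyletic burst clade of roughly a target size
#'
#' Returns the tips of the internal node whose clade size is closest to
#' `fraction` of the tips (never the whole tree) — used to emulate a
#' lineage-specific burst of AREs, like the myomorph rodent explosion.
#'
#' @param tree An `ape::phylo`.
#' @param fraction Target clade fraction of all tips.
#' @export
pick_burst_clade <- function(tree, fraction = 0.5) {
  n <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  sizes <- lengths(parts)
  ok <- sizes < n
  best <- which(ok)[which.min(abs(sizes[ok] - fraction * n))]
  tree$tip.label[parts[[best]]]
}

.draw_counts <- function(n, lambda, dispersion) {
  if (is.infinite(dispersion)) stats::rpois(n, lambda)
  else stats::rnbinom(n, mu = lambda, size = dispersion)
}

#' Evolve per-species motif rates on the tree and realize planted counts
#'
#' The natural log of the per-gene planted rate evolves by Brownian motion on
#' the tree (ARE and ERE streams independent); the burst clade's ARE ln rate
#' is shifted by `log(burst_multiplier)`. Realized per-gene counts are Poisson
#' (or negative binomial) at the species rate.
#'
#' @param tree An `ape::phylo`.
#' @param config A [simulation_config()].
#' @return List with `are` and `ere` (each `log_rate` per species and a
#'   species-by-gene `counts` matrix) and `totals` (data frame with `species`,
#'   `are_count`, `ere_count`).
#' @export
sim_rates_and_counts <- function(tree, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  tips <- tree$tip.label
  gene_ids <- sprintf("gene%03d", seq_len(config$n_genes))
  sim_class <- function(root_lr, bm_var, burst_tips = NULL, mult = 1) {
    g <- if (bm_var > 0) {
      ape::rTraitCont(tree, model = "BM", sigma = sqrt(bm_var), root.value = root_lr)
    } else {
      stats::setNames(rep(root_lr, length(tips)), tips)
    }
    if (!is.null(burst_tips)) {
      missing_tips <- setdiff(burst_tips, tips)
      if (length(missing_tips) > 0L) {
        stop(sprintf("burst tips not in tree: %s", paste(missing_tips, collapse = ", ")),
             call. = FALSE)
      }
      g[burst_tips] <- g[burst_tips] + log(mult)
    }
    counts <- t(vapply(tips, function(sp) {
      .draw_counts(config$n_genes, exp(g[[sp]]), config$dispersion)
    }, numeric(config$n_genes)))
    counts <- matrix(as.integer(counts), nrow = length(tips),
                     dimnames = list(tips, gene_ids))
    list(log_rate = g[tips], counts = counts)
  }
  are <- sim_class(config$root_log_rate, config$rate_bm_var,
                   config$burst_tips, config$burst_multiplier)
  ere <- sim_class(config$ere_root_log_rate, config$ere_rate_bm_var)
  list(are = are, ere = ere,
       totals = data.frame(species = tips,
                           are_count = rowSums(are$counts),
                           ere_count = rowSums(ere$counts),
                           row.names = NULL, stringsAsFactors = FALSE))
}

.random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Replace bases at spurious motif matches (outside protected intervals) until
# the sequence is motif-free there; protected is a 2-column matrix of 0-based
# half-open intervals.
.scrub_motifs <- function(chars, motifs, protected = NULL, gc = 0.42,
                          max_iter = 1000L) {
  seq_str <- function() paste(chars, collapse = "")
  in_protected <- function(start, width) {
    if (is.null(protected) || nrow(protected) == 0L) return(FALSE)
    any(start < protected[, 2L] & start + width > protected[, 1L])
  }
  for (iter in seq_len(max_iter)) {
    hits <- scan_genome(stats::setNames(seq_str(), "x"), motifs, quiet = TRUE)
    if (nrow(hits) > 0L) {
      keep <- !vapply(seq_len(nrow(hits)), function(i) {
        in_protected(hits$start[i], hits$width[i])
      }, logical(1L))
      hits <- hits[keep, , drop = FALSE]
    }
    if (nrow(hits) == 0L) return(chars)
    for (i in seq_len(nrow(hits))) {
      span <- (hits$start[i] + 1L):(hits$start[i] + hits$width[i])
      if (!is.null(protected) && nrow(protected) > 0L) {
        pos0 <- span - 1L
        prot <- vapply(pos0, function(p) {
          any(p >= protected[, 1L] & p < protected[, 2L])
        }, logical(1L))
        span <- span[!prot]
      }
      chars[span] <- .random_bases(length(span), gc)
    }
  }
  stop("could not scrub spurious motif matches within 1000 iterations", call. = FALSE)
}

.instantiate_motif <- function(motif, strand) {
  chars <- strsplit(motif$iupac, "", fixed = TRUE)[[1L]]
  chars[chars == "N"] <- sample(c("A", "C", "G", "T"), sum(chars == "N"),
                                replace = TRUE)
  inst <- paste(chars, collapse = "")
  if (strand == "-") inst <- reverse_complement_iupac(inst)
  strsplit(inst, "", fixed = TRUE)[[1L]]
}

#' Build per-species genomes with planted motif instances
#'
#' One contig per species; genes placed at regular TSS spacing with category
#' Intact. Each gene receives its realized count of planted ARE and ERE
#' instances at uniform non-overlapping positions within its flanking window
#' (alternating strand for non-palindromic motifs; palindromic motifs are
#' always planted forward). With `clean_background` the background is
#' rejection-resampled so the scanner finds exactly the planted occurrences.
#'
#' @param rates_counts Result of [sim_rates_and_counts()].
#' @param config A [simulation_config()].
#' @return List: `genomes` (named character, one contig `contig1` each),
#'   `annotations` (list of per-species annotation data frames) and
#'   `ground_truth` (data frame of planted positions: `species`, `contig`,
#'   `start`, `strand`, `motif_name`, `hre_class`, `gene_id`).
#' @export
sim_genomes <- function(rates_counts, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  motifs <- default_motifs()
  mlen_max <- max(vapply(motifs, `[[`, integer(1L), "length"))
  spacing <- 2 * config$flank + 4 * mlen_max + 100
  tss <- config$flank + 50 + (seq_len(config$n_genes) - 1L) * spacing
  needed <- tss[config$n_genes] + config$flank + 51
  contig_len <- if (is.null(config$contig_length)) needed else config$contig_length
  if (contig_len < needed) {
    stop(sprintf("contig_length %d too short: need %d for %d genes at flank %d",
                 contig_len, needed, config$n_genes, config$flank), call. = FALSE)
  }
  species <- rownames(rates_counts$are$counts)
  gene_ids <- colnames(rates_counts$are$counts)
  ann <- data.frame(gene_id = gene_ids, contig = "contig1", strand = "+",
                    tss = as.integer(tss), category = "Intact",
                    stringsAsFactors = FALSE)

  genomes <- character(0)
  gt <- list()
  for (sp in species) {
    chars <- .random_bases(contig_len, config$gc_fraction)
    if (config$clean_background) {
      chars <- .scrub_motifs(chars, motifs, gc = config$gc_fraction)
    }
    occupied <- matrix(numeric(0), ncol = 2L)  # padded planted intervals
    flip <- TRUE
    for (gi in seq_along(gene_ids)) {
      lo <- max(0, tss[gi] - config$flank)
      for (cls in c("ARE", "ERE")) {
        motif <- if (cls == "ARE") motifs$ARE_canonical else motifs$ERE_canonical
        k <- rates_counts[[tolower(cls)]]$counts[sp, gi]
        hi <- min(contig_len, tss[gi] + config$flank + 1) - motif$length
        for (j in seq_len(k)) {
          placed <- FALSE
          for (attempt in seq_len(1000L)) {
            pos <- sample(seq.int(lo, hi), 1L)
            clash <- nrow(occupied) > 0L &&
              any(pos < occupied[, 2L] & pos + motif$length > occupied[, 1L])
            if (!clash) { placed <- TRUE; break }
          }
          if (!placed) stop("infeasible packing: too many motifs for the window",
                            call. = FALSE)
          if (motif$palindromic) {
            strand <- "+"
          } else {
            flip <- !flip
            strand <- if (flip) "+" else "-"
          }
          chars[(pos + 1L):(pos + motif$length)] <- .instantiate_motif(motif, strand)
          occupied <- rbind(occupied,
                            c(pos - mlen_max + 1, pos + motif$length + mlen_max - 1))
          gt[[length(gt) + 1L]] <- data.frame(
            species = sp, contig = "contig1", start = pos, strand = strand,
            motif_name = motif$name, hre_class = cls, gene_id = gene_ids[gi],
            stringsAsFactors = FALSE)
        }
      }
    }
    if (config$clean_background) {
      # planting can create spurious matches at junctions; scrub background
      # bases only (planted spans are protected)
      prot <- if (length(gt) > 0L) {
        g <- do.call(rbind, gt)
        g <- g[g$species == sp, , drop = FALSE]
        w <- vapply(g$motif_name, function(m) motifs[[m]]$length, integer(1L))
        cbind(g$start, g$start + w)
      } else matrix(numeric(0), ncol = 2L)
      chars <- .scrub_motifs(chars, motifs, protected = prot,
                             gc = config$gc_fraction)
    }
    genomes[[sp]] <- paste(chars, collapse = "")
  }
  ground_truth <- if (length(gt) > 0L) do.call(rbind, gt) else
    data.frame(species = character(0), contig = character(0), start = integer(0),
               strand = character(0), motif_name = character(0),
               hre_class = character(0), gene_id = character(0))
  list(genomes = genomes,
       annotations = stats::setNames(rep(list(ann), length(species)), species),
       contig_lengths = c(contig1 = contig_len),
       ground_truth = ground_truth)
}

#' Simulate species traits from the inverse of the analysis model
#'
#' ln body mass is a Brownian motion on the tree; SSD is generated as
#' `intercept + beta_are * ln(ARE total) + beta_body * ln(body)` plus
#' phylogenetically structured noise with covariance
#' `resid_sd^2 * pagel_transform(C, lambda)`. Male and female masses are
#' back-solved so that `ln(male/female)` equals the generated SSD and the
#' mean mass equals the generated body size. Contig N50 is drawn log-normal,
#' independent of everything else.
#'
#' @param tree An `ape::phylo`.
#' @param are_totals Named positive per-species ARE totals.
#' @param config A [simulation_config()].
#' @return List: `traits` data frame (`species`, `male_mass`, `female_mass`,
#'   `contig_n50`) and `truth` (generated `ssd`, `ln_body` and the model
#'   parameters).
#' @export
sim_traits <- function(tree, are_totals, config) {
  stopifnot(inherits(config, "simulation_config"))
  tips <- tree$tip.label
  stopifnot(all(tips %in% names(are_totals)))
  totals <- are_totals[tips]
  if (any(totals <= 0)) stop("ARE totals must be positive", call. = FALSE)
  set.seed(config$seed + 3L)
  n <- length(tips)
  ln_body <- if (config$body_bm_var > 0) {
    ape::rTraitCont(tree, model = "BM", sigma = sqrt(config$body_bm_var),
                    root.value = config$body_root_log_mass)[tips]
  } else {
    stats::setNames(rep(config$body_root_log_mass, n), tips)
  }
  V <- pagel_transform(phylo_vcv(tree)[tips, tips], config$lambda)
  eps <- if (config$resid_sd > 0) {
    config$resid_sd * drop(t(chol(V)) %*% stats::rnorm(n))
  } else rep(0, n)
  ssd <- config$intercept + config$beta_are * log(totals) +
    config$beta_body * ln_body + eps
  body <- exp(ln_body)
  female <- 2 * body / (1 + exp(ssd))
  male <- 2 * body - female
  traits <- data.frame(species = tips, male_mass = male, female_mass = female,
                       contig_n50 = stats::rlnorm(n, config$n50_meanlog,
                                                  config$n50_sdlog),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(traits = traits,
       truth = list(ssd = stats::setNames(ssd, tips), ln_body = ln_body,
                    beta_are = config$beta_are, beta_body = config$beta_body,
                    intercept = config$intercept, lambda = config$lambda,
                    resid_sd = config$resid_sd))
}

#' Simulate per-gene counts with planted gene-level effects
#'
#' For the gene-centric scan: gene g's count in species s is Poisson with
#' `log mean = base_log_rate + gamma[g] * ssd[s]`, so a positive `gamma`
#' plants a positive association between the gene's counts and SSD.
#'
#' @param ssd Named per-species SSD vector.
#' @param n_genes Number of genes.
#' @param gamma Per-gene effect (scalar recycled, or length `n_genes`).
#' @param base_log_rate Baseline ln count.
#' @param seed Integer seed.
#' @return Genes-by-species integer matrix.
#' @export
sim_gene_counts <- function(ssd, n_genes, gamma = 1, base_log_rate = log(20),
                            seed = 1) {
  stopifnot(!is.null(names(ssd)))
  gamma <- rep_len(gamma, n_genes)
  set.seed(seed)
  counts <- t(vapply(seq_len(n_genes), function(g) {
    stats::rpois(length(ssd), exp(base_log_rate + gamma[g] * ssd))
  }, numeric(length(ssd))))
  dimnames(counts) <- list(sprintf("gene%03d", seq_len(n_genes)), names(ssd))
  counts
}

#' A minimal two-genes/one-shared-hit fixture
#'
#' Two genes whose windows overlap, with exactly one planted canonical ARE in
#' the shared region: merged-window counting must report 1, per-gene counting
#' must credit each gene once (sum 2). Used to pin down the once-only
#' counting rule at any flank where the windows overlap.
#'
#' @param flank Flank size; the two TSSs are placed `1.2 * flank` apart so
#'   windows overlap, with the hit midway between them.
#' @return List: `genome`, `genes`, `contig_lengths`, `hit_start`.
#' @export
shared_hit_fixture <- function(flank = 50000) {
  motif <- default_motifs()$ARE_canonical
  gap <- ceiling(1.2 * flank)
  tss1 <- flank + 10
  tss2 <- tss1 + gap
  hit_start <- tss1 + floor(gap / 2)
  contig_len <- tss2 + flank + 100
  chars <- rep("T", contig_len)  # poly-T background matches neither motif
  inst <- strsplit("AGAACATTTTGTTCT", "", fixed = TRUE)[[1L]]
  chars[(hit_start + 1L):(hit_start + motif$length)] <- inst
  genes <- data.frame(gene_id = c("geneA", "geneB"), contig = "contig1",
                      strand = "+", tss = as.integer(c(tss1, tss2)),
                      category = "Intact", stringsAsFactors = FALSE)
  list(genome = c(contig1 = paste(chars, collapse = "")), genes = genes,
       contig_lengths = c(contig1 = contig_len), hit_start = hit_start)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits per-species FASTA genomes, annotation TSVs, a traits CSV, the Newick
#' tree, a ground-truth JSON (planted positions, true rates and trait-model
#' parameters) and the config used — in exactly the dialects the pipeline
#' reads.
#'
#' @param outdir Output directory.
#' @param config A [simulation_config()].
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, a named list of the written paths.
#' @export
write_dataset <- function(outdir, config, force = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (dir.exists(outdir) && length(list.files(outdir)) > 0L && !force) {
    stop(sprintf("directory '%s' is not empty (use force = TRUE)", outdir),
         call. = FALSE)
  }
  dir.create(file.path(outdir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "annotations"), showWarnings = FALSE)

  tree <- sim_tree(config$n_species, config$birth_rate, config$seed)
  rc <- sim_rates_and_counts(tree, config)
  gen <- sim_genomes(rc, config)
  totals <- stats::setNames(rc$totals$are_count, rc$totals$species)
  tr <- sim_traits(tree, totals, config)

  paths <- list(tree = file.path(outdir, "tree.nwk"),
                traits = file.path(outdir, "traits.csv"),
                ground_truth = file.path(outdir, "ground_truth.json"),
                config = file.path(outdir, "config.json"),
                genomes_dir = file.path(outdir, "genomes"),
                annotations_dir = file.path(outdir, "annotations"))
  ape::write.tree(tree, paths$tree)
  utils::write.csv(tr$traits, paths$traits, row.names = FALSE, quote = FALSE)
  for (sp in names(gen$genomes)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(gen$genomes[[sp]], "contig1")),
      file.path(paths$genomes_dir, paste0(sp, ".fa")))
    utils::write.table(gen$annotations[[sp]],
                       file.path(paths$annotations_dir, paste0(sp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- list(planted = gen$ground_truth,
                are_log_rate = as.list(rc$are$log_rate),
                ere_log_rate = as.list(rc$ere$log_rate),
                totals = rc$totals,
                trait_model = tr$truth[c("beta_are", "beta_body", "intercept",
                                         "lambda", "resid_sd")],
                ssd = as.list(tr$truth$ssd),
                seed = config$seed)
  jsonlite::write_json(truth, paths$ground_truth, auto_unbox = TRUE, digits = NA)
  cfg <- unclass(config)
  cfg$dispersion <- if (is.infinite(cfg$dispersion)) "Inf" else cfg$dispersion
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
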