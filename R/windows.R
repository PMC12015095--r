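# TSS flanking windows and counting. Two counting modes mirror the two
# analyses: merged windows where each genomic occurrence is counted once
# regardless of how many genes it sits near, and per-gene windows where an
# occurrence is credited to every gene whose window contains it.

TOGA_CATEGORIES <- c("Intact", "PartiallyIntact", "Lost", "Missing",
                     "UncertainLost", "ParalogousProjection")

#' Read gene annotations from the canonical 5-column TSV
#'
#' Expects a header with columns `gene_id`, `contig`, `strand`, `tss`
#' (0-based) and `category` (one of the six TOGA-style calls: Intact,
#' PartiallyIntact, Lost, Missing, UncertainLost, ParalogousProjection).
#' Rows whose category is not in `keep_categories` are dropped; by default
#' only Intact and ParalogousProjection genes are analyzed, the categories
#' with a trustworthy TSS.
#'
#' @param path TSV path.
#' @param keep_categories Character vector of categories to keep.
#' @param quiet Suppress the dropped-row message.
#' @return Data frame of kept annotations.
#' @export
read_annotations <- function(path,
                             keep_categories = c("Intact", "ParalogousProjection"),
                             quiet = FALSE) {
  stopifnot(file.exists(path))
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "contig", "strand", "tss", "category")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0L) {
    stop(sprintf("annotation file missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(ann$tss) || any(ann$tss != as.integer(ann$tss))) {
    stop("annotation 'tss' column must be integer", call. = FALSE)
  }
  ann$tss <- as.integer(ann$tss)
  unknown <- setdiff(unique(ann$category), TOGA_CATEGORIES)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown annotation category: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  bad_keep <- setdiff(keep_categories, TOGA_CATEGORIES)
  if (length(bad_keep) > 0L) {
    stop(sprintf("unknown keep category: %s", paste(bad_keep, collapse = ", ")),
         call. = FALSE)
  }
  keep <- ann$category %in% keep_categories
  if (!quiet && any(!keep)) {
    message(sprintf("dropped %d of %d annotation rows outside categories {%s}",
                    sum(!keep), nrow(ann), paste(keep_categories, collapse = ", ")))
  }
  out <- ann[keep, required, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene annotations from GFF3
#'
#' Adapter over `rtracklayer::import`: takes `gene` features, uses the
#' strand-aware 5' end as the TSS (converted to 0-based), and reads the
#' category from a `toga_status` attribute, defaulting to `Intact` (with a
#' message) when absent.
#'
#' @inheritParams read_annotations
#' @export
read_annotations_gff3 <- function(path,
                                  keep_categories = c("Intact", "ParalogousProjection"),
                                  quiet = FALSE) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("the GFF3 adapter requires the 'rtracklayer' package", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) stop("no 'gene' features found in GFF3", call. = FALSE)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  tss <- ifelse(strand == "+", BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr) - 1L)
  gene_id <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  category <- if ("toga_status" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$toga_status)
  } else {
    if (!quiet) message("GFF3 has no 'toga_status' attribute; assuming category 'Intact'")
    rep("Intact", length(gr))
  }
  ann <- data.frame(gene_id = gene_id,
                    contig = as.character(GenomeInfoDb::seqnames(gr)),
                    strand = strand, tss = as.integer(tss),
                    category = category, stringsAsFactors = FALSE)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(ann, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  read_annotations(tmp, keep_categories = keep_categories, quiet = quiet)
}

#' Symmetric TSS flanking window, clamped to the contig
#'
#' Returns the 0-based half-open interval
#' `[max(0, tss - flank), min(contig_length, tss + flank + 1))`: `flank` bases
#' on each side of the TSS plus the TSS base itself, irrespective of gene
#' strand.
#'
#' @param tss 0-based TSS position.
#' @param flank Flank size in bases (> 0).
#' @param contig_length Contig length in bases.
#' @return Numeric vector `c(start, end)`.
#' @export
tss_window <- function(tss, flank, contig_length) {
  stopifnot(flank > 0, tss >= 0, tss < contig_length)
  c(start = max(0, tss - flank), end = min(contig_length, tss + flank + 1))
}

#' Per-gene windows for an annotation table
#'
#' @param genes Annotation data frame (see [read_annotations()]).
#' @param flank Flank size in bases.
#' @param contig_lengths Named numeric vector of contig lengths.
#' @return Data frame `gene_id`, `contig`, `start`, `end` (0-based half-open).
#' @export
build_gene_windows <- function(genes, flank, contig_lengths) {
  missing_ctg <- setdiff(unique(genes$contig), names(contig_lengths))
  if (length(missing_ctg) > 0L) {
    stop(sprintf("no contig length for: %s", paste(missing_ctg, collapse = ", ")),
         call. = FALSE)
  }
  len <- contig_lengths[genes$contig]
  data.frame(gene_id = genes$gene_id, contig = genes$contig,
             start = pmax(0, genes$tss - flank),
             end = pmin(len, genes$tss + flank + 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Merge per-gene windows into a disjoint union
#'
#' Overlapping and touching intervals are merged per contig, giving the set of
#' bases interrogated exactly once — the basis for once-only genome-wide
#' counting.
#'
#' @param windows Data frame with `contig`, `start`, `end` (0-based half-open),
#'   e.g. from [build_gene_windows()].
#' @param flank Optional flank size recorded in the result.
#' @return A `window_set`: list with `intervals` (data frame `contig`, `start`,
#'   `end`, sorted and disjoint), `flank` and `interrogated_bp`.
#' @export
merge_windows <- function(windows, flank = NA_real_) {
  stopifnot(all(c("contig", "start", "end") %in% names(windows)),
            all(windows$end > windows$start), all(windows$start >= 0))
  pieces <- lapply(split(windows, windows$contig), function(w) {
    ir <- IRanges::reduce(IRanges::IRanges(start = w$start + 1L, end = w$end))
    data.frame(contig = w$contig[1L],
               start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  intervals <- do.call(rbind, pieces)
  intervals <- intervals[order(intervals$contig, intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(intervals = intervals, flank = flank,
                 interrogated_bp = sum(intervals$end - intervals$start)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set: %d merged interval(s), %.0f bp interrogated%s>\n",
              nrow(x$intervals), x$interrogated_bp,
              if (is.na(x$flank)) "" else sprintf(", flank %g bp", x$flank)))
  invisible(x)
}

.hits_in_intervals <- function(hits, intervals, quiet = FALSE) {
  # membership by motif start position
  inside <- logical(nrow(hits))
  known <- hits$contig %in% unique(intervals$contig)
  if (!quiet && any(!known)) {
    message(sprintf("%d hit(s) on contigs with no windows counted as outside",
                    sum(!known)))
  }
  for (ctg in unique(hits$contig[known])) {
    hi <- which(hits$contig == ctg)
    iv <- intervals[intervals$contig == ctg, , drop = FALSE]
    q <- IRanges::IRanges(start = hits$start[hi] + 1L, width = 1L)
    s <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    inside[hi] <- IRanges::overlapsAny(q, s)
  }
  inside
}

#' Count hits once within merged windows
#'
#' A hit is counted if and only if its start position lies inside a merged
#' interval; because the intervals are disjoint, every genomic occurrence
#' contributes at most once to its class total, even when it sits near
#' multiple genes.
#'
#' @param hits Hit data frame from [scan_genome()].
#' @param windows A merged `window_set` from [merge_windows()].
#' @param quiet Suppress the unknown-contig message.
#' @return List with `by_class` (named counts for ARE and ERE), `by_motif`
#'   (named counts per motif), `n_hits_inside` and `interrogated_bp`.
#' @export
count_hits_dedup <- function(hits, windows, quiet = FALSE) {
  stopifnot(inherits(windows, "window_set"))
  by_class <- stats::setNames(rep(0L, length(HRE_CLASSES)), HRE_CLASSES)
  if (nrow(hits) == 0L) {
    return(list(by_class = by_class, by_motif = integer(0),
                n_hits_inside = 0L, interrogated_bp = windows$interrogated_bp))
  }
  inside <- .hits_in_intervals(hits, windows$intervals, quiet = quiet)
  kept <- hits[inside, , drop = FALSE]
  tab_class <- table(factor(kept$hre_class, levels = HRE_CLASSES))
  by_class[names(tab_class)] <- as.integer(tab_class)
  by_motif <- as.integer(table(kept$motif_name))
  names(by_motif) <- names(table(kept$motif_name))
  list(by_class = by_class, by_motif = by_motif,
       n_hits_inside = nrow(kept), interrogated_bp = windows$interrogated_bp)
}

#' Count hits per gene (multi-counting allowed)
#'
#' Every (gene, hit) pair with the hit's start inside that gene's window
#' contributes 1, so an occurrence near several genes is credited to each of
#' them — the gene-centric convention, in contrast to [count_hits_dedup()].
#'
#' @param hits Hit data frame from [scan_genome()].
#' @param genes Annotation data frame.
#' @param flank Flank size in bases.
#' @param contig_lengths Named vector of contig lengths.
#' @return Data frame `gene_id`, `ARE`, `ERE` with one row per gene (zeros
#'   included).
#' @export
count_hits_per_gene <- function(hits, genes, flank, contig_lengths) {
  win <- build_gene_windows(genes, flank, contig_lengths)
  out <- data.frame(gene_id = win$gene_id,
                    ARE = 0L, ERE = 0L, stringsAsFactors = FALSE)
  if (nrow(hits) == 0L || nrow(win) == 0L) return(out)
  for (ctg in intersect(unique(win$contig), unique(hits$contig))) {
    wi <- which(win$contig == ctg)
    hi <- which(hits$contig == ctg)
    q <- IRanges::IRanges(start = hits$start[hi] + 1L, width = 1L)
    s <- IRanges::IRanges(start = win$start[wi] + 1L, end = win$end[wi])
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0L) next
    cls <- hits$hre_class[hi[S4Vectors::queryHits(ov)]]
    gene_row <- wi[S4Vectors::subjectHits(ov)]
    for (k in HRE_CLASSES) {
      add <- table(factor(gene_row[cls == k], levels = wi))
      out[[k]][wi] <- out[[k]][wi] + as.integer(add)
    }
  }
  out
}

#' Write merged windows as BED3
#' @param windows A `window_set`.
#' @param path Output path.
#' @export
write_windows_bed <- function(windows, path) {
  stopifnot(inherits(windows, "window_set"))
  utils::write.table(windows$intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
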