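# Sliding-window motif scanning. Overlapping matches are all reported; motif
# 'N' matches an unambiguous base only, so motifs never match inside assembly
# gaps. Coordinates are 0-based half-open internally; BED output keeps that
# convention.

SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

.check_sequence_chars <- function(chars, contig = NULL) {
  bad <- which(!chars %in% SEQ_ALPHABET)
  if (length(bad) > 0L) {
    where <- if (is.null(contig)) "" else sprintf(" in contig '%s'", contig)
    stop(sprintf("non-DNA character '%s' at position %d%s",
                 chars[bad[1L]], bad[1L], where), call. = FALSE)
  }
  invisible(TRUE)
}

#' Find all forward-strand matches of a motif in a DNA sequence
#'
#' Every valid start position is reported, so overlapping occurrences are all
#' counted. Matching is case-insensitive (input is uppercased). A motif `N`
#' matches A, C, G or T in the subject but never an assembly `N`: unresolved
#' gap bases cannot produce motif hits.
#'
#' @param sequence A DNA string over A/C/G/T/N (character scalar or
#'   `Biostrings::DNAString`).
#' @param motif A [motif_pattern].
#' @return Integer vector of 0-based start positions, strictly increasing.
#' @export
scan_forward <- function(sequence, motif) {
  stopifnot(inherits(motif, "motif_pattern"))
  if (!is.character(sequence)) sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L)
  seq <- toupper(sequence)
  n <- nchar(seq)
  m <- motif$length
  if (n < m) return(integer(0))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  .check_sequence_chars(chars)
  mchars <- strsplit(motif$iupac, "", fixed = TRUE)[[1L]]
  # progressive candidate filtering: cheap because the first fixed position
  # already eliminates ~3/4 of starts
  cand <- seq_len(n - m + 1L)
  for (j in seq_len(m)) {
    sub <- chars[cand + (j - 1L)]
    keep <- if (mchars[j] == "N") sub != "N" else sub == mchars[j]
    cand <- cand[keep]
    if (length(cand) == 0L) return(integer(0))
  }
  cand - 1L
}

#' Scan a genome for a set of motifs on both strands
#'
#' Palindromic motifs are scanned on the forward strand only: their reverse
#' complement is the same pattern, so a second scan would double-count every
#' occurrence. Non-palindromic motifs are scanned twice — once as given
#' (strand `+`) and once as their reverse complement (reported as strand `-`,
#' with the start in forward-reference coordinates) — so forward and
#' reverse-complement occurrences are added up.
#'
#' @param genome Named character vector of contig sequences, or a
#'   `Biostrings::DNAStringSet` (e.g. from [read_genome_fasta()]).
#' @param motifs A list of [motif_pattern]s (default: [default_motifs()]).
#' @param quiet Suppress the lowercase-input warning message.
#' @return A data frame of hits with columns `contig`, `start` (0-based),
#'   `strand`, `motif_name`, `hre_class`, `width`, sorted by
#'   (contig, start, motif_name).
#' @export
scan_genome <- function(genome, motifs = default_motifs(), quiet = FALSE) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  stopifnot(is.character(genome))
  if (length(genome) > 0L && (is.null(names(genome)) || anyNA(names(genome)) ||
                              any(!nzchar(names(genome))))) {
    stop("genome contigs must be named", call. = FALSE)
  }
  if (is.list(motifs) && inherits(motifs, "motif_pattern")) motifs <- list(motifs)
  stopifnot(all(vapply(motifs, inherits, logical(1L), "motif_pattern")))

  has_lower <- vapply(genome, function(s) grepl("[a-z]", s), logical(1L))
  if (any(has_lower)) {
    if (!quiet) {
      message(sprintf("uppercasing %d contig(s) containing lowercase (soft-masked) bases",
                      sum(has_lower)))
    }
    genome[has_lower] <- toupper(genome[has_lower])
  }

  out <- list()
  for (contig in names(genome)) {
    seq <- genome[[contig]]
    .check_sequence_chars(strsplit(toupper(seq), "", fixed = TRUE)[[1L]], contig)
    for (motif in motifs) {
      fwd <- scan_forward(seq, motif)
      if (length(fwd) > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          contig = contig, start = fwd, strand = "+",
          motif_name = motif$name, hre_class = motif$hre_class,
          width = motif$length, stringsAsFactors = FALSE)
      }
      if (!motif$palindromic) {
        rc <- motif_pattern(motif$name, reverse_complement_iupac(motif$iupac),
                            motif$hre_class)
        rev_hits <- scan_forward(seq, rc)
        if (length(rev_hits) > 0L) {
          out[[length(out) + 1L]] <- data.frame(
            contig = contig, start = rev_hits, strand = "-",
            motif_name = motif$name, hre_class = motif$hre_class,
            width = motif$length, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      strand = character(0), motif_name = character(0),
                      hre_class = character(0), width = integer(0),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$contig, hits$start, hits$motif_name), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Read a (possibly gzipped) multi-contig FASTA genome
#'
#' @param path FASTA file path.
#' @return A `Biostrings::DNAStringSet`; contig names are truncated at the
#'   first whitespace, as is conventional.
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write motif hits as BED6
#'
#' BED is 0-based half-open, matching the internal hit coordinates directly.
#' The score column is 0.
#'
#' @param hits Hit data frame from [scan_genome()].
#' @param path Output path.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$contig, hits$start, hits$start + hits$width,
                    hits$motif_name, 0L, hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
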