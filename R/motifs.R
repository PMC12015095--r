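# Hormone response element motifs: degenerate IUPAC patterns over {A,C,G,T,N}.
# 'N' in a motif is a spacer that matches an unambiguous base (A/C/G/T) in the
# subject sequence; it never matches an assembly 'N'.

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", N = "N",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D"
)

MOTIF_ALPHABET <- c("A", "C", "G", "T", "N")
HRE_CLASSES <- c("ARE", "ERE")

#' Reverse complement of a degenerate IUPAC DNA string
#'
#' Complements each character under the IUPAC pairing rules (`N` maps to `N`,
#' `R` to `Y`, and so on) and reverses the result. Palindromy of a degenerate
#' motif is defined as equality with its own reverse complement, which is how
#' the two canonical hormone response elements (AGAACANNNTGTTCT and
#' GGTCANNNTGACC) come out palindromic.
#'
#' @param iupac A single character string over the IUPAC alphabet.
#' @return The reverse-complemented string, uppercase.
#' @examples
#' reverse_complement_iupac("AAGG")            # "CCTT"
#' reverse_complement_iupac("AGAACANNNTGTTCT") # itself: a palindrome
#' @export
reverse_complement_iupac <- function(iupac) {
  stopifnot(is.character(iupac), length(iupac) == 1L, !is.na(iupac))
  chars <- strsplit(toupper(iupac), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(IUPAC_COMPLEMENT))
  if (length(bad) > 0L) {
    stop(sprintf("unsupported IUPAC character '%s' at position %d",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Construct a validated motif pattern
#'
#' @param name Short unique label for the motif.
#' @param iupac Degenerate DNA string over A/C/G/T/N, at least 4 bases.
#'   (Further IUPAC codes are rejected here: the scanner's semantics are only
#'   specified and tested for the spacer code `N`.)
#' @param hre_class `"ARE"` or `"ERE"`.
#' @return An object of class `motif_pattern` with fields `name`, `iupac`,
#'   `length`, `palindromic` (computed, never user-set) and `hre_class`.
#' @export
motif_pattern <- function(name, iupac, hre_class = c("ARE", "ERE")) {
  hre_class <- match.arg(hre_class)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  iupac <- toupper(iupac)
  chars <- strsplit(iupac, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% MOTIF_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("motif '%s': unsupported character '%s' at position %d (allowed: %s)",
                 name, chars[bad[1L]], bad[1L],
                 paste(MOTIF_ALPHABET, collapse = "")), call. = FALSE)
  }
  if (length(chars) < 4L) {
    stop(sprintf("motif '%s' is shorter than 4 bases", name), call. = FALSE)
  }
  structure(
    list(name = name, iupac = iupac, length = length(chars),
         palindromic = identical(reverse_complement_iupac(iupac), iupac),
         hre_class = hre_class),
    class = "motif_pattern"
  )
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif %s: %s (%s, %d bp%s)>\n", x$name, x$iupac, x$hre_class,
              x$length, if (x$palindromic) ", palindromic" else ""))
  invisible(x)
}

#' Read motif definitions from a TSV file
#'
#' Expects two or three tab-separated columns per line: name, IUPAC string and
#' an optional class (`ARE`/`ERE`, default `ARE`). Lines starting with `#` and
#' blank lines are ignored.
#'
#' @param path Path to the motif file.
#' @return A named list of [motif_pattern] objects.
#' @seealso [default_motifs()] for the two canonical motifs shipped with the
#'   package.
#' @export
parse_motif_file <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("motif file contains no motif definitions", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  motifs <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 2L || length(f) > 3L) {
      stop(sprintf("motif file line %d: expected 2 or 3 tab-separated fields, got %d",
                   i, length(f)), call. = FALSE)
    }
    cls <- if (length(f) == 3L) f[3L] else "ARE"
    if (!cls %in% HRE_CLASSES) {
      stop(sprintf("motif file line %d: unknown class '%s'", i, cls), call. = FALSE)
    }
    motif_pattern(f[1L], f[2L], cls)
  })
  names(motifs) <- vapply(motifs, `[[`, character(1L), "name")
  dup <- names(motifs)[duplicated(names(motifs))]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate motif names: %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  }
  motifs
}

#' The two canonical hormone response element motifs
#'
#' The canonical androgen response element AGAACANNNTGTTCT (two palindromic
#' half-sites around a 3-base spacer) and the estrogen response element
#' GGTCANNNTGACC. Additional androgen response elements reported in the
#' literature can be supplied via a user motif file (see [parse_motif_file()]
#' and the file shipped at `system.file("extdata", "hre_motifs.tsv", package =
#' "hrescan")`).
#'
#' @return A named list of two [motif_pattern] objects.
#' @export
default_motifs <- function() {
  list(
    ARE_canonical = motif_pattern("ARE_canonical", "AGAACANNNTGTTCT", "ARE"),
    ERE_canonical = motif_pattern("ERE_canonical", "GGTCANNNTGACC", "ERE")
  )
}
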