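# Tagging scheme for multiplexed amplicon reads:
# read structure is MID + PERMUTAG + linker + primer + insert.

#' Expand a degenerate IUPAC pattern into all concrete DNA sequences
#'
#' The PERMUTAG is an 8-base degenerate tag inserted between the multiplex
#' identifier and the primer. Its default pattern `WGNGNNGW` (W = A/T,
#' N = A/C/G/T) expands to 2*1*4*1*4*4*1*2 = 256 distinct tags, enough to
#' discriminate independent template molecules from emulsion-PCR duplicates.
#'
#' @param pattern a non-empty IUPAC nucleotide string.
#' @return character vector of all concrete expansions (no duplicates).
#' @examples
#' length(expand_degenerate("WGNGNNGW"))  # 256
#' expand_degenerate("ACGT")              # itself
#' @export
expand_degenerate <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) == 0L)
    stop("pattern must be a single non-empty string", call. = FALSE)
  ch <- validate_iupac(pattern)
  sets <- IUPAC_CODES[ch]
  grid <- do.call(expand.grid,
                  c(rev(unname(sets)), stringsAsFactors = FALSE))
  # rev() so the leftmost position varies slowest -> lexicographic order
  out <- do.call(paste0, rev(grid))
  sort(unique(out))
}

#' Construct a tagging scheme
#'
#' Bundles the multiplex identifiers (MIDs), the degenerate PERMUTAG pattern,
#' the two-base linker and the amplification primers that together define the
#' read structure `MID + PERMUTAG + linker + forward primer + insert`.
#'
#' MIDs are designed barcodes and must all share one length; they are matched
#' exactly during demultiplexing. Names of `mids` are the library identifiers.
#'
#' @param mids named character vector of MID barcode sequences (A/C/G/T only),
#'   named by library id.
#' @param permutag_pattern IUPAC pattern of the degenerate tag.
#' @param linker linker sequence between tag and primer.
#' @param forward_primer,reverse_primer amplification primers (IUPAC allowed);
#'   defaults are the 27F and 530R universal 16S rDNA primers.
#' @return an object of class `tag_scheme`.
#' @export
tag_scheme <- function(mids,
                       permutag_pattern = "WGNGNNGW",
                       linker = "TC",
                       forward_primer = "AGAGTTTGATCMTGGCTCAG",
                       reverse_primer = "CCGCGGCKGCTGGCAC") {
  if (length(mids) == 0L) stop("scheme needs at least one MID", call. = FALSE)
  if (is.null(names(mids)) || anyDuplicated(names(mids)))
    stop("mids must be uniquely named by library id", call. = FALSE)
  mids <- toupper(mids)
  if (any(grepl("[^ACGT]", mids)))
    stop("MIDs must contain only A/C/G/T", call. = FALSE)
  if (length(unique(nchar(mids))) != 1L)
    stop("all MIDs must have the same length", call. = FALSE)
  if (anyDuplicated(mids)) stop("MID sequences must be distinct", call. = FALSE)
  validate_iupac(permutag_pattern, "permutag_pattern")
  validate_iupac(linker, "linker")
  validate_iupac(forward_primer, "forward_primer")
  validate_iupac(reverse_primer, "reverse_primer")
  structure(list(mids = mids,
                 permutag_pattern = toupper(permutag_pattern),
                 linker = toupper(linker),
                 forward_primer = toupper(forward_primer),
                 reverse_primer = toupper(reverse_primer)),
            class = "tag_scheme")
}

#' @export
print.tag_scheme <- function(x, ...) {
  cat(sprintf("tag_scheme: %d MIDs (length %d), PERMUTAG %s (%d expansions), linker %s\n",
              length(x$mids), nchar(x$mids[[1L]]), x$permutag_pattern,
              prod(lengths(IUPAC_CODES[iupac_chars(x$permutag_pattern)])),
              x$linker))
  cat(sprintf("  forward primer %s, reverse primer %s\n",
              x$forward_primer, x$reverse_primer))
  invisible(x)
}

#' Test concrete tags against a degenerate pattern, positionwise
#'
#' @param tags character vector of concrete tags.
#' @param pattern IUPAC pattern.
#' @return logical vector; `TRUE` where the tag matches the pattern at every
#'   position (length must match too).
#' @export
permutag_matches <- function(tags, pattern) {
  n <- nchar(pattern)
  ok <- nchar(tags) == n
  ok[is.na(ok)] <- FALSE
  idx <- which(ok)
  if (length(idx)) ok[idx] <- iupac_mismatches(tags[idx], pattern) == 0L
  ok
}

#' Generate a set of distinct MID barcodes
#'
#' Deterministic for a fixed seed; used by the synthetic-data module (the
#' original study's MID list is instrument-vendor configuration, so synthetic
#' runs draw their own).
#'
#' @param library_ids character vector of library identifiers to barcode.
#' @param width barcode length in bases.
#' @param seed integer seed.
#' @return named character vector of MIDs, one per library.
#' @export
make_mids <- function(library_ids, width = 8L, seed = 1L) {
  n <- length(library_ids)
  if (n == 0L) stop("library_ids is empty", call. = FALSE)
  if (4^width < n * 4) stop("width too small for that many MIDs", call. = FALSE)
  hamming <- function(a, b) sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  with_seed(seed, {
    mids <- character(0)
    while (length(mids) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
                    collapse = "")
      # demux matches MIDs exactly, so require pairwise distance >= 2 so a
      # single substitution cannot turn one code into another
      if (!length(mids) || min(vapply(mids, hamming, 0L, a = cand)) >= 2L)
        mids <- c(mids, cand)
    }
    names(mids) <- library_ids
    mids
  })
}
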