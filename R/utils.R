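# Shared low-level helpers: IUPAC degeneracy, seed splitting, headed TSV I/O.

# IUPAC nucleotide codes and the concrete bases each stands for.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

TAX_RANKS <- c("root", "domain", "phylum", "class", "order", "family",
               "genus", "species")

#' Derive a child seed from a parent seed and a stage label
#'
#' All randomness in the synthetic-data module flows from one user seed;
#' independent stages (taxonomy, community, reads, hits, ...) draw their own
#' seeds from it so each stage is reproducible in isolation.
#'
#' @param seed integer parent seed.
#' @param tag character stage label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  s <- (abs(seed) %% m)
  for (k in utf8ToInt(tag)) {
    s <- (s * 31 + k) %% m
  }
  as.integer(s %% (m - 1L) + 1L)
}

#' @keywords internal
iupac_chars <- function(pattern) strsplit(pattern, "", fixed = TRUE)[[1L]]

#' @keywords internal
validate_iupac <- function(pattern, what = "pattern") {
  ch <- iupac_chars(toupper(pattern))
  bad <- which(!ch %in% names(IUPAC_CODES))
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC character '%s' at position %d of %s",
                 ch[bad[1L]], bad[1L], what), call. = FALSE)
  }
  invisible(ch)
}

# Count mismatches between concrete sequences and an IUPAC pattern of the
# same length, positionwise; vectorized over `seqs`.
iupac_mismatches <- function(seqs, pattern) {
  pat <- validate_iupac(pattern)
  n <- length(pat)
  mism <- integer(length(seqs))
  for (p in seq_len(n)) {
    ok <- substr(seqs, p, p) %in% IUPAC_CODES[[pat[p]]]
    mism <- mism + !ok
  }
  mism
}

#' Write a TSV with a provenance header comment
#'
#' Output files carry a `#`-prefixed header recording the package version,
#' the seed and an optional configuration hash, so a run can be traced back
#' to its inputs.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param seed integer seed recorded in the header (or `NA`).
#' @param config_hash character hash recorded in the header (or `NA`).
#' @return `path`, invisibly.
#' @export
write_headed_tsv <- function(x, path, seed = NA, config_hash = NA) {
  ver <- as.character(utils::packageVersion("orburb"))
  hdr <- sprintf("# orburb %s | seed=%s | config=%s", ver,
                 as.character(seed), as.character(config_hash))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_headed_tsv()]
#' @param path file path.
#' @return a data.frame.
#' @export
read_headed_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Evaluate `expr` with a locally set RNG seed, restoring the caller's RNG
# state afterwards so generators do not clobber the global stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
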