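# Tag-aware read preparation: parse the MID-PERMUTAG-linker-primer
# structure, demultiplex by MID, dereplicate exact duplicates with the
# PERMUTAG treated as part of the sequence, and strip tags.

#' Parse tagged amplicon reads against a scheme
#'
#' Reads are matched stage by stage: the MID exactly at position 0 (with an
#' optional reverse-complement retry), the next bases against the degenerate
#' PERMUTAG pattern positionwise, the linker exactly, and the forward primer
#' allowing at most `primer_mismatch` substitutions (no indels). A read
#' failing any stage is kept as unassigned with the failing stage named
#' (`no_mid`, `bad_permutag`, `bad_linker`, `bad_primer`); the remainder
#' after the primer is the insert.
#'
#' @param reads named character vector of read sequences.
#' @param scheme a [tag_scheme()].
#' @param primer_mismatch maximum substitutions tolerated in the primer.
#' @param check_revcomp if `TRUE`, a read with no MID at its start is also
#'   tried reverse-complemented before being declared `no_mid`.
#' @return an object of class `parsed_reads`: data.frame with columns
#'   `read_id`, `status` (`assigned` or a failure stage), `library_id`,
#'   `permutag`, `insert`, `sequence` (the full, possibly re-oriented read).
#' @export
parse_reads <- function(reads, scheme, primer_mismatch = 2L,
                        check_revcomp = FALSE) {
  stopifnot(inherits(scheme, "tag_scheme"))
  n <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_len(n))
  seqs <- toupper(unname(reads))
  mid_len <- nchar(scheme$mids[[1L]])
  tag_len <- nchar(scheme$permutag_pattern)
  link_len <- nchar(scheme$linker)
  prim_len <- nchar(scheme$forward_primer)
  head_len <- mid_len + tag_len + link_len + prim_len

  status <- rep("assigned", n)
  lib <- rep(NA_character_, n)
  permutag <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)

  too_short <- nchar(seqs) <= head_len
  status[too_short] <- "no_mid"

  mid_of <- function(s) names(scheme$mids)[match(substr(s, 1L, mid_len),
                                                 scheme$mids)]
  lib_try <- mid_of(seqs)
  if (check_revcomp) {
    miss <- which(is.na(lib_try) & !too_short)
    if (length(miss)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[miss])))
      hit <- !is.na(mid_of(rc))
      seqs[miss[hit]] <- rc[hit]
      lib_try[miss[hit]] <- mid_of(rc[hit])
    }
  }
  ok <- !too_short & !is.na(lib_try)
  status[!too_short & is.na(lib_try)] <- "no_mid"
  lib[ok] <- lib_try[ok]

  idx <- which(ok)
  if (length(idx)) {
    tag <- substr(seqs[idx], mid_len + 1L, mid_len + tag_len)
    good_tag <- permutag_matches(tag, scheme$permutag_pattern)
    status[idx[!good_tag]] <- "bad_permutag"
    permutag[idx[good_tag]] <- tag[good_tag]
    idx <- idx[good_tag]
  }
  if (length(idx)) {
    lk <- substr(seqs[idx], mid_len + tag_len + 1L, mid_len + tag_len + link_len)
    good_lk <- lk == scheme$linker
    status[idx[!good_lk]] <- "bad_linker"
    idx <- idx[good_lk]
  }
  if (length(idx)) {
    pr <- substr(seqs[idx], mid_len + tag_len + link_len + 1L, head_len)
    mism <- iupac_mismatches(pr, scheme$forward_primer)
    good_pr <- mism <= primer_mismatch
    status[idx[!good_pr]] <- "bad_primer"
    idx <- idx[good_pr]
  }
  insert[idx] <- substr(seqs[idx], head_len + 1L, nchar(seqs[idx]))
  out <- data.frame(read_id = ids, status = status, library_id = lib,
                    permutag = permutag, insert = insert, sequence = seqs,
                    stringsAsFactors = FALSE)
  class(out) <- c("parsed_reads", "data.frame")
  out
}

#' Dereplicate exact duplicate reads, PERMUTAG included
#'
#' Collapses assigned reads that are identical in length and full tagged
#' sequence -- the PERMUTAG counts as part of the sequence, so two reads with
#' the same insert but different PERMUTAGs (independent template molecules)
#' are both retained, while byte-identical copies (emulsion-PCR duplicates)
#' collapse to the first occurrence in input order.
#'
#' @param parsed a `parsed_reads` data.frame from [parse_reads()].
#' @return an object of class `derep_result`: list with `reads` (the retained
#'   assigned reads, plus a `multiplicity` column), `removed_count`, and
#'   `unassigned` (the non-assigned rows, untouched).
#' @export
dereplicate <- function(parsed) {
  stopifnot(is.data.frame(parsed))
  asg <- parsed[parsed$status == "assigned", , drop = FALSE]
  una <- parsed[parsed$status != "assigned", , drop = FALSE]
  if (nrow(asg) == 0L) {
    asg$multiplicity <- integer(0)
    return(structure(list(reads = asg, removed_count = 0L, unassigned = una),
                     class = "derep_result"))
  }
  key <- asg$sequence  # identical string implies identical length
  first <- !duplicated(key)
  mult <- as.integer(table(factor(key, levels = key[first]))[key[first]])
  out <- asg[first, , drop = FALSE]
  out$multiplicity <- mult
  rownames(out) <- NULL
  structure(list(reads = out,
                 removed_count = nrow(asg) - sum(first),
                 unassigned = una),
            class = "derep_result")
}

#' @export
print.derep_result <- function(x, ...) {
  cat(sprintf("derep_result: %d unique reads, %d duplicates removed, %d unassigned\n",
              nrow(x$reads), x$removed_count, nrow(x$unassigned)))
  invisible(x)
}

#' Strip tags from dereplicated reads
#'
#' Drops MID, PERMUTAG, linker and primer, leaving the clean insert with its
#' library assignment -- the per-library dataset all downstream profiling
#' runs on.
#'
#' @param derep a `derep_result` from [dereplicate()].
#' @return data.frame with columns `read_id`, `library_id`, `insert`.
#' @export
strip_tags <- function(derep) {
  stopifnot(inherits(derep, "derep_result"))
  data.frame(read_id = derep$reads$read_id,
             library_id = derep$reads$library_id,
             insert = derep$reads$insert,
             stringsAsFactors = FALSE)
}

#' Demultiplexing report
#'
#' Per-library counts of assigned reads and of each failure category, plus
#' duplicates removed. Failures after the MID stage are attributed to the
#' read's library; reads with no recognizable MID appear under the
#' pseudo-library `"(no_mid)"`.
#'
#' @param parsed a `parsed_reads` data.frame.
#' @param derep optional `derep_result` (adds the `removed_duplicates` column).
#' @return data.frame, one row per library.
#' @export
demux_report <- function(parsed, derep = NULL) {
  lib <- ifelse(is.na(parsed$library_id), "(no_mid)", parsed$library_id)
  cats <- c("assigned", "no_mid", "bad_permutag", "bad_linker", "bad_primer")
  tab <- table(factor(lib), factor(parsed$status, levels = cats))
  out <- data.frame(library_id = rownames(tab), as.data.frame.matrix(tab),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(derep)) {
    rem <- stats::aggregate(mult ~ lib, data.frame(
      lib = derep$reads$library_id, mult = derep$reads$multiplicity - 1L),
      FUN = sum)
    out$removed_duplicates <- rem$mult[match(out$library_id, rem$lib)]
    out$removed_duplicates[is.na(out$removed_duplicates)] <- 0L
  }
  out
}
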