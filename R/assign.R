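# LCA taxonomic assignment from tabular similarity-search hits, per-rank
# count tables, and the best-hit-identity "fingerprint" distribution.

utils::globalVariables(c("bitscore", "pident", "qseqid", "sseqid",
                         ".keep", ".SD"))

#' Retain the informative hits of each read
#'
#' Drops hits below `min_identity`, then keeps, per read, every hit whose
#' bitscore is at least `score_window` times the read's maximum bitscore
#' (the best hit, and any hit tied with it, is always retained).
#'
#' @param hits 12-column hit data.frame (see [gen_hits()] for the layout).
#' @param min_identity minimum percent identity for a hit to count.
#' @param score_window fraction of the top bitscore defining the retention
#'   window.
#' @return the retained subset of `hits`. Reads whose hits all fall below
#'   `min_identity` disappear from the result (they become unassigned).
#' @export
retain_hits <- function(hits, min_identity = 80, score_window = 0.9) {
  h <- data.table::as.data.table(hits)[pident >= min_identity]
  if (nrow(h) == 0L) return(as.data.frame(h))
  h[, `:=`(.keep = bitscore >= score_window * max(bitscore)), by = qseqid]
  out <- as.data.frame(h[h$.keep == TRUE][, .keep := NULL])
  out
}

#' Assign reads to taxonomy nodes by lowest common ancestor
#'
#' Each read is assigned to the deepest taxonomy node lying on the lineage
#' of every retained hit's subject species. The best retained hit's percent
#' identity is recorded for the fingerprint distribution.
#'
#' @param hits 12-column hit data.frame; `sseqid` must be species node ids
#'   of `tree`.
#' @param tree a [taxonomy_tree()].
#' @inheritParams retain_hits
#' @return data.frame with columns `read_id`, `node_id`, `rank`,
#'   `best_identity`; one row per read that kept at least one hit.
#' @export
assign_reads <- function(hits, tree, min_identity = 80, score_window = 0.9) {
  ret <- retain_hits(hits, min_identity, score_window)
  if (nrow(ret) == 0L)
    return(data.frame(read_id = character(0), node_id = integer(0),
                      rank = character(0), best_identity = numeric(0)))
  sp <- unique(ret$sseqid)
  known <- sp %in% tree$nodes$id[tree$nodes$rank == "species"]
  if (!all(known))
    stop("hit subjects are not species nodes of the tree: ",
         paste(utils::head(sp[!known]), collapse = ", "))
  lm <- lineage_matrix(tree, sp)  # species lineages: full depth, no NAs

  dt <- data.table::data.table(qseqid = ret$qseqid,
                               lm[match(ret$sseqid, sp), , drop = FALSE])
  lv <- TAX_RANKS
  mn <- dt[, lapply(.SD, min), by = qseqid, .SDcols = lv]
  mx <- dt[, lapply(.SD, max), by = qseqid, .SDcols = lv]
  eq <- as.matrix(mn[, lv, with = FALSE]) == as.matrix(mx[, lv, with = FALSE])
  depth <- rowSums(eq)  # lineages agree on a prefix, so eq is TRUE up to depth
  node <- as.matrix(mn[, lv, with = FALSE])[cbind(seq_len(nrow(mn)), depth)]

  best <- data.table::as.data.table(ret)[order(qseqid, -bitscore, sseqid),
                                         .SD[1L], by = qseqid]
  out <- data.frame(read_id = mn$qseqid,
                    node_id = as.integer(node),
                    rank = TAX_RANKS[depth],
                    stringsAsFactors = FALSE)
  out$best_identity <- best$pident[match(out$read_id, best$qseqid)]
  out
}

#' Roll LCA assignments up into a per-rank count table
#'
#' Reads whose assignment is at or below `rank` are counted under their
#' ancestor at `rank`; reads assigned above `rank` (their retained hits span
#' several taxa of that rank) are counted as `"unclassified"`. Reads with no
#' assignment at all are not in the table -- they are reported separately.
#'
#' @param assignments data.frame from [assign_reads()].
#' @param read_libraries named character vector mapping `read_id` to
#'   `library_id` (e.g. built from [strip_tags()] output).
#' @param tree a [taxonomy_tree()].
#' @param rank target rank (default `"family"`).
#' @return integer matrix taxa x libraries with an `"unclassified"` row;
#'   attribute `rank` records the rank. Column sums equal the number of
#'   assigned reads per library.
#' @export
rank_counts <- function(assignments, read_libraries, tree, rank = "family") {
  if (!rank %in% TAX_RANKS) stop("unknown rank: ", rank)
  lib <- read_libraries[assignments$read_id]
  if (anyNA(lib)) stop("read_libraries lacks entries for some assigned reads")
  tgt <- match(rank, TAX_RANKS)
  deep_enough <- match(assignments$rank, TAX_RANKS) >= tgt
  taxon <- rep("unclassified", nrow(assignments))
  if (any(deep_enough)) {
    nodes <- unique(assignments$node_id[deep_enough])
    anc <- ancestor_at_rank(tree, nodes, rank)
    anc_name <- node_name(tree, anc)
    taxon[deep_enough] <- anc_name[match(assignments$node_id[deep_enough], nodes)]
  }
  libs <- sort(unique(unname(read_libraries)))
  taxa <- c(sort(setdiff(unique(taxon), "unclassified")), "unclassified")
  m <- table(factor(taxon, levels = taxa), factor(lib, levels = libs))
  m <- matrix(as.integer(m), nrow = length(taxa),
              dimnames = list(taxa, libs))
  attr(m, "rank") <- rank
  m
}

#' Best-hit identity fingerprint per library
#'
#' Histogram of per-read best-hit percent identities, normalized so the
#' densities of each library sum to 1 -- the per-library shape of this
#' distribution acts as a fingerprint of how far the community sits from the
#' reference database.
#'
#' @inheritParams rank_counts
#' @param bin_width bin width in identity percentage points.
#' @return data.frame with columns `library_id`, `bin_left`, `density`.
#' @export
identity_fingerprint <- function(assignments, read_libraries, bin_width = 1) {
  lib <- read_libraries[assignments$read_id]
  ids <- assignments$best_identity
  lo <- floor(min(ids) / bin_width) * bin_width
  breaks <- seq(lo, 100 + bin_width, by = bin_width)
  by_lib <- split(ids, lib)
  out <- do.call(rbind, lapply(by_lib, function(v) {
    cnt <- table(cut(v, breaks = breaks, right = FALSE))
    data.frame(bin_left = breaks[-length(breaks)],
               density = as.numeric(cnt) / sum(cnt))
  }))
  data.frame(library_id = rep(names(by_lib), each = length(breaks) - 1L),
             out, row.names = NULL, stringsAsFactors = FALSE)
}
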