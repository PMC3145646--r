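# Community statistics: percentage normalization, Bray-Curtis
# dissimilarity, complete-linkage clustering, rarefaction at a chosen rank,
# and Shannon diversity.

#' Normalize a count table to column percentages
#'
#' @param x numeric matrix, taxa x libraries, non-negative.
#' @return matrix of the same shape whose columns each sum to 100.
#' @export
normalize_percent <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  cs <- colSums(x)
  if (any(cs == 0)) {
    bad <- colnames(x)[cs == 0]
    if (is.null(bad)) bad <- which(cs == 0)
    stop("library with zero total count: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sweep(x, 2, cs, "/") * 100
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`: 0 for identical profiles, 1 for disjoint
#' supports.
#'
#' @param x,y non-negative numeric vectors of equal length, not both all-zero.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative", call. = FALSE)
  tot <- sum(x + y)
  if (tot == 0) stop("both vectors are all-zero", call. = FALSE)
  sum(abs(x - y)) / tot
}

#' Bray-Curtis distance matrix over the libraries of an abundance table
#'
#' @param x numeric matrix, taxa x libraries.
#' @return a `dist` object over the columns of `x`.
#' @export
bray_curtis_matrix <- function(x) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 2L) stop("need at least two libraries", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- bray_curtis(x[, i], x[, j])
  }
  stats::as.dist(d)
}

#' Complete-linkage hierarchical clustering of libraries
#'
#' Agglomerative clustering where the distance between two clusters is the
#' maximum pairwise distance between their members, as used for the
#' between-library dendrogram.
#'
#' @param d a `dist` object (e.g. from [bray_curtis_matrix()]).
#' @return an object of class `hclust`.
#' @export
cluster_complete <- function(d) {
  if (attr(d, "Size") < 2L) stop("need at least two libraries", call. = FALSE)
  stats::hclust(d, method = "complete")
}

#' Export a dendrogram as a newick string
#'
#' Branch lengths are derived from the merge heights.
#'
#' @param hc an `hclust` object.
#' @param path optional file to write to.
#' @return the newick string, invisibly if `path` is given.
#' @export
export_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Expected taxon richness under rarefaction
#'
#' Analytic mode evaluates the hypergeometric expectation
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))` for each depth
#' `n` (computed on the log scale for stability); resampling mode averages
#' the observed richness of seeded random subsamples.
#'
#' @param counts non-negative integer vector of per-taxon counts.
#' @param depths subsample depths, each `<= sum(counts)`.
#' @param mode `"analytic"` (deterministic, the default) or `"resample"`.
#' @param nrep number of subsamples in resampling mode.
#' @param seed integer seed for resampling mode.
#' @return numeric vector of expected richness, one per depth.
#' @export
rarefaction <- function(counts, depths, mode = c("analytic", "resample"),
                        nrep = 100L, seed = 1L) {
  mode <- match.arg(mode)
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(depths > N)) stop("depth exceeds total count", call. = FALSE)
  if (any(depths < 0)) stop("negative depth", call. = FALSE)
  if (mode == "analytic") {
    vapply(depths, function(n) {
      if (n == 0) return(0)
      sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
    }, numeric(1))
  } else {
    pool <- rep(seq_along(counts), counts)
    with_seed(seed, {
      vapply(depths, function(n) {
        if (n == 0) return(0)
        mean(vapply(seq_len(nrep), function(r)
          length(unique(sample(pool, n))), numeric(1)))
      }, numeric(1))
    })
  }
}

#' Rarefaction curves for every library of a count table
#'
#' @param x integer matrix, taxa x libraries.
#' @param depths depths to evaluate; defaults to 10 points up to each
#'   library's own total.
#' @param ... passed to [rarefaction()].
#' @return data.frame with columns `library_id`, `depth`, `expected_richness`.
#' @export
rarefaction_curves <- function(x, depths = NULL, ...) {
  out <- lapply(colnames(x), function(lib) {
    tot <- sum(x[, lib])
    dp <- if (is.null(depths)) unique(round(seq(1, tot, length.out = 10)))
          else depths[depths <= tot]
    data.frame(library_id = lib, depth = dp,
               expected_richness = rarefaction(x[, lib], dp, ...),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Shannon diversity index (natural log)
#'
#' `H = -sum(p_i * log(p_i))` over taxa with positive abundance.
#'
#' @param counts non-negative numeric vector with a positive sum.
#' @return the Shannon index.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  s <- sum(counts)
  if (s == 0) stop("all counts are zero", call. = FALSE)
  p <- counts[counts > 0] / s
  -sum(p * log(p))
}

#' Per-library diversity summary
#'
#' @param x numeric matrix, taxa x libraries.
#' @return data.frame with columns `library_id`, `richness`, `shannon`.
#' @export
diversity_table <- function(x) {
  data.frame(library_id = colnames(x),
             richness = colSums(x > 0),
             shannon = apply(x, 2, shannon),
             row.names = NULL, stringsAsFactors = FALSE)
}
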