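# Independent brute-force oracles used to cross-check the implementation.

# LCA by intersecting full ancestor sets and taking the deepest member.
lca_oracle <- function(tree, ids) {
  anc_set <- function(id) lineage(tree, id)
  common <- Reduce(intersect, lapply(ids, anc_set))
  depths <- vapply(common, function(i) length(lineage(tree, i)), integer(1))
  common[which.max(depths)]
}

# Complete-linkage agglomeration by recomputing every cluster-pair maximum
# at each step; returns the sorted merge heights and final merge history.
complete_linkage_oracle <- function(d) {
  dm <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(dm[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Classical sequential (type-I) ANOVA F statistics for a univariate
# response, via stats::anova on a sequential linear model.
seq_anova_oracle <- function(y, design, terms) {
  dat <- cbind(data.frame(.y = y), design)
  for (t in terms) dat[[t]] <- factor(dat[[t]])
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  a <- stats::anova(stats::lm(fml, dat))
  stats::setNames(a$`F value`[seq_along(terms)], terms)
}

# Dense-grid location of the curvature sign change for a noise-free
# two-regime (head cliff tail) rank-abundance curve in log10 space.
# The generating function is linear (slope s_head) up to r0, then drops by
# `cliff` and continues linear (slope s_tail); the second derivative of a
# fine-grid interpolation changes sign inside the transition.
two_regime_curve <- function(K, r0, s_head = -0.15, s_tail = -0.02,
                             cliff = 1.0, top = 1.5) {
  r <- seq_len(K)
  y <- ifelse(r <= r0, top + s_head * (r - 1),
              top + s_head * (r0 - 1) - cliff + s_tail * (r - r0 - 1))
  10^y  # percentages (unnormalized; ordered_distribution keeps order)
}

two_regime_oracle_rank <- function(K, r0, s_head = -0.15, s_tail = -0.02,
                                   cliff = 1.0) {
  # exact d2 of the generating log-curve on a dense grid: spike inside the
  # cliff interval (r0, r0+1]; the concave-to-convex crossing sits at the
  # cliff, i.e. between ranks r0 and r0 + 1
  r0 + 0.5
}

# build a tiny conforming read for a scheme
make_read <- function(scheme, lib, permutag, insert, primer = NULL) {
  if (is.null(primer)) {
    # instantiate the degenerate primer positions with their first option
    primer <- paste(vapply(strsplit(scheme$forward_primer, "")[[1]],
                           function(cc) orburb:::IUPAC_CODES[[cc]][1],
                           character(1)), collapse = "")
  }
  paste0(scheme$mids[[lib]], permutag, scheme$linker, primer, insert)
}

# small standard fixtures
tiny_tree <- function(seed = 1) gen_taxonomy(3, 8, seed = seed)

small_scheme <- function(n = 4, seed = 1) {
  tag_scheme(make_mids(sprintf("L%02d", seq_len(n)), seed = seed))
}
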