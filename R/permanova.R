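# Sequential permutational multivariate analysis of variance on a distance
# matrix (the Adonis-style decomposition behind the active-vs-total,
# sample and fraction variance table).

#' Sequential PERMANOVA on a distance matrix
#'
#' Partitions the total sum of squares of a distance matrix among design
#' factors, fitted sequentially in the given order. The Gower-centered
#' inner-product matrix is `G = -1/2 * J %*% D^2 %*% J` with `J` the centering
#' projector; the total SS is `trace(G)`; each term's sequential SS is
#' `trace(H_k %*% G)` for the orthogonal projector `H_k` onto the column
#' space that term adds beyond the terms before it. The pseudo-F statistic is
#' `(SS_k / df_k) / (SS_res / df_res)` and its p-value comes from freely
#' permuting library labels, with the `(count + 1) / (n_perm + 1)` convention
#' so a finite permutation run never reports p = 0.
#'
#' A term whose contrasts are entirely absorbed by earlier terms (for
#' example a five-level fraction factor fitted after the active-vs-total
#' contrast loses one of its four contrasts) simply contributes fewer
#' degrees of freedom; a term reduced to zero degrees of freedom is reported
#' as aliased and gets no test.
#'
#' @param d a `dist` object or symmetric distance matrix over libraries.
#' @param design data.frame with one row per library, in the order of `d`'s
#'   labels; factor columns named by `terms`.
#' @param terms character vector of design column names, fitted in this
#'   order (order changes the sequential SS).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @return an object of class `variance_decomposition`: a data.frame with
#'   rows for each term, `Residuals` and `Total`, and columns `Df`,
#'   `SumsOfSqs`, `MeanSqs`, `F.Model`, `R2`, `Pr..F.`.
#' @export
permanova <- function(d, design, terms, n_perm = 999L, seed = 1L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n != ncol(dm) || max(abs(dm - t(dm))) > 1e-8)
    stop("d must be a symmetric distance matrix", call. = FALSE)
  if (nrow(design) != n)
    stop("design must have one row per library", call. = FALSE)
  miss <- setdiff(terms, names(design))
  if (length(miss)) stop("terms not in design: ", paste(miss, collapse = ", "),
                         call. = FALSE)

  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% dm^2 %*% J
  ss_total <- sum(diag(G))

  # incremental orthogonal projectors, one per term
  proj <- function(X) {
    qr_ <- qr(X)
    Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
    tcrossprod(Q)
  }
  X <- matrix(1, n, 1)
  P_prev <- proj(X)
  rank_prev <- 1L
  H <- list(); df <- integer(length(terms))
  for (k in seq_along(terms)) {
    f <- factor(design[[terms[k]]])
    if (nlevels(f) >= 2L)
      X <- cbind(X, stats::model.matrix(~ f)[, -1, drop = FALSE])
    qr_ <- qr(X)
    P_cur <- proj(X)
    H[[k]] <- P_cur - P_prev
    df[k] <- qr_$rank - rank_prev
    P_prev <- P_cur
    rank_prev <- qr_$rank
  }
  H_res <- diag(n) - P_prev
  df_res <- n - rank_prev
  if (df_res <= 0) stop("no residual degrees of freedom", call. = FALSE)
  aliased <- terms[df == 0L]
  if (length(aliased))
    message("term(s) fully aliased by earlier terms: ",
            paste(aliased, collapse = ", "))

  stat_for <- function(Gm) {
    ss <- vapply(H, function(h) sum(h * Gm), numeric(1))
    ss_res <- sum(H_res * Gm)
    f <- ifelse(df > 0L, (ss / pmax(df, 1L)) / (ss_res / df_res), NA_real_)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- stat_for(G)

  p <- rep(NA_real_, length(terms))
  if (n_perm > 0L) {
    exceed <- integer(length(terms))
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        pm <- sample.int(n)
        fp <- stat_for(G[pm, pm])$f
        exceed <- exceed + (!is.na(fp) & fp >= obs$f - 1e-12)
      }
    })
    p <- ifelse(df > 0L, (exceed + 1) / (n_perm + 1), NA_real_)
  }

  out <- data.frame(
    Df = c(df, df_res, n - 1L),
    SumsOfSqs = c(obs$ss, obs$ss_res, ss_total),
    MeanSqs = c(ifelse(df > 0L, obs$ss / pmax(df, 1L), NA_real_),
                obs$ss_res / df_res, NA_real_),
    F.Model = c(obs$f, NA_real_, NA_real_),
    R2 = c(obs$ss / ss_total, obs$ss_res / ss_total, 1),
    `Pr..F.` = c(p, NA_real_, NA_real_),
    row.names = c(terms, "Residuals", "Total"),
    check.names = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "aliased") <- aliased
  class(out) <- c("variance_decomposition", "data.frame")
  out
}

#' @export
print.variance_decomposition <- function(x, digits = 3, ...) {
  cat(sprintf("Sequential PERMANOVA (%d permutations)\n", attr(x, "n_perm")))
  y <- as.data.frame(x)
  names(y) <- c("Df", "SumsOfSqs", "MeanSqs", "F.Model", "R2", "Pr(>F)")
  print(round(y, digits))
  if (length(attr(x, "aliased")))
    cat("aliased term(s):", paste(attr(x, "aliased"), collapse = ", "), "\n")
  invisible(x)
}
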