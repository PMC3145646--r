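# ORB/URB classification: inflection-point detection on ordered family
# distributions, consensus cut-off selection, over/under-represented
# labelling, and the per-family active-vs-total Welch comparison.

#' Ordered percentage distribution of a library
#'
#' Families present in the library (percentage > 0), sorted by descending
#' percentage; ties broken alphabetically by family name so the ranking is
#' deterministic.
#'
#' @param pct named numeric vector of family percentages for one library.
#' @param library_id label carried through to diagnostics.
#' @return an object of class `ordered_distribution`: data.frame with
#'   columns `rank`, `family`, `pct`.
#' @export
ordered_distribution <- function(pct, library_id = "library") {
  if (length(pct) == 0L || all(pct == 0)) stop("empty library", call. = FALSE)
  fam <- names(pct)
  if (is.null(fam)) fam <- sprintf("taxon%03d", seq_along(pct))
  keep <- pct > 0
  pct <- pct[keep]; fam <- fam[keep]
  o <- order(-pct, fam)
  out <- data.frame(rank = seq_along(o), family = fam[o], pct = unname(pct[o]),
                    stringsAsFactors = FALSE)
  attr(out, "library_id") <- library_id
  class(out) <- c("ordered_distribution", "data.frame")
  out
}

#' Locate inflection points on an ordered abundance curve
#'
#' Fits a local linear regression of `log10(percentage)` against rank (span
#' given as a fraction of the points), evaluates the smoothed curve at each
#' rank, takes its second derivative by central finite differences, and
#' reports the ranks where that second derivative changes sign. On a pure
#' geometric decay -- log-linear in rank -- the smoothed curve is linear and
#' no inflection is reported. A local quadratic smoother is available via
#' `degree = 2`, but it overshoots ("rings") around the sharp head-to-tail
#' drop of strongly two-regime curves, scattering echo inflections into the
#' tail; the damped linear fit keeps the regime change as the dominant sign
#' change.
#'
#' Sampling noise in the rare tail (families drawn at a handful of reads)
#' wrinkles the smoothed curve, so a sign change only counts as an
#' inflection when the curvature on both of its sides is *prominent*: at
#' least `min_prominence` times the curve's maximum absolute second
#' derivative. Weak reversals riding on the tail are thereby ignored while
#' the dominant head-to-tail regime change is kept.
#'
#' @param dist an [ordered_distribution()].
#' @param span smoother span as a fraction of the number of families; for
#'   very short curves the span is widened to keep at least five points in
#'   each local window.
#' @param zero_tol absolute second-derivative values below this are treated
#'   as zero (guards against floating-point jitter on exactly log-linear
#'   curves).
#' @param min_prominence fraction of the maximum absolute second derivative
#'   below which curvature is ignored when pairing sign changes.
#' @param degree degree of the local regression (1 = linear, the default;
#'   2 = quadratic).
#' @return list with `rank`, `smoothed` (log10 scale), `second_derivative`
#'   (NA at the two boundary ranks), `inflections` (integer ranks), and
#'   `too_short` (TRUE when fewer than 5 families were available).
#' @export
find_inflections <- function(dist, span = 0.5, zero_tol = 1e-6,
                             min_prominence = 0.2, degree = 1L) {
  K <- nrow(dist)
  if (K < 5L) {
    return(list(rank = dist$rank, smoothed = log10(dist$pct),
                second_derivative = rep(NA_real_, K),
                inflections = integer(0), too_short = TRUE))
  }
  y <- log10(dist$pct)
  r <- dist$rank
  span_used <- max(span, min(1, 5 / K))
  fit <- stats::loess(y ~ r, span = span_used, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  s <- stats::predict(fit, r)
  d2 <- rep(NA_real_, K)
  d2[2:(K - 1L)] <- s[3:K] - 2 * s[2:(K - 1L)] + s[1:(K - 2L)]
  sg <- sign(d2)
  thr <- max(zero_tol, min_prominence * max(abs(d2), na.rm = TRUE))
  sg[!is.na(d2) & abs(d2) < thr] <- 0
  inner <- 2:(K - 1L)
  infl <- integer(0)
  prev <- 0; prev_rank <- NA_integer_
  for (i in inner) {
    if (is.na(sg[i]) || sg[i] == 0) next
    if (prev != 0 && sg[i] != prev) infl <- c(infl, prev_rank)
    prev <- sg[i]; prev_rank <- i
  }
  list(rank = r, smoothed = s, second_derivative = d2,
       inflections = infl, too_short = FALSE)
}

#' Cut-off of one library from its inflection points
#'
#' The cut-off is the smoothed percentage at the *last* inflection point --
#' the sign change nearest the low-abundance end of the descending-sorted
#' curve (the boundary where the head regime finally hands over to the
#' tail). `direction = "first"` selects the opposite reading.
#'
#' @param infl result of [find_inflections()].
#' @param direction `"last"` (default) or `"first"`.
#' @return the cut-off percentage, or `NA` if the curve has no inflection.
#' @export
library_cutoff <- function(infl, direction = c("last", "first")) {
  direction <- match.arg(direction)
  if (length(infl$inflections) == 0L) return(NA_real_)
  r <- if (direction == "last") max(infl$inflections) else min(infl$inflections)
  10^infl$smoothed[match(r, infl$rank)]
}

#' Consensus cut-off across libraries
#'
#' Histograms the per-library cut-offs on a log10 scale in bins of
#' `bin_width` centred on integer multiples of `bin_width`, and returns the
#' geometric midpoint of the most populated bin (the "most recurrent"
#' inflection value). Ties go to the lower bin.
#'
#' @param cutoffs numeric vector of per-library cut-off percentages
#'   (`NA`s, from libraries without inflections, are dropped).
#' @param bin_width histogram bin width in log10 units.
#' @return the consensus cut-off percentage.
#' @export
consensus_cutoff <- function(cutoffs, bin_width = 0.25) {
  cutoffs <- cutoffs[!is.na(cutoffs)]
  if (length(cutoffs) == 0L)
    stop("no library produced an inflection cut-off; supply one manually",
         call. = FALSE)
  lg <- log10(cutoffs)
  centre <- round(lg / bin_width)  # bin = (centre*bw - bw/2, centre*bw + bw/2]
  tab <- table(centre)
  best <- as.numeric(names(tab)[tab == max(tab)])
  10^(min(best) * bin_width)
}

#' Run the whole cut-off analysis on a percentage table
#'
#' Builds each library's ordered distribution, finds its inflection points
#' and cut-off, and derives the consensus cut-off, keeping the smoothing
#' diagnostics (smoothed curve and second derivative per rank) for each
#' library.
#'
#' @param pct numeric matrix, families x libraries, columns in percent.
#' @param span,zero_tol,min_prominence passed to [find_inflections()].
#' @param direction passed to [library_cutoff()].
#' @param bin_width passed to [consensus_cutoff()].
#' @return an object of class `cutoff_result`: list with `per_library`
#'   (data.frame `library_id`, `cutoff`, `n_inflections`), `consensus`,
#'   `diagnostics` (long data.frame of rank-level curves), `span`,
#'   `direction`.
#' @export
cutoff_analysis <- function(pct, span = 0.5, zero_tol = 1e-6,
                            min_prominence = 0.2,
                            direction = "last", bin_width = 0.25) {
  libs <- colnames(pct)
  per <- data.frame(library_id = libs, cutoff = NA_real_,
                    n_inflections = 0L, stringsAsFactors = FALSE)
  diags <- list()
  for (l in seq_along(libs)) {
    od <- ordered_distribution(pct[, l], libs[l])
    fi <- find_inflections(od, span = span, zero_tol = zero_tol,
                           min_prominence = min_prominence)
    per$cutoff[l] <- library_cutoff(fi, direction = direction)
    per$n_inflections[l] <- length(fi$inflections)
    diags[[l]] <- data.frame(library_id = libs[l], rank = od$rank,
                             family = od$family, pct = od$pct,
                             smoothed_log10 = fi$smoothed,
                             second_derivative = fi$second_derivative,
                             stringsAsFactors = FALSE)
  }
  structure(list(per_library = per,
                 consensus = consensus_cutoff(per$cutoff, bin_width),
                 diagnostics = do.call(rbind, diags),
                 span = span, direction = direction),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("cutoff_result: consensus cut-off %.4g%% (span %.2f, %s inflection)\n",
              x$consensus, x$span, x$direction))
  print(x$per_library)
  invisible(x)
}

#' Classify families as over- or under-represented
#'
#' A family is ORB (over-represented) in a library when its percentage
#' exceeds the cut-off, URB (under-represented) when it is positive but at
#' or below the cut-off; a percentage exactly at the cut-off is URB. At the
#' group level (active vs total) the family's median percentage across the
#' group's libraries decides, and a family counts as present in a group if
#' it appears in any of its libraries.
#'
#' @param pct numeric matrix, families x libraries, in percent.
#' @param cutoff positive cut-off percentage (e.g. the consensus).
#' @param design optional design data.frame (columns `library_id`, `group`)
#'   enabling the per-group classification.
#' @return an object of class `orb_urb`: list with `per_library` (character
#'   matrix of `"ORB"`/`"URB"`/`NA`), `per_group` (data.frame `family`,
#'   `group`, `median_pct`, `present`, `label`), `counts` (per-group class
#'   totals), `cutoff`.
#' @export
classify <- function(pct, cutoff, design = NULL) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  lab <- ifelse(pct > cutoff, "ORB", ifelse(pct > 0, "URB", NA_character_))
  dim(lab) <- dim(pct); dimnames(lab) <- dimnames(pct)
  per_group <- NULL; counts <- NULL
  if (!is.null(design)) {
    groups <- unique(design$group)
    per_group <- do.call(rbind, lapply(groups, function(g) {
      libs <- design$library_id[design$group == g]
      sub <- pct[, libs, drop = FALSE]
      med <- apply(sub, 1, stats::median)
      data.frame(family = rownames(pct), group = g, median_pct = med,
                 present = rowSums(sub > 0) > 0,
                 label = ifelse(med > cutoff, "ORB", "URB"),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
    pres <- per_group[per_group$present, ]
    counts <- as.data.frame(table(group = pres$group, label = pres$label),
                            stringsAsFactors = FALSE)
  }
  structure(list(per_library = lab, per_group = per_group, counts = counts,
                 cutoff = cutoff),
            class = "orb_urb")
}

#' @export
print.orb_urb <- function(x, ...) {
  cat(sprintf("orb_urb classification at cut-off %.4g%%\n", x$cutoff))
  if (!is.null(x$counts)) print(x$counts)
  invisible(x)
}

#' Welch's unequal-variance two-sample t statistic
#'
#' Handles the degenerate zero-variance cases explicitly: equal means with
#' zero variance in both groups give `t = 0, p = 1`; unequal means with zero
#' variance are flagged degenerate (`p = 0`) rather than silently divided.
#'
#' @param a,b numeric vectors (each of length >= 2 for a finite df).
#' @return list with `t`, `df` (Welch-Satterthwaite), `p` (two-sided),
#'   `degenerate`.
#' @export
welch_test <- function(a, b) {
  na_ <- length(a); nb_ <- length(b)
  if (na_ < 2L || nb_ < 2L)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, degenerate = FALSE))
  va <- stats::var(a) / na_; vb <- stats::var(b) / nb_
  dm <- mean(a) - mean(b)
  if (va + vb == 0) {
    if (dm == 0) return(list(t = 0, df = NA_real_, p = 1, degenerate = FALSE))
    return(list(t = sign(dm) * Inf, df = NA_real_, p = 0, degenerate = TRUE))
  }
  t <- dm / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na_ - 1L) + vb^2 / (nb_ - 1L))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, degenerate = FALSE)
}

#' Per-family Welch comparison of active vs total fractions
#'
#' For each family, each subject's active-fraction percentages (PA, LC, HC)
#' are summarized by their median, and likewise the total-fraction
#' percentages (FS, R), giving one active and one total value per subject;
#' the two per-subject vectors are then compared with Welch's t-test. By
#' default a subject whose group median is zero (family absent from that
#' whole group) drops out of that group's vector rather than contributing a
#' zero. With `per_sample_medians = FALSE` the pooled per-library values are
#' compared instead.
#'
#' @param pct numeric matrix, families x libraries, in percent.
#' @param design design data.frame (columns `library_id`, `sample`, `group`).
#' @param alpha two-sided significance level for the `significant` flag.
#' @param per_sample_medians summarize each subject by its median first
#'   (default) or pool libraries.
#' @param include_zeros keep zero medians in the group vectors.
#' @param p_adjust `"none"` (default, per-family raw significance) or
#'   `"BH"` for Benjamini-Hochberg adjusted p-values; the `significant`
#'   flag uses the (possibly adjusted) `p`.
#' @return data.frame, one row per family: `family`, `active_median`,
#'   `total_median`, `max_pct`, `t`, `df`, `p`, `significant`, `degenerate`.
#' @export
welch_family_test <- function(pct, design, alpha = 0.05,
                              per_sample_medians = TRUE,
                              include_zeros = FALSE,
                              p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(all(design$library_id %in% colnames(pct)))
  groups <- split(design, design$group)
  if (!all(c("active", "total") %in% names(groups)))
    stop("design must contain both active and total libraries", call. = FALSE)
  group_values <- function(fam_row, g) {
    dsub <- groups[[g]]
    if (per_sample_medians) {
      v <- vapply(split(dsub$library_id, dsub$sample),
                  function(libs) stats::median(fam_row[libs]), numeric(1))
    } else {
      v <- fam_row[dsub$library_id]
    }
    if (!include_zeros) v <- v[v > 0]
    v
  }
  rows <- lapply(rownames(pct), function(fam) {
    a <- group_values(pct[fam, ], "active")
    b <- group_values(pct[fam, ], "total")
    w <- welch_test(a, b)
    data.frame(family = fam,
               active_median = if (length(a)) stats::median(a) else 0,
               total_median = if (length(b)) stats::median(b) else 0,
               max_pct = max(pct[fam, ]),
               t = w$t, df = w$df, p = w$p,
               significant = !is.na(w$p) && w$p <= alpha,
               degenerate = w$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (p_adjust == "BH") {
    out$p <- stats::p.adjust(out$p, method = "BH")
    out$significant <- !is.na(out$p) & out$p <= alpha
  }
  out
}
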