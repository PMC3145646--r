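# Ordered distributions, inflection detection, cut-off selection,
# ORB/URB classification and the per-family Welch comparison.

test_that("ordered distributions sort descending with alphabetical ties", {
  od <- ordered_distribution(c(B = 30, A = 50, C = 20))
  expect_equal(od$family, c("A", "B", "C"))
  expect_equal(od$pct, c(50, 30, 20))
  expect_equal(sum(od$pct), 100)
  tie <- ordered_distribution(c(Zeta = 25, Alpha = 25, Mid = 25, Beta = 25))
  expect_equal(tie$family, c("Alpha", "Beta", "Mid", "Zeta"))
  # zero-abundance families are dropped, the rest keeps its mass
  oz <- ordered_distribution(c(A = 60, B = 0, C = 40))
  expect_equal(nrow(oz), 2L)
  expect_error(ordered_distribution(numeric(0)), "empty")
})

test_that("a planted two-regime curve yields an inflection at the cliff", {
  # modest smoothing localizes the noise-free regime change sharply; the
  # wider default span trades localization for noise robustness and is
  # validated by the sampled-data recovery tests instead
  for (r0 in c(8, 15, 23)) {
    K <- 50
    od <- ordered_distribution(setNames(two_regime_curve(K, r0),
                                        sprintf("F%02d", 1:K)))
    fi <- find_inflections(od, span = 0.15)
    expect_length(fi$inflections, 1L)
    expect_lte(abs(fi$inflections - two_regime_oracle_rank(K, r0)), 2)
  }
})

test_that("log-linear curves produce no inflection for any span", {
  K <- 40
  pure <- setNames(10^(1.5 - 0.08 * (1:K)), sprintf("F%02d", 1:K))
  od <- ordered_distribution(pure)
  for (span in c(0.3, 0.45, 0.6, 0.8)) {
    fi <- find_inflections(od, span = span)
    expect_length(fi$inflections, 0L)
    expect_true(all(abs(fi$second_derivative[2:(K - 1)]) < 1e-6))
  }
  # constant distributions are flat too
  flat <- ordered_distribution(setNames(rep(2, 10), sprintf("F%02d", 1:10)))
  expect_length(find_inflections(flat)$inflections, 0L)
})

test_that("short curves are flagged instead of smoothed", {
  od <- ordered_distribution(c(A = 50, B = 30, C = 20))
  fi <- find_inflections(od)
  expect_true(fi$too_short)
  expect_length(fi$inflections, 0L)
  expect_true(is.na(library_cutoff(fi)))
})

test_that("the library cutoff takes the last (or first) inflection", {
  infl <- list(rank = 1:60, smoothed = seq(2, -2, length.out = 60),
               inflections = c(5L, 23L))
  expect_equal(library_cutoff(infl), 10^infl$smoothed[23])
  expect_equal(library_cutoff(infl, direction = "first"),
               10^infl$smoothed[5])
  expect_true(is.na(library_cutoff(list(inflections = integer(0)))))
})

test_that("consensus cutoff is the modal log-bin midpoint", {
  expect_equal(consensus_cutoff(c(0.9, 1.0, 1.1, 3.2), bin_width = 0.25), 1)
  expect_equal(consensus_cutoff(rep(0.7, 5)), 10^(round(log10(0.7) / 0.25) * 0.25))
  expect_equal(consensus_cutoff(2.5), 10^(round(log10(2.5) / 0.25) * 0.25))
  expect_equal(consensus_cutoff(c(NA, 1)), 1)
  expect_error(consensus_cutoff(c(NA_real_, NA_real_)), "manually")
})

test_that("classification partitions present families and respects the boundary", {
  pct <- matrix(c(5, 1, 0.2, 0, 4, 1.5, 0.1, 0.3), 4,
                dimnames = list(c("F1", "F2", "F3", "F4"), c("L1", "L2")))
  cls <- classify(pct, cutoff = 1)
  expect_equal(cls$per_library["F1", "L1"], "ORB")
  expect_equal(cls$per_library["F2", "L1"], "URB")  # exactly at cutoff -> URB
  expect_true(is.na(cls$per_library["F4", "L1"]))   # absent -> no label
  # ORB + URB = present families, per library
  for (l in colnames(pct)) {
    lab <- cls$per_library[, l]
    expect_equal(sum(!is.na(lab)), sum(pct[, l] > 0))
  }
  expect_error(classify(pct, 0), "positive")
})

test_that("labels are invariant to a common rescaling of percentages", {
  design <- make_design(4)
  tree <- gen_taxonomy(5, 60, seed = 1)
  truth <- gen_community(tree, design, seed = 3)
  pct <- normalize_percent(sample_counts(truth, 5000, seed = 4))
  co <- cutoff_analysis(pct)
  cls <- classify(pct, co$consensus, design)
  # scaling counts by a constant leaves percentages, hence labels, unchanged
  pct2 <- normalize_percent(sample_counts(truth, 5000, seed = 4) * 17)
  co2 <- cutoff_analysis(pct2)
  expect_equal(co2$consensus, co$consensus)
  cls2 <- classify(pct2, co2$consensus, design)
  expect_identical(cls$per_library, cls2$per_library)
})

test_that("group-level classification counts per class per group", {
  design <- make_design(4)
  tree <- gen_taxonomy(5, 60, seed = 1)
  truth <- gen_community(tree, design, seed = 3)
  pct <- normalize_percent(sample_counts(truth, 5000, seed = 4))
  cls <- classify(pct, 1, design)
  pg <- cls$per_group
  expect_setequal(unique(pg$group), c("active", "total"))
  # partition within each group: ORB + URB = present families
  for (g in c("active", "total")) {
    sub <- pg[pg$group == g & pg$present, ]
    expect_equal(nrow(sub), sum(table(sub$label)))
  }
})

test_that("welch_test matches the closed form and stats::t.test", {
  w <- welch_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -1 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(w$t, -1.2247, tolerance = 1e-4)
  expect_equal(w$df, 4, tolerance = 1e-9)
  ref <- t.test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  set.seed(20)
  for (rep in 1:10) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1), sd = 2)
    w <- welch_test(a, b); ref <- t.test(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("welch_test handles degenerate zero-variance input explicitly", {
  same <- welch_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_false(same$degenerate)
  diff <- welch_test(c(2, 2, 2), c(3, 3, 3))
  expect_true(diff$degenerate)
  expect_equal(diff$p, 0)
  short <- welch_test(1, c(1, 2))
  expect_true(is.na(short$t))
})

test_that("per-family Welch uses per-subject medians of each group", {
  design <- make_design(2)
  pct <- matrix(1, 2, nrow(design),
                dimnames = list(c("F1", "F2"), design$library_id))
  # F1: subject medians actives (2, 4), totals (6, 12)
  pct["F1", ] <- c(2, 2, 3, 6, 6.5,   4, 4, 5, 12, 12.5)
  w <- welch_family_test(pct, design, per_sample_medians = TRUE)
  r <- w[w$family == "F1", ]
  ref <- welch_test(c(2, 4), c(6.25, 12.25))
  expect_equal(r$t, ref$t, tolerance = 1e-9)
  expect_equal(r$active_median, median(c(2, 4)))
  expect_equal(r$total_median, median(c(6.25, 12.25)))
  # identical groups: t = 0, p = 1
  r2 <- w[w$family == "F2", ]
  expect_equal(r2$t, 0); expect_equal(r2$p, 1)
})

test_that("planted enrichment is detected and nulls stay calm", {
  design <- make_design(4)
  tree <- gen_taxonomy(5, 60, seed = 1)
  base <- gen_community(tree, design, seed = 5)
  fam9 <- names(sort(base$base_pct, decreasing = TRUE))[8]
  truth <- gen_community(tree, design, effects = setNames(9, fam9),
                         noise_sd = 0.15, seed = 5)
  pct <- normalize_percent(sample_counts(truth, 10000, seed = 6))
  w <- welch_family_test(pct, design)
  expect_true(w$significant[w$family == fam9])
  expect_gte(w$total_median[w$family == fam9] /
               w$active_median[w$family == fam9], 5)
  # BH adjustment never lowers a p-value and keeps the planted hit
  wb <- welch_family_test(pct, design, p_adjust = "BH")
  ok <- !is.na(w$p)
  expect_true(all(wb$p[ok] >= w$p[ok] - 1e-12))
  expect_true(wb$significant[wb$family == fam9])
})
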