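# Hit retention, LCA read assignment, rank rollup and the identity
# fingerprint.

mk_hits <- function(qseqid, sseqid, pident, bitscore) {
  n <- length(qseqid)
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = rep(500L, n), mismatch = 0L, gapopen = 0L,
             qstart = 1L, qend = 500L, sstart = 1L, send = 500L,
             evalue = 1e-100, bitscore = bitscore)
}

test_that("hit retention keeps the score window above the best hit", {
  h <- mk_hits(rep("r1", 3), c(11L, 12L, 13L), c(99, 98, 90), c(100, 95, 80))
  kept <- retain_hits(h, min_identity = 80, score_window = 0.9)
  expect_setequal(kept$bitscore, c(100, 95))
  # single hit survives any window
  h1 <- mk_hits("r1", 11L, 85, 50)
  expect_equal(nrow(retain_hits(h1, score_window = 1)), 1L)
  # window 1.0 with a unique maximum keeps the best hit only
  kept1 <- retain_hits(h, score_window = 1)
  expect_equal(kept1$sseqid, 11L)
  # hits below min_identity vanish entirely
  expect_equal(nrow(retain_hits(mk_hits("r1", 11L, 50, 100))), 0L)
})

test_that("assignment takes the LCA of retained hit lineages", {
  tree <- tiny_tree()
  nd <- tree$nodes
  sp <- nd$id[nd$rank == "species"]
  sp_gen <- nd$parent_id[match(sp, nd$id)]
  same_genus <- sp[sp_gen == sp_gen[which(duplicated(sp_gen))[1]]][1:2]
  h <- mk_hits(rep("r1", 2), same_genus, c(99, 98), c(100, 99))
  a <- assign_reads(h, tree)
  expect_equal(a$rank, "genus")
  expect_equal(a$node_id, sp_gen[match(same_genus[1], sp)])
  expect_equal(a$best_identity, 99)

  # window 1.0: best hit only, LCA = that species
  a1 <- assign_reads(h, tree, score_window = 1)
  expect_equal(a1$rank, "species")
  expect_equal(a1$node_id, same_genus[1])
})

test_that("reads spanning two families roll up as unclassified at family rank", {
  tree <- tiny_tree()
  nd <- tree$nodes
  sp <- nd$id[nd$rank == "species"]
  fam <- ancestor_at_rank(tree, sp, "family")
  ord <- ancestor_at_rank(tree, sp, "order")
  pick <- which(ord == ord[1] & fam != fam[1])[1]
  two_fam <- c(sp[1], sp[pick])
  h <- rbind(mk_hits(rep("r1", 2), two_fam, c(99, 98), c(100, 99)),
             mk_hits("r2", sp[1], 99, 100))
  a <- assign_reads(h, tree)
  libs <- c(r1 = "L1", r2 = "L1")
  fam_tab <- rank_counts(a, libs, tree, "family")
  expect_equal(fam_tab["unclassified", "L1"], 1L)
  # the same read still counts at order rank for its order
  ord_tab <- rank_counts(a, libs, tree, "order")
  ord_name <- nd$name[match(ord[1], nd$id)]
  expect_equal(ord_tab[ord_name, "L1"], 2L)
})

test_that("rank tables conserve assigned reads per library", {
  tree <- gen_taxonomy(4, 12, seed = 2)
  design <- make_design(2, c("PA", "FS"))
  truth <- gen_community(tree, design, n_orb = 4, n_urb = 6, seed = 3)
  scheme <- tag_scheme(make_mids(design$library_id, seed = 4))
  sim <- gen_reads(truth, tree, scheme, reads_per_library = 400, seed = 5)
  clean <- strip_tags(dereplicate(parse_reads(sim$reads, scheme)))
  hits <- gen_hits(sim$truth, tree, seed = 6)
  hits <- hits[hits$qseqid %in% clean$read_id, ]
  a <- assign_reads(hits, tree)
  libs <- setNames(clean$library_id, clean$read_id)
  for (rank in c("phylum", "family", "genus")) {
    tab <- rank_counts(a, libs, tree, rank)
    per_lib <- table(libs[a$read_id])
    expect_equal(colSums(tab)[names(per_lib)], per_lib + 0,
                 ignore_attr = TRUE)
  }
  # assigned + unassigned = clean reads in
  expect_equal(nrow(a) + sum(!clean$read_id %in% a$read_id), nrow(clean))
})

test_that("family-level accuracy is perfect with confamilial decoys", {
  tree <- gen_taxonomy(4, 12, seed = 2)
  design <- make_design(1, c("PA", "FS"))
  truth <- gen_community(tree, design, n_orb = 4, n_urb = 6, seed = 3)
  scheme <- tag_scheme(make_mids(design$library_id, seed = 4))
  sim <- gen_reads(truth, tree, scheme, reads_per_library = 300,
                   error_rate = 0, seed = 5)
  hits <- gen_hits(sim$truth, tree, decoy_rank = "family", seed = 6)
  a <- assign_reads(hits, tree)
  fam_true <- sim$truth$source_family[match(a$read_id, sim$truth$read_id)]
  deep <- match(a$rank, orburb:::TAX_RANKS) >=
    match("family", orburb:::TAX_RANKS)
  expect_true(all(deep))
  fam_called <- orburb:::node_name(tree,
    ancestor_at_rank(tree, a$node_id, "family"))
  expect_equal(fam_called, fam_true)
})

test_that("the identity fingerprint is a normalized density", {
  a <- data.frame(read_id = sprintf("r%d", 1:100),
                  node_id = 1L, rank = "species",
                  best_identity = c(rep(100, 40), runif(60, 90, 100)))
  libs <- setNames(rep(c("A", "B"), each = 50), a$read_id)
  fp <- identity_fingerprint(a, libs, bin_width = 0.5)
  sums <- tapply(fp$density, fp$library_id, sum)
  expect_equal(as.vector(sums), c(1, 1), tolerance = 1e-9)
  # all identities 100 -> point mass in the top bin
  a2 <- a; a2$best_identity <- 100
  fp2 <- identity_fingerprint(a2, libs, bin_width = 1)
  top <- fp2[fp2$density > 0, ]
  expect_true(all(top$bin_left == 100))
  expect_equal(top$density, c(1, 1))
})

test_that("libraries with different planted divergences separate in the fingerprint", {
  tree <- gen_taxonomy(3, 8, seed = 1)
  design <- make_design(1, c("PA", "FS"))
  truth <- gen_community(tree, design, n_orb = 3, n_urb = 4, seed = 2)
  scheme <- tag_scheme(make_mids(design$library_id, seed = 3))
  # one library error-free, one strongly diverged
  simA <- gen_reads(truth, tree, scheme, reads_per_library = 300,
                    error_rate = 0, seed = 4)
  simB <- gen_reads(truth, tree, scheme, reads_per_library = 300,
                    error_rate = 0.05, seed = 4)
  tA <- simA$truth[simA$truth$library_id == design$library_id[1], ]
  tB <- simB$truth[simB$truth$library_id == design$library_id[2], ]
  both <- rbind(tA, tB)
  hits <- gen_hits(both, tree, identity_noise_sd = 0.2, seed = 5)
  a <- assign_reads(hits, tree)
  libs <- setNames(both$library_id, both$read_id)
  med <- tapply(a$best_identity, libs[a$read_id], median)
  expect_gt(med[[design$library_id[1]]], med[[design$library_id[2]]] + 2)
})
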