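# Read parsing, tag-aware dereplication and tag stripping.

test_that("a conforming read parses into its parts", {
  sc <- tag_scheme(c(L1 = "ACGTACGT", L2 = "TTTTCCCC"))
  insert <- "ACGTACGTACGTACGTACGTACGT"
  r <- make_read(sc, "L1", "AGAGTTGA", insert)
  p <- parse_reads(c(read1 = r), sc)
  expect_equal(p$status, "assigned")
  expect_equal(p$library_id, "L1")
  expect_equal(p$permutag, "AGAGTTGA")
  expect_equal(p$insert, insert)
})

test_that("each failing stage is named", {
  sc <- tag_scheme(c(L1 = "ACGTACGT"))
  insert <- strrep("ACGT", 10)
  good <- make_read(sc, "L1", "AGAGTTGA", insert)
  # unknown MID
  bad_mid <- paste0("GGGGGGGG", substr(good, 9, nchar(good)))
  # position 1 of the tag must be W = {A,T}
  bad_tag <- make_read(sc, "L1", "CGAGTTGA", insert)
  # break the linker
  bad_linker <- sub("TC", "GG", good, fixed = FALSE)
  bad_linker <- paste0(substr(good, 1, 16), "GG", substr(good, 19, nchar(good)))
  # three substitutions in the primer exceed the <=2 tolerance
  primer <- vapply(strsplit(sc$forward_primer, "")[[1]],
                   function(cc) orburb:::IUPAC_CODES[[cc]][1], character(1))
  primer[1:3] <- ifelse(primer[1:3] == "A", "C", "A")
  bad_primer <- make_read(sc, "L1", "AGAGTTGA", insert,
                          primer = paste(primer, collapse = ""))
  p <- parse_reads(c(a = good, b = bad_mid, c = bad_tag, d = bad_linker,
                     e = bad_primer), sc)
  expect_equal(p$status, c("assigned", "no_mid", "bad_permutag",
                           "bad_linker", "bad_primer"))
  # conservation: assigned + unassigned = input
  expect_equal(sum(p$status == "assigned") + sum(p$status != "assigned"),
               nrow(p))
})

test_that("two primer mismatches pass, three fail", {
  sc <- tag_scheme(c(L1 = "ACGTACGT"))
  insert <- strrep("TGCA", 10)
  primer0 <- vapply(strsplit(sc$forward_primer, "")[[1]],
                    function(cc) orburb:::IUPAC_CODES[[cc]][1], character(1))
  flip <- function(k) {
    pr <- primer0
    pr[seq_len(k)] <- ifelse(pr[seq_len(k)] == "A", "C", "A")
    make_read(sc, "L1", "AGAGTTGA", insert, primer = paste(pr, collapse = ""))
  }
  p <- parse_reads(c(m2 = flip(2), m3 = flip(3)), sc)
  expect_equal(p$status, c("assigned", "bad_primer"))
})

test_that("reverse-complement rescue is optional", {
  sc <- tag_scheme(c(L1 = "ACGTACGT"))
  fwd <- make_read(sc, "L1", "AGAGTTGA", strrep("GATC", 12))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(fwd)))
  p0 <- parse_reads(c(r = rc), sc)
  expect_equal(p0$status, "no_mid")
  p1 <- parse_reads(c(r = rc), sc, check_revcomp = TRUE)
  expect_equal(p1$status, "assigned")
  expect_equal(p1$insert, strrep("GATC", 12))
})

test_that("dereplication collapses byte-identical reads only", {
  sc <- tag_scheme(c(L1 = "ACGTACGT"))
  insert <- strrep("CAGT", 11)
  a <- make_read(sc, "L1", "AGAGTTGA", insert)
  b <- make_read(sc, "L1", "TGAGTTGA", insert)  # same insert, other PERMUTAG
  p <- parse_reads(c(r1 = a, r2 = a, r3 = b), sc)
  d <- dereplicate(p)
  expect_equal(nrow(d$reads), 2L)
  expect_equal(d$removed_count, 1L)
  expect_equal(sum(d$reads$multiplicity), 3L)  # multiplicities conserve input
  expect_equal(d$reads$read_id[1], "r1")       # first occurrence retained
  # same insert under different PERMUTAGs stays distinct
  expect_setequal(d$reads$permutag, c("AGAGTTGA", "TGAGTTGA"))
})

test_that("dereplication is idempotent and tolerates empty input", {
  sc <- tag_scheme(c(L1 = "ACGTACGT"))
  p <- parse_reads(setNames(character(0), character(0)), sc)
  d <- dereplicate(p)
  expect_equal(nrow(d$reads), 0L)
  expect_equal(d$removed_count, 0L)

  reads <- c(r1 = make_read(sc, "L1", "AGAGTTGA", strrep("AC", 30)),
             r2 = make_read(sc, "L1", "AGAGTTGA", strrep("AC", 30)),
             r3 = make_read(sc, "L1", "AGCGATGT", strrep("GT", 30)))
  d1 <- dereplicate(parse_reads(reads, sc))
  p2 <- d1$reads; p2$multiplicity <- NULL
  d2 <- dereplicate(p2)
  expect_identical(d2$reads$sequence, d1$reads$sequence)
  expect_equal(d2$removed_count, 0L)
})

test_that("removed duplicates equal the generator ledger when copies are exact", {
  tree <- gen_taxonomy(3, 10, seed = 1)
  design <- make_design(2, c("PA", "FS"))
  truth <- gen_community(tree, design, n_orb = 4, n_urb = 5, seed = 2)
  scheme <- tag_scheme(make_mids(design$library_id, seed = 3))
  sim <- gen_reads(truth, tree, scheme, reads_per_library = 800,
                   dup_rate = 0.15, error_rate = 0.005, seed = 4)
  p <- parse_reads(sim$reads, scheme)
  d <- dereplicate(p)
  expect_equal(d$removed_count, sum(sim$truth$is_emulsion_duplicate))
  # dup_rate 0: dereplication is the identity on read count
  sim0 <- gen_reads(truth, tree, scheme, reads_per_library = 300,
                    dup_rate = 0, seed = 4)
  d0 <- dereplicate(parse_reads(sim0$reads, scheme))
  expect_equal(d0$removed_count, 0L)
  expect_equal(nrow(d0$reads), length(sim0$reads))
})

test_that("strip_tags removes exactly the tag block and keeps libraries", {
  sc <- tag_scheme(c(L1 = "ACGTACGT", L2 = "TTTTCCCC"))
  insert <- strrep("ACGGT", 10)
  r <- make_read(sc, "L2", "TGCGTTGT", insert)
  d <- dereplicate(parse_reads(c(x = r), sc))
  s <- strip_tags(d)
  expect_equal(nchar(s$insert), nchar(r) - 8 - 8 - 2 - nchar(sc$forward_primer))
  expect_equal(s$insert, insert)   # round-trip recovers the input insert
  expect_equal(s$library_id, "L2")
})

test_that("per-library clean read counts match the generator ledger", {
  tree <- gen_taxonomy(3, 10, seed = 1)
  design <- make_design(2, c("PA", "FS"))
  truth <- gen_community(tree, design, n_orb = 4, n_urb = 5, seed = 2)
  scheme <- tag_scheme(make_mids(design$library_id, seed = 3))
  sim <- gen_reads(truth, tree, scheme, reads_per_library = 500,
                   dup_rate = 0.1, seed = 9)
  clean <- strip_tags(dereplicate(parse_reads(sim$reads, scheme)))
  led <- sim$truth[!sim$truth$is_emulsion_duplicate, ]
  expect_equal(table(clean$library_id), table(led$library_id))
  rep_ <- demux_report(parse_reads(sim$reads, scheme),
                       dereplicate(parse_reads(sim$reads, scheme)))
  expect_equal(sum(rep_$assigned), length(sim$reads))
  expect_equal(sum(rep_$removed_duplicates),
               sum(sim$truth$is_emulsion_duplicate))
})
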