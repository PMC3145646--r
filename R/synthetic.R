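# Synthetic-data module: generates every input the pipeline consumes --
# a taxonomy, a ground-truth community, tagged reads with emulsion-PCR
# duplicate artifacts, and a simulated similarity-search hit table --
# with a complete truth ledger for recovery tests.

ACTIVE_FRACTIONS <- c("PA", "LC", "HC")
TOTAL_FRACTIONS <- c("FS", "R")
ALL_FRACTIONS <- c(ACTIVE_FRACTIONS, TOTAL_FRACTIONS)

#' Group sorted-cell fractions into active vs total
#'
#' PA (pyronin-Y activated), LC (low Cy5) and HC (high Cy5) are the
#' RNA-content-sorted "active" views of the community; FS (fecal suspension)
#' and R (density-gradient ring) are the unsorted "total" views.
#'
#' @param fractions character vector of fraction codes.
#' @return character vector, `"active"` or `"total"`.
#' @export
fraction_group <- function(fractions) {
  bad <- setdiff(fractions, ALL_FRACTIONS)
  if (length(bad)) stop("unknown fraction(s): ", paste(bad, collapse = ", "))
  ifelse(fractions %in% ACTIVE_FRACTIONS, "active", "total")
}

#' Build the standard sample-by-fraction design
#'
#' @param n_samples number of subjects.
#' @param fractions fraction codes per subject.
#' @return data.frame with columns `library_id`, `sample`, `fraction`, `group`.
#' @export
make_design <- function(n_samples = 4L, fractions = ALL_FRACTIONS) {
  d <- expand.grid(fraction = fractions,
                   sample = sprintf("S%d", seq_len(n_samples)),
                   stringsAsFactors = FALSE)[, c("sample", "fraction")]
  d$library_id <- paste(d$sample, d$fraction, sep = "_")
  d$group <- fraction_group(d$fraction)
  d[, c("library_id", "sample", "fraction", "group")]
}

# log-series tail values for the under-represented taxa: a long, slowly
# decaying tail (the shape behind the high Shannon indices of gut surveys)
logseries_tail <- function(n, theta = 0.95) {
  j <- seq_len(n)
  theta^j / j
}

#' Generate a ground-truth community
#'
#' Plants a two-regime rank-abundance curve in every library: a geometric
#' "head" of over-represented families whose smallest member sits at three
#' times the knee, and a log-series "tail" of under-represented families whose
#' largest member sits at a third of the knee. The regime change at
#' `knee_pct` is the curvature feature the downstream inflection-point
#' classifier must recover. Active-vs-total differences are planted as
#' multiplicative fold changes applied to the total-fraction libraries and
#' renormalized.
#'
#' @param tree a [taxonomy_tree()] supplying family nodes and lineages.
#' @param design data.frame from [make_design()] (columns `library_id`,
#'   `sample`, `fraction`).
#' @param knee_pct planted knee, in percent of a library (0 < knee < 100).
#' @param n_orb,n_urb number of head (over-represented) and tail
#'   (under-represented) families.
#' @param effects named numeric vector of total:active fold changes keyed by
#'   family name (values > 1 enrich the family in total fractions, < 1 in
#'   active fractions); `NULL` for none.
#' @param noise_sd standard deviation of per-library lognormal abundance
#'   noise, on the natural-log scale.
#' @param seed integer seed.
#' @return an object of class `community_truth` with elements `families`,
#'   `base_pct` (planted percentages, sum 100), `expected` (post-effect,
#'   pre-noise fractions per library), `abundance` (realized fractions per
#'   library, columns sum to 1), `orb_flag`, `effect_map`, `knee_pct`,
#'   `design`.
#' @export
gen_community <- function(tree, design, knee_pct = 1, n_orb = 8L, n_urb = 40L,
                          effects = NULL, noise_sd = 0.25, seed = 1L) {
  if (nrow(design) == 0L) stop("design is empty", call. = FALSE)
  if (!(knee_pct > 0 && knee_pct < 100)) stop("knee_pct must be in (0,100)", call. = FALSE)
  invisible(fraction_group(design$fraction))
  if (is.null(design$library_id))
    design$library_id <- paste(design$sample, design$fraction, sep = "_")
  design$group <- fraction_group(design$fraction)
  K <- n_orb + n_urb
  if (K < 1L) stop("need at least one family", call. = FALSE)
  fam_nodes <- tree$nodes[tree$nodes$rank == "family", ]
  if (nrow(fam_nodes) < K)
    stop("tree has only ", nrow(fam_nodes), " families, need ", K, call. = FALSE)

  # tail: log-series scaled so its largest value is knee/3
  tail_pct <- numeric(0)
  if (n_urb > 0L) {
    t0 <- logseries_tail(n_urb)
    tail_pct <- t0 / t0[1L] * (knee_pct / 3)
  }
  # head: geometric decay whose smallest value is 3*knee and which fills the
  # remaining probability mass; solve the decay ratio for sum = 100 - tail
  head_pct <- numeric(0)
  if (n_orb > 0L) {
    target <- 100 - sum(tail_pct)
    if (target <= 3 * knee_pct * n_orb)
      stop("knee_pct too large for ", n_orb, " head families", call. = FALSE)
    if (n_orb == 1L) {
      head_pct <- target
    } else {
      f <- function(r) {
        a <- 3 * knee_pct * r^-(n_orb - 1)
        a * (1 - r^n_orb) / (1 - r) - target
      }
      r <- stats::uniroot(f, c(1e-4, 1 - 1e-9), tol = 1e-12)$root
      head_pct <- 3 * knee_pct * r^-(n_orb - 1) * r^(seq_len(n_orb) - 1)
    }
  } else {
    tail_pct <- tail_pct / sum(tail_pct) * 100  # no head: tail carries all mass
  }
  base_pct <- c(head_pct, tail_pct)

  with_seed(seed, {
    picked <- fam_nodes[sample.int(nrow(fam_nodes), K), ]
    fams <- picked$name
    names(base_pct) <- fams
    effect_map <- stats::setNames(rep(1, K), fams)
    if (!is.null(effects)) {
      unknown <- setdiff(names(effects), fams)
      if (length(unknown))
        stop("effects reference unknown families: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      effect_map[names(effects)] <- effects
    }
    L <- nrow(design)
    expected <- matrix(0, K, L, dimnames = list(fams, design$library_id))
    abundance <- expected
    for (l in seq_len(L)) {
      prof <- base_pct
      if (design$group[l] == "total") prof <- prof * effect_map
      expected[, l] <- prof / sum(prof)
      noisy <- expected[, l] * exp(stats::rnorm(K, 0, noise_sd))
      abundance[, l] <- noisy / sum(noisy)
    }
    lin_str <- vapply(picked$id, function(id) {
      lin <- lineage(tree, id)
      paste(tree$nodes$name[match(lin, tree$nodes$id)], collapse = ";")
    }, character(1))
    structure(list(
      families = data.frame(id = picked$id, name = fams, lineage = lin_str,
                            stringsAsFactors = FALSE),
      base_pct = base_pct,
      expected = expected,
      abundance = abundance,
      orb_flag = stats::setNames(base_pct > knee_pct, fams),
      effect_map = effect_map,
      knee_pct = knee_pct,
      design = design
    ), class = "community_truth")
  })
}

#' @export
print.community_truth <- function(x, ...) {
  cat(sprintf("community_truth: %d families (%d ORB / %d URB at knee %.3g%%), %d libraries\n",
              nrow(x$families), sum(x$orb_flag), sum(!x$orb_flag),
              x$knee_pct, nrow(x$design)))
  ne <- sum(x$effect_map != 1)
  if (ne) cat(sprintf("  %d planted active-vs-total fold changes\n", ne))
  invisible(x)
}

#' Default planted active-vs-total fold changes
#'
#' Mirrors the study's qualitative findings: one moderately abundant family
#' strongly enriched in total fractions (about 9-fold, the Bacteroidetes
#' pattern), a second at about 5-fold, and several families enriched in the
#' active fractions (fold 1/3). The total-enriched families are taken from
#' the low end of the head so renormalization does not swamp the planted
#' ratio; the active-enriched ones from the head's middle and the tail's top.
#'
#' @param truth_or_base a `community_truth` or a named base-percentage vector.
#' @return named numeric vector of total:active folds, keyed by family name.
#' @export
default_effects <- function(truth_or_base) {
  base <- if (inherits(truth_or_base, "community_truth"))
    truth_or_base$base_pct else truth_or_base
  ord <- names(sort(base, decreasing = TRUE))
  orb <- ord[seq_len(min(8L, length(ord)))]
  eff <- numeric(0)
  if (length(orb) >= 8L) {
    eff[orb[8L]] <- 9
    eff[orb[7L]] <- 5
    eff[orb[2L]] <- 1 / 3
    eff[orb[5L]] <- 1 / 3
  }
  urb <- setdiff(ord, orb)
  if (length(urb) >= 2L) eff[urb[1:2]] <- 1 / 3
  eff
}

#' Draw per-library read counts from a community
#'
#' Multinomial sampling of `reads_per_library` reads per library from the
#' realized abundance profile.
#'
#' @param truth a `community_truth`.
#' @param reads_per_library sequencing depth per library.
#' @param seed integer seed.
#' @return integer matrix, families x libraries.
#' @export
sample_counts <- function(truth, reads_per_library, seed = 1L) {
  with_seed(seed, {
    m <- apply(truth$abundance, 2, function(p)
      stats::rmultinom(1, reads_per_library, p)[, 1L])
    dimnames(m) <- dimnames(truth$abundance)
    m
  })
}

# deterministic random reference sequence per species
gen_ref_seqs <- function(tree, len = 900L, seed = 1L) {
  sp <- tree$nodes$id[tree$nodes$rank == "species"]
  with_seed(seed, {
    refs <- vapply(sp, function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1))
    names(refs) <- as.character(sp)
    refs
  })
}

# substitute random bases at random positions; events is a data.frame
# (idx, pos); returns the mutated sequences
inject_substitutions <- function(seqs, events) {
  if (nrow(events) == 0L) return(seqs)
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(nrow(events))) {
    i <- events$idx[k]; p <- events$pos[k]
    cur <- substr(seqs[i], p, p)
    substr(seqs[i], p, p) <- sample(setdiff(bases, cur), 1L)
  }
  seqs
}

#' Generate tagged amplicon reads with emulsion-PCR duplicates
#'
#' Each read is `MID + PERMUTAG + linker + forward primer + insert`, where
#' the insert is a 460-520 nt window of the source species' reference
#' sequence with substitution errors applied at `error_rate` per base, and
#' the PERMUTAG is drawn uniformly from the degenerate pattern's expansions.
#' A `dup_rate` share of each library's reads are emulsion-PCR duplicates:
#' byte-identical copies of earlier reads (same PERMUTAG, same insert,
#' drawn after error injection), which is exactly what tag-aware exact
#' dereplication is designed to remove.
#'
#' @param truth a `community_truth`.
#' @param tree the [taxonomy_tree()] the community was drawn from.
#' @param scheme a [tag_scheme()] whose MID names cover the design's
#'   library ids.
#' @param reads_per_library total reads per library (duplicates included).
#' @param dup_rate expected share of duplicate reads, in `[0, 1)`.
#' @param error_rate per-base substitution probability, in `[0, 1)`.
#' @param seed integer seed.
#' @return an object of class `synthetic_reads`: list with `reads` (named
#'   character vector), `truth` (per-read ledger data.frame with columns
#'   `read_id`, `library_id`, `sample`, `fraction`, `source_family`,
#'   `source_species`, `mid_id`, `permutag`, `is_emulsion_duplicate`,
#'   `parent_read`, `n_errors`, `insert_length`), and `ref_seqs`.
#' @export
gen_reads <- function(truth, tree, scheme, reads_per_library = 2000L,
                      dup_rate = 0.1, error_rate = 0.005, seed = 1L) {
  stopifnot(inherits(truth, "community_truth"), inherits(scheme, "tag_scheme"))
  if (dup_rate < 0 || dup_rate >= 1) stop("dup_rate must be in [0,1)", call. = FALSE)
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0,1)", call. = FALSE)
  libs <- truth$design$library_id
  missing_mid <- setdiff(libs, names(scheme$mids))
  if (length(missing_mid))
    stop("scheme lacks MIDs for libraries: ", paste(missing_mid, collapse = ", "),
         call. = FALSE)
  ref_seqs <- gen_ref_seqs(tree, seed = child_seed(seed, "refs"))
  ref_len <- nchar(ref_seqs[[1L]])

  # species pool per selected family
  fam_ids <- truth$families$id
  sp_nodes <- tree$nodes[tree$nodes$rank == "species", "id"]
  sp_fam <- ancestor_at_rank(tree, sp_nodes, "family")
  fam_species <- split(sp_nodes, factor(sp_fam, levels = fam_ids))
  names(fam_species) <- truth$families$name
  if (any(lengths(fam_species) == 0L))
    stop("a selected family has no species leaf", call. = FALSE)

  pat <- iupac_chars(scheme$permutag_pattern)
  primer_pat <- iupac_chars(scheme$forward_primer)
  draw_degenerate <- function(chars, n) {
    cols <- lapply(chars, function(cc) {
      s <- IUPAC_CODES[[cc]]
      if (length(s) == 1L) rep(s, n) else sample(s, n, replace = TRUE)
    })
    do.call(paste0, cols)
  }

  all_reads <- list(); all_truth <- list()
  with_seed(child_seed(seed, "reads"), {
    for (l in seq_along(libs)) {
      lib <- libs[l]
      N <- as.integer(reads_per_library)
      if (N == 0L) next
      n_dup <- stats::rbinom(1L, N, dup_rate)
      n_orig <- N - n_dup
      if (n_orig == 0L) { n_orig <- 1L; n_dup <- N - 1L }
      fam <- sample(truth$families$name, n_orig, replace = TRUE,
                    prob = truth$abundance[, lib])
      # species uniform within family, drawn per family group
      sp <- integer(n_orig)
      for (f in unique(fam)) {
        idx <- which(fam == f)
        pool <- fam_species[[f]]
        sp[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
      }
      len <- sample(460:520, n_orig, replace = TRUE)
      start <- vapply(len, function(L) sample.int(ref_len - L + 1L, 1L), 1L)
      insert <- substr(ref_seqs[as.character(sp)], start, start + len - 1L)
      n_err <- stats::rbinom(n_orig, len, error_rate)
      if (sum(n_err) > 0L) {
        ev <- data.frame(
          idx = rep(seq_len(n_orig), n_err),
          pos = unlist(lapply(seq_len(n_orig), function(i)
            if (n_err[i] > 0L) sample.int(len[i], n_err[i]) else integer(0))))
        insert <- inject_substitutions(insert, ev)
      }
      permutag <- draw_degenerate(pat, n_orig)
      primer <- draw_degenerate(primer_pat, n_orig)
      seqs <- paste0(scheme$mids[[lib]], permutag, scheme$linker, primer, insert)
      ids <- sprintf("%s_r%06d", lib, seq_len(n_orig))
      td <- data.frame(read_id = ids, library_id = lib,
                       sample = truth$design$sample[l],
                       fraction = truth$design$fraction[l],
                       source_family = fam, source_species = sp,
                       mid_id = lib, permutag = permutag,
                       is_emulsion_duplicate = FALSE,
                       parent_read = NA_character_,
                       n_errors = n_err, insert_length = len,
                       stringsAsFactors = FALSE)
      if (n_dup > 0L) {
        parent <- sample.int(n_orig, n_dup, replace = TRUE)
        dd <- td[parent, ]
        dd$read_id <- sprintf("%s_r%06d", lib, n_orig + seq_len(n_dup))
        dd$is_emulsion_duplicate <- TRUE
        dd$parent_read <- ids[parent]
        seqs <- c(seqs, seqs[parent])
        ids <- c(ids, dd$read_id)
        td <- rbind(td, dd)
      }
      names(seqs) <- ids
      all_reads[[lib]] <- seqs
      all_truth[[lib]] <- td
    }
  })
  reads <- unlist(unname(all_reads))
  if (is.null(reads)) reads <- stats::setNames(character(0), character(0))
  truth_df <- if (length(all_truth)) do.call(rbind, all_truth) else
    data.frame(read_id = character(0))
  rownames(truth_df) <- NULL
  structure(list(reads = reads, truth = truth_df, ref_seqs = ref_seqs),
            class = "synthetic_reads")
}

#' @export
print.synthetic_reads <- function(x, ...) {
  cat(sprintf("synthetic_reads: %d reads (%d emulsion duplicates) over %d libraries\n",
              length(x$reads), sum(x$truth$is_emulsion_duplicate),
              length(unique(x$truth$library_id))))
  invisible(x)
}

#' Write reads to FASTA or FASTQ
#'
#' FASTQ output carries a flat quality of Q30 (substitution-only error model;
#' no per-base quality simulation).
#'
#' @param reads named character vector of sequences (e.g. from [gen_reads()]).
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(reads)
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta", width = 20000L)
  } else {
    q <- Biostrings::BStringSet(vapply(Biostrings::width(x), function(w)
      paste(rep("?", w), collapse = ""), character(1)))  # '?' = Q30
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  invisible(path)
}

#' Read amplicon reads from FASTA/FASTQ
#' @param path input file.
#' @return named character vector of sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Simulate a similarity-search hit table
#'
#' Stands in for an external search of each read against a 16S reference
#' database. The true source species always receives the top bitscore, with
#' percent identity `100 * (1 - errors/length)` plus Gaussian noise; decoy
#' hits target random other species within the read's true genus or family
#' at lower scores. The resulting per-read best-hit identity distribution is
#' the "fingerprint" a real run would show.
#'
#' @param read_truth the `truth` ledger from [gen_reads()] (duplicates
#'   included; they hit like their parents).
#' @param tree the [taxonomy_tree()].
#' @param identity_noise_sd Gaussian noise on percent identity, in points.
#' @param max_decoys at most this many decoy hits per read (uniform 0..max).
#' @param decoy_rank `"family"` or `"genus"`: the clade decoys are drawn from.
#' @param seed integer seed.
#' @return data.frame in 12-column tabular-search order: `qseqid sseqid
#'   pident length mismatch gapopen qstart qend sstart send evalue bitscore`.
#' @export
gen_hits <- function(read_truth, tree, identity_noise_sd = 0.5,
                     max_decoys = 3L, decoy_rank = c("family", "genus"),
                     seed = 1L) {
  decoy_rank <- match.arg(decoy_rank)
  n <- nrow(read_truth)
  if (n == 0L)
    return(data.frame(qseqid = character(0), sseqid = integer(0),
                      pident = numeric(0), length = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      evalue = numeric(0), bitscore = numeric(0)))
  sp_nodes <- tree$nodes$id[tree$nodes$rank == "species"]
  grp_of_sp <- ancestor_at_rank(tree, sp_nodes, decoy_rank)
  pool <- split(sp_nodes, grp_of_sp)

  with_seed(seed, {
    len <- read_truth$insert_length
    pid_true <- 100 * (1 - read_truth$n_errors / len) +
      stats::rnorm(n, 0, identity_noise_sd)
    pid_true <- pmin(100, pmax(0, pid_true))
    bit_true <- round(1.9 * len * pid_true / 100, 1)
    sp_true <- read_truth$source_species
    read_grp <- grp_of_sp[match(sp_true, sp_nodes)]

    n_dec <- sample.int(max_decoys + 1L, n, replace = TRUE) - 1L
    di <- rep(seq_len(n), n_dec)  # read index per decoy row
    dec_sp <- integer(length(di))
    if (length(di)) {
      # draw a confamilial/congeneric species != the true one, per group
      for (g in unique(read_grp[di])) {
        rows <- which(read_grp[di] == g)
        p <- pool[[as.character(g)]]
        if (length(p) < 2L) { dec_sp[rows] <- NA_integer_; next }
        tpos <- match(sp_true[di[rows]], p)
        r <- sample.int(length(p) - 1L, length(rows), replace = TRUE)
        r <- r + (r >= tpos)  # skip the true species' slot
        dec_sp[rows] <- p[r]
      }
      keep <- !is.na(dec_sp)
      di <- di[keep]; dec_sp <- dec_sp[keep]
    }
    pid_dec <- pmax(0, pid_true[di] - stats::runif(length(di), 2, 10))
    bit_dec <- round(bit_true[di] * stats::runif(length(di), 0.75, 0.98), 1)
    mism_dec <- read_truth$n_errors[di] +
      as.integer(round((pid_true[di] - pid_dec) / 100 * len[di]))

    mkrows <- function(idx, sp, pid, bit, mism) {
      data.frame(qseqid = read_truth$read_id[idx], sseqid = sp,
                 pident = round(pid, 2), length = len[idx],
                 mismatch = mism, gapopen = 0L,
                 qstart = 1L, qend = len[idx],
                 sstart = 1L, send = len[idx],
                 evalue = signif(10^-pmin(180, bit / 3), 3),
                 bitscore = bit, stringsAsFactors = FALSE)
    }
    hits <- rbind(mkrows(seq_len(n), sp_true, pid_true, bit_true,
                         read_truth$n_errors),
                  if (length(di)) mkrows(di, dec_sp, pid_dec, bit_dec, mism_dec))
    ord <- order(match(hits$qseqid, read_truth$read_id), -hits$bitscore)
    hits <- hits[ord, ]
    rownames(hits) <- NULL
    hits
  })
}

#' Read / write a 12-column hit table
#' @param hits data.frame as produced by [gen_hits()].
#' @param path file path.
#' @param seed,config_hash provenance for the file header.
#' @export
write_hits <- function(hits, path, seed = NA, config_hash = NA) {
  write_headed_tsv(hits, path, seed, config_hash)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  h <- read_headed_tsv(path)
  req <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
           "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!all(req %in% names(h)))
    stop("hit table must have the 12 tabular-search columns")
  h
}
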