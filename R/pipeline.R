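# End-to-end orchestration: simulate a complete dataset to disk, then run
# demultiplexing -> LCA assignment -> profiling -> community metrics ->
# ORB/URB classification from a single configuration with reproducible
# seeds and provenance headers on every output.

#' Default pipeline configuration
#'
#' Returns the full parameter list with the study-scale defaults: 4 subjects
#' times 5 fractions, a 13-phylum / 79-family taxonomy, an 8-family head
#' over a 40-family tail with the knee planted at 1%, the default planted
#' active-vs-total fold changes, and the standard analysis parameters.
#'
#' @return a named list.
#' @export
default_config <- function() {
  list(
    n_samples = 4L, fractions = ALL_FRACTIONS,
    n_phyla = 13L, n_families = 79L,
    knee_pct = 1, n_orb = 8L, n_urb = 40L,
    noise_sd = 0.25,
    reads_per_library = 2000L, dup_rate = 0.1, error_rate = 0.005,
    identity_noise_sd = 0.5, max_decoys = 3L, decoy_rank = "family",
    primer_mismatch = 2L,
    min_identity = 80, score_window = 0.9,
    n_perm = 999L,
    span = 0.5, bin_width = 0.25, alpha = 0.05, direction = "last",
    fingerprint_bin = 1,
    seed = 1L
  )
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

#' Simulate a complete dataset to disk
#'
#' Writes everything a pipeline run needs: tagged reads (FASTA), the
#' 12-column hit table, the taxonomy node/name tables, the design table, the
#' community and per-read truth ledgers, the tag scheme (MID list), and a
#' manifest recording seed, parameters and configuration hash.
#'
#' @param dir output directory.
#' @param config parameter list; defaults from [default_config()], with
#'   entries in `...` overriding.
#' @param overwrite allow writing into a directory that already holds a
#'   manifest.
#' @param ... individual parameter overrides.
#' @return invisibly, a list with the in-memory objects (`tree`, `truth`,
#'   `scheme`, `reads`, `hits`, `paths`).
#' @export
simulate_dataset <- function(dir, config = default_config(), overwrite = FALSE,
                             ...) {
  config[names(list(...))] <- list(...)
  hash <- config_hash(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man_path <- file.path(dir, "manifest.yaml")
  if (file.exists(man_path) && !overwrite)
    stop("directory already holds a run (", man_path, "); use overwrite = TRUE",
         call. = FALSE)
  seed <- config$seed
  design <- make_design(config$n_samples, config$fractions)
  tree <- gen_taxonomy(config$n_phyla, config$n_families,
                       seed = child_seed(seed, "taxonomy"))
  truth <- gen_community(tree, design, knee_pct = config$knee_pct,
                         n_orb = config$n_orb, n_urb = config$n_urb,
                         effects = NULL, noise_sd = config$noise_sd,
                         seed = child_seed(seed, "community"))
  # plant the default active-vs-total effects on the realized head/tail
  eff <- default_effects(truth)
  truth <- gen_community(tree, design, knee_pct = config$knee_pct,
                         n_orb = config$n_orb, n_urb = config$n_urb,
                         effects = eff, noise_sd = config$noise_sd,
                         seed = child_seed(seed, "community"))
  scheme <- tag_scheme(make_mids(design$library_id,
                                 seed = child_seed(seed, "mids")))
  sim <- gen_reads(truth, tree, scheme,
                   reads_per_library = config$reads_per_library,
                   dup_rate = config$dup_rate, error_rate = config$error_rate,
                   seed = child_seed(seed, "reads"))
  hits <- gen_hits(sim$truth, tree,
                   identity_noise_sd = config$identity_noise_sd,
                   max_decoys = config$max_decoys,
                   decoy_rank = config$decoy_rank,
                   seed = child_seed(seed, "hits"))

  paths <- list(
    reads = file.path(dir, "reads.fasta"),
    hits = file.path(dir, "hits.tsv"),
    nodes = file.path(dir, "taxonomy_nodes.tsv"),
    names = file.path(dir, "taxonomy_names.tsv"),
    design = file.path(dir, "design.tsv"),
    mids = file.path(dir, "mids.tsv"),
    truth_community = file.path(dir, "truth_community.tsv"),
    truth_reads = file.path(dir, "truth_reads.tsv"),
    manifest = man_path
  )
  write_reads(sim$reads, paths$reads)
  write_hits(hits, paths$hits, seed, hash)
  write_taxonomy(tree, paths$nodes, paths$names, seed, hash)
  write_headed_tsv(design, paths$design, seed, hash)
  write_headed_tsv(data.frame(library_id = names(scheme$mids),
                              mid = unname(scheme$mids)),
                   paths$mids, seed, hash)
  comm <- data.frame(family = names(truth$base_pct),
                     base_pct = unname(truth$base_pct),
                     orb_flag = unname(truth$orb_flag),
                     effect = unname(truth$effect_map),
                     stringsAsFactors = FALSE)
  write_headed_tsv(comm, paths$truth_community, seed, hash)
  write_headed_tsv(sim$truth, paths$truth_reads, seed, hash)
  writeLines(yaml::as.yaml(list(
    tool = "orburb", version = as.character(utils::packageVersion("orburb")),
    seed = seed, config_hash = hash, config = config)), man_path)
  invisible(list(tree = tree, truth = truth, scheme = scheme, sim = sim,
                 hits = hits, paths = paths, config = config, hash = hash))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes demultiplexing, dereplication, tag stripping, LCA assignment,
#' family-level profiling, community metrics (Bray-Curtis distances,
#' complete-linkage dendrogram, rarefaction, diversity, sequential
#' PERMANOVA) and the ORB/URB classification with Welch tests, writing every
#' stage's table under `out_dir` with provenance headers. Any stage failure
#' halts the run with the stage named; tables already written stay on disk.
#'
#' @param reads_path FASTA/FASTQ of tagged reads.
#' @param hits_path 12-column hit TSV.
#' @param nodes_path,names_path taxonomy tables.
#' @param design_path design TSV (`library_id`, `sample`, `fraction`).
#' @param mids_path MID TSV (`library_id`, `mid`).
#' @param out_dir output directory.
#' @param config parameter list (see [default_config()]).
#' @return invisibly, a list with all stage results.
#' @export
run_pipeline <- function(reads_path, hits_path, nodes_path, names_path,
                         design_path, mids_path, out_dir,
                         config = default_config()) {
  for (p in c(reads_path, hits_path, nodes_path, names_path, design_path,
              mids_path))
    if (!file.exists(p)) stop("input not found: ", p, call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed
  hash <- config_hash(config)
  put <- function(x, name) write_headed_tsv(x, file.path(out_dir, name),
                                            seed, hash)

  design <- read_headed_tsv(design_path)
  design$group <- fraction_group(design$fraction)
  mids_df <- read_headed_tsv(mids_path)
  scheme <- tag_scheme(stats::setNames(mids_df$mid, mids_df$library_id))
  tree <- run_stage("taxonomy", read_taxonomy(nodes_path, names_path))

  parsed <- run_stage("demux", {
    reads <- read_reads(reads_path)
    parse_reads(reads, scheme, primer_mismatch = config$primer_mismatch)
  })
  derep <- run_stage("dereplicate", dereplicate(parsed))
  clean <- run_stage("strip", strip_tags(derep))
  report <- demux_report(parsed, derep)
  put(report, "demux_report.tsv")
  clean_dir <- file.path(out_dir, "clean")
  if (!dir.exists(clean_dir)) dir.create(clean_dir)
  for (lib in unique(clean$library_id)) {
    sub <- clean[clean$library_id == lib, ]
    write_reads(stats::setNames(sub$insert, sub$read_id),
                file.path(clean_dir, paste0(lib, ".fasta")))
  }
  message(sprintf("demux: %d reads in, %d assigned, %d duplicates removed",
                  nrow(parsed), nrow(derep$reads) + derep$removed_count,
                  derep$removed_count))

  assignments <- run_stage("assign", {
    hits <- read_hits(hits_path)
    hits <- hits[hits$qseqid %in% clean$read_id, , drop = FALSE]
    assign_reads(hits, tree, min_identity = config$min_identity,
                 score_window = config$score_window)
  })
  read_libs <- stats::setNames(clean$library_id, clean$read_id)
  put(assignments, "assignments.tsv")
  n_unassigned <- sum(!clean$read_id %in% assignments$read_id)
  message(sprintf("assign: %d reads assigned, %d unassigned",
                  nrow(assignments), n_unassigned))

  profile <- run_stage("profile", {
    fam_counts <- rank_counts(assignments, read_libs, tree, "family")
    phy_counts <- rank_counts(assignments, read_libs, tree, "phylum")
    list(family = fam_counts, phylum = phy_counts)
  })
  put(data.frame(taxon = rownames(profile$family), profile$family,
                 check.names = FALSE), "family_counts.tsv")
  put(data.frame(taxon = rownames(profile$phylum), profile$phylum,
                 check.names = FALSE), "phylum_counts.tsv")
  fingerprint <- identity_fingerprint(assignments, read_libs,
                                      config$fingerprint_bin)
  put(fingerprint, "fingerprint.tsv")

  metrics <- run_stage("metrics", {
    pct <- normalize_percent(profile$family)
    d <- bray_curtis_matrix(pct)
    hc <- cluster_complete(d)
    nwk <- export_newick(hc)
    rar <- rarefaction_curves(profile$family)
    div <- diversity_table(profile$family)
    pv <- permanova(d, design[match(colnames(pct), design$library_id), ],
                    terms = c("group", "sample", "fraction"),
                    n_perm = config$n_perm, seed = child_seed(seed, "perm"))
    list(pct = pct, dist = d, hclust = hc, newick = nwk, rarefaction = rar,
         diversity = div, permanova = pv)
  })
  dm <- as.matrix(metrics$dist)
  put(data.frame(library_id = rownames(dm), dm, check.names = FALSE),
      "bray_curtis.tsv")
  writeLines(metrics$newick, file.path(out_dir, "dendrogram.nwk"))
  put(metrics$rarefaction, "rarefaction.tsv")
  put(metrics$diversity, "diversity.tsv")
  pv_df <- data.frame(SourceVar = rownames(metrics$permanova),
                      as.data.frame(metrics$permanova), check.names = FALSE)
  put(pv_df, "variance_decomposition.tsv")

  orb <- run_stage("classify", {
    fam_pct <- metrics$pct[rownames(metrics$pct) != "unclassified", ,
                           drop = FALSE]
    co <- cutoff_analysis(fam_pct, span = config$span,
                          bin_width = config$bin_width,
                          direction = config$direction)
    cls <- classify(fam_pct, co$consensus, design)
    welch <- welch_family_test(fam_pct, design, alpha = config$alpha)
    list(pct = fam_pct, cutoffs = co, classification = cls, welch = welch)
  })
  put(orb$cutoffs$per_library, "cutoffs.tsv")
  put(orb$cutoffs$diagnostics, "cutoff_diagnostics.tsv")
  put(orb$classification$per_group, "classification.tsv")
  put(orb$welch, "welch.tsv")
  fig5 <- data.frame(orb$welch[, c("family", "active_median", "total_median",
                                   "max_pct", "significant")])
  put(fig5, "family_summary.tsv")

  summary_tbl <- run_stage("summary", {
    pg <- orb$classification$per_group
    act <- pg$family[pg$group == "active" & pg$present]
    tot <- pg$family[pg$group == "total" & pg$present]
    data.frame(metric = c("families_total_fractions", "families_active_fractions",
                          "families_shared", "families_active_only",
                          "families_total_only", "consensus_cutoff_pct"),
               value = c(length(tot), length(act),
                         length(intersect(act, tot)),
                         length(setdiff(act, tot)), length(setdiff(tot, act)),
                         orb$cutoffs$consensus))
  })
  put(summary_tbl, "summary.tsv")
  message("pipeline complete: ", out_dir)
  invisible(list(design = design, scheme = scheme, tree = tree,
                 parsed = parsed, derep = derep, clean = clean,
                 report = report, assignments = assignments,
                 n_unassigned = n_unassigned, profile = profile,
                 fingerprint = fingerprint, metrics = metrics, orb = orb,
                 summary = summary_tbl))
}

#' Simulate and analyse in one call
#'
#' Convenience wrapper: [simulate_dataset()] into `dir/input`, then
#' [run_pipeline()] into `dir/output`.
#'
#' @param dir working directory for the run.
#' @param config parameter list; `...` overrides as in [simulate_dataset()].
#' @param overwrite passed to [simulate_dataset()].
#' @param ... parameter overrides.
#' @return invisibly, the [run_pipeline()] result with the simulation
#'   attached as `$simulation`.
#' @export
run_all <- function(dir, config = default_config(), overwrite = FALSE, ...) {
  config[names(list(...))] <- list(...)
  sim <- simulate_dataset(file.path(dir, "input"), config, overwrite)
  res <- run_pipeline(sim$paths$reads, sim$paths$hits, sim$paths$nodes,
                      sim$paths$names, sim$paths$design, sim$paths$mids,
                      file.path(dir, "output"), config)
  res$simulation <- sim
  invisible(res)
}
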