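# Rooted, rank-labelled taxonomy tree: container, lineage and LCA queries,
# NCBI-dump-like two-file TSV I/O, and a synthetic tree generator.

#' Construct a taxonomy tree
#'
#' A rooted tree whose nodes carry one of the ordered ranks
#' root < domain < phylum < class < order < family < genus < species.
#' The root is the unique node whose parent is itself.
#'
#' @param nodes data.frame with columns `id` (integer), `parent_id` (integer),
#'   `rank` (character), `name` (character).
#' @return an object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(nodes) {
  req <- c("id", "parent_id", "rank", "name")
  if (!all(req %in% names(nodes))) stop("nodes needs columns id, parent_id, rank, name")
  nodes <- as.data.frame(nodes)[, req]
  nodes$id <- as.integer(nodes$id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(nodes$rank %in% TAX_RANKS))
    stop("unknown rank(s): ", paste(setdiff(nodes$rank, TAX_RANKS), collapse = ", "))
  root <- nodes$id[nodes$parent_id == nodes$id]
  if (length(root) != 1L) stop("tree must have exactly one root (parent_id == id)")
  if (!all(nodes$parent_id %in% nodes$id)) stop("parent_id refers to missing node")
  # reachability / acyclicity: every node must reach the root in <= n steps
  for (i in seq_len(nrow(nodes))) {
    cur <- nodes$id[i]; steps <- 0L
    while (cur != root) {
      cur <- nodes$parent_id[match(cur, nodes$id)]
      steps <- steps + 1L
      if (steps > nrow(nodes)) stop("cycle detected in taxonomy")
    }
  }
  structure(list(nodes = nodes, root = root), class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  tab <- table(factor(x$nodes$rank, levels = TAX_RANKS))
  cat("taxonomy_tree:", nrow(x$nodes), "nodes\n")
  print(tab)
  invisible(x)
}

#' Root-to-node lineage of a taxonomy node
#'
#' @param tree a [taxonomy_tree()].
#' @param id node id.
#' @return integer vector of node ids from the root down to `id`.
#' @export
lineage <- function(tree, id) {
  pos <- match(id, tree$nodes$id)
  if (is.na(pos)) stop("unknown node id: ", id)
  path <- integer(0)
  cur <- id
  repeat {
    path <- c(cur, path)
    p <- tree$nodes$parent_id[match(cur, tree$nodes$id)]
    if (p == cur) break
    cur <- p
  }
  path
}

#' Lowest common ancestor of a set of taxonomy nodes
#'
#' The deepest node lying on the root-to-node lineage of every input node.
#' Because lineages are root-anchored paths, the LCA is the last element of
#' their common prefix; it is therefore invariant to the order of `ids` and
#' can only deepen (or stay put) when `ids` shrinks.
#'
#' @param tree a [taxonomy_tree()].
#' @param ids integer vector of node ids (at least one).
#' @return the LCA node id.
#' @export
lca <- function(tree, ids) {
  if (length(ids) == 0L) stop("lca needs at least one node", call. = FALSE)
  ids <- unique(ids)
  lins <- lapply(ids, function(i) lineage(tree, i))
  if (length(lins) == 1L) return(lins[[1L]][length(lins[[1L]])])
  depth <- min(lengths(lins))
  anc <- tree$root
  for (d in seq_len(depth)) {
    level <- vapply(lins, `[[`, integer(1), d)
    if (all(level == level[1L])) anc <- level[1L] else break
  }
  anc
}

#' @keywords internal
node_rank <- function(tree, id) tree$nodes$rank[match(id, tree$nodes$id)]

#' @keywords internal
node_name <- function(tree, id) tree$nodes$name[match(id, tree$nodes$id)]

#' Ancestor of a node at a given rank
#'
#' @param tree a [taxonomy_tree()].
#' @param ids integer vector of node ids.
#' @param rank target rank.
#' @return integer vector of ancestor ids at `rank` (`NA` where the node's
#'   own rank is shallower than `rank`).
#' @export
ancestor_at_rank <- function(tree, ids, rank) {
  if (!rank %in% TAX_RANKS) stop("unknown rank: ", rank)
  vapply(ids, function(i) {
    lin <- lineage(tree, i)
    rk <- tree$nodes$rank[match(lin, tree$nodes$id)]
    hit <- which(rk == rank)
    if (length(hit)) lin[hit[1L]] else NA_integer_
  }, integer(1))
}

# lineage table used by the vectorized assignment step: one row per node,
# one column per rank, entries are ancestor ids (NA below the node's rank)
lineage_matrix <- function(tree, ids = tree$nodes$id) {
  m <- matrix(NA_integer_, nrow = length(ids), ncol = length(TAX_RANKS),
              dimnames = list(as.character(ids), TAX_RANKS))
  for (j in seq_along(ids)) {
    lin <- lineage(tree, ids[j])
    rk <- tree$nodes$rank[match(lin, tree$nodes$id)]
    m[j, match(rk, TAX_RANKS)] <- lin
  }
  m
}

#' Read / write a taxonomy as node and name tables
#'
#' The on-disk dialect mirrors an NCBI-style dump split in two TSVs:
#' `nodes` with columns `id`, `parent_id`, `rank` and `names` with columns
#' `id`, `name`.
#'
#' @param nodes_path,names_path file paths.
#' @return [read_taxonomy()] returns a [taxonomy_tree()];
#'   [write_taxonomy()] returns the paths invisibly.
#' @export
read_taxonomy <- function(nodes_path, names_path) {
  nd <- read_headed_tsv(nodes_path)
  nm <- read_headed_tsv(names_path)
  nd$name <- nm$name[match(nd$id, nm$id)]
  taxonomy_tree(nd)
}

#' @rdname read_taxonomy
#' @param tree a [taxonomy_tree()].
#' @param seed,config_hash provenance recorded in the file headers.
#' @export
write_taxonomy <- function(tree, nodes_path, names_path,
                           seed = NA, config_hash = NA) {
  write_headed_tsv(tree$nodes[, c("id", "parent_id", "rank")], nodes_path,
                   seed, config_hash)
  write_headed_tsv(tree$nodes[, c("id", "name")], names_path,
                   seed, config_hash)
  invisible(c(nodes_path, names_path))
}

#' Read a taxonomy from a one-file lineage-string table
#'
#' Alternative input dialect: a TSV with columns `species_id` and `lineage`,
#' the latter a semicolon-separated path
#' `domain;phylum;class;order;family;genus;species` of names.
#'
#' @param path file path.
#' @return a [taxonomy_tree()].
#' @export
read_taxonomy_lineages <- function(path) {
  x <- read_headed_tsv(path)
  if (!all(c("species_id", "lineage") %in% names(x)))
    stop("lineage table needs columns species_id, lineage")
  ranks <- TAX_RANKS[-1L]  # domain..species
  nodes <- data.frame(id = 1L, parent_id = 1L, rank = "root", name = "root",
                      stringsAsFactors = FALSE)
  key <- c(root = 1L)
  next_id <- 2L
  for (r in seq_len(nrow(x))) {
    parts <- strsplit(x$lineage[r], ";", fixed = TRUE)[[1L]]
    if (length(parts) != length(ranks))
      stop("lineage must have ", length(ranks), " fields: ", x$lineage[r])
    parent <- 1L
    for (d in seq_along(parts)) {
      k <- paste(parts[seq_len(d)], collapse = ";")
      if (is.na(key[k])) {
        id <- if (d == length(parts)) as.integer(x$species_id[r]) else next_id
        if (d < length(parts)) next_id <- next_id + 1L
        nodes <- rbind(nodes, data.frame(id = id, parent_id = parent,
                                         rank = ranks[d], name = parts[d],
                                         stringsAsFactors = FALSE))
        key[k] <- id
      }
      parent <- key[[k]]
    }
  }
  # species ids supplied by the file may collide with internal ids; remap if so
  if (anyDuplicated(nodes$id)) stop("species_id collides with internal node ids; use ids > ", max(nodes$id))
  taxonomy_tree(nodes)
}

#' Generate a synthetic taxonomy tree
#'
#' Builds a rooted eight-rank tree (root, domain, phylum, class, order,
#' family, genus, species) with the requested numbers of phyla and families.
#' Families are spread over phyla (each phylum gets at least one), each
#' family holds 1-3 genera and each genus 1-3 species, which is the scale of
#' diversity a family-level 16S survey of the human gut resolves.
#'
#' @param n_phyla,n_families positive counts, `n_families >= n_phyla`.
#' @param seed integer seed; identical arguments and seed give identical trees.
#' @return a [taxonomy_tree()].
#' @export
gen_taxonomy <- function(n_phyla, n_families, seed = 1L) {
  if (!is.numeric(n_phyla) || !is.numeric(n_families) ||
      n_phyla < 1L || n_families < 1L)
    stop("counts must be positive", call. = FALSE)
  if (n_families < n_phyla) stop("need n_families >= n_phyla", call. = FALSE)
  with_seed(seed, {
    rows <- list(data.frame(id = 1L, parent_id = 1L, rank = "root",
                            name = "root", stringsAsFactors = FALSE),
                 data.frame(id = 2L, parent_id = 1L, rank = "domain",
                            name = "Bacteria", stringsAsFactors = FALSE))
    next_id <- 3L
    new_node <- function(parent, rank, name) {
      id <- next_id; next_id <<- next_id + 1L
      rows[[length(rows) + 1L]] <<- data.frame(id = id, parent_id = parent,
                                               rank = rank, name = name,
                                               stringsAsFactors = FALSE)
      id
    }
    # each phylum >= 1 family; spread the rest at random
    fam_per_phy <- rep(1L, n_phyla)
    extra <- n_families - n_phyla
    if (extra > 0L) {
      add <- table(factor(sample.int(n_phyla, extra, replace = TRUE),
                          levels = seq_len(n_phyla)))
      fam_per_phy <- fam_per_phy + as.integer(add)
    }
    fam_i <- 0L
    for (p in seq_len(n_phyla)) {
      phy <- new_node(2L, "phylum", sprintf("Phylum_%02d", p))
      cls <- new_node(phy, "class", sprintf("Class_%02d", p))
      ord <- new_node(cls, "order", sprintf("Order_%02d", p))
      for (f in seq_len(fam_per_phy[p])) {
        fam_i <- fam_i + 1L
        fam <- new_node(ord, "family", sprintf("Family_%03d", fam_i))
        for (g in seq_len(sample.int(3L, 1L))) {
          gen <- new_node(fam, "genus", sprintf("Genus_%03d_%d", fam_i, g))
          for (s in seq_len(sample.int(3L, 1L))) {
            new_node(gen, "species", sprintf("Species_%03d_%d_%d", fam_i, g, s))
          }
        }
      }
    }
    taxonomy_tree(do.call(rbind, rows))
  })
}
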