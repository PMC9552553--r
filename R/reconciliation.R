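# Species-overlap event calling on gene trees, mapping of duplications onto
# the species tree, duplication ratios, ortholog/paralog extraction, and
# Dollo gain/loss inference from presence patterns.

#' Root a gene tree
#'
#' Three strategies are offered. \code{"seed-farthest"} places the root on
#' the edge leading to the leaf farthest from the phylome seed sequence
#' (path length when branch lengths are present, node count otherwise).
#' \code{"midpoint"} is classical midpoint rooting. \code{"min-duplications"}
#' enumerates every edge rooting and returns one attaining the minimum
#' species-overlap duplication count; ties are broken by the
#' lexicographically smallest canonical newick, so the result is
#' deterministic. \code{"none"} returns an already rooted tree unchanged.
#'
#' @param tree a \code{gene_tree} with at least 2 leaves.
#' @param strategy one of \code{"min-duplications"}, \code{"seed-farthest"},
#'   \code{"midpoint"}, \code{"none"}.
#' @return a rooted \code{gene_tree}.
#' @export
root_gene_tree <- function(tree, strategy = c("min-duplications",
                                              "seed-farthest", "midpoint",
                                              "none")) {
  strategy <- match.arg(strategy)
  stopifnot(ape::Ntip(tree) >= 2)
  sp <- attr(tree, "species"); seed <- attr(tree, "seed_id")
  regene <- function(phy) gene_tree(phy, sp, seed)
  if (strategy == "none") {
    if (!ape::is.rooted(tree)) stop("strategy 'none' requires a rooted tree")
    return(tree)
  }
  if (ape::Ntip(tree) == 2L) return(all_rootings(tree)[[1]])
  switch(strategy,
    "midpoint" = regene(phangorn::midpoint(ape::as.phylo(tree))),
    "seed-farthest" = {
      if (is.null(seed))
        stop("seed-farthest rooting requires a seed sequence ID")
      phy <- ape::as.phylo(tree)
      if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))
      d <- ape::cophenetic.phylo(phy)[seed, ]
      far <- names(which.max(d[setdiff(names(d), seed)]))
      regene(ape::root(phy, outgroup = far, resolve.root = TRUE))
    },
    "min-duplications" = {
      cand <- all_rootings(tree)
      scores <- vapply(cand, function(r) {
        sum(annotate_events(r)$event == "duplication")
      }, numeric(1))
      best <- which(scores == min(scores))
      keys <- vapply(cand[best], canonical_newick, character(1))
      cand[[best[order(keys)[1]]]]
    })
}

#' Call speciation and duplication events by species overlap
#'
#' Traverses a rooted gene tree and, at each internal node, compares the
#' species sets of the daughter partitions. The species-overlap score is
#' |intersection| / |union|; a node is a duplication when the score exceeds
#' \code{overlap_cutoff}. The default cutoff 0 reproduces the plain rule:
#' any species present on both sides implies a duplication. Multifurcating
#' nodes are scored over all pairs of child partitions (a duplication if any
#' pair overlaps; the reported score is the maximum pairwise score).
#'
#' @param tree a rooted \code{gene_tree}.
#' @param overlap_cutoff real in [0, 1); duplication iff score > cutoff.
#' @return a \code{data.frame} with one row per internal node: \code{node}
#'   (ape node id), \code{event}, \code{score}, and list columns
#'   \code{left_species}, \code{right_species} (the two largest child
#'   partitions for multifurcations), \code{overlap}.
#' @export
annotate_events <- function(tree, overlap_cutoff = 0) {
  stopifnot(overlap_cutoff >= 0, overlap_cutoff < 1)
  if (!ape::is.rooted(tree))
    stop("annotate_events requires a rooted tree")
  nt <- ape::Ntip(tree)
  sp <- tip_species(tree)
  tipsets <- node_tipsets(tree)
  spsets <- lapply(tipsets, function(t) unique(unname(sp[t])))
  nodes <- nt + seq_len(tree$Nnode)
  rows <- lapply(nodes, function(v) {
    kids <- node_children(tree, v)
    ksets <- spsets[kids]
    best <- 0; ov <- character(0)
    for (i in seq_along(ksets)[-length(ksets)]) {
      for (j in (i + 1L):length(ksets)) {
        int <- intersect(ksets[[i]], ksets[[j]])
        sc <- length(int) / length(union(ksets[[i]], ksets[[j]]))
        if (sc > best) best <- sc
        ov <- union(ov, int)
      }
    }
    ord <- order(lengths(ksets), decreasing = TRUE)
    list(node = v,
         event = if (best > overlap_cutoff) "duplication" else "speciation",
         score = best,
         left_species = sort(ksets[[ord[1]]]),
         right_species = if (length(ksets) > 1) sort(ksets[[ord[2]]])
                         else character(0),
         overlap = sort(ov))
  })
  data.frame(
    node = vapply(rows, `[[`, integer(1), "node"),
    event = vapply(rows, `[[`, character(1), "event"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    left_species = I(lapply(rows, `[[`, "left_species")),
    right_species = I(lapply(rows, `[[`, "right_species")),
    overlap = I(lapply(rows, `[[`, "overlap"))
  )
}

#' Map duplication events onto species-tree nodes
#'
#' Each duplication node of the gene tree is dated to the species-tree MRCA
#' of the union of its daughter species sets, and counts are aggregated per
#' species-tree node.
#'
#' @param events event table from \code{\link{annotate_events}}.
#' @param gene_tree the annotated \code{gene_tree}.
#' @param sp_tree the \code{species_tree}; must contain every species in the
#'   gene tree.
#' @return data.frame with \code{node}, \code{label}, \code{count} for every
#'   species-tree node (zero rows included).
#' @export
map_duplications <- function(events, gene_tree, sp_tree) {
  gsp <- unique(tip_species(gene_tree))
  absent <- setdiff(gsp, sp_tree$tip.label)
  if (length(absent))
    stop("gene-tree species absent from species tree: ",
         paste(absent, collapse = ", "))
  n_nodes <- ape::Ntip(sp_tree) + sp_tree$Nnode
  counts <- integer(n_nodes)
  dup <- events[events$event == "duplication", , drop = FALSE]
  for (k in seq_len(nrow(dup))) {
    spset <- union(dup$left_species[[k]], dup$right_species[[k]])
    m <- species_mrca(sp_tree, spset)
    counts[m] <- counts[m] + 1L
  }
  data.frame(node = seq_len(n_nodes),
             label = species_node_labels(sp_tree),
             count = counts)
}

# does the species set of a gene tree make species-tree node `v` countable?
# strict rule: intersects >= 2 daughter clades of v (internal) or contains
# the species (leaf); loose rule: intersects the clade of v at all.
contains_node <- function(v, spset, sp_tree, tipsets, rule) {
  nt <- ape::Ntip(sp_tree)
  if (rule == "clade")
    return(any(sp_tree$tip.label[tipsets[[v]]] %in% spset))
  if (v <= nt) return(sp_tree$tip.label[v] %in% spset)
  kids <- node_children(sp_tree, v)
  hit <- vapply(kids, function(k)
    any(sp_tree$tip.label[tipsets[[k]]] %in% spset), logical(1))
  sum(hit) >= 2L
}

#' Per-node duplication ratios over a collection of gene trees
#'
#' For each species-tree node, the ratio of duplications mapped to that node
#' to the number of gene trees containing the node: 0 means no duplication,
#' 1 an average of one duplication per gene, >1 multiple duplications per
#' gene and node. A gene tree "contains" an internal node when its species
#' set intersects at least two daughter clades of the node (the only trees
#' in which a duplication could map there); \code{containment = "clade"}
#' relaxes this to any intersection with the node's clade. Setting
#' \code{expansion_cap} bounds the duplications any single gene tree may
#' contribute to one node, screening out large lineage-specific expansions.
#'
#' @param gene_trees list of rooted \code{gene_tree}s.
#' @param sp_tree the shared \code{species_tree}.
#' @param overlap_cutoff passed to \code{\link{annotate_events}}.
#' @param expansion_cap optional positive integer cap per tree per node.
#' @param containment \code{"both-daughters"} (default) or \code{"clade"}.
#' @return data.frame with \code{node}, \code{label}, \code{count},
#'   \code{trees_containing}, \code{ratio} (NA when no tree contains the
#'   node).
#' @export
duplication_ratios <- function(gene_trees, sp_tree, overlap_cutoff = 0,
                               expansion_cap = NULL,
                               containment = c("both-daughters", "clade")) {
  containment <- match.arg(containment)
  stopifnot(length(gene_trees) >= 1)
  if (!is.null(expansion_cap)) stopifnot(expansion_cap >= 1)
  n_nodes <- ape::Ntip(sp_tree) + sp_tree$Nnode
  tipsets <- node_tipsets(sp_tree)
  counts <- numeric(n_nodes)
  containing <- integer(n_nodes)
  rule <- if (containment == "clade") "clade" else "both"
  for (gt in gene_trees) {
    ev <- annotate_events(gt, overlap_cutoff)
    percount <- map_duplications(ev, gt, sp_tree)$count
    if (!is.null(expansion_cap)) percount <- pmin(percount, expansion_cap)
    counts <- counts + percount
    spset <- unique(tip_species(gt))
    inn <- vapply(seq_len(n_nodes), contains_node, logical(1),
                  spset = spset, sp_tree = sp_tree, tipsets = tipsets,
                  rule = rule)
    containing <- containing + inn
  }
  data.frame(node = seq_len(n_nodes),
             label = species_node_labels(sp_tree),
             count = counts,
             trees_containing = containing,
             ratio = ifelse(containing > 0, counts / containing, NA_real_))
}

#' Extract ortholog and paralog relations from an annotated gene tree
#'
#' A pair of genes from different species is orthologous when the event at
#' their gene-tree MRCA is a speciation, paralogous when it is a
#' duplication; same-species pairs with a duplication MRCA are (in)paralogs.
#' Ortholog pairs are typed one-to-one / one-to-many / many-to-one /
#' many-to-many by counting, within the MRCA's subtree, the sequences each
#' side's species contributes.
#'
#' @param events event table from \code{\link{annotate_events}}.
#' @param gene_tree the annotated \code{gene_tree}.
#' @return list with data.frames \code{orthologs} (\code{gene1, gene2,
#'   species1, species2, type, node}) and \code{paralogs} (\code{gene1,
#'   gene2, node}).
#' @export
extract_relations <- function(events, gene_tree) {
  nt <- ape::Ntip(gene_tree)
  sp <- tip_species(gene_tree)
  labs <- gene_tree$tip.label
  ev <- setNames(events$event, events$node)
  tipsets <- node_tipsets(gene_tree)
  orth <- list(); para <- list()
  if (nt >= 2) {
    mr <- ape::mrca(gene_tree)
    for (i in seq_len(nt - 1L)) {
      for (j in (i + 1L):nt) {
        v <- mr[i, j]
        is_dup <- identical(unname(ev[as.character(v)]), "duplication")
        if (sp[i] == sp[j]) {
          if (is_dup)
            para[[length(para) + 1L]] <- list(labs[i], labs[j], v)
          next
        }
        if (is_dup) {
          para[[length(para) + 1L]] <- list(labs[i], labs[j], v)
        } else {
          sub <- sp[tipsets[[v]]]
          ni <- sum(sub == sp[i]); nj <- sum(sub == sp[j])
          type <- if (ni == 1 && nj == 1) "one-to-one"
            else if (ni == 1) "one-to-many"
            else if (nj == 1) "many-to-one"
            else "many-to-many"
          orth[[length(orth) + 1L]] <-
            list(labs[i], labs[j], unname(sp[i]), unname(sp[j]), type, v)
        }
      }
    }
  }
  list(
    orthologs = data.frame(
      gene1 = vapply(orth, `[[`, character(1), 1),
      gene2 = vapply(orth, `[[`, character(1), 2),
      species1 = vapply(orth, `[[`, character(1), 3),
      species2 = vapply(orth, `[[`, character(1), 4),
      type = vapply(orth, `[[`, character(1), 5),
      node = vapply(orth, function(x) as.integer(x[[6]]), integer(1))
    ),
    paralogs = data.frame(
      gene1 = vapply(para, `[[`, character(1), 1),
      gene2 = vapply(para, `[[`, character(1), 2),
      node = vapply(para, function(x) as.integer(x[[3]]), integer(1))
    )
  )
}

#' Dollo gain/loss inference from ortholog presence patterns
#'
#' Under single-gain (Dollo) parsimony each orthologous family is gained
#' once, at the species-tree MRCA of the species carrying it, and lost along
#' branches below that gain. Losses are placed minimally: a loss is reported
#' at the highest node whose entire subtree lacks the family while its
#' parent's subtree does not, so no loss is double-counted at descendants.
#'
#' @param presence logical matrix or data.frame, orthogroups in rows,
#'   species in columns (column names = species labels).
#' @param sp_tree the \code{species_tree}.
#' @return list with \code{per_family} (orthogroup, gain node id and label,
#'   list column of loss node ids, n_losses) and \code{per_node} aggregate
#'   data.frame (node, label, gains, losses).
#' @export
infer_gain_loss <- function(presence, sp_tree) {
  presence <- as.matrix(presence)
  mode(presence) <- "logical"
  absent_sp <- setdiff(colnames(presence), sp_tree$tip.label)
  if (length(absent_sp))
    stop("presence species absent from species tree: ",
         paste(absent_sp, collapse = ", "))
  nt <- ape::Ntip(sp_tree)
  n_nodes <- nt + sp_tree$Nnode
  tipsets <- node_tipsets(sp_tree)
  labels <- species_node_labels(sp_tree)
  gains <- integer(n_nodes); losses <- integer(n_nodes)
  fam_rows <- vector("list", nrow(presence))
  og_names <- rownames(presence)
  if (is.null(og_names)) og_names <- paste0("OG", seq_len(nrow(presence)))
  for (f in seq_len(nrow(presence))) {
    present <- colnames(presence)[presence[f, ]]
    if (!length(present))
      stop("orthogroup with empty presence row: ", og_names[f])
    gain <- species_mrca(sp_tree, present)
    gains[gain] <- gains[gain] + 1L
    # loss nodes: maximal subtrees below the gain with no present species
    has_present <- vapply(tipsets, function(t)
      any(sp_tree$tip.label[t] %in% present), logical(1))
    loss_nodes <- integer(0)
    walk <- function(v) {
      for (k in node_children(sp_tree, v)) {
        if (!has_present[k]) {
          loss_nodes <<- c(loss_nodes, k)
        } else if (k > nt) {
          walk(k)
        }
      }
    }
    if (gain > nt) walk(gain)
    losses[loss_nodes] <- losses[loss_nodes] + 1L
    fam_rows[[f]] <- list(orthogroup = og_names[f], gain = gain,
                          loss_nodes = loss_nodes)
  }
  list(
    per_family = data.frame(
      orthogroup = vapply(fam_rows, `[[`, character(1), "orthogroup"),
      gain_node = vapply(fam_rows, function(x) as.integer(x$gain),
                         integer(1)),
      gain_label = labels[vapply(fam_rows, function(x) as.integer(x$gain),
                                 integer(1))],
      loss_nodes = I(lapply(fam_rows, `[[`, "loss_nodes")),
      n_losses = vapply(fam_rows, function(x) length(x$loss_nodes),
                        integer(1))
    ),
    per_node = data.frame(node = seq_len(n_nodes), label = labels,
                          gains = gains, losses = losses)
  )
}
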