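# Core tree containers and traversal helpers shared by every module.
# Trees are ape "phylo" objects; gene trees additionally carry a named
# character vector mapping tip labels to species mnemonics.

#' Construct a gene tree
#'
#' A gene tree is an ape \code{phylo} whose tips are sequence IDs, each
#' resolved to a species mnemonic. The species assignment is carried as an
#' attribute aligned to \code{tip.label} names.
#'
#' @param phy an ape \code{phylo} object; tip labels must be unique.
#' @param species named character vector, names = tip labels, values =
#'   species mnemonics. Every tip must be covered.
#' @param seed_id optional sequence ID of the phylome seed (must be a tip).
#' @return an object of class \code{c("gene_tree", "phylo")}.
#' @export
gene_tree <- function(phy, species, seed_id = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label))
    stop("gene tree tip labels must be unique")
  missing <- setdiff(phy$tip.label, names(species))
  if (length(missing))
    stop("no species mapping for leaf: ", paste(missing, collapse = ", "))
  if (!is.null(seed_id) && !seed_id %in% phy$tip.label)
    stop("seed sequence ", seed_id, " is not a tip of the tree")
  attr(phy, "species") <- species[phy$tip.label]
  attr(phy, "seed_id") <- seed_id
  class(phy) <- unique(c("gene_tree", class(phy)))
  phy
}

#' Construct a species tree
#'
#' Validates the invariants expected of a species tree: unique leaf labels,
#' every internal node with at least two children, and (when supplied) node
#' age ranks that are non-decreasing from the leaves towards the root.
#'
#' @param phy an ape \code{phylo} (binary or multifurcating, rooted).
#' @param age_rank optional integer vector of length \code{Nnode} (one per
#'   internal node, in ape node order) of non-negative age ranks.
#' @return an object of class \code{c("species_tree", "phylo")}.
#' @export
species_tree <- function(phy, age_rank = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label))
    stop("species tree leaf labels must be unique")
  if (!ape::is.rooted(phy) && ape::Ntip(phy) > 2)
    stop("species tree must be rooted")
  if (!is.null(age_rank)) {
    if (length(age_rank) != phy$Nnode)
      stop("age_rank must have one value per internal node")
    if (any(age_rank < 0)) stop("age ranks must be non-negative")
    nt <- ape::Ntip(phy)
    for (k in seq_len(nrow(phy$edge))) {
      p <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
      if (ch > nt && age_rank[p - nt] < age_rank[ch - nt])
        stop("age ranks must be non-decreasing towards the root")
    }
    attr(phy, "age_rank") <- age_rank
  }
  class(phy) <- unique(c("species_tree", class(phy)))
  phy
}

#' Species of each tip of a gene tree
#'
#' @param tree a \code{gene_tree}.
#' @return character vector of species mnemonics named by tip label.
#' @export
tip_species <- function(tree) {
  sp <- attr(tree, "species")
  if (is.null(sp)) stop("tree carries no species mapping; see gene_tree()")
  sp[tree$tip.label]
}

# children of an internal node
node_children <- function(phy, node) phy$edge[phy$edge[, 1] == node, 2]

# list over all node ids (1..Ntip+Nnode) of the tip indices under each node
node_tipsets <- function(phy) {
  nt <- ape::Ntip(phy)
  sets <- vector("list", nt + phy$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- i
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    sets[[eo[k, 1]]] <- c(sets[[eo[k, 1]]], sets[[eo[k, 2]]])
  }
  sets
}

# per-node species sets of a gene tree (sorted unique character vectors)
node_species_sets <- function(tree) {
  sp <- tip_species(tree)
  lapply(node_tipsets(tree), function(tips) sort(unique(unname(sp[tips]))))
}

root_node <- function(phy) ape::Ntip(phy) + 1L

# Labels for every species-tree node: tip label for leaves, node.label when
# present, otherwise "node<N>".
species_node_labels <- function(sp_tree) {
  nt <- ape::Ntip(sp_tree)
  lab <- character(nt + sp_tree$Nnode)
  lab[seq_len(nt)] <- sp_tree$tip.label
  inner <- sp_tree$node.label
  for (i in seq_len(sp_tree$Nnode)) {
    nl <- if (!is.null(inner) && nzchar(inner[i]) && !is.na(inner[i]))
      inner[i] else paste0("node", nt + i)
    lab[nt + i] <- nl
  }
  lab
}

# MRCA node id of a set of species labels in a species tree
species_mrca <- function(sp_tree, species) {
  idx <- match(species, sp_tree$tip.label)
  if (anyNA(idx))
    stop("species absent from species tree: ",
         paste(species[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(sp_tree, idx)
}

# Topology-only canonical newick: children sorted recursively by their own
# canonical string, branch lengths dropped. Used for deterministic
# tie-breaking and topology identity.
canonical_newick <- function(phy) {
  nt <- ape::Ntip(phy)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  rec <- function(node) {
    if (node <= nt) return(phy$tip.label[node])
    parts <- sort(vapply(kids[[as.character(node)]], rec, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(root_node(phy)), ";")
}

# All rootings of a tree: one rooted tree per edge of its unrooted version.
# Attributes (species map, seed) are preserved.
all_rootings <- function(tree) {
  sp <- attr(tree, "species"); seed <- attr(tree, "seed_id")
  keep <- function(phy) {
    if (!is.null(sp)) gene_tree(phy, sp, seed) else phy
  }
  if (ape::Ntip(tree) == 2L) {
    phy <- tree
    if (!ape::is.rooted(phy)) phy <- ape::root(phy, 1, resolve.root = TRUE)
    return(list(keep(phy)))
  }
  u <- ape::unroot(ape::as.phylo(tree))
  nt <- ape::Ntip(u)
  sets <- node_tipsets(u)
  out <- list()
  for (k in seq_len(nrow(u$edge))) {
    tips <- u$tip.label[sets[[u$edge[k, 2]]]]
    if (length(tips) >= nt) next
    r <- ape::root(u, outgroup = tips, resolve.root = TRUE)
    out[[length(out) + 1L]] <- keep(r)
  }
  out
}

# -- rooted binary topology enumeration --------------------------------------
# Trees are nested 2-lists of labels during construction; converted to newick
# and parsed once at the end. Insertion of taxon k offers 2k-3 positions,
# yielding all (2n-3)!! rooted labelled topologies exactly once.

tree_to_newick <- function(t) {
  rec <- function(x) {
    if (!is.list(x)) return(x)
    paste0("(", rec(x[[1]]), ",", rec(x[[2]]), ")")
  }
  paste0(rec(t), ";")
}

insert_everywhere <- function(t, x) {
  res <- list(list(t, x))
  if (is.list(t)) {
    for (i in 1:2) {
      for (s in insert_everywhere(t[[i]], x)) {
        nt <- t; nt[[i]] <- s
        res <- c(res, list(nt))
      }
    }
  }
  res
}

# all rooted binary labelled topologies over a taxa set, as phylo objects
enumerate_rooted_topologies <- function(taxa) {
  stopifnot(length(taxa) >= 2)
  forest <- list(list(taxa[[1]], taxa[[2]]))
  for (x in taxa[-(1:2)]) {
    forest <- unlist(lapply(forest, insert_everywhere, x = x),
                     recursive = FALSE)
  }
  lapply(forest, function(t) ape::read.tree(text = tree_to_newick(t)))
}
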