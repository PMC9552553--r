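# Duplication-minimizing species-tree scoring and search (the gene
# duplication supertree criterion), single-copy family selection, and
# supermatrix concatenation.

# ancestor chain (node -> root) for every node of a rooted tree
ancestor_chains <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  parent <- integer(n)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  r <- root_node(phy)
  lapply(seq_len(n), function(v) {
    chain <- v
    while (v != r) { v <- parent[v]; chain <- c(chain, v) }
    chain
  })
}

# LCA-mapping reconciliation duplication count of a rooted gene tree against
# a rooted species tree: node v is a duplication iff its species-tree map
# equals the map of one of its children.
lca_duplications <- function(gtree, sp_tree) {
  nt <- ape::Ntip(gtree)
  sp <- tip_species(gtree)
  absent <- setdiff(unique(sp), sp_tree$tip.label)
  if (length(absent))
    stop("gene-tree species absent from species tree: ",
         paste(absent, collapse = ", "))
  chains <- ancestor_chains(sp_tree)
  # pairwise species-tree mrca via ancestor chains
  mrca2 <- function(a, b) {
    if (a == b) return(a)
    ca <- chains[[a]]
    cb <- chains[[b]]
    ca[ca %in% cb][1]
  }
  n <- nt + gtree$Nnode
  m <- integer(n)
  m[seq_len(nt)] <- match(sp, sp_tree$tip.label)
  eo <- ape::reorder.phylo(gtree, "postorder")$edge
  dups <- 0L
  done <- logical(n); done[seq_len(nt)] <- TRUE
  kids <- split(eo[, 2], eo[, 1])
  # a parent is resolvable once its last child edge has been visited
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1]
    ch <- kids[[as.character(p)]]
    if (!done[p] && all(done[ch])) {
      mv <- m[ch[1]]
      for (c2 in ch[-1]) mv <- mrca2(mv, m[c2])
      m[p] <- mv
      done[p] <- TRUE
      if (any(m[ch] == mv)) dups <- dups + 1L
    }
  }
  dups
}

#' Score a species-tree topology by reconciliation duplications
#'
#' The gene-duplication supertree criterion: each gene tree is reconciled
#' against the candidate species tree by LCA mapping and its duplication
#' events counted; the topology's score is the sum over gene trees. Gene
#' trees are treated as unrooted and each is given the rooting that
#' minimizes its own duplication count against the candidate (set
#' \code{rooting = "fixed"} to respect the supplied rootings).
#'
#' @param sp_tree candidate \code{species_tree} (rooted).
#' @param gene_trees list of \code{gene_tree}s.
#' @param rooting \code{"optimal"} (default) or \code{"fixed"}.
#' @return list of class \code{topology_score}: \code{topology},
#'   \code{total}, numeric \code{breakdown} (one entry per gene tree).
#' @export
duplication_score <- function(sp_tree, gene_trees,
                              rooting = c("optimal", "fixed")) {
  rooting <- match.arg(rooting)
  stopifnot(length(gene_trees) >= 1)
  breakdown <- vapply(gene_trees, function(gt) {
    if (rooting == "fixed") {
      if (!ape::is.rooted(gt)) stop("rooting 'fixed' requires rooted trees")
      return(lca_duplications(gt, sp_tree))
    }
    min(vapply(all_rootings(gt), lca_duplications, numeric(1),
               sp_tree = sp_tree))
  }, numeric(1))
  structure(list(topology = sp_tree, total = sum(breakdown),
                 breakdown = breakdown),
            class = "topology_score")
}

# nested-list representation of a rooted binary tree, for NNI rearrangement
phylo_to_nested <- function(phy) {
  nt <- ape::Ntip(phy)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  rec <- function(v) {
    if (v <= nt) return(phy$tip.label[v])
    k <- lapply(kids[[as.character(v)]], rec)
    Reduce(function(a, b) list(a, b), k)
  }
  rec(root_node(phy))
}

# all rooted NNI neighbours of a nested-list tree
nested_nni <- function(t) {
  res <- list()
  if (!is.list(t)) return(res)
  for (i in 1:2) {
    v <- t[[i]]; s <- t[[3 - i]]
    if (is.list(v)) {
      n1 <- t; n1[[i]] <- list(s, v[[2]]); n1[[3 - i]] <- v[[1]]
      n2 <- t; n2[[i]] <- list(v[[1]], s); n2[[3 - i]] <- v[[2]]
      res <- c(res, list(n1, n2))
    }
    for (sub in nested_nni(t[[i]])) {
      nt2 <- t; nt2[[i]] <- sub
      res <- c(res, list(nt2))
    }
  }
  res
}

#' Search for the duplication-minimizing species tree
#'
#' \code{mode = "exhaustive"} enumerates every rooted binary labelled
#' topology over the taxa (3 taxa: 3; 4: 15; 5: 105; ...) and returns a
#' global minimum; it refuses more than 7 taxa. \code{mode = "nni"}
#' hill-climbs over rooted nearest-neighbour-interchange rearrangements from
#' \code{start} (default: the caterpillar over the taxa in the given order),
#' accepting the best strictly improving neighbour, with ties broken by the
#' lexicographically smallest canonical newick; the returned score never
#' exceeds the start score. All tie-breaking is deterministic.
#'
#' @param gene_trees list of \code{gene_tree}s.
#' @param taxa character vector of species labels; defaults to the union of
#'   species over the gene trees.
#' @param mode \code{"exhaustive"} or \code{"nni"}.
#' @param start optional starting \code{species_tree} for NNI.
#' @return a \code{topology_score} for the best topology found.
#' @export
search_min_dup <- function(gene_trees, taxa = NULL,
                           mode = c("exhaustive", "nni"), start = NULL) {
  mode <- match.arg(mode)
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(gene_trees, tip_species))))
  stopifnot(length(taxa) >= 2)
  score_of <- function(phy)
    duplication_score(species_tree(phy), gene_trees)
  if (mode == "exhaustive") {
    if (length(taxa) > 7)
      stop("exhaustive search supports at most 7 taxa; use mode = 'nni'")
    cands <- enumerate_rooted_topologies(taxa)
    scores <- vapply(cands, function(p) score_of(p)$total, numeric(1))
    best <- which(scores == min(scores))
    keys <- vapply(cands[best], canonical_newick, character(1))
    return(score_of(cands[[best[order(keys)[1]]]]))
  }
  if (is.null(start)) {
    t <- taxa[[1]]
    for (x in taxa[-1]) t <- list(t, x)
    start <- ape::read.tree(text = tree_to_newick(t))
  }
  cur <- ape::as.phylo(start)
  cur_score <- score_of(cur)$total
  repeat {
    nb <- nested_nni(phylo_to_nested(cur))
    if (!length(nb)) break
    phys <- lapply(nb, function(x) ape::read.tree(text = tree_to_newick(x)))
    keys <- vapply(phys, canonical_newick, character(1))
    phys <- phys[!duplicated(keys)]
    scores <- vapply(phys, function(p) score_of(p)$total, numeric(1))
    if (min(scores) >= cur_score) break
    best <- which(scores == min(scores))
    keys <- vapply(phys[best], canonical_newick, character(1))
    cur <- phys[[best[order(keys)[1]]]]
    cur_score <- min(scores)
  }
  score_of(cur)
}

#' Select single-copy families
#'
#' Keeps families that never have more than one member in any species and
#' have exactly one member in at least \code{min_species} species — the
#' marker-selection rule behind concatenated species-tree inference (e.g.
#' one-to-one orthologs in 14 out of 15 species).
#'
#' @param families data.frame with columns \code{family}, \code{gene},
#'   \code{species} (one row per member).
#' @param min_species minimum number of species with exactly one member.
#' @param total_species total species in the study; \code{min_species} may
#'   not exceed it.
#' @return character vector of retained family IDs.
#' @export
select_single_copy <- function(families, min_species, total_species) {
  stopifnot(min_species <= total_species,
            all(c("family", "gene", "species") %in% names(families)))
  keep <- vapply(split(families, families$family), function(fam) {
    cnt <- table(fam$species)
    all(cnt <= 1) && sum(cnt == 1) >= min_species
  }, logical(1))
  names(keep)[keep]
}

#' Concatenate per-family alignment blocks into a supermatrix
#'
#' @param alignments named list of families; each element a named character
#'   vector of aligned sequences (taxon -> sequence, equal lengths within a
#'   family).
#' @param taxa optional taxon order; defaults to order of first appearance.
#' @param gap gap character used to pad taxa absent from a family.
#' @return object of class \code{supermatrix}: \code{seqs} (named character
#'   vector), \code{partitions} (data.frame family/start/end, 0-based
#'   half-open), \code{mask} (taxa x family logical, TRUE = present).
#' @export
concatenate <- function(alignments, taxa = NULL, gap = "-") {
  stopifnot(length(alignments) >= 1, !is.null(names(alignments)))
  widths <- integer(length(alignments))
  for (i in seq_along(alignments)) {
    w <- unique(nchar(alignments[[i]]))
    if (length(w) != 1)
      stop("unequal sequence lengths within family ", names(alignments)[i])
    widths[i] <- w
  }
  if (is.null(taxa))
    taxa <- unique(unlist(lapply(alignments, names)))
  ends <- cumsum(widths)
  starts <- c(0L, ends[-length(ends)])
  mask <- matrix(FALSE, length(taxa), length(alignments),
                 dimnames = list(taxa, names(alignments)))
  seqs <- setNames(character(length(taxa)), taxa)
  for (i in seq_along(alignments)) {
    block <- alignments[[i]]
    pad <- strrep(gap, widths[i])
    piece <- ifelse(taxa %in% names(block), block[taxa], pad)
    seqs <- paste0(seqs, piece)
    mask[, i] <- taxa %in% names(block)
  }
  names(seqs) <- taxa
  structure(list(seqs = seqs,
                 partitions = data.frame(family = names(alignments),
                                         start = starts, end = ends),
                 mask = mask),
            class = "supermatrix")
}

#' Write a supermatrix as FASTA plus a partition table
#'
#' @param sm a \code{supermatrix}.
#' @param fasta_path output FASTA path.
#' @param partition_path output TSV path (family, start, end; 0-based
#'   half-open).
#' @export
write_supermatrix <- function(sm, fasta_path, partition_path) {
  stopifnot(inherits(sm, "supermatrix"))
  con <- file(fasta_path, "w")
  on.exit(close(con))
  for (tx in names(sm$seqs))
    writeLines(c(paste0(">", tx), sm$seqs[[tx]]), con)
  utils::write.table(sm$partitions, partition_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}
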