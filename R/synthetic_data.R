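# Simulators with known ground truth: species trees, gene families evolving
# by duplication and loss, multi-tool orthology calls with planted error,
# and unimodal developmental expression time courses. Every simulator is a
# pure function of its parameters and seed.

#' Simulate a random rooted binary species tree
#'
#' Taxa are inserted sequentially at a uniformly chosen position (any edge
#' or above the root), which draws uniformly from all (2n-3)!! rooted
#' labelled topologies.
#'
#' @param n_taxa number of taxa (>= 3).
#' @param seed optional RNG seed.
#' @param labels taxon labels; default \code{sp1..spN}.
#' @return a \code{species_tree}.
#' @export
simulate_species_tree <- function(n_taxa, seed = NULL, labels = NULL) {
  stopifnot(n_taxa >= 3)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- paste0("sp", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa)
  t <- list(labels[[1]], labels[[2]])
  for (x in labels[-(1:2)]) {
    pos <- insert_everywhere(t, x)
    t <- pos[[sample.int(length(pos), 1)]]
  }
  species_tree(ape::read.tree(text = tree_to_newick(t)))
}

#' Simulate a gene family along a species tree
#'
#' One ancestral copy enters at the root. Along each species-tree branch,
#' every entering copy duplicates with probability \code{lambda} (one event
#' per copy per branch, logged on the branch's lower node), and each
#' resulting lineage is independently lost with probability \code{mu}.
#' Families that lose every copy are re-drawn (the number of redraws is
#' reported). With \code{mu = 0} every species carries at least one gene and
#' the observable gene tree records the true events exactly.
#'
#' Gene-tree leaves are labelled \code{g<k>_<species>}, so the default
#' suffix species map applies. Internal nodes carry \code{"D"}/\code{"S"}
#' labels recording the true event type.
#'
#' @param sp_tree a rooted binary \code{species_tree}.
#' @param lambda per-branch per-copy duplication probability in [0, 1).
#' @param mu per-branch per-lineage loss probability in [0, 1).
#' @param prefix leaf-label prefix; give each family a distinct prefix when
#'   gene IDs must be unique across families.
#' @param seed optional RNG seed.
#' @return list of class \code{simulated_family}: \code{tree} (a
#'   \code{gene_tree}), \code{dup_counts} and \code{loss_counts} (named by
#'   species-tree node label), \code{n_redraws}, \code{params}.
#' @export
simulate_family <- function(sp_tree, lambda, mu = 0, prefix = "g",
                            seed = NULL) {
  stopifnot(lambda >= 0, lambda < 1, mu >= 0, mu < 1)
  if (!is.null(seed)) set.seed(seed)
  nt <- ape::Ntip(sp_tree)
  labels <- species_node_labels(sp_tree)
  n_nodes <- nt + sp_tree$Nnode
  redraws <- 0L
  repeat {
    counter <- 0L
    dup <- integer(n_nodes); loss <- integer(n_nodes)
    evolve_node <- function(v) {
      if (v <= nt) {
        counter <<- counter + 1L
        return(paste0(prefix, counter, "_", sp_tree$tip.label[v]))
      }
      parts <- list()
      for (ch in node_children(sp_tree, v)) {
        sub <- evolve_branch(ch)
        if (!is.null(sub)) parts[[length(parts) + 1L]] <- sub
      }
      if (!length(parts)) return(NULL)
      out <- parts[[1]]
      for (p in parts[-1]) out <- list(out, p, ev = "S")
      out
    }
    evolve_branch <- function(ch) {
      # one copy enters the branch above node ch
      if (stats::runif(1) < lambda) {
        dup[ch] <<- dup[ch] + 1L
        daughters <- list(survive_then(ch), survive_then(ch))
        daughters <- Filter(Negate(is.null), daughters)
        if (!length(daughters)) return(NULL)
        if (length(daughters) == 1L) return(daughters[[1]])
        return(list(daughters[[1]], daughters[[2]], ev = "D"))
      }
      survive_then(ch)
    }
    survive_then <- function(ch) {
      if (stats::runif(1) < mu) {
        loss[ch] <<- loss[ch] + 1L
        return(NULL)
      }
      evolve_node(ch)
    }
    t <- evolve_node(root_node(sp_tree))
    if (!is.null(t)) break
    redraws <- redraws + 1L
  }
  to_newick <- function(x) {
    if (!is.list(x)) return(x)
    paste0("(", to_newick(x[[1]]), ",", to_newick(x[[2]]), ")", x$ev)
  }
  txt <- paste0(to_newick(t), ";")
  if (!is.list(t)) txt <- paste0("(", t, ");")  # single surviving copy
  phy <- ape::read.tree(text = txt)
  tree <- gene_tree(phy, map_species(phy$tip.label, species_map_suffix()))
  structure(list(tree = tree,
                 dup_counts = setNames(dup, labels),
                 loss_counts = setNames(loss, labels),
                 n_redraws = redraws,
                 params = list(lambda = lambda, mu = mu)),
            class = "simulated_family")
}

# event table (node, event) reconstructed from the simulator's D/S labels
true_events <- function(tree) {
  nt <- ape::Ntip(tree)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("S", tree$Nnode)
  ev <- ifelse(lab == "D", "duplication", "speciation")
  data.frame(node = nt + seq_len(tree$Nnode), event = ev)
}

#' True one-to-one ortholog pairs of simulated families
#'
#' Reads the simulator's per-node event labels (not re-inferred) and
#' extracts cross-species one-to-one ortholog pairs.
#'
#' @param families list of \code{simulated_family} objects.
#' @return data.frame \code{gene1, gene2, species1, species2}.
#' @export
true_orthologs <- function(families) {
  out <- lapply(families, function(fam) {
    rel <- extract_relations(true_events(fam$tree), fam$tree)
    o <- rel$orthologs
    o[o$type == "one-to-one",
      c("gene1", "gene2", "species1", "species2"), drop = FALSE]
  })
  do.call(rbind, out)
}

#' Simulate multi-tool orthology calls with planted error
#'
#' Every true one-to-one ortholog pair is emitted by every tool (both
#' directions), then each record is independently dropped with the tool's
#' false-negative rate; spurious cross-species calls are added with the
#' false-positive rate from the non-ortholog pair pool.
#'
#' @param families list of \code{simulated_family} objects.
#' @param tools tool names.
#' @param fn_rate scalar or per-tool named vector of miss probabilities.
#' @param fp_rate scalar spurious-call probability.
#' @param seed optional RNG seed.
#' @return orthology call data.frame (\code{query, tool, target_species,
#'   target_gene, one_to_one}).
#' @export
simulate_calls <- function(families, tools = orthology_tools(),
                           fn_rate = 0, fp_rate = 0, seed = NULL) {
  stopifnot(all(fn_rate >= 0 & fn_rate < 1), fp_rate >= 0, fp_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  if (length(fn_rate) == 1L)
    fn_rate <- setNames(rep(fn_rate, length(tools)), tools)
  to <- true_orthologs(families)
  # the false-negative unit is the ortholog pair: a missed pair is absent in
  # both directions for that tool
  rows <- lapply(tools, function(tl) {
    keep <- stats::runif(nrow(to)) >= fn_rate[[tl]]
    sub <- to[keep, , drop = FALSE]
    out <- rbind(
      data.frame(query = sub$gene1, target_species = sub$species2,
                 target_gene = sub$gene2),
      data.frame(query = sub$gene2, target_species = sub$species1,
                 target_gene = sub$gene1))
    if (nrow(out)) out$tool <- tl
    out
  })
  calls <- do.call(rbind, Filter(nrow, rows))
  if (fp_rate > 0) {
    fake <- lapply(families, function(fam) {
      sp <- tip_species(fam$tree)
      g <- fam$tree$tip.label
      if (length(g) < 2) return(NULL)
      pairs <- utils::combn(seq_along(g), 2)
      cross <- pairs[, sp[pairs[1, ]] != sp[pairs[2, ]], drop = FALSE]
      if (!ncol(cross)) return(NULL)
      key <- paste(pmin(g[cross[1, ]], g[cross[2, ]]),
                   pmax(g[cross[1, ]], g[cross[2, ]]))
      truekey <- paste(pmin(to$gene1, to$gene2), pmax(to$gene1, to$gene2))
      non <- cross[, !key %in% truekey, drop = FALSE]
      if (!ncol(non)) return(NULL)
      picks <- lapply(tools, function(tl) {
        sel <- stats::runif(ncol(non)) < fp_rate
        if (!any(sel)) return(NULL)
        idx <- non[, sel, drop = FALSE]
        data.frame(query = g[idx[1, ]],
                   target_species = unname(sp[g[idx[2, ]]]),
                   target_gene = g[idx[2, ]], tool = tl)
      })
      do.call(rbind, Filter(Negate(is.null), picks))
    })
    fake <- do.call(rbind, Filter(Negate(is.null), fake))
    if (!is.null(fake) && nrow(fake)) calls <- rbind(calls, fake)
  }
  if (is.null(calls) || !nrow(calls))
    return(data.frame(query = character(0), tool = character(0),
                      target_species = character(0),
                      target_gene = character(0),
                      one_to_one = logical(0)))
  calls$one_to_one <- TRUE
  rownames(calls) <- NULL
  calls[c("query", "tool", "target_species", "target_gene", "one_to_one")]
}

#' Simulate a developmental expression time course
#'
#' Unimodal (Gaussian-in-time, log-normal peak height) profiles over the
#' nine-point embryonic grid, with peak times drawn between 18 and 24 hours.
#' An exact number of genes — \code{round(peak_fraction * n)}, or the
#' explicit \code{planted} set — is planted with peak TPM strictly above
#' \code{threshold}; every other gene peaks below it. Planting is exact by
#' construction, not sampled.
#'
#' @param genes character vector of gene IDs.
#' @param timepoints sampling grid in hours; default \code{dev_timepoints()}.
#' @param peak_fraction fraction of genes planted above the threshold.
#' @param planted optional explicit character vector of genes to plant.
#' @param threshold TPM threshold the planted genes must exceed.
#' @param peak_window hours between which peak times are drawn.
#' @param sd_hours spread of the unimodal profile.
#' @param seed optional RNG seed.
#' @return numeric matrix genes x timepoints with attribute
#'   \code{"planted"} (the gene IDs planted above the threshold).
#' @export
simulate_expression <- function(genes, timepoints = dev_timepoints(),
                                peak_fraction = 0.1, planted = NULL,
                                threshold = 50, peak_window = c(18, 24),
                                sd_hours = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(genes)
  if (is.null(planted)) {
    stopifnot(peak_fraction >= 0, peak_fraction <= 1)
    k <- round(peak_fraction * n)
    planted <- if (k > 0) sample(genes, k) else character(0)
  }
  stopifnot(all(planted %in% genes))
  peak <- stats::setNames(stats::runif(n, 0.5, 0.9) * threshold, genes)
  peak[planted] <- threshold * (1 + stats::rlnorm(length(planted),
                                                  meanlog = -1, sdlog = 0.8))
  tpeak <- stats::runif(n, peak_window[1], peak_window[2])
  m <- matrix(0, n, length(timepoints),
              dimnames = list(genes, timepoints))
  for (i in seq_len(n)) {
    prof <- exp(-(timepoints - tpeak[i])^2 / (2 * sd_hours^2))
    m[i, ] <- prof / max(prof) * peak[i]
  }
  attr(m, "planted") <- sort(planted)
  m
}
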