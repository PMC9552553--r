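# Independent oracles and fixture builders. Each oracle re-derives its
# quantity from first principles through a different code path than the
# implementation it checks.

# gene tree from newick with species = prefix before the first underscore
make_gt <- function(nwk) {
  read_newick(nwk, "gene", species_map_regex("^([A-Za-z0-9]+)_", 1))
}

# random gene tree: random topology, leaves assigned to species randomly
random_gene_tree <- function(n_leaves, n_species, multiple = TRUE) {
  phy <- ape::rtree(n_leaves)
  sp <- sample(paste0("S", seq_len(n_species)), n_leaves,
               replace = multiple)
  phy$tip.label <- paste0(sp, "_g", seq_len(n_leaves))
  make_gt(paste0(ape::write.tree(phy)))
}

# brute-force species-overlap caller: recomputes leaf species sets from
# scratch at every node via phangorn::Descendants
oracle_species_overlap <- function(tree, overlap_cutoff = 0) {
  nt <- ape::Ntip(tree)
  spv <- tip_species(tree)
  events <- character(tree$Nnode)
  for (i in seq_len(tree$Nnode)) {
    v <- nt + i
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    sets <- lapply(kids, function(k) {
      tips <- unlist(phangorn::Descendants(tree, k, "tips"))
      unique(unname(spv[tree$tip.label[tips]]))
    })
    dup <- FALSE
    for (a in seq_along(sets)) for (b in seq_along(sets)) {
      if (a < b) {
        ov <- length(intersect(sets[[a]], sets[[b]]))
        sc <- ov / length(union(sets[[a]], sets[[b]]))
        if (sc > overlap_cutoff) dup <- TRUE
      }
    }
    events[i] <- if (dup) "duplication" else "speciation"
  }
  data.frame(node = nt + seq_len(tree$Nnode), event = events)
}

# exact hypergeometric upper tail by explicit summation of the mass function
oracle_hyper_upper <- function(k, K, N, n) {
  total <- 0
  for (i in k:min(K, n)) {
    total <- total +
      choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }
  total
}

# minimum Dollo loss count by exhaustive enumeration of loss-node subsets
oracle_dollo_min_losses <- function(present, sp_tree) {
  nt <- ape::Ntip(sp_tree)
  gain <- if (length(present) == 1) match(present, sp_tree$tip.label) else
    ape::getMRCA(sp_tree, present)
  below <- setdiff(unlist(phangorn::Descendants(sp_tree, gain, "all")),
                   gain)
  if (gain <= nt) below <- integer(0)
  tips_under <- function(v)
    sp_tree$tip.label[unlist(phangorn::Descendants(sp_tree, v, "tips"))]
  gain_tips <- tips_under(gain)
  absent <- setdiff(gain_tips, present)
  best <- Inf
  for (mask in 0:(2^length(below) - 1)) {
    sel <- below[bitwAnd(mask, 2^(seq_along(below) - 1)) > 0]
    covered <- unique(unlist(lapply(sel, tips_under)))
    if (setequal(covered, absent)) best <- min(best, length(sel))
  }
  if (!length(absent)) best <- 0
  best
}

# expected copies entering each branch (child node indexed) with mu = 0
expected_dups_mu0 <- function(sp_tree, lambda) {
  nt <- ape::Ntip(sp_tree)
  enter <- numeric(nt + sp_tree$Nnode)
  walk <- function(v, e_in) {
    for (ch in sp_tree$edge[sp_tree$edge[, 1] == v, 2]) {
      enter[ch] <<- e_in
      walk(ch, e_in * (1 + lambda))
    }
  }
  walk(ape::Ntip(sp_tree) + 1L, 1)
  sum(enter) * lambda
}

# small synthetic study used by replicated cascade properties
small_study <- function(seed, fn_rate = 0, fp_rate = 0) {
  simulate_study(n_candidates = 40, n_outgroup_hit = 10, n_annotated = 15,
                 n_extra_isoforms = 3, n_expressed = 5, n_rbbh = 3,
                 n_tree = 3, n_interpro = 1,
                 fn_rate = fn_rate, fp_rate = fp_rate, seed = seed)
}

# hit table fixture builder
mk_hits <- function(q, s, evalue, bitscore = 100, qstart = 1, qend = 100,
                    qlen = NULL) {
  n <- max(length(q), length(s), length(evalue))
  df <- data.frame(qseqid = rep_len(q, n), sseqid = rep_len(s, n),
                   pident = 90, length = 100, mismatch = 5, gapopen = 0,
                   qstart = rep_len(qstart, n), qend = rep_len(qend, n),
                   sstart = 1, send = 100,
                   evalue = rep_len(evalue, n),
                   bitscore = rep_len(bitscore, n))
  hit_table(df, qlen)
}
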