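test_that("species-overlap calls match hand-worked cases", {
  sp_regex <- function(nwk) make_gt(nwk)

  t1 <- sp_regex("((A_g1,B_g1),C_g1);")
  ev1 <- annotate_events(t1)
  expect_equal(sum(ev1$event == "duplication"), 0)
  expect_equal(sum(ev1$event == "speciation"), 2)

  t2 <- sp_regex("((A_g1,A_g2),B_g1);")
  ev2 <- annotate_events(t2)
  expect_equal(sum(ev2$event == "duplication"), 1)
  dup <- ev2[ev2$event == "duplication", ]
  expect_identical(dup$overlap[[1]], "A")

  t3 <- sp_regex("((A_g1,B_g1),(A_g2,B_g2));")
  ev3 <- annotate_events(t3)
  root_row <- ev3[ev3$node == ape::Ntip(t3) + 1L, ]
  expect_equal(root_row$event, "duplication")
  expect_equal(root_row$score, 1.0)
  expect_equal(sum(ev3$event == "speciation"), 2)
})

test_that("species-overlap agrees with a brute-force oracle on random trees", {
  set.seed(202)
  for (i in 1:150) {
    gt <- random_gene_tree(sample(3:12, 1), sample(2:5, 1))
    cutoff <- sample(c(0, 0.2, 0.5), 1)
    got <- annotate_events(gt, cutoff)
    want <- oracle_species_overlap(gt, cutoff)
    expect_identical(got$event[order(got$node)],
                     want$event[order(want$node)])
  }
})

test_that("raising the overlap cutoff never adds duplication calls", {
  set.seed(11)
  for (i in 1:40) {
    gt <- random_gene_tree(sample(4:12, 1), sample(2:4, 1))
    counts <- vapply(c(0, 0.1, 0.3, 0.5, 0.8), function(co)
      sum(annotate_events(gt, co)$event == "duplication"), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("duplications map to the species-tree MRCA of their daughters", {
  sp <- read_newick("((A,B),C);", "species")
  m1 <- map_duplications(annotate_events(make_gt("((A_g1,A_g2),B_g1);")),
                         make_gt("((A_g1,A_g2),B_g1);"), sp)
  expect_equal(m1$count[m1$label == "A"], 1)
  expect_equal(sum(m1$count), 1)

  gt <- make_gt("((A_g1,B_g1),(A_g2,B_g2));")
  m2 <- map_duplications(annotate_events(gt), gt, sp)
  ab <- ape::getMRCA(sp, c("A", "B"))
  expect_equal(m2$count[m2$node == ab], 1)
  expect_equal(sum(m2$count), 1)

  gt0 <- make_gt("((A_g1,B_g1),C_g1);")
  expect_equal(sum(map_duplications(annotate_events(gt0), gt0, sp)$count), 0)

  bad <- make_gt("(A_g1,Z_g1);")
  expect_error(map_duplications(annotate_events(bad), bad, sp), "Z")
})

test_that("duplication counts are conserved when aggregated per node", {
  set.seed(37)
  for (i in 1:200) {
    spt <- simulate_species_tree(sample(4:7, 1))
    fam <- simulate_family(spt, lambda = 0.3, mu = 0.15)
    ev <- annotate_events(fam$tree)
    mapped <- map_duplications(ev, fam$tree, spt)
    expect_equal(sum(mapped$count), sum(ev$event == "duplication"))
  }
})

test_that("duplication ratios follow count / trees-containing", {
  sp <- read_newick("((A,B),C);", "species")
  # 10 congruent single-copy trees: every defined ratio is 0
  trees <- replicate(10, make_gt("((A_g1,B_g1),C_g1);"), simplify = FALSE)
  r0 <- duplication_ratios(trees, sp)
  expect_true(all(r0$ratio[!is.na(r0$ratio)] == 0))

  # 2 trees spanning (A,B); one duplicated there: ratio 1/2
  trees2 <- list(make_gt("((A_g1,B_g1),(A_g2,B_g2));"),
                 make_gt("(A_g1,B_g1);"))
  r2 <- duplication_ratios(trees2, sp)
  ab <- ape::getMRCA(sp, c("A", "B"))
  expect_equal(r2$ratio[r2$node == ab], 0.5)
  # nodes contained by no tree are undefined, not zero
  expect_true(is.na(r2$ratio[r2$label == "C"]))

  # three trees, each one duplication at (A,B): one duplication per gene
  trees3 <- replicate(3, make_gt("((A_g1,B_g1),(A_g2,B_g2));"),
                      simplify = FALSE)
  r3 <- duplication_ratios(trees3, sp)
  expect_equal(r3$ratio[r3$node == ab], 1.0)
})

test_that("the expansion cap bounds any single tree's contribution", {
  sp <- read_newick("(A,B);", "species")
  big <- make_gt("(((A_g1,A_g2),(A_g3,A_g4)),B_g1);")
  r_uncapped <- duplication_ratios(list(big), sp)
  r_capped <- duplication_ratios(list(big), sp, expansion_cap = 1)
  expect_equal(sum(r_uncapped$count), 3)
  expect_equal(r_capped$count[r_capped$label == "A"], 1)
})

test_that("ortholog/paralog relations follow the event at the pair MRCA", {
  t1 <- make_gt("((A_g1,B_g1),C_g1);")
  rel1 <- extract_relations(annotate_events(t1), t1)
  ab <- rel1$orthologs[rel1$orthologs$gene1 == "A_g1" &
                         rel1$orthologs$gene2 == "B_g1", ]
  expect_equal(ab$type, "one-to-one")
  expect_equal(nrow(rel1$paralogs), 0)

  t2 <- make_gt("((A_g1,A_g2),B_g1);")
  rel2 <- extract_relations(annotate_events(t2), t2)
  expect_true(nrow(rel2$paralogs) == 1)
  expect_setequal(unlist(rel2$paralogs[1, c("gene1", "gene2")]),
                  c("A_g1", "A_g2"))
  expect_setequal(rel2$orthologs$type,
                  "many-to-one")
  expect_equal(nrow(rel2$orthologs), 2)

  t3 <- make_gt("(A_g1,A_g2);")
  rel3 <- extract_relations(annotate_events(t3), t3)
  expect_equal(nrow(rel3$orthologs), 0)
})

test_that("Dollo gain/loss places gains at MRCAs and losses minimally", {
  sp <- read_newick("((A,B),(C,D));", "species")
  all4 <- matrix(TRUE, 1, 4, dimnames = list("og", c("A", "B", "C", "D")))
  gl <- infer_gain_loss(all4, sp)
  expect_equal(gl$per_family$gain_node, ape::Ntip(sp) + 1L)
  expect_equal(gl$per_family$n_losses, 0)

  abc <- matrix(c(TRUE, TRUE, TRUE, FALSE), 1,
                dimnames = list("og", c("A", "B", "C", "D")))
  gl2 <- infer_gain_loss(abc, sp)
  expect_equal(gl2$per_family$n_losses, 1)
  expect_equal(sp$tip.label[gl2$per_family$loss_nodes[[1]]], "D")

  ac <- matrix(c(TRUE, FALSE, TRUE, FALSE), 1,
               dimnames = list("og", c("A", "B", "C", "D")))
  gl3 <- infer_gain_loss(ac, sp)
  expect_equal(gl3$per_family$n_losses, 2)
  expect_setequal(sp$tip.label[gl3$per_family$loss_nodes[[1]]], c("B", "D"))

  empty <- matrix(FALSE, 1, 4, dimnames = list("og9", c("A", "B", "C", "D")))
  expect_error(infer_gain_loss(empty, sp), "og9")
})

test_that("inferred loss count equals the exhaustive Dollo minimum", {
  set.seed(93)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    spt <- simulate_species_tree(n)
    k <- sample(1:n, 1)
    present <- sample(spt$tip.label, k)
    pres <- matrix(spt$tip.label %in% present, 1,
                   dimnames = list("og", spt$tip.label))
    gl <- infer_gain_loss(pres, spt)
    expect_equal(gl$per_family$n_losses,
                 oracle_dollo_min_losses(present, spt))
  }
})

test_that("min-duplications rooting attains the exhaustive-edge minimum", {
  u <- make_gt("((A_g1,B_g1),(A_g2,C_g1));")
  rooted <- root_gene_tree(u, "min-duplications")
  dups <- sum(annotate_events(rooted)$event == "duplication")
  # oracle: enumerate every edge rooting
  all_d <- vapply(phylotrg:::all_rootings(u), function(r)
    sum(annotate_events(r)$event == "duplication"), numeric(1))
  expect_equal(dups, min(all_d))
  expect_equal(min(all_d), 1)

  set.seed(5)
  for (i in 1:20) {
    gt <- random_gene_tree(sample(4:10, 1), sample(2:4, 1))
    r <- root_gene_tree(gt, "min-duplications")
    d <- sum(annotate_events(r)$event == "duplication")
    o <- min(vapply(phylotrg:::all_rootings(gt), function(x)
      sum(annotate_events(x)$event == "duplication"), numeric(1)))
    expect_equal(d, o)
  }
})

test_that("congruent single-copy trees stay duplication-free under rooting", {
  set.seed(17)
  for (i in 1:20) {
    spt <- simulate_species_tree(sample(4:8, 1))
    fam <- simulate_family(spt, 0, 0)
    r <- root_gene_tree(fam$tree, "min-duplications")
    expect_equal(sum(annotate_events(r)$event == "duplication"), 0)
  }
})

test_that("two-leaf trees admit only one rooting under every strategy", {
  t2 <- make_gt("(A_g1,B_g1);")
  for (s in c("min-duplications", "midpoint", "seed-farthest")) {
    r <- root_gene_tree(t2, s)
    expect_true(ape::is.rooted(r))
    expect_setequal(r$tip.label, c("A_g1", "B_g1"))
  }
})

test_that("seed-farthest rooting needs a declared seed sequence", {
  t3 <- ape::read.tree(text = "((A_g1,B_g1),C_g1);")
  gt <- gene_tree(t3, map_species(t3$tip.label,
                                  species_map_regex("^([A-Z]+)_", 1)))
  expect_error(root_gene_tree(gt, "seed-farthest"), "seed")
  gt_seeded <- gene_tree(t3, map_species(t3$tip.label,
                                         species_map_regex("^([A-Z]+)_", 1)),
                         seed_id = "A_g1")
  r <- root_gene_tree(gt_seeded, "seed-farthest")
  expect_true(ape::is.rooted(r))
})
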