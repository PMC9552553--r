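test_that("hit filtering enforces e-value, contiguous coverage, and the cap", {
  qlen <- c(q1 = 100)
  pass <- mk_hits("q1", "s1", 1e-6, qstart = 21, qend = 80, qlen = qlen)
  expect_equal(nrow(filter_hits(pass)), 1)  # 60/100 coverage, 1e-6

  bad_e <- mk_hits("q1", "s1", 1e-4, qstart = 1, qend = 100, qlen = qlen)
  expect_equal(nrow(filter_hits(bad_e)), 0)

  bad_cov <- mk_hits("q1", "s1", 1e-6, qstart = 1, qend = 40, qlen = qlen)
  expect_equal(nrow(filter_hits(bad_cov)), 0)

  # the threshold is strict: exactly 1e-5 is rejected
  at_e <- mk_hits("q1", "s1", 1e-5, qstart = 1, qend = 100, qlen = qlen)
  expect_equal(nrow(filter_hits(at_e)), 0)

  # 200 passing hits -> the 150 smallest e-values survive
  many <- mk_hits("q1", sprintf("s%03d", 1:200),
                  evalue = 1e-20 * (1:200), qlen = qlen)
  kept <- filter_hits(many)
  expect_equal(nrow(kept), 150)
  expect_setequal(kept$sseqid, sprintf("s%03d", 1:150))

  expect_error(filter_hits(mk_hits("qX", "s1", 1e-9, qlen = qlen)), "qX")
})

test_that("consensus requires every tool for every ingroup species", {
  tools <- c("inparanoid", "proteinortho", "swiftortho", "fastortho",
             "orthofinder")
  full <- expand.grid(query = c("g1", "g2"), tool = tools,
                      target_species = c("ACAPL", "ANNJA"),
                      stringsAsFactors = FALSE)
  full$target_gene <- paste0(full$target_species, "_x")
  full$one_to_one <- TRUE
  # g2 misses one tool for one species
  drop <- !(full$query == "g2" & full$tool == "fastortho" &
              full$target_species == "ANNJA")
  calls <- full[drop, ]
  got <- consensus_echinoderm(calls, c("ACAPL", "ANNJA"), tools)
  expect_identical(got, "g1")
  expect_identical(consensus_echinoderm(calls[0, ], c("ACAPL", "ANNJA"),
                                        tools), character(0))
  # per-pair registry: dropping the missing tool requirement readmits g2
  reg <- list(ACAPL = tools, ANNJA = setdiff(tools, "fastortho"))
  expect_setequal(consensus_echinoderm(calls, c("ACAPL", "ANNJA"), reg),
                  c("g1", "g2"))
})

test_that("any outgroup call from any tool disqualifies a candidate", {
  calls <- data.frame(query = c("g1", "g2"),
                      tool = c("oma", "inparanoid"),
                      target_species = c("MUSMU", "ACAPL"),
                      target_gene = c("m1", "a1"),
                      one_to_one = c(FALSE, TRUE))
  out <- exclude_outgroup_homologs(c("g1", "g2"), calls,
                                   outgroup = c("HUMAN", "MUSMU"))
  expect_identical(out, "g2")
})

test_that("annotation and TE filters retain only uncharacterized genes", {
  ann <- data.frame(gene = c("g1", "g2", "g3"),
                    isoform = c("g1", "g2", "g3"), length = 100,
                    domains = I(list(character(0), character(0),
                                     "PF03221")),
                    go_terms = I(list("GO:0005515", character(0),
                                      character(0))))
  te <- "PF03221"
  got <- unannotated_only(c("g1", "g2", "g3", "g4"), ann, te)
  expect_setequal(got, c("g2", "g4"))  # g4 absent from table = unannotated
})

test_that("longest-isoform selection is maximal with deterministic ties", {
  iso <- data.frame(gene = c("g1", "g1", "g2", "g3", "g3"),
                    isoform = c("g1.a", "g1.b", "g2.a", "g3.b", "g3.a"),
                    length = c(100, 250, 70, 200, 200))
  out <- longest_isoform(c("g1", "g2", "g3"), iso)
  expect_equal(out$isoform[out$gene == "g1"], "g1.b")
  expect_equal(out$isoform[out$gene == "g2"], "g2.a")
  # equal lengths: lexicographically first isoform ID wins
  expect_equal(out$isoform[out$gene == "g3"], "g3.a")
  expect_error(longest_isoform("gX", iso), "gX")
})

test_that("expression filter applies a strict threshold", {
  expr <- rbind(a = c(0, 51, 3), b = c(0, 50, 3), c = c(0, 0, 0))
  colnames(expr) <- c(0, 24, 72)
  expect_identical(expression_filter(c("a", "b", "c"), expr), "a")
  expect_identical(expression_filter("zz", expr), character(0))
  bad <- expr; bad[1, 1] <- -1
  expect_error(expression_filter("a", bad), "negative")
})

test_that("reciprocal best hits require mutual unique bests", {
  ab <- mk_hits(c("a1", "a2"), c("b1", "b2"), c(1e-30, 1e-25))
  ba <- mk_hits(c("b1", "b2"), c("a1", "a2"), c(1e-30, 1e-25))
  pairs <- reciprocal_best_hits(ab, ba)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$b[pairs$a == "a1"], "b1")

  # a -> b best, but b -> c best: no pair for a
  ab2 <- mk_hits("a1", "b1", 1e-30)
  ba2 <- mk_hits("b1", "c9", 1e-40)
  expect_equal(nrow(reciprocal_best_hits(ab2, ba2)), 0)

  # unresolved tie (same e-value and bit score) -> ambiguity, no pair
  ab3 <- mk_hits(c("a1", "a1"), c("b1", "b2"), 1e-30, bitscore = 100)
  ba3 <- mk_hits("b1", "a1", 1e-30)
  expect_equal(nrow(reciprocal_best_hits(ab3, ba3)), 0)

  # a bit-score difference resolves the e-value tie
  ab4 <- mk_hits(c("a1", "a1"), c("b1", "b2"), 1e-30,
                 bitscore = c(200, 100))
  expect_equal(reciprocal_best_hits(ab4, ba3)$b, "b1")

  # the e-value gate is strict and applied to both tables
  weak <- mk_hits("a1", "b1", 1e-6)
  expect_equal(nrow(reciprocal_best_hits(weak, ba3, max_evalue = 1e-7)), 0)
})

test_that("RBBH pairs are symmetric under table exchange", {
  set.seed(14)
  for (i in 1:20) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    ab <- mk_hits(sample(paste0("a", 1:na), 20, TRUE),
                  sample(paste0("b", 1:nb), 20, TRUE),
                  10^-sample(8:40, 20, TRUE),
                  bitscore = sample(50:300, 20, TRUE))
    ba <- mk_hits(sample(paste0("b", 1:nb), 20, TRUE),
                  sample(paste0("a", 1:na), 20, TRUE),
                  10^-sample(8:40, 20, TRUE),
                  bitscore = sample(50:300, 20, TRUE))
    fwd <- reciprocal_best_hits(ab, ba)
    rev <- reciprocal_best_hits(ba, ab)
    expect_setequal(paste(fwd$a, fwd$b), paste(rev$b, rev$a))
  }
})

test_that("evidence report counts the packaged gene set correctly", {
  rep <- table2_report()
  expect_equal(unname(rep$summary["total"]), 14)
  expect_equal(unname(rep$summary["with_rbbh"]), 7)
  expect_equal(unname(rep$summary["ontology_absent"]), 11)
  expect_equal(unname(rep$summary["with_tree"]), 8)
  expect_equal(unname(rep$summary["without_tree"]), 6)
  expect_equal(unname(rep$summary["no_evidence"]), 1)
  ev <- rep$evidence
  zero <- ev$gene[is.na(ev$rbbh) & lengths(ev$ontology) == 0 & !ev$has_tree]
  expect_identical(zero, "LOC578009")
  expect_equal(ev$rbbh[ev$gene == "LOC577313"], "F6REZ6_CIOIN")
  expect_true(ev$has_tree[ev$gene == "LOC577313"])
})

test_that("evidence report handles empty sets and proteome priority", {
  empty <- evidence_report(character(0))
  expect_true(all(empty$summary == 0))

  rb <- list(NEMVE = data.frame(a = "g1", b = "nv1"),
             BRAFL = data.frame(a = "g1", b = "bf1"))
  rep <- evidence_report("g1", rbbh = rb)
  expect_equal(rep$evidence$rbbh, "nv1")  # first proteome in priority order
  expect_setequal(rep$evidence$rbbh_all[[1]], c("nv1", "bf1"))
})

test_that("the cascade recovers the planted gene set at zero tool error", {
  st <- simulate_study(seed = 77)
  res <- run_study(st)
  expect_identical(res$genes, st$planted_trg)
  expect_equal(res$trace$n_out[res$trace$stage == "outgroup_exclusion"], 145)
  expect_equal(res$trace$n_out[res$trace$stage == "longest_isoform"], 31)
  expect_equal(res$trace$n_out[res$trace$stage == "expression"], 14)
  # the trace chains: output of stage i is input of stage i+1, never growing
  expect_equal(res$trace$n_in[-1], res$trace$n_out[-nrow(res$trace)])
  expect_true(all(res$trace$n_out <= res$trace$n_in))
  expect_equal(unname(res$report$summary["total"]), 14)
  expect_equal(unname(res$report$summary["with_rbbh"]), 7)
  expect_equal(unname(res$report$summary["with_tree"]), 8)
  expect_equal(unname(res$report$summary["ontology_absent"]), 11)
})

test_that("degenerate thresholds reduce the cascade to consensus minus annotation", {
  st <- simulate_study(seed = 12, n_outgroup_hit = 0, n_extra_isoforms = 0)
  res <- run_cascade(st$calls, st$ingroup, st$outgroup,
                     annotations = st$annotations, isoforms = st$isoforms,
                     expr = st$expr, tools = st$tools, min_peak = 0)
  consensus <- consensus_echinoderm(st$calls, st$ingroup, st$tools)
  annotated <- st$annotations$gene[lengths(st$annotations$go_terms) > 0]
  expect_setequal(res$genes, setdiff(consensus, annotated))
})

test_that("planted recovery is exact without error and degrades with it", {
  rates <- c(0, 0.05, 0.1)
  recalls <- sapply(seq_along(rates), function(ri) {
    mean(vapply(1:33, function(rep) {
      st <- small_study(seed = 1000 * ri + rep, fn_rate = rates[ri])
      res <- run_study(st)
      if (rates[ri] == 0) {
        # precision and recall are both exactly 1 at zero error
        expect_identical(res$genes, st$planted_trg)
      }
      length(intersect(res$genes, st$planted_trg)) /
        length(st$planted_trg)
    }, numeric(1)))
  })
  expect_equal(recalls[1], 1)
  expect_true(all(diff(recalls) <= 0))
  expect_lt(recalls[3], 1)
})

test_that("unannotated-only and longest-isoform stages commute", {
  set.seed(40)
  for (i in 1:10) {
    genes <- paste0("g", 1:12)
    # per-gene-consistent annotations over isoform pairs
    iso <- data.frame(gene = rep(paste0("L", 1:6), each = 2),
                      isoform = genes,
                      length = sample(100:300, 12))
    annotated_loci <- sample(paste0("L", 1:6), 3)
    ann <- data.frame(
      gene = genes, isoform = genes, length = 100,
      domains = I(rep(list(character(0)), 12)),
      go_terms = I(lapply(iso$gene, function(l)
        if (l %in% annotated_loci) "GO:0000001" else character(0))))
    path_a <- unannotated_only(genes, ann)
    sub_a <- iso[iso$isoform %in% path_a, ]
    keep_a <- sort(c(setdiff(path_a, iso$isoform),
                     longest_isoform(unique(sub_a$gene), sub_a)$isoform))
    keep_b0 <- longest_isoform(unique(iso$gene), iso)$isoform
    keep_b <- sort(unannotated_only(keep_b0, ann))
    expect_identical(keep_a, keep_b)
  }
})
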