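# End-to-end synthetic study generator: a full input bundle for the TRG
# cascade with a planted ground-truth gene set.

#' Simulate a complete TRG-discovery study
#'
#' Builds every input the filtering cascade consumes, with a known planted
#' answer. A pool of focal-species candidate genes receives one-to-one calls
#' to both ingroup species from every required tool; planted subsets then
#' receive disqualifying evidence: outgroup homolog calls, GO annotations,
#' shorter-isoform partners, and sub-threshold expression. Under zero tool
#' error the cascade recovers exactly the planted TRG set. The default
#' layer sizes mirror the published echinoderm screen: 200 consensus
#' candidates, 145 surviving outgroup exclusion, 31 surviving the
#' annotation and isoform stages, and 14 passing the expression filter.
#'
#' @param n_candidates genes with full ingroup consensus calls.
#' @param n_outgroup_hit of those, genes planted with an outgroup call.
#' @param n_annotated of the survivors, genes planted with GO terms.
#' @param n_extra_isoforms survivors that are shorter isoforms of another
#'   surviving gene (removed at the isoform stage).
#' @param n_expressed survivors planted with peak TPM above
#'   \code{min_peak}; this is the planted TRG set.
#' @param ingroup,outgroup target species sets.
#' @param tools required tools for the ingroup consensus (default: the tool
#'   registry minus OMA, which never ran on the echinoderm pairs).
#' @param fn_rate,fp_rate per-record tool error rates applied to the
#'   consensus calls.
#' @param n_rbbh,n_tree planted counts of RBBH partners and phylome trees
#'   among the planted TRG set.
#' @param n_interpro planted TRGs carrying report-level (InterProScan-style)
#'   ontology terms; these never affect the filter, only the final report,
#'   mirroring the distinct annotation sources of the two stages.
#' @param min_peak strict TPM threshold.
#' @param seed RNG seed.
#' @return list of class \code{synthetic_study} with components
#'   \code{calls, annotations, isoforms, expr, rbbh, tree_registry,
#'   ingroup, outgroup, tools, min_peak, planted_trg}.
#' @export
simulate_study <- function(n_candidates = 200, n_outgroup_hit = 55,
                           n_annotated = 104, n_extra_isoforms = 10,
                           n_expressed = 14,
                           ingroup = c("ACAPL", "ANNJA"),
                           outgroup = c("HUMAN", "MUSMU", "RATNO", "DANRE",
                                        "XENTR", "DROME", "CAEEL", "ARATH",
                                        "YEAST", "SCHPO"),
                           tools = setdiff(orthology_tools(), "oma"),
                           fn_rate = 0, fp_rate = 0,
                           n_rbbh = 7, n_tree = 8, n_interpro = 3,
                           min_peak = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_surv <- n_candidates - n_outgroup_hit
  n_unann <- n_surv - n_annotated
  n_final_pool <- n_unann - n_extra_isoforms
  stopifnot(n_outgroup_hit <= n_candidates, n_annotated <= n_surv,
            2 * n_extra_isoforms <= n_unann, n_expressed <= n_final_pool,
            n_rbbh <= n_expressed, n_tree <= n_expressed)
  genes <- sprintf("SPU_%06d", seq_len(n_candidates))
  # consensus calls to every ingroup species from every required tool
  grid <- expand.grid(query = genes, tool = unlist(tools),
                      target_species = ingroup,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$target_gene <- paste0(grid$target_species, "_", grid$query)
  grid$one_to_one <- TRUE
  if (fn_rate > 0)
    grid <- grid[stats::runif(nrow(grid)) >= fn_rate, , drop = FALSE]
  # planted outgroup homology evidence
  out_hit <- sample(genes, n_outgroup_hit)
  og <- data.frame(query = character(0), tool = character(0),
                   target_species = character(0),
                   target_gene = character(0), one_to_one = logical(0))
  if (n_outgroup_hit > 0) {
    og <- data.frame(
      query = out_hit,
      tool = sample(unlist(tools), n_outgroup_hit, replace = TRUE),
      target_species = sample(outgroup, n_outgroup_hit, replace = TRUE),
      stringsAsFactors = FALSE)
    og$target_gene <- paste0(og$target_species, "_", og$query)
    og$one_to_one <- FALSE
  }
  if (fp_rate > 0) {
    extra <- genes[stats::runif(n_candidates) < fp_rate]
    if (length(extra)) {
      fe <- data.frame(
        query = extra,
        tool = sample(unlist(tools), length(extra), replace = TRUE),
        target_species = sample(outgroup, length(extra), replace = TRUE),
        stringsAsFactors = FALSE)
      fe$target_gene <- paste0(fe$target_species, "_", fe$query)
      fe$one_to_one <- FALSE
      og <- rbind(og, fe)
    }
  }
  calls <- rbind(grid, og)[c("query", "tool", "target_species",
                             "target_gene", "one_to_one")]
  survivors <- setdiff(genes, out_hit)
  annotated <- sample(survivors, n_annotated)
  unann <- setdiff(survivors, annotated)
  # isoform structure: pair each extra (shorter) isoform with a keeper
  keepers <- sample(unann, n_extra_isoforms)
  shorter <- sample(setdiff(unann, keepers), n_extra_isoforms)
  iso_rows <- list()
  for (i in seq_len(n_extra_isoforms)) {
    gid <- paste0("locus_", keepers[i])
    iso_rows[[length(iso_rows) + 1L]] <-
      data.frame(gene = gid, isoform = keepers[i], length = 300)
    iso_rows[[length(iso_rows) + 1L]] <-
      data.frame(gene = gid, isoform = shorter[i], length = 180)
  }
  isoforms <- if (length(iso_rows)) do.call(rbind, iso_rows) else
    data.frame(gene = character(0), isoform = character(0),
               length = numeric(0))
  final_pool <- setdiff(unann, shorter)
  trg <- sort(sample(final_pool, n_expressed))
  annotations <- data.frame(
    gene = c(annotated, trg),
    isoform = c(annotated, trg),
    length = 300,
    domains = I(c(rep(list(character(0)), length(annotated)),
                  rep(list(character(0)), length(trg)))),
    go_terms = I(c(lapply(seq_along(annotated), function(i)
                     sprintf("GO:%07d", sample.int(9999999, 1))),
                   rep(list(character(0)), length(trg)))))
  expr <- simulate_expression(genes, planted = trg, threshold = min_peak)
  with_rbbh <- if (n_rbbh > 0) sample(trg, n_rbbh) else character(0)
  proteomes <- c("NEMVE", "BRAFL", "CIOIN")
  rbbh <- setNames(lapply(proteomes, function(p)
    data.frame(a = character(0), b = character(0))), proteomes)
  for (g in with_rbbh) {
    p <- sample(proteomes, 1)
    rbbh[[p]] <- rbind(rbbh[[p]],
                       data.frame(a = g, b = paste0(p, "_", g)))
  }
  with_tree <- if (n_tree > 0) sample(trg, n_tree) else character(0)
  tree_registry <- setNames(genes %in% with_tree, genes)
  stopifnot(n_interpro <= n_expressed)
  with_ipr <- if (n_interpro > 0) sample(trg, n_interpro) else character(0)
  report_annotations <- data.frame(
    gene = with_ipr,
    go_terms = I(lapply(seq_along(with_ipr), function(i)
      sprintf("GO:%07d", sample.int(9999999, 1)))))
  structure(list(calls = calls, annotations = annotations,
                 isoforms = isoforms, expr = expr, rbbh = rbbh,
                 tree_registry = tree_registry,
                 report_annotations = report_annotations,
                 ingroup = ingroup, outgroup = outgroup, tools = tools,
                 min_peak = min_peak, planted_trg = trg),
            class = "synthetic_study")
}

#' Run the cascade on a synthetic study
#'
#' Convenience wrapper passing a \code{\link{simulate_study}} bundle through
#' \code{\link{run_cascade}} with its own species sets and thresholds.
#'
#' @param study a \code{synthetic_study}.
#' @return a \code{trg_cascade}.
#' @export
run_study <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  run_cascade(study$calls, study$ingroup, study$outgroup,
              annotations = study$annotations, isoforms = study$isoforms,
              expr = study$expr, rbbh = study$rbbh,
              tree_registry = study$tree_registry, tools = study$tools,
              min_peak = study$min_peak,
              report_annotations = study$report_annotations)
}
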