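# The taxonomically-restricted-gene filtering cascade: similarity-hit
# filtering, multi-tool consensus orthology, outgroup exclusion, annotation /
# isoform / expression filters, reciprocal-best-hit classification, and the
# per-gene evidence report.

#' Filter similarity-search hits by e-value, coverage and hit cap
#'
#' Retains hits with e-value strictly below \code{max_evalue} whose single
#' contiguous aligned query segment covers at least \code{min_coverage} of
#' the query length, then keeps at most \code{max_hits} closest hits per
#' query (smallest e-value; ties by descending bit score, then subject ID).
#' Defaults are the phylome homolog-search thresholds (1e-5, 50%, 150).
#'
#' @param hits hit table (see \code{\link{read_hit_table}}) whose
#'   \code{query_lengths} attribute (or the \code{query_lengths} argument)
#'   covers every query.
#' @param max_evalue strict upper bound on e-value.
#' @param min_coverage minimum fraction of the query covered by the hit.
#' @param max_hits per-query cap on retained hits.
#' @param query_lengths optional named numeric vector overriding the
#'   attribute.
#' @return the filtered hit table (row order: by query, then closeness).
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, min_coverage = 0.5,
                        max_hits = 150L, query_lengths = NULL) {
  if (is.null(query_lengths)) query_lengths <- attr(hits, "query_lengths")
  if (is.null(query_lengths))
    stop("query lengths must be registered to filter on coverage")
  if (!nrow(hits)) return(hits)
  unreg <- setdiff(unique(hits$qseqid), names(query_lengths))
  if (length(unreg))
    stop("no registered length for query: ", paste(unreg, collapse = ", "))
  qlen <- query_lengths[hits$qseqid]
  cov <- (hits$qend - hits$qstart + 1) / qlen
  keep <- hits$evalue < max_evalue & cov >= min_coverage
  out <- hits[keep, , drop = FALSE]
  ord <- order(out$qseqid, out$evalue, -out$bitscore, out$sseqid)
  out <- out[ord, , drop = FALSE]
  ranks <- stats::ave(seq_len(nrow(out)), out$qseqid, FUN = seq_along)
  out <- out[ranks <= max_hits, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "query_lengths") <- query_lengths
  out
}

#' Consensus orthology across the ingroup
#'
#' A query gene passes when, for every ingroup species, every tool required
#' for that species reports a one-to-one ortholog. The per-species tool
#' registry accommodates tools that never ran on a given pair (e.g. OMA
#' absent for two of the echinoderm comparisons): supply \code{tools} as a
#' named list, species -> required tool names, or a single character vector
#' applied to all species.
#'
#' @param calls orthology call data.frame (\code{query, tool,
#'   target_species, target_gene, one_to_one}).
#' @param ingroup character vector of ingroup target species.
#' @param tools required tools: character vector or named list per species.
#' @return sorted character vector of passing query genes.
#' @export
consensus_echinoderm <- function(calls, ingroup, tools = orthology_tools()) {
  stopifnot(length(ingroup) >= 1)
  if (!is.list(tools)) tools <- setNames(rep(list(tools), length(ingroup)),
                                         ingroup)
  if (length(unlist(tools)) == 0) stop("required tool set must be non-empty")
  if (!nrow(calls)) return(character(0))
  ok <- calls[calls$one_to_one & calls$target_species %in% ingroup, ,
              drop = FALSE]
  cand <- unique(ok$query)
  pass <- vapply(cand, function(g) {
    sub <- ok[ok$query == g, ]
    all(vapply(ingroup, function(s) {
      req <- tools[[s]]
      length(req) > 0 &&
        all(req %in% sub$tool[sub$target_species == s])
    }, logical(1)))
  }, logical(1))
  sort(cand[pass])
}

#' Exclude candidates with any outgroup homology evidence
#'
#' Any call, by any tool, to any outgroup species disqualifies a candidate
#' (one-to-one or not): homology evidence outside the ingroup means the gene
#' is not taxonomically restricted.
#'
#' @param candidates character vector of candidate genes.
#' @param calls orthology call data.frame.
#' @param outgroup character vector of non-ingroup species.
#' @return the surviving gene set (sorted).
#' @export
exclude_outgroup_homologs <- function(candidates, calls, outgroup) {
  if (!length(candidates)) return(character(0))
  hit <- unique(calls$query[calls$target_species %in% outgroup])
  sort(setdiff(candidates, hit))
}

#' Keep only unannotated genes
#'
#' Retains genes whose ontology term set is empty and that carry no
#' transposable-element domain. Genes absent from the annotation table count
#' as unannotated.
#'
#' @param genes character vector of genes.
#' @param annotations annotation data.frame (\code{gene}, list columns
#'   \code{domains}, \code{go_terms}); see \code{\link{read_table}}.
#' @param te_domains character vector of transposable-element domain IDs.
#' @return the surviving gene set (sorted).
#' @export
unannotated_only <- function(genes, annotations, te_domains = character(0)) {
  if (!length(genes)) return(character(0))
  ann_genes <- unique(annotations$gene)
  bad <- vapply(genes, function(g) {
    rows <- which(annotations$gene == g)
    if (!length(rows)) return(FALSE)
    any(lengths(annotations$go_terms[rows]) > 0) ||
      any(vapply(annotations$domains[rows],
                 function(d) any(d %in% te_domains), logical(1)))
  }, logical(1))
  sort(genes[!bad])
}

#' Keep the longest isoform of each gene
#'
#' @param genes character vector of genes.
#' @param isoforms data.frame with columns \code{gene, isoform, length};
#'   every gene must have at least one isoform.
#' @return data.frame \code{gene, isoform, length} with exactly one row per
#'   gene: the maximal-length isoform, ties broken by ascending isoform ID.
#' @export
longest_isoform <- function(genes, isoforms) {
  if (!length(genes))
    return(data.frame(gene = character(0), isoform = character(0),
                      length = numeric(0)))
  missing <- setdiff(genes, isoforms$gene)
  if (length(missing))
    stop("gene without isoform record: ", paste(missing, collapse = ", "))
  sub <- isoforms[isoforms$gene %in% genes, , drop = FALSE]
  sub <- sub[order(sub$gene, -sub$length, sub$isoform), , drop = FALSE]
  out <- sub[!duplicated(sub$gene), c("gene", "isoform", "length")]
  rownames(out) <- NULL
  out
}

#' Filter genes by peak expression
#'
#' Retains genes whose maximum TPM across the time course is strictly
#' greater than \code{min_peak} (default 50, the top-decile cutoff used to
#' screen out low-level expression noise). Genes without an expression row
#' are treated as all-zero.
#'
#' @param genes character vector of genes.
#' @param expr numeric expression matrix, genes in rows (see
#'   \code{\link{read_table}} schema \code{"expression"}).
#' @param min_peak strict lower bound on the peak TPM.
#' @return the surviving gene set (sorted).
#' @export
expression_filter <- function(genes, expr, min_peak = 50) {
  if (!length(genes)) return(character(0))
  if (any(expr < 0)) stop("negative TPM value in expression matrix")
  peaks <- vapply(genes, function(g) {
    if (g %in% rownames(expr)) max(expr[g, ]) else 0
  }, numeric(1))
  sort(genes[peaks > min_peak])
}

# best hit per query: smallest e-value, ties by bit score desc then subject
# asc; an unresolved tie (equal e-value AND bit score) yields no best hit.
best_hits <- function(hits) {
  if (!nrow(hits))
    return(data.frame(q = character(0), s = character(0)))
  ord <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid)
  h <- hits[ord, , drop = FALSE]
  first <- !duplicated(h$qseqid)
  top <- h[first, , drop = FALSE]
  runner <- h[!first, , drop = FALSE]
  runner <- runner[!duplicated(runner$qseqid), , drop = FALSE]
  amb <- top$qseqid[match(top$qseqid, runner$qseqid, nomatch = 0) > 0 &
    top$evalue == runner$evalue[match(top$qseqid, runner$qseqid)] &
    top$bitscore == runner$bitscore[match(top$qseqid, runner$qseqid)] &
    top$sseqid != runner$sseqid[match(top$qseqid, runner$qseqid)]]
  top <- top[!top$qseqid %in% amb, , drop = FALSE]
  data.frame(q = top$qseqid, s = top$sseqid)
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (a, b) is a reciprocal best hit when b is a's unique best hit in
#' the forward table and a is b's unique best hit in the reverse table.
#' Both tables are first restricted to e-value strictly below
#' \code{max_evalue} (default 1e-7, the relaxed synapomorphy-screen
#' threshold). Best = smallest e-value, ties by descending bit score then
#' subject ID; a tie that neither rule resolves makes the query ambiguous
#' and yields no pair.
#'
#' @param hits_ab hit table A -> B.
#' @param hits_ba hit table B -> A.
#' @param max_evalue strict e-value bound applied to both tables.
#' @return data.frame \code{a, b} of reciprocal pairs (sorted by \code{a}).
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, max_evalue = 1e-7) {
  fa <- hits_ab[hits_ab$evalue < max_evalue, , drop = FALSE]
  fb <- hits_ba[hits_ba$evalue < max_evalue, , drop = FALSE]
  ba <- best_hits(fa)
  bb <- best_hits(fb)
  m <- merge(ba, bb, by.x = c("q", "s"), by.y = c("s", "q"))
  out <- data.frame(a = m$q, b = m$s)
  out <- out[order(out$a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene evidence report
#'
#' Assembles the final evidence table: for each gene, its reciprocal best
#' hit (the first available partner in declared proteome priority order, all
#' partners recorded), its ontology terms, and whether a phylome gene tree
#' exists; plus the headline summary counts.
#'
#' @param genes character vector of genes (report rows, in this order).
#' @param rbbh named list: proteome name -> RBBH pair data.frame
#'   (\code{a, b}) with \code{a} in gene space; list order is the priority
#'   order.
#' @param annotations annotation data.frame with list column
#'   \code{go_terms} (or a \code{gene_evidence}-style character ontology
#'   column), or NULL for none.
#' @param tree_registry named logical vector, gene -> has a phylome tree.
#' @return list of class \code{gene_evidence_report}: \code{evidence}
#'   data.frame (gene, rbbh, rbbh_all, ontology, has_tree) and
#'   \code{summary} named numeric vector (total, with_rbbh,
#'   ontology_absent, with_tree, without_tree, no_evidence).
#' @export
evidence_report <- function(genes, rbbh = list(), annotations = NULL,
                            tree_registry = logical(0)) {
  onto <- setNames(vector("list", length(genes)), genes)
  for (g in genes) onto[[g]] <- character(0)
  if (!is.null(annotations) && nrow(annotations)) {
    for (k in seq_len(nrow(annotations))) {
      g <- annotations$gene[k]
      if (g %in% genes) {
        terms <- annotations$go_terms[[k]]
        onto[[g]] <- union(onto[[g]], terms)
      }
    }
  }
  partner_all <- lapply(genes, function(g) {
    hits <- character(0)
    for (p in names(rbbh)) {
      tab <- rbbh[[p]]
      if (!is.null(tab) && nrow(tab) && g %in% tab$a)
        hits <- c(hits, setNames(tab$b[match(g, tab$a)], p))
    }
    hits
  })
  partner <- vapply(partner_all, function(h)
    if (length(h)) unname(h[1]) else NA_character_, character(1))
  has_tree <- vapply(genes, function(g)
    isTRUE(unname(tree_registry[g])[1]), logical(1))
  ev <- data.frame(gene = genes,
                   rbbh = partner,
                   rbbh_all = I(partner_all),
                   ontology = I(unname(onto[genes])),
                   has_tree = unname(has_tree))
  summary <- evidence_summary(ev)
  structure(list(evidence = ev, summary = summary),
            class = "gene_evidence_report")
}

#' Summary counts of an evidence table
#'
#' @param ev evidence data.frame with columns \code{rbbh} (NA = none),
#'   \code{ontology} (list column), \code{has_tree}.
#' @return named numeric vector: total, with_rbbh, ontology_absent,
#'   with_tree, without_tree, no_evidence (no RBBH, no ontology, no tree).
#' @export
evidence_summary <- function(ev) {
  with_rbbh <- !is.na(ev$rbbh)
  onto_absent <- lengths(ev$ontology) == 0
  c(total = nrow(ev),
    with_rbbh = sum(with_rbbh),
    ontology_absent = sum(onto_absent),
    with_tree = sum(ev$has_tree),
    without_tree = sum(!ev$has_tree),
    no_evidence = sum(!with_rbbh & onto_absent & !ev$has_tree))
}

#' Run the full TRG filtering cascade
#'
#' Stages in order: multi-tool consensus across the ingroup, outgroup
#' homolog exclusion, unannotated-only, longest isoform, peak-expression
#' filter, then the RBBH/evidence report on the survivors. Every removal is
#' logged per stage in the filter trace.
#'
#' @param calls orthology call data.frame.
#' @param ingroup,outgroup species sets.
#' @param annotations annotation data.frame (may be NULL).
#' @param isoforms isoform data.frame (\code{gene, isoform, length}); genes
#'   missing from it are assumed single-isoform.
#' @param expr expression matrix.
#' @param rbbh named list of per-proteome RBBH pair tables.
#' @param tree_registry named logical vector, gene -> has tree.
#' @param tools required-tool registry for the consensus stage.
#' @param te_domains TE domain IDs for the annotation stage.
#' @param min_peak strict TPM peak threshold.
#' @param report_annotations annotation table used for the ontology column
#'   of the final report; defaults to \code{annotations}. The filter stage
#'   and the report may draw on different annotation sources (e.g. PFAM
#'   domain ontology for filtering, a full InterProScan scan for
#'   reporting), so a gene can pass the unannotated filter yet still show
#'   ontology terms in the report.
#' @return list of class \code{trg_cascade}: \code{trace} (data.frame
#'   stage/n_in/n_out/removed), \code{genes} (final set), \code{report}
#'   (a \code{gene_evidence_report}).
#' @export
run_cascade <- function(calls, ingroup, outgroup, annotations = NULL,
                        isoforms = NULL, expr = NULL, rbbh = list(),
                        tree_registry = logical(0),
                        tools = orthology_tools(),
                        te_domains = character(0), min_peak = 50,
                        report_annotations = annotations) {
  trace <- list()
  log_stage <- function(stage, before, after) {
    trace[[length(trace) + 1L]] <<-
      list(stage = stage, n_in = length(before), n_out = length(after),
           removed = sort(setdiff(before, after)))
    after
  }
  all_queries <- sort(unique(calls$query))
  cur <- log_stage("consensus",
                   all_queries,
                   consensus_echinoderm(calls, ingroup, tools))
  cur <- log_stage("outgroup_exclusion", cur,
                   exclude_outgroup_homologs(cur, calls, outgroup))
  if (!is.null(annotations))
    cur <- log_stage("unannotated", cur,
                     unannotated_only(cur, annotations, te_domains))
  if (!is.null(isoforms)) {
    # candidates may be isoform-level protein models: collapse each gene to
    # its longest isoform still in the running; IDs not in the isoform table
    # are single-isoform genes and pass through
    iso_ids <- cur[cur %in% isoforms$isoform]
    nxt <- cur
    if (length(iso_ids)) {
      sub <- isoforms[isoforms$isoform %in% iso_ids, , drop = FALSE]
      keep <- longest_isoform(unique(sub$gene), sub)$isoform
      nxt <- sort(c(setdiff(cur, iso_ids), keep))
    }
    cur <- log_stage("longest_isoform", cur, nxt)
  }
  if (!is.null(expr))
    cur <- log_stage("expression", cur,
                     expression_filter(cur, expr, min_peak))
  report <- evidence_report(cur, rbbh, report_annotations, tree_registry)
  trace_df <- data.frame(
    stage = vapply(trace, `[[`, character(1), "stage"),
    n_in = vapply(trace, `[[`, integer(1), "n_in"),
    n_out = vapply(trace, `[[`, integer(1), "n_out"),
    removed = I(lapply(trace, `[[`, "removed")))
  structure(list(trace = trace_df, genes = as.character(cur),
                 report = report),
            class = "trg_cascade")
}
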