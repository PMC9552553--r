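# GO-term enrichment between gene lists (FatiGO-style hypergeometric tests)
# and summarization of per-site selection posteriors.

#' GO-term enrichment of a study set against a background
#'
#' For each term annotated in the background, the 2x2 table (study genes
#' with the term, study genes without, background-minus-study genes with,
#' rest) is tested with the hypergeometric distribution. The default is the
#' one-sided over-representation test, P(X >= k); \code{alternative =
#' "two.sided"} uses Fisher's exact test. P-values are adjusted across the
#' tested terms by Benjamini-Hochberg. Terms annotating no study gene and no
#' background-minus-study gene are skipped.
#'
#' @param study character vector of study genes; must be a subset of
#'   \code{background}.
#' @param background character vector of background genes.
#' @param annotations named list, gene -> character vector of term IDs (or
#'   an annotation data.frame with \code{gene} and list column
#'   \code{go_terms}).
#' @param alternative \code{"over"} (default) or \code{"two.sided"}.
#' @return data.frame per term: \code{term, study_count, study_size,
#'   bg_count, bg_size, direction, p, p_adj}, sorted by \code{p}.
#' @export
go_enrichment <- function(study, background, annotations,
                          alternative = c("over", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(background) >= 1)
  study <- unique(study); background <- unique(background)
  offenders <- setdiff(study, background)
  if (length(offenders))
    stop("study genes missing from background: ",
         paste(offenders, collapse = ", "))
  if (is.data.frame(annotations))
    annotations <- setNames(annotations$go_terms, annotations$gene)
  gene2terms <- lapply(setNames(background, background), function(g) {
    t <- annotations[[g]]
    if (is.null(t)) character(0) else unique(t)
  })
  terms <- sort(unique(unlist(gene2terms)))
  N <- length(background); n <- length(study)
  study_terms <- gene2terms[study]
  rows <- lapply(terms, function(tm) {
    K <- sum(vapply(gene2terms, function(t) tm %in% t, logical(1)))
    k <- sum(vapply(study_terms, function(t) tm %in% t, logical(1)))
    if (k == 0 && K - k == 0) return(NULL)
    p <- if (alternative == "over") {
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else {
      stats::fisher.test(matrix(c(k, n - k, K - k, N - K - (n - k)), 2))$p.value
    }
    expected <- n * K / N
    list(term = tm, study_count = k, bg_count = K,
         direction = if (k >= expected) "over" else "under", p = p)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- data.frame(
    term = vapply(rows, `[[`, character(1), "term"),
    study_count = vapply(rows, function(x) as.integer(x$study_count),
                         integer(1)),
    study_size = rep(n, length(rows)),
    bg_count = vapply(rows, function(x) as.integer(x$bg_count), integer(1)),
    bg_size = rep(N, length(rows)),
    direction = vapply(rows, `[[`, character(1), "direction"),
    p = vapply(rows, `[[`, numeric(1), "p"))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize per-site selection posteriors
#'
#' Counts, per gene, the sites whose posterior probability of negative or
#' positive selection meets the threshold (inclusive, default 0.95 — the
#' conventional reporting cutoff for site-level selection inference), and
#' reports the corresponding percentages to one decimal place.
#'
#' @param site_table data.frame with columns \code{gene, site, pp_positive,
#'   pp_negative}; posteriors in [0, 1].
#' @param threshold inclusive posterior-probability cutoff.
#' @return data.frame per gene: \code{gene, sites_total, sites_negative,
#'   sites_positive, pct_negative, pct_positive} (percentages NA when a gene
#'   has no sites).
#' @export
selection_summary <- function(site_table, threshold = 0.95) {
  stopifnot(all(c("gene", "site", "pp_positive", "pp_negative") %in%
                  names(site_table)))
  pp <- c(site_table$pp_positive, site_table$pp_negative)
  if (length(pp) && (any(is.na(pp)) || any(pp < 0 | pp > 1)))
    stop("site posteriors must lie in [0, 1]")
  if (!nrow(site_table))
    return(data.frame(gene = character(0), sites_total = integer(0),
                      sites_negative = integer(0),
                      sites_positive = integer(0),
                      pct_negative = numeric(0), pct_positive = numeric(0)))
  agg <- lapply(split(site_table, site_table$gene), function(g) {
    tot <- nrow(g)
    neg <- sum(g$pp_negative >= threshold)
    pos <- sum(g$pp_positive >= threshold)
    data.frame(gene = g$gene[1], sites_total = tot, sites_negative = neg,
               sites_positive = pos,
               pct_negative = round(100 * neg / tot, 1),
               pct_positive = round(100 * pos / tot, 1))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
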