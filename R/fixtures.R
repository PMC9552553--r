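# Packaged in-study fixtures: the 15-proteome species panel and the
# 14-gene evidence table.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "phylotrg")
  if (!nzchar(p)) p <- file.path("inst", "extdata", name)
  p
}

#' The 15-species phylome panel
#'
#' The pan-metazoan proteome panel used for phylome reconstruction: species
#' mnemonic (two entries carry the NCBI taxid where the source table lists
#' no mnemonic), NCBI taxonomy ID, species name and proteome source.
#'
#' @return data.frame with 15 rows: \code{abbreviation, ncbi_taxid,
#'   species, source}.
#' @export
table1_species <- function() {
  utils::read.delim(fixture_path("table1_species.tsv"),
                    colClasses = c("character", "integer", "character",
                                   "character"))
}

#' The 14-gene evidence table
#'
#' The final gene set of the echinoderm TRG screen: per gene, its
#' reciprocal-best-hit partner (if any), its phylome database ID — a
#' trailing asterisk in the source marks genes with no phylome tree, parsed
#' here into \code{has_tree} — and its InterProScan ontology terms.
#'
#' @return data.frame with 14 rows: \code{gene, rbbh, rbbh_proteome,
#'   phylomedb_id, has_tree}, list column \code{ontology}.
#' @export
table2_fixture <- function() {
  df <- utils::read.delim(fixture_path("table2_gene_set.tsv"),
                          colClasses = "character")
  df$has_tree <- !grepl("\\*$", df$phylomedb_id)
  df$phylomedb_id <- sub("\\*$", "", df$phylomedb_id)
  df$rbbh[df$rbbh == "N/A"] <- NA_character_
  df$rbbh_proteome <- ifelse(is.na(df$rbbh), NA_character_,
                             sub("^.*_", "", df$rbbh))
  df$ontology <- I(split_terms(df$ontology))
  df[c("gene", "rbbh", "rbbh_proteome", "phylomedb_id", "has_tree",
       "ontology")]
}

#' Evidence report for the packaged 14-gene set
#'
#' Decomposes the packaged evidence table back into the raw ingredients the
#' reporting stage consumes — per-proteome RBBH pair tables, an annotation
#' table and a tree registry — and recomputes the report through
#' \code{\link{evidence_report}}. Proteome priority follows the order
#' partners appear in the table (NEMVE, BRAFL, CIOIN for this set).
#'
#' @return a \code{gene_evidence_report}; \code{$summary} carries the
#'   headline counts (total, with_rbbh, ontology_absent, with_tree,
#'   without_tree, no_evidence).
#' @export
table2_report <- function() {
  fx <- table2_fixture()
  proteomes <- unique(stats::na.omit(fx$rbbh_proteome))
  rbbh <- setNames(lapply(proteomes, function(p) {
    sub <- fx[!is.na(fx$rbbh_proteome) & fx$rbbh_proteome == p, ]
    data.frame(a = sub$gene, b = sub$rbbh)
  }), proteomes)
  annotations <- data.frame(gene = fx$gene,
                            go_terms = I(unclass(fx$ontology)))
  tree_registry <- setNames(fx$has_tree, fx$gene)
  evidence_report(fx$gene, rbbh = rbbh, annotations = annotations,
                  tree_registry = tree_registry)
}

#' Newick for the 15-species panel topology
#'
#' A rooted topology over the panel mnemonics consistent with current
#' metazoan phylogeny: echinoderms (sea urchin, sea star, feather star)
#' with the hemichordate as sister, chordates, protostomes, and the
#' non-bilaterian outgroups branching basally.
#'
#' @return a \code{species_tree} over the 15 panel abbreviations.
#' @export
table1_species_tree <- function() {
  abb <- table1_species()$abbreviation
  nwk <- paste0(
    "(AMPQE,(NEMVE,((((STRPU,(ACAPL,1529436)),SACKO),",
    "(BRAFL,(CIOIN,(XENTR,(CHICK,HUMAN))))),",
    "((DROME,CAEEL),(CRAVI,283909)))));")
  tr <- species_tree(ape::read.tree(text = nwk))
  stopifnot(setequal(tr$tip.label, abb))
  tr
}
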