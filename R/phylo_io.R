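# Readers and writers for the external formats the pipeline touches:
# newick trees, 12-column tabular similarity-search hits, and headered TSV
# tables (orthology calls, annotations, expression matrices, site posteriors).

#' Leaf-to-species mapping rules
#'
#' Gene-tree leaves are sequence IDs; a species map resolves each to a
#' species mnemonic. Three rule kinds are supported: \code{species_map_suffix}
#' (the text after the final separator is the mnemonic, the PhylomeDB-style
#' convention and the default), \code{species_map_regex} (a capture group
#' extracts the mnemonic), and \code{species_map_table} (an explicit
#' sequence-ID to species lookup). Unmappable leaves are always an error,
#' never dropped.
#'
#' @param sep separator character for the suffix rule.
#' @param pattern regular expression containing at least one capture group.
#' @param group index of the capture group holding the mnemonic.
#' @param mapping named character vector, names = sequence IDs, values =
#'   species mnemonics.
#' @return a \code{species_map} object.
#' @export
species_map_suffix <- function(sep = "_") {
  structure(list(kind = "suffix", sep = sep), class = "species_map")
}

#' @rdname species_map_suffix
#' @export
species_map_regex <- function(pattern, group = 1L) {
  structure(list(kind = "regex", pattern = pattern, group = group),
            class = "species_map")
}

#' @rdname species_map_suffix
#' @export
species_map_table <- function(mapping) {
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  structure(list(kind = "table", mapping = mapping), class = "species_map")
}

#' Resolve sequence IDs to species under a mapping rule
#'
#' @param labels character vector of sequence IDs.
#' @param map a \code{species_map}.
#' @return character vector of species mnemonics, named by \code{labels};
#'   errors naming the first offending leaf if any ID fails to map.
#' @export
map_species <- function(labels, map) {
  stopifnot(inherits(map, "species_map"))
  out <- switch(map$kind,
    suffix = {
      has_sep <- grepl(map$sep, labels, fixed = TRUE)
      esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", map$sep)
      ifelse(has_sep, sub(paste0(".*", esc), "", labels), NA_character_)
    },
    regex = {
      m <- regexec(map$pattern, labels)
      vapply(regmatches(labels, m), function(g) {
        if (length(g) > map$group) g[map$group + 1L] else NA_character_
      }, character(1))
    },
    table = unname(map$mapping[labels])
  )
  bad <- labels[is.na(out) | !nzchar(out)]
  if (length(bad))
    stop("cannot map leaf to a species: ", paste(bad, collapse = ", "))
  names(out) <- labels
  out
}

# light syntax scan so parse errors carry a character position
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick: unbalanced ')' at character ", i)
    }
  }
  if (depth > 0L)
    stop("malformed newick: ", depth, " unclosed '(' at character ",
         length(chars))
  if (!grepl(";\\s*$", text))
    stop("malformed newick: missing terminal ';' at character ",
         length(chars))
  invisible(TRUE)
}

#' Read a newick tree
#'
#' Parses plain newick with optional branch lengths and support values stored
#' as internal-node labels; NHX-style \code{[&&NHX...]} comment blocks are
#' tolerated and discarded. For \code{kind = "gene"} every leaf is resolved
#' to a species through \code{species_map}; unmappable leaves are an error.
#'
#' @param text newick string (or a path when \code{file = TRUE}).
#' @param kind \code{"species"} or \code{"gene"}.
#' @param species_map mapping rule for gene trees; defaults to the
#'   suffix-after-final-underscore convention.
#' @param file set \code{TRUE} to read \code{text} as a file path.
#' @return a \code{species_tree} or \code{gene_tree}.
#' @export
read_newick <- function(text, kind = c("species", "gene"),
                        species_map = species_map_suffix(), file = FALSE) {
  kind <- match.arg(kind)
  if (file) text <- paste(readLines(text, warn = FALSE), collapse = "")
  text <- gsub("\\[&&NHX[^]]*\\]", "", text)
  check_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("malformed newick: parser rejected input at character 1")
  if (kind == "species") return(species_tree(phy))
  gene_tree(phy, map_species(phy$tip.label, species_map))
}

#' Write a tree as newick
#'
#' @param tree a \code{phylo} (or \code{gene_tree}/\code{species_tree}).
#' @param path optional output file; when missing the string is returned.
#' @return the newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(ape::as.phylo(tree))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

hit_table_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                    "gapopen", "qstart", "qend", "sstart", "send",
                    "evalue", "bitscore")

#' Read a 12-column tabular similarity-search hit table
#'
#' The classic 12-column tab-separated dialect (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score). Row order is preserved; numeric
#' fields including scientific-notation e-values are parsed as doubles.
#'
#' @param path file path.
#' @param query_lengths optional named numeric vector of query sequence
#'   lengths, required downstream by coverage filtering.
#' @return a \code{data.frame} with the standard column names and a
#'   \code{query_lengths} attribute.
#' @export
read_hit_table <- function(path, query_lengths = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 10)),
      hit_table_cols))
    return(hit_table(out, query_lengths))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    stop("hit table format error: expected 12 tab-separated columns, got ",
         lengths(fields)[bad[1]], " at line ", bad[1])
  m <- do.call(rbind, fields)
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                    apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  names(out) <- hit_table_cols
  hit_table(out, query_lengths)
}

#' Construct (and validate) a hit table from a data frame
#'
#' @param df data frame with the 12 standard columns.
#' @param query_lengths optional named numeric vector of query lengths.
#' @return validated hit table data frame.
#' @export
hit_table <- function(df, query_lengths = NULL) {
  missing <- setdiff(hit_table_cols, names(df))
  if (length(missing))
    stop("hit table missing column(s): ", paste(missing, collapse = ", "))
  df <- df[hit_table_cols]
  if (nrow(df)) {
    if (any(df$evalue < 0)) stop("hit table: negative e-value")
    if (any(df$bitscore < 0)) stop("hit table: negative bit score")
    if (any(df$qstart < 1 | df$qstart > df$qend))
      stop("hit table: require 1 <= qstart <= qend")
  }
  attr(df, "query_lengths") <- query_lengths
  df
}

#' Write a hit table in the 12-column tabular dialect
#'
#' @param hits hit table data frame.
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[hit_table_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Registry of recognized orthology-prediction tools
#'
#' The six tools whose one-to-one calls feed the consensus stage.
#'
#' @return character vector of tool names.
#' @export
orthology_tools <- function() {
  c("inparanoid", "proteinortho", "swiftortho", "fastortho", "oma",
    "orthofinder")
}

#' Developmental time-course grid (hours post-fertilization)
#'
#' Nine unique sampling times of the embryonic expression time course.
#' Duplicate timepoint headers in input tables are rejected.
#'
#' @return numeric vector of 9 timepoints.
#' @export
dev_timepoints <- function() c(0, 10, 18, 24, 40, 48, 56, 64, 72)

split_terms <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v) || toupper(v) %in% c("N/A", "NA", "NONE"))
      return(character(0))
    trimws(strsplit(v, ",")[[1]])
  })
}

#' Read a typed headered TSV table
#'
#' Four schemas cover the pipeline's tabular inputs:
#' \describe{
#'   \item{orthology}{columns \code{query, tool, target_species, target_gene}
#'     and optional logical \code{one_to_one} (default \code{TRUE}); tool
#'     names must come from \code{\link{orthology_tools}}.}
#'   \item{annotation}{columns \code{gene, isoform, length, domains,
#'     go_terms}; the last two are comma-separated sets, with \code{N/A} or
#'     empty cells becoming explicit empty sets (list columns).}
#'   \item{expression}{column \code{gene} followed by numeric timepoint
#'     columns; duplicate timepoint headers are an error; negative values
#'     are an error.}
#'   \item{selection}{columns \code{gene, site, pp_positive, pp_negative};
#'     posteriors must lie in [0, 1].}
#' }
#'
#' @param path file path of a tab-separated file with a header row.
#' @param schema one of \code{"orthology"}, \code{"annotation"},
#'   \code{"expression"}, \code{"selection"}.
#' @return a typed \code{data.frame} (expression: a numeric matrix with gene
#'   row names, timepoints as numeric column names).
#' @export
read_table <- function(path, schema = c("orthology", "annotation",
                                        "expression", "selection")) {
  schema <- match.arg(schema)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- function(cols) {
    missing <- setdiff(cols, names(df))
    if (length(missing))
      stop("schema '", schema, "': missing required column(s): ",
           paste(missing, collapse = ", "))
  }
  switch(schema,
    orthology = {
      need(c("query", "tool", "target_species", "target_gene"))
      bad <- setdiff(unique(df$tool), orthology_tools())
      if (length(bad))
        stop("unknown orthology tool(s): ", paste(bad, collapse = ", "))
      if (!"one_to_one" %in% names(df)) df$one_to_one <- TRUE
      df$one_to_one <- as.logical(df$one_to_one)
      df
    },
    annotation = {
      need(c("gene", "isoform", "length", "domains", "go_terms"))
      df$length <- as.numeric(df$length)
      df$domains <- split_terms(df$domains)
      df$go_terms <- split_terms(df$go_terms)
      df
    },
    expression = {
      need("gene")
      tp <- names(df)[names(df) != "gene"]
      if (anyDuplicated(tp))
        stop("duplicate timepoint column(s): ",
             paste(unique(tp[duplicated(tp)]), collapse = ", "))
      m <- as.matrix(df[tp])
      mode(m) <- "numeric"
      if (anyNA(m)) stop("expression matrix contains non-numeric cells")
      if (any(m < 0)) stop("negative TPM value in expression matrix")
      rownames(m) <- df$gene
      colnames(m) <- tp
      m
    },
    selection = {
      need(c("gene", "site", "pp_positive", "pp_negative"))
      df$pp_positive <- as.numeric(df$pp_positive)
      df$pp_negative <- as.numeric(df$pp_negative)
      pp <- c(df$pp_positive, df$pp_negative)
      if (any(is.na(pp)) || any(pp < 0 | pp > 1))
        stop("site posteriors must lie in [0, 1]")
      df
    })
}
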