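# Readers and writers for the plain-text interchange formats used by the
# pipeline: TSV tables, GMT gene sets, GraphML networks, JSON truth/reports.

#' Write / read an expression matrix as TSV
#'
#' Rows are subjects; the first column is `subject_id`, remaining columns
#' are genes.
#' @param x subjects-by-genes matrix with dimnames.
#' @param path file path.
#' @export
write_expression_tsv <- function(x, path) {
  df <- as_tibble(x, rownames = "subject_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$subject_id
  m
}

#' Write / read a genes-by-regions atlas as TSV
#' @param atlas genes-by-regions matrix with dimnames.
#' @param path file path.
#' @export
write_atlas_tsv <- function(atlas, path) {
  readr::write_tsv(as_tibble(atlas, rownames = "gene"), path)
  invisible(path)
}

#' @rdname write_atlas_tsv
#' @export
read_atlas_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$gene
  m
}

#' Write / read named gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated genes.
#' @param sets named list of character vectors.
#' @param path file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "personet", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) p[-(1:2)]),
           vapply(parts, `[[`, "", 1))
}

#' Write a network as node and edge TSV tables plus GraphML
#'
#' @param net an `omic_network`.
#' @param prefix path prefix; writes `<prefix>_nodes.tsv`,
#'   `<prefix>_edges.tsv` and `<prefix>.graphml`.
#' @export
write_network <- function(net, prefix) {
  nodes <- net$nodes
  nodes$provenance <- NULL
  readr::write_tsv(nodes, paste0(prefix, "_nodes.tsv"))
  readr::write_tsv(network_edges(net), paste0(prefix, "_edges.tsv"))
  igraph::write_graph(net$graph, paste0(prefix, ".graphml"),
                      format = "graphml")
  invisible(prefix)
}

#' Write all fixture inputs of a bundle to a directory
#'
#' Emits expression and label TSVs, the atlas TSV, edge tables, annotation
#' table, gene-set GMTs, and the planted truth as JSON.
#' @param fx a [make_fixtures()] bundle.
#' @param dir output directory (created if needed).
#' @export
write_fixtures <- function(fx, dir) {
  stopifnot(inherits(fx, "personet_fixtures"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_expression_tsv(fx$expression$values, p("expression.tsv"))
  readr::write_tsv(fx$expression$labels, p("labels.tsv"))
  write_atlas_tsv(fx$atlas, p("atlas.tsv"))
  readr::write_tsv(fx$interactions$edges, p("edges.tsv"))
  readr::write_tsv(fx$interactions$lnc_expansion, p("lnc_expansion.tsv"))
  readr::write_tsv(fx$interactions$lnc_links, p("lnc_links.tsv"))
  readr::write_tsv(fx$interactions$node_types, p("node_types.tsv"))
  readr::write_tsv(fx$annotations, p("annotations.tsv"))
  write_gmt(fx$t_sets, p("t_sets.gmt"))
  write_gmt(fx$ge_sets, p("ge_sets.gmt"))
  writeLines(fx$personality_genes, p("personality_genes.txt"))
  writeLines(fx$switch_genes, p("switch_genes.txt"))
  writeLines(fx$personality_lncrnas, p("personality_lncrnas.txt"))
  jsonlite::write_json(fx$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a planted-truth JSON file
#' @param path file path.
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
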