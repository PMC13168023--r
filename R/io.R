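#' Read an abundance table from TSV
#'
#' Expects a tab-separated file whose first column holds feature ids and
#' whose remaining columns are numeric per-sample values. Duplicate feature
#' ids, missing cells, and non-numeric cells are rejected with the offending
#' id or row/column named.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, features x samples.
#' @export
read_abundance <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("abundance table needs an id column plus samples")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicated feature id: ", ids[duplicated(ids)][1])
  }
  vals <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    x <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(x))
    if (length(bad) > 0) {
      stop("non-numeric or missing cell at row ", bad[1] + 1,
           " (feature ", ids[bad[1]], "), column ", colnames(vals)[j])
    }
    m[, j] <- x
  }
  m
}

#' Write an abundance table to TSV
#'
#' @param counts Matrix, features x samples.
#' @param path Output path.
#' @param id_column Name of the feature-id column (default "taxon").
#' @return The path, invisibly.
#' @export
write_abundance <- function(counts, path, id_column = "taxon") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network edge list to TSV
#'
#' Columns: `taxon_a`, `taxon_b`, `r`, `p`, `q`, `stage`; rows sorted by
#' pair id for diffability.
#'
#' @param net A `coab_network`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edge_table <- function(net, path) {
  stopifnot(inherits(net, "coab_network"))
  ed <- net$edges
  df <- data.frame(taxon_a = ed$from, taxon_b = ed$to, r = ed$r, p = ed$p,
                   q = ed$q, stage = rep(as.character(net$stage), nrow(ed)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$taxon_a, df$taxon_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a network as GraphML
#'
#' Edge attributes `r`, `p`, `q`, `sign` and node attributes
#' `mean_abundance`, `beneficial` survive the round trip (GraphML is also
#' what desktop viewers such as Cytoscape import).
#'
#' @param net A `coab_network`.
#' @param path File path.
#' @return `write_graphml()` returns the path invisibly; `read_graphml()`
#'   returns the restored `coab_network`.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "coab_network"))
  g <- as_igraph(net)
  igraph::graph_attr(g, "stage") <- as.character(net$stage)
  igraph::graph_attr(g, "n_samples") <- as.integer(net$n_samples)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  vt <- igraph::as_data_frame(g, what = "vertices")
  nodes <- data.frame(taxon = vt$name,
                      mean_abundance = if ("mean_abundance" %in% names(vt))
                        vt$mean_abundance else NA_real_,
                      beneficial = if ("beneficial" %in% names(vt))
                        as.logical(vt$beneficial) else FALSE,
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = ed$from, to = ed$to,
                      r = if (nrow(ed)) ed$r else numeric(0),
                      p = if ("p" %in% names(ed)) ed$p else NA_real_,
                      q = if ("q" %in% names(ed)) ed$q else NA_real_,
                      stringsAsFactors = FALSE)
  stage <- igraph::graph_attr(g, "stage")
  n_samples <- igraph::graph_attr(g, "n_samples")
  ns <- if (is.null(n_samples)) NA_integer_ else
    suppressWarnings(as.integer(n_samples))
  coab_network(edges, nodes,
               stage = if (is.null(stage)) NA else stage,
               n_samples = ns)
}

#' Write sample metadata (stage, phenotype) to TSV
#'
#' @param metadata data.frame with at least `sample` and `stage` columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  stopifnot(all(c("sample", "stage") %in% names(metadata)))
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a taxonomy table with beneficial flags to TSV
#'
#' @param taxa Character vector of taxon ids.
#' @param beneficial Logical flags.
#' @param lineage Optional lineage strings (default the taxon id).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_taxonomy <- function(taxa, beneficial, path, lineage = NULL) {
  if (is.null(lineage)) lineage <- taxa
  df <- data.frame(taxon = taxa, lineage = lineage,
                   beneficial = as.integer(beneficial),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
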