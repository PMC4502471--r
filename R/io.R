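## Tabular readers/writers. Dialect everywhere: tab-separated, UTF-8,
## "#"-prefixed comment lines ignored, case-sensitive gene symbols.

CATALOG_FAMILIES <- c("SR", "hnRNP", "snRNP", "LSm", "other")
CATALOG_ACTIVITIES <- c("activator", "repressor", "unknown")

#' Construct a protein catalog
#'
#' The catalog is the authority on which proteins belong to the system
#' under study (here, the spliceosome and splicing-related factors), plus
#' per-protein annotations: protein family, regulatory activity and a set
#' of functional terms.
#'
#' @param protein_id unique character ids.
#' @param family one of `"SR"`, `"hnRNP"`, `"snRNP"`, `"LSm"`, `"other"`.
#' @param activity one of `"activator"`, `"repressor"`, `"unknown"`.
#' @param functional_terms list of character vectors (one per protein), or a
#'   `";"`-separated string per protein.
#' @param cluster_id optional integer cluster labels.
#' @return a data frame of class `protein_catalog`.
#' @export
protein_catalog <- function(protein_id,
                            family = "other",
                            activity = "unknown",
                            functional_terms = NULL,
                            cluster_id = NA_integer_) {
  protein_id <- as.character(protein_id)
  if (anyDuplicated(protein_id)) {
    stop("duplicate protein ids: ",
         paste(unique(protein_id[duplicated(protein_id)]), collapse = ", "))
  }
  n <- length(protein_id)
  family <- rep_len(as.character(family), n)
  activity <- rep_len(as.character(activity), n)
  activity[is.na(activity) | activity == ""] <- "unknown"
  if (!all(family %in% CATALOG_FAMILIES)) {
    stop("family must be one of: ", paste(CATALOG_FAMILIES, collapse = ", "))
  }
  if (!all(activity %in% CATALOG_ACTIVITIES)) {
    stop("activity must be one of: ", paste(CATALOG_ACTIVITIES, collapse = ", "))
  }
  if (is.null(functional_terms)) {
    functional_terms <- replicate(n, character(0), simplify = FALSE)
  } else if (is.character(functional_terms)) {
    functional_terms <- strsplit(rep_len(functional_terms, n), ";", fixed = TRUE)
    functional_terms <- lapply(functional_terms, function(x) x[nzchar(x)])
  }
  out <- data.frame(protein_id = protein_id, family = family,
                    activity = activity,
                    cluster_id = rep_len(as.integer(cluster_id), n),
                    stringsAsFactors = FALSE)
  out$functional_terms <- functional_terms
  class(out) <- c("protein_catalog", "data.frame")
  out
}

#' Read a protein catalog from TSV
#'
#' Expected columns (header required): `protein_id`, and optionally
#' `family`, `activity`, `functional_terms` (";"-separated term ids).
#'
#' @param path file path.
#' @return a `protein_catalog`.
#' @export
read_protein_catalog <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"protein_id" %in% names(df)) stop("catalog needs a 'protein_id' column")
  protein_catalog(
    df$protein_id,
    family = if ("family" %in% names(df)) df$family else "other",
    activity = if ("activity" %in% names(df)) df$activity else "unknown",
    functional_terms = if ("functional_terms" %in% names(df))
      df$functional_terms else NULL)
}

#' Read an undirected PPI edge table
#'
#' Reads a TSV whose first two columns are protein symbols (an optional
#' third column is kept as the edge source tag). Reversed duplicates are
#' collapsed and self-edges dropped (their count is reported via
#' `message()`). A header line is recognised when the first two fields
#' start with `protein`.
#'
#' @param path file path.
#' @param catalog optional `protein_catalog`; if supplied, edges are
#'   restricted to catalog proteins and all catalog proteins become nodes
#'   (so catalog proteins without interactions are isolates, not absent).
#' @return an `interaction_network`.
#' @export
read_ppi_table <- function(path, catalog = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty PPI table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lineno[vapply(fields, function(f) sum(nzchar(f[1:2])) < 2 ||
                         length(f) < 2, logical(1))]
  if (length(bad) > 0) {
    stop("malformed rows (need >= 2 protein columns) at line(s): ",
         paste(bad, collapse = ", "))
  }
  a <- vapply(fields, `[`, character(1), 1)
  b <- vapply(fields, `[`, character(1), 2)
  src <- vapply(fields, function(f) if (length(f) >= 3) f[3] else NA_character_,
                character(1))
  if (grepl("^protein", a[1], ignore.case = TRUE) &&
      grepl("^protein", b[1], ignore.case = TRUE)) {
    a <- a[-1]; b <- b[-1]; src <- src[-1]
  }
  if (length(a) == 0) stop("empty PPI table: ", path)
  self <- a == b
  if (any(self)) {
    message("read_ppi_table: dropped ", sum(self), " self-edge(s)")
    a <- a[!self]; b <- b[!self]; src <- src[!self]
  }
  nodes <- NULL
  if (!is.null(catalog)) {
    in_cat <- a %in% catalog$protein_id & b %in% catalog$protein_id
    a <- a[in_cat]; b <- b[in_cat]; src <- src[in_cat]
    nodes <- catalog$protein_id
  }
  interaction_network(cbind(a, b), nodes = nodes, edge_source = src)
}

#' Read a gene expression matrix from TSV
#'
#' First column gene ids, remaining columns numeric sample values; a header
#' row of sample ids is required. At least three samples are needed for a
#' Pearson correlation to be defined, so narrower files are rejected.
#'
#' @param path file path.
#' @return numeric matrix, rows named by gene id, columns by sample id.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 4) stop("need >= 3 sample columns, got ", ncol(df) - 1)
  genes <- df[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num) && !anyNA(vals)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    stop("non-numeric expression value at gene ", genes[bad[1, 1]],
         ", sample ", colnames(df)[-1][bad[1, 2]])
  }
  dimnames(num) <- list(genes, colnames(df)[-1])
  num
}

#' Write a gene expression matrix to TSV
#'
#' Values are written with full double precision so that
#' `read_expression_matrix()` round-trips exactly.
#'
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  body <- apply(expr, 1:2, function(x) sprintf("%.17g", x))
  lines <- c(paste(c("gene_id", colnames(expr)), collapse = "\t"),
             paste(rownames(expr), apply(body, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Export a network for external tools
#'
#' Writes Cytoscape-compatible files: SIF (`a pp b`), GraphML (with a
#' numeric `pin` edge attribute when the input is probabilistic), or a
#' three-column TSV (`protein_a`, `protein_b`, `pin`; deterministic edges
#' get `pin = 1`).
#'
#' @param net an `interaction_network` or `probabilistic_network`.
#' @param format one of `"SIF"`, `"GraphML"`, `"TSV"`.
#' @param path output path.
#' @param cutoff for probabilistic input, only pairs with `pin >= cutoff`
#'   are written (default: every pair with positive probability).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, format = c("SIF", "GraphML", "TSV"), path,
                           cutoff = NULL) {
  format <- match.arg(format)
  if (inherits(net, "probabilistic_network")) {
    ut <- upper.tri(net$pin)
    thr <- if (is.null(cutoff)) .Machine$double.xmin else cutoff
    sel <- which(ut & net$pin >= thr, arr.ind = TRUE)
    a <- net$protein_ids[sel[, 1]]
    b <- net$protein_ids[sel[, 2]]
    w <- net$pin[sel]
    nodes <- net$protein_ids
  } else if (inherits(net, "interaction_network")) {
    a <- net$edges[, 1]; b <- net$edges[, 2]
    w <- rep(1, length(a))
    nodes <- net$nodes
  } else {
    stop("unsupported network object")
  }
  switch(format,
    SIF = writeLines(paste(a, "pp", b), path, useBytes = TRUE),
    TSV = writeLines(c("protein_a\tprotein_b\tpin",
                       sprintf("%s\t%s\t%.17g", a, b, w)),
                     path, useBytes = TRUE),
    GraphML = {
      g <- igraph::make_empty_graph(n = 0, directed = FALSE)
      g <- igraph::add_vertices(g, length(nodes), name = nodes)
      if (length(a) > 0) {
        g <- igraph::add_edges(g, rbind(match(a, nodes), match(b, nodes)))
        igraph::E(g)$pin <- w
      }
      igraph::write_graph(g, path, format = "graphml")
    })
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' SIF yields an `interaction_network`. TSV and GraphML carry edge
#' probabilities and yield a `probabilistic_network` whose matrix holds the
#' stored `pin` on listed pairs and zero elsewhere.
#'
#' @param path input path.
#' @param format one of `"SIF"`, `"GraphML"`, `"TSV"`.
#' @return an `interaction_network` (SIF) or `probabilistic_network`.
#' @export
import_network <- function(path, format = c("SIF", "GraphML", "TSV")) {
  format <- match.arg(format)
  if (format == "SIF") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(interaction_network())
    parts <- strsplit(lines, "[ \t]+")
    a <- vapply(parts, `[`, character(1), 1)
    b <- vapply(parts, `[`, character(1), 3)
    return(interaction_network(cbind(a, b)))
  }
  if (format == "TSV") {
    df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                            stringsAsFactors = FALSE)
    a <- as.character(df[[1]]); b <- as.character(df[[2]])
    w <- as.numeric(df[[3]])
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_edgelist(g, names = TRUE)
    a <- el[, 1]; b <- el[, 2]
    w <- if ("pin" %in% igraph::edge_attr_names(g)) igraph::E(g)$pin else
      rep(1, nrow(el))
    ids <- igraph::V(g)$name
    return(edge_list_to_pnet(a, b, w, ids))
  }
  edge_list_to_pnet(a, b, w)
}

edge_list_to_pnet <- function(a, b, w, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(a, b)))
  n <- length(ids)
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(a, ids); j <- match(b, ids)
  P[cbind(i, j)] <- w
  P[cbind(j, i)] <- w
  probabilistic_network(ids, P)
}
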