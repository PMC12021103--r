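# The heterogeneous biomedical graph (BioHG): typed nodes, typed edges,
# per-type feature matrices, and the graph queries used by sampling and
# mechanism analysis.

NODE_TYPES <- c("drug", "protein", "cell_line", "pathway", "go_term")

# Allowed (src_type, dst_type) per edge type.  Drugs and cell lines are never
# directly connected: drug response information must flow through proteins.
EDGE_SCHEMA <- data.frame(
  edge_type = c("dti", "ppi", "protein_pathway", "protein_go", "protein_cell"),
  src_type  = c("drug", "protein", "protein", "protein", "protein"),
  dst_type  = c("protein", "protein", "pathway", "go_term", "cell_line"),
  stringsAsFactors = FALSE
)

#' Build a heterogeneous biomedical graph
#'
#' Assembles a typed graph over drugs, proteins, cell lines, pathways and
#' GO terms from edge tables plus a cell-line-by-gene expression matrix.
#' Protein--cell-line edges are not supplied directly: they are derived from
#' the expression matrix by [derive_expression_edges()], connecting each cell
#' line to the proteins whose expression lies strictly above that cell's mean,
#' with the expression value stored as the edge weight.  These weights feed
#' training-sample generation only; message passing never reads them.
#'
#' Drugs and cell lines are deliberately never adjacent, so any predictive
#' signal between them has to be carried through the protein layer.
#'
#' @param dti_edges data.frame with columns `src_id` (drug), `dst_id`
#'   (protein); drug--target interactions.
#' @param ppi_edges data.frame `src_id`, `dst_id`, both proteins; treated as
#'   undirected (one canonical record per pair is stored).
#' @param pathway_edges data.frame `src_id` (protein), `dst_id` (pathway).
#' @param go_edges data.frame `src_id` (protein), `dst_id` (GO term).
#' @param expr numeric matrix, cell lines in rows, genes in columns, with
#'   dimnames; or `NULL` for a graph without cell lines.
#' @param drug_features numeric matrix of per-drug feature vectors
#'   (e.g. 1024-bit circular fingerprints), rownames = drug IDs.  Every drug
#'   appearing in `dti_edges` must have a row.
#' @param gene_map optional two-column data.frame (`gene_id`, `protein_id`)
#'   mapping expression columns onto protein nodes; columns whose gene has no
#'   mapping are dropped with a message.  Default: gene IDs are protein IDs.
#' @return An object of class `biohg`: node ID vectors per type (sorted, so
#'   construction is deterministic), an edge table, and the feature matrices.
#' @export
build_biohg <- function(dti_edges = NULL, ppi_edges = NULL,
                        pathway_edges = NULL, go_edges = NULL,
                        expr = NULL, drug_features = NULL, gene_map = NULL) {
  as_edges <- function(df, type) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    sc <- EDGE_SCHEMA[EDGE_SCHEMA$edge_type == type, ]
    data.frame(src_type = sc$src_type, src_id = as.character(df$src_id),
               dst_type = sc$dst_type, dst_id = as.character(df$dst_id),
               edge_type = type, weight = NA_real_, stringsAsFactors = FALSE)
  }
  edges <- rbind(as_edges(dti_edges, "dti"),
                 as_edges(ppi_edges, "ppi"),
                 as_edges(pathway_edges, "protein_pathway"),
                 as_edges(go_edges, "protein_go"))

  if (!is.null(expr)) {
    expr <- map_expression_genes(expr, gene_map)
    edges <- rbind(edges, derive_expression_edges(expr))
  }
  if (is.null(edges)) stop("no edges supplied")

  # canonicalize ppi direction so rebuilds are byte-identical
  is_ppi <- edges$edge_type == "ppi"
  if (any(is_ppi)) {
    a <- pmin(edges$src_id[is_ppi], edges$dst_id[is_ppi])
    b <- pmax(edges$src_id[is_ppi], edges$dst_id[is_ppi])
    edges$src_id[is_ppi] <- a
    edges$dst_id[is_ppi] <- b
    drop <- logical(nrow(edges))
    drop[is_ppi] <- a == b              # self-loops carry no information
    edges <- edges[!drop, , drop = FALSE]
  }
  edges <- unique(edges)
  o <- order(edges$edge_type, edges$src_id, edges$dst_id)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- lapply(NODE_TYPES, function(tp) {
    ids <- c(edges$src_id[edges$src_type == tp], edges$dst_id[edges$dst_type == tp])
    if (tp == "drug" && !is.null(drug_features)) ids <- c(ids, rownames(drug_features))
    if (tp == "cell_line" && !is.null(expr)) ids <- c(ids, rownames(expr))
    sort(unique(ids))
  })
  names(nodes) <- NODE_TYPES

  if (length(nodes$drug) > 0L) {
    if (is.null(drug_features)) stop("drug nodes present but no drug_features given")
    missing <- setdiff(nodes$drug, rownames(drug_features))
    if (length(missing)) {
      stop("drugs without feature vectors: ", paste(missing, collapse = ", "))
    }
    drug_features <- drug_features[nodes$drug, , drop = FALSE]
  }
  cell_features <- NULL
  if (!is.null(expr)) cell_features <- expr[nodes$cell_line, , drop = FALSE]

  g <- structure(list(nodes = nodes, edges = edges,
                      drug_features = drug_features,
                      cell_features = cell_features),
                 class = "biohg")
  validate_biohg(g)
  g
}

#' Validate a heterogeneous graph against the edge-type schema
#'
#' Checks that every edge's endpoint types match the type-pairing table (in
#' particular that no edge joins a drug to a cell line), that all endpoints
#' exist as nodes, and that weights appear exactly on protein--cell edges.
#'
#' @param g a `biohg` object.
#' @return `g`, invisibly; errors describe the first violation found.
#' @export
validate_biohg <- function(g) {
  e <- g$edges
  m <- merge(e, EDGE_SCHEMA, by = "edge_type", suffixes = c("", ".ok"))
  bad <- m$src_type != m$src_type.ok | m$dst_type != m$dst_type.ok
  if (nrow(m) != nrow(e) || any(bad)) {
    off <- if (any(bad)) m[bad, c("edge_type", "src_type", "dst_type")][1, ] else
      e[!e$edge_type %in% EDGE_SCHEMA$edge_type, ][1, ]
    stop("schema violation: edge type '", off$edge_type, "' does not admit ",
         off$src_type, " -> ", off$dst_type)
  }
  dc <- (e$src_type == "drug" & e$dst_type == "cell_line") |
    (e$src_type == "cell_line" & e$dst_type == "drug")
  if (any(dc)) stop("schema violation: drugs and cell lines must not be directly connected")
  all_nodes <- unlist(lapply(names(g$nodes), function(tp)
    biohg_vertex(tp, g$nodes[[tp]])), use.names = FALSE)
  miss <- !(biohg_vertex(e$src_type, e$src_id) %in% all_nodes) |
    !(biohg_vertex(e$dst_type, e$dst_id) %in% all_nodes)
  if (any(miss)) {
    stop("edge endpoint not present as node: ", e$src_id[which(miss)[1]],
         " -> ", e$dst_id[which(miss)[1]])
  }
  pc <- e$edge_type == "protein_cell"
  if (any(is.na(e$weight[pc]))) stop("protein_cell edges must carry weights")
  if (any(!is.na(e$weight[!pc]))) stop("only protein_cell edges may carry weights")
  invisible(g)
}

# Apply a gene -> protein mapping to expression column names, dropping and
# counting unmapped genes.
map_expression_genes <- function(expr, gene_map = NULL) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (is.null(gene_map)) return(expr)
  idx <- match(colnames(expr), gene_map$gene_id)
  dropped <- sum(is.na(idx))
  if (dropped > 0L) {
    message(dropped, " expression gene(s) without a protein mapping dropped")
  }
  keep <- !is.na(idx)
  if (!sum(keep)) stop("no expression genes map to protein nodes")
  prot <- as.character(gene_map$protein_id[idx[keep]])
  if (anyDuplicated(prot)) stop("gene -> protein mapping is not injective on the kept genes")
  expr <- expr[, keep, drop = FALSE]
  colnames(expr) <- prot
  expr
}

#' Derive protein--cell-line edges from an expression matrix
#'
#' For each cell line, connects exactly the proteins whose expression value
#' is strictly greater than that cell line's mean expression; the expression
#' value becomes the edge weight.  Ties at the mean produce no edge, and a
#' constant row produces no edges (with a warning), since nothing exceeds
#' its own mean.
#'
#' @param expr numeric matrix, cell lines in rows, protein-mapped genes in
#'   columns.
#' @return data.frame of `protein_cell` edge records.
#' @export
derive_expression_edges <- function(expr) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (anyNA(expr) || any(!is.finite(expr))) stop("expression matrix must be finite")
  out <- vector("list", nrow(expr))
  for (i in seq_len(nrow(expr))) {
    row <- expr[i, ]
    keep <- row > mean(row)
    if (!any(keep)) {
      warning("cell line '", rownames(expr)[i],
              "' has no above-mean genes; zero expression edges emitted")
      next
    }
    out[[i]] <- data.frame(src_type = "protein", src_id = colnames(expr)[keep],
                           dst_type = "cell_line", dst_id = rownames(expr)[i],
                           edge_type = "protein_cell", weight = unname(row[keep]),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(src_type = character(), src_id = character(),
                      dst_type = character(), dst_id = character(),
                      edge_type = character(), weight = numeric())
  }
  out
}

## ---- queries -------------------------------------------------------------

#' @export
print.biohg <- function(x, ...) {
  nc <- biohg_node_counts(x)
  ec <- biohg_edge_counts(x)
  cat("<biohg> ", sum(nc), " nodes, ", sum(ec), " edges\n", sep = "")
  cat("  nodes:", paste(names(nc), nc, collapse = ", "), "\n")
  cat("  edges:", paste(names(ec), ec, collapse = ", "), "\n")
  invisible(x)
}

#' Per-type node counts of a heterogeneous graph
#' @param g a `biohg` object.
#' @return named integer vector over node types.
#' @export
biohg_node_counts <- function(g) vapply(g$nodes, length, integer(1))

#' Per-type edge counts of a heterogeneous graph
#' @param g a `biohg` object.
#' @return named integer vector over edge types.
#' @export
biohg_edge_counts <- function(g) {
  out <- integer(nrow(EDGE_SCHEMA))
  names(out) <- EDGE_SCHEMA$edge_type
  tb <- table(g$edges$edge_type)
  out[names(tb)] <- as.integer(tb)
  out
}

# Globally unique vertex names (IDs are unique only per type).  The empty
# case must short-circuit: paste() would recycle a zero-length id to "".
biohg_vertex <- function(type, id) {
  if (length(id) == 0L) return(character(0))
  paste(type, id, sep = "\r")
}

#' Convert a typed graph to an igraph over selected edge types
#'
#' All edges are treated as undirected for path queries.  Vertex names embed
#' the node type so IDs from different types cannot collide.
#'
#' @param g a `biohg` object.
#' @param edge_types character vector of edge types to include.
#' @return an undirected `igraph` graph containing every node of `g`.
#' @export
biohg_igraph <- function(g, edge_types = EDGE_SCHEMA$edge_type) {
  if (length(edge_types) == 0L) stop("edge_types must be non-empty")
  e <- g$edges[g$edges$edge_type %in% edge_types, , drop = FALSE]
  verts <- unlist(lapply(names(g$nodes), function(tp) biohg_vertex(tp, g$nodes[[tp]])))
  igraph::graph_from_data_frame(
    data.frame(from = biohg_vertex(e$src_type, e$src_id),
               to = biohg_vertex(e$dst_type, e$dst_id)),
    directed = FALSE,
    vertices = data.frame(name = verts))
}

#' Unweighted shortest-path hop counts from one node to a set of nodes
#'
#' Breadth-first distances over the union of the listed edge types, with all
#' edges treated as undirected; unreachable targets get `Inf`.
#'
#' @param g a `biohg` object.
#' @param src_type,src_id the source node.
#' @param dst_type,dst_ids the target node type and IDs.
#' @param edge_types edge types whose union defines the traversable graph.
#' @return named numeric vector of hop counts (Inf when unreachable).
#' @export
shortest_path_distance <- function(g, src_type, src_id, dst_type, dst_ids,
                                   edge_types = c("dti", "ppi")) {
  if (length(edge_types) == 0L) stop("edge_types must be non-empty")
  if (!src_id %in% g$nodes[[src_type]]) stop("source node not in graph: ", src_id)
  ig <- biohg_igraph(g, edge_types)
  d <- igraph::distances(ig, v = biohg_vertex(src_type, src_id),
                         to = biohg_vertex(dst_type, dst_ids))
  stats::setNames(as.numeric(d[1, ]), dst_ids)
}

#' Subgraph induced by all shortest source-to-sink paths
#'
#' Collects every node lying on any shortest path from any source node to the
#' sink over the protein--protein and drug--target edges, and returns the
#' induced heterogeneous subgraph (sources and sink always included).  When no
#' source reaches the sink the result is flagged via its `status` attribute.
#'
#' @param g a `biohg` object.
#' @param source_type,source_ids source nodes (e.g. predicted targets).
#' @param sink_type,sink_id the sink node (e.g. a disease-associated protein).
#' @param edge_types edge types the paths may traverse.
#' @return a `biohg` object with attribute `status` (`"ok"` or
#'   `"unreachable"`).
#' @export
mechanism_subgraph <- function(g, source_type, source_ids, sink_type, sink_id,
                               edge_types = c("ppi", "dti")) {
  ig <- biohg_igraph(g, edge_types)
  sinkv <- biohg_vertex(sink_type, sink_id)
  keep <- character(0)
  reached <- FALSE
  for (sid in source_ids) {
    sp <- suppressWarnings(
      igraph::all_shortest_paths(ig, from = biohg_vertex(source_type, sid),
                                 to = sinkv)$vpaths)
    if (length(sp) > 0L) {
      reached <- TRUE
      keep <- union(keep, unlist(lapply(sp, function(p) names(p))))
    }
  }
  keep <- union(keep, c(biohg_vertex(source_type, source_ids), sinkv))
  parts <- strsplit(keep, "\r", fixed = TRUE)
  ktype <- vapply(parts, `[[`, character(1), 1L)
  kid <- vapply(parts, `[[`, character(1), 2L)
  nodes <- lapply(NODE_TYPES, function(tp) sort(unique(kid[ktype == tp])))
  names(nodes) <- NODE_TYPES
  e <- g$edges
  inset <- function(tp, id) paste(tp, id, sep = "\r") %in% keep
  e <- e[e$edge_type %in% edge_types & inset(e$src_type, e$src_id) &
           inset(e$dst_type, e$dst_id), , drop = FALSE]
  rownames(e) <- NULL
  sub <- structure(list(nodes = nodes, edges = e,
                        drug_features = if (!is.null(g$drug_features))
                          g$drug_features[intersect(rownames(g$drug_features), nodes$drug), , drop = FALSE],
                        cell_features = NULL),
                   class = "biohg")
  attr(sub, "status") <- if (reached) "ok" else "unreachable"
  attr(sub, "sources") <- source_ids
  attr(sub, "sink") <- sink_id
  sub
}

## ---- serialization -------------------------------------------------------

#' Read/write a heterogeneous graph as a directory of TSV tables
#'
#' Layout (version 1): `nodes.tsv` (`node_type`, `node_id`), `edges.tsv`
#' (`src_type src_id dst_type dst_id edge_type weight`), optional
#' `drug_features.tsv` / `cell_features.tsv` (first column the node ID), and
#' `manifest.json` with the format version.
#'
#' @param g a `biohg` object.
#' @param path directory to create/read.
#' @return `write_biohg` returns `path` invisibly; `read_biohg` a `biohg`.
#' @export
write_biohg <- function(g, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  nodes <- do.call(rbind, lapply(names(g$nodes), function(tp) {
    if (!length(g$nodes[[tp]])) return(NULL)
    data.frame(node_type = tp, node_id = g$nodes[[tp]])
  }))
  utils::write.table(nodes, file.path(path, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(g$edges, file.path(path, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  wr_feat <- function(m, fn) {
    if (is.null(m)) return(invisible(NULL))
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(path, fn), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr_feat(g$drug_features, "drug_features.tsv")
  wr_feat(g$cell_features, "cell_features.tsv")
  jsonlite::write_json(list(format = "biohg", version = 1L),
                       file.path(path, "manifest.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_biohg
#' @export
read_biohg <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"))
  if (!identical(man$format, "biohg")) stop("not a biohg archive: ", path)
  nodes_df <- utils::read.delim(file.path(path, "nodes.tsv"),
                                colClasses = "character")
  edges <- utils::read.delim(file.path(path, "edges.tsv"),
                             colClasses = c(rep("character", 5L), "numeric"))
  nodes <- lapply(NODE_TYPES, function(tp)
    sort(nodes_df$node_id[nodes_df$node_type == tp]))
  names(nodes) <- NODE_TYPES
  rd_feat <- function(fn) {
    fp <- file.path(path, fn)
    if (!file.exists(fp)) return(NULL)
    df <- utils::read.delim(fp, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  g <- structure(list(nodes = nodes, edges = edges,
                      drug_features = rd_feat("drug_features.tsv"),
                      cell_features = rd_feat("cell_features.tsv")),
                 class = "biohg")
  validate_biohg(g)
  g
}

#' Read and write edge tables in the standard TSV layout
#'
#' Columns: `src_type src_id dst_type dst_id edge_type` and optional `weight`.
#'
#' @param path TSV file path.
#' @param edges edge data.frame in that layout.
#' @return `read_edge_table` returns the data.frame; `write_edge_table` the
#'   path, invisibly.
#' @export
read_edge_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("src_type", "src_id", "dst_type", "dst_id", "edge_type")
  if (!all(need %in% names(df))) {
    stop("edge table must have columns: ", paste(need, collapse = " "))
  }
  df$weight <- if ("weight" %in% names(df)) as.numeric(df$weight) else NA_real_
  df
}

#' @rdname read_edge_table
#' @export
write_edge_table <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix (first column the cell-line ID)
#' @param path TSV file with header; remaining columns are genes.
#' @return numeric matrix with cell lines as rows.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains missing values")
  m
}

#' Restrict a graph for cold-start training
#'
#' Removes the drug--target edges of held-out drugs and the protein--cell
#' edges of held-out cell lines, while keeping the nodes and their feature
#' vectors so that the fingerprint / expression encoding paths still apply.
#'
#' @param g a `biohg` object.
#' @param drop_drugs,drop_cells IDs whose relational edges are removed.
#' @return a `biohg` object.
#' @export
restrict_biohg <- function(g, drop_drugs = character(0), drop_cells = character(0)) {
  e <- g$edges
  e <- e[!(e$edge_type == "dti" & e$src_id %in% drop_drugs), , drop = FALSE]
  e <- e[!(e$edge_type == "protein_cell" & e$dst_id %in% drop_cells), , drop = FALSE]
  rownames(e) <- NULL
  g$edges <- e
  g
}
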