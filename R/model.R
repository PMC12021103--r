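# The heterogeneous message-passing model.
#
# Per layer, each protein / pathway / GO node is updated by the SUM of
# per-edge-type convolutions: GraphSAGE-style convolutions over the
# protein-protein, protein-pathway, protein-GO and (reversed) drug-target
# edge types, and a symmetric-normalized GCN convolution over the
# expression-derived protein-cell edges.  Drug and cell-line nodes emit
# messages but are never updated: a drug's representation is a learned
# linear map of its fingerprint (the cold-start path) and a cell line's is a
# learned linear projection of its expression profile.  Protein-cell edge
# weights are never consulted here -- only the unweighted incidence pattern.

#' Model hyperparameters for the heterogeneous GNN
#'
#' @param embed_dim node embedding width (all types share it).
#' @param n_layers number of message-passing layers.
#' @param aggregator neighborhood aggregator for the SAGE convolutions:
#'   `"mean"`, `"sum"` or `"pool"` (elementwise max; forward-only, not
#'   available during training).
#' @param dropout feature dropout rate in \[0, 1), applied to node features
#'   during training.
#' @param activation nonlinearity: `"relu"`, `"tanh"`, `"sigmoid"` or
#'   `"identity"`.
#' @param head_hidden hidden width of the MLP prediction heads.
#' @param drug_messages if `TRUE` (default) drug->protein messages flow along
#'   drug-target edges during convolution; set `FALSE` to confine drug
#'   information to the interaction-predictor loss.
#' @return an `hgnn_config` list.
#' @export
hgnn_config <- function(embed_dim = 16L, n_layers = 2L,
                        aggregator = c("mean", "sum", "pool"),
                        dropout = 0, activation = "relu",
                        head_hidden = 64L, drug_messages = TRUE) {
  aggregator <- match.arg(aggregator)
  stopifnot(embed_dim >= 1L, n_layers >= 1L, dropout >= 0, dropout < 1)
  structure(list(embed_dim = as.integer(embed_dim),
                 n_layers = as.integer(n_layers), aggregator = aggregator,
                 dropout = dropout, activation = activation,
                 head_hidden = as.integer(head_hidden),
                 drug_messages = isTRUE(drug_messages)),
            class = "hgnn_config")
}

## ---- functional layer primitives (also the oracle-checked surface) -------

#' GraphSAGE-style convolution for one node
#'
#' Computes `act(W %*% c(h_self, aggregate(neighbors)))`.  An empty
#' neighborhood aggregates to the zero vector, so the update degenerates to a
#' transform of the self embedding alone.
#'
#' @param h_self numeric vector, the node's current embedding (length d).
#' @param h_neighbors numeric matrix with one neighbor embedding per row
#'   (0-row matrix for an isolated node).
#' @param W weight matrix, `d_out x 2d`.
#' @param activation nonlinearity name.
#' @param aggregator `"mean"`, `"sum"` or `"pool"` (elementwise max).
#' @return numeric vector of length `d_out`.
#' @export
sage_layer <- function(h_self, h_neighbors, W, activation = "identity",
                       aggregator = "mean") {
  d <- length(h_self)
  if (!is.matrix(h_neighbors)) h_neighbors <- matrix(h_neighbors, ncol = d)
  stopifnot(ncol(h_neighbors) == d, ncol(W) == 2L * d)
  agg <- if (nrow(h_neighbors) == 0L) rep(0, d) else switch(aggregator,
    mean = colMeans(h_neighbors),
    sum = colSums(h_neighbors),
    pool = apply(h_neighbors, 2L, max),
    stop("unknown aggregator: ", aggregator))
  act <- .act_fun(activation)
  as.numeric(act(W %*% c(h_self, agg)))
}

#' Batched GraphSAGE convolution over a bipartite relation
#'
#' Row-vector convention: `act(cbind(H_dst, A_norm %*% H_src) %*% t(W))`
#' where `A_norm` encodes the chosen aggregator (row-normalized adjacency for
#' `"mean"`, raw adjacency for `"sum"`).  Rows with no neighbors aggregate to
#' zero.
#'
#' @param H_dst `n_dst x d` matrix of destination-node embeddings.
#' @param H_src `n_src x d` matrix of source-node embeddings.
#' @param A `n_dst x n_src` 0/1 adjacency (dense or sparse).
#' @param W `d_out x 2d` weight matrix.
#' @param activation,aggregator as in [sage_layer()].
#' @return `n_dst x d_out` matrix.
#' @export
sage_conv <- function(H_dst, H_src, A, W, activation = "identity",
                      aggregator = "mean") {
  act <- .act_fun(activation)
  if (aggregator == "pool") {
    agg <- t(vapply(seq_len(nrow(H_dst)), function(i) {
      nb <- which(A[i, ] > 0)
      if (!length(nb)) rep(0, ncol(H_src))
      else apply(H_src[nb, , drop = FALSE], 2L, max)
    }, numeric(ncol(H_src))))
    if (ncol(H_src) == 1L) agg <- matrix(agg, ncol = 1L)
  } else {
    An <- .agg_operator(A, aggregator)
    agg <- as.matrix(An %*% H_src)
  }
  act(cbind(H_dst, agg) %*% t(W))
}

#' Symmetric-normalized GCN convolution over a bipartite relation
#'
#' `act((S %*% H_src) %*% t(W))` with
#' `S[i, j] = A[i, j] / sqrt(deg(i) * deg(j))`; isolated destination nodes
#' receive the zero vector before the activation.  Edge weights play no role:
#' only the incidence pattern enters.
#'
#' @param H_src `n_src x d` source embeddings.
#' @param A `n_dst x n_src` 0/1 adjacency.
#' @param W `d_out x d` weight matrix.
#' @param activation nonlinearity name.
#' @return `n_dst x d_out` matrix.
#' @export
gcn_conv <- function(H_src, A, W, activation = "identity") {
  act <- .act_fun(activation)
  S <- .gcn_operator(A)
  act(as.matrix(S %*% H_src) %*% t(W))
}

#' Linear fingerprint-to-embedding transform for drugs
#'
#' The cold-start path: a drug with no edges in the graph is still
#' representable through `fingerprint %*% W_drug` (no bias, no activation).
#'
#' @param fingerprint numeric vector (length `F`) or `n x F` matrix.
#' @param W_drug `F x d` weight matrix.
#' @return embedding vector / matrix.
#' @export
drug_embed <- function(fingerprint, W_drug) {
  if (!is.matrix(fingerprint)) fingerprint <- matrix(fingerprint, nrow = 1L)
  if (ncol(fingerprint) != nrow(W_drug)) {
    stop("fingerprint length ", ncol(fingerprint),
         " does not match transform input ", nrow(W_drug))
  }
  fingerprint %*% W_drug
}

.act_fun <- function(name) {
  switch(name,
         identity = identity,
         relu = function(x) pmax(x, 0),
         tanh = tanh,
         sigmoid = stats::plogis,
         stop("unknown activation: ", name))
}

.as_sparse <- function(A) {
  if (!methods::is(A, "Matrix")) A <- Matrix::Matrix(A * 1.0, sparse = TRUE)
  methods::as(methods::as(A, "dMatrix"), "generalMatrix")
}

# Aggregation operator as a sparse matrix (mean: row-normalized, zero rows
# stay zero).
.agg_operator <- function(A, aggregator = "mean") {
  A <- .as_sparse(A)
  if (aggregator == "mean") {
    rs <- Matrix::rowSums(A)
    rs[rs == 0] <- 1
    A <- Matrix::Diagonal(x = 1 / rs) %*% A
  } else if (aggregator != "sum") stop("unsupported aggregator: ", aggregator)
  A
}

.gcn_operator <- function(A) {
  A <- .as_sparse(A)
  dd <- Matrix::rowSums(A)
  ds <- Matrix::colSums(A)
  dd[dd == 0] <- 1
  ds[ds == 0] <- 1
  Matrix::Diagonal(x = 1 / sqrt(dd)) %*% A %*% Matrix::Diagonal(x = 1 / sqrt(ds))
}

## ---- model assembly ------------------------------------------------------

# Sparse 0/1 adjacency (n_dst x n_src) for one relation of the graph.
.relation_adjacency <- function(g, edge_type, dst_type, dst_ids, src_type, src_ids,
                                reverse = FALSE) {
  e <- g$edges[g$edges$edge_type == edge_type, , drop = FALSE]
  if (reverse) {
    from <- e$dst_id; to <- e$src_id
  } else {
    from <- e$src_id; to <- e$dst_id
  }
  # rows: dst side receiving messages; cols: src side emitting
  i <- match(to, dst_ids)
  j <- match(from, src_ids)
  keep <- !is.na(i) & !is.na(j)
  A <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                            dims = c(length(dst_ids), length(src_ids)),
                            dimnames = list(dst_ids, src_ids))
  sign(A)   # collapse duplicate records to a 0/1 incidence pattern
}

#' Initialize a heterogeneous GNN on a graph
#'
#' Builds the fixed aggregation operators from the graph's edge pattern and
#' randomly initializes all learnable parameters: per-type node embeddings
#' for proteins, pathways and GO terms; the fingerprint transform for drugs;
#' the expression projection for cell lines; per-layer, per-edge-type
#' convolution weights; and the five MLP prediction heads (expression
#' comparator, response comparator, drug-target predictor, biological-process
#' predictor, response regressor).
#'
#' @param g a `biohg` with drug and cell features.
#' @param cfg an [hgnn_config()].
#' @param seed RNG seed for the initialization.
#' @return an `hgnn_model` list with elements `params` (named matrices),
#'   `ops` (sparse operators), `vocab` (node orderings) and `cfg`.
#' @export
hgnn_init <- function(g, cfg = hgnn_config(), seed = 1L) {
  if (cfg$aggregator == "pool") {
    stop("the pool aggregator is forward-only; train with mean or sum")
  }
  set.seed(as.integer(seed))
  d <- cfg$embed_dim
  vocab <- list(drug = g$nodes$drug, protein = g$nodes$protein,
                cell = g$nodes$cell_line, pathway = g$nodes$pathway,
                go = g$nodes$go_term)
  np <- length(vocab$protein); nw <- length(vocab$pathway); ng <- length(vocab$go)
  if (np == 0L) stop("graph has no protein nodes")
  if (is.null(g$drug_features) || is.null(g$cell_features)) {
    stop("the model needs drug fingerprints and cell expression features")
  }

  rmat <- function(nr, nc, scale = NULL) {
    if (is.null(scale)) scale <- sqrt(2 / (nr + nc))
    matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
  }
  # cell features enter as z-scores per gene (constant genes to zero),
  # mirroring the standardized expression the encoder expects
  cf <- g$cell_features
  if (nrow(cf) > 1L) {
    mu <- colMeans(cf)
    sdv <- apply(cf, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    cf <- sweep(sweep(cf, 2L, mu, "-"), 2L, sdv, "/")
  }
  params <- list(
    E_protein = rmat(np, d, 0.1),
    W_drug = rmat(ncol(g$drug_features), d),
    W_cell = rmat(ncol(g$cell_features), d)
  )
  if (nw > 0L) params$E_pathway <- rmat(nw, d, 0.1)
  if (ng > 0L) params$E_go <- rmat(ng, d, 0.1)

  # relations: name = c(receiver, conv kind)
  rel <- list(
    pr_from_pr = list(A = .relation_adjacency(g, "ppi", "protein", vocab$protein,
                                              "protein", vocab$protein),
                      kind = "sage", dst = "protein", src = "protein"),
    pw_from_pr = list(A = .relation_adjacency(g, "protein_pathway", "pathway",
                                              vocab$pathway, "protein", vocab$protein),
                      kind = "sage", dst = "pathway", src = "protein"),
    pr_from_pw = list(A = .relation_adjacency(g, "protein_pathway", "protein",
                                              vocab$protein, "pathway", vocab$pathway,
                                              reverse = TRUE),
                      kind = "sage", dst = "protein", src = "pathway"),
    go_from_pr = list(A = .relation_adjacency(g, "protein_go", "go", vocab$go,
                                              "protein", vocab$protein),
                      kind = "sage", dst = "go", src = "protein"),
    pr_from_go = list(A = .relation_adjacency(g, "protein_go", "protein",
                                              vocab$protein, "go", vocab$go,
                                              reverse = TRUE),
                      kind = "sage", dst = "protein", src = "go"),
    pr_from_dr = list(A = .relation_adjacency(g, "dti", "protein", vocab$protein,
                                              "drug", vocab$drug),
                      kind = "sage", dst = "protein", src = "drug"),
    pr_from_cl = list(A = .relation_adjacency(g, "protein_cell", "protein",
                                              vocab$protein, "cell", vocab$cell,
                                              reverse = TRUE),
                      kind = "gcn", dst = "protein", src = "cell")
  )
  # ppi is undirected: symmetrize its stored canonical direction
  rel$pr_from_pr$A <- sign(rel$pr_from_pr$A + Matrix::t(rel$pr_from_pr$A))
  if (!cfg$drug_messages) rel$pr_from_dr <- NULL
  rel <- Filter(function(r) Matrix::nnzero(r$A) > 0L, rel)

  ops <- lapply(rel, function(r) {
    S <- if (r$kind == "gcn") .gcn_operator(r$A) else .agg_operator(r$A, cfg$aggregator)
    list(S = S, tS = Matrix::t(S), kind = r$kind, dst = r$dst, src = r$src)
  })
  for (l in seq_len(cfg$n_layers)) {
    for (rn in names(ops)) {
      w_in <- if (ops[[rn]]$kind == "gcn") d else 2L * d
      params[[sprintf("W_%s_l%d", rn, l)]] <- rmat(w_in, d)
    }
  }

  hidden <- cfg$head_hidden
  mlp_params <- function(in_dim, out_dim = 1L) {
    list(W1 = rmat(in_dim, hidden), b1 = matrix(0, 1L, hidden),
         W2 = rmat(hidden, out_dim), b2 = matrix(0, 1L, out_dim))
  }
  heads <- list(expr = 3L * d, resp = 3L * d, dti = 2L * d, bp = 2L * d,
                reg = 2L * d)
  for (hn in names(heads)) {
    hp <- mlp_params(heads[[hn]])
    for (pn in names(hp)) params[[sprintf("H_%s_%s", hn, pn)]] <- hp[[pn]]
  }

  structure(list(params = params, ops = ops, vocab = vocab, cfg = cfg,
                 drug_features = g$drug_features,
                 cell_features = cf),
            class = "hgnn_model")
}

# Forward pass on the tape; returns ad nodes for the final per-type
# embedding matrices.  `training` switches feature dropout on.
hgnn_embeddings <- function(model, tape, params_nodes, training = FALSE) {
  cfg <- model$cfg
  drop <- function(nd) {
    if (!training || cfg$dropout <= 0) return(nd)
    mask <- matrix(stats::rbinom(length(nd$value), 1L, 1 - cfg$dropout) /
                     (1 - cfg$dropout), nrow(nd$value))
    ad_mask(tape, nd, mask)
  }
  P <- params_nodes
  h <- list(
    drug = drop(ad_matmul(tape, ad_const(tape, model$drug_features), P$W_drug)),
    cell = drop(ad_matmul(tape, ad_const(tape, model$cell_features), P$W_cell)),
    protein = drop(P$E_protein),
    pathway = if (!is.null(P$E_pathway)) drop(P$E_pathway),
    go = if (!is.null(P$E_go)) drop(P$E_go)
  )
  for (l in seq_len(cfg$n_layers)) {
    upd <- list()
    for (rn in names(model$ops)) {
      op <- model$ops[[rn]]
      src <- h[[op$src]]
      if (is.null(src)) next
      W <- P[[sprintf("W_%s_l%d", rn, l)]]
      agg <- ad_spmm(tape, op$S, op$tS, src)
      conv <- if (op$kind == "gcn") ad_matmul(tape, agg, W)
      else ad_matmul(tape, ad_cbind(tape, h[[op$dst]], agg), W)
      conv <- ad_activate(tape, conv, cfg$activation)
      upd[[op$dst]] <- if (is.null(upd[[op$dst]])) conv
      else ad_add(tape, upd[[op$dst]], conv)
    }
    for (tp in names(upd)) h[[tp]] <- upd[[tp]]
  }
  h
}

# One-hidden-layer MLP head on the tape.
mlp_head <- function(tape, P, prefix, X) {
  h1 <- ad_relu(tape, ad_add_bias(tape,
         ad_matmul(tape, X, P[[paste0("H_", prefix, "_W1")]]),
         P[[paste0("H_", prefix, "_b1")]]))
  ad_add_bias(tape, ad_matmul(tape, h1, P[[paste0("H_", prefix, "_W2")]]),
              P[[paste0("H_", prefix, "_b2")]])
}

# Wrap current parameter matrices as tape nodes.
wrap_params <- function(tape, params) {
  out <- lapply(names(params), function(nm) ad_param(tape, params[[nm]], nm))
  names(out) <- names(params)
  out
}

#' Compute final node embeddings of a trained model
#'
#' @param model an `hgnn_model`.
#' @param params optionally, a parameter list overriding `model$params`
#'   (e.g. a training checkpoint).
#' @return list of numeric matrices `drug`, `cell`, `protein`, `pathway`,
#'   `go`, with node IDs as rownames.
#' @export
hgnn_forward <- function(model, params = model$params) {
  tape <- ad_tape()
  h <- hgnn_embeddings(model, tape, wrap_params(tape, params), training = FALSE)
  out <- lapply(h, function(nd) if (!is.null(nd)) nd$value)
  rownames(out$drug) <- model$vocab$drug
  rownames(out$cell) <- model$vocab$cell
  rownames(out$protein) <- model$vocab$protein
  if (!is.null(out$pathway)) rownames(out$pathway) <- model$vocab$pathway
  if (!is.null(out$go)) rownames(out$go) <- model$vocab$go
  out
}

## ---- checkpoint serialization -------------------------------------------

#' Save / load a model checkpoint as a plain-text archive
#'
#' The checkpoint directory holds one TSV per parameter matrix, the model
#' configuration, and hashes of the node vocabularies; loading onto a graph
#' with a different vocabulary is refused.
#'
#' @param model an `hgnn_model` (with trained `params`).
#' @param path checkpoint directory.
#' @param extra optional named list of additional metadata to store (e.g.
#'   the response-head mode).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   restores the parameter list and config onto `model`.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(model$params)) {
    utils::write.table(model$params[[nm]],
                       file.path(path, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  meta <- list(cfg = unclass(model$cfg),
               params = names(model$params),
               vocab_hash = lapply(model$vocab, .vocab_hash),
               extra = extra)
  jsonlite::write_json(meta, file.path(path, "checkpoint.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param g the graph the checkpoint is being loaded onto.
#' @param cfg optional [hgnn_config()] override; default re-reads the stored
#'   configuration.
#' @export
load_checkpoint <- function(path, g, cfg = NULL) {
  meta <- jsonlite::read_json(file.path(path, "checkpoint.json"),
                              simplifyVector = TRUE)
  if (is.null(cfg)) {
    cfg <- do.call(hgnn_config, meta$cfg[setdiff(names(meta$cfg), character(0))])
  }
  model <- hgnn_init(g, cfg, seed = 1L)
  for (tp in names(model$vocab)) {
    if (!identical(.vocab_hash(model$vocab[[tp]]), meta$vocab_hash[[tp]])) {
      stop("checkpoint vocabulary mismatch for node type '", tp, "'")
    }
  }
  for (nm in meta$params) {
    m <- as.matrix(utils::read.table(file.path(path, paste0(nm, ".tsv")),
                                     sep = "\t"))
    dimnames(m) <- NULL
    if (!all(dim(m) == dim(model$params[[nm]]))) {
      stop("checkpoint parameter '", nm, "' has unexpected shape")
    }
    model$params[[nm]] <- m
  }
  model
}

.vocab_hash <- function(ids) {
  if (!length(ids)) return("empty")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(ids, f)
  unname(tools::md5sum(f))
}
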