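# Mechanism analysis: integrated-gradients attribution for the cell-state
# classifier, betweenness-centrality ranking of mechanism subgraphs, and
# GO-frequency / pathway-score summaries for ranked targets.

#' Integrated gradients attribution
#'
#' Approximates the path integral of the gradient of `f` along the straight
#' line from the baseline `x_prime` to `x` with an `m`-step left-point
#' Riemann sum:
#' `attr_i = (x_i - x'_i) * (1/m) * sum_{k=0}^{m-1} dF/dx_i(x' + k/m (x - x'))`.
#' The completeness residual `|sum(attr) - (F(x) - F(x'))|` is recorded; it
#' vanishes as `m` grows and is identically zero for linear `f`.
#'
#' @param f function mapping a feature vector to a scalar output (e.g. a
#'   classifier logit).
#' @param grad function mapping a feature vector to the gradient of `f`
#'   (same length as `x`).  For an [train_mlp_classifier()] object, pass
#'   `clf$logit` and `clf$grad`.
#' @param x the input to attribute.
#' @param x_prime reference input; default the all-zeros state.
#' @param m number of interpolation steps (>= 1).
#' @param feature_ids optional names for the attribution vector.
#' @return an `attribution` object: data.frame `feature_id`, `score`, with
#'   attributes `residual`, `m`, `baseline`, `delta_f`.
#' @export
integrated_gradients <- function(f, grad, x, x_prime = rep(0, length(x)),
                                 m = 50L, feature_ids = names(x)) {
  stopifnot(m >= 1L, length(x_prime) == length(x))
  diffv <- x - x_prime
  total <- numeric(length(x))
  for (k in 0:(m - 1L)) {
    gk <- grad(x_prime + (k / m) * diffv)
    if (any(!is.finite(gk))) stop("non-finite gradient at interpolation step ", k)
    total <- total + gk
  }
  scores <- diffv * total / m
  delta_f <- f(x) - f(x_prime)
  residual <- abs(sum(scores) - delta_f)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_along(x))
  out <- data.frame(feature_id = feature_ids, score = scores)
  attr(out, "residual") <- residual
  attr(out, "delta_f") <- delta_f
  attr(out, "m") <- m
  attr(out, "baseline") <- x_prime
  class(out) <- c("attribution", "data.frame")
  out
}

#' Betweenness centrality of graph nodes
#'
#' `g(v) = sum_{s != v != t} sigma_st(v) / sigma_st` where `sigma_st` counts
#' shortest paths between s and t and `sigma_st(v)` those passing through v
#' as an interior node.  Computed exactly (Brandes accumulation) on the
#' undirected union of the selected edge types; unreachable pairs contribute
#' nothing.  Unnormalized by default, matching the raw definition.
#'
#' @param g a `biohg` object.
#' @param edge_types edge types defining the traversable graph.
#' @param normalized divide by the number of ordered interior pairs.
#' @return data.frame `node_type`, `node_id`, `betweenness`, sorted
#'   decreasing.
#' @export
betweenness_centrality <- function(g, edge_types = c("ppi", "dti"),
                                   normalized = FALSE) {
  ig <- biohg_igraph(g, edge_types)
  b <- igraph::betweenness(ig, directed = FALSE, normalized = normalized)
  parts <- strsplit(names(b), "\r", fixed = TRUE)
  out <- data.frame(node_type = vapply(parts, `[[`, character(1), 1L),
                    node_id = vapply(parts, `[[`, character(1), 2L),
                    betweenness = as.numeric(b))
  out <- out[order(-out$betweenness, out$node_id), ]
  rownames(out) <- NULL
  out
}

#' Rank the mediators between a drug's predicted targets and a gene
#'
#' Takes the drug's top-k predicted targets (drug-target head), builds the
#' subgraph induced by all shortest paths from any of those targets to the
#' sink protein over the protein-protein and drug-target networks, computes
#' betweenness centrality inside that subgraph, and ranks the interior
#' (non-source, non-sink) nodes -- the candidate mechanistic mediators.
#'
#' @param fit an `hgnn_fit`.
#' @param g the `biohg` the model was trained on.
#' @param drug_id drug to explain.
#' @param gene_id sink protein (e.g. a disease-associated gene product).
#' @param top_k_targets number of predicted targets used as path sources.
#' @return list with `targets` (the predicted target IDs), `subgraph`, and
#'   `mediators` (data.frame `node_id`, `betweenness`, `rank`; empty with
#'   status `"unreachable"` when no source reaches the sink).
#' @export
explain_drug_gene <- function(fit, g, drug_id, gene_id, top_k_targets = 5L) {
  stopifnot(gene_id %in% g$nodes$protein)
  sc <- predict_dti(fit, drugs = drug_id)[1, ]
  targets <- names(sort(sc, decreasing = TRUE))[seq_len(min(top_k_targets, length(sc)))]
  sub <- mechanism_subgraph(g, "protein", targets, "protein", gene_id)
  if (identical(attr(sub, "status"), "unreachable")) {
    return(list(targets = targets, subgraph = sub,
                mediators = data.frame(node_id = character(),
                                       betweenness = numeric(), rank = integer()),
                status = "unreachable"))
  }
  bc <- betweenness_centrality(sub, edge_types = c("ppi", "dti"))
  interior <- bc[bc$node_type == "protein" &
                   !bc$node_id %in% c(targets, gene_id), , drop = FALSE]
  interior <- interior[order(-interior$betweenness, interior$node_id), ]
  mediators <- data.frame(node_id = interior$node_id,
                          betweenness = interior$betweenness,
                          rank = seq_len(nrow(interior)))
  list(targets = targets, subgraph = sub, mediators = mediators, status = "ok")
}

#' Mechanism-of-action summary for a set of ranked targets
#'
#' Two complementary tables for the top-ranked predicted targets of a drug:
#' the occurrence frequency of their GO annotations (how often each GO term
#' is attached to the top targets), and pathways ranked by the mean
#' biological-process-predictor score against those targets.
#'
#' @param g a `biohg` object.
#' @param fit an `hgnn_fit` (for the biological-process head).
#' @param ranked_targets character vector of protein IDs, best first.
#' @param top_n how many leading targets to summarize.
#' @return list with `go_frequency` (data.frame `go_id`, `count`, sorted
#'   decreasing) and `pathway_scores` (data.frame `pathway_id`,
#'   `mean_score`, sorted decreasing); both empty for `top_n = 0`.
#' @export
moa_summary <- function(g, fit, ranked_targets, top_n = 10L) {
  top <- utils::head(ranked_targets, top_n)
  if (!length(top)) {
    return(list(go_frequency = data.frame(go_id = character(), count = integer()),
                pathway_scores = data.frame(pathway_id = character(),
                                            mean_score = numeric())))
  }
  ge <- g$edges[g$edges$edge_type == "protein_go" & g$edges$src_id %in% top, ]
  no_go <- setdiff(top, ge$src_id)
  if (length(no_go)) {
    message(length(no_go), " target(s) with no GO annotation contribute nothing")
  }
  go_frequency <- if (nrow(ge)) {
    tb <- sort(table(ge$dst_id), decreasing = TRUE)
    data.frame(go_id = names(tb), count = as.integer(tb))
  } else data.frame(go_id = character(), count = integer())

  pw <- g$nodes$pathway
  pathway_scores <- if (length(pw)) {
    sc <- stats::plogis(predict_bioprocess(fit, proteins = top, pathways = pw))
    ms <- colMeans(sc)
    ord <- order(-ms, pw)
    data.frame(pathway_id = pw[ord], mean_score = as.numeric(ms[ord]))
  } else data.frame(pathway_id = character(), mean_score = numeric())
  list(go_frequency = go_frequency, pathway_scores = pathway_scores)
}

#' Write an attribution vector as a ranked TSV (`gene_id score rank`)
#' @param attribution an `attribution` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_attribution <- function(attribution, path) {
  o <- order(-abs(attribution$score))
  out <- data.frame(gene_id = attribution$feature_id[o],
                    score = attribution$score[o],
                    rank = seq_along(o))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
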