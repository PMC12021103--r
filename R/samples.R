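# Training-sample streams: value-comparison triples, network-based negative
# sampling for interaction pairs, and the four cross-validation scenarios.

#' Build value-comparison triples within each context
#'
#' Reformulates value fitting (drug response, gene expression) as pairwise
#' comparison: for two entities measured in the same context (cell line), the
#' label is 1 when the first value is strictly larger.  Pairs whose absolute
#' difference does not exceed `margin` are excluded, which both removes ties
#' and (for a positive margin) absorbs assay noise.
#'
#' @param value_table data.frame with columns `entity_id`, `context_id`,
#'   `value`.
#' @param margin minimum absolute value difference for a pair to be kept.
#' @param max_per_context cap on triples emitted per context (`Inf` = all).
#' @param seed RNG seed for pair subsampling and label-side randomization.
#' @return data.frame `entity_a`, `context_id`, `entity_b`, `label` with
#'   `label = 1` iff `value(entity_a) > value(entity_b)`.
#' @export
make_comparison_triples <- function(value_table, margin = 0,
                                    max_per_context = Inf, seed = 1L) {
  stopifnot(all(c("entity_id", "context_id", "value") %in% names(value_table)))
  set.seed(as.integer(seed))
  out <- lapply(split(value_table, value_table$context_id), function(df) {
    if (nrow(df) < 2L) {
      message("context '", df$context_id[1], "' has fewer than 2 entities; skipped")
      return(NULL)
    }
    n <- nrow(df)
    pairs <- utils::combn(n, 2L)
    keep <- abs(df$value[pairs[1, ]] - df$value[pairs[2, ]]) > margin
    pairs <- pairs[, keep, drop = FALSE]
    if (!ncol(pairs)) return(NULL)
    if (ncol(pairs) > max_per_context) {
      pairs <- pairs[, sample.int(ncol(pairs), max_per_context), drop = FALSE]
    }
    # randomize which side is entity_a so labels are balanced
    flip <- sample(c(TRUE, FALSE), ncol(pairs), replace = TRUE)
    a <- ifelse(flip, pairs[2, ], pairs[1, ])
    b <- ifelse(flip, pairs[1, ], pairs[2, ])
    data.frame(entity_a = df$entity_id[a], context_id = df$context_id[1],
               entity_b = df$entity_id[b],
               label = as.integer(df$value[a] > df$value[b]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(entity_a = character(), context_id = character(),
                      entity_b = character(), label = integer())
  }
  rownames(out) <- NULL
  out
}

#' Network-distance negative sampling for interaction pairs
#'
#' Positives are the existing graph edges of the requested pair type.  For
#' each anchor (drug for `dti`, pathway for `protein_pathway`), candidate
#' negatives are partner proteins whose shortest-path distance from the
#' anchor -- over the union of the pair's own edge type and the PPI network --
#' is at least `d_min` hops (unreachable counts as infinite, hence eligible).
#' Sampled negatives never collide with positive edges.
#'
#' @param g a `biohg` object.
#' @param pair_type `"dti"` or `"protein_pathway"`.
#' @param d_min minimum hop distance for a negative candidate (default 3,
#'   which excludes direct partners and shared-neighbor proteins).
#' @param ratio negatives sampled per positive, per anchor.
#' @param seed RNG seed.
#' @return data.frame `src_id`, `dst_id`, `label` (1 for positives, 0 for
#'   sampled negatives), `pair_type`.
#' @export
sample_negatives <- function(g, pair_type = c("dti", "protein_pathway"),
                             d_min = 3L, ratio = 1, seed = 1L) {
  pair_type <- match.arg(pair_type)
  set.seed(as.integer(seed))
  e <- g$edges[g$edges$edge_type == pair_type, , drop = FALSE]
  if (!nrow(e)) stop("no positive edges of type ", pair_type, " in graph")
  # anchors are the non-protein side of the pair
  if (pair_type == "dti") {
    anchors <- split(e$dst_id, e$src_id)      # drug -> its target proteins
    anchor_type <- "drug"
  } else {
    anchors <- split(e$src_id, e$dst_id)      # pathway -> its member proteins
    anchor_type <- "pathway"
  }
  proteins <- g$nodes$protein
  ig <- biohg_igraph(g, c(pair_type, "ppi"))
  pos <- data.frame(src_id = if (pair_type == "dti") e$src_id else e$dst_id,
                    dst_id = if (pair_type == "dti") e$dst_id else e$src_id,
                    label = 1L, pair_type = pair_type)
  negs <- lapply(names(anchors), function(a) {
    d <- igraph::distances(ig, v = biohg_vertex(anchor_type, a),
                           to = biohg_vertex("protein", proteins))[1, ]
    cand <- proteins[d >= d_min]
    cand <- setdiff(cand, anchors[[a]])
    if (!length(cand)) {
      warning("anchor '", a, "' has no candidate at distance >= ", d_min,
              "; skipped")
      return(NULL)
    }
    k <- min(length(cand), ceiling(ratio * length(anchors[[a]])))
    data.frame(src_id = a, dst_id = sample(cand, k), label = 0L,
               pair_type = pair_type)
  })
  out <- rbind(pos, do.call(rbind, negs))
  rownames(out) <- NULL
  out
}

#' Cross-validation folds for the four evaluation scenarios
#'
#' * `warm`: the (drug, cell) pairs themselves are partitioned at random.
#' * `cold_cell` / `cold_drug`: the cell-line / drug IDs are partitioned, so
#'   every test pair involves an unseen cell (drug).
#' * `cold_both`: drugs and cells are partitioned independently; fold k's
#'   test set contains pairs whose drug AND cell are both in fold k's held-out
#'   sets, its training set excludes every pair touching a held-out drug or
#'   cell, and the remaining mixed pairs are used in neither role.
#'
#' @param response_table data.frame with columns `drug_id`, `cell_id`
#'   (and typically `value`).
#' @param scenario one of `"warm"`, `"cold_cell"`, `"cold_drug"`,
#'   `"cold_both"`.
#' @param n_folds number of folds (default 20).
#' @param seed RNG seed.
#' @return object of class `response_folds`: list of folds, each with integer
#'   row indices `train` and `test` into `response_table`.
#' @export
make_splits <- function(response_table,
                        scenario = c("warm", "cold_cell", "cold_drug", "cold_both"),
                        n_folds = 20L, seed = 1L) {
  scenario <- match.arg(scenario)
  if (!nrow(response_table)) stop("response table is empty")
  set.seed(as.integer(seed))
  n <- nrow(response_table)
  partition <- function(ids) {
    ids <- sample(ids)
    split(ids, rep_len(seq_len(n_folds), length(ids)))
  }
  drugs <- unique(response_table$drug_id)
  cells <- unique(response_table$cell_id)
  if (scenario %in% c("cold_drug", "cold_both") && length(drugs) < n_folds) {
    stop("fewer distinct drugs (", length(drugs), ") than folds (", n_folds, ")")
  }
  if (scenario %in% c("cold_cell", "cold_both") && length(cells) < n_folds) {
    stop("fewer distinct cell lines (", length(cells), ") than folds (", n_folds, ")")
  }
  folds <- switch(scenario,
    warm = {
      fold_of <- rep_len(seq_len(n_folds), n)[sample.int(n)]
      lapply(seq_len(n_folds), function(k)
        list(train = which(fold_of != k), test = which(fold_of == k)))
    },
    cold_cell = {
      cf <- partition(cells)
      lapply(cf, function(held) {
        te <- response_table$cell_id %in% held
        list(train = which(!te), test = which(te))
      })
    },
    cold_drug = {
      df <- partition(drugs)
      lapply(df, function(held) {
        te <- response_table$drug_id %in% held
        list(train = which(!te), test = which(te))
      })
    },
    cold_both = {
      df <- partition(drugs)
      cf <- partition(cells)
      lapply(seq_len(n_folds), function(k) {
        d_held <- response_table$drug_id %in% df[[k]]
        c_held <- response_table$cell_id %in% cf[[k]]
        list(train = which(!d_held & !c_held), test = which(d_held & c_held))
      })
    })
  structure(folds, class = "response_folds", scenario = scenario,
            n = n, seed = as.integer(seed))
}

#' Assert that a fold set is free of cold-start leakage
#'
#' Exhaustively checks, for every fold, that test drugs (cell lines) never
#' appear in that fold's training rows under the cold scenarios, and that the
#' test sets partition the table under the warm scenario.
#'
#' @param folds a `response_folds` object.
#' @param response_table the table the folds index into.
#' @return `TRUE` invisibly; errors on the first violation.
#' @export
check_split_leakage <- function(folds, response_table) {
  scenario <- attr(folds, "scenario")
  for (k in seq_along(folds)) {
    tr <- response_table[folds[[k]]$train, ]
    te <- response_table[folds[[k]]$test, ]
    if (length(intersect(folds[[k]]$train, folds[[k]]$test))) {
      stop("fold ", k, ": train and test overlap")
    }
    if (scenario %in% c("cold_drug", "cold_both") &&
        length(intersect(unique(te$drug_id), unique(tr$drug_id)))) {
      stop("fold ", k, ": test drug leaks into training")
    }
    if (scenario %in% c("cold_cell", "cold_both") &&
        length(intersect(unique(te$cell_id), unique(tr$cell_id)))) {
      stop("fold ", k, ": test cell line leaks into training")
    }
  }
  if (scenario == "warm") {
    test_all <- sort(unlist(lapply(folds, `[[`, "test")))
    if (!identical(test_all, seq_len(attr(folds, "n")))) {
      stop("warm folds do not partition the response table")
    }
  }
  invisible(TRUE)
}

#' Serialize folds as a TSV of `drug_id cell_id fold role` rows
#' @param folds a `response_folds` object.
#' @param response_table the indexed table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_splits <- function(folds, response_table, path) {
  rows <- lapply(seq_along(folds), function(k) {
    rbind(data.frame(drug_id = response_table$drug_id[folds[[k]]$train],
                     cell_id = response_table$cell_id[folds[[k]]$train],
                     fold = k, role = "train"),
          data.frame(drug_id = response_table$drug_id[folds[[k]]$test],
                     cell_id = response_table$cell_id[folds[[k]]$test],
                     fold = k, role = "test"))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
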