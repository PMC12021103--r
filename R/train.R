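# Multi-task optimization: joint representation learning over the four
# sample streams, then a scalar response head fitted on the frozen
# embeddings, with early stopping on validation rank correlation.

#' Numerically stabilized mean binary cross-entropy with logits
#'
#' `mean(-(y * log(sigmoid(x)) + (1 - y) * log(1 - sigmoid(x))))`, computed
#' in the overflow-safe form `max(x, 0) - x y + log(1 + exp(-|x|))`.
#'
#' @param logits numeric vector of raw scores.
#' @param labels 0/1 vector of the same length.
#' @return scalar loss.
#' @export
bce_with_logits <- function(logits, labels) {
  if (length(logits) == 0L) stop("bce loss on an empty batch")
  stopifnot(length(logits) == length(labels), all(labels %in% c(0, 1)))
  mean(pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits))))
}

#' Weighted multi-task loss
#'
#' `w_pc * loss_pc + w_dc * loss_dc + w_dpi * loss_dpi +
#'  w_pro_path * loss_pro_path`, where the streams are the expression
#' comparator (`pc`), the response comparator (`dc`), the drug-target
#' predictor (`dpi`) and the biological-process predictor (`pro_path`).
#'
#' @param stream_losses named numeric vector with elements `pc`, `dc`,
#'   `dpi`, `pro_path`.
#' @param weights nonnegative weights in the same naming; at least one > 0.
#' @return scalar total loss.
#' @export
total_loss <- function(stream_losses,
                       weights = c(pc = 1, dc = 1, dpi = 1, pro_path = 1)) {
  nms <- c("pc", "dc", "dpi", "pro_path")
  stopifnot(all(nms %in% names(stream_losses)), all(nms %in% names(weights)))
  if (all(weights[nms] <= 0)) stop("at least one loss weight must be positive")
  bad <- nms[!is.finite(stream_losses[nms])]
  if (length(bad)) stop("non-finite loss in stream(s): ", paste(bad, collapse = ", "))
  sum(weights[nms] * stream_losses[nms])
}

#' Training hyperparameters
#'
#' @param lr Adam learning rate (default 0.001).
#' @param weight_decay L2 weight decay passed to Adam (default 1e-6).
#' @param max_epochs,patience early-stopping budget: training stops once the
#'   validation rank correlation has not improved for `patience` epochs.
#' @param min_epochs warm-up period during which early stopping is inactive
#'   (the validation signal of a full-batch run is noisy at first; the best
#'   checkpoint is still tracked from epoch 1).
#' @param loss_weights named weights `pc`, `dc`, `dpi`, `pro_path`.
#' @param sample_sizes named list of per-epoch sample caps for the streams
#'   `expr`, `resp`, `dti`, `pp` (`Inf` = use all).
#' @param resample_each_epoch if `TRUE`, stream subsamples are redrawn each
#'   epoch; default fixes them once per run.
#' @param n_ref_drugs reference drugs per cell used to turn the pairwise
#'   response comparator into a per-pair score (win rate) for validation.
#' @param stage2_epochs,stage2_patience budget for the frozen-embedding
#'   response head fit.
#' @param joint if `TRUE`, the scalar response head is trained in-loop with
#'   the comparison losses instead of on frozen embeddings.
#' @param seed RNG seed controlling initialization and all sampling.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 0.001, weight_decay = 1e-6, max_epochs = 150L,
                         patience = 25L, min_epochs = 50L,
                         loss_weights = c(pc = 1, dc = 1, dpi = 1, pro_path = 1),
                         sample_sizes = list(expr = 2000L, resp = 2000L,
                                             dti = Inf, pp = Inf),
                         resample_each_epoch = FALSE, n_ref_drugs = 10L,
                         stage2_epochs = 300L, stage2_patience = 25L,
                         joint = FALSE, seed = 1L) {
  stopifnot(lr > 0, patience >= 1L, max_epochs >= 1L)
  structure(list(lr = lr, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 loss_weights = loss_weights,
                 sample_sizes = sample_sizes,
                 resample_each_epoch = isTRUE(resample_each_epoch),
                 n_ref_drugs = as.integer(n_ref_drugs),
                 stage2_epochs = as.integer(stage2_epochs),
                 stage2_patience = as.integer(stage2_patience),
                 joint = isTRUE(joint), seed = as.integer(seed)),
            class = "train_config")
}

#' Early-stopping rule
#'
#' Training stops after the first epoch (past the warm-up) at which the best
#' validation epoch lies `patience` or more epochs in the past.
#'
#' @param epoch current epoch (1-based).
#' @param best_epoch epoch of the best validation value so far (0 = none).
#' @param patience epochs without improvement tolerated.
#' @param min_epochs warm-up period during which stopping is inactive.
#' @return `TRUE` when training should stop after this epoch.
#' @export
early_stop_reached <- function(epoch, best_epoch, patience, min_epochs = 0L) {
  best_epoch > 0L && epoch >= min_epochs && (epoch - best_epoch) >= patience
}

#' Assemble the four training-sample streams from a graph and response table
#'
#' Expression comparison triples come from the stored protein-cell edge
#' weights (the one place those weights are consumed); response comparison
#' triples from the training response pairs; drug-target and
#' protein-pathway pairs from network-distance negative sampling.
#'
#' @param g a `biohg` object.
#' @param response_table training response rows (`drug_id`, `cell_id`,
#'   `value`).
#' @param margin_expr margin for the expression comparator (absorbs assay
#'   noise); response comparisons use margin 0.
#' @param d_min,neg_ratio negative-sampling controls (see
#'   [sample_negatives()]).
#' @param max_expr_per_cell,max_resp_per_cell caps on comparison triples
#'   per cell line.
#' @param seed RNG seed.
#' @return named list of streams `expr`, `resp`, `dti`, `pp`.
#' @export
build_streams <- function(g, response_table, margin_expr = 0.1, d_min = 3L,
                          neg_ratio = 1, max_expr_per_cell = 200L,
                          max_resp_per_cell = 200L, seed = 1L) {
  pc <- g$edges[g$edges$edge_type == "protein_cell", , drop = FALSE]
  expr_tbl <- data.frame(entity_id = pc$src_id, context_id = pc$dst_id,
                         value = pc$weight)
  resp_tbl <- data.frame(entity_id = response_table$drug_id,
                         context_id = response_table$cell_id,
                         value = response_table$value)
  list(
    expr = make_comparison_triples(expr_tbl, margin = margin_expr,
                                   max_per_context = max_expr_per_cell,
                                   seed = seed),
    resp = make_comparison_triples(resp_tbl, margin = 0,
                                   max_per_context = max_resp_per_cell,
                                   seed = seed + 1L),
    dti = sample_negatives(g, "dti", d_min = d_min, ratio = neg_ratio,
                           seed = seed + 2L),
    pp = sample_negatives(g, "protein_pathway", d_min = d_min,
                          ratio = neg_ratio, seed = seed + 3L)
  )
}

# Stream losses on the tape for the current embeddings.
.stream_loss_nodes <- function(model, tape, P, h, streams) {
  v <- model$vocab
  gather3 <- function(Ea, ia, Ec, ic, Eb, ib) {
    ad_cbind(tape, ad_rows(tape, Ea, ia), ad_rows(tape, Ec, ic),
             ad_rows(tape, Eb, ib))
  }
  out <- list()
  if (nrow(streams$expr)) {
    X <- gather3(h$protein, match(streams$expr$entity_a, v$protein),
                 h$cell, match(streams$expr$context_id, v$cell),
                 h$protein, match(streams$expr$entity_b, v$protein))
    out$pc <- ad_bce_logits(tape, mlp_head(tape, P, "expr", X), streams$expr$label)
  }
  if (nrow(streams$resp)) {
    X <- gather3(h$drug, match(streams$resp$entity_a, v$drug),
                 h$cell, match(streams$resp$context_id, v$cell),
                 h$drug, match(streams$resp$entity_b, v$drug))
    out$dc <- ad_bce_logits(tape, mlp_head(tape, P, "resp", X), streams$resp$label)
  }
  if (nrow(streams$dti)) {
    X <- ad_cbind(tape, ad_rows(tape, h$drug, match(streams$dti$src_id, v$drug)),
                  ad_rows(tape, h$protein, match(streams$dti$dst_id, v$protein)))
    out$dpi <- ad_bce_logits(tape, mlp_head(tape, P, "dti", X), streams$dti$label)
  }
  if (nrow(streams$pp)) {
    X <- ad_cbind(tape, ad_rows(tape, h$protein, match(streams$pp$dst_id, v$protein)),
                  ad_rows(tape, h$pathway, match(streams$pp$src_id, v$pathway)))
    out$pro_path <- ad_bce_logits(tape, mlp_head(tape, P, "bp", X), streams$pp$label)
  }
  out
}

.subsample_stream <- function(df, k) {
  if (!is.finite(k) || nrow(df) <= k) return(df)
  df[sample.int(nrow(df), k), , drop = FALSE]
}

# Win-rate response score: probability, averaged over reference drugs, that
# the comparator ranks `drug` above the reference in the same cell.  Higher
# score tracks higher response value (lnIC50).
comparator_scores <- function(model, params, emb, pairs, ref_drugs) {
  v <- model$vocab
  n <- nrow(pairs)
  nr <- length(ref_drugs)
  ia <- rep(match(pairs$drug_id, v$drug), each = nr)
  ic <- rep(match(pairs$cell_id, v$cell), each = nr)
  ib <- rep(match(ref_drugs, v$drug), times = n)
  X <- cbind(emb$drug[ia, , drop = FALSE], emb$cell[ic, , drop = FALSE],
             emb$drug[ib, , drop = FALSE])
  logit <- .mlp_numeric(params, "resp", X)
  rowMeans(matrix(stats::plogis(logit), nrow = n, byrow = TRUE))
}

.mlp_numeric <- function(params, prefix, X) {
  h1 <- pmax(sweep(X %*% params[[paste0("H_", prefix, "_W1")]], 2L,
                   as.numeric(params[[paste0("H_", prefix, "_b1")]]), "+"), 0)
  as.numeric(sweep(h1 %*% params[[paste0("H_", prefix, "_W2")]], 2L,
                   as.numeric(params[[paste0("H_", prefix, "_b2")]]), "+"))
}

#' Train the heterogeneous GNN
#'
#' Stage 1 jointly minimizes the weighted sum of the four stream losses with
#' Adam, monitoring the validation rank correlation of the response task
#' (computed from the pairwise comparator via a reference-drug win-rate
#' score) and early-stopping on it.  Stage 2 fits the scalar response
#' regressor head on the frozen stage-1 embeddings.  Fully deterministic
#' given the seed.
#'
#' @param model an [hgnn_init()] model.
#' @param streams output of [build_streams()] on the training rows.
#' @param train_pairs,val_pairs response rows (`drug_id`, `cell_id`,
#'   `value`); validation must be disjoint from training.
#' @param tc a [train_config()].
#' @return an `hgnn_fit`: the model with trained parameters, the per-epoch
#'   history, and the best epoch.
#' @export
train_hgnn <- function(model, streams, train_pairs, val_pairs,
                       tc = train_config()) {
  set.seed(tc$seed)
  params <- model$params
  state <- adam_state(params)
  ref_drugs <- unique(train_pairs$drug_id)
  if (length(ref_drugs) > tc$n_ref_drugs) {
    ref_drugs <- sample(ref_drugs, tc$n_ref_drugs)
  }
  stream_names <- c(expr = "expr", resp = "resp", dti = "dti", pp = "pp")
  fixed <- lapply(names(stream_names), function(sn)
    .subsample_stream(streams[[sn]], tc$sample_sizes[[sn]]))
  names(fixed) <- names(stream_names)

  history <- data.frame(epoch = integer(), loss = numeric(), val_scc = numeric())
  best <- list(scc = -Inf, epoch = 0L, params = params)
  for (epoch in seq_len(tc$max_epochs)) {
    batch <- if (tc$resample_each_epoch) {
      bs <- lapply(names(stream_names), function(sn)
        .subsample_stream(streams[[sn]], tc$sample_sizes[[sn]]))
      names(bs) <- names(stream_names)
      bs
    } else fixed
    tape <- ad_tape()
    P <- wrap_params(tape, params)
    h <- hgnn_embeddings(model, tape, P, training = TRUE)
    losses <- .stream_loss_nodes(model, tape, P, h, batch)
    if (tc$joint && nrow(train_pairs)) {
      v <- model$vocab
      X <- ad_cbind(tape,
                    ad_rows(tape, h$drug, match(train_pairs$drug_id, v$drug)),
                    ad_rows(tape, h$cell, match(train_pairs$cell_id, v$cell)))
      losses$reg <- ad_mse(tape, mlp_head(tape, P, "reg", X), train_pairs$value)
    }
    w <- vapply(names(losses), function(nm)
      if (nm == "reg") 1 else unname(tc$loss_weights[nm]), numeric(1))
    lvals <- vapply(losses, function(nd) as.numeric(nd$value), numeric(1))
    if (any(!is.finite(lvals))) {
      stop("divergent loss in stream(s) ",
           paste(names(lvals)[!is.finite(lvals)], collapse = ", "),
           " at epoch ", epoch, "; last finite epoch: ", epoch - 1L)
    }
    total <- ad_weighted_sum(tape, unname(losses), w)
    grads <- ad_backward(tape, total)
    st <- adam_step(params, grads, state, lr = tc$lr,
                    weight_decay = tc$weight_decay)
    params <- st$params
    state <- st$state

    emb <- hgnn_forward(model, params)
    val_scc <- if (nrow(val_pairs)) {
      sc <- comparator_scores(model, params, emb, val_pairs, ref_drugs)
      suppressWarnings(scc(sc, val_pairs$value))
    } else NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = as.numeric(total$value),
                                         val_scc = val_scc))
    if (!is.na(val_scc) && val_scc > best$scc) {
      best <- list(scc = val_scc, epoch = epoch, params = params)
    }
    if (is.na(val_scc)) best$params <- params
    if (early_stop_reached(epoch, best$epoch, tc$patience, tc$min_epochs)) break
  }
  model$params <- best$params
  fit <- list(model = model, history = history, best_epoch = best$epoch,
              train_config = tc)
  class(fit) <- "hgnn_fit"
  fit$embeddings <- hgnn_forward(model)
  fit <- fit_response_head(fit, train_pairs, val_pairs, tc, mode = "regression")
  fit
}

#' Fit the scalar response head on frozen embeddings
#'
#' Refits the response head of a trained model without touching the
#' representation: `"regression"` fits the lnIC50-scale regressor,
#' `"classification"` a sensitive/resistant classifier on labels
#' `value < class_threshold` (default -2 on the lnIC50 scale), the mode used
#' for zero-shot phenotypic screening.
#'
#' @param fit an `hgnn_fit` from [train_hgnn()].
#' @param train_pairs,val_pairs response rows (`drug_id`, `cell_id`,
#'   `value`).
#' @param tc a [train_config()] (defaults to the one used for the fit).
#' @param mode `"regression"` or `"classification"`.
#' @param class_threshold sensitivity threshold for classification labels.
#' @return the `hgnn_fit` with the refitted head and `response_mode` set.
#' @export
fit_response_head <- function(fit, train_pairs, val_pairs, tc = fit$train_config,
                              mode = c("regression", "classification"),
                              class_threshold = -2) {
  mode <- match.arg(mode)
  model <- fit$model
  emb <- fit$embeddings
  v <- model$vocab
  Z <- cbind(emb$drug[match(train_pairs$drug_id, v$drug), , drop = FALSE],
             emb$cell[match(train_pairs$cell_id, v$cell), , drop = FALSE])
  Zv <- cbind(emb$drug[match(val_pairs$drug_id, v$drug), , drop = FALSE],
              emb$cell[match(val_pairs$cell_id, v$cell), , drop = FALSE])
  y <- train_pairs$value
  yv <- val_pairs$value
  if (mode == "classification") {
    y <- as.integer(train_pairs$value < class_threshold)
    yv <- as.integer(val_pairs$value < class_threshold)
  }
  hp <- grep("^H_reg_", names(model$params), value = TRUE)
  params <- model$params[hp]
  state <- adam_state(params)
  best <- list(crit = -Inf, params = params, epoch = 0L)
  for (epoch in seq_len(tc$stage2_epochs)) {
    tape <- ad_tape()
    P <- wrap_params(tape, params)
    names(P) <- names(params)
    out <- mlp_head(tape, P, "reg", ad_const(tape, Z))
    loss <- if (mode == "regression") ad_mse(tape, out, y)
    else ad_bce_logits(tape, out, y)
    grads <- ad_backward(tape, loss)
    st <- adam_step(params, grads, state, lr = 0.01,
                    weight_decay = tc$weight_decay)
    params <- st$params
    state <- st$state
    crit <- if (!nrow(val_pairs)) -as.numeric(loss$value) else {
      pv <- .mlp_numeric(params, "reg", Zv)
      if (mode == "regression") suppressWarnings(scc(pv, yv))
      else -bce_with_logits(pv, yv)
    }
    if (!is.na(crit) && crit > best$crit) {
      best <- list(crit = crit, params = params, epoch = epoch)
    }
    if (early_stop_reached(epoch, best$epoch, tc$stage2_patience, 0L)) break
  }
  for (nm in hp) fit$model$params[[nm]] <- best$params[[nm]]
  fit$response_mode <- mode
  fit$class_threshold <- if (mode == "classification") class_threshold else NULL
  fit
}

#' Predictions from a trained model
#'
#' `predict_response` returns the scalar response score of the frozen-
#' embedding head for (drug, cell) pairs; `predict_response_class` its
#' sigmoid when the head was fitted in classification mode.
#' `predict_dti` scores drug-protein pairs with the drug-target head; a
#' `drug_features` matrix may be supplied to score drugs that are absent
#' from the graph (the cold-start fingerprint path).
#' `predict_bioprocess` scores protein-pathway pairs.
#'
#' @param fit an `hgnn_fit`.
#' @param pairs data.frame `drug_id`, `cell_id`.
#' @return numeric vector/matrix of scores.
#' @export
predict_response <- function(fit, pairs) {
  emb <- fit$embeddings
  v <- fit$model$vocab
  Z <- cbind(emb$drug[match(pairs$drug_id, v$drug), , drop = FALSE],
             emb$cell[match(pairs$cell_id, v$cell), , drop = FALSE])
  out <- .mlp_numeric(fit$model$params, "reg", Z)
  if (identical(fit$response_mode, "classification")) stats::plogis(out) else out
}

#' @rdname predict_response
#' @param expression z-scored expression matrix for cells outside the graph
#'   (rows = new cell IDs, columns = the model's gene order); their
#'   embeddings come from the learned expression projection alone.
#' @export
predict_response_external <- function(fit, expression, pairs) {
  emb <- fit$embeddings
  v <- fit$model$vocab
  stopifnot(ncol(expression) == nrow(fit$model$params$W_cell))
  h_new <- expression %*% fit$model$params$W_cell
  Z <- cbind(emb$drug[match(pairs$drug_id, v$drug), , drop = FALSE],
             h_new[match(pairs$cell_id, rownames(expression)), , drop = FALSE])
  out <- .mlp_numeric(fit$model$params, "reg", Z)
  if (identical(fit$response_mode, "classification")) stats::plogis(out) else out
}

#' @rdname predict_response
#' @param drugs,proteins node IDs to score (default: all in the graph).
#' @param drug_features optional fingerprint matrix (rownames = drug IDs) for
#'   drugs outside the graph.
#' @export
predict_dti <- function(fit, drugs = NULL, proteins = NULL, drug_features = NULL) {
  emb <- fit$embeddings
  v <- fit$model$vocab
  if (is.null(proteins)) proteins <- v$protein
  if (is.null(drug_features)) {
    if (is.null(drugs)) drugs <- v$drug
    D <- emb$drug[match(drugs, v$drug), , drop = FALSE]
  } else {
    drugs <- rownames(drug_features)
    D <- drug_embed(drug_features, fit$model$params$W_drug)
  }
  Pm <- emb$protein[match(proteins, v$protein), , drop = FALSE]
  out <- matrix(NA_real_, length(drugs), length(proteins),
                dimnames = list(drugs, proteins))
  for (i in seq_along(drugs)) {
    X <- cbind(matrix(D[i, ], length(proteins), ncol(D), byrow = TRUE), Pm)
    out[i, ] <- .mlp_numeric(fit$model$params, "dti", X)
  }
  out
}

#' @rdname predict_response
#' @param pathways pathway IDs to score.
#' @export
predict_bioprocess <- function(fit, proteins = NULL, pathways = NULL) {
  emb <- fit$embeddings
  v <- fit$model$vocab
  if (is.null(proteins)) proteins <- v$protein
  if (is.null(pathways)) pathways <- v$pathway
  out <- matrix(NA_real_, length(proteins), length(pathways),
                dimnames = list(proteins, pathways))
  Wm <- emb$pathway[match(pathways, v$pathway), , drop = FALSE]
  for (i in seq_along(proteins)) {
    X <- cbind(matrix(emb$protein[match(proteins[i], v$protein), ],
                      length(pathways), ncol(emb$protein), byrow = TRUE), Wm)
    out[i, ] <- .mlp_numeric(fit$model$params, "bp", X)
  }
  out
}

#' Random-search hyperparameter tuning
#'
#' Sequentially samples configurations from a declared discrete search space
#' and keeps the best by the supplied objective (e.g. validation rank
#' correlation).  Deterministic given the seed.
#'
#' @param search_space named list; each element a vector of candidate values.
#' @param objective function taking a named list (one sampled value per
#'   entry) and returning a numeric score to maximize.
#' @param budget number of trials (>= 1).
#' @param seed RNG seed.
#' @return list with `best_config`, `best_value` and the `trials` log.
#' @export
tune <- function(search_space, objective, budget = 20L, seed = 1L) {
  if (!length(search_space)) stop("empty search space")
  stopifnot(budget >= 1L)
  set.seed(as.integer(seed))
  trials <- vector("list", budget)
  best <- list(value = -Inf, config = NULL)
  for (t in seq_len(budget)) {
    cfg <- lapply(search_space, function(v) v[[sample.int(length(v), 1L)]])
    val <- objective(cfg)
    trials[[t]] <- data.frame(trial = t, value = val,
                              config = I(list(cfg)))
    if (val > best$value) best <- list(value = val, config = cfg)
  }
  list(best_config = best$config, best_value = best$value,
       trials = do.call(rbind, trials))
}

## ---- standalone MLP classifier (zero-shot cell states) -------------------

#' Train a small MLP classifier (e.g. infected vs healthy cell states)
#'
#' A two-layer network (one hidden ReLU layer) trained with Adam on binary
#' cross-entropy.  Used as the cell-state classifier whose per-gene input
#' attributions are computed with [integrated_gradients()].
#'
#' @param X numeric feature matrix (rows = samples, e.g. expression
#'   profiles).
#' @param y 0/1 labels.
#' @param hidden hidden width.
#' @param epochs,lr optimization budget.
#' @param seed RNG seed.
#' @return an `mlp_classifier` with `$predict(X)` (probabilities),
#'   `$logit(x)` and `$grad(x)` (gradient of the logit w.r.t. one input row).
#' @export
train_mlp_classifier <- function(X, y, hidden = 16L, epochs = 300L, lr = 0.01,
                                 seed = 1L) {
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  set.seed(as.integer(seed))
  d <- ncol(X)
  params <- list(W1 = matrix(stats::rnorm(d * hidden, sd = sqrt(2 / (d + hidden))),
                             d, hidden),
                 b1 = matrix(0, 1L, hidden),
                 W2 = matrix(stats::rnorm(hidden, sd = sqrt(2 / (hidden + 1))),
                             hidden, 1L),
                 b2 = matrix(0, 1L, 1L))
  state <- adam_state(params)
  for (e in seq_len(epochs)) {
    tape <- ad_tape()
    P <- wrap_params(tape, params)
    h1 <- ad_relu(tape, ad_add_bias(tape, ad_matmul(tape, ad_const(tape, X),
                                                    P$W1), P$b1))
    logit <- ad_add_bias(tape, ad_matmul(tape, h1, P$W2), P$b2)
    loss <- ad_bce_logits(tape, logit, y)
    grads <- ad_backward(tape, loss)
    st <- adam_step(params, grads, state, lr = lr, weight_decay = 0)
    params <- st$params
    state <- st$state
  }
  logit_fn <- function(x) {
    x <- matrix(x, nrow = 1L)
    h1 <- pmax(sweep(x %*% params$W1, 2L, as.numeric(params$b1), "+"), 0)
    as.numeric(h1 %*% params$W2 + as.numeric(params$b2))
  }
  grad_fn <- function(x) {
    x <- matrix(x, nrow = 1L)
    z1 <- sweep(x %*% params$W1, 2L, as.numeric(params$b1), "+")
    act <- as.numeric(z1 > 0)
    as.numeric(params$W1 %*% (act * as.numeric(params$W2)))
  }
  structure(list(params = params,
                 predict = function(Xn) {
                   h1 <- pmax(sweep(Xn %*% params$W1, 2L,
                                    as.numeric(params$b1), "+"), 0)
                   stats::plogis(as.numeric(h1 %*% params$W2 +
                                              as.numeric(params$b2)))
                 },
                 logit = logit_fn, grad = grad_fn),
            class = "mlp_classifier")
}
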