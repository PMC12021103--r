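# Metrics, the cross-validated scenario harness, target prioritization, the
# external-cohort report, and zero-shot screening.

#' Root mean square error
#' @param pred,obs numeric vectors of equal nonzero length.
#' @return `sqrt(mean((pred - obs)^2))`.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  if (!length(pred)) stop("empty vectors")
  sqrt(mean((pred - obs)^2))
}

#' Pearson correlation coefficient
#'
#' Returns `NA` with a warning when either vector has zero variance
#' (the correlation is then undefined; reporting 0 would overstate
#' certainty).
#'
#' @param a,b numeric vectors of equal length.
#' @return correlation in \[-1, 1\], or `NA`.
#' @export
pcc <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Spearman correlation coefficient
#'
#' Pearson correlation of ranks, with ties given average ranks.  All-tied
#' input yields `NA` with a warning.
#'
#' @param a,b numeric vectors of equal length.
#' @return rank correlation in \[-1, 1\], or `NA`.
#' @export
scc <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
    warning("all-tied vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}

.metrics_report <- function(pred, obs, grouping = "pooled") {
  data.frame(rmse = rmse(pred, obs),
             pcc = suppressWarnings(pcc(pred, obs)),
             scc = suppressWarnings(scc(pred, obs)),
             n = length(pred), grouping = grouping)
}

#' Cross-validated scenario evaluation
#'
#' Runs a prediction routine over every fold of a [make_splits()] fold set
#' and reports per-fold RMSE / PCC / SCC on the test pairs only, plus the
#' across-fold mean and standard error.  The prediction routine sees test
#' labels never: it receives the training rows (with values) and the test
#' rows with the `value` column removed.
#'
#' @param response_table data.frame `drug_id`, `cell_id`, `value`.
#' @param folds a `response_folds` object.
#' @param predict_fn `function(train_df, test_df) -> numeric` returning one
#'   prediction per test row.
#' @param folds_to_run optionally, a subset of fold indices (full
#'   cross-validation can be expensive when each fold trains a model).
#' @return list with `per_fold` (data.frame) and `summary`
#'   (mean and standard error per metric).
#' @export
evaluate_scenario <- function(response_table, folds, predict_fn,
                              folds_to_run = seq_along(folds)) {
  check_split_leakage(folds, response_table)
  per_fold <- lapply(folds_to_run, function(k) {
    tr <- response_table[folds[[k]]$train, , drop = FALSE]
    te <- response_table[folds[[k]]$test, , drop = FALSE]
    if (!nrow(te)) stop("fold ", k, " has an empty test set")
    pred <- predict_fn(tr, te[, setdiff(names(te), "value"), drop = FALSE])
    cbind(fold = k, .metrics_report(pred, te$value))
  })
  per_fold <- do.call(rbind, per_fold)
  summarize <- function(x) {
    x <- x[is.finite(x)]
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  }
  list(per_fold = per_fold,
       summary = data.frame(
         metric = c("rmse", "pcc", "scc"),
         mean = c(summarize(per_fold$rmse)["mean"], summarize(per_fold$pcc)["mean"],
                  summarize(per_fold$scc)["mean"]),
         se = c(summarize(per_fold$rmse)["se"], summarize(per_fold$pcc)["se"],
                summarize(per_fold$scc)["se"])))
}

#' Train-and-evaluate convenience for one scenario fold
#'
#' Restricts the graph for cold-start honesty (held-out drugs lose their
#' drug-target edges, held-out cells their protein-cell edges), builds the
#' four streams from the training rows only, carves a warm validation subset
#' out of training for early stopping, trains, and predicts the test rows
#' with the frozen-embedding response head.
#'
#' @param g a `biohg`.
#' @param train_df,test_df response rows (test values unused).
#' @param cfg an [hgnn_config()].
#' @param tc a [train_config()].
#' @param val_frac warm validation fraction carved from training.
#' @return list `fit` (the trained model) and `pred` (test predictions).
#' @export
fit_fold <- function(g, train_df, test_df, cfg = hgnn_config(),
                     tc = train_config(), val_frac = 0.1) {
  set.seed(tc$seed)
  cold_drugs <- setdiff(unique(test_df$drug_id), unique(train_df$drug_id))
  cold_cells <- setdiff(unique(test_df$cell_id), unique(train_df$cell_id))
  g_tr <- restrict_biohg(g, drop_drugs = cold_drugs, drop_cells = cold_cells)
  iv <- sample.int(nrow(train_df), max(1L, round(val_frac * nrow(train_df))))
  val <- train_df[iv, , drop = FALSE]
  tr <- train_df[-iv, , drop = FALSE]
  streams <- build_streams(g_tr, tr, seed = tc$seed)
  model <- hgnn_init(g_tr, cfg, seed = tc$seed)
  fit <- train_hgnn(model, streams, tr, val, tc)
  list(fit = fit, pred = predict_response(fit, test_df))
}

#' Target prioritization: ranked drug-target recall
#'
#' Scores every candidate protein for each drug with the drug-target head,
#' ranks candidates per drug (ties broken deterministically by protein ID),
#' and reports pooled recall of the held-out positives at fractional rank
#' cutoffs.  Pooled (micro) recall counts all positives together; per-drug
#' macro recall is available via `per_drug = TRUE`.
#'
#' @param scores numeric matrix of drug-target scores (drugs x proteins,
#'   dimnames required), e.g. from [predict_dti()].
#' @param positives data.frame `drug_id`, `protein_id` of held-out true
#'   interactions (disjoint from training edges).
#' @param fractions rank cutoffs as fractions of the candidate universe.
#' @param universe optional character vector restricting the candidate
#'   proteins (e.g. proteins with known interactions vs all proteins).
#' @param per_drug report macro (per-drug mean) recall instead of pooled.
#' @return list with `recall_at` (named numeric, nondecreasing), `ranks`
#'   (per-positive rank table) and `n_unrecoverable` (positives outside the
#'   universe).
#' @export
rank_targets <- function(scores, positives, fractions = c(0.03, 0.10),
                         universe = NULL, per_drug = FALSE) {
  if (is.null(universe)) universe <- colnames(scores)
  universe <- intersect(colnames(scores), universe)
  scores <- scores[, universe, drop = FALSE]
  inuniv <- positives$protein_id %in% universe &
    positives$drug_id %in% rownames(scores)
  n_unrec <- sum(!inuniv)
  if (n_unrec) message(n_unrec, " positive pair(s) outside the candidate universe")
  pos <- positives[inuniv, , drop = FALSE]
  ranks <- vapply(seq_len(nrow(pos)), function(i) {
    s <- scores[pos$drug_id[i], ]
    ord <- order(-s, names(s))          # deterministic tie-break by ID
    match(pos$protein_id[i], names(s)[ord])
  }, numeric(1))
  fractions <- sort(fractions)
  m <- length(universe)
  recall_at <- vapply(fractions, function(f) {
    cut <- ceiling(f * m)
    if (!per_drug) mean(ranks <= cut)
    else mean(tapply(ranks <= cut, pos$drug_id, mean))
  }, numeric(1))
  names(recall_at) <- sprintf("top%g%%", 100 * fractions)
  list(recall_at = recall_at,
       ranks = data.frame(drug_id = pos$drug_id, protein_id = pos$protein_id,
                          rank = ranks, universe_size = m),
       n_unrecoverable = n_unrec)
}

#' External-cohort transfer report (per-model and per-drug correlations)
#'
#' For a cohort of models (e.g. xenografts) never seen in training, computes
#' PCC and SCC between predictions and observed responses grouped per cohort
#' model and per drug; groups with fewer than 3 observations are skipped.
#'
#' @param predictions data.frame with columns `drug_id`, `cell_id`, `obs`,
#'   `pred`.
#' @return list of data.frames `per_model` and `per_drug` with columns
#'   `id`, `pcc`, `scc`, `n`.
#' @export
external_cohort_report <- function(predictions) {
  grouped <- function(key) {
    out <- lapply(split(predictions, predictions[[key]]), function(df) {
      if (nrow(df) < 3L) {
        message("group '", df[[key]][1], "' has fewer than 3 observations; skipped")
        return(NULL)
      }
      data.frame(id = df[[key]][1],
                 pcc = suppressWarnings(pcc(df$pred, df$obs)),
                 scc = suppressWarnings(scc(df$pred, df$obs)),
                 n = nrow(df))
    })
    out <- do.call(rbind, out)
    if (!is.null(out)) rownames(out) <- NULL
    out
  }
  list(per_model = grouped("cell_id"), per_drug = grouped("drug_id"))
}

#' Zero-shot phenotypic screening rule
#'
#' Given classifier-mode response probabilities, selects the drugs scoring
#' above the threshold on every case sample and below it on every control
#' sample -- i.e. drugs predicted active specifically in the perturbed state.
#'
#' @param scores numeric matrix of response probabilities, drugs x cells
#'   (dimnames required).
#' @param case_cells,control_cells cell IDs of the two states (non-empty).
#' @param threshold decision threshold, default 0.5.
#' @return character vector of selected drug IDs.
#' @export
screen_zero_shot <- function(scores, case_cells, control_cells, threshold = 0.5) {
  if (!length(case_cells) || !length(control_cells)) {
    stop("case and control sets must be non-empty")
  }
  stopifnot(all(case_cells %in% colnames(scores)),
            all(control_cells %in% colnames(scores)))
  hi <- rowSums(scores[, case_cells, drop = FALSE] > threshold) == length(case_cells)
  lo <- rowSums(scores[, control_cells, drop = FALSE] < threshold) == length(control_cells)
  rownames(scores)[hi & lo]
}
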