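# Loss functions, the multi-task optimizer wiring, early stopping, and the
# random-search tuner.

test_that("binary cross-entropy matches closed forms and the naive formula", {
  expect_equal(bce_with_logits(0, 1), log(2), tolerance = 1e-12)
  expect_equal(bce_with_logits(0, 0), log(2), tolerance = 1e-12)
  # loss decreases monotonically toward the limit as logits grow with label 1
  ls <- vapply(c(1, 5, 10), function(x) bce_with_logits(x, 1), numeric(1))
  expect_true(all(diff(ls) < 0))
  expect_lt(ls[3], 1e-4)
  # random batch vs the unstabilized textbook expression
  set.seed(14)
  x <- rnorm(50, sd = 2)
  y <- rbinom(50, 1, 0.5)
  naive <- mean(-(y * log(plogis(x)) + (1 - y) * log(1 - plogis(x))))
  expect_equal(bce_with_logits(x, y), naive, tolerance = 1e-6)
  expect_error(bce_with_logits(numeric(0), numeric(0)), "empty")
})

test_that("the total loss is the exact weighted sum of the four streams", {
  sl <- c(pc = 0.1, dc = 0.2, dpi = 0.3, pro_path = 0.4)
  expect_equal(total_loss(sl, c(pc = 1, dc = 1, dpi = 1, pro_path = 1)), 1.0)
  # a zero weight annihilates its stream
  w <- c(pc = 1, dc = 0, dpi = 1, pro_path = 1)
  sl2 <- sl; sl2["dc"] <- 99
  expect_equal(total_loss(sl, w), total_loss(sl2, w))
  set.seed(15)
  for (rep in 1:5) {
    sl <- setNames(runif(4), c("pc", "dc", "dpi", "pro_path"))
    w <- setNames(runif(4), c("pc", "dc", "dpi", "pro_path"))
    expect_equal(total_loss(sl, w), sum(sl * w), tolerance = 1e-12)
  }
  sl_bad <- c(pc = 0.1, dc = NaN, dpi = 0.3, pro_path = 0.4)
  expect_error(total_loss(sl_bad), "dc")
  expect_error(total_loss(sl, c(pc = 0, dc = 0, dpi = 0, pro_path = 0)),
               "positive")
})

test_that("early stopping fires at the documented epoch", {
  # validation sequence .1 .2 .2 .2 .2 with patience 3: best epoch 2,
  # stop after epoch 5
  seq_scc <- c(0.1, 0.2, 0.2, 0.2, 0.2, 0.3)
  best <- 0L; best_val <- -Inf; stopped_at <- NA_integer_
  for (e in seq_along(seq_scc)) {
    if (seq_scc[e] > best_val) { best_val <- seq_scc[e]; best <- e }
    if (early_stop_reached(e, best, patience = 3L, min_epochs = 0L)) {
      stopped_at <- e
      break
    }
  }
  expect_equal(best, 2L)
  expect_equal(stopped_at, 5L)
  # warm-up defers stopping
  expect_false(early_stop_reached(5L, 2L, 3L, min_epochs = 10L))
})

test_that("one optimization step reaches the fingerprint transform and convolutions", {
  s <- simulate_biohg(sim_config(n_drugs = 6, n_proteins = 20, n_cells = 5,
                                 n_pathways = 3, n_go = 3, fp_bits = 32,
                                 seed = 20))
  streams <- suppressWarnings(build_streams(s$graph, s$response, seed = 1))
  model <- hgnn_init(s$graph, hgnn_config(embed_dim = 4), seed = 1)
  before <- model$params
  fit <- train_hgnn(model, streams, s$response, s$response[1:10, ],
                    desk_tc(seed = 1, max_epochs = 1, stage2_epochs = 1))
  after <- fit$model$params
  expect_false(isTRUE(all.equal(before$W_drug, after$W_drug)))
  conv_names <- grep("^W_pr_from", names(before), value = TRUE)
  changed <- vapply(conv_names, function(nm)
    !isTRUE(all.equal(before[[nm]], after[[nm]])), logical(1))
  expect_true(any(changed))
})

test_that("training is reproducible and its loss decreases over early epochs", {
  s <- simulate_biohg(sim_config(n_drugs = 10, n_proteins = 40, n_cells = 8,
                                 n_pathways = 4, n_go = 4, fp_bits = 64,
                                 seed = 21))
  streams <- build_streams(s$graph, s$response, seed = 2)
  val <- s$response[sample.int(nrow(s$response), 20), ]
  run <- function() {
    model <- hgnn_init(s$graph, hgnn_config(embed_dim = 8), seed = 3)
    train_hgnn(model, streams, s$response, val,
               desk_tc(seed = 3, max_epochs = 12, stage2_epochs = 5))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_lt(f1$history$loss[12], f1$history$loss[1])
})

test_that("divergent losses abort with the offending stream named", {
  s <- simulate_biohg(sim_config(n_drugs = 5, n_proteins = 15, n_cells = 4,
                                 n_pathways = 2, n_go = 2, fp_bits = 16,
                                 seed = 22))
  streams <- suppressWarnings(build_streams(s$graph, s$response, seed = 1))
  model <- hgnn_init(s$graph, hgnn_config(embed_dim = 4), seed = 1)
  model$params$E_protein[1, 1] <- NaN
  expect_error(
    train_hgnn(model, streams, s$response, s$response[1:5, ], desk_tc(seed = 1)),
    "divergent loss")
})

test_that("training beats an untrained model on the warm scenario", {
  # median over 3 seeds of (trained - untrained) validation rank correlation
  s <- standard_sim(seed = 7)
  deltas <- vapply(1:3, function(sd) {
    set.seed(sd)
    iv <- sample.int(nrow(s$response), 300)
    val <- s$response[iv, ]; trn <- s$response[-iv, ]
    streams <- build_streams(s$graph, trn, seed = sd)
    model <- hgnn_init(s$graph, hgnn_config(), seed = sd)
    fit <- train_hgnn(model, streams, trn, val,
                      desk_tc(seed = sd, max_epochs = 60, stage2_epochs = 200))
    untrained <- list(model = hgnn_init(s$graph, hgnn_config(), seed = sd + 50),
                      response_mode = "regression")
    untrained$embeddings <- hgnn_forward(untrained$model)
    class(untrained) <- "hgnn_fit"
    scc_of <- function(f) suppressWarnings(scc(predict_response(f, val), val$value))
    scc_of(fit) - scc_of(untrained)
  }, numeric(1))
  expect_gt(median(deltas), 0)
})

test_that("random search finds a planted optimum and logs every trial", {
  res <- tune(list(x = 1:7), function(cfg) -(cfg$x - 3)^2, budget = 30, seed = 4)
  expect_lte(abs(res$best_config$x - 3), 1)
  expect_equal(nrow(res$trials), 30L)
  # constant objective: any config valid, budget respected
  res2 <- tune(list(x = 1:3, y = c("a", "b")), function(cfg) 1,
               budget = 5, seed = 1)
  expect_equal(nrow(res2$trials), 5L)
  expect_equal(res2$best_value, 1)
  res3 <- tune(list(x = 2), function(cfg) cfg$x, budget = 1, seed = 1)
  expect_equal(res3$best_config$x, 2)
  expect_error(tune(list(), identity, budget = 2), "empty")
})
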