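# Metrics against textbook oracles, the scenario harness, target ranking,
# the external-cohort report, and the screening rule.

test_that("rmse matches its definition", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(2, 3, 4), c(1, 2, 3)), 1)
  set.seed(30)
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(rmse(a, b), naive_rmse(a, b), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("correlations match textbook formulas and handle degeneracy", {
  set.seed(31)
  a <- rnorm(30)
  expect_equal(pcc(a, 2 * a + 3), 1)
  expect_equal(pcc(a, -a), -1)
  expect_equal(scc(a, exp(a)), 1)           # strictly increasing transform
  expect_equal(scc(a, rev(sort(a))[rank(a)]), -1)
  expect_warning(expect_true(is.na(pcc(rep(1, 5), 1:5))), "zero variance")
  expect_warning(expect_true(is.na(scc(rep(1, 5), 1:5))), "all-tied")
  for (rep in 1:20) {
    x <- rnorm(25); y <- rnorm(25)
    expect_equal(pcc(x, y), naive_pcc(x, y), tolerance = 1e-12)
    expect_equal(scc(x, y), naive_scc(x, y), tolerance = 1e-12)
  }
  # ties handled by average ranks
  x <- c(1, 2, 2, 3, 3, 3, 4)
  y <- c(2, 1, 5, 4, 4, 6, 9)
  expect_equal(scc(x, y), naive_scc(x, y), tolerance = 1e-12)
})

test_that("the scenario harness scores oracle and degenerate models correctly", {
  set.seed(32)
  resp <- expand.grid(drug_id = sprintf("D%02d", 1:8),
                      cell_id = sprintf("C%02d", 1:6), stringsAsFactors = FALSE)
  resp$value <- rnorm(nrow(resp))
  folds <- make_splits(resp, "warm", n_folds = 4, seed = 1)
  lookup <- function(tr, te) {
    resp$value[match(paste(te$drug_id, te$cell_id),
                     paste(resp$drug_id, resp$cell_id))]
  }
  rep_oracle <- evaluate_scenario(resp, folds, lookup)
  expect_equal(rep_oracle$per_fold$rmse, rep(0, 4))
  expect_equal(rep_oracle$per_fold$pcc, rep(1, 4), tolerance = 1e-12)
  expect_equal(rep_oracle$per_fold$scc, rep(1, 4), tolerance = 1e-12)
  # constant-output model: rmse is the spread around the constant,
  # correlations undefined
  const <- function(tr, te) rep(0, nrow(te))
  rep_const <- evaluate_scenario(resp, folds, const)
  k <- folds[[1]]$test
  expect_equal(rep_const$per_fold$rmse[1], sqrt(mean(resp$value[k]^2)))
  expect_true(all(is.na(rep_const$per_fold$pcc)))
  expect_equal(rep_const$summary$metric, c("rmse", "pcc", "scc"))
})

test_that("target ranking recalls planted positives and stays monotone", {
  # all positives scored above all negatives: full recall at any cutoff
  # at or above prevalence
  prot <- sprintf("P%03d", 1:100)
  sc <- matrix(0, 2, 100, dimnames = list(c("D1", "D2"), prot))
  pos <- data.frame(drug_id = c("D1", "D1", "D2"),
                    protein_id = c("P001", "P002", "P003"))
  sc["D1", c("P001", "P002")] <- 5
  sc["D2", "P003"] <- 5
  rep1 <- rank_targets(sc, pos, fractions = c(0.02, 0.10))
  expect_equal(unname(rep1$recall_at["top2%"]), 1)
  expect_equal(unname(rep1$recall_at["top10%"]), 1)
  expect_true(all(diff(rep1$recall_at) >= 0))
  # positives outside the universe are unrecoverable but counted
  expect_message(
    rep2 <- rank_targets(sc, rbind(pos, data.frame(drug_id = "D1",
                                                   protein_id = "PXXX"))),
    "outside")
  expect_equal(rep2$n_unrecoverable, 1L)
  # deterministic tie-break by protein ID
  sc2 <- matrix(0, 1, 10,
                dimnames = list("D1", sprintf("P%03d", 10:1)))
  r <- rank_targets(sc2, data.frame(drug_id = "D1", protein_id = "P001"),
                    fractions = 0.1)
  expect_equal(r$ranks$rank, 1)   # ties sorted by ID, P001 first
})

test_that("random scores recall positives at the cutoff rate", {
  # 1 positive among 100 candidates, cutoff 10%: mean recall near 0.10
  set.seed(33)
  prot <- sprintf("P%03d", 1:100)
  rec <- vapply(1:1000, function(i) {
    sc <- matrix(rnorm(100), 1, 100, dimnames = list("D1", prot))
    pos <- data.frame(drug_id = "D1", protein_id = sample(prot, 1))
    rank_targets(sc, pos, fractions = 0.10)$recall_at
  }, numeric(1))
  expect_gt(mean(rec), 0.07)
  expect_lt(mean(rec), 0.13)
})

test_that("external-cohort report groups correlations and skips tiny groups", {
  set.seed(34)
  pr <- expand.grid(drug_id = sprintf("D%d", 1:5),
                    cell_id = sprintf("X%d", 1:4), stringsAsFactors = FALSE)
  pr$obs <- rnorm(nrow(pr))
  pr$pred <- pr$obs                        # oracle predictions
  repo <- external_cohort_report(pr)
  expect_true(all(repo$per_model$pcc == 1))
  expect_true(all(repo$per_drug$scc == 1))
  # a cohort model with only 2 observations is skipped
  pr2 <- pr[!(pr$cell_id == "X1" & pr$drug_id %in% c("D1", "D2", "D3")), ]
  expect_message(repo2 <- external_cohort_report(pr2), "skipped")
  expect_false("X1" %in% repo2$per_model$id)
})

test_that("a trained model transfers to a synthetic external cohort", {
  s <- simulate_biohg(sim_config(n_drugs = 20, n_proteins = 80, n_cells = 15,
                                 n_pathways = 5, n_go = 6, fp_bits = 256,
                                 seed = 35))
  set.seed(35)
  iv <- sample.int(nrow(s$response), 60)
  val <- s$response[iv, ]; trn <- s$response[-iv, ]
  streams <- suppressWarnings(build_streams(s$graph, trn, seed = 35))
  model <- hgnn_init(s$graph, hgnn_config(embed_dim = 8), seed = 35)
  fit <- train_hgnn(model, streams, trn, val,
                    desk_tc(seed = 35, max_epochs = 80, stage2_epochs = 200))
  co <- simulate_external_cohort(s$truth, n_new_cells = 6, seed = 1)
  pred <- predict_response_external(fit, co$expression, co$response)
  repo <- external_cohort_report(
    data.frame(drug_id = co$response$drug_id, cell_id = co$response$cell_id,
               obs = co$response$value, pred = pred))
  expect_equal(nrow(repo$per_model), 6L)
  # the planted response structure carries over to unseen cohort models
  expect_gt(median(repo$per_model$scc), 0)
})

test_that("the screening rule selects case-specific drugs only", {
  sc <- rbind(DA = c(0.9, 0.8, 0.1, 0.2),
              DB = c(0.9, 0.8, 0.9, 0.2),   # high on a control: rejected
              DC = c(0.9, 0.4, 0.1, 0.2))   # low on a case: rejected
  colnames(sc) <- c("case1", "case2", "ctrl1", "ctrl2")
  sel <- screen_zero_shot(sc, c("case1", "case2"), c("ctrl1", "ctrl2"), 0.5)
  expect_equal(sel, "DA")
  expect_error(screen_zero_shot(sc, character(0), "ctrl1"), "non-empty")
})
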