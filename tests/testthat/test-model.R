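# Layer semantics, the heterogeneous forward pass, and the cold-start
# fingerprint path.

test_that("sage_layer matches hand evaluation with a block-identity weight", {
  d <- 3
  W <- cbind(diag(d), diag(d))        # h' = h_self + mean(neighbors)
  h <- c(1, 2, 3)
  nb <- matrix(c(4, 5, 6), 1, 3)
  expect_equal(sage_layer(h, nb, W), h + c(4, 5, 6))
  # empty neighborhood aggregates to zero
  expect_equal(sage_layer(h, matrix(0, 0, 3), W), h)
  # sum and pool aggregators
  nb2 <- rbind(c(1, 0, 2), c(3, 1, 0))
  expect_equal(sage_layer(h, nb2, W, aggregator = "sum"), h + c(4, 1, 2))
  expect_equal(sage_layer(h, nb2, W, aggregator = "pool"), h + c(3, 1, 2))
})

test_that("batched SAGE convolution equals the dense per-node oracle", {
  set.seed(8)
  for (rep in 1:10) {
    nd <- sample(3:8, 1); ns <- sample(3:8, 1); d <- 4; dout <- 5
    A <- matrix(rbinom(nd * ns, 1, 0.4), nd, ns)
    Hd <- matrix(rnorm(nd * d), nd, d)
    Hs <- matrix(rnorm(ns * d), ns, d)
    W <- matrix(rnorm(dout * 2 * d), dout, 2 * d)
    for (agg in c("mean", "sum", "pool")) {
      got <- sage_conv(Hd, Hs, A, W, activation = "relu", aggregator = agg)
      want <- naive_sage(Hd, Hs, A, W, act = function(x) pmax(x, 0),
                         aggregator = agg)
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("GCN convolution normalizes symmetrically and matches its oracle", {
  # two nodes joined by one edge, degree 1 each: h' = h_neighbor
  A <- matrix(1, 1, 1)
  Hs <- matrix(c(2, -1), 1, 2)
  expect_equal(gcn_conv(Hs, A, diag(2)), Hs)
  # isolated destination: zero vector before activation
  A2 <- rbind(c(1, 0), c(0, 0))
  Hs2 <- matrix(rnorm(4), 2, 2)
  out <- gcn_conv(Hs2, A2, diag(2))
  expect_equal(out[2, ], c(0, 0))
  set.seed(9)
  for (rep in 1:10) {
    nd <- sample(3:9, 1); ns <- sample(3:9, 1); d <- 4
    A <- matrix(rbinom(nd * ns, 1, 0.4), nd, ns)
    Hs <- matrix(rnorm(ns * d), ns, d)
    W <- matrix(rnorm(3 * d), 3, d)
    expect_equal(gcn_conv(Hs, A, W, activation = "tanh"),
                 naive_gcn(Hs, A, W, act = tanh), tolerance = 1e-6)
  }
})

test_that("drug transform is a pure linear map", {
  W <- matrix(rnorm(12), 4, 3)
  expect_equal(drug_embed(rep(0, 4), W), matrix(0, 1, 3))
  expect_equal(drug_embed(c(1, 2, 0, 1), diag(4)[, 1:4]),
               matrix(c(1, 2, 0, 1), 1))
  a <- runif(4); b <- runif(4)
  expect_equal(drug_embed(a, W) + drug_embed(b, W), drug_embed(a + b, W),
               tolerance = 1e-6)
  expect_error(drug_embed(rep(1, 5), W), "does not match")
})

test_that("forward pass matches a hand-rolled dense computation on a toy graph", {
  s <- simulate_biohg(sim_config(n_drugs = 3, n_proteins = 6, n_cells = 2,
                                 n_pathways = 2, n_go = 2, dti_per_drug = 2,
                                 fp_bits = 8, seed = 2))
  g <- s$graph
  cfg <- hgnn_config(embed_dim = 4, n_layers = 1, activation = "relu")
  model <- hgnn_init(g, cfg, seed = 1)
  emb <- hgnn_forward(model)
  p <- model$params
  # dense re-computation, relation by relation
  adj <- function(et, rows, cols, rev = FALSE) {
    e <- g$edges[g$edges$edge_type == et, ]
    A <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
    from <- if (rev) e$dst_id else e$src_id
    to <- if (rev) e$src_id else e$dst_id
    for (k in seq_len(nrow(e))) A[to[k], from[k]] <- 1
    A
  }
  v <- model$vocab
  Appi <- adj("ppi", v$protein, v$protein)
  Appi <- pmin(Appi + t(Appi), 1)
  h_drug <- model$drug_features %*% p$W_drug
  h_cell <- model$cell_features %*% p$W_cell
  relu <- function(x) pmax(x, 0)
  want <- naive_sage(p$E_protein, p$E_protein, Appi,
                     t(p$W_pr_from_pr_l1), act = relu) +
    naive_sage(p$E_protein, p$E_pathway,
               adj("protein_pathway", v$protein, v$pathway, rev = TRUE),
               t(p$W_pr_from_pw_l1), act = relu) +
    naive_sage(p$E_protein, p$E_go,
               adj("protein_go", v$protein, v$go, rev = TRUE),
               t(p$W_pr_from_go_l1), act = relu) +
    naive_sage(p$E_protein, h_drug, adj("dti", v$protein, v$drug),
               t(p$W_pr_from_dr_l1), act = relu) +
    naive_gcn(h_cell, adj("protein_cell", v$protein, v$cell, rev = TRUE),
              t(p$W_pr_from_cl_l1), act = relu)
  expect_equal(unname(emb$protein), want, tolerance = 1e-6)
  expect_equal(unname(emb$drug), unname(h_drug), tolerance = 1e-12)
})

test_that("protein-cell edge weights never influence the forward pass", {
  s <- simulate_biohg(sim_config(n_drugs = 4, n_proteins = 12, n_cells = 3,
                                 n_pathways = 2, n_go = 3, fp_bits = 16,
                                 seed = 6))
  g1 <- s$graph
  g2 <- g1
  pc <- g2$edges$edge_type == "protein_cell"
  g2$edges$weight[pc] <- g2$edges$weight[pc] * 10 + 1
  m1 <- hgnn_init(g1, hgnn_config(embed_dim = 4), seed = 3)
  m2 <- hgnn_init(g2, hgnn_config(embed_dim = 4), seed = 3)
  expect_identical(hgnn_forward(m1), hgnn_forward(m2))
})

test_that("graphs without drug-target or expression edges still propagate", {
  # protein embeddings then depend only on ppi/pathway/GO convolutions
  pid <- sprintf("P%d", 1:5)
  expr <- matrix(seq(0.1, 1.5, length.out = 10), 2, 5,
                 dimnames = list(c("C1", "C2"), pid))
  base <- list(
    ppi_edges = data.frame(src_id = pid[1:4], dst_id = pid[2:5]),
    pathway_edges = data.frame(src_id = pid, dst_id = "W1"),
    drug_features = matrix(rbinom(16, 1, 0.5), 2, 8,
                           dimnames = list(c("D1", "D2"), NULL)))
  g_full <- do.call(build_biohg, c(base, list(
    dti_edges = data.frame(src_id = "D1", dst_id = "P1"), expr = expr)))
  g_bare <- do.call(build_biohg, c(base, list(expr = expr)))
  g_bare$edges <- g_bare$edges[g_bare$edges$edge_type != "protein_cell", ]
  m_full <- hgnn_init(g_full, hgnn_config(embed_dim = 4), seed = 4)
  m_bare <- hgnn_init(g_bare, hgnn_config(embed_dim = 4), seed = 4)
  # shared relations use identical seeds, so the bare graph's protein
  # embeddings must be reproducible from ppi/pathway convolutions alone
  expect_false(is.null(hgnn_forward(m_bare)$protein))
  expect_true(all(is.finite(hgnn_forward(m_bare)$protein)))
  expect_false("pr_from_dr" %in% names(m_bare$ops))
  expect_false("pr_from_cl" %in% names(m_bare$ops))
})

test_that("forward is deterministic with dropout off and random under dropout", {
  s <- simulate_biohg(sim_config(n_drugs = 4, n_proteins = 10, n_cells = 3,
                                 n_pathways = 2, n_go = 2, fp_bits = 16,
                                 seed = 8))
  m <- hgnn_init(s$graph, hgnn_config(embed_dim = 4, dropout = 0), seed = 5)
  expect_identical(hgnn_forward(m), hgnn_forward(m))
})

test_that("a drug with zero graph edges is scored via its fingerprint", {
  s <- simulate_biohg(sim_config(n_drugs = 6, n_proteins = 15, n_cells = 4,
                                 n_pathways = 3, n_go = 3, fp_bits = 32,
                                 seed = 10))
  model <- hgnn_init(s$graph, hgnn_config(embed_dim = 4), seed = 1)
  fit <- list(model = model, embeddings = hgnn_forward(model),
              response_mode = "regression")
  class(fit) <- "hgnn_fit"
  fp_new <- matrix(rbinom(32, 1, 0.5), 1, 32, dimnames = list("DNEW", NULL))
  sc <- predict_dti(fit, drug_features = fp_new)
  expect_equal(dim(sc), c(1L, 15L))
  expect_true(all(is.finite(sc)))
  # the score path is exactly the linear fingerprint transform + DTI head
  h_new <- drug_embed(fp_new, model$params$W_drug)
  X <- cbind(h_new[rep(1, 15), ], fit$embeddings$protein)
  expect_equal(unname(sc[1, ]),
               unname(hgdrp:::.mlp_numeric(model$params, "dti", X)),
               tolerance = 1e-12)
})

test_that("checkpoints round-trip and refuse mismatched vocabularies", {
  s <- simulate_biohg(sim_config(n_drugs = 4, n_proteins = 10, n_cells = 3,
                                 n_pathways = 2, n_go = 2, fp_bits = 16,
                                 seed = 12))
  m <- hgnn_init(s$graph, hgnn_config(embed_dim = 4), seed = 2)
  ck <- file.path(tempdir(), "ck1")
  save_checkpoint(m, ck, extra = list(response_mode = "regression"))
  m2 <- load_checkpoint(ck, s$graph)
  for (nm in names(m$params)) {
    expect_equal(m2$params[[nm]], m$params[[nm]], tolerance = 1e-12)
  }
  s2 <- simulate_biohg(sim_config(n_drugs = 5, n_proteins = 10, n_cells = 3,
                                  n_pathways = 2, n_go = 2, fp_bits = 16,
                                  seed = 13))
  expect_error(load_checkpoint(ck, s2$graph), "vocabulary mismatch")
})
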