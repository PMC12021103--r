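# Small graphs and simulations reused across test files.

# A seven-node toy graph: 2 drugs, 3 proteins, 1 cell line, 1 pathway.
toy_biohg <- function() {
  expr <- matrix(c(1, 2, 3), 1, 3, dimnames = list("C1", c("P1", "P2", "P3")))
  fp <- matrix(c(1, 0, 0, 1, 1, 1, 0, 0), 2, 4, dimnames = list(c("D1", "D2"), NULL))
  build_biohg(
    dti_edges = data.frame(src_id = c("D1", "D2"), dst_id = c("P1", "P2")),
    ppi_edges = data.frame(src_id = "P1", dst_id = "P2"),
    pathway_edges = data.frame(src_id = "P1", dst_id = "W1"),
    expr = expr, drug_features = fp)
}

# Random biohg over index-named proteins with a given ppi edge list
# (indices), one drug wired to given targets; used for distance oracles.
indexed_biohg <- function(n_prot, ppi_idx, dti_targets = 1L) {
  pid <- sprintf("P%02d", seq_len(n_prot))
  ppi <- data.frame(src_id = pid[ppi_idx[, 1]], dst_id = pid[ppi_idx[, 2]])
  build_biohg(
    dti_edges = data.frame(src_id = "D1", dst_id = pid[dti_targets]),
    ppi_edges = ppi,
    # a shared pathway keeps isolated proteins present as nodes without
    # touching the ppi/dti paths that distance queries traverse
    pathway_edges = data.frame(src_id = pid, dst_id = "W1"),
    drug_features = matrix(1, 1, 4, dimnames = list("D1", NULL)))
}

# A hand-built fit over a chain graph whose DTI head scores proteins by
# their first embedding coordinate, making P01 the unique top target.
hgnn_init_chain_fit <- function(g) {
  d <- 2L
  emb <- list(
    drug = matrix(0, 1, d, dimnames = list("D1", NULL)),
    protein = matrix(c(1, 0, 0, 0, 0, 0), 3, d, byrow = TRUE,
                     dimnames = list(g$nodes$protein, NULL)))
  W1 <- matrix(0, 2 * d, 1)
  W1[d + 1, 1] <- 1                  # hidden unit = protein coordinate 1
  params <- list(H_dti_W1 = W1, H_dti_b1 = matrix(0, 1, 1),
                 H_dti_W2 = matrix(1, 1, 1), H_dti_b2 = matrix(0, 1, 1))
  model <- list(vocab = list(drug = "D1", protein = g$nodes$protein,
                             cell = character(0), pathway = character(0),
                             go = character(0)),
                params = params)
  fit <- list(model = model, embeddings = emb, response_mode = "regression")
  class(fit) <- "hgnn_fit"
  fit
}

# The standard desk-scale simulation used by learning tests.
standard_sim <- function(seed = 7) {
  simulate_biohg(sim_config(seed = seed))
}

# Training configuration for desk-scale full-batch runs: higher learning
# rate than the large-data default, capped stream sizes, per-epoch stream
# resampling (regularizes the interaction heads).
desk_tc <- function(seed, max_epochs = 150L, ...) {
  train_config(lr = 0.01, max_epochs = max_epochs, seed = seed,
               resample_each_epoch = TRUE,
               sample_sizes = list(expr = 2000L, resp = 2500L,
                                   dti = Inf, pp = Inf), ...)
}

# Matching model configuration: feature dropout against head memorization.
desk_cfg <- function(...) hgnn_config(dropout = 0.2, ...)
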