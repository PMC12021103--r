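# Graph construction, schema enforcement, expression-derived edges, path
# queries, and serialization.

test_that("build_biohg assembles the toy graph with derived expression edges", {
  g <- toy_biohg()
  nc <- biohg_node_counts(g)
  expect_equal(unname(nc[c("drug", "protein", "cell_line", "pathway")]),
               c(2L, 3L, 1L, 1L))
  ec <- biohg_edge_counts(g)
  expect_equal(unname(ec[c("dti", "ppi", "protein_pathway")]), c(2L, 1L, 1L))
  # expression row (1,2,3), mean 2: only P3 strictly above
  pc <- g$edges[g$edges$edge_type == "protein_cell", ]
  expect_equal(pc$src_id, "P3")
  expect_equal(pc$weight, 3)
})

test_that("schema rejects drug-cell edges and unknown type pairings", {
  g <- toy_biohg()
  bad <- g
  bad$edges <- rbind(bad$edges,
                     data.frame(src_type = "drug", src_id = "D1",
                                dst_type = "cell_line", dst_id = "C1",
                                edge_type = "dti", weight = NA_real_))
  expect_error(validate_biohg(bad), "dti")
  bad2 <- g
  bad2$edges$edge_type[bad2$edges$edge_type == "ppi"] <- "friendship"
  expect_error(validate_biohg(bad2), "schema")
  # missing feature vector for a referenced drug
  expect_error(
    build_biohg(dti_edges = data.frame(src_id = c("D1", "DX"),
                                       dst_id = c("P1", "P1")),
                ppi_edges = data.frame(src_id = "P1", dst_id = "P2"),
                drug_features = matrix(1, 1, 4, dimnames = list("D1", NULL))),
    "DX")
})

test_that("construction is deterministic and serialization round-trips", {
  g1 <- toy_biohg()
  g2 <- toy_biohg()
  expect_identical(g1, g2)
  d1 <- file.path(tempdir(), "bh1"); d2 <- file.path(tempdir(), "bh2")
  write_biohg(g1, d1)
  write_biohg(g2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  g3 <- read_biohg(d1)
  expect_identical(g3$nodes, g1$nodes)
  expect_equal(g3$edges, g1$edges)
  expect_equal(g3$cell_features, g1$cell_features)
})

test_that("expression edges equal an independent row-mean filter", {
  set.seed(11)
  expr <- matrix(rnorm(200), 10, 20,
                 dimnames = list(sprintf("C%02d", 1:10), sprintf("P%02d", 1:20)))
  edges <- derive_expression_edges(expr)
  for (i in 1:10) {
    keep <- which(expr[i, ] > mean(expr[i, ]))   # independent filter
    got <- edges[edges$dst_id == rownames(expr)[i], ]
    expect_setequal(got$src_id, colnames(expr)[keep])
    expect_equal(sort(got$weight), sort(unname(expr[i, keep])))
  }
  # constant row: nothing exceeds its own mean
  expect_warning(e0 <- derive_expression_edges(
    matrix(5, 1, 3, dimnames = list("C1", c("a", "b", "c")))), "no above-mean")
  expect_equal(nrow(e0), 0L)
})

test_that("hop distances match a Floyd-Warshall oracle on random graphs", {
  # spec toy: D-P1 (dti), P1-P2 (ppi), isolated P3
  g <- indexed_biohg(3, matrix(c(1, 2), 1), dti_targets = 1L)
  d <- shortest_path_distance(g, "drug", "D1", "protein", g$nodes$protein)
  expect_equal(unname(d), c(1, 2, Inf))
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    el <- random_edge_list(n, 0.25)
    if (!nrow(el)) next
    g <- indexed_biohg(n, el)
    D <- fw_distances(n + 1, rbind(el, c(n + 1, 1)))  # drug node appended, wired to P1
    for (src in sample(n, 3)) {
      d <- shortest_path_distance(g, "protein", sprintf("P%02d", src),
                                  "protein", g$nodes$protein,
                                  edge_types = c("ppi", "dti"))
      expect_equal(unname(d), D[src, seq_len(n)])
      # symmetry of undirected BFS
      back <- shortest_path_distance(g, "protein", sprintf("P%02d", 1),
                                     "protein", sprintf("P%02d", src),
                                     edge_types = c("ppi", "dti"))
      expect_equal(unname(back), D[1, src])
    }
  }
  expect_error(shortest_path_distance(g, "protein", "P01", "protein", "P02",
                                      edge_types = character(0)), "non-empty")
})

test_that("mechanism subgraph keeps exactly the nodes on shortest paths", {
  # chain S-A-T
  g <- indexed_biohg(3, matrix(c(1, 2, 2, 3), 2, byrow = TRUE))
  sub <- mechanism_subgraph(g, "protein", "P01", "protein", "P03")
  expect_setequal(sub$nodes$protein, c("P01", "P02", "P03"))
  expect_equal(attr(sub, "status"), "ok")
  # two equal-length paths: both interiors kept
  g2 <- indexed_biohg(4, matrix(c(1, 2, 2, 4, 1, 3, 3, 4), 4, byrow = TRUE))
  sub2 <- mechanism_subgraph(g2, "protein", "P01", "protein", "P04")
  expect_setequal(sub2$nodes$protein, c("P01", "P02", "P03", "P04"))
  # unreachable sink
  g3 <- indexed_biohg(3, matrix(c(1, 2), 1))
  sub3 <- mechanism_subgraph(g3, "protein", "P01", "protein", "P03")
  expect_equal(attr(sub3, "status"), "unreachable")
  # random graphs vs exhaustive enumeration of all shortest paths
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(6:12, 1)
    el <- random_edge_list(n, 0.25)
    g <- indexed_biohg(n, el)
    adj <- matrix(0, n, n)
    adj[el] <- 1; adj[el[, 2:1, drop = FALSE]] <- 1
    s <- sample(n, 1); t <- sample(setdiff(1:n, s), 1)
    paths <- enumerate_shortest_paths(adj, s, t)
    sub <- mechanism_subgraph(g, "protein", sprintf("P%02d", s),
                              "protein", sprintf("P%02d", t))
    expected <- union(unique(unlist(paths)), c(s, t))
    expect_setequal(sub$nodes$protein, sprintf("P%02d", sort(expected)))
  }
})

test_that("gene mapping drops unmapped genes and restricting removes edges", {
  expr <- matrix(1:6, 2, 3,
                 dimnames = list(c("C1", "C2"), c("g1", "g2", "g3")))
  gm <- data.frame(gene_id = c("g1", "g3"), protein_id = c("P1", "P3"))
  expect_message(m <- hgdrp:::map_expression_genes(expr, gm), "1 expression")
  expect_equal(colnames(m), c("P1", "P3"))
  g <- toy_biohg()
  r <- restrict_biohg(g, drop_drugs = "D1", drop_cells = "C1")
  expect_false(any(r$edges$edge_type == "dti" & r$edges$src_id == "D1"))
  expect_false(any(r$edges$edge_type == "protein_cell"))
  expect_true("D1" %in% r$nodes$drug)     # node and features remain
})
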