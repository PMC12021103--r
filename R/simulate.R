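# Seeded synthetic biomedical graphs with planted ground truth.
#
# The generator emulates the statistical shape of the real data sources the
# model is meant for: a sparse bipartite drug-target layer, a protein-protein
# interaction network whose edges prefer functionally similar proteins,
# pathway/GO memberships that cluster proteins in a latent function space,
# expression profiles driven by per-cell pathway activity, and drug response
# values (on an lnIC50-like scale, lower = more sensitive) driven by the
# overlap between a drug's target pathways and a cell's active pathways.

#' Configuration for the synthetic heterogeneous-graph generator
#'
#' Defaults define the standard desk-scale fixture: 50 drugs, 200 proteins,
#' 30 cell lines, 10 pathways, 20 GO terms, response noise 0.3 on the
#' lnIC50-like scale.
#'
#' @param n_drugs,n_proteins,n_cells,n_pathways,n_go entity counts.
#' @param latent_dim dimension of the latent protein-function space.
#' @param dti_per_drug planted targets per drug.
#' @param ppi_degree mean protein--protein degree.
#' @param response_noise_sd standard deviation of the additive response noise.
#' @param response_scale slope linking planted target/pathway-activity overlap
#'   to the response value (negated: higher overlap means more sensitive,
#'   i.e. lower lnIC50).
#' @param fp_bits fingerprint width for the hashed synthetic drug features.
#' @param infection if `TRUE`, plant an "infected" cell subset with a shifted
#'   expression signature and an "antiviral" drug subset whose targets sit in
#'   the signature pathway, for exercising zero-shot screening.
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_drugs = 50L, n_proteins = 200L, n_cells = 30L,
                       n_pathways = 10L, n_go = 20L, latent_dim = 8L,
                       dti_per_drug = 3L, ppi_degree = 4, response_noise_sd = 0.3,
                       response_scale = 1.5, fp_bits = 1024L,
                       infection = FALSE, seed = 1L) {
  cfg <- list(n_drugs = as.integer(n_drugs), n_proteins = as.integer(n_proteins),
              n_cells = as.integer(n_cells), n_pathways = as.integer(n_pathways),
              n_go = as.integer(n_go), latent_dim = as.integer(latent_dim),
              dti_per_drug = as.integer(dti_per_drug), ppi_degree = ppi_degree,
              response_noise_sd = response_noise_sd,
              response_scale = response_scale, fp_bits = as.integer(fp_bits),
              infection = isTRUE(infection), seed = as.integer(seed))
  counts <- c("n_drugs", "n_proteins", "n_cells", "n_pathways", "n_go",
              "latent_dim", "dti_per_drug")
  if (any(unlist(cfg[counts]) < 1L)) stop("all counts must be >= 1")
  if (cfg$response_noise_sd < 0) stop("response_noise_sd must be >= 0")
  if (cfg$dti_per_drug > cfg$n_proteins) {
    stop("infeasible config: dti_per_drug exceeds n_proteins")
  }
  class(cfg) <- "sim_config"
  cfg
}

.pad_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

#' Simulate a heterogeneous biomedical graph with planted ground truth
#'
#' Proteins live in a latent function space clustered by pathway; GO terms
#' are a second, coarser clustering.  PPI edges preferentially connect
#' latent-similar proteins.  Each drug is anchored to a pathway and targets
#' latent-coherent proteins near that anchor; its binary fingerprint is
#' hashed from the anchor direction (plus bit noise), so the fingerprint
#' carries a learnable signal about the drug's targets -- the property the
#' cold-start fingerprint transform relies on.  Cell expression is pathway
#' activity plus noise, and the response of drug d in cell c is
#' `-response_scale * overlap(d, c) + eps`, where the overlap is the mean
#' activity, in cell c, of the pathways of d's targets.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `graph` (a `biohg`), `response` (data.frame
#'   `drug_id`, `cell_id`, `value`), `expression` (the raw matrix), and
#'   `truth` (planted latents, target sets, pathway memberships, activities,
#'   the noise-free response surface, and -- under `infection = TRUE` -- the
#'   planted infected-cell and antiviral-drug subsets).
#' @export
simulate_biohg <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  did <- .pad_ids("D", cfg$n_drugs)
  pid <- .pad_ids("P", cfg$n_proteins)
  cid <- .pad_ids("C", cfg$n_cells)
  wid <- .pad_ids("PW", cfg$n_pathways)
  gid <- .pad_ids("GO", cfg$n_go)

  # latent function space
  pw_centers <- matrix(stats::rnorm(cfg$n_pathways * cfg$latent_dim, sd = 2),
                       cfg$n_pathways, cfg$latent_dim)
  pw_of_protein <- sample(cfg$n_pathways, cfg$n_proteins, replace = TRUE)
  latents <- pw_centers[pw_of_protein, , drop = FALSE] +
    matrix(stats::rnorm(cfg$n_proteins * cfg$latent_dim, sd = 0.5),
           cfg$n_proteins, cfg$latent_dim)
  rownames(latents) <- pid

  # pathway membership: primary pathway plus occasional second membership
  pw_edges <- data.frame(src_id = pid, dst_id = wid[pw_of_protein])
  extra <- which(stats::runif(cfg$n_proteins) < 0.1)
  if (length(extra) && cfg$n_pathways > 1L) {
    second <- vapply(pw_of_protein[extra], function(k)
      sample(setdiff(seq_len(cfg$n_pathways), k), 1L), integer(1))
    pw_edges <- rbind(pw_edges, data.frame(src_id = pid[extra],
                                           dst_id = wid[second]))
  }

  # GO terms: coarser latent clustering (nearest GO center, some extras)
  go_centers <- matrix(stats::rnorm(cfg$n_go * cfg$latent_dim, sd = 2),
                       cfg$n_go, cfg$latent_dim)
  d2 <- as.matrix(stats::dist(rbind(latents, go_centers)))
  d2 <- d2[seq_len(cfg$n_proteins), cfg$n_proteins + seq_len(cfg$n_go), drop = FALSE]
  go_primary <- apply(d2, 1L, which.min)
  go_edges <- data.frame(src_id = pid, dst_id = gid[go_primary])
  extra <- which(stats::runif(cfg$n_proteins) < 0.2)
  if (length(extra) && cfg$n_go > 1L) {
    second <- vapply(extra, function(i)
      sample(setdiff(seq_len(cfg$n_go), go_primary[i]), 1L), integer(1))
    go_edges <- rbind(go_edges, data.frame(src_id = pid[extra], dst_id = gid[second]))
  }

  # PPI: each protein links to ~ppi_degree/2 partners, mostly latent-near
  k_per <- max(1L, round(cfg$ppi_degree / 2))
  sim_order <- t(apply(as.matrix(stats::dist(latents)), 1L, order))
  ppi_src <- ppi_dst <- character(0)
  for (i in seq_len(cfg$n_proteins)) {
    near <- sim_order[i, 2:min(16L, cfg$n_proteins)]
    for (k in seq_len(k_per)) {
      j <- if (stats::runif(1) < 0.8) near[sample.int(length(near), 1L)]
      else sample.int(cfg$n_proteins, 1L)
      if (j != i) {
        ppi_src <- c(ppi_src, pid[i]); ppi_dst <- c(ppi_dst, pid[j])
      }
    }
  }
  ppi_edges <- data.frame(src_id = ppi_src, dst_id = ppi_dst)

  # cells: nonnegative pathway activity; infection shifts a signature pathway
  activity <- matrix(stats::rgamma(cfg$n_cells * cfg$n_pathways, shape = 2, rate = 1),
                     cfg$n_cells, cfg$n_pathways)
  rownames(activity) <- cid
  infected <- character(0)
  sig_pw <- NA_integer_
  if (cfg$infection) {
    sig_pw <- 1L
    infected <- cid[seq_len(max(2L, floor(cfg$n_cells / 2)))]
    activity[, sig_pw] <- 0.1 * stats::rgamma(cfg$n_cells, shape = 1, rate = 2)
    activity[infected, sig_pw] <- 4 + stats::rgamma(length(infected), shape = 2, rate = 1)
  }

  # drugs: anchor pathway, latent-coherent targets, hashed fingerprint
  anchor <- sample(cfg$n_pathways, cfg$n_drugs, replace = TRUE)
  if (cfg$infection && sum(anchor == sig_pw) < 2L) {
    # guarantee a planted antiviral subset of at least two drugs
    anchor[sample(which(anchor != sig_pw), 2L - sum(anchor == sig_pw))] <- sig_pw
  }
  target_sets <- vector("list", cfg$n_drugs)
  u <- matrix(0, cfg$n_drugs, cfg$latent_dim)
  for (d in seq_len(cfg$n_drugs)) {
    u[d, ] <- pw_centers[anchor[d], ] + stats::rnorm(cfg$latent_dim, sd = 0.4)
    dist_to_u <- sqrt(colSums((t(latents) - u[d, ])^2))
    pool <- order(dist_to_u)[seq_len(min(10L, cfg$n_proteins))]
    target_sets[[d]] <- pid[sort(sample(pool, cfg$dti_per_drug))]
  }
  names(target_sets) <- did
  dti_edges <- data.frame(
    src_id = rep(did, each = cfg$dti_per_drug),
    dst_id = unlist(target_sets))

  hash_mat <- matrix(stats::rnorm(cfg$fp_bits * cfg$latent_dim),
                     cfg$fp_bits, cfg$latent_dim)
  p_on <- stats::plogis(hash_mat %*% t(u) * 0.8)          # fp_bits x n_drugs
  fp <- matrix(stats::rbinom(length(p_on), 1L, p_on), nrow(p_on))
  flip <- matrix(stats::runif(length(fp)) < 0.02, nrow(fp))
  fp[flip] <- 1L - fp[flip]
  drug_features <- t(fp)
  rownames(drug_features) <- did

  antiviral <- if (cfg$infection) did[anchor == sig_pw] else character(0)

  gene_scale <- stats::runif(cfg$n_proteins, 0.8, 1.2)
  expr <- activity[, pw_of_protein, drop = FALSE] *
    matrix(gene_scale, cfg$n_cells, cfg$n_proteins, byrow = TRUE) +
    matrix(stats::rnorm(cfg$n_cells * cfg$n_proteins, sd = 0.3),
           cfg$n_cells, cfg$n_proteins)
  dimnames(expr) <- list(cid, pid)

  overlap <- matrix(0, cfg$n_drugs, cfg$n_cells, dimnames = list(did, cid))
  for (d in seq_len(cfg$n_drugs)) {
    pws <- pw_of_protein[match(target_sets[[d]], pid)]
    overlap[d, ] <- rowMeans(activity[, pws, drop = FALSE])
  }
  noisefree <- -cfg$response_scale * overlap
  response_mat <- noisefree +
    matrix(stats::rnorm(length(overlap), sd = cfg$response_noise_sd),
           nrow(overlap))
  response <- data.frame(
    drug_id = rep(did, times = cfg$n_cells),
    cell_id = rep(cid, each = cfg$n_drugs),
    value = as.numeric(response_mat))

  graph <- build_biohg(dti_edges = dti_edges, ppi_edges = ppi_edges,
                       pathway_edges = pw_edges, go_edges = go_edges,
                       expr = expr, drug_features = drug_features)

  truth <- list(protein_latents = latents,
                pathway_of_protein = stats::setNames(wid[pw_of_protein], pid),
                pw_index_of_protein = stats::setNames(pw_of_protein, pid),
                drug_target_sets = target_sets,
                drug_anchor_pathway = stats::setNames(wid[anchor], did),
                pathway_membership = split(pid, wid[pw_of_protein]),
                cell_activity = activity, gene_scale =
                  stats::setNames(gene_scale, pid),
                pathway_centers = pw_centers,
                true_response = noisefree, overlap = overlap,
                infected_cells = infected, antiviral_drugs = antiviral,
                config = cfg)
  list(graph = graph, response = response, expression = expr, truth = truth)
}

#' Simulate an external cohort (xenograft-style transfer set)
#'
#' Draws new cell-line-like models from the same generative process as the
#' training world but with unseen IDs, z-scores their expression per gene,
#' and reports responses as log10 IC50 values clamped to \[-10, 10\] -- the
#' preprocessing used when transferring a screening-trained model to an
#' external cohort measured on a different scale.
#'
#' @param truth the `truth` element returned by [simulate_biohg()].
#' @param n_new_cells number of cohort models to draw (>= 1).
#' @param seed seed for the cohort draw.
#' @return list with `expression` (z-scored matrix, rows `XC...`) and
#'   `response` (data.frame `drug_id`, `cell_id`, `value` on the clamped
#'   log10 scale).
#' @export
simulate_external_cohort <- function(truth, n_new_cells, seed = 1L) {
  if (n_new_cells < 1L) stop("n_new_cells must be >= 1")
  cfg <- truth$config
  set.seed(as.integer(seed))
  xcid <- sprintf("XC%03d", seq_len(n_new_cells))
  activity <- matrix(stats::rgamma(n_new_cells * cfg$n_pathways, shape = 2, rate = 1),
                     n_new_cells, cfg$n_pathways, dimnames = list(xcid, NULL))
  pid <- names(truth$gene_scale)
  pw_idx <- as.integer(truth$pw_index_of_protein)
  expr <- activity[, pw_idx, drop = FALSE] *
    matrix(truth$gene_scale, n_new_cells, length(pid), byrow = TRUE) +
    matrix(stats::rnorm(n_new_cells * length(pid), sd = 0.3), n_new_cells)
  dimnames(expr) <- list(xcid, pid)
  expr_z <- scale(expr)
  attr(expr_z, "scaled:center") <- NULL
  attr(expr_z, "scaled:scale") <- NULL

  did <- names(truth$drug_target_sets)
  overlap <- matrix(0, length(did), n_new_cells, dimnames = list(did, xcid))
  for (d in seq_along(did)) {
    pws <- pw_idx[match(truth$drug_target_sets[[d]], pid)]
    overlap[d, ] <- rowMeans(activity[, pws, drop = FALSE])
  }
  ln_ic50 <- -cfg$response_scale * overlap +
    matrix(stats::rnorm(length(overlap), sd = cfg$response_noise_sd), nrow(overlap))
  raw_ic50 <- exp(ln_ic50)
  value <- clamp_log10_response(raw_ic50)
  response <- data.frame(drug_id = rep(did, times = n_new_cells),
                         cell_id = rep(xcid, each = length(did)),
                         value = as.numeric(value))
  list(expression = expr_z, response = response)
}

#' Log10-transform and clamp raw IC50 values to \[-10, 10\]
#' @param raw_ic50 positive raw concentration values.
#' @return clamped log10 values.
#' @export
clamp_log10_response <- function(raw_ic50) {
  pmin(10, pmax(-10, log10(raw_ic50)))
}
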