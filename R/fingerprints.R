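# Circular (Morgan/ECFP4) fingerprints for drug structures.

#' Compute 1024-bit circular fingerprints from SMILES
#'
#' Extended-connectivity fingerprints of diameter 4 (radius 2) computed with
#' OpenBabel through the ChemmineOB package, folded from OpenBabel's native
#' 4096-bit vector down to `n_bits` by OR-ing congruent positions.  The
#' synthetic-data pipeline does not need SMILES at all (it hashes fingerprints
#' from planted target structure), so this helper only matters when real
#' structure tables are supplied.
#'
#' @param smiles named character vector of SMILES strings (names = drug IDs).
#' @param n_bits folded fingerprint width, default 1024.
#' @return binary 0/1 matrix, one row per drug.
#' @export
morgan_fingerprints <- function(smiles, n_bits = 1024L) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("morgan_fingerprints requires the ChemmineOB package")
  }
  stopifnot(length(smiles) > 0L, !is.null(names(smiles)))
  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                 identity)
  fp <- ChemmineOB::fingerprint_OB(mols, "ECFP4")
  fold <- matrix(0, nrow(fp), n_bits)
  idx <- ((seq_len(ncol(fp)) - 1L) %% n_bits) + 1L
  for (j in seq_len(ncol(fp))) {
    fold[, idx[j]] <- pmax(fold[, idx[j]], fp[, j])
  }
  rownames(fold) <- names(smiles)
  fold
}

#' Read a drug structure table (`drug_id smiles`) and featurize it
#' @param path TSV with columns `drug_id` and `smiles`.
#' @param n_bits fingerprint width.
#' @return binary feature matrix with drug IDs as rownames.
#' @export
read_drug_table <- function(path, n_bits = 1024L) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("drug_id", "smiles") %in% names(df))) {
    stop("drug table must have columns drug_id and smiles")
  }
  morgan_fingerprints(stats::setNames(df$smiles, df$drug_id), n_bits = n_bits)
}
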