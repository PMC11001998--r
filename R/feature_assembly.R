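## Assembling model features.
##
## Protein fingerprints (targets x 16,381 bits) are reduced by centered
## PCA; the number of components either matches the number of targets or
## captures at least 99% of the variance. Molecule bits are used directly.
## A feature row is the 2048 molecule bits followed by the k protein
## components of the activity's target, labelled with spKi.
##
## PCA is fitted on all targets' fingerprints, including any later held
## out for blind validation: the fit is unsupervised and uses no activity
## labels, so no label information can leak through it; projections must
## exist for held-out targets.

#' Binary fingerprint matrix from a list of fingerprints
#'
#' @param fps List of `ProteinFingerprint` objects with uniform `n_bits`.
#' @return Binary matrix, one row per fingerprint (rownames =
#'   structure ids), `n_bits` columns.
#' @export
fingerprint_matrix <- function(fps) {
  stopifnot(length(fps) >= 1)
  nb <- unique(vapply(fps, function(f) f$n_bits, integer(1)))
  if (length(nb) != 1) stop("fingerprints have different n_bits")
  ids <- vapply(fps, function(f) f$structure_id, character(1))
  m <- matrix(0L, nrow = length(fps), ncol = nb,
              dimnames = list(ids, paste0("pbit", seq_len(nb) - 1L)))
  for (i in seq_along(fps)) m[i, fps[[i]]$on_bits + 1L] <- 1L
  m
}

#' Fit the protein-fingerprint PCA projection
#'
#' Centered (not scaled) PCA of the target fingerprint matrix. Under the
#' `n_targets` policy, k equals the number of targets, truncated to the
#' matrix rank with a warning when smaller; under `variance_99`, k is the
#' smallest number of components whose cumulative explained variance
#' reaches 99%. The sign of each component is fixed so its
#' largest-magnitude loading is positive, making the fit deterministic.
#'
#' @param fp_matrix Binary targets x n_bits matrix (rownames = target ids).
#' @param policy `"n_targets"` or `"variance_99"`.
#' @return Object of class `ProjectionModel`: `loadings` (n_bits x k),
#'   `center`, `sdev`, `variance_explained`, `n_components`, `policy`,
#'   `fitted_on`.
#' @export
fit_projection <- function(fp_matrix, policy = c("n_targets", "variance_99")) {
  policy <- match.arg(policy)
  stopifnot(is.matrix(fp_matrix), nrow(fp_matrix) >= 2)
  if (is.null(rownames(fp_matrix)))
    rownames(fp_matrix) <- paste0("T", seq_len(nrow(fp_matrix)))
  pc <- stats::prcomp(fp_matrix, center = TRUE, scale. = FALSE)
  pos <- pc$sdev > max(pc$sdev) * 1e-8
  rank <- sum(pos)
  if (rank == 0)
    stop("degenerate input: all fingerprints are identical, PCA undefined")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- switch(policy,
    n_targets = {
      k0 <- min(nrow(fp_matrix), ncol(fp_matrix))
      if (rank < k0)
        warning("rank ", rank, " < number of targets ", k0,
                "; truncating components to rank")
      min(k0, rank)
    },
    variance_99 = which(cumsum(ve) >= 0.99)[1])
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest |loading| of each component made positive
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  structure(
    list(loadings = load, center = pc$center, sdev = pc$sdev[seq_len(k)],
         variance_explained = ve[seq_len(k)], n_components = k,
         policy = policy, fitted_on = rownames(fp_matrix)),
    class = "ProjectionModel")
}

#' @export
print.ProjectionModel <- function(x, ...) {
  cat(sprintf("ProjectionModel: %d components (%s policy), %.1f%% variance, fitted on %d targets\n",
              x$n_components, x$policy, 100 * sum(x$variance_explained),
              length(x$fitted_on)))
  invisible(x)
}

#' Project fingerprints onto fitted components
#'
#' Defined for any fingerprint with matching bit length, including targets
#' not used in fitting (required by the blind regimes).
#'
#' @param model A `ProjectionModel`.
#' @param fp A `ProteinFingerprint`, or a binary matrix with `n_bits`
#'   columns.
#' @return Matrix of component scores (rows = structures, k columns).
#' @export
project <- function(model, fp) {
  stopifnot(inherits(model, "ProjectionModel"))
  if (inherits(fp, "ProteinFingerprint")) fp <- fingerprint_matrix(list(fp))
  stopifnot(is.matrix(fp))
  if (ncol(fp) != nrow(model$loadings))
    stop("fingerprint length ", ncol(fp), " does not match model (",
         nrow(model$loadings), ")")
  scores <- sweep(fp, 2, model$center) %*% model$loadings
  colnames(scores) <- paste0("pc", seq_len(model$n_components))
  scores
}

#' Assemble the modeling dataset
#'
#' Joins curated activities with molecule fingerprints and projected
#' protein components into feature rows of length 2048 + k. Activities
#' whose molecule or target lacks features are reported, never silently
#' dropped.
#'
#' @param curated Curated activities (`molecule_id`, `target_id`, `spki`).
#' @param mol_fps Binary molecule matrix (rownames = molecule ids).
#' @param protein_proj Projection score matrix (rownames = target ids).
#' @return Object of class `AssembledDataset`: `features` (numeric
#'   matrix), `label` (spKi vector), `molecule_id`, `target_id`,
#'   `n_mol_bits`, `n_components`, and `missing` (report of unjoinable
#'   activities).
#' @export
assemble <- function(curated, mol_fps, protein_proj) {
  stopifnot(is.data.frame(curated), is.matrix(mol_fps), is.matrix(protein_proj))
  key <- paste(curated$molecule_id, curated$target_id)
  if (anyDuplicated(key)) stop("duplicate (molecule, target) pairs in curated data")
  has_mol <- curated$molecule_id %in% rownames(mol_fps)
  has_tgt <- curated$target_id %in% rownames(protein_proj)
  ok <- has_mol & has_tgt
  missing <- curated[!ok, c("molecule_id", "target_id"), drop = FALSE]
  if (nrow(missing))
    missing$reason <- ifelse(!has_mol[!ok], "no_molecule_fingerprint",
                             "no_target_projection")
  cur <- curated[ok, , drop = FALSE]
  features <- cbind(mol_fps[cur$molecule_id, , drop = FALSE],
                    protein_proj[cur$target_id, , drop = FALSE])
  rownames(features) <- NULL
  structure(
    list(features = features, label = cur$spki,
         molecule_id = cur$molecule_id, target_id = cur$target_id,
         n_mol_bits = ncol(mol_fps), n_components = ncol(protein_proj),
         missing = missing),
    class = "AssembledDataset")
}

#' @export
print.AssembledDataset <- function(x, ...) {
  cat(sprintf("AssembledDataset: %d rows x (%d molecule bits + %d components), %d targets\n",
              nrow(x$features), x$n_mol_bits, x$n_components,
              length(unique(x$target_id))))
  invisible(x)
}

# subset rows of an AssembledDataset
dataset_rows <- function(ds, idx) {
  structure(
    list(features = ds$features[idx, , drop = FALSE], label = ds$label[idx],
         molecule_id = ds$molecule_id[idx], target_id = ds$target_id[idx],
         n_mol_bits = ds$n_mol_bits, n_components = ds$n_components,
         missing = ds$missing[0, , drop = FALSE]),
    class = "AssembledDataset")
}
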