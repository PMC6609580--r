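#' z-score matrices by adjacent-normal statistics
#'
#' Standardizes every feature of both matrices by the mean and (n-1) standard
#' deviation of the normal matrix. Features with zero normal variance are
#' dropped from both outputs with a warning.
#'
#' @param tumor,normal matrices (samples x features) sharing feature ids.
#' @return list with `tumor`, `normal`, `center`, `scale`, `dropped`.
#' @export
zscore_by_normal <- function(tumor, normal) {
  if (!identical(colnames(tumor), colnames(normal)))
    stop("tumor and normal must share feature ids in the same order")
  if (nrow(normal) < 2) stop("normal needs >= 2 samples")
  ctr <- colMeans(normal)
  scl <- apply(normal, 2, stats::sd)
  drop_idx <- which(!is.finite(scl) | scl == 0)
  if (length(drop_idx) > 0) {
    warning(length(drop_idx),
            " zero-variance feature(s) dropped at z-score step")
    tumor <- tumor[, -drop_idx, drop = FALSE]
    normal <- normal[, -drop_idx, drop = FALSE]
    ctr <- ctr[-drop_idx]
    scl <- scl[-drop_idx]
  }
  zs <- function(m) sweep(sweep(m, 2, ctr, "-"), 2, scl, "/")
  list(tumor = zs(tumor), normal = zs(normal), center = ctr, scale = scl,
       dropped = names(drop_idx))
}

#' Remove the top principal components of the normal matrix
#'
#' Subtracts from every sample (tumor and normal alike) its projection onto
#' the `n_components` leading right singular vectors of the normal matrix.
#' Inputs are expected to be z-scored already.
#'
#' @param tumor,normal z-scored matrices with identical feature columns.
#' @param n_components how many leading directions to remove (default 3).
#' @return list with `tumor`, `normal`, `components` (features x
#'   `n_components`, orthonormal).
#' @export
svd_detrend <- function(tumor, normal, n_components = 3) {
  if (!identical(colnames(tumor), colnames(normal)))
    stop("tumor and normal must share feature ids in the same order")
  if (n_components == 0)
    return(list(tumor = tumor, normal = normal,
                components = matrix(0, ncol(normal), 0)))
  cap <- min(dim(normal))
  if (n_components >= cap)
    stop("n_components must be < min(dim(normal)) = ", cap)
  sv <- svd(normal, nu = 0, nv = n_components)
  v <- sv$v[, seq_len(n_components), drop = FALSE]
  rownames(v) <- colnames(normal)
  detrend <- function(m) m - (m %*% v) %*% t(v)
  list(tumor = detrend(tumor), normal = detrend(normal), components = v)
}

#' Full DNA-methylation standardization
#'
#' Applies, in order: z-score by normal statistics, removal of the top three
#' normal-derived principal directions, and a final z-score by normal
#' statistics. All steps use the adjacent-normal samples to define the
#' transformation and apply it to tumor samples with the same parameters.
#'
#' @param tumor,normal per-tissue paired matrices.
#' @param n_components principal directions removed (default 3).
#' @return list with `tumor`, `normal`, and `state` (class
#'   `normalization_state`: centers/scales of both z-score passes,
#'   `top_components`, `applied_steps`, `dropped_features`).
#' @export
normalize_dnam <- function(tumor, normal, n_components = 3) {
  z1 <- zscore_by_normal(tumor, normal)
  sv <- svd_detrend(z1$tumor, z1$normal, n_components)
  z2 <- zscore_by_normal(sv$tumor, sv$normal)
  state <- structure(list(
    center1 = z1$center, scale1 = z1$scale,
    top_components = sv$components,
    center2 = z2$center, scale2 = z2$scale,
    applied_steps = c("zscore", paste0("svd", n_components), "zscore"),
    dropped_features = union(z1$dropped, z2$dropped)),
    class = "normalization_state")
  list(tumor = z2$tumor, normal = z2$normal, state = state)
}

#' Median normalization of expression
#'
#' Scales each sample (row) so that its median equals the grand median of the
#' pre-scaling per-sample medians (with an even number of samples, the grand
#' median is the midpoint of the two central values).
#'
#' @param expression nonnegative matrix, samples x genes.
#' @return rescaled matrix of the same shape.
#' @export
median_normalize <- function(expression) {
  if (any(expression < 0)) stop("expression must be nonnegative")
  med <- apply(expression, 1, stats::median)
  zero <- which(med == 0)
  if (length(zero) > 0)
    stop("sample with zero median expression: ",
         rownames(expression)[zero[1]])
  grand <- stats::median(med)
  sweep(expression, 1, grand / med, "*")
}

#' Binarize a mutation-count matrix
#'
#' A gene is 1 in a sample iff it carries at least one non-synonymous
#' mutation there.
#'
#' @param raw matrix of nonnegative mutation counts.
#' @return integer 0/1 matrix of the same shape.
#' @export
binarize_mutations <- function(raw) {
  if (any(raw < 0)) stop("mutation counts must be nonnegative")
  out <- (raw > 0) + 0L
  dimnames(out) <- dimnames(raw)
  out
}

#' Preprocess a paired cohort
#'
#' Runs the full standardization per tissue: DNAm via [normalize_dnam()]
#' (using that tissue's adjacent normals), expression via
#' [median_normalize()] over all samples, mutations via
#' [binarize_mutations()]. Features dropped in any tissue are dropped
#' globally so matrices stay rectangular.
#'
#' @param cohort a `paired_cohort`.
#' @param n_components principal directions removed per tissue (default 3).
#' @return a `paired_cohort` with normalized matrices and a
#'   `normalization_states` element (one `normalization_state` per tissue).
#' @export
preprocess_cohort <- function(cohort, n_components = 3) {
  anno <- cohort$annotations
  tissues <- unique(anno$tissue)
  per_tissue <- lapply(tissues, function(ts) {
    sub <- anno[anno$tissue == ts, ]
    pm <- pair_matrices(cohort$dnam[sub$sample_id, , drop = FALSE], sub)
    normalize_dnam(pm$tumor, pm$normal, n_components)
  })
  names(per_tissue) <- tissues
  kept <- Reduce(intersect, lapply(per_tissue, function(r) colnames(r$normal)))
  dnam <- matrix(NA_real_, nrow(anno), length(kept),
                 dimnames = list(anno$sample_id, kept))
  for (ts in tissues) {
    sub <- anno[anno$tissue == ts, ]
    res <- per_tissue[[ts]]
    pm_ids <- rownames(res$tumor)
    # map pair ids back to sample ids
    tum <- sub[sub$status == "tumor", ]
    nor <- sub[sub$status == "normal", ]
    dnam[tum$sample_id[match(pm_ids, tum$pair_id)], ] <-
      res$tumor[, kept, drop = FALSE]
    dnam[nor$sample_id[match(pm_ids, nor$pair_id)], ] <-
      res$normal[, kept, drop = FALSE]
  }
  structure(list(
    dnam = dnam,
    expression = median_normalize(cohort$expression),
    mutation = binarize_mutations(cohort$mutation),
    annotations = anno,
    normalization_states = lapply(per_tissue, `[[`, "state")),
    class = "paired_cohort")
}
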