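#' Binary age-group label
#'
#' Samples older than 60 years are labeled 1 ("old"), all others 0.
#'
#' @param age_years nonnegative age(s) in years.
#' @return integer 0/1 vector.
#' @export
age_label <- function(age_years) {
  if (any(age_years < 0)) stop("age must be nonnegative")
  as.integer(age_years > 60)
}

#' Screen candidate aging CpGs
#'
#' Per-CpG two-group Kruskal-Wallis test of methylation against the binary
#' age label, Benjamini-Hochberg adjustment over all CpGs, and retention at
#' p < 0.05 and FDR < 0.2. Results are sorted by ascending p, ties broken by
#' CpG id.
#'
#' @param dnam_normal normalized adjacent-normal methylation, samples x CpGs.
#' @param labels binary age labels aligned with rows.
#' @param p_cut,fdr_cut retention thresholds.
#' @return data frame with `cpg_id`, `p_value`, `fdr`.
#' @export
screen_markers <- function(dnam_normal, labels, p_cut = 0.05, fdr_cut = 0.2) {
  if (length(unique(labels)) < 2)
    stop("both age classes must be present")
  p <- kw_columns(dnam_normal, labels)
  fdr <- bh_fdr(p)
  keep <- which(p < p_cut & fdr < fdr_cut)
  out <- data.frame(cpg_id = colnames(dnam_normal)[keep],
                    p_value = p[keep], fdr = fdr[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_value, out$cpg_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Train the multi-tissue aging-score predictor
#'
#' Sweeps the number of markers k over a grid (default `1..min(50,
#' #candidates)`, candidates in screen order). For each k, a linear
#' epsilon-insensitive SVR is fitted on all tissues but one and the balanced
#' classification error (score threshold 0.5) is computed on the held-out
#' tissue; the per-k error is the unweighted mean over folds. The smallest k
#' attaining the minimal mean error is chosen and the model refitted on all
#' training data.
#'
#' @param dnam_normal normalized normal-tissue methylation, samples x CpGs.
#' @param labels binary age labels.
#' @param tissues tissue label per sample (folds = one per tissue).
#' @param candidates CpG ids ordered by the marker screen.
#' @param k_grid marker counts to sweep (default `1:min(50, #candidates)`).
#' @param cost,epsilon SVR hyperparameters (defaults 1 and 0.1).
#' @return object of class `clock_model`: `marker_ids`, fitted `svr`,
#'   `score_threshold` (0.5), `learning_curve` (data frame k, cv_error),
#'   `chosen_k`.
#' @export
train_clock <- function(dnam_normal, labels, tissues, candidates,
                        k_grid = NULL, cost = 1, epsilon = 0.1) {
  fold_ids <- unique(tissues)
  if (length(fold_ids) < 2) stop("need >= 2 training tissues")
  candidates <- candidates[candidates %in% colnames(dnam_normal)]
  if (length(candidates) == 0) stop("no candidate markers available")
  if (is.null(k_grid)) k_grid <- seq_len(min(50, length(candidates)))
  k_grid <- k_grid[k_grid <= length(candidates)]
  x_all <- dnam_normal[, candidates, drop = FALSE]
  errs <- matrix(NA_real_, length(fold_ids), length(k_grid),
                 dimnames = list(fold_ids, k_grid))
  for (f in fold_ids) {
    te <- tissues == f
    if (length(unique(labels[te])) < 2) {
      warning("fold ", f, " has a single age class; skipped")
      next
    }
    for (j in seq_along(k_grid)) {
      k <- k_grid[j]
      # a few hundred passes suffice for fold-error estimation; the final
      # refit below uses the solver default
      fit <- linear_svr(x_all[!te, seq_len(k), drop = FALSE], labels[!te],
                        cost = cost, epsilon = epsilon, max_iter = 300L)
      pred <- as.integer(
        predict(fit, x_all[te, seq_len(k), drop = FALSE]) > 0.5)
      errs[f, j] <- balanced_error(pred, labels[te])
    }
  }
  curve <- colMeans(errs, na.rm = TRUE)
  chosen_k <- k_grid[which(curve <= min(curve) + 1e-12)[1]]
  markers <- candidates[seq_len(chosen_k)]
  svr <- linear_svr(x_all[, seq_len(chosen_k), drop = FALSE], labels,
                    cost = cost, epsilon = epsilon)
  structure(list(marker_ids = markers, svr = svr, score_threshold = 0.5,
                 learning_curve = data.frame(k = k_grid, cv_error = curve,
                                             row.names = NULL),
                 chosen_k = chosen_k,
                 folds = rownames(errs)[rowSums(!is.na(errs)) > 0]),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("DNAm aging clock:", length(x$marker_ids), "markers, CV error",
      format(min(x$learning_curve$cv_error), digits = 4), "\n")
  invisible(x)
}

#' Score samples with a trained clock
#'
#' Applies the linear regressor to the marker columns; scores are unclipped,
#' and a sample is labeled old (1) iff its score exceeds 0.5. When
#' annotations are supplied, aging acceleration (tumor score minus the paired
#' normal score) is computed for every complete pair.
#'
#' @param model a `clock_model`.
#' @param dnam methylation matrix containing all marker columns.
#' @param annotations optional sample annotations (`sample_id`, `pair_id`,
#'   `status`) for acceleration.
#' @return object of class `aging_scores`: `samples` (data frame sample_id,
#'   score, label) and, when annotations are given, `pairs` (pair_id,
#'   tumor_score, normal_score, acceleration).
#' @export
score_samples <- function(model, dnam, annotations = NULL) {
  missing <- setdiff(model$marker_ids, colnames(dnam))
  if (length(missing) > 0)
    stop("missing marker column(s): ", paste(missing, collapse = ", "))
  score <- predict(model$svr, dnam[, model$marker_ids, drop = FALSE])
  samples <- data.frame(sample_id = rownames(dnam), score = score,
                        label = as.integer(score > model$score_threshold),
                        stringsAsFactors = FALSE, row.names = NULL)
  pairs <- NULL
  if (!is.null(annotations)) {
    a <- annotations[match(samples$sample_id, annotations$sample_id), ]
    tum <- samples[a$status == "tumor", ]
    nor <- samples[a$status == "normal", ]
    tum$pair_id <- a$pair_id[a$status == "tumor"]
    nor$pair_id <- a$pair_id[a$status == "normal"]
    common <- intersect(tum$pair_id, nor$pair_id)
    tum <- tum[match(common, tum$pair_id), ]
    nor <- nor[match(common, nor$pair_id), ]
    pairs <- data.frame(pair_id = common,
                        tumor_score = tum$score, normal_score = nor$score,
                        acceleration = tum$score - nor$score,
                        stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(samples = samples, pairs = pairs), class = "aging_scores")
}

#' Test the significance of aging acceleration
#'
#' Two-group Kruskal-Wallis test of tumor versus normal aging scores, plus
#' the median and mean score differences.
#'
#' @param tumor_scores,normal_scores nonempty numeric vectors.
#' @return list with `H`, `p`, `median_diff`, `mean_diff`.
#' @export
acceleration_test <- function(tumor_scores, normal_scores) {
  if (length(tumor_scores) == 0 || length(normal_scores) == 0)
    stop("score vectors must be nonempty")
  kw <- kruskal_wallis(list(tumor_scores, normal_scores))
  list(H = kw$H, p = kw$p,
       median_diff = stats::median(tumor_scores) - stats::median(normal_scores),
       mean_diff = mean(tumor_scores) - mean(normal_scores))
}
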