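#' Differentially expressed candidate genes
#'
#' Per gene: an exact two-sided sign test on the paired tumor-minus-normal
#' differences, Benjamini-Hochberg adjustment over all genes, and the fold
#' change as the median over pairs of the tumor/normal expression ratio
#' (pairs with a nonpositive normal value are skipped for that gene's fold
#' change). A gene is retained when p < 0.05, FDR < 0.2 and the fold change
#' exceeds 2 (or is below 0.5 for downregulation).
#'
#' @param tumor,normal paired expression matrices, rows = pair ids.
#' @param p_cut,fdr_cut,fc_cut thresholds (defaults 0.05, 0.2, 2).
#' @return data frame `gene_id`, `p_value`, `fdr`, `fold_change`,
#'   `retained`.
#' @export
deg_candidates <- function(tumor, normal, p_cut = 0.05, fdr_cut = 0.2,
                           fc_cut = 2) {
  if (!identical(rownames(tumor), rownames(normal)))
    stop("tumor and normal must be aligned by pair id")
  genes <- colnames(tumor)
  p <- vapply(genes, function(g) sign_test(tumor[, g] - normal[, g]),
              numeric(1))
  skipped <- 0L
  fc <- vapply(genes, function(g) {
    ok <- normal[, g] > 0
    if (!all(ok)) skipped <<- skipped + 1L
    if (!any(ok)) return(NA_real_)
    stats::median(tumor[ok, g] / normal[ok, g])
  }, numeric(1))
  if (skipped > 0)
    message(skipped, " gene(s) had pairs with nonpositive normal values",
            " skipped for fold change")
  fdr <- bh_fdr(p)
  retained <- p < p_cut & fdr < fdr_cut &
    !is.na(fc) & (fc > fc_cut | fc < 1 / fc_cut)
  data.frame(gene_id = genes, p_value = p, fdr = fdr, fold_change = fc,
             retained = retained, stringsAsFactors = FALSE, row.names = NULL)
}

#' mRMR greedy gene ranking
#'
#' Greedy minimum-redundancy maximum-relevance forward selection: the first
#' gene maximizes the mutual information with the mutation label; each next
#' gene maximizes relevance minus the mean mutual information with already
#' selected genes. Deterministic; ties are broken by gene id.
#'
#' @param expr_discrete discretized expression matrix (samples x genes),
#'   e.g. from [ternary_discretize()].
#' @param label binary mutation-status vector.
#' @param k how many genes to rank.
#' @return ordered character vector of gene ids (length `k`).
#' @export
mrmr_rank <- function(expr_discrete, label, k) {
  genes <- colnames(expr_discrete)
  if (k > length(genes)) stop("k must be <= number of genes")
  if (k == 0) return(character(0))
  if (length(unique(label)) < 2) stop("label must contain both classes")
  rel <- vapply(genes, function(g)
    mutual_information(expr_discrete[, g], label), numeric(1))
  selected <- character(0)
  remaining <- genes
  red_sum <- stats::setNames(numeric(length(genes)), genes)
  for (step in seq_len(k)) {
    score <- if (step == 1) rel[remaining]
             else rel[remaining] - red_sum[remaining] / length(selected)
    best <- remaining[order(-score, remaining)][1]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining) > 0 && step < k)
      red_sum[remaining] <- red_sum[remaining] + vapply(
        remaining, function(g)
          mutual_information(expr_discrete[, g], expr_discrete[, best]),
        numeric(1))
  }
  selected
}

#' Module sizing by leave-one-out cross-validation
#'
#' For each candidate module size s, classifies the mutation label by a
#' linear support vector classifier on the top-s genes under leave-one-out
#' cross-validation; the error is the misclassification fraction. The module
#' size is the smallest s attaining the minimal error.
#'
#' @param expr expression matrix (samples x genes) with columns already in
#'   mRMR order.
#' @param label binary mutation-status vector (both classes >= 2 samples).
#' @param max_size largest module size tried.
#' @param cost SVC box constraint (default 1).
#' @return list with `error_curve` (length `max_size`) and `module_size`.
#' @export
loocv_size <- function(expr, label, max_size, cost = 1) {
  tab <- table(label)
  if (length(tab) < 2 || any(tab < 2))
    stop("each class needs >= 2 samples for LOOCV")
  max_size <- min(max_size, ncol(expr))
  n <- nrow(expr)
  curve <- vapply(seq_len(max_size), function(s) {
    xs <- expr[, seq_len(s), drop = FALSE]
    wrong <- vapply(seq_len(n), function(i) {
      if (length(unique(label[-i])) < 2) return(NA)
      fit <- linear_svc(xs[-i, , drop = FALSE], label[-i], cost = cost)
      predict(fit, xs[i, , drop = FALSE]) != label[i]
    }, logical(1))
    mean(wrong, na.rm = TRUE)
  }, numeric(1))
  list(error_curve = curve,
       module_size = which(curve <= min(curve) + 1e-12)[1])
}

#' Mutation-associated differential-expression modules (eQTL procedure)
#'
#' For each selected mutation of one cancer: restrict to the differentially
#' expressed candidate genes, rank them by the Kruskal-Wallis p-value of
#' their paired expression differences against the mutation status, ternary
#' discretize each gene, re-rank by mRMR, and size the module by LOOCV.
#' Mutations with fewer than `min_mutated` mutated (or unmutated) tumors
#' are skipped with a warning, as are mutations with no candidate gene.
#'
#' @param tumor,normal paired expression matrices, rows = pair ids.
#' @param mutations tumor 0/1 mutation matrix, rows = pair ids.
#' @param selected_mutations mutation ids to process.
#' @param min_mutated minimum samples per status class (default 3).
#' @param max_rank candidate genes carried into mRMR (default 30).
#' @param max_size largest module size tried in LOOCV (default 15).
#' @param noninformative_error LOOCV error at or above which the module is
#'   flagged non-informative (default 0.4).
#' @param loocv_features whether the LOOCV classifier sees the
#'   ternary-discretized features (default, matching the workflow order in
#'   which discretization precedes the module search) or the continuous
#'   expression differences.
#' @return named list of `eqtl_module` objects: `mutation_id`,
#'   `mrmr_order`, `loocv_error_curve`, `module_size`, `module_gene_ids`,
#'   `informative`.
#' @export
find_modules <- function(tumor, normal, mutations, selected_mutations,
                         min_mutated = 3, max_rank = 30, max_size = 15,
                         noninformative_error = 0.4,
                         loocv_features = c("discretized", "continuous")) {
  loocv_features <- match.arg(loocv_features)
  deg <- deg_candidates(tumor, normal)
  cand <- deg$gene_id[deg$retained]
  deltas <- expression_delta(tumor, normal)
  out <- list()
  for (m in selected_mutations) {
    status <- mutations[rownames(deltas), m]
    tab <- table(status)
    if (length(tab) < 2 || any(tab < min_mutated)) {
      warning("mutation ", m, " has < ", min_mutated,
              " samples in a status class; skipped")
      next
    }
    if (length(cand) == 0) next
    p <- kw_columns(deltas[, cand, drop = FALSE], status)
    ranked <- cand[order(p, cand)][seq_len(min(max_rank, length(cand)))]
    disc <- apply(deltas[, ranked, drop = FALSE], 2, ternary_discretize)
    ord <- mrmr_rank(disc, status, k = length(ranked))
    feats <- if (loocv_features == "discretized") disc[, ord, drop = FALSE]
             else deltas[, ord, drop = FALSE]
    sizing <- loocv_size(feats, status, max_size = max_size)
    out[[m]] <- structure(list(
      mutation_id = m, mrmr_order = ord,
      loocv_error_curve = sizing$error_curve,
      module_size = sizing$module_size,
      module_gene_ids = ord[seq_len(sizing$module_size)],
      informative = min(sizing$error_curve) < noninformative_error),
      class = "eqtl_module")
  }
  out
}
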