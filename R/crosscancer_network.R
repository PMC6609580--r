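#' Partition pairs by aging acceleration
#'
#' A pair is aging-accelerated iff its acceleration (tumor score minus
#' paired normal score) is strictly greater than 0.
#'
#' @param scores an `aging_scores` object with a `pairs` table, or a data
#'   frame with `pair_id` and `acceleration`.
#' @return list with `accelerated` and `non_accelerated` pair-id vectors.
#' @export
split_by_acceleration <- function(scores) {
  pairs <- if (inherits(scores, "aging_scores")) scores$pairs else scores
  if (is.null(pairs) || is.null(pairs$acceleration))
    stop("acceleration must be defined for each pair")
  list(accelerated = pairs$pair_id[pairs$acceleration > 0],
       non_accelerated = pairs$pair_id[pairs$acceleration <= 0])
}

#' Aging-acceleration similarity between two cancers
#'
#' For every cross-cancer gene pair (g1 in module 1, g2 in module 2) two
#' Kolmogorov-Smirnov statistics are computed: between g1's values over the
#' accelerated samples of cancer 1 and g2's values over the accelerated
#' samples of cancer 2, and analogously over the non-accelerated samples.
#' The similarity is the accumulated absolute difference
#' `sum |KS_acc - KS_non|` over all N1 x N2 pairs, divided by
#' `ln(N1) + ln(N2)`.
#'
#' @param expr_1,expr_2 expression matrices over the module genes of each
#'   cancer (rows = samples, named by pair id).
#' @param split_1,split_2 partitions from [split_by_acceleration()].
#' @return object of class `similarity_score`: `N1`, `N2`, `ks_acc_sum`,
#'   `ks_non_sum`, `sum_abs_diff`, `similarity`.
#' @export
cancer_pair_similarity <- function(expr_1, expr_2, split_1, split_2) {
  if (ncol(expr_1) == 0 || ncol(expr_2) == 0)
    stop("both modules must be nonempty")
  for (side in c("accelerated", "non_accelerated")) {
    n1 <- sum(rownames(expr_1) %in% split_1[[side]])
    n2 <- sum(rownames(expr_2) %in% split_2[[side]])
    if (n1 < 2 || n2 < 2)
      stop("split side '", side, "' has < 2 samples in ",
           if (n1 < 2) "cancer 1" else "cancer 2")
  }
  n1g <- ncol(expr_1); n2g <- ncol(expr_2)
  denom <- log(n1g) + log(n2g)
  if (denom == 0)
    stop("degenerate denominator: ln(N1) + ln(N2) = 0 for single-gene modules")
  acc1 <- expr_1[rownames(expr_1) %in% split_1$accelerated, , drop = FALSE]
  non1 <- expr_1[rownames(expr_1) %in% split_1$non_accelerated, , drop = FALSE]
  acc2 <- expr_2[rownames(expr_2) %in% split_2$accelerated, , drop = FALSE]
  non2 <- expr_2[rownames(expr_2) %in% split_2$non_accelerated, , drop = FALSE]
  ka <- matrix(0, n1g, n2g); kn <- matrix(0, n1g, n2g)
  for (g1 in seq_len(n1g)) for (g2 in seq_len(n2g)) {
    ka[g1, g2] <- ks_statistic(acc1[, g1], acc2[, g2])
    kn[g1, g2] <- ks_statistic(non1[, g1], non2[, g2])
  }
  # sums over sorted values are invariant to argument order, keeping the
  # similarity exactly symmetric under swapping the two cancers
  structure(list(N1 = n1g, N2 = n2g,
                 ks_acc_sum = sum(sort(ka)), ks_non_sum = sum(sort(kn)),
                 sum_abs_diff = sum(sort(abs(ka - kn))),
                 similarity = sum(sort(abs(ka - kn))) / denom),
            class = "similarity_score")
}

#' All pairwise cancer similarities
#'
#' @param module_exprs named list (one per cancer) of expression matrices
#'   over that cancer's module genes, rows named by pair id.
#' @param splits named list of partitions from [split_by_acceleration()].
#' @return list with `matrix` (symmetric cancer x cancer) and `edges`
#'   (long-format data frame `cancer_a`, `cancer_b`, `similarity`).
#' @export
similarity_matrix <- function(module_exprs, splits) {
  cancers <- names(module_exprs)
  m <- matrix(NA_real_, length(cancers), length(cancers),
              dimnames = list(cancers, cancers))
  diag(m) <- 0
  rows <- list()
  if (length(cancers) >= 2) {
    for (i in seq_len(length(cancers) - 1)) for (j in (i + 1):length(cancers)) {
      a <- cancers[i]; b <- cancers[j]
      s <- cancer_pair_similarity(module_exprs[[a]], module_exprs[[b]],
                                  splits[[a]], splits[[b]])
      m[a, b] <- m[b, a] <- s$similarity
      rows[[paste(a, b)]] <- data.frame(cancer_a = a, cancer_b = b,
                                        similarity = s$similarity,
                                        stringsAsFactors = FALSE)
    }
  }
  list(matrix = m,
       edges = if (length(rows)) do.call(rbind, rows) else
         data.frame(cancer_a = character(0), cancer_b = character(0),
                    similarity = numeric(0)))
}

#' Select network edges
#'
#' `top_k` mode keeps the k largest-similarity cancer pairs (ties at the
#' boundary broken by lexicographic pair name); `threshold` mode keeps all
#' pairs with similarity strictly greater than the cutoff.
#'
#' @param similarities data frame `cancer_a`, `cancer_b`, `similarity`
#'   (e.g. `similarity_matrix()$edges`).
#' @param mode `"top_k"` or `"threshold"`.
#' @param parameter k (default 10) or the cutoff (default 100).
#' @return object of class `network_edge_set`: `mode`, `parameter`,
#'   `edges`, `degrees` (named node degrees).
#' @export
build_network <- function(similarities,
                          mode = c("top_k", "threshold"),
                          parameter = NULL) {
  mode <- match.arg(mode)
  if (nrow(similarities) < 1) stop("need >= 1 cancer pair")
  if (is.null(parameter)) parameter <- if (mode == "top_k") 10 else 100
  pair_name <- paste(pmin(similarities$cancer_a, similarities$cancer_b),
                     pmax(similarities$cancer_a, similarities$cancer_b))
  ord <- order(-similarities$similarity, pair_name)
  edges <- if (mode == "top_k") {
    similarities[ord[seq_len(min(parameter, nrow(similarities)))], ]
  } else {
    similarities[ord, ][similarities$similarity[ord] > parameter, ]
  }
  rownames(edges) <- NULL
  nodes <- c(edges$cancer_a, edges$cancer_b)
  degrees <- if (length(nodes)) sort(table(nodes), decreasing = TRUE)
             else table(character(0))
  structure(list(mode = mode, parameter = parameter, edges = edges,
                 degrees = degrees),
            class = "network_edge_set")
}
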