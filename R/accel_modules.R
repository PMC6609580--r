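#' Paired expression difference matrix
#'
#' One row per pair: tumor expression minus normal expression, genewise.
#' Rows of the two inputs are matched by pair id (rownames).
#'
#' @param tumor,normal matrices with pair ids as rownames.
#' @return matrix of differences, rows = pair ids.
#' @export
expression_delta <- function(tumor, normal) {
  if (is.null(rownames(tumor)) || is.null(rownames(normal)))
    stop("tumor and normal must carry pair ids as rownames")
  unpaired <- c(setdiff(rownames(tumor), rownames(normal)),
                setdiff(rownames(normal), rownames(tumor)))
  if (length(unpaired) > 0)
    stop("unpaired sample for pair id: ", unpaired[1])
  tumor - normal[rownames(tumor), , drop = FALSE]
}

#' LASSO selection of acceleration-associated features
#'
#' L1-penalized regression of the aging-acceleration vector on a feature
#' matrix over a descending lambda path with 5-fold cross-validated MSE
#' (glmnet, alpha = 1). The chosen lambda attains the minimal CV MSE; among
#' (numerically tied) minimizers the sparsest model, i.e. the largest lambda,
#' is taken. Fold assignment is deterministic given `seed`.
#'
#' @param x predictor matrix (samples x features).
#' @param y aging-acceleration vector aligned with rows of `x`.
#' @param folds CV folds (default 5).
#' @param seed seed controlling fold assignment.
#' @param lambda optional user-supplied descending lambda sequence
#'   (defaults to the glmnet-derived path).
#' @return object of class `lasso_fit`: `B` (coefficients, feature x
#'   lambda), `lambda`, `mse_per_lambda`, `chosen_lambda`, `selected_ids`,
#'   `coefficients` (named nonzero coefficients at the chosen lambda).
#' @export
lasso_select <- function(x, y, folds = 5, seed = 1L, lambda = NULL) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("rows of x must align with y")
  if (nrow(x) < folds) stop("need at least `folds` rows")
  if (stats::sd(y) == 0) {
    warning("zero-variance response; returning empty selection")
    return(structure(list(B = NULL, lambda = numeric(0),
                          mse_per_lambda = numeric(0),
                          chosen_lambda = NA_real_,
                          selected_ids = character(0),
                          coefficients = numeric(0)),
                     class = "lasso_fit"))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), nrow(x)))
  cv <- glmnet::cv.glmnet(x, y, alpha = 1, foldid = foldid,
                          type.measure = "mse", lambda = lambda)
  b <- as.matrix(cv$glmnet.fit$beta)
  minim <- which(cv$cvm <= min(cv$cvm) + 1e-10)
  chosen <- minim[1]  # lambdas descend, so the first tie is the sparsest
  coefs <- b[, chosen]
  sel <- names(coefs)[coefs != 0]
  structure(list(B = b, lambda = cv$lambda, mse_per_lambda = cv$cvm,
                 chosen_lambda = cv$lambda[chosen],
                 selected_ids = sel, coefficients = coefs[coefs != 0],
                 foldid = foldid),
            class = "lasso_fit")
}

#' Mutation-expression bipartite network
#'
#' For every (mutation, gene) pair, a two-group Kruskal-Wallis test of the
#' gene's paired expression differences split by the mutation's 0/1 status;
#' Benjamini-Hochberg adjustment over all pairs within the cancer; retention
#' at p < 0.05 and FDR < 0.2, sorted by p. Mutations that are constant
#' (all 0 or all 1) are skipped with a warning.
#'
#' @param mutations 0/1 matrix restricted to the selected mutation set,
#'   rows = pairs.
#' @param deltas expression-difference matrix restricted to the selected
#'   expression set, rows aligned with `mutations`.
#' @param p_cut,fdr_cut retention thresholds.
#' @return data frame of edges: `mutation_id`, `expression_id`, `p_value`,
#'   `fdr`.
#' @export
bipartite_network <- function(mutations, deltas, p_cut = 0.05, fdr_cut = 0.2) {
  if (ncol(mutations) == 0 || ncol(deltas) == 0)
    stop("both feature sets must be nonempty")
  if (nrow(mutations) != nrow(deltas)) stop("row mismatch")
  rows <- list()
  for (m in colnames(mutations)) {
    status <- mutations[, m]
    if (length(unique(status)) < 2) {
      warning("mutation ", m, " is constant; its pairs skipped")
      next
    }
    p <- kw_columns(deltas, status)
    rows[[m]] <- data.frame(mutation_id = m,
                            expression_id = colnames(deltas),
                            p_value = p, stringsAsFactors = FALSE,
                            row.names = NULL)
  }
  if (length(rows) == 0)
    return(data.frame(mutation_id = character(0),
                      expression_id = character(0),
                      p_value = numeric(0), fdr = numeric(0)))
  all_edges <- do.call(rbind, rows)
  all_edges$fdr <- bh_fdr(all_edges$p_value)
  keep <- all_edges[all_edges$p_value < p_cut & all_edges$fdr < fdr_cut, ]
  keep <- keep[order(keep$p_value, keep$mutation_id, keep$expression_id), ]
  rownames(keep) <- NULL
  keep
}

#' Per-cancer acceleration-associated module selection
#'
#' Runs [lasso_select()] separately on the binary mutation matrix and on the
#' paired expression-difference matrix of one cancer against its aging
#' acceleration, then links the two selected sets with
#' [bipartite_network()]. Mutations observed in fewer than `min_mutated`
#' tumors are excluded from the LASSO input.
#'
#' @param mutations tumor 0/1 mutation matrix, rows = pairs.
#' @param deltas expression-difference matrix, rows = pairs.
#' @param acceleration acceleration vector named by pair id.
#' @param min_mutated minimum mutated samples for a mutation predictor.
#' @param seed fold-assignment seed.
#' @return list with `mutation_fit`, `expression_fit` (both `lasso_fit`) and
#'   `edges` (bipartite data frame; empty when either set is empty).
#' @export
accel_modules <- function(mutations, deltas, acceleration,
                          min_mutated = 3, seed = 1L) {
  pid <- rownames(mutations)
  stopifnot(identical(pid, rownames(deltas)))
  acc <- acceleration[pid]
  keep <- colSums(mutations) >= min_mutated
  if (any(!keep))
    message(sum(!keep), " mutation(s) with < ", min_mutated,
            " mutated samples excluded from LASSO")
  mut_fit <- lasso_select(mutations[, keep, drop = FALSE], acc, seed = seed)
  expr_fit <- lasso_select(deltas, acc, seed = seed + 1L)
  edges <- if (length(mut_fit$selected_ids) > 0 &&
               length(expr_fit$selected_ids) > 0) {
    bipartite_network(
      mutations[, mut_fit$selected_ids, drop = FALSE],
      deltas[, expr_fit$selected_ids, drop = FALSE])
  } else {
    data.frame(mutation_id = character(0), expression_id = character(0),
               p_value = numeric(0), fdr = numeric(0))
  }
  list(mutation_fit = mut_fit, expression_fit = expr_fit, edges = edges)
}
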