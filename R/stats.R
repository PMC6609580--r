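#' Kruskal-Wallis rank test
#'
#' H statistic on midranks with the standard tie correction; p-value from the
#' upper chi-square tail with `length(groups) - 1` degrees of freedom. If all
#' values are identical across groups the test is degenerate and `p = 1` is
#' returned.
#'
#' @param groups list of two or more nonempty numeric vectors.
#' @return list with elements `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("groups must be a list of >= 2 numeric vectors")
  n_g <- lengths(groups)
  if (any(n_g == 0)) stop("all groups must be nonempty")
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  if (n < 3) stop("total sample size must be >= 3")
  r <- rank(x)
  g <- rep.int(seq_along(groups), n_g)
  rsum <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / n_g) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr <= 0) return(list(H = 0, p = 1))  # all values identical
  h <- h / corr
  list(H = h, p = stats::pchisq(h, df = length(groups) - 1, lower.tail = FALSE))
}

# Vectorized two-group Kruskal-Wallis p-values over the columns of a matrix.
# Used by the marker screen and the bipartite network; equivalent to calling
# kruskal_wallis(split(x[, j], label)) per column.
kw_columns <- function(x, label) {
  lab <- as.integer(factor(label))
  if (length(unique(lab)) < 2) stop("label must contain two groups")
  apply(x, 2, function(v) kruskal_wallis(split(v, lab))$p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; the input order is preserved in the output.
#'
#' @param p_values numeric vector with all values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p_values[o] * m / (m:1)))[ro]
}

#' Exact two-sided sign test
#'
#' Binomial(n, 1/2) tail doubling on the count of positive differences among
#' the nonzero paired differences. All-zero differences give `p = 1`.
#'
#' @param paired_diffs numeric vector of paired differences.
#' @return two-sided p-value.
#' @export
sign_test <- function(paired_diffs) {
  if (length(paired_diffs) == 0) stop("paired_diffs must be nonempty")
  d <- paired_diffs[paired_diffs != 0]
  n <- length(d)
  if (n == 0) return(1)
  s <- sum(d > 0)
  min(1, 2 * stats::pbinom(min(s, n - s), n, 0.5))
}

#' Plug-in mutual information of two discrete vectors
#'
#' Empirical mutual information in bits (base-2 logarithm); `0 * log 0` terms
#' contribute zero.
#'
#' @param x,y equal-length discrete vectors.
#' @return nonnegative mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) == 0) stop("inputs must be nonempty")
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  terms <- joint * log2(joint / outer(px, py))
  mi <- sum(terms[joint > 0])
  max(mi, 0)
}

#' Ternary discretization by mean +/- sd/2
#'
#' Maps values to 1 above `mean + sd/2`, -1 below `mean - sd/2`, and 0 in
#' between (boundaries fall in the middle bin; strict inequalities). Constant
#' vectors map to all zeros.
#'
#' @param values numeric vector of length >= 2.
#' @return integer vector in \{-1, 0, 1\}.
#' @export
ternary_discretize <- function(values) {
  if (length(values) < 2) stop("need >= 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(rep(0L, length(values)))
  out <- integer(length(values))
  out[values > m + s / 2] <- 1L
  out[values < m - s / 2] <- -1L
  out
}

#' Exact hypergeometric upper-tail probability
#'
#' P(X >= k) for the number of successes when drawing `n` items without
#' replacement from a universe of `N` items of which `M` are marked. Computed
#' by log-space summation of exact terms for numerical robustness.
#'
#' @param N universe size.
#' @param M marked (gene-set) size.
#' @param n draw (query) size.
#' @param k observed overlap.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeom_upper <- function(N, M, n, k) {
  if (any(c(N, M, n, k) < 0) || M > N || n > N || k > min(M, n))
    stop("inconsistent hypergeometric counts")
  if (k == 0) return(1)
  j <- k:min(M, n)
  lg <- lchoose(M, j) + lchoose(N - M, n - j) - lchoose(N, n)
  min(1, sum(exp(lg)))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum absolute difference of the two empirical CDFs, evaluated over the
#' pooled support.
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @return statistic in \[0, 1\].
#' @export
ks_statistic <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("both samples must be nonempty")
  sup <- sort(unique(c(sample_a, sample_b)))
  fa <- findInterval(sup, sort(sample_a)) / length(sample_a)
  fb <- findInterval(sup, sort(sample_b)) / length(sample_b)
  max(abs(fa - fb))
}

#' Balanced error rate
#'
#' Mean of the false-negative and false-positive rates of a binary prediction.
#'
#' @param predicted,truth binary (0/1) vectors of equal length; `truth` must
#'   contain both classes.
#' @return balanced error in \[0, 1\].
#' @export
balanced_error <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (length(unique(truth)) < 2)
    stop("truth must contain both classes")
  fnr <- mean(predicted[truth == 1] != 1)
  fpr <- mean(predicted[truth == 0] != 0)
  (fnr + fpr) / 2
}
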