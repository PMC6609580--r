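#' Linear epsilon-insensitive support vector regression
#'
#' Fits `min 0.5||w||^2 + C sum max(0, |w'x + b - y| - eps)` by exact dual
#' coordinate descent. Features are standardized internally (training mean and
#' standard deviation); the bias is carried as an augmented constant column, so
#' it is mildly regularized, as in LIBLINEAR with `-B 1`.
#'
#' @param x numeric matrix, samples in rows.
#' @param y numeric response vector.
#' @param cost box constraint C (default 1, the `fitrsvm` default scale).
#' @param epsilon half-width of the insensitive tube (default 0.1).
#' @param max_iter,tol coordinate-descent stopping controls.
#' @return an object of class `linear_svr` with elements `weights`, `offset`,
#'   `center`, `scale`.
#' @export
linear_svr <- function(x, y, cost = 1, epsilon = 0.1,
                       max_iter = 1000L, tol = 1e-6) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  xa <- cbind(xs, `(bias)` = 1)
  w <- svr_dcd(xa, as.numeric(y), cost, epsilon, as.integer(max_iter), tol)
  structure(list(weights = w[-length(w)], offset = w[length(w)],
                 center = ctr, scale = scl,
                 cost = cost, epsilon = epsilon,
                 feature_ids = colnames(x)),
            class = "linear_svr")
}

#' @rdname linear_svr
#' @param object a fitted `linear_svr`.
#' @param newdata matrix with the training features (by name when named).
#' @param ... unused.
#' @export
predict.linear_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_ids)) {
    missing <- setdiff(object$feature_ids, colnames(newdata))
    if (length(missing) > 0)
      stop("missing feature column(s): ", paste(missing, collapse = ", "))
    newdata <- newdata[, object$feature_ids, drop = FALSE]
  }
  xs <- sweep(sweep(newdata, 2, object$center, "-"), 2, object$scale, "/")
  drop(xs %*% object$weights + object$offset)
}

#' Linear hinge-loss support vector classifier
#'
#' Binary classifier `min 0.5||w||^2 + C sum max(0, 1 - y w'x)` with labels
#' coded internally as -1/+1, fitted by exact dual coordinate descent.
#' Standardization and bias handling as in [linear_svr()].
#'
#' @param x numeric matrix, samples in rows.
#' @param y binary label vector (two distinct values; 0/1 accepted).
#' @inheritParams linear_svr
#' @return object of class `linear_svc`; `predict()` returns labels on the
#'   original coding.
#' @export
linear_svc <- function(x, y, cost = 1, max_iter = 1000L, tol = 1e-6) {
  x <- as.matrix(x)
  lev <- sort(unique(y))
  if (length(lev) != 2) stop("y must contain exactly two classes")
  ypm <- ifelse(y == lev[2], 1, -1)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  xa <- cbind(xs, `(bias)` = 1)
  w <- svc_dcd(xa, ypm, cost, as.integer(max_iter), tol)
  structure(list(weights = w[-length(w)], offset = w[length(w)],
                 center = ctr, scale = scl, levels = lev, cost = cost,
                 feature_ids = colnames(x)),
            class = "linear_svc")
}

#' @rdname linear_svc
#' @param object a fitted `linear_svc`.
#' @param newdata matrix of features.
#' @param ... unused.
#' @export
predict.linear_svc <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_ids)) {
    newdata <- newdata[, object$feature_ids, drop = FALSE]
  }
  xs <- sweep(sweep(newdata, 2, object$center, "-"), 2, object$scale, "/")
  f <- drop(xs %*% object$weights + object$offset)
  ifelse(f > 0, object$levels[2], object$levels[1])
}
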