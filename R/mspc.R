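#' Fit a multivariate statistical process control (MSPC) anomaly model
#'
#' Models the correlation structure of feature vectors collected under
#' normal operation with principal component analysis, and monitors new
#' samples with Hotelling's T-squared statistic on the retained components.
#' Training proceeds by standardising each feature to its training mean and
#' standard deviation, taking the singular value decomposition
#' \eqn{Z = U S V^\top} of the standardised matrix, and retaining the first
#' \code{ncomp} right singular vectors. A new standardised sample \eqn{z}
#' scores
#' \deqn{T^2 = z V_R S_R^{-2} V_R^\top z^\top,}
#' and is declared anomalous when \eqn{T^2} strictly exceeds the control
#' limit. The control limit is the empirical nearest-rank
#' \code{percentile}-quantile of the training T-squared values, so that (for
#' the default 90) 90\% of the training samples fall at or below the limit
#' and 10\% above.
#'
#' The training T-squared values satisfy the algebraic identity
#' \eqn{\sum_i T^2_i = R}: columns of \eqn{U} are orthonormal, so the sum of
#' squared normalised scores per component is 1.
#'
#' @param x Numeric matrix or data frame of training feature vectors, one row
#'   per window, one column per feature. A column named \code{t_end} is
#'   ignored. Rows containing \code{NA} are rejected with an error naming the
#'   first offending row and feature.
#' @param ncomp Number of principal components retained (default 1).
#' @param percentile Calibration percentile of the control limit, in
#'   (0, 100); default 90.
#' @param scale Standardise each feature to unit training variance (default
#'   \code{TRUE}). Set \code{FALSE} to centre only, e.g. when all features
#'   share a unit and their relative magnitudes are meaningful.
#' @return An object of class \code{mspc}: list with \code{feature_names},
#'   \code{center}, \code{scale}, \code{loadings} (P x R), \code{singular_values},
#'   \code{ncomp}, \code{percentile}, \code{control_limit}, \code{t2_train},
#'   \code{n_train}, \code{dropped} (zero-variance features removed with a
#'   warning).
#' @seealso \code{\link{predict.mspc}}, \code{\link{detect}},
#'   \code{\link{save_mspc}}
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200 * 4), 200, 4)
#' m <- mspc(X, ncomp = 1, percentile = 90)
#' m
#' mean(m$t2_train > m$control_limit)  # 0.10 by construction
#' @export
mspc <- function(x, ncomp = 1, percentile = 90, scale = TRUE) {
  X <- as_feature_matrix(x)
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 100)
    stop("'percentile' must lie strictly between 0 and 100")
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop(sprintf("NA feature value in training data: row %d, feature '%s'",
                 idx[1], colnames(X)[idx[2]]))
  }
  N <- nrow(X)
  if (N < 2) stop("need at least 2 training samples")
  ctr <- colMeans(X)
  sds <- apply(X, 2, sd)
  scl <- if (scale) sds else rep(1, ncol(X))
  names(scl) <- colnames(X)
  drop_idx <- which(sds == 0)
  dropped <- colnames(X)[drop_idx]
  if (length(drop_idx)) {
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, -drop_idx, drop = FALSE]
    ctr <- ctr[-drop_idx]; scl <- scl[-drop_idx]
  }
  P <- ncol(X)
  if (P < 1) stop("no non-degenerate features left")
  if (N <= P)
    warning(sprintf("fewer training samples (%d) than features (%d): model may be unstable", N, P))
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  sv <- svd(Z)
  rank_tol <- max(dim(Z)) * .Machine$double.eps * sv$d[1]
  rnk <- sum(sv$d > rank_tol)
  if (ncomp < 1 || ncomp > min(N, P) || ncomp > rnk)
    stop(sprintf("ncomp = %d exceeds the rank (%d) of the training data", ncomp, rnk))
  V <- sv$v[, seq_len(ncomp), drop = FALSE]
  U <- sv$u[, seq_len(ncomp), drop = FALSE]
  s <- sv$d[seq_len(ncomp)]
  ## fix singular-vector signs (largest-magnitude loading positive) so
  ## serialized models are bit-reproducible; T2 is sign-invariant
  for (r in seq_len(ncomp)) {
    i <- which.max(abs(V[, r]))
    if (V[i, r] < 0) { V[, r] <- -V[, r]; U[, r] <- -U[, r] }
  }
  t2_train <- rowSums(U^2)
  limit <- sort(t2_train)[ceiling(percentile / 100 * N)]
  spe_train <- rowSums((Z - (Z %*% V) %*% t(V))^2)
  structure(
    list(feature_names = colnames(X), center = ctr, scale = scl,
         loadings = V, singular_values = s, ncomp = ncomp,
         percentile = percentile, control_limit = limit,
         t2_train = t2_train, spe_train = spe_train, n_train = N,
         dropped = dropped, all_singular_values = sv$d),
    class = "mspc")
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[, setdiff(names(x), "t_end"), drop = FALSE]
    x <- as.matrix(x)
  }
  if (is.matrix(x) && is.logical(x)) storage.mode(x) <- "double"  # all-NA
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix or data frame")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

#' Standardise feature vectors with a model's training statistics
#'
#' @param model A fitted \code{\link{mspc}} model.
#' @param x Matrix/data frame of feature vectors; must contain the model's
#'   features by name (order is enforced via name lookup).
#' @return Standardised matrix in the model's feature order.
#' @export
standardize <- function(model, x) {
  stopifnot(inherits(model, "mspc"))
  X <- as_feature_matrix(x)
  miss <- setdiff(model$feature_names, colnames(X))
  if (length(miss))
    stop("features missing from input: ", paste(miss, collapse = ", "))
  X <- X[, model$feature_names, drop = FALSE]
  sweep(sweep(X, 2, model$center), 2, model$scale, "/")
}

#' Score new samples with a fitted MSPC model
#'
#' Computes Hotelling's T-squared for each row of \code{newdata} and flags
#' anomalies by strict comparison with the model's control limit. Rows with
#' any missing feature score \code{NA} (missing), never 0.
#'
#' @param object A fitted \code{\link{mspc}} model.
#' @param newdata Matrix or data frame containing the model's features
#'   (a \code{t_end} column, if present, is carried through).
#' @param type \code{"response"} (default): data frame with \code{t2} and
#'   \code{anomaly}; \code{"t2"}: numeric vector; \code{"scores"}: matrix of
#'   PCA scores; \code{"spe"}: squared prediction error (Q statistic) in the
#'   residual subspace.
#' @param ... Unused.
#' @return See \code{type}.
#' @export
predict.mspc <- function(object, newdata, type = c("response", "t2", "scores", "spe"),
                         ...) {
  type <- match.arg(type)
  t_end <- if (is.data.frame(newdata) && "t_end" %in% names(newdata))
    newdata$t_end else NULL
  Xn <- as_feature_matrix(newdata)
  miss <- setdiff(object$feature_names, colnames(Xn))
  if (length(miss))
    stop("features missing from input: ", paste(miss, collapse = ", "))
  Xn <- Xn[, object$feature_names, drop = FALSE]
  ok <- !apply(Xn, 1, anyNA)
  Z <- matrix(NA_real_, nrow(Xn), ncol(Xn))
  if (any(ok))
    Z[ok, ] <- standardize(object, Xn[ok, , drop = FALSE])
  scores <- Z %*% object$loadings
  if (type == "scores") return(scores)
  if (type == "spe") {
    resid <- Z - scores %*% t(object$loadings)
    return(rowSums(resid^2))
  }
  t2 <- rowSums(sweep(scores, 2, object$singular_values, "/")^2)
  if (type == "t2") return(t2)
  out <- data.frame(t2 = t2, anomaly = t2 > object$control_limit)
  if (!is.null(t_end)) out <- cbind(data.frame(t_end = t_end), out)
  out
}

#' Hotelling's T-squared of a single feature vector
#'
#' Convenience wrapper around \code{\link{predict.mspc}} for one sample.
#'
#' @param model A fitted \code{\link{mspc}} model.
#' @param x Named numeric vector (or 1-row matrix/data frame) of features.
#' @return A single nonnegative T-squared value (\code{NA} if any feature is
#'   missing).
#' @export
t2_statistic <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  predict(model, x, type = "t2")[1]
}

#' Score a feature stream into a T-squared series
#'
#' Applies a fitted MSPC model to a time-indexed feature stream and returns
#' the T-squared control chart: end time, statistic, and anomaly flag
#' (strictly above the control limit).
#'
#' @param model A fitted \code{\link{mspc}} model.
#' @param features Data frame with a \code{t_end} column plus the model's
#'   features, e.g. from \code{\link{extract_hrv_features}}.
#' @return Data frame of class \code{t2_series} with columns
#'   \code{t_end}, \code{t2}, \code{anomaly} (logical; \code{NA} where input
#'   features are missing).
#' @export
detect <- function(model, features) {
  stopifnot(inherits(model, "mspc"), "t_end" %in% names(features))
  out <- predict(model, features)
  attr(out, "control_limit") <- model$control_limit
  class(out) <- c("t2_series", "data.frame")
  out
}

#' @export
print.mspc <- function(x, ...) {
  cat(sprintf("MSPC anomaly model: %d feature(s), %d component(s), fitted on %d windows\n",
              length(x$feature_names), x$ncomp, x$n_train))
  cat(sprintf("control limit: T2 > %.4g (empirical %g%% of training)\n",
              x$control_limit, x$percentile))
  if (length(x$dropped))
    cat("dropped zero-variance features:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mspc <- function(object, ...) {
  d2 <- object$all_singular_values^2
  expl <- d2 / sum(d2)
  out <- list(model = object,
              variance_explained = expl[seq_len(object$ncomp)],
              total_retained = sum(expl[seq_len(object$ncomp)]),
              t2_train_quantiles = quantile(object$t2_train,
                                            c(0.5, 0.9, 0.95, 0.99)))
  class(out) <- "summary.mspc"
  out
}

#' @export
print.summary.mspc <- function(x, ...) {
  print(x$model)
  cat(sprintf("variance explained by retained component(s): %s (total %.1f%%)\n",
              paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
              100 * x$total_retained))
  cat("training T2 quantiles:\n")
  print(round(x$t2_train_quantiles, 4))
  invisible(x)
}

#' @export
coef.mspc <- function(object, ...) object$loadings

#' Training residuals of an MSPC model
#'
#' Reconstruction residuals of the standardised training data in the
#' discarded (residual) subspace; their squared row sums are the Q
#' statistic (SPE). Provided for diagnostics; detection uses T-squared only.
#'
#' @param object A fitted \code{\link{mspc}} model.
#' @param ... Unused.
#' @return Numeric vector of training SPE values.
#' @export
residuals.mspc <- function(object, ...) object$spe_train

#' @export
plot.mspc <- function(x, ...) {
  plot(x$t2_train, type = "h", xlab = "training window",
       ylab = expression(T^2), main = "MSPC training control chart", ...)
  abline(h = x$control_limit, col = 2, lty = 2)
  invisible(x)
}

#' @export
plot.t2_series <- function(x, ...) {
  plot(x$t_end, x$t2, type = "l", xlab = "time [s]", ylab = expression(T^2),
       ...)
  lim <- attr(x, "control_limit")
  if (!is.null(lim)) abline(h = lim, col = 2, lty = 2)
  if (any(x$anomaly, na.rm = TRUE))
    points(x$t_end[which(x$anomaly)], x$t2[which(x$anomaly)], col = 2, pch = 20,
           cex = 0.5)
  invisible(x)
}

## ---- Model serialization -------------------------------------------------

MSPC_SCHEMA <- "mspc-1"

#' Save / load an MSPC model as JSON
#'
#' The file stores the schema version, feature names, training mean/scale,
#' loadings, singular values, percentile and control limit at full double
#' precision; a reloaded model reproduces T-squared scores to within 1e-12.
#' Loading refuses files with an unknown schema version or inconsistent
#' feature dimensions.
#'
#' @param model A fitted \code{\link{mspc}} model.
#' @param path Destination / source file path.
#' @return \code{save_mspc} returns \code{path} invisibly; \code{load_mspc}
#'   returns the restored \code{mspc} object.
#' @export
save_mspc <- function(model, path) {
  stopifnot(inherits(model, "mspc"))
  obj <- list(schema = MSPC_SCHEMA,
              feature_names = model$feature_names,
              center = unname(model$center), scale = unname(model$scale),
              loadings = model$loadings,  # column-major P x R
              singular_values = model$singular_values,
              ncomp = model$ncomp, percentile = model$percentile,
              control_limit = model$control_limit,
              t2_train = model$t2_train, spe_train = model$spe_train,
              n_train = model$n_train,
              dropped = model$dropped,
              all_singular_values = model$all_singular_values)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_mspc
#' @export
load_mspc <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !identical(obj$schema, MSPC_SCHEMA))
    stop("unrecognised model schema: ",
         if (is.null(obj$schema)) "<none>" else obj$schema)
  P <- length(obj$feature_names)
  lvals <- unlist(obj$loadings)
  if (length(lvals) != P * obj$ncomp)
    stop("corrupt model file: loadings dimensions do not match feature names")
  L <- matrix(lvals, nrow = P)
  if (length(obj$center) != P || length(obj$scale) != P)
    stop("corrupt model file: center/scale length mismatch")
  structure(
    list(feature_names = obj$feature_names,
         center = stats::setNames(obj$center, obj$feature_names),
         scale = stats::setNames(obj$scale, obj$feature_names),
         loadings = L, singular_values = obj$singular_values,
         ncomp = obj$ncomp, percentile = obj$percentile,
         control_limit = obj$control_limit, t2_train = obj$t2_train,
         spe_train = obj$spe_train, n_train = obj$n_train,
         dropped = if (length(obj$dropped)) obj$dropped else character(0),
         all_singular_values = obj$all_singular_values),
    class = "mspc")
}
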