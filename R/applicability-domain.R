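#' Applicability-domain assessment
#'
#' Four complementary definitions of the region of descriptor space where
#' the model's predictions are trustworthy, each calibrated on the training
#' compounds and applied to query compounds: a PCA bounding box, a
#' percentile threshold on Euclidean distance to the training centroid, and
#' mean k-nearest-neighbour distance thresholds (k = 5 and k = 25 by
#' default), plus a leverage/standardized-residual diagnostic. All methods
#' assume train and query share one scaling; [run_ad_suite()] takes care of
#' that.
#'
#' @name applicability_domain
NULL

ad_result <- function(method, inside, score, threshold, details = NULL) {
  out <- list(method = method, inside = inside, score = score,
              threshold = threshold,
              n_inside = sum(inside), n_outside = sum(!inside),
              details = details)
  class(out) <- "ad_result"
  out
}

#' @export
print.ad_result <- function(x, ...) {
  cat(sprintf("%s: %d inside / %d outside\n",
              x$method, x$n_inside, x$n_outside))
  invisible(x)
}

#' PCA bounding-box applicability domain
#'
#' Principal components are fitted on the training rows (centered, not
#' re-scaled: the caller supplies a shared scaling). A query is inside the
#' domain iff each of its retained component scores lies within the
#' \[min, max\] range of the training scores on that component. The score
#' reported per query is the number of violated components.
#'
#' @param x_train,x_query matrices on a shared scaling, equal column sets.
#' @param n_components number of components to retain; `NULL` keeps the
#'   smallest number explaining at least 95% of training variance.
#' @return an `ad_result`; `details` holds the per-component box.
#' @export
pca_bounding_box <- function(x_train, x_query, n_components = NULL) {
  stopifnot(ncol(x_train) == ncol(x_query))
  pc <- stats::prcomp(x_train, center = TRUE, scale. = FALSE)
  rank_x <- sum(pc$sdev > 1e-10)
  if (is.null(n_components)) {
    cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    n_components <- which(cumvar >= 0.95)[1L]
  }
  if (n_components > rank_x)
    stop("n_components (", n_components, ") exceeds the training rank (",
         rank_x, ")", call. = FALSE)
  if (nrow(x_train) <= n_components)
    stop("need more training rows than components", call. = FALSE)
  idx <- seq_len(n_components)
  tr_scores <- pc$x[, idx, drop = FALSE]
  lo <- apply(tr_scores, 2L, min); hi <- apply(tr_scores, 2L, max)
  q_scores <- stats::predict(pc, x_query)[, idx, drop = FALSE]
  viol <- rowSums(sweep(q_scores, 2L, lo, `<`) | sweep(q_scores, 2L, hi, `>`))
  ad_result("pca_bounding_box", inside = viol == 0L, score = viol,
            threshold = 0,
            details = list(n_components = n_components, lower = lo, upper = hi))
}

#' Centroid-distance applicability domain
#'
#' The threshold is the given percentile of the training rows' Euclidean
#' distances to the training centroid; a query is inside iff its own
#' centroid distance does not exceed it.
#'
#' @inheritParams pca_bounding_box
#' @param percentile calibration percentile in (0, 100\].
#' @return an `ad_result` with per-query distances as scores.
#' @export
centroid_distance_ad <- function(x_train, x_query, percentile = 95) {
  stopifnot(nrow(x_train) >= 1L, ncol(x_train) == ncol(x_query),
            percentile > 0, percentile <= 100)
  centroid <- colMeans(x_train)
  d_train <- sqrt(rowSums(sweep(x_train, 2L, centroid, `-`)^2))
  thr <- stats::quantile(d_train, percentile / 100, type = 7, names = FALSE)
  d_query <- sqrt(rowSums(sweep(x_query, 2L, centroid, `-`)^2))
  ad_result("centroid_distance", inside = d_query <= thr, score = d_query,
            threshold = thr)
}

# Pairwise Euclidean distances between the rows of a and b (na x nb).
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' k-nearest-neighbour applicability domain
#'
#' A query's score is its mean Euclidean distance to its k nearest training
#' rows. The threshold is the given percentile of the training rows' own
#' leave-self-out mean kNN distances, so training compounds calibrate the
#' density the queries are judged against.
#'
#' @inheritParams centroid_distance_ad
#' @param k neighbour count, strictly less than the number of training rows.
#' @return an `ad_result` with mean kNN distances as scores.
#' @export
knn_ad <- function(x_train, x_query, k = 5L, percentile = 95) {
  n <- nrow(x_train)
  stopifnot(ncol(x_train) == ncol(x_query), percentile > 0, percentile <= 100)
  if (k >= n) stop("k (", k, ") must be below the number of training rows (",
                   n, ")", call. = FALSE)
  d_tt <- cross_dist(x_train, x_train)
  diag(d_tt) <- Inf                                  # leave-self-out
  self_knn <- apply(d_tt, 1L, function(d) mean(sort(d)[seq_len(k)]))
  thr <- stats::quantile(self_knn, percentile / 100, type = 7, names = FALSE)
  d_qt <- cross_dist(x_query, x_train)
  score <- apply(d_qt, 1L, function(d) mean(sort(d)[seq_len(k)]))
  ad_result(sprintf("knn_k%d", k), inside = score <= thr, score = score,
            threshold = thr)
}

#' Leverage and standardized-residual diagnostic
#'
#' Leverage of a query is \eqn{h = x (X^T X)^{-1} x^T} on the
#' intercept-augmented training design; the warning threshold is
#' \eqn{h^* = 3(p+1)/n}. Combined with the standardized prediction
#' residual this classifies each query as `in_domain`, `good_leverage`
#' (structurally far but well predicted), `bad_leverage` (far and badly
#' predicted) or `outlier` (near but badly predicted, |standardized
#' residual| > 3).
#'
#' @inheritParams pca_bounding_box
#' @param y_obs_query,y_pred_query observed and predicted responses for the
#'   queries; `NULL` classifies on leverage alone.
#' @param residual_scale scale used to standardize query residuals
#'   (typically the training RMSE); default is the standard deviation of
#'   the query residuals themselves.
#' @return list with `query` (data.frame: leverage, std_residual,
#'   category), `h_star`, and `train_leverage` (whose sum equals p + 1).
#' @export
leverage_diagnostic <- function(x_train, x_query, y_obs_query = NULL,
                                y_pred_query = NULL, residual_scale = NULL) {
  stopifnot(ncol(x_train) == ncol(x_query))
  n <- nrow(x_train); p <- ncol(x_train)
  X <- cbind(1, x_train)
  qrX <- qr(X)
  if (qrX$rank < p + 1L)
    stop("training design is rank deficient; reduce descriptors further ",
         "before the leverage diagnostic", call. = FALSE)
  R <- qr.R(qrX)
  lev_of <- function(M) {
    # h = || R^-T m ||^2 row by row
    B <- forwardsolve(t(R), t(cbind(1, M)))
    colSums(B^2)
  }
  h_train <- lev_of(x_train)
  h_query <- lev_of(x_query)
  h_star <- 3 * (p + 1) / n
  if (is.null(y_obs_query)) {
    std_res <- rep(NA_real_, nrow(x_query))
  } else {
    resid <- y_obs_query - y_pred_query
    if (is.null(residual_scale)) residual_scale <- stats::sd(resid)
    if (!is.finite(residual_scale) || residual_scale <= 0) residual_scale <- 1
    std_res <- resid / residual_scale
  }
  category <- ifelse(h_query > h_star,
                     ifelse(!is.na(std_res) & abs(std_res) > 3,
                            "bad_leverage", "good_leverage"),
                     ifelse(!is.na(std_res) & abs(std_res) > 3,
                            "outlier", "in_domain"))
  list(query = data.frame(leverage = h_query, std_residual = std_res,
                          category = category,
                          row.names = rownames(x_query)),
       h_star = h_star, train_leverage = h_train)
}

#' Run the four applicability-domain methods with shared scaling
#'
#' Standardizes the training rows (mean 0, sd 1), applies the same
#' transform to the queries, then runs the PCA bounding box, the centroid
#' distance percentile, and the kNN methods for each configured k.
#'
#' @param x_train,x_query descriptor matrices (same columns), typically the
#'   filtered descriptor space.
#' @param config a [pipeline_config()]; uses `percentile`, `knn_k` and
#'   `n_components`.
#' @return object of class `ad_suite`: list of `ad_result` plus a `summary`
#'   data.frame (method, inside, outside).
#' @export
run_ad_suite <- function(x_train, x_query, config = pipeline_config()) {
  stopifnot(identical(colnames(x_train), colnames(x_query)))
  scaler <- fit_scaler(x_train)
  tr <- scale_apply(scaler, x_train)
  qu <- scale_apply(scaler, x_query)
  results <- c(
    list(pca_bounding_box(tr, qu, config$n_components),
         centroid_distance_ad(tr, qu, config$percentile)),
    lapply(config$knn_k, function(k) knn_ad(tr, qu, k, config$percentile)))
  summary <- data.frame(
    method = vapply(results, `[[`, "", "method"),
    inside = vapply(results, `[[`, 0L, "n_inside"),
    outside = vapply(results, `[[`, 0L, "n_outside"))
  structure(list(results = results, summary = summary), class = "ad_suite")
}

#' @export
print.ad_suite <- function(x, ...) {
  cat("applicability domain (", x$summary$inside[1] + x$summary$outside[1],
      " queries)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
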