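#' Descriptor filter cascade
#'
#' Five-stage filter feature selection for wide descriptor matrices, applied
#' in a fixed order: exactly constant columns, quasi-constant columns (25th
#' percentile equal to 75th percentile), low relative standard deviation,
#' pairwise Pearson correlation, and variance inflation factor. Each stage
#' returns the reduced matrix together with an audit record of what was
#' removed and the diagnostic value that condemned it.
#'
#' @name filter_cascade
NULL

stage_record <- function(stage, threshold, removed, diagnostics, n_before) {
  stopifnot(length(removed) == length(diagnostics))
  list(stage = stage, threshold = threshold,
       removed = removed, diagnostics = diagnostics,
       n_before = n_before, n_after = n_before - length(removed))
}

#' Remove exactly constant descriptors
#'
#' Drops every column whose minimum equals its maximum; the constant value is
#' recorded as the diagnostic.
#'
#' @param x descriptor matrix.
#' @return list with `x` (reduced matrix) and `record` (stage record).
#' @export
remove_constant <- function(x) {
  validate_descriptor_matrix(x)
  rng <- apply(x, 2L, range)
  const <- rng[1L, ] == rng[2L, ]
  if (all(const)) stop("all descriptors are constant; nothing left to model",
                       call. = FALSE)
  list(x = x[, !const, drop = FALSE],
       record = stage_record("constant", NA_real_,
                             colnames(x)[const], rng[1L, const],
                             ncol(x)))
}

#' Remove quasi-constant descriptors
#'
#' Drops every column whose 25th and 75th percentiles coincide (quartiles by
#' linear interpolation between order statistics, `quantile` type 7, fixed so
#' the rule is reproducible across platforms). The shared quartile value is
#' the diagnostic.
#'
#' @inheritParams remove_constant
#' @return list with `x` and `record`.
#' @export
remove_quasi_constant <- function(x) {
  validate_descriptor_matrix(x)
  if (nrow(x) < 4L) stop("need at least 4 compounds to assess quartiles", call. = FALSE)
  q <- apply(x, 2L, stats::quantile, probs = c(0.25, 0.75), type = 7, names = FALSE)
  quasi <- q[1L, ] == q[2L, ]
  if (all(quasi)) stop("all descriptors are quasi-constant; nothing left to model",
                       call. = FALSE)
  list(x = x[, !quasi, drop = FALSE],
       record = stage_record("quasi_constant", NA_real_,
                             colnames(x)[quasi], q[1L, quasi],
                             ncol(x)))
}

#' Remove descriptors with low relative standard deviation
#'
#' The relative standard deviation of a column is its sample standard
#' deviation (n - 1 denominator) divided by the absolute value of its mean.
#' Columns with RSD below `rsd_min` carry almost no relative dispersion and
#' are dropped. Columns whose mean is exactly zero are retained (RSD treated
#' as infinite).
#'
#' @inheritParams remove_constant
#' @param rsd_min positive threshold, default 0.05.
#' @return list with `x` and `record`.
#' @export
remove_low_rsd <- function(x, rsd_min = 0.05) {
  validate_descriptor_matrix(x)
  stopifnot(rsd_min > 0)
  m <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  rsd <- ifelse(m == 0, Inf, s / abs(m))
  low <- rsd < rsd_min
  if (all(low)) stop("all descriptors fall below the RSD threshold", call. = FALSE)
  list(x = x[, !low, drop = FALSE],
       record = stage_record("low_rsd", rsd_min,
                             colnames(x)[low], rsd[low], ncol(x)))
}

#' Remove pairwise-correlated descriptors
#'
#' Greedy elimination of redundant columns: while any pair has absolute
#' Pearson correlation above `r_max`, take the worst pair and drop the member
#' with the larger mean absolute correlation to all other remaining columns
#' (ties broken toward the later column). Anti-correlated duplicates are as
#' redundant as correlated ones, hence the absolute value.
#'
#' @inheritParams remove_constant
#' @param r_max threshold in (0, 1), default 0.75.
#' @return list with `x` and `record`; the diagnostics are the offending
#'   |R| values and the `partners` attribute names each removal's partner.
#' @export
remove_correlated <- function(x, r_max = 0.75) {
  validate_descriptor_matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 compounds for correlations", call. = FALSE)
  stopifnot(r_max > 0, r_max < 1)
  n_before <- ncol(x)
  C <- abs(stats::cor(x))
  diag(C) <- 0
  removed <- character(0); diag_r <- numeric(0); partners <- character(0)
  repeat {
    w <- arrayInd(which.max(C), dim(C))
    r <- C[w]
    if (r <= r_max) break
    i <- w[1L]; j <- w[2L]
    # mean |R| of each member against every other remaining column
    mi <- mean(C[i, -i]); mj <- mean(C[j, -j])
    drop_j <- if (mi == mj) max(i, j) == j else mj > mi
    drop <- if (drop_j) j else i
    keep <- if (drop_j) i else j
    removed <- c(removed, colnames(C)[drop])
    diag_r <- c(diag_r, r)
    partners <- c(partners, colnames(C)[keep])
    C <- C[-drop, -drop, drop = FALSE]
    if (ncol(C) < 2L) break
  }
  rec <- stage_record("pairwise_correlation", r_max, removed, diag_r, n_before)
  rec$partners <- partners
  list(x = x[, setdiff(colnames(x), removed), drop = FALSE], record = rec)
}

#' Variance inflation factors
#'
#' VIF of descriptor i is 1 / (1 - R_i^2) where R_i^2 comes from regressing
#' descriptor i on all other descriptors (with intercept). Computed as the
#' diagonal of the inverse correlation matrix when that matrix is positive
#' definite, otherwise column by column via rank-revealing least squares;
#' exact collinearity yields `Inf`, never an error.
#'
#' @param x descriptor matrix with more compounds than descriptors + 1 and no
#'   constant columns.
#' @return named numeric vector of VIF values (>= 1 up to rounding).
#' @export
compute_vif <- function(x) {
  validate_descriptor_matrix(x)
  p <- ncol(x)
  if (p == 1L) return(stats::setNames(1, colnames(x)))
  if (nrow(x) <= p + 1L)
    stop("VIF needs more compounds (", nrow(x), ") than descriptors + 1 (",
         p + 1L, "); reduce descriptors first", call. = FALSE)
  if (any(apply(x, 2L, stats::sd) == 0))
    stop("constant columns must be removed before VIF", call. = FALSE)
  C <- stats::cor(x)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (!is.null(ch) && min(diag(ch)) > 1e-7) {
    v <- diag(chol2inv(ch))
  } else {
    # near-singular: per-column least squares with pivoting
    xs <- scale(x)
    v <- vapply(seq_len(p), function(i) {
      fit <- stats::lm.fit(cbind(1, xs[, -i, drop = FALSE]), xs[, i])
      r2 <- 1 - sum(fit$residuals^2) / sum(xs[, i]^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  stats::setNames(pmax(v, 1), colnames(x))
}

#' Remove descriptors with high variance inflation
#'
#' Iterative worst-first elimination: drop the single column with the largest
#' VIF above `vif_max`, recompute on the survivors, repeat. One-pass removal
#' can strand inflated columns; the iterative rule guarantees every survivor
#' ends below the threshold. Final survivor VIFs are recorded.
#'
#' @inheritParams compute_vif
#' @param vif_max threshold, default 5.
#' @return list with `x` and `record`; `record$final_vif` holds survivor VIFs.
#' @export
remove_high_vif <- function(x, vif_max = 5) {
  removed <- character(0); diag_v <- numeric(0)
  n_before <- ncol(x)
  repeat {
    v <- compute_vif(x)
    worst <- which.max(v)
    if (v[worst] <= vif_max) break
    # ties toward the later column
    worst <- max(which(v == v[worst]))
    removed <- c(removed, colnames(x)[worst])
    diag_v <- c(diag_v, v[worst])
    x <- x[, -worst, drop = FALSE]
    if (ncol(x) < 2L) break
  }
  rec <- stage_record("vif", vif_max, removed, diag_v, n_before)
  rec$final_vif <- compute_vif(x)
  list(x = x, record = rec)
}

#' Run the full descriptor filter cascade
#'
#' Applies the five stages in order (constant, quasi-constant, RSD, pairwise
#' correlation, VIF). When `rows` is given, all filtering statistics are
#' computed on those compounds only — typically the modeling set, so the
#' external validation set never influences the thresholds — and the
#' resulting column selection is then applied to the full matrix.
#'
#' @param x descriptor matrix.
#' @param config [pipeline_config()] carrying `rsd_min`, `r_max`, `vif_max`.
#' @param rows optional character vector of compound ids to compute the
#'   filter statistics on.
#' @return list with `x` (reduced matrix over all rows) and `report`
#'   (class `filter_report`).
#' @export
run_filter_cascade <- function(x, config = pipeline_config(), rows = NULL) {
  validate_descriptor_matrix(x)
  xs <- if (is.null(rows)) x else {
    if (!all(rows %in% rownames(x))) stop("unknown ids in rows", call. = FALSE)
    x[rows, , drop = FALSE]
  }
  s1 <- remove_constant(xs)
  s2 <- remove_quasi_constant(s1$x)
  s3 <- remove_low_rsd(s2$x, config$rsd_min)
  s4 <- remove_correlated(s3$x, config$r_max)
  s5 <- remove_high_vif(s4$x, config$vif_max)
  report <- structure(
    list(stages = list(s1$record, s2$record, s3$record, s4$record, s5$record),
         n_initial = ncol(x), retained = colnames(s5$x),
         stat_rows = if (is.null(rows)) rownames(x) else rows),
    class = "filter_report")
  list(x = x[, report$retained, drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("descriptor filter cascade:", x$n_initial, "->",
      length(x$retained), "descriptors\n")
  for (s in x$stages)
    cat(sprintf("  %-22s removed %4d  (%d -> %d)\n",
                s$stage, length(s$removed), s$n_before, s$n_after))
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report a `filter_report`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
filter_report_json <- function(report, path = NULL) {
  obj <- list(
    n_initial = report$n_initial,
    n_retained = length(report$retained),
    retained = report$retained,
    stages = lapply(report$stages, function(s) {
      list(stage = s$stage, threshold = s$threshold,
           n_before = s$n_before, n_after = s$n_after,
           removed = as.list(stats::setNames(s$diagnostics, s$removed)))
    }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
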