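#' @keywords internal
"_PACKAGE"

#' Validate a descriptor matrix
#'
#' A descriptor matrix is a plain numeric matrix whose rows are compounds
#' (rownames are unique compound identifiers) and whose columns are named
#' molecular descriptors. All cells must be finite; missing values are
#' rejected at load time, not imputed.
#'
#' @param x numeric matrix with unique rownames (compound ids) and unique
#'   colnames (descriptor names).
#' @return `x`, invisibly, after validation.
#' @export
validate_descriptor_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("descriptor matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("descriptor matrix must carry compound ids as rownames and descriptor names as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate compound ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate descriptor names: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at compound '%s', descriptor '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]), call. = FALSE)
  }
  invisible(x)
}

#' Validate a bound-fraction response vector against a descriptor matrix
#'
#' The response is the plasma protein-bound fraction fb, dimensionless in
#' \[0, 1\], carried as a named numeric vector aligned by compound id.
#'
#' @param fb named numeric vector of bound fractions.
#' @param x descriptor matrix the response must align with (optional).
#' @return `fb`, invisibly.
#' @export
validate_response <- function(fb, x = NULL) {
  if (!is.numeric(fb) || is.null(names(fb)))
    stop("response must be a named numeric vector", call. = FALSE)
  if (!all(is.finite(fb)))
    stop("non-finite response for compound(s): ",
         paste(names(fb)[!is.finite(fb)], collapse = ", "), call. = FALSE)
  if (any(fb < 0 | fb > 1))
    stop("bound fraction outside [0, 1] for compound(s): ",
         paste(names(fb)[fb < 0 | fb > 1], collapse = ", "), call. = FALSE)
  if (!is.null(x)) {
    if (length(fb) != nrow(x) || !identical(names(fb), rownames(x)))
      stop("response compound ids do not match descriptor matrix rows; ",
           "refusing to reorder silently", call. = FALSE)
  }
  invisible(fb)
}

#' Read a compound-by-descriptor table with its response column
#'
#' Reads a delimited text file (comma for `.csv`, tab for `.tsv`/`.txt`,
#' autodetected from the extension) with a header row and compound ids in the
#' first column, splits off the response column, and validates everything:
#' all cells must parse as finite numbers, ids must be unique, and the
#' response must lie in \[0, 1\] (or \[0, 100\] with `percent = TRUE`).
#'
#' @param path path to the delimited file.
#' @param response_column name of the response column (default `"fb"`).
#' @param percent if `TRUE` the response is a percentage and is divided by 100.
#' @return list with components `x` (descriptor matrix) and `fb` (named
#'   response vector aligned with `x`).
#' @export
read_descriptor_table <- function(path, response_column = "fb", percent = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 3L)
    stop("expected at least an id column, one descriptor and the response column",
         call. = FALSE)
  ids <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  if (!response_column %in% colnames(body))
    stop("response column '", response_column, "' not found in ", path, call. = FALSE)
  num <- matrix(NA_real_, nrow(body), ncol(body),
                dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    blank <- is.na(v)
    if (any(blank)) {
      i <- which(blank)[1L]
      stop(sprintf("cell for compound '%s', column '%s' is missing or not numeric",
                   ids[i], colnames(body)[j]), call. = FALSE)
    }
    num[, j] <- v
  }
  fb <- num[, response_column]
  if (percent) fb <- fb / 100
  x <- num[, setdiff(colnames(num), response_column), drop = FALSE]
  validate_descriptor_matrix(x)
  validate_response(fb, x)
  list(x = x, fb = fb)
}

#' Write a descriptor matrix and response to delimited text
#'
#' Inverse of [read_descriptor_table()]: values are written at full double
#' precision (17 significant digits) so a write/read round trip is exact.
#'
#' @param x descriptor matrix.
#' @param fb named response vector aligned with `x`.
#' @param path output path; `.csv` writes comma-separated, anything else tab.
#' @param response_column name for the response column.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(x, fb, path, response_column = "fb") {
  validate_descriptor_matrix(x)
  validate_response(fb, x)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(compound_id = rownames(x),
                   formatC(x, format = "g", digits = 17),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[[response_column]] <- formatC(fb, format = "g", digits = 17)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Partition compound ids by holdout cross-validation
#'
#' Splits the ids at random (seed-controlled) into disjoint training,
#' internal-validation and external-validation sets covering the whole
#' dataset. Set sizes follow largest-remainder apportionment of
#' `fractions * length(ids)`: each set gets the floor of its quota and the
#' leftover compounds go to the sets with the largest fractional parts, ties
#' broken toward the later set. The default external fraction mirrors a
#' 42-of-277 external holdout (about 15%).
#'
#' @param ids character vector of unique compound ids.
#' @param fractions length-3 positive numeric summing to 1:
#'   (train, internal validation, external validation).
#' @param seed integer seed; equal seeds give identical splits.
#' @return object of class `holdout_split`: list with `train`, `internal`,
#'   `external` (character vectors), `fractions` and `seed`.
#' @export
make_holdout_split <- function(ids, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (anyDuplicated(ids)) stop("duplicate ids", call. = FALSE)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three positive numbers summing to 1", call. = FALSE)
  n <- length(ids)
  sizes <- split_sizes(n, fractions)
  if (any(sizes < 1L))
    stop("too few compounds (", n, ") for three non-empty sets", call. = FALSE)
  shuffled <- with_seed(seed, sample(ids))
  out <- list(train    = sort(shuffled[seq_len(sizes[1L])]),
              internal = sort(shuffled[sizes[1L] + seq_len(sizes[2L])]),
              external = sort(shuffled[sizes[1L] + sizes[2L] + seq_len(sizes[3L])]),
              fractions = fractions, seed = as.integer(seed))
  class(out) <- "holdout_split"
  out
}

# Largest-remainder apportionment; ties on the fractional part go to the
# later set so the external holdout wins an even split of the leftovers.
split_sizes <- function(n, fractions) {
  quota <- n * fractions
  sizes <- floor(quota)
  left <- n - sum(sizes)
  if (left > 0) {
    frac <- quota - sizes
    ord <- order(frac, seq_along(frac), decreasing = TRUE)
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1
  }
  as.integer(sizes)
}

#' @export
print.holdout_split <- function(x, ...) {
  cat(sprintf("holdout split (seed %d): %d train / %d internal validation / %d external\n",
              x$seed, length(x$train), length(x$internal), length(x$external)))
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with defaults reproducing the
#' reference settings: descriptor filters RSD >= 0.05, pairwise |R| <= 0.75,
#' VIF <= 5; hidden-layer growth 5, 10, ..., 50; applicability-domain
#' percentile 95 with kNN at k = 5 and k = 25.
#'
#' @param rsd_min minimum relative standard deviation a descriptor must show.
#' @param r_max maximum tolerated absolute pairwise Pearson correlation.
#' @param vif_max maximum tolerated variance inflation factor.
#' @param k_start,k_step,k_max hidden-neuron growth schedule.
#' @param max_iterations,lm_lambda_init,lm_lambda_factor,tolerance
#'   Levenberg-Marquardt controls (iteration cap, initial damping, damping
#'   factor, relative sum-of-squares improvement tolerance).
#' @param percentile applicability-domain calibration percentile (0-100).
#' @param knn_k neighbour counts for the kNN applicability-domain methods.
#' @param n_components PCA bounding-box component count; `NULL` keeps the
#'   components explaining 95% of training variance.
#' @param fractions holdout fractions (train, internal, external).
#' @param clip clip network predictions to \[0, 1\] (the response is a fraction).
#' @param warm_start retain trained neurons when growing the hidden layer.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(rsd_min = 0.05, r_max = 0.75, vif_max = 5,
                            k_start = 5L, k_step = 5L, k_max = 50L,
                            max_iterations = 200L, lm_lambda_init = 1e-3,
                            lm_lambda_factor = 10, tolerance = 1e-10,
                            percentile = 95, knn_k = c(5L, 25L),
                            n_components = NULL,
                            fractions = c(0.70, 0.15, 0.15),
                            clip = TRUE, warm_start = TRUE, seed = 1L) {
  stopifnot(rsd_min > 0, r_max > 0, r_max < 1, vif_max >= 1,
            k_start >= 1, k_step >= 1, k_max >= k_start,
            max_iterations >= 1, lm_lambda_init > 0, lm_lambda_factor > 1,
            tolerance > 0, percentile > 0, percentile < 100 + 1e-9,
            all(knn_k >= 1))
  out <- list(rsd_min = rsd_min, r_max = r_max, vif_max = vif_max,
              k_start = as.integer(k_start), k_step = as.integer(k_step),
              k_max = as.integer(k_max),
              max_iterations = as.integer(max_iterations),
              lm_lambda_init = lm_lambda_init,
              lm_lambda_factor = lm_lambda_factor, tolerance = tolerance,
              percentile = percentile, knn_k = as.integer(knn_k),
              n_components = n_components, fractions = fractions,
              clip = clip, warm_start = warm_start, seed = as.integer(seed))
  class(out) <- "pipeline_config"
  out
}

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Stable per-stage seed derived from the master seed and a stage label,
# kept below 2^31 so it is a valid R integer.
derive_seed <- function(seed, label) {
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 1000003
  as.integer((as.double(seed) * 7919 + h) %% 2147483587)
}
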