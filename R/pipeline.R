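#' End-to-end QSAR pipeline
#'
#' Orchestrates the five stages on an aligned descriptor matrix and bound
#' fraction response: holdout split, descriptor filter cascade (statistics
#' on the modeling rows only), hidden-neuron growth search, validation
#' metric batteries (internal and external), and the applicability-domain
#' suite on the external compounds. External rows never influence the
#' filter thresholds, the scaler, the training, or the AD calibration.
#'
#' @param x descriptor matrix (compounds x descriptors).
#' @param fb named bound-fraction response aligned with `x`.
#' @param config a [pipeline_config()].
#' @return object of class `qsar_run` — see [run_report_json()] for the
#'   serialized layout. Carries the fitted `model` ([ffnn_model()]), the
#'   `split`, `filter_report`, `growth` trace, `metrics` (internal /
#'   external blocks), `ad` suite, `robustness`, and stage input
#'   fingerprints.
#' @export
run_pipeline <- function(x, fb, config = pipeline_config()) {
  validate_descriptor_matrix(x)
  validate_response(fb, x)
  split <- make_holdout_split(rownames(x), config$fractions,
                              derive_seed(config$seed, "split"))
  modeling <- c(split$train, split$internal)
  fingerprints <- list(input = fingerprint(x),
                       filter_input = fingerprint(x[modeling, , drop = FALSE]))

  filt <- run_filter_cascade(x, config, rows = modeling)
  xr <- filt$x
  fingerprints$filtered <- fingerprint(xr[modeling, , drop = FALSE])

  scaler <- fit_scaler(xr[split$train, , drop = FALSE])
  x_tr <- scale_apply(scaler, xr[split$train, , drop = FALSE])
  x_val <- scale_apply(scaler, xr[split$internal, , drop = FALSE])
  fingerprints$train_scaled <- fingerprint(x_tr)

  growth <- grow_hidden_layer(x_tr, fb[split$train], x_val, fb[split$internal],
                              config)
  model <- ffnn_model(growth$net, scaler, clip = config$clip)

  pred_tr <- predict(model, xr[split$train, , drop = FALSE])
  pred_val <- predict(model, xr[split$internal, , drop = FALSE])
  pred_ext <- predict(model, xr[split$external, , drop = FALSE])

  internal <- fit_metrics(fb[split$internal], pred_val,
                          n_predictors = ncol(xr))
  train_metrics <- fit_metrics(fb[split$train], pred_tr,
                               n_predictors = ncol(xr))
  external <- fit_metrics(fb[split$external], pred_ext,
                          n_predictors = ncol(xr))
  r_all <- stats::cor(c(pred_tr, pred_val), c(fb[split$train], fb[split$internal]))
  q2_internal <- external_q2(fb[split$internal], pred_val)
  q2_external <- external_q2(fb[split$external], pred_ext)
  robustness <- robustness_gap(train_metrics$r2, q2_internal)

  ad <- run_ad_suite(xr[split$train, , drop = FALSE],
                     xr[split$external, , drop = FALSE], config)
  leverage <- leverage_diagnostic(
    scale_apply(scaler, xr[split$train, , drop = FALSE]),
    scale_apply(scaler, xr[split$external, , drop = FALSE]),
    y_obs_query = fb[split$external], y_pred_query = pred_ext,
    residual_scale = train_metrics$rmse)

  out <- list(config = config, split = split,
              filter_report = filt$report,
              retained = colnames(xr),
              growth = growth, model = model,
              metrics = list(r_all = r_all,
                             train = train_metrics,
                             internal = internal,
                             q2_internal = q2_internal,
                             external = external,
                             q2_external = q2_external),
              robustness = robustness,
              ad = ad, leverage = leverage,
              predictions = list(train = pred_tr, internal = pred_val,
                                 external = pred_ext),
              fingerprints = fingerprints,
              seed = config$seed)
  class(out) <- "qsar_run"
  out
}

#' @export
print.qsar_run <- function(x, ...) {
  cat("QSAR pipeline run (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  split: %d train / %d internal / %d external\n",
              length(x$split$train), length(x$split$internal),
              length(x$split$external)))
  cat(sprintf("  descriptors: %d -> %d\n",
              x$filter_report$n_initial, length(x$retained)))
  cat(sprintf("  selected hidden neurons: %d\n", x$growth$selected_k))
  cat(sprintf("  R(all) = %.3f  R2(train) = %.3f  Q2(val) = %.3f  MSE(val) = %.4g\n",
              x$metrics$r_all, x$metrics$train$r2, x$metrics$q2_internal,
              x$metrics$internal$mse))
  cat(sprintf("  external: Q2 = %.3f  RMSE = %.4f  MAE = %.4f\n",
              x$metrics$q2_external, x$metrics$external$rmse,
              x$metrics$external$mae))
  cat(sprintf("  robustness gap = %.4f (%s)\n", x$robustness$gap,
              if (x$robustness$pass) "pass" else "FAIL"))
  print(x$ad$summary, row.names = FALSE)
  invisible(x)
}

# Deterministic content fingerprint of a numeric payload: dimensions plus
# value summaries formatted to 15 significant digits. Serves the audit and
# determinism purposes of a digest without a hashing dependency.
fingerprint <- function(x) {
  v <- as.vector(x)
  paste(collapse = ":",
        c(paste(dim(x) %||% length(x), collapse = "x"),
          formatC(c(sum(v), sum(v * v), min(v), max(v),
                    v[1L], v[length(v)]),
                  format = "g", digits = 15)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

metrics_block <- function(m) {
  list(n = m$n, r = m$r, r2 = m$r2, r2_adjusted = m$r2_adjusted,
       q2 = m$q2, mse = m$mse, rmse = m$rmse, mae = m$mae,
       rss = m$rss, ss = m$ss)
}

#' Serialize a pipeline run report to JSON
#'
#' Deterministic serialization of everything a reader needs to audit a run:
#' configuration echo, split sizes and membership, filter stage summary,
#' growth trace, metric batteries, applicability-domain summary, stage
#' fingerprints and the seed. No timestamps or absolute paths, so two runs
#' with identical inputs, config and seed produce byte-identical files.
#'
#' @param run a `qsar_run`.
#' @param path optional file path.
#' @return JSON string (invisibly when written to `path`).
#' @export
run_report_json <- function(run, path = NULL) {
  cfg <- unclass(run$config)
  cfg$n_components <- cfg$n_components %||% "auto95"
  obj <- list(
    seed = run$seed,
    config = cfg,
    split = list(n_train = length(run$split$train),
                 n_internal = length(run$split$internal),
                 n_external = length(run$split$external),
                 train = run$split$train,
                 internal = run$split$internal,
                 external = run$split$external),
    filter = jsonlite::fromJSON(filter_report_json(run$filter_report),
                                simplifyVector = FALSE),
    growth = list(trace = run$growth$trace, selected_k = run$growth$selected_k),
    metrics = list(r_all = run$metrics$r_all,
                   r2_train = run$metrics$train$r2,
                   q2_internal = run$metrics$q2_internal,
                   q2_external = run$metrics$q2_external,
                   train = metrics_block(run$metrics$train),
                   internal = metrics_block(run$metrics$internal),
                   external = metrics_block(run$metrics$external)),
    robustness = run$robustness,
    applicability_domain = run$ad$summary,
    leverage = list(h_star = run$leverage$h_star,
                    categories = as.list(table(run$leverage$query$category))),
    fingerprints = run$fingerprints)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
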