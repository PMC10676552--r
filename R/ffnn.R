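#' Single-hidden-layer feed-forward network
#'
#' The regression model is
#' \deqn{fb = \sum_{j=1}^{k} w2_j \tanh\Big(\sum_{i=1}^{p} x_i w_{ij} + b_j\Big) + b}
#' a feed-forward network with `p` inputs, one hidden layer of `k` tanh
#' units, and a single identity-output neuron. Parameters are held in a
#' `ffnn` object: `w_in` (k x p), `b_hidden` (k), `w_out` (k), `b_out`
#' (scalar).
#'
#' @name ffnn
NULL

#' Initialize network parameters
#'
#' Weights are drawn uniformly from a symmetric interval scaled by the
#' inverse square root of the fan-in, which keeps early tanh pre-activations
#' away from saturation. Deterministic for a fixed seed.
#'
#' @param p number of inputs (>= 1).
#' @param k number of hidden neurons (>= 1).
#' @param seed integer seed.
#' @return object of class `ffnn`.
#' @export
init_network <- function(p, k, seed = 1L) {
  if (p < 1 || k < 1) stop("p and k must be >= 1", call. = FALSE)
  with_seed(seed, {
    r_in <- 1 / sqrt(p)
    net <- list(p = as.integer(p), k = as.integer(k),
                w_in = matrix(stats::runif(k * p, -r_in, r_in), k, p),
                b_hidden = stats::runif(k, -r_in, r_in),
                w_out = stats::runif(k, -1 / sqrt(k), 1 / sqrt(k)),
                b_out = 0)
    class(net) <- "ffnn"
    net
  })
}

#' Forward pass
#'
#' Evaluates the network on a matrix of pre-scaled inputs, one row per
#' compound.
#'
#' @param net a `ffnn` object.
#' @param x numeric matrix (n x p) or length-p vector.
#' @return numeric vector of n predictions.
#' @export
ffnn_forward <- function(net, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != net$p)
    stop("input has ", ncol(x), " columns; network expects ", net$p, call. = FALSE)
  h <- tanh(sweep(x %*% t(net$w_in), 2L, net$b_hidden, `+`))
  unname(drop(h %*% net$w_out)) + net$b_out
}

# ---- parameter flattening ----------------------------------------------
# Order: w_in (column-major k x p), b_hidden, w_out, b_out.

flatten_params <- function(net) {
  c(as.vector(net$w_in), net$b_hidden, net$w_out, net$b_out)
}

unflatten_params <- function(theta, p, k) {
  stopifnot(length(theta) == k * p + 2L * k + 1L)
  net <- list(p = as.integer(p), k = as.integer(k),
              w_in = matrix(theta[seq_len(k * p)], k, p),
              b_hidden = theta[k * p + seq_len(k)],
              w_out = theta[k * p + k + seq_len(k)],
              b_out = theta[k * p + 2L * k + 1L])
  class(net) <- "ffnn"
  net
}

# Residuals r = yhat - y and the Jacobian of r with respect to the
# flattened parameters, built blockwise from the hidden activations.
ffnn_residual_jacobian <- function(theta, x, y, p, k) {
  n <- nrow(x)
  w_in <- matrix(theta[seq_len(k * p)], k, p)
  b_h <- theta[k * p + seq_len(k)]
  w_out <- theta[k * p + k + seq_len(k)]
  b_out <- theta[k * p + 2L * k + 1L]
  h <- tanh(sweep(x %*% t(w_in), 2L, b_h, `+`))      # n x k
  yhat <- drop(h %*% w_out) + b_out
  d <- (1 - h * h) * rep(w_out, each = n)            # n x k: w2_j (1 - h_j^2)
  # d yhat / d w_in[j, i] = d[, j] * x[, i]; column-major over (j, i)
  J_win <- d[, rep(seq_len(k), times = p), drop = FALSE] *
    x[, rep(seq_len(p), each = k), drop = FALSE]
  J <- cbind(J_win, d, h, 1)
  list(r = yhat - y, J = J, yhat = yhat)
}

#' Train a network by Levenberg-Marquardt least squares
#'
#' Minimizes the sum of squared residuals with the damped Gauss-Newton
#' update \eqn{(J^T J + \lambda I)\,\delta = J^T r}. Accepted steps divide
#' the damping by `lambda_factor`, rejected steps multiply it, so the
#' accepted-step training MSE is monotone non-increasing. Terminates when
#' the relative sum-of-squares improvement drops below `tolerance`, the
#' gradient or step collapses, the damping exceeds `lambda_max`, or
#' `max_iterations` is hit.
#'
#' With a validation set (`x_val`, `y_val`) the trainer additionally
#' monitors the validation MSE after every accepted step, remembers the
#' parameters at the validation minimum, and stops once validation has
#' failed to improve for `patience` consecutive accepted steps — the
#' standard early-stopping regularizer for networks with more parameters
#' than training compounds. The returned network is the one at the
#' validation minimum; without a validation set it is the final iterate.
#'
#' @param net initial `ffnn`.
#' @param x pre-scaled training inputs (n x p).
#' @param y training targets (length n).
#' @param max_iterations iteration cap.
#' @param lambda_init initial damping.
#' @param lambda_factor damping multiplier (> 1).
#' @param tolerance relative SSE improvement below which training stops.
#' @param lambda_max damping above which the search is declared stalled.
#' @param x_val,y_val optional validation set for early stopping.
#' @param patience accepted steps without validation improvement tolerated
#'   before stopping (only with a validation set).
#' @return list with `net` (trained), `trace` (data.frame of accepted
#'   iterations: iteration, mse, lambda, and mse_val when validating),
#'   `converged`, `iterations`, `mse` (training MSE of the returned net).
#' @export
train_lm <- function(net, x, y, max_iterations = 200L, lambda_init = 1e-3,
                     lambda_factor = 10, tolerance = 1e-10,
                     lambda_max = 1e12, x_val = NULL, y_val = NULL,
                     patience = 6L) {
  stopifnot(inherits(net, "ffnn"), nrow(x) == length(y),
            ncol(x) == net$p, max_iterations >= 1, tolerance > 0)
  p <- net$p; k <- net$k; n <- nrow(x)
  theta <- flatten_params(net)
  m <- length(theta)
  validating <- !is.null(x_val)
  val_mse_of <- function(th) {
    pred <- ffnn_forward(unflatten_params(th, p, k), x_val)
    mean((pred - y_val)^2)
  }
  rj <- ffnn_residual_jacobian(theta, x, y, p, k)
  sse <- sum(rj$r^2)
  if (!is.finite(sse)) stop("non-finite loss at initialization", call. = FALSE)
  lambda <- lambda_init
  trace_it <- c(0L); trace_mse <- c(sse / n); trace_lambda <- c(lambda)
  best_val <- if (validating) val_mse_of(theta) else NA_real_
  trace_val <- c(best_val)
  best_theta <- theta; best_sse <- sse; val_fails <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    g <- crossprod(rj$J, rj$r)                       # m x 1 gradient (1/2 SSE)
    if (max(abs(g)) < 1e-12) { converged <- TRUE; break }
    A <- crossprod(rj$J)
    accepted <- FALSE
    repeat {
      ch <- tryCatch(chol(A + diag(lambda, m)), error = function(e) NULL)
      if (!is.null(ch)) {
        delta <- backsolve(ch, forwardsolve(t(ch), g))
        theta_new <- theta - delta
        rj_new <- ffnn_residual_jacobian(theta_new, x, y, p, k)
        sse_new <- sum(rj_new$r^2)
        if (!is.finite(sse_new))
          stop("non-finite loss at iteration ", iter, call. = FALSE)
        if (sse_new < sse) {
          improvement <- (sse - sse_new) / max(sse, .Machine$double.xmin)
          theta <- theta_new; rj <- rj_new; sse <- sse_new
          lambda <- lambda / lambda_factor
          accepted <- TRUE
          trace_it <- c(trace_it, iter); trace_mse <- c(trace_mse, sse / n)
          trace_lambda <- c(trace_lambda, lambda)
          if (validating) {
            vm <- val_mse_of(theta)
            trace_val <- c(trace_val, vm)
            if (vm < best_val) {
              best_val <- vm; best_theta <- theta; best_sse <- sse
              val_fails <- 0L
            } else {
              val_fails <- val_fails + 1L
              if (val_fails >= patience) converged <- TRUE
            }
          }
          if (improvement < tolerance ||
              sqrt(sum(delta^2)) < 1e-14 * (1 + sqrt(sum(theta^2))))
            converged <- TRUE
          break
        }
      }
      lambda <- lambda * lambda_factor
      if (lambda > lambda_max) break
    }
    if (!accepted || converged) { converged <- TRUE; break }
    if (sse / n < .Machine$double.eps) { converged <- TRUE; break }
  }
  if (validating) { theta <- best_theta; sse <- best_sse }
  trace <- data.frame(iteration = trace_it, mse = trace_mse,
                      lambda = trace_lambda)
  if (validating) trace$mse_val <- trace_val
  list(net = unflatten_params(theta, p, k), trace = trace,
       converged = converged, iterations = iter, mse = sse / n)
}

# ---- input scaling ------------------------------------------------------

#' Fit a per-descriptor standardizer on training rows
#'
#' Location/scale standardization (mean 0, sd 1) fitted on training rows
#' only; constant columns get scale 1 so transforms stay finite.
#'
#' @param x training descriptor matrix.
#' @return object of class `ffnn_scaler`.
#' @export
fit_scaler <- function(x) {
  s <- apply(x, 2L, stats::sd)
  out <- list(center = colMeans(x), scale = ifelse(s == 0, 1, s),
              names = colnames(x))
  class(out) <- "ffnn_scaler"
  out
}

#' Apply or invert a fitted standardizer
#'
#' @param scaler a `ffnn_scaler`.
#' @param x matrix whose columns match the scaler.
#' @return transformed matrix.
#' @export
scale_apply <- function(scaler, x) {
  stopifnot(inherits(scaler, "ffnn_scaler"))
  if (!identical(colnames(x), scaler$names))
    stop("columns do not match the fitted scaler", call. = FALSE)
  sweep(sweep(x, 2L, scaler$center, `-`), 2L, scaler$scale, `/`)
}

#' @rdname scale_apply
#' @export
scale_invert <- function(scaler, x) {
  stopifnot(inherits(scaler, "ffnn_scaler"))
  sweep(sweep(x, 2L, scaler$scale, `*`), 2L, scaler$center, `+`)
}

# ---- hidden-neuron growth search ---------------------------------------

# Warm start: keep the trained neurons, append k_step freshly seeded ones,
# and resume training from the previous optimum.
grow_network <- function(net, k_step, seed) {
  p <- net$p
  fresh <- init_network(p, k_step, seed)
  out <- list(p = p, k = net$k + as.integer(k_step),
              w_in = rbind(net$w_in, fresh$w_in),
              b_hidden = c(net$b_hidden, fresh$b_hidden),
              w_out = c(net$w_out, fresh$w_out),
              b_out = net$b_out)
  class(out) <- "ffnn"
  out
}

#' Hidden-neuron growth search
#'
#' Starts from a small hidden layer, trains to convergence, then repeatedly
#' appends `k_step` freshly seeded neurons and resumes training, recording
#' for each size the correlation over train + validation rows (`r_all`),
#' the training \eqn{R^2}, the validation \eqn{Q^2}, and the validation
#' MSE. The search stops at `k_max` or earlier when the validation MSE has
#' worsened relative to the best seen for two consecutive sizes. The
#' selected size minimizes validation MSE; ties break toward larger
#' \eqn{Q^2}, then larger training \eqn{R^2}, then smaller `k`.
#'
#' @param x_train,y_train pre-scaled training inputs and targets.
#' @param x_val,y_val pre-scaled internal-validation inputs and targets.
#' @param config a [pipeline_config()]; uses the growth schedule, the
#'   Levenberg-Marquardt controls, `warm_start` and the seed.
#' @return object of class `growth_trace`: data.frame `trace` with one row
#'   per size, `selected_k`, and `net` (the trained network of the selected
#'   size).
#' @export
grow_hidden_layer <- function(x_train, y_train, x_val, y_val,
                              config = pipeline_config()) {
  schedule <- seq.int(config$k_start, config$k_max, by = config$k_step)
  stopifnot(length(schedule) >= 1L, nrow(x_train) == length(y_train),
            nrow(x_val) == length(y_val), ncol(x_train) == ncol(x_val))
  p <- ncol(x_train)
  nets <- vector("list", length(schedule))
  rows <- vector("list", length(schedule))
  net <- NULL
  best_mse <- Inf; worse_streak <- 0L; n_done <- 0L
  for (s in seq_along(schedule)) {
    k <- schedule[s]
    seed_k <- derive_seed(config$seed, paste0("grow_k", k))
    net <- if (is.null(net)) {
      init_network(p, k, seed_k)
    } else if (config$warm_start) {
      grow_network(net, k - net$k, seed_k)
    } else {
      init_network(p, k, seed_k)
    }
    fit <- train_lm(net, x_train, y_train,
                    max_iterations = config$max_iterations,
                    lambda_init = config$lm_lambda_init,
                    lambda_factor = config$lm_lambda_factor,
                    tolerance = config$tolerance,
                    x_val = x_val, y_val = y_val)
    net <- fit$net
    pred_tr <- ffnn_forward(net, x_train)
    pred_val <- ffnn_forward(net, x_val)
    r_all <- stats::cor(c(pred_tr, pred_val), c(y_train, y_val))
    r2_train <- 1 - sum((pred_tr - y_train)^2) / sum((y_train - mean(y_train))^2)
    q2 <- external_q2(y_val, pred_val)
    mse_val <- mean((pred_val - y_val)^2)
    nets[[s]] <- net
    rows[[s]] <- data.frame(k = k, r_all = r_all, r2_train = r2_train,
                            q2 = q2, mse_validation = mse_val,
                            train_mse = fit$mse, iterations = fit$iterations)
    n_done <- s
    if (mse_val < best_mse) {
      best_mse <- mse_val; worse_streak <- 0L
    } else {
      worse_streak <- worse_streak + 1L
      if (worse_streak >= 2L) break
    }
  }
  trace <- do.call(rbind, rows[seq_len(n_done)])
  ord <- order(trace$mse_validation, -trace$q2, -trace$r2_train, trace$k)
  sel <- ord[1L]
  out <- list(trace = trace, selected_k = trace$k[sel], net = nets[[sel]])
  class(out) <- "growth_trace"
  out
}

#' @export
print.growth_trace <- function(x, ...) {
  cat("hidden-neuron growth search; selected k =", x$selected_k, "\n")
  print(x$trace[, c("k", "r_all", "r2_train", "q2", "mse_validation")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Bundle a trained network with its scaler
#'
#' @param net trained `ffnn`.
#' @param scaler the `ffnn_scaler` fitted on the training rows.
#' @param clip clip predictions to \[0, 1\] (the bound fraction is a
#'   physical fraction; raw network output can overshoot slightly).
#' @return object of class `ffnn_model`.
#' @export
ffnn_model <- function(net, scaler, clip = TRUE) {
  stopifnot(inherits(net, "ffnn"), inherits(scaler, "ffnn_scaler"))
  structure(list(net = net, scaler = scaler, clip = clip),
            class = "ffnn_model")
}

#' Predict bound fractions for new compounds
#'
#' Applies the fitted scaler, runs the forward pass, and (by default) clips
#' predictions to \[0, 1\].
#'
#' @param object a `ffnn_model`.
#' @param newdata descriptor matrix with the model's columns.
#' @param clip overrides the model's clip flag when not `NULL`.
#' @param ... unused.
#' @return named numeric vector of predictions.
#' @export
predict.ffnn_model <- function(object, newdata, clip = NULL, ...) {
  if (is.null(object$scaler)) stop("model has no fitted scaler", call. = FALSE)
  do_clip <- if (is.null(clip)) object$clip else clip
  pred <- ffnn_forward(object$net, scale_apply(object$scaler, newdata))
  if (do_clip) pred <- pmin(1, pmax(0, pred))
  stats::setNames(pred, rownames(newdata))
}

#' Serialize a fitted model to JSON (topology, weights, scaler)
#'
#' @param model a `ffnn_model`.
#' @param path optional output path.
#' @return JSON string (invisibly when written).
#' @export
ffnn_model_json <- function(model, path = NULL) {
  obj <- list(p = model$net$p, k = model$net$k,
              w_in = as.vector(model$net$w_in),
              b_hidden = model$net$b_hidden, w_out = model$net$w_out,
              b_out = model$net$b_out,
              scaler = list(center = as.vector(model$scaler$center),
                            scale = as.vector(model$scaler$scale),
                            names = model$scaler$names),
              clip = model$clip)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
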