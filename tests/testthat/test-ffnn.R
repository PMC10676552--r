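test_that("forward pass matches closed forms", {
  # zero weights return the output bias for any input
  net <- init_network(3, 2, seed = 1)
  net$w_in[] <- 0; net$b_hidden[] <- 0; net$w_out[] <- 0; net$b_out <- 0.4
  x <- rand_matrix(6, 3)
  expect_equal(ffnn_forward(net, x), rep(0.4, 6))

  # p = 1, k = 1 closed form: 2 tanh(0.5)
  net1 <- init_network(1, 1, seed = 1)
  net1$w_in[] <- 1; net1$b_hidden <- 0; net1$w_out <- 2; net1$b_out <- 0
  expect_equal(ffnn_forward(net1, matrix(0.5)), 2 * tanh(0.5),
               tolerance = 1e-12)

  # batch predictions equal row-wise single calls
  net <- init_network(4, 3, seed = 2)
  xb <- rand_matrix(5, 4, seed = 5)
  batch <- ffnn_forward(net, xb)
  single <- vapply(seq_len(5), function(i) ffnn_forward(net, xb[i, ]),
                   numeric(1))
  expect_equal(batch, single, tolerance = 1e-15)

  expect_error(ffnn_forward(net, rand_matrix(5, 3)), "expects")
})

test_that("hidden activation equals the exponential-quotient form", {
  s <- seq(-10, 10, length.out = 1e4)
  net <- init_network(1, 1, seed = 1)
  net$w_in[] <- 1; net$b_hidden <- 0; net$w_out <- 1; net$b_out <- 0
  quotient <- (exp(s) - exp(-s)) / (exp(s) + exp(-s))
  expect_equal(ffnn_forward(net, matrix(s, ncol = 1)), quotient,
               tolerance = 1e-12)
})

test_that("initialization is seed-deterministic with fan-in scaling", {
  a <- init_network(55, 40, seed = 3)
  b <- init_network(55, 40, seed = 3)
  expect_identical(a, b)
  expect_equal(dim(a$w_in), c(40L, 55L))
  expect_length(a$b_hidden, 40L)
  expect_length(a$w_out, 40L)
  expect_length(a$b_out, 1L)
  expect_lte(max(abs(a$w_in)), 1 / sqrt(55))
  expect_error(init_network(5, 0), ">= 1")
})

test_that("residual Jacobian matches central finite differences", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- sample(2:5, 1); k <- sample(1:4, 1); n <- 7
    net <- init_network(p, k, seed = seed)
    x <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    theta <- ppbnet:::flatten_params(net)
    rj <- ppbnet:::ffnn_residual_jacobian(theta, x, y, p, k)
    h <- 1e-6
    J_fd <- vapply(seq_along(theta), function(j) {
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      (ffnn_forward(ppbnet:::unflatten_params(tp, p, k), x) -
         ffnn_forward(ppbnet:::unflatten_params(tm, p, k), x)) / (2 * h)
    }, numeric(n))
    expect_equal(rj$J, J_fd, tolerance = 1e-5)
  }
})

test_that("Levenberg-Marquardt recovers a realizable target", {
  set.seed(31)
  p <- 3; k <- 2; n <- 60
  truth <- init_network(p, k, seed = 8)
  truth$w_in <- truth$w_in * 2; truth$w_out <- truth$w_out * 3
  x <- matrix(rnorm(n * p), n, p)
  y <- ffnn_forward(truth, x)
  # init near the truth converges to machine-level training error
  near <- truth
  near$w_in <- near$w_in + rnorm(k * p, sd = 0.05)
  near$w_out <- near$w_out + rnorm(k, sd = 0.05)
  fit <- train_lm(near, x, y, max_iterations = 300)
  expect_lt(fit$mse, 1e-8)
  # accepted-step training MSE is monotone non-increasing
  expect_true(all(diff(fit$trace$mse) <= 0))
})

test_that("training a constant target converges to the constant", {
  x <- rand_matrix(20, 2, seed = 4)
  y <- rep(0.37, 20)
  fit <- train_lm(init_network(2, 2, seed = 1), x, y, max_iterations = 200)
  expect_lt(fit$mse, 1e-10)
  expect_equal(unname(ffnn_forward(fit$net, x)), y, tolerance = 1e-4)
})

test_that("validation early stopping returns the validation-best weights", {
  set.seed(17)
  p <- 5; n <- 40
  x <- matrix(rnorm(n * p), n, p)
  y <- drop(tanh(x %*% rnorm(p))) + rnorm(n, sd = 0.2)
  xv <- matrix(rnorm(30 * p), 30, p)
  yv <- drop(tanh(xv %*% rnorm(p))) + rnorm(30, sd = 0.2)
  fit <- train_lm(init_network(p, 10, seed = 2), x, y,
                  x_val = xv, y_val = yv, max_iterations = 200)
  returned_val <- mean((ffnn_forward(fit$net, xv) - yv)^2)
  expect_equal(returned_val, min(fit$trace$mse_val), tolerance = 1e-12)
})

test_that("growth search follows the schedule and its selection rule", {
  set.seed(5)
  p <- 4
  x <- matrix(rnorm(80 * p), 80, p)
  y <- drop(tanh(x %*% rnorm(p)) * 0.4 + 0.5) + rnorm(80, sd = 0.02)
  cfg <- pipeline_config(k_start = 5, k_step = 5, k_max = 5, seed = 3)
  g <- grow_hidden_layer(x[1:60, ], y[1:60], x[61:80, ], y[61:80], cfg)
  expect_equal(nrow(g$trace), 1L)
  expect_equal(g$selected_k, 5L)

  cfg2 <- pipeline_config(k_start = 2, k_step = 2, k_max = 8, seed = 3)
  g2 <- grow_hidden_layer(x[1:60, ], y[1:60], x[61:80, ], y[61:80], cfg2)
  expect_true(all(g2$trace$k %in% seq(2, 8, 2)))
  # selected k minimizes validation MSE over the recorded trace
  expect_equal(g2$trace$mse_validation[g2$trace$k == g2$selected_k],
               min(g2$trace$mse_validation))
  # determinism: identical config + seed gives an identical trace
  g3 <- grow_hidden_layer(x[1:60, ], y[1:60], x[61:80, ], y[61:80], cfg2)
  expect_identical(g2$trace, g3$trace)
  expect_identical(g2$net, g3$net)
})

test_that("growth search tracks the generating network's capacity", {
  selected <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    p <- 8; n <- 300; nv <- 80
    truth <- init_network(p, 20, seed = 5000 + s)
    truth$w_in <- truth$w_in * 4; truth$w_out <- truth$w_out * 3
    x <- matrix(rnorm((n + nv) * p), ncol = p)
    y <- ffnn_forward(truth, x) + rnorm(n + nv, sd = 0.05)
    cfg <- pipeline_config(seed = s)
    grow_hidden_layer(x[1:n, ], y[1:n],
                      x[(n + 1):(n + nv), ], y[(n + 1):(n + nv)],
                      cfg)$selected_k
  }, integer(1))
  expect_gte(sum(selected >= 15 & selected <= 30), 8L)
})

test_that("scaler round-trips and model prediction composes scale+forward", {
  x <- rand_matrix(30, 6, seed = 10)
  sc <- fit_scaler(x)
  expect_equal(scale_invert(sc, scale_apply(sc, x)), x, tolerance = 1e-12)
  net <- init_network(6, 3, seed = 2)
  model <- ffnn_model(net, sc, clip = TRUE)
  raw <- ffnn_forward(net, scale_apply(sc, x))
  expect_equal(unname(predict(model, x, clip = FALSE)), raw)
  expect_equal(unname(predict(model, x)), pmin(1, pmax(0, raw)))
  # serialized model re-evaluates identically
  js <- jsonlite::fromJSON(ffnn_model_json(model))
  net2 <- ppbnet:::unflatten_params(
    c(js$w_in, js$b_hidden, js$w_out, js$b_out), js$p, js$k)
  expect_equal(ffnn_forward(net2, scale_apply(sc, x)), raw, tolerance = 1e-12)
})
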