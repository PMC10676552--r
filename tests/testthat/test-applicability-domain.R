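unit_square <- function() {
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  dimnames(x) <- list(sprintf("t%d", 1:4), c("d1", "d2"))
  x
}

qmat <- function(...) {
  q <- rbind(...)
  dimnames(q) <- list(sprintf("q%d", seq_len(nrow(q))), c("d1", "d2"))
  q
}

test_that("PCA bounding box contains the training cloud and rejects far points", {
  tr <- unit_square()
  res <- pca_bounding_box(tr, qmat(c(0.5, 0.5), c(2, 0.5), c(0, 0)),
                          n_components = 2)
  expect_equal(unname(res$inside), c(TRUE, FALSE, TRUE))
  expect_equal(res$n_inside, 2L)
  expect_error(pca_bounding_box(tr, tr, n_components = 3), "rank")
  # default keeps the components explaining 95% of variance
  set.seed(2)
  wide <- cbind(rnorm(50, sd = 5), matrix(rnorm(50 * 3, sd = 0.1), 50))
  colnames(wide) <- paste0("d", 1:4); rownames(wide) <- sprintf("t%02d", 1:50)
  auto <- pca_bounding_box(wide, wide[1:5, , drop = FALSE])
  expect_lt(auto$details$n_components, 4)
  expect_true(all(auto$inside))
})

test_that("centroid-distance threshold is the stated training percentile", {
  set.seed(4)
  tr <- matrix(rnorm(100 * 3), 100, 3,
               dimnames = list(sprintf("t%03d", 1:100), paste0("d", 1:3)))
  res <- centroid_distance_ad(tr, tr, percentile = 95)
  # ~5 of 100 training rows lie outside their own 95th percentile
  d <- sqrt(rowSums(sweep(tr, 2, colMeans(tr))^2))
  expect_equal(res$n_outside, sum(d > quantile(d, 0.95, type = 7)))
  expect_lte(res$n_outside, 5L)
  # centroid itself is inside; a gross extrapolation is not
  ctr <- matrix(colMeans(tr), 1, dimnames = list("q1", paste0("d", 1:3)))
  expect_true(all(centroid_distance_ad(tr, ctr)$inside))
  far <- ctr + 100
  expect_false(any(centroid_distance_ad(tr, far)$inside))
})

test_that("centroid-distance verdicts are radially monotone", {
  set.seed(5)
  tr <- matrix(rnorm(60 * 2), 60, 2,
               dimnames = list(sprintf("t%02d", 1:60), c("d1", "d2")))
  dir <- c(1, 1) / sqrt(2)
  radii <- seq(0, 8, length.out = 30)
  q <- t(vapply(radii, function(r) colMeans(tr) + r * dir, numeric(2)))
  dimnames(q) <- list(sprintf("q%02d", 1:30), c("d1", "d2"))
  verdicts <- centroid_distance_ad(tr, q)$inside
  expect_true(all(diff(as.integer(verdicts)) <= 0))  # inside never re-entered
})

test_that("kNN scores and calibration match hand enumeration", {
  tr <- matrix(0:4, 5, 1, dimnames = list(sprintf("t%d", 1:5), "d1"))
  q <- matrix(c(2, 10), 2, 1, dimnames = list(c("q1", "q2"), "d1"))
  res <- knn_ad(tr, q, k = 2, percentile = 95)
  # query 2.0: nearest training distances {0, 1} -> mean 0.5
  expect_equal(unname(res$score), c(0.5, mean(c(6, 7))))
  # leave-self-out calibration: {1.5, 1, 1, 1, 1.5}; 95th percentile 1.5
  expect_equal(res$threshold, 1.5)
  expect_equal(unname(res$inside), c(TRUE, FALSE))
  expect_error(knn_ad(tr, q, k = 5), "below the number")
  # duplicate of a training row is inside
  dup <- matrix(3, 1, 1, dimnames = list("q1", "d1"))
  expect_true(all(knn_ad(tr, dup, k = 1)$inside))
})

test_that("leverage diagnostic satisfies the hat-matrix identities", {
  set.seed(6)
  tr <- matrix(rnorm(40 * 4), 40, 4,
               dimnames = list(sprintf("t%02d", 1:40), paste0("d", 1:4)))
  ctr <- matrix(colMeans(tr), 1, dimnames = list("q1", paste0("d", 1:4)))
  out <- leverage_diagnostic(tr, ctr)
  expect_equal(out$query$leverage, 1 / 40, tolerance = 1e-12)
  expect_equal(sum(out$train_leverage), 4 + 1, tolerance = 1e-10)
  expect_equal(out$h_star, 3 * 5 / 40)

  # far query with a tiny residual is a good leverage point
  far <- matrix(colMeans(tr) + 10, 1, dimnames = list("q1", paste0("d", 1:4)))
  lev <- leverage_diagnostic(tr, far, y_obs_query = 0.5,
                             y_pred_query = 0.501, residual_scale = 0.05)
  expect_equal(lev$query$category, "good_leverage")
  # near query with a huge residual is an outlier
  near <- ctr
  lev2 <- leverage_diagnostic(tr, near, y_obs_query = 0.9,
                              y_pred_query = 0.1, residual_scale = 0.05)
  expect_equal(lev2$query$category, "outlier")
  # rank deficiency is refused with advice
  trdef <- cbind(tr, d5 = tr[, 1] + tr[, 2])
  expect_error(leverage_diagnostic(trdef, cbind(ctr, d5 = 0)), "rank deficient")
})

test_that("the four-method suite is calibrated and self-consistent", {
  set.seed(8)
  p <- 6
  tr <- matrix(rnorm(200 * p), 200, p,
               dimnames = list(sprintf("t%03d", 1:200), paste0("d", 1:p)))
  qu <- matrix(rnorm(100 * p), 100, p,
               dimnames = list(sprintf("q%03d", 1:100), paste0("d", 1:p)))
  cfg <- pipeline_config(percentile = 95)
  suite <- run_ad_suite(tr, qu, cfg)
  expect_equal(suite$summary$method,
               c("pca_bounding_box", "centroid_distance", "knn_k5", "knn_k25"))
  expect_true(all(suite$summary$inside + suite$summary$outside == 100))
  expect_true(all(suite$summary$inside >= 90))
  # gross extrapolation: every query 10 training SD away is outside
  shifted <- qu + 10
  suite_far <- run_ad_suite(tr, shifted, cfg)
  expect_true(all(suite_far$summary$outside == 100))
  # percentile 100 self-application keeps every training row inside
  suite_self <- run_ad_suite(tr, tr, pipeline_config(percentile = 100))
  expect_true(all(suite_self$summary$inside == 200))
})
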