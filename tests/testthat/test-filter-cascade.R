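make_mat <- function(...) {
  cols <- list(...)
  x <- do.call(cbind, cols)
  rownames(x) <- sprintf("c%02d", seq_len(nrow(x)))
  x
}

test_that("constant and quasi-constant screens use exact rules", {
  x <- make_mat(a = rep(7.3, 10), b = c(1, 1, 2, rep(1, 7)),
                c = c(rep(0, 9), 5), d = 1:10)
  s1 <- remove_constant(x)
  expect_equal(s1$record$removed, "a")
  expect_equal(unname(s1$record$diagnostics), 7.3)
  s2 <- remove_quasi_constant(s1$x)
  # {0 x9, 5}: both quartiles 0 (linear-interpolation quantiles)
  # {1,1,2,1...}: 25th and 75th percentile both 1
  expect_setequal(s2$record$removed, c("b", "c"))
  expect_equal(colnames(s2$x), "d")
  expect_equal(s2$record$n_before, 3L)
  expect_equal(s2$record$n_after, 1L)
})

test_that("relative standard deviation screen matches hand arithmetic", {
  x <- make_mat(lowdisp = c(100, 101, 100, 99), spread = c(1, 2, 3, 4),
                zeromean = c(-1, 1, -1, 1))
  out <- remove_low_rsd(x, rsd_min = 0.05)
  # sd({100,101,100,99}) = sqrt(2/3), mean 100 -> RSD 0.0081650 < 0.05
  expect_equal(out$record$removed, "lowdisp")
  expect_equal(unname(out$record$diagnostics), sqrt(2 / 3) / 100,
               tolerance = 1e-12)
  # sd({1,2,3,4})/2.5 = 0.5163978 retained; zero-mean column retained
  expect_setequal(colnames(out$x), c("spread", "zeromean"))
})

test_that("pairwise correlation screen drops the more redundant member", {
  set.seed(42)
  base <- rnorm(30)
  x <- make_mat(u = base, dup = base, anti = -base + rnorm(30, sd = 1e-8),
                w = rnorm(30))
  out <- remove_correlated(x, r_max = 0.75)
  # u, dup, anti are one perfect cluster: exactly two removals, one survivor
  surv <- intersect(colnames(out$x), c("u", "dup", "anti"))
  expect_length(surv, 1L)
  expect_true("w" %in% colnames(out$x))
  expect_equal(length(out$record$removed), 2L)
  expect_true(all(out$record$diagnostics > 0.75))
  # every removal cites its partner
  expect_length(out$record$partners, 2L)
  # survivors truly decorrelated
  expect_lt(max(abs(cor(out$x))[upper.tri(diag(ncol(out$x)))]), 0.75)
})

test_that("VIF matches the per-column least-squares oracle", {
  x <- rand_matrix(25, 6, seed = 9)
  expect_equal(unname(compute_vif(x)), oracle_vif(x), tolerance = 1e-8)
  # mutually uncorrelated centered columns -> VIF 1
  q <- prcomp(rand_matrix(12, 6, seed = 2))$x[, 1:4]
  colnames(q) <- paste0("q", 1:4); rownames(q) <- sprintf("c%02d", 1:12)
  expect_equal(unname(compute_vif(q)), rep(1, 4), tolerance = 1e-8)
  # perfect collinearity -> Inf, not an error
  xx <- cbind(x, lin = x[, 1] + x[, 2])
  v <- compute_vif(xx)
  expect_true(is.infinite(v["lin"]))
  # identifiability precondition
  expect_error(compute_vif(rand_matrix(6, 6)), "more compounds")
})

test_that("iterative VIF removal drops one column from a noisy sum", {
  set.seed(11)
  x1 <- rnorm(40); x2 <- rnorm(40)
  x <- make_mat(x1 = x1, x2 = x2, x3 = x1 + x2 + rnorm(40, sd = 1e-4),
                x4 = rnorm(40))
  out <- remove_high_vif(x, vif_max = 5)
  expect_length(out$record$removed, 1L)
  expect_true(out$record$removed %in% c("x1", "x2", "x3"))
  expect_lt(max(out$record$final_vif), 5)
  # fixed point: a clean matrix is untouched
  clean <- rand_matrix(30, 5, seed = 13)
  expect_identical(remove_high_vif(clean, 5)$x, clean)
})

test_that("cascade is idempotent and row-permutation invariant", {
  d <- generate_dataset(small_spec(seed = 21))
  cfg <- pipeline_config()
  once <- run_filter_cascade(d$x, cfg)
  twice <- run_filter_cascade(once$x, cfg)
  expect_identical(colnames(twice$x), colnames(once$x))
  expect_true(all(vapply(twice$report$stages,
                         function(s) length(s$removed) == 0L, logical(1))))
  set.seed(99)
  shuffled <- run_filter_cascade(d$x[sample(nrow(d$x)), ], cfg)
  expect_setequal(shuffled$report$retained, once$report$retained)
})

test_that("filter report is a consistent ledger of the reduction", {
  d <- generate_dataset(small_spec(seed = 22))
  out <- run_filter_cascade(d$x, pipeline_config())
  rep <- out$report
  stages <- rep$stages
  for (i in seq_len(length(stages) - 1))
    expect_equal(stages[[i]]$n_after, stages[[i + 1]]$n_before)
  removed <- unlist(lapply(stages, `[[`, "removed"))
  expect_equal(anyDuplicated(removed), 0L)
  expect_setequal(c(removed, rep$retained), colnames(d$x))
  # every removal cites a diagnostic violating its stage threshold
  expect_true(all(stages[[3]]$diagnostics < stages[[3]]$threshold))
  expect_true(all(stages[[4]]$diagnostics > stages[[4]]$threshold))
  expect_true(all(stages[[5]]$diagnostics > stages[[5]]$threshold))
  # JSON serialization round-trips the counts
  js <- jsonlite::fromJSON(filter_report_json(rep))
  expect_equal(js$n_initial, ncol(d$x))
  expect_equal(js$n_retained, length(rep$retained))
})

test_that("filter statistics can be restricted to modeling rows", {
  d <- generate_dataset(small_spec(seed = 23))
  rows <- rownames(d$x)[1:80]
  out <- run_filter_cascade(d$x, pipeline_config(), rows = rows)
  expect_equal(nrow(out$x), nrow(d$x))       # selection applied to all rows
  expect_identical(out$report$stat_rows, rows)
  # perturbing held-out rows does not change the retained set
  x2 <- d$x
  x2[81:120, ] <- x2[81:120, ] + 100
  out2 <- run_filter_cascade(x2, pipeline_config(), rows = rows)
  expect_identical(out2$report$retained, out$report$retained)
})
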