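#' Synthetic descriptor-matrix specification
#'
#' Describes a seeded synthetic dataset with the statistical structure of a
#' large computed-descriptor table: a few informative columns driving a
#' bounded nonlinear response, plus the pathologies the filter cascade
#' exists to remove — constant columns, quasi-constant columns (two-point
#' 95%/5% distributions), low-relative-dispersion columns (large mean, tiny
#' spread), blocks of pairwise-correlated columns built from a shared latent
#' factor, multicollinear groups (noisy sums of named parent columns),
#' large redundant families (the latent-factor construction at family size,
#' emulating the block redundancy of real descriptor software where whole
#' categories measure the same underlying property), and independent noise
#' columns.
#'
#' The defaults emulate a 277-compound, 1666-descriptor table that the
#' cascade reduces to roughly 55 columns (the dimensionality collapse typical
#' of computed descriptor tables): 15 informative + 50 constant + 50
#' quasi-constant + 100 low-RSD + 10 correlated blocks of 5 (rho 0.9) +
#' 5 multicollinear groups (3 parents + 1 dependent) + 8 redundant
#' families of 172 (rho 0.85) + 5 independent noise columns.
#'
#' @param n_compounds number of compounds (rows).
#' @param n_informative columns feeding the true response network.
#' @param n_constant exactly constant columns.
#' @param n_quasi_constant two-point 95%/5% columns.
#' @param n_low_rsd large-mean, tiny-spread columns (RSD well below 0.05).
#' @param n_corr_blocks,corr_block_size,corr_rho correlated-block plan.
#' @param n_mc_groups,mc_parents,mc_noise_sd multicollinear-group plan: each
#'   group has `mc_parents` parent columns and one dependent column equal to
#'   their sum plus Gaussian noise of sd `mc_noise_sd`.
#' @param n_families,family_size,family_rho redundant-family plan.
#' @param n_noise independent irrelevant columns.
#' @param p_true,k_true topology of the true response network (`p_true`
#'   must equal `n_informative`).
#' @param w_scale multiplier on the true network's fan-in-scaled weights;
#'   controls how far the hidden units saturate and hence how nonlinear the
#'   latent signal is (1 is close to a single linear index through the
#'   squash, 3 is strongly nonlinear).
#' @param g_sd spread of the standardized latent signal before the logistic
#'   squash; 2 gives bound fractions spanning most of (0, 1).
#' @param response_noise_sd additive Gaussian noise on the bound fraction.
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 277L, n_informative = 15L,
                           n_constant = 50L, n_quasi_constant = 50L,
                           n_low_rsd = 100L,
                           n_corr_blocks = 10L, corr_block_size = 5L,
                           corr_rho = 0.9,
                           n_mc_groups = 5L, mc_parents = 3L,
                           mc_noise_sd = 0.05,
                           n_families = 8L, family_size = 172L,
                           family_rho = 0.85,
                           n_noise = 5L,
                           p_true = n_informative, k_true = 10L, w_scale = 1,
                           g_sd = 2,
                           response_noise_sd = 0.02, seed = 1L) {
  stopifnot(n_compounds >= 8, n_informative >= 1,
            corr_rho > -1, corr_rho < 1, family_rho > -1, family_rho < 1,
            response_noise_sd >= 0, mc_noise_sd > 0, w_scale > 0,
            p_true == n_informative, k_true >= 1)
  out <- list(n_compounds = as.integer(n_compounds),
              n_informative = as.integer(n_informative),
              n_constant = as.integer(n_constant),
              n_quasi_constant = as.integer(n_quasi_constant),
              n_low_rsd = as.integer(n_low_rsd),
              n_corr_blocks = as.integer(n_corr_blocks),
              corr_block_size = as.integer(corr_block_size),
              corr_rho = corr_rho,
              n_mc_groups = as.integer(n_mc_groups),
              mc_parents = as.integer(mc_parents),
              mc_noise_sd = mc_noise_sd,
              n_families = as.integer(n_families),
              family_size = as.integer(family_size),
              family_rho = family_rho,
              n_noise = as.integer(n_noise),
              p_true = as.integer(p_true), k_true = as.integer(k_true),
              w_scale = w_scale, g_sd = g_sd,
              response_noise_sd = response_noise_sd,
              seed = as.integer(seed))
  out$n_descriptors <- with(out, n_informative + n_constant +
    n_quasi_constant + n_low_rsd + n_corr_blocks * corr_block_size +
    n_mc_groups * (mc_parents + 1L) + n_families * family_size + n_noise)
  class(out) <- "synthetic_spec"
  out
}

# Columns sharing a latent factor f: x_j = sqrt(rho) f + sqrt(1 - rho) e_j,
# giving pairwise population correlation rho at O(n * d) cost.
latent_block <- function(n, size, rho) {
  f <- stats::rnorm(n)
  sqrt(rho) * matrix(f, n, size) +
    sqrt(1 - rho) * matrix(stats::rnorm(n * size), n, size)
}

#' Generate a synthetic descriptor matrix with a ground-truth ledger
#'
#' Builds the matrix a column role at a time under the spec's seed and
#' records every column's role (and its block/group/family membership) in a
#' ledger so tests can assert exactly which columns each filter stage must
#' remove.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `x` (descriptor matrix) and `ledger` (data.frame with
#'   columns `name`, `role`, `group`).
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_compounds
  with_seed(derive_seed(spec$seed, "matrix"), {
    cols <- list(); roles <- list()
    add <- function(values, names, role, group = NA_character_) {
      colnames(values) <- names
      cols[[length(cols) + 1L]] <<- values
      roles[[length(roles) + 1L]] <<-
        data.frame(name = names, role = role, group = group,
                   stringsAsFactors = FALSE)
    }
    if (spec$n_informative > 0)
      add(matrix(stats::rnorm(n * spec$n_informative), n),
          sprintf("inf_%03d", seq_len(spec$n_informative)), "informative")
    if (spec$n_constant > 0) {
      vals <- stats::rnorm(spec$n_constant)
      add(matrix(rep(vals, each = n), n),
          sprintf("const_%03d", seq_len(spec$n_constant)), "constant")
    }
    if (spec$n_quasi_constant > 0) {
      n_shift <- max(1L, ceiling(0.05 * n))
      m <- vapply(seq_len(spec$n_quasi_constant), function(j) {
        base <- stats::rnorm(1)
        v <- rep(base, n)
        v[sample.int(n, n_shift)] <- base + stats::runif(1, 0.5, 2)
        v
      }, numeric(n))
      add(m, sprintf("quasi_%03d", seq_len(spec$n_quasi_constant)),
          "quasi_constant")
    }
    if (spec$n_low_rsd > 0) {
      m <- vapply(seq_len(spec$n_low_rsd), function(j) {
        mu <- stats::runif(1, 50, 200)
        mu + stats::rnorm(n, sd = mu * stats::runif(1, 0.001, 0.02))
      }, numeric(n))
      add(m, sprintf("lowrsd_%03d", seq_len(spec$n_low_rsd)), "low_rsd")
    }
    if (spec$n_corr_blocks > 0)
      for (b in seq_len(spec$n_corr_blocks))
        add(latent_block(n, spec$corr_block_size, spec$corr_rho),
            sprintf("corr_b%02d_%02d", b, seq_len(spec$corr_block_size)),
            "corr_block", sprintf("block_%02d", b))
    if (spec$n_mc_groups > 0)
      for (g in seq_len(spec$n_mc_groups)) {
        parents <- matrix(stats::rnorm(n * spec$mc_parents), n)
        child <- rowSums(parents) + stats::rnorm(n, sd = spec$mc_noise_sd)
        add(parents, sprintf("mcg_%02d_parent_%d", g, seq_len(spec$mc_parents)),
            "mc_parent", sprintf("mc_%02d", g))
        add(matrix(child, n), sprintf("mcg_%02d_child", g),
            "mc_child", sprintf("mc_%02d", g))
      }
    if (spec$n_families > 0)
      for (f in seq_len(spec$n_families))
        add(latent_block(n, spec$family_size, spec$family_rho),
            sprintf("fam_%02d_%03d", f, seq_len(spec$family_size)),
            "family", sprintf("family_%02d", f))
    if (spec$n_noise > 0)
      add(matrix(stats::rnorm(n * spec$n_noise), n),
          sprintf("noise_%03d", seq_len(spec$n_noise)), "noise")
    x <- do.call(cbind, cols)
    rownames(x) <- sprintf("cmp_%03d", seq_len(n))
    ledger <- do.call(rbind, roles)
    stopifnot(ncol(x) == spec$n_descriptors)
    validate_descriptor_matrix(x)
    list(x = x, ledger = ledger)
  })
}

#' Generate a bounded response from the informative columns
#'
#' The bound fraction is
#' `fb = clip01( logistic(g_std(informative columns)) + noise )` where `g`
#' is a randomly seeded single-hidden-layer tanh network of topology
#' (`p_true`, `k_true`) — the same functional family the pipeline fits —
#' affinely standardized to mean 0 and sd `g_sd` so the logistic squash
#' spreads the response over (0, 1). The true network and the affine
#' constants are returned so recovery tests can reconstruct the noiseless
#' signal.
#'
#' @param x descriptor matrix from [generate_matrix()] (must contain the
#'   informative columns).
#' @param spec the [synthetic_spec()] used to generate `x`.
#' @return list with `fb` (named response vector), `truth` (list: `net`,
#'   `shift`, `scale`, `informative`, `fb_clean`).
#' @export
generate_response <- function(x, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  informative <- grep("^inf_", colnames(x), value = TRUE)
  if (length(informative) != spec$p_true)
    stop("matrix does not carry the spec's informative columns", call. = FALSE)
  xi <- x[, informative, drop = FALSE]
  with_seed(derive_seed(spec$seed, "response"), {
    net <- init_network(spec$p_true, spec$k_true,
                        derive_seed(spec$seed, "truth_net"))
    net$w_in <- net$w_in * spec$w_scale
    net$w_out <- net$w_out * spec$w_scale
    g <- ffnn_forward(net, xi)
    shift <- mean(g); sc <- stats::sd(g)
    if (sc == 0) sc <- 1
    g_std <- (g - shift) / sc * spec$g_sd
    fb_clean <- stats::plogis(g_std)
    fb <- fb_clean + stats::rnorm(nrow(xi), sd = spec$response_noise_sd)
    fb <- pmin(1, pmax(0, fb))
    names(fb) <- rownames(x)
    list(fb = fb,
         truth = list(net = net, shift = shift, scale = sc, g_sd = spec$g_sd,
                      informative = informative,
                      fb_clean = stats::setNames(fb_clean, rownames(x))))
  })
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper: matrix, ledger and response in one call.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `x`, `fb`, `ledger`, `truth`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  gm <- generate_matrix(spec)
  gr <- generate_response(gm$x, spec)
  list(x = gm$x, fb = gr$fb, ledger = gm$ledger, truth = gr$truth)
}
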