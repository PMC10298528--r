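test_that("climate PCA standardizes, orders components, and fixes signs", {
  clim <- tibble::tibble(site = sprintf("s%d", 1:6),
                         a = c(1, 2, 3, 4, 5, 6),
                         b = c(2, 4, 6, 8, 10, 12),   # perfectly correlated
                         flat = 1)
  expect_warning(p <- env_pca(clim, n_components = 2), "constant")
  expect_equal(p$explained_variance[1], 1)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # sign convention: the largest-magnitude loading is positive
  expect_gt(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)

  # 4 sites x 3 variables against a direct eigendecomposition
  set.seed(1)
  clim2 <- tibble::tibble(site = sprintf("s%d", 1:4),
                          x = rnorm(4), y = rnorm(4), z = rnorm(4))
  p2 <- env_pca(clim2, n_components = 3)
  Xs <- scale(as.matrix(clim2[, c("x", "y", "z")]))
  eg <- eigen(cov(Xs))
  expect_equal(p2$explained_variance, eg$values / sum(eg$values),
               tolerance = 1e-10)
  scores_oracle <- Xs %*% eg$vectors
  for (k in 1:2) {
    expect_equal(abs(p2$scores[[k + 1]]), abs(scores_oracle[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("logistic Wald test handles null, separated, and regular cases", {
  null_fit <- logistic_wald(c(0, 1, 0, 1), c(1, 1, 2, 2))
  expect_equal(null_fit$beta, 0, tolerance = 1e-8)
  expect_equal(null_fit$p_raw, 1, tolerance = 1e-6)

  sep <- logistic_wald(c(0, 0, 0, 1, 1, 1), 1:6)
  expect_true(sep$flagged)
  expect_true(is.na(sep$p_raw))

  expect_error(logistic_wald(rep(1, 5), rnorm(5)), "degenerate response")
})

test_that("logistic Wald estimates match a Newton-Raphson oracle", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.3 * x))
    if (length(unique(y)) < 2) next
    got <- logistic_wald(y, x)
    if (got$flagged) next
    want <- nr_logistic(y, cbind(1, x))
    expect_equal(got$beta, unname(want$beta[2]), tolerance = 1e-6)
    expect_equal(got$se, unname(want$se[2]), tolerance = 1e-5)
  }
})

test_that("the univariate scan enumerates the full model grid with Bonferroni control", {
  w <- generate_world(world_config(n_sites = 10, samples_per_site = 10,
                                   n_cnv_loci = 40, n_planted = 0,
                                   effect_size = 0, cluster_sd = 0, seed = 31))
  G <- build_genotype_matrix(w$calls, samples = w$samples$sample)
  env <- sample_climate(w$samples, w$climate, c("SUN_yr", "TMP_yr", "PR_yr"))
  res <- sambada_scan(G, env)
  expect_equal(nrow(res), ncol(G) * 3)
  expect_equal(attr(res, "n_models"), scan_grid_size(ncol(G), 3))
  # Bonferroni: p_adj = min(1, m * p_raw), monotone in p_raw
  ok <- !is.na(res$p_raw)
  expect_equal(res$p_adj[ok], pmin(1, res$p_raw[ok] * nrow(res)))
  # null world: (almost) nothing selected at adjusted 0.01
  expect_lte(sum(res$selected, na.rm = TRUE), 1)
  expect_error(sample_climate(dplyr::mutate(w$samples, site = "nope"),
                              w$climate, "SUN_yr"), "without site climate")
})

test_that("scan p-values are uniform under permuted environment labels", {
  w <- generate_world(world_config(n_sites = 12, samples_per_site = 10,
                                   n_cnv_loci = 120, n_planted = 0,
                                   effect_size = 0, seed = 17))
  G <- build_genotype_matrix(w$calls, samples = w$samples$sample)
  env <- sample_climate(w$samples, w$climate,
                        c("SUN_yr", "TMP_yr", "PR_yr", "REH_yr", "DTR_yr"))
  set.seed(99)
  env_perm <- env[sample(nrow(env)), , drop = FALSE]
  res <- sambada_scan(G, env_perm)
  p <- res$p_raw[!is.na(res$p_raw)]
  expect_gt(length(p), 400)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("LFMM with K = 0 reduces exactly to per-locus ordinary regression", {
  w <- small_world(seed = 8)
  G <- build_genotype_matrix(w$calls, samples = w$samples$sample)
  X <- sample_climate(w$samples, w$climate, "SUN_yr")
  fit <- lfmm_scan(G, X, K = 0)
  Xs <- scale(X)
  for (j in sample(ncol(G), 5)) {
    lmfit <- summary(lm(G[, j] ~ Xs))
    expect_equal(fit$results$z[j], lmfit$coefficients[2, "t value"],
                 tolerance = 1e-10)
  }
})

test_that("LFMM latent factors absorb confounding population structure", {
  w <- generate_world(world_config(n_sites = 20, samples_per_site = 10,
                                   n_cnv_loci = 150, n_planted = 0,
                                   effect_size = 0, cluster_sd = 1.5,
                                   seed = 4))
  G <- build_genotype_matrix(w$calls, samples = w$samples$sample)
  X <- sample_climate(w$samples, w$climate, "SUN_yr")
  corrected <- lfmm_scan(G, X, K = 4)
  uncorrected <- lfmm_scan(G, X, K = 0)
  # the uncalibrated scan is strongly inflated by the confounding
  expect_gt(uncorrected$lambda[["SUN_yr"]], 1.2)
  # after GIF calibration the z-scores are on the null scale: no locus in a
  # null world reaches the selection thresholds
  expect_equal(sum(corrected$results$selected, na.rm = TRUE), 0)
  expect_equal(stats::median(corrected$results$z_calibrated^2, na.rm = TRUE),
               stats::qchisq(0.5, 1), tolerance = 1e-8)
  # factors are orthonormal by construction (SVD)
  expect_equal(crossprod(corrected$factors), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  # BH adjustment never decreases a p-value
  ok <- !is.na(corrected$results$p_raw)
  expect_true(all(corrected$results$p_adj[ok] >= corrected$results$p_raw[ok]))
  expect_error(lfmm_scan(G[, 1:3], X, K = 3), "smaller")
})

test_that("tidiers summarise fitted scans", {
  w <- small_world(seed = 12)
  G <- build_genotype_matrix(w$calls, samples = w$samples$sample)
  X <- sample_climate(w$samples, w$climate, "SUN_yr")
  fit <- lfmm_scan(G, X, K = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), ncol(G))
  gl <- glance(fit)
  expect_equal(gl$K, 2)
  expect_equal(gl$m, ncol(G))
})
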