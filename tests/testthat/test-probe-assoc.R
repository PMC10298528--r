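probe_map <- function(n, chrom = "chr1", spacing = 100) {
  tibble::tibble(probe = sprintf("%s_p%03d", chrom, seq_len(n)),
                 chrom = chrom, position = seq_len(n) * spacing)
}

test_that("probe matrices mark spanned probes per polarity, boundaries inclusive", {
  probes <- probe_map(6)
  calls <- tibble::tibble(sample = "s1", chrom = "chr1",
                          start = 200, end = 400, cn = "CN1", num_snps = 3)
  Mdel <- build_probe_matrix(calls, probes, "del", samples = c("s1", "s2"))
  expect_equal(unname(Mdel["s1", ]), c(0, 1, 1, 1, 0, 0))
  expect_equal(unname(Mdel["s2", ]), rep(0, 6))
  Mdup <- build_probe_matrix(calls, probes, "dup", samples = c("s1", "s2"))
  expect_true(all(Mdup == 0))
  expect_error(build_probe_matrix(calls, probes[0, ], "del"), "empty")
})

test_that("probe matrix construction equals the triple-loop oracle", {
  set.seed(5)
  probes <- dplyr::bind_rows(probe_map(25, "chr1"), probe_map(25, "chr2"))
  for (i in 1:50) {
    calls <- random_calls(sample(1:30, 1), n_samples = 8, max_pos = 2500,
                          max_len = 600)
    samples <- sprintf("s%d", 1:8)
    for (pol in c("del", "dup")) {
      got <- build_probe_matrix(calls, probes, pol, samples = samples)
      want <- naive_probe_matrix(calls, probes, pol, samples)
      expect_equal(unclass(got)[, ], want)
    }
  }
})

test_that("Balding-Nichols kinship matches hand arithmetic and is well behaved", {
  M <- matrix(c(0, 1), 2, 1, dimnames = list(c("a", "b"), "p1"))
  K <- bn_kinship(M)
  expect_equal(unname(K), matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12)

  # duplicated sample rows give identical kinship rows/columns
  M2 <- matrix(rbinom(40, 1, 0.4), 4, 10)
  M2[2, ] <- M2[1, ]
  rownames(M2) <- letters[1:4]
  K2 <- bn_kinship(M2)
  expect_equal(K2[1, ], K2[2, ], ignore_attr = TRUE)

  # probe-order invariance and monomorphic exclusion
  set.seed(8)
  M3 <- cbind(matrix(rbinom(60, 1, 0.5), 6), 0, 1)
  K3a <- bn_kinship(M3)
  K3b <- bn_kinship(M3[, sample(ncol(M3))])
  expect_equal(K3a, K3b)
  expect_error(bn_kinship(matrix(1, 3, 2)), "polymorphic")

  # E[diag] = 1 under independent binomial sampling
  set.seed(9)
  p <- runif(600, 0.1, 0.9)
  M4 <- sapply(p, function(pp) rbinom(40, 1, pp))
  expect_equal(mean(diag(bn_kinship(M4))), 1, tolerance = 0.1)
})

test_that("REML variance ratio matches a dense grid-search oracle", {
  set.seed(14)
  n <- 40
  Z <- matrix(rnorm(n * 8), n)
  K <- tcrossprod(Z) / 8
  cl <- rep(1:4, each = 10)
  y <- rnorm(4)[cl] + rnorm(n) + 0.5 * Z[, 1]
  fit <- emma_reml_fit(y, K)
  oracle <- reml_grid_delta(y, K)
  expect_equal(log(fit$delta), oracle$log_delta, tolerance = 0.03)
  expect_equal(as.numeric(fit$reml_loglik), as.numeric(oracle$loglik),
               tolerance = 1e-3)
})

test_that("cluster-structured phenotype aligned with kinship gives small delta", {
  set.seed(15)
  cl <- rep(1:4, each = 12)
  M <- do.call(rbind, lapply(cl, function(c) {
    rbinom(80, 1, plogis(qlogis(0.3) + c(-2, -0.7, 0.7, 2)[c]))
  }))
  rownames(M) <- sprintf("s%02d", seq_along(cl))
  K <- bn_kinship(M)
  y_struct <- c(-3, -1, 1, 3)[cl] + rnorm(length(cl), 0, 0.3)
  y_noise <- rnorm(length(cl))
  fit_struct <- emma_reml_fit(y_struct, K)
  fit_noise <- emma_reml_fit(y_noise, K)
  expect_lt(fit_struct$delta, fit_noise$delta)
})

test_that("mixed-model scan with identity kinship equals OLS to 1e-8", {
  set.seed(16)
  n <- 50
  M <- matrix(rbinom(n * 20, 1, 0.3), n,
              dimnames = list(sprintf("s%d", 1:n), sprintf("p%02d", 1:20)))
  y <- rnorm(n) + 0.8 * M[, 3]
  res <- mlm_scan(y, M, K = diag(n))
  for (j in which(!is.na(res$p_raw))) {
    ols <- summary(lm(y ~ M[, j]))$coefficients
    expect_equal(res$p_raw[j], ols[2, 4], tolerance = 1e-8)
    expect_equal(res$beta[j], ols[2, 1], tolerance = 1e-8)
  }
  # constant probes are skipped with NA
  M2 <- cbind(M, const = 1L)
  expect_message(res2 <- mlm_scan(y, M2, K = diag(n)), "constant probe")
  expect_true(is.na(res2$p_raw[res2$probe == "const"]))
})

test_that("logistic probe scan composes per-probe Wald fits", {
  set.seed(18)
  n <- 60
  M <- matrix(rbinom(n * 8, 1, 0.4), n,
              dimnames = list(NULL, sprintf("p%d", 1:8)))
  rad <- rnorm(n)
  res <- logistic_scan(M, rad)
  for (j in 1:8) {
    expect_equal(res$p_raw[j], logistic_wald(M[, j], rad)$p_raw,
                 tolerance = 1e-12)
  }
  Mc <- cbind(M, allzero = 0L)
  res2 <- logistic_scan(Mc, rad)
  expect_true(is.na(res2$p_raw[res2$probe == "allzero"]))
})

test_that("consensus probes intersect the two scans' significant sets", {
  ra <- tibble::tibble(probe = c("p1", "p2", "p3"), p_raw = c(1e-5, 0.2, 1e-6))
  rb <- tibble::tibble(probe = c("p1", "p2", "p3"), p_raw = c(1e-7, 1e-9, 0.5))
  expect_equal(consensus_probes(ra, rb, 1e-4, 1e-6), "p1")
  expect_equal(consensus_probes(ra, ra, 1e-4, 1e-4), c("p1", "p3"))
  expect_length(consensus_probes(ra, rb, 1e-8, 1e-8), 0)
})

test_that("probe merging forms runs of >= 3 significant probes within the gap", {
  probes <- dplyr::bind_rows(probe_map(10, "chr1"), probe_map(10, "chr2"))
  res <- tibble::tibble(probe = probes$probe,
                        statistic = 4, p_raw = 0.5)
  res$p_raw[probes$probe %in% sprintf("chr1_p%03d", 2:4)] <- 1e-6
  r <- merge_probes_to_regions(res, probes, p_thr = 1e-4)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end, r$n_probes), c(200, 400, 3))
  # two probes only: below min_probes
  res2 <- dplyr::mutate(res, p_raw = ifelse(
    probe %in% sprintf("chr1_p%03d", 2:3), 1e-6, 0.5))
  expect_equal(nrow(merge_probes_to_regions(res2, probes, p_thr = 1e-4)), 0)
  # significant probes on different chromosomes never merge
  res3 <- dplyr::mutate(res, p_raw = ifelse(
    probe %in% c(sprintf("chr1_p%03d", 8:10), sprintf("chr2_p%03d", 1:3)),
    1e-6, 0.5))
  r3 <- merge_probes_to_regions(res3, probes, p_thr = 1e-4)
  expect_equal(nrow(r3), 2)
  expect_equal(r3$chrom, c("chr1", "chr2"))
  # a gap beyond max_gap_bp splits a run
  res4 <- dplyr::mutate(res, p_raw = ifelse(
    probe %in% sprintf("chr1_p%03d", c(1:3, 8:10)), 1e-6, 0.5))
  expect_equal(nrow(merge_probes_to_regions(res4, probes, p_thr = 1e-4,
                                            max_gap_bp = 200)), 2)
  expect_equal(nrow(merge_probes_to_regions(res4, probes, p_thr = 1e-4,
                                            max_gap_bp = 1000)), 1)
})

test_that("max(T) adjustment is seeded, bounded, and monotone in the statistic", {
  w <- generate_world(world_config(n_sites = 8, samples_per_site = 8,
                                   n_cnv_loci = 12, n_planted = 0,
                                   effect_size = 0, seed = 23))
  M <- build_probe_matrix(w$calls, w$probes, "del",
                          samples = w$samples$sample)
  K <- bn_kinship(M)
  y <- estimate_solar(dplyr::transmute(w$climate, site, latitude,
                                       sun = SUN_yr))$H
  y <- y[match(w$samples$site, w$climate$site)]
  fit <- emma_reml_fit(y, K)
  scan <- mlm_scan(y, M, fit = fit)
  regions <- merge_probes_to_regions(scan, w$probes, p_thr = 0.5)
  expect_gt(nrow(regions), 0)
  B <- 99
  adj1 <- maxt_adjust(regions, y, M, fit = fit, B = B, seed = 7)
  adj2 <- maxt_adjust(regions, y, M, fit = fit, B = B, seed = 7)
  expect_identical(adj1$p_adj, adj2$p_adj)
  expect_true(all(adj1$p_adj >= 1 / (B + 1)))
  expect_true(all(adj1$p_adj <= 1))
  ord <- order(adj1$max_stat)
  expect_true(all(diff(adj1$p_adj[ord]) <= 0))
  expect_error(maxt_adjust(regions, y, M, fit = fit, B = 0), "B must")
})
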