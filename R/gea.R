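#' PCA of climate variables
#'
#' Standardizes the climate variables (and elevation) to zero mean and unit
#' variance and decomposes them, returning per-site component scores,
#' loadings, and the proportion of variance explained. Constant columns are
#' dropped with a warning. A deterministic sign convention is applied: within
#' each component the largest-magnitude loading is made positive.
#'
#' @param climate Climate tibble with a `site` column; `latitude` and
#'   `longitude` are excluded from the decomposition, every other numeric
#'   column (including `elevation`) enters.
#' @param n_components Number of components to return. Default 2.
#' @return A list of class `env_pca`: `scores` (tibble, site + components),
#'   `loadings` (matrix), `explained_variance` (proportions).
#' @export
env_pca <- function(climate, n_components = 2) {
  stopifnot(is.data.frame(climate), "site" %in% names(climate))
  vars <- dplyr::select(climate, dplyr::where(is.numeric),
                        -dplyr::any_of(c("latitude", "longitude")))
  if (nrow(vars) < 2 || ncol(vars) < 2) {
    stop("PCA needs at least 2 sites and 2 variables", call. = FALSE)
  }
  sds <- vapply(vars, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(names(vars)[sds == 0], collapse = ", "))
    vars <- vars[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(vars, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  out <- list(
    scores = dplyr::bind_cols(climate["site"], tibble::as_tibble(scores)),
    loadings = rot,
    explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  )
  class(out) <- "env_pca"
  out
}

#' Univariate logistic regression with a Wald test
#'
#' Fits `y ~ x (+ covariates)` by maximum likelihood (IRLS via
#' [stats::glm()]) and reports the slope on `x`, its standard error, the Wald
#' statistic \eqn{(\hat\beta/se)^2} and its two-sided chi-square(1) p-value.
#' Non-convergence and (quasi-)separation are detected and flagged; a flagged
#' fit reports `NA` p rather than a spurious finite estimate.
#'
#' @param y Binary response (0/1) with both classes present.
#' @param x Numeric predictor.
#' @param covariates Optional numeric matrix of additional covariates.
#' @return A one-row tibble: `beta`, `se`, `statistic`, `p_raw`, `flagged`.
#' @export
logistic_wald <- function(y, x, covariates = NULL) {
  stopifnot(length(y) == length(x))
  if (length(unique(y)) < 2) {
    stop("degenerate response: y must contain both classes", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, x = x, covariates)
  flagged <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12,
                                                maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) flagged <- TRUE
  cov_un <- chol2inv(fit$qr$qr[seq_len(fit$qr$rank), seq_len(fit$qr$rank),
                               drop = FALSE])
  idx <- which(fit$qr$pivot == 2L)  # column of x after any pivoting
  beta <- unname(fit$coefficients["x"])
  se <- sqrt(cov_un[idx, idx])
  wald <- (beta / se)^2
  tibble::tibble(
    beta = beta, se = se, statistic = wald,
    p_raw = if (flagged) NA_real_ else stats::pchisq(wald, 1, lower.tail = FALSE),
    flagged = flagged
  )
}

#' Size of a genotype-by-environment model grid
#'
#' Number of univariate models enumerated by [sambada_scan()]:
#' loci times climate variables.
#'
#' @param n_loci,n_variables Counts.
#' @return The model count (double, exact for counts below 2^53).
#' @export
scan_grid_size <- function(n_loci, n_variables) {
  stopifnot(n_loci >= 0, n_variables >= 0)
  as.double(n_loci) * as.double(n_variables)
}

#' Binary CNV genotype matrix
#'
#' Samples x loci presence/absence matrix: entry 1 iff the sample carries a
#' call at the locus's exact coordinates. Loci are identified as
#' `chrom:start-end`.
#'
#' @param calls CNV call tibble.
#' @param samples Character vector of sample ids defining the rows (defaults
#'   to the samples present in `calls`).
#' @return A binary integer matrix with sample/locus dimnames.
#' @export
build_genotype_matrix <- function(calls, samples = sort(unique(calls$sample))) {
  assert_calls(calls)
  loci <- dedupe_unique(calls)
  locus_id <- sprintf("%s:%d-%d", loci$chrom, loci$start, loci$end)
  G <- matrix(0L, nrow = length(samples), ncol = nrow(loci),
              dimnames = list(samples, locus_id))
  call_id <- sprintf("%s:%d-%d", calls$chrom, calls$start, calls$end)
  i <- match(calls$sample, samples)
  j <- match(call_id, locus_id)
  keep <- !is.na(i)
  G[cbind(i[keep], j[keep])] <- 1L
  G
}

#' Join per-site climate values onto samples
#'
#' @param samples Tibble with `sample` and `site`.
#' @param climate Climate tibble with `site`.
#' @param variables Character vector of climate columns to extract.
#' @return A numeric matrix, samples x variables.
#' @export
sample_climate <- function(samples, climate, variables) {
  idx <- match(samples$site, climate$site)
  if (anyNA(idx)) {
    stop("sample(s) without site climate: ",
         paste(unique(samples$site[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(variables, names(climate))
  if (length(bad)) stop("unknown climate variable(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  X <- as.matrix(climate[idx, variables, drop = FALSE])
  rownames(X) <- samples$sample
  X
}

#' Univariate logistic genotype--environment scan
#'
#' Fits one logistic model per (locus, climate variable) pair, optionally with
#' population-structure covariates (e.g. climate or genotype principal
#' components), Bonferroni-adjusts the p-values over the full model grid, and
#' selects models with adjusted p below `p_threshold` and Wald score above
#' `wald_min`.
#'
#' Loci with fewer than `min_carriers` carriers (or fewer non-carriers) are
#' skipped: their models are counted in the Bonferroni denominator but
#' reported with `NA` statistics.
#'
#' @param G Binary genotype matrix (samples x loci) from
#'   [build_genotype_matrix()].
#' @param env Numeric matrix of per-sample climate values (samples x
#'   variables), e.g. from [sample_climate()].
#' @param covariates Optional numeric matrix of structure covariates.
#' @param p_threshold Bonferroni-adjusted significance level. Default 0.01.
#' @param wald_min Secondary Wald-score filter. Default 34.
#' @param min_carriers Minimum carriers and non-carriers per locus. Default 5.
#' @return A tibble of class `cnvclim_assoc`: `locus`, `variable`, `beta`,
#'   `se`, `statistic`, `p_raw`, `p_adj`, `method`, `selected`, `flagged`.
#' @export
sambada_scan <- function(G, env, covariates = NULL, p_threshold = 0.01,
                         wald_min = 34, min_carriers = 5) {
  stopifnot(is.matrix(G), is.matrix(env), nrow(G) == nrow(env))
  m <- scan_grid_size(ncol(G), ncol(env))
  carriers <- colSums(G)
  testable <- carriers >= min_carriers & (nrow(G) - carriers) >= min_carriers
  grid <- tidyr::expand_grid(locus = colnames(G), variable = colnames(env))
  res <- purrr::pmap(grid, function(locus, variable) {
    if (!testable[[locus]]) {
      return(tibble::tibble(beta = NA_real_, se = NA_real_,
                            statistic = NA_real_, p_raw = NA_real_,
                            flagged = NA))
    }
    logistic_wald(G[, locus], env[, variable], covariates)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  out$p_adj <- pmin(1, out$p_raw * m)
  out$method <- "sambada"
  out$selected <- !is.na(out$p_adj) & out$p_adj < p_threshold &
    out$statistic > wald_min
  class(out) <- c("cnvclim_assoc", class(out))
  attr(out, "n_models") <- m
  out
}

#' Latent factor mixed model scan
#'
#' Least-squares latent factor mixed model: (1) center the genotype
#' matrix; (2) estimate K latent factors as the top-K left singular vectors of
#' the genotype residual after regressing out the environment (preserving
#' locus-level environmental effects); (3) refit every
#' locus on environment plus latent factors; (4) form z-scores beta/se; (5)
#' calibrate them by the genomic inflation factor
#' \eqn{\lambda = \mathrm{median}(z^2) / 0.456} (per variable); (6)
#' Benjamini-Hochberg adjust the calibrated p-values. Selection requires
#' calibrated |z| at or above `z_min` and adjusted p below `p_threshold`.
#' With `K = 0` the scan reduces exactly to ordinary per-locus regression.
#'
#' @param G Binary (or numeric) genotype matrix, samples x loci.
#' @param X Environment matrix, samples x variables (column-standardized
#'   internally).
#' @param K Number of latent factors.
#' @param ridge Ridge penalty applied when the design is ill-conditioned.
#' @param z_min Calibrated |z| selection threshold. Default 10.
#' @param p_threshold BH-adjusted p selection threshold. Default 1e-6.
#' @return A list of class `lfmm_fit`: `K`, `factors` (n x K), `lambda`
#'   (genomic inflation per variable), `results` (a `cnvclim_assoc` tibble
#'   with `z`, `z_calibrated` columns), `df`.
#' @export
lfmm_scan <- function(G, X, K = 4, ridge = 1e-5, z_min = 10,
                      p_threshold = 1e-6) {
  stopifnot(is.matrix(G), nrow(G) == NROW(X))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(G)
  if (K >= min(dim(G))) {
    stop("K must be smaller than both the sample and locus counts",
         call. = FALSE)
  }
  Xs <- scale(X)
  Gc <- scale(G, center = TRUE, scale = FALSE)
  keep <- colSums(Gc^2) > 0

  if (K > 0) {
    # factors from the environment-residualized genotypes: structure collinear
    # with X is deliberately left out so locus-level effects are not absorbed;
    # the global inflation this leaves behind is handled by GIF calibration
    W0 <- cbind(1, Xs)
    resid0 <- Gc - W0 %*% solve(crossprod(W0), crossprod(W0, Gc))
    U <- svd(resid0, nu = K, nv = 0)$u
    colnames(U) <- paste0("LF", seq_len(K))
  } else {
    U <- matrix(0, n, 0)
  }
  W <- cbind(`(Intercept)` = 1, Xs, U)
  p <- ncol(W)
  WtW <- crossprod(W)
  inv <- tryCatch(chol2inv(chol(WtW)), error = function(e) {
    message("ill-conditioned design; applying ridge penalty ", ridge)
    chol2inv(chol(WtW + ridge * diag(p)))
  })
  B <- inv %*% crossprod(W, Gc)
  resid <- Gc - W %*% B
  df <- n - p
  s2 <- colSums(resid^2) / df
  env_idx <- 1 + seq_len(ncol(Xs))
  z <- matrix(NA_real_, ncol(G), ncol(Xs),
              dimnames = list(colnames(G), colnames(X)))
  for (k in seq_along(env_idx)) {
    se <- sqrt(inv[env_idx[k], env_idx[k]] * s2)
    zk <- B[env_idx[k], ] / se
    zk[!keep | se == 0] <- NA_real_
    z[, k] <- zk
  }
  lambda <- apply(z, 2, function(col) {
    stats::median(col^2, na.rm = TRUE) / stats::qchisq(0.5, 1)
  })
  z_cal <- sweep(z, 2, sqrt(lambda), "/")
  p_cal <- stats::pchisq(z_cal^2, 1, lower.tail = FALSE)

  results <- tibble::tibble(
    locus = rep(rownames(z), times = ncol(z)),
    variable = rep(colnames(z), each = nrow(z)),
    beta = as.vector(B[env_idx, , drop = FALSE] |> t()),
    z = as.vector(z),
    z_calibrated = as.vector(z_cal),
    statistic = as.vector(z_cal),
    p_raw = as.vector(p_cal)
  )
  results$p_adj <- stats::p.adjust(results$p_raw, method = "BH")
  results$method <- "lfmm"
  results$selected <- !is.na(results$p_adj) &
    abs(results$z_calibrated) >= z_min & results$p_adj < p_threshold
  class(results) <- c("cnvclim_assoc", class(results))

  structure(list(K = K, factors = U, lambda = lambda, results = results,
                 df = df, n = n, m = ncol(G)),
            class = "lfmm_fit")
}

#' @export
print.lfmm_fit <- function(x, ...) {
  cat("Latent factor mixed model scan: K =", x$K, ",", x$m, "loci,",
      x$n, "samples\n")
  cat("genomic inflation factor(s):",
      paste(sprintf("%s=%.3f", names(x$lambda), x$lambda), collapse = ", "),
      "\n")
  invisible(x)
}
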