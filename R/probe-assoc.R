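#' Probe occurrence matrix
#'
#' Binary samples x probes matrix: entry 1 iff a call of the requested
#' polarity (deletion = CN0/CN1, duplication = CN3/CN4) in that sample spans
#' the probe position, boundaries inclusive (`start <= position <= end`).
#' Deletions and duplications are kept in separate matrices.
#'
#' @param calls CNV call tibble (post QC).
#' @param probes Probe map tibble (`probe`, `chrom`, `position`).
#' @param polarity `"del"` or `"dup"`.
#' @param samples Sample ids defining the rows; defaults to samples in
#'   `calls`.
#' @return Binary integer matrix with sample/probe dimnames and attribute
#'   `polarity`.
#' @export
build_probe_matrix <- function(calls, probes, polarity = c("del", "dup"),
                               samples = sort(unique(calls$sample))) {
  polarity <- match.arg(polarity)
  assert_calls(calls)
  if (nrow(probes) == 0) stop("probe map is empty", call. = FALSE)
  states <- if (polarity == "del") deletion_states else duplication_states
  sel <- dplyr::filter(tibble::as_tibble(calls), .data$cn %in% states)
  M <- matrix(0L, nrow = length(samples), ncol = nrow(probes),
              dimnames = list(samples, probes$probe))
  if (nrow(sel) > 0) {
    hits <- dplyr::inner_join(sel, probes, by = "chrom",
                              relationship = "many-to-many") |>
      dplyr::filter(.data$position >= .data$start,
                    .data$position <= .data$end)
    i <- match(hits$sample, samples)
    j <- match(hits$probe, probes$probe)
    keep <- !is.na(i)
    M[cbind(i[keep], j[keep])] <- 1L
  }
  attr(M, "polarity") <- polarity
  M
}

#' Balding-Nichols kinship matrix
#'
#' Frequency-standardized kinship from a binary occurrence matrix:
#' \deqn{K_{ij} = \frac{1}{M^*} \sum_m \frac{(x_{im}-\hat p_m)(x_{jm}-\hat p_m)}
#'       {\hat p_m (1-\hat p_m)}}
#' over the \eqn{M^*} polymorphic probes (frequency strictly between 0 and 1);
#' monomorphic probes are excluded. The result is symmetric and positive
#' semidefinite by construction; should numerical error leave a negative
#' eigenvalue below `-1e-8`, a minimal diagonal ridge is added (with a
#' message).
#'
#' @param M Binary occurrence matrix, samples x probes.
#' @return Symmetric kinship matrix, samples x samples.
#' @export
bn_kinship <- function(M) {
  stopifnot(is.matrix(M), nrow(M) >= 2)
  p <- colMeans(M)
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic probes", call. = FALSE)
  p <- p[poly]
  Z <- sweep(sweep(M[, poly, drop = FALSE], 2, p), 2, sqrt(p * (1 - p)), "/")
  K <- tcrossprod(Z) / sum(poly)
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    ridge <- -min(ev) + 1e-8
    message("kinship adjusted to PSD with diagonal ridge ", signif(ridge, 3))
    K <- K + diag(ridge, nrow(K))
  }
  rownames(K) <- colnames(K) <- rownames(M)
  K
}

#' REML variance-component fit for a kinship mixed model
#'
#' Single-trait mixed model \eqn{y = X\beta + u + e} with
#' \eqn{\mathrm{var}(u) = \sigma_g^2 K} and \eqn{\mathrm{var}(e) =
#' \sigma_e^2 I}. The kinship is spectrally decomposed once and the variance
#' ratio \eqn{\delta = \sigma_e^2/\sigma_g^2} maximizing the restricted
#' likelihood is found by one-dimensional optimization of
#' \eqn{\log\delta \in [-10, 10]}. The returned cache (rotation at the fitted
#' \eqn{\delta}) is reused by every probe test.
#'
#' @param y Numeric response (e.g. solar radiation per sample).
#' @param K Kinship matrix (PSD).
#' @param covariates Optional numeric matrix of fixed covariates (an
#'   intercept is always included).
#' @return A list of class `emma_fit`: `delta`, `sigma_g2`, `sigma_e2`,
#'   eigendecomposition (`U`, `D`), the fixed-effect design `X`, the
#'   whitening rotation `A` (so `A %*% y` has iid errors), and `reml_loglik`.
#' @export
emma_reml_fit <- function(y, K, covariates = NULL) {
  stopifnot(is.numeric(y), all(is.finite(y)), nrow(K) == length(y))
  X <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  n <- length(y)
  q <- ncol(X)
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-6) stop("kinship matrix is not PSD", call. = FALSE)
  D <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)

  neg_reml <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (D + delta)
    XtWX <- crossprod(Xt, Xt * w)
    beta <- solve(XtWX, crossprod(Xt, yt * w))
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    (n - q) * log(rss) + sum(log(D + delta)) +
      determinant(XtWX, logarithm = TRUE)$modulus
  }
  opt <- stats::optimize(neg_reml, interval = c(-10, 10))
  delta <- exp(opt$minimum)
  w <- 1 / (D + delta)
  XtWX <- crossprod(Xt, Xt * w)
  beta <- solve(XtWX, crossprod(Xt, yt * w))
  rss <- sum(w * (yt - Xt %*% beta)^2)
  sigma_g2 <- rss / (n - q)
  structure(list(
    delta = delta, sigma_g2 = sigma_g2, sigma_e2 = delta * sigma_g2,
    U = U, D = D, X = X, y = y,
    A = t(U) / sqrt(D + delta),  # whitening rotation: rows scaled
    reml_loglik = -0.5 * opt$objective,
    n = n, q = q
  ), class = "emma_fit")
}

#' @export
print.emma_fit <- function(x, ...) {
  cat("Kinship mixed-model REML fit:",
      sprintf("delta = %.4g, sigma_g^2 = %.4g, sigma_e^2 = %.4g\n",
              x$delta, x$sigma_g2, x$sigma_e2))
  invisible(x)
}

# Whitened, covariate-residualized pieces shared by the scan and max(T).
whiten_scan_inputs <- function(fit, M) {
  A <- fit$A
  yt <- as.vector(A %*% fit$y)
  Xt <- A %*% fit$X
  Mt <- A %*% M
  Q <- qr(Xt)
  yr <- qr.resid(Q, yt)
  Mr <- qr.resid(Q, Mt)
  xss <- colSums(Mr^2)
  list(Q = Q, yr = yr, Mr = Mr, xss = xss, df = fit$n - fit$q - 1)
}

#' Mixed linear model probe scan
#'
#' Tests each probe's occurrence against a quantitative phenotype (solar
#' radiation) under the fitted variance structure
#' \eqn{\sigma_g^2 K + \sigma_e^2 I}: generalized least squares per probe at
#' the REML \eqn{\delta}, with a two-sided t-test. Probes constant across
#' samples are skipped (reported with `NA`).
#'
#' @param y Phenotype per sample.
#' @param M Probe occurrence matrix (samples x probes).
#' @param K Kinship matrix; ignored if `fit` is supplied.
#' @param covariates Optional fixed covariates (e.g. principal components).
#' @param fit Optional precomputed [emma_reml_fit()].
#' @param suggestive Suggestive significance threshold on raw p. Default
#'   5e-4.
#' @return A `cnvclim_assoc` tibble: `probe`, `beta`, `se`, `statistic`
#'   (t), `p_raw`, `p_adj` (BH), `selected` (raw p below `suggestive`).
#' @export
mlm_scan <- function(y, M, K = NULL, covariates = NULL, fit = NULL,
                     suggestive = 5e-4) {
  if (is.null(fit)) fit <- emma_reml_fit(y, K, covariates)
  ws <- whiten_scan_inputs(fit, M)
  xss <- unname(ws$xss)
  ok <- xss > 1e-12
  if (any(!ok)) message(sum(!ok), " constant probe(s) skipped")
  bnum <- as.vector(crossprod(ws$Mr, ws$yr))
  beta <- ifelse(ok, bnum / xss, NA_real_)
  yss <- sum(ws$yr^2)
  rss <- yss - ifelse(ok, bnum^2 / xss, 0)
  se <- ifelse(ok, sqrt((rss / ws$df) / xss), NA_real_)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), ws$df)
  out <- tibble::tibble(
    probe = colnames(M), beta = beta, se = se, statistic = tval,
    p_raw = p, p_adj = stats::p.adjust(p, "BH"),
    method = "mlm", selected = !is.na(p) & p < suggestive
  )
  class(out) <- c("cnvclim_assoc", class(out))
  attr(out, "fit") <- fit
  out
}

#' Logistic probe scan with covariates
#'
#' Per probe, regresses occurrence (0/1) on the phenotype plus optional
#' population-stratification principal components, via [logistic_wald()].
#' Probes constant across samples are skipped.
#'
#' @param M Probe occurrence matrix.
#' @param radiation Phenotype per sample.
#' @param pcs Optional covariate matrix.
#' @param p_threshold Raw-p selection threshold. Default 5e-5.
#' @return A `cnvclim_assoc` tibble (statistic = Wald).
#' @export
logistic_scan <- function(M, radiation, pcs = NULL, p_threshold = 5e-5) {
  stopifnot(nrow(M) == length(radiation))
  rows <- purrr::map(colnames(M), function(pr) {
    occ <- M[, pr]
    if (length(unique(occ)) < 2) {
      return(tibble::tibble(beta = NA_real_, se = NA_real_,
                            statistic = NA_real_, p_raw = NA_real_,
                            flagged = NA))
    }
    logistic_wald(occ, radiation, pcs)
  })
  out <- dplyr::bind_cols(tibble::tibble(probe = colnames(M)),
                          dplyr::bind_rows(rows))
  out$p_adj <- stats::p.adjust(out$p_raw, "BH")
  out$method <- "plink_logistic"
  out$selected <- !is.na(out$p_raw) & out$p_raw < p_threshold
  class(out) <- c("cnvclim_assoc", class(out))
  out
}

#' Consensus probes across two scans
#'
#' Probes significant in both association approaches at their respective raw-p
#' thresholds (defaults: 5e-4 for the mixed-model scan, 5e-5 for the logistic
#' scan).
#'
#' @param res_a,res_b `cnvclim_assoc` tibbles sharing a `probe` column.
#' @param thr_a,thr_b Raw-p thresholds.
#' @return Sorted character vector of probe ids.
#' @export
consensus_probes <- function(res_a, res_b, thr_a = 5e-4, thr_b = 5e-5) {
  pass <- function(res, thr) res$probe[!is.na(res$p_raw) & res$p_raw < thr]
  sort(intersect(pass(res_a, thr_a), pass(res_b, thr_b)))
}

#' Merge adjacent significant probes into regions
#'
#' Maximal runs of probes with raw p below `p_thr`, allowing gaps up to
#' `max_gap_bp` between consecutive significant probes on the same
#' chromosome, form candidate regions. Runs with fewer than `min_probes`
#' probes are discarded. Region raw p is the minimum probe p (peak-probe
#' significance) and the region statistic is the maximum |t| among its
#' probes.
#'
#' @param res A `cnvclim_assoc` tibble with `probe`, `statistic`, `p_raw`.
#' @param probes Probe map tibble.
#' @param p_thr Probe significance threshold. Default 5e-4.
#' @param min_probes Minimum probes per region. Default 3.
#' @param max_gap_bp Maximum gap between consecutive significant probes.
#'   Default 1e6.
#' @return A tibble of class `cnvclim_regions`: `chrom`, `start`, `end`,
#'   `n_probes`, `p_raw`, `max_stat`, `probes` (list-column of ids).
#' @export
merge_probes_to_regions <- function(res, probes, p_thr = 5e-4,
                                    min_probes = 3, max_gap_bp = 1e6) {
  sig <- dplyr::inner_join(
    dplyr::filter(res, !is.na(.data$p_raw), .data$p_raw < p_thr),
    probes, by = "probe"
  ) |>
    dplyr::arrange(.data$chrom, .data$position)
  if (nrow(sig) == 0) {
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_probes = integer(),
                          p_raw = double(), max_stat = double(),
                          probes = list())
    class(out) <- c("cnvclim_regions", class(out))
    return(out)
  }
  out <- sig |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(run = cumsum(
      .data$position - dplyr::lag(.data$position,
                                  default = .data$position[1]) > max_gap_bp
    )) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(
      start = min(.data$position), end = max(.data$position),
      n_probes = dplyr::n(), p_raw = min(.data$p_raw),
      max_stat = max(abs(.data$statistic)),
      probes = list(.data$probe), .groups = "drop"
    ) |>
    dplyr::filter(.data$n_probes >= min_probes) |>
    dplyr::select(-"run") |>
    dplyr::arrange(.data$chrom, .data$start)
  class(out) <- c("cnvclim_regions", class(out))
  out
}

#' max(T) permutation adjustment of region significance
#'
#' Family-wise error control for region associations by the permutation
#' distribution of the genome-wide maximum probe statistic: the phenotype is
#' permuted `B` times with a seeded generator; for each permutation the
#' per-probe generalized-least-squares |t| is recomputed at the fixed REML
#' \eqn{\delta} (the standard fixed-variance max(T) shortcut) and its maximum
#' over probes recorded. A region's adjusted p is
#' \eqn{(1 + \#\{ \max_b \ge \max\text{-stat}_r \})/(B+1)}.
#'
#' @param regions A `cnvclim_regions` tibble (from
#'   [merge_probes_to_regions()]).
#' @param y Phenotype per sample.
#' @param M Probe occurrence matrix used for the scan.
#' @param K Kinship matrix; ignored if `fit` supplied.
#' @param covariates Optional fixed covariates.
#' @param B Number of permutations. Default 10000.
#' @param seed Integer seed for the permutation generator.
#' @param fit Optional precomputed [emma_reml_fit()].
#' @param alpha Family-wise significance level. Default 0.05.
#' @return `regions` with `p_adj` and `significant` columns.
#' @export
maxt_adjust <- function(regions, y, M, K = NULL, covariates = NULL,
                        B = 10000, seed = 1L, fit = NULL, alpha = 0.05) {
  if (B < 1) stop("B must be at least 1", call. = FALSE)
  if (is.null(fit)) fit <- emma_reml_fit(y, K, covariates)
  ws <- whiten_scan_inputs(fit, M)
  ok <- ws$xss > 1e-12
  Mr <- ws$Mr[, ok, drop = FALSE]
  xss <- ws$xss[ok]
  df <- ws$df
  set.seed(seed)
  n <- length(y)
  max_t <- numeric(B)
  done <- 0L
  chunk <- 256L
  while (done < B) {
    b <- min(chunk, B - done)
    Yp <- vapply(seq_len(b), function(i) y[sample.int(n)], numeric(n))
    Yt <- fit$A %*% Yp
    Yr <- qr.resid(ws$Q, Yt)
    C <- crossprod(Mr, Yr)                       # probes x b
    Q2 <- C^2 / xss                              # recycled by row
    yss <- colSums(Yr^2)
    T2 <- Q2 / ((rep(yss, each = nrow(Q2)) - Q2) / df)
    max_t[done + seq_len(b)] <- sqrt(apply(T2, 2, max))
    done <- done + b
  }
  regions$p_adj <- vapply(regions$max_stat, function(s) {
    (1 + sum(max_t >= s)) / (B + 1)
  }, numeric(1))
  regions$significant <- regions$p_adj < alpha
  attr(regions, "perm_max") <- max_t
  regions
}
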