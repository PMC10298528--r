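# Independent brute-force oracles used to validate the package's optimized
# implementations on small instances. These deliberately use the slowest,
# most literal formulation of each computation.

# Interval union by boolean coverage on the 0-based half-open transform.
naive_merge <- function(calls) {
  out <- lapply(split(calls, calls$chrom), function(d) {
    lo <- min(d$start)
    hi <- max(d$end)
    covered <- rep(FALSE, hi - lo + 1)
    for (i in seq_len(nrow(d))) {
      covered[(d$start[i] - lo + 1):(d$end[i] - lo + 1)] <- TRUE
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    data.frame(chrom = d$chrom[1],
               start = starts[keep] + lo - 1,
               end = ends[keep] + lo - 1)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

# Textbook Newton-Raphson on the logistic log-likelihood.
nr_logistic <- function(y, X, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    score <- crossprod(X, y - p)
    info <- crossprod(X, X * W)
    step <- solve(info, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  info <- crossprod(X, X * p * (1 - p))
  list(beta = beta, se = sqrt(diag(solve(info))))
}

# Triple loop over (sample, probe, call).
naive_probe_matrix <- function(calls, probes, polarity, samples) {
  states <- if (polarity == "del") c("CN0", "CN1") else c("CN3", "CN4")
  M <- matrix(0L, length(samples), nrow(probes),
              dimnames = list(samples, probes$probe))
  for (s in samples) {
    for (k in seq_len(nrow(probes))) {
      for (i in which(calls$sample == s)) {
        if (calls$cn[i] %in% states &&
            calls$chrom[i] == probes$chrom[k] &&
            calls$start[i] <= probes$position[k] &&
            calls$end[i] >= probes$position[k]) {
          M[s, k] <- 1L
        }
      }
    }
  }
  M
}

# All-pairs interval overlap with a region-fraction rule.
naive_overlap_pairs <- function(regions, features, min_frac) {
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(features))) {
      if (regions$chrom[i] != features$chrom[j]) next
      ov <- min(regions$end[i], features$end[j]) -
        max(regions$start[i], features$start[j]) + 1
      if (ov <= 0) next
      len <- regions$end[i] - regions$start[i] + 1
      if (ov / len >= min_frac) {
        rows[[length(rows) + 1]] <- data.frame(
          region = sprintf("%s:%d-%d", regions$chrom[i], regions$start[i],
                           regions$end[i]),
          feature = features$name[j], overlap_bp = ov)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(region = character(), feature = character(),
                      overlap_bp = integer()))
  }
  res <- do.call(rbind, rows)
  res[order(res$region, res$feature), , drop = FALSE]
}

# Dense-matrix restricted log-likelihood for the kinship mixed model,
# evaluated on a grid of log(delta). Independent of the eigendecomposition
# shortcut used by the package.
reml_grid_delta <- function(y, K, X = matrix(1, length(y), 1), n_grid = 1001) {
  n <- length(y)
  q <- ncol(X)
  grid <- seq(-10, 10, length.out = n_grid)
  ll <- vapply(grid, function(ld) {
    H <- K + exp(ld) * diag(n)
    Hi <- solve(H)
    XtHiX <- crossprod(X, Hi %*% X)
    P <- Hi - Hi %*% X %*% solve(XtHiX, crossprod(X, Hi))
    -0.5 * ((n - q) * log(drop(crossprod(y, P %*% y))) +
              determinant(H, logarithm = TRUE)$modulus +
              determinant(XtHiX, logarithm = TRUE)$modulus)
  }, numeric(1))
  list(log_delta = grid[which.max(ll)], loglik = max(ll))
}

# Random CNV call tables for property tests.
random_calls <- function(n, n_samples = 4, n_chrom = 2, max_pos = 300,
                         max_len = 40) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    sample = sample(sprintf("s%d", seq_len(n_samples)), n, replace = TRUE),
    chrom = sample(sprintf("chr%d", seq_len(n_chrom)), n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE) - 1L,
    cn = sample(c("CN0", "CN1", "CN3", "CN4"), n, replace = TRUE),
    num_snps = sample(4:20, n, replace = TRUE)
  )
}

random_intervals <- function(n, prefix, n_chrom = 2, max_pos = 500,
                             max_len = 80) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    name = sprintf("%s%03d", prefix, seq_len(n)),
    chrom = sample(sprintf("chr%d", seq_len(n_chrom)), n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE) - 1L
  )
}

small_world <- function(seed = 1, ...) {
  generate_world(world_config(n_sites = 8, samples_per_site = 6,
                              n_cnv_loci = 30, n_planted = 3, seed = seed,
                              ...))
}
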