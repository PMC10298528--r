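#' Configuration for a synthetic CNV--climate world
#'
#' Describes a multi-site sampling design: sites grouped into geographic
#' clusters along a latitudinal gradient, individuals sampled per site, CNV
#' loci with baseline carrier frequencies, and a subset of "planted" loci whose
#' per-sample presence probability follows a logistic function of one
#' standardized climate variable. Hierarchical population structure enters as
#' cluster-specific offsets on each locus's logit frequency, creating the
#' climate--ancestry confounding that structure-aware scans must correct.
#'
#' @param n_sites Number of sampling sites. Default 47.
#' @param samples_per_site Individuals per site. Default 15.
#' @param n_clusters Number of latent ancestry/geography clusters (K).
#'   Default 4.
#' @param n_cnv_loci Number of CNV loci. Default 200.
#' @param n_planted Number of loci carrying a climate effect. Default 10.
#' @param effect_size Logistic slope on the standardized target climate
#'   variable for planted loci. Default 1.5.
#' @param baseline_freq_range Range of baseline carrier frequencies.
#' @param cluster_sd Standard deviation of the per-locus, per-cluster logit
#'   offsets (population structure strength). Default 0.5.
#' @param probe_spacing_bp Distance between adjacent array probes. Default
#'   1000.
#' @param locus_span_probes Range (integer pair) of the number of consecutive
#'   probes a locus spans. Default `c(3, 8)` so every locus covers at least
#'   3 probes.
#' @param n_chrom Number of chromosomes loci are spread over. Default 3.
#' @param qc_fail_frac Fraction of samples drawn to violate a signal-quality
#'   threshold. Default 0.05.
#' @param target_variable Climate column targeted by planted loci.
#'   Default `"SUN_yr"` (annual sunshine fraction).
#' @param n_genes,n_qtls Number of synthetic gene / QTL intervals.
#' @param cn_weights Sampling weights of copy-number classes CN0, CN1, CN3,
#'   CN4; default the observed class proportions of a large sheep call set
#'   (4726, 23298, 11018, 103).
#' @param seed Integer seed; identical seeds give identical worlds.
#'
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_sites = 47, samples_per_site = 15, n_clusters = 4,
                         n_cnv_loci = 200, n_planted = 10, effect_size = 1.5,
                         baseline_freq_range = c(0.05, 0.4), cluster_sd = 0.5,
                         probe_spacing_bp = 1000,
                         locus_span_probes = c(3L, 8L), n_chrom = 3,
                         qc_fail_frac = 0.05, target_variable = "SUN_yr",
                         n_genes = 100, n_qtls = 30,
                         cn_weights = c(CN0 = 4726, CN1 = 23298,
                                        CN3 = 11018, CN4 = 103),
                         seed = 1L) {
  cfg <- list(n_sites = n_sites, samples_per_site = samples_per_site,
              n_clusters = n_clusters, n_cnv_loci = n_cnv_loci,
              n_planted = n_planted, effect_size = effect_size,
              baseline_freq_range = baseline_freq_range,
              cluster_sd = cluster_sd, probe_spacing_bp = probe_spacing_bp,
              locus_span_probes = as.integer(locus_span_probes),
              n_chrom = n_chrom, qc_fail_frac = qc_fail_frac,
              target_variable = target_variable, n_genes = n_genes,
              n_qtls = n_qtls, cn_weights = cn_weights, seed = as.integer(seed))
  with(cfg, {
    if (n_planted > n_cnv_loci) {
      stop("n_planted must not exceed n_cnv_loci", call. = FALSE)
    }
    stopifnot(n_sites > 0, samples_per_site > 0, n_clusters > 0,
              n_cnv_loci > 0, n_planted >= 0,
              all(baseline_freq_range > 0), all(baseline_freq_range < 1),
              probe_spacing_bp >= 1, locus_span_probes[1] >= 1,
              qc_fail_frac >= 0, qc_fail_frac < 1)
  })
  structure(cfg, class = "world_config")
}

climate_params <- function() {
  # intercept/latitude slope/seasonal amplitude/noise sd per climate parameter
  tibble::tribble(
    ~param, ~intercept, ~lat_slope, ~seas_amp, ~noise_sd, ~lower, ~upper,
    "SUN",  0.85, -0.006, 0.06, 0.02, 0.02, 1,
    "DTR",  12.0,  0.050, 2.00, 0.50, 0, Inf,
    "REH",  55.0,  0.300, 5.00, 2.00, 0, 100,
    "PR",   90.0, -0.800, 20.0, 8.00, 0, Inf,
    "TMP",  28.0, -0.550, 8.00, 1.00, -Inf, Inf,
    "PRCV", 40.0,  0.200, 5.00, 3.00, 0, Inf,
    "FRS",  -4.0,  0.500, 3.00, 1.00, 0, Inf,
    "WND",  4.00,  0.020, 0.50, 0.30, 0, Inf,
    "RDO",  14.0, -0.050, 3.00, 1.00, 0, 31
  )
}

#' Generate a synthetic CNV--climate world
#'
#' Draws sites, per-site climates (9 parameters x 12 monthly values whose mean,
#' plus small noise, gives the yearly column, plus elevation), structured
#' samples, probe map, CNV calls with optional planted climate effects,
#' per-sample QC metrics, gene and QTL intervals, and a truth table recording
#' which loci were planted.
#'
#' @param config A [world_config()].
#' @return A list of class `cnvclim_world` with elements `config`, `sites`,
#'   `climate`, `samples`, `loci`, `calls`, `qc`, `probes`, `genes`, `qtls`,
#'   `truth`.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  K <- config$n_clusters

  # --- sites on a latitudinal gradient, grouped into clusters -------------
  centers_lat <- if (K <= 4) c(55, 42, 35, 10)[seq_len(K)] else {
    seq(55, 10, length.out = K)
  }
  centers_lon <- seq(-5, 95, length.out = K)
  cluster <- sort(rep_len(seq_len(K), config$n_sites))
  sites <- tibble::tibble(
    site = sprintf("S%03d", seq_len(config$n_sites)),
    cluster = cluster,
    latitude = centers_lat[cluster] + stats::rnorm(config$n_sites, 0, 3),
    longitude = centers_lon[cluster] + stats::rnorm(config$n_sites, 0, 8),
    elevation = pmax(0, stats::rnorm(config$n_sites, 800, 500))
  )

  # --- climate: 9 parameters x (12 monthly + yearly) ----------------------
  pars <- climate_params()
  climate <- sites[, c("site", "latitude", "longitude", "elevation")]
  for (i in seq_len(nrow(pars))) {
    p <- pars[i, ]
    monthly <- sapply(1:12, function(m) {
      v <- p$intercept + p$lat_slope * sites$latitude +
        p$seas_amp * cos(2 * pi * (m - 7) / 12) +
        stats::rnorm(config$n_sites, 0, p$noise_sd)
      pmin(p$upper, pmax(p$lower, v))
    })
    colnames(monthly) <- sprintf("%s_m%02d", p$param, 1:12)
    yearly <- rowMeans(monthly) + stats::rnorm(config$n_sites, 0, p$noise_sd / 10)
    yearly <- pmin(p$upper, pmax(p$lower, yearly))
    climate[colnames(monthly)] <- tibble::as_tibble(monthly)
    climate[[sprintf("%s_yr", p$param)]] <- yearly
  }

  # --- samples ------------------------------------------------------------
  samples <- tidyr::expand_grid(site = sites$site,
                                rep = seq_len(config$samples_per_site)) |>
    dplyr::mutate(sample = sprintf("%s_i%02d", .data$site, .data$rep)) |>
    dplyr::left_join(sites[, c("site", "cluster")], by = "site") |>
    dplyr::select("sample", "site", "cluster")

  # --- probes and probe-aligned CNV loci ----------------------------------
  span <- config$locus_span_probes
  gap_probes <- 4L
  loci_per_chrom <- ceiling(config$n_cnv_loci / config$n_chrom)
  spans <- sample(seq(span[1], span[2]), config$n_cnv_loci, replace = TRUE)
  loci <- tibble::tibble(
    locus = sprintf("L%04d", seq_len(config$n_cnv_loci)),
    chrom = sprintf("chr%d", rep(seq_len(config$n_chrom),
                                 each = loci_per_chrom)[seq_len(config$n_cnv_loci)]),
    span = spans
  ) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      first_probe = cumsum(dplyr::lag(.data$span, default = 0) + gap_probes) + 1
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      start = .data$first_probe * config$probe_spacing_bp,
      end = (.data$first_probe + .data$span - 1) * config$probe_spacing_bp,
      cn = sample(names(config$cn_weights), config$n_cnv_loci, replace = TRUE,
                  prob = config$cn_weights),
      base_freq = stats::runif(config$n_cnv_loci,
                               config$baseline_freq_range[1],
                               config$baseline_freq_range[2])
    )
  probes <- loci |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(idx = seq_len(max(.data$first_probe + .data$span) + gap_probes)) |>
    dplyr::mutate(position = .data$idx * config$probe_spacing_bp,
                  probe = sprintf("%s_p%05d", .data$chrom, .data$idx)) |>
    dplyr::select("probe", "chrom", "position")

  # --- planted effects and truth table ------------------------------------
  planted <- sample(loci$locus, config$n_planted)
  truth <- tibble::tibble(
    locus = loci$locus,
    is_planted = loci$locus %in% planted,
    target_variable = ifelse(loci$locus %in% planted,
                             config$target_variable, NA_character_),
    effect = ifelse(loci$locus %in% planted, config$effect_size, 0)
  )

  # --- presence draws: logistic in climate + cluster offsets --------------
  env <- climate[[config$target_variable]]
  if (is.null(env)) {
    stop("target_variable not found in climate table: ",
         config$target_variable, call. = FALSE)
  }
  z_site <- as.numeric(scale(env))
  z <- z_site[match(samples$site, climate$site)]
  offsets <- matrix(stats::rnorm(config$n_cnv_loci * K, 0, config$cluster_sd),
                    nrow = config$n_cnv_loci)
  n_samp <- nrow(samples)
  call_rows <- purrr::map(seq_len(config$n_cnv_loci), function(j) {
    eta <- stats::qlogis(loci$base_freq[j]) + offsets[j, samples$cluster] +
      truth$effect[j] * z
    present <- stats::rbinom(n_samp, 1, stats::plogis(eta)) == 1
    if (!any(present)) return(NULL)
    tibble::tibble(sample = samples$sample[present], chrom = loci$chrom[j],
                   start = loci$start[j], end = loci$end[j], cn = loci$cn[j],
                   num_snps = loci$span[j])
  })
  calls <- dplyr::bind_rows(call_rows) |>
    dplyr::arrange(.data$sample, .data$chrom, .data$start)

  # --- per-sample QC metrics ----------------------------------------------
  qc <- tibble::tibble(
    sample = samples$sample,
    lrr_sd = abs(stats::rnorm(n_samp, 0.13, 0.05)),
    baf_drift = abs(stats::rnorm(n_samp, 0.002, 0.002)),
    waviness = abs(stats::rnorm(n_samp, 0.015, 0.01))
  )
  qc$lrr_sd <- pmin(qc$lrr_sd, 0.29)
  qc$baf_drift <- pmin(qc$baf_drift, 0.009)
  qc$waviness <- pmin(qc$waviness, 0.049)
  n_fail <- round(config$qc_fail_frac * n_samp)
  if (n_fail > 0) {
    bad <- sample(n_samp, n_fail)
    which_metric <- sample(c("lrr_sd", "baf_drift", "waviness"), n_fail,
                           replace = TRUE)
    bump <- c(lrr_sd = 0.35, baf_drift = 0.02, waviness = 0.08)
    for (i in seq_len(n_fail)) {
      qc[[which_metric[i]]][bad[i]] <- bump[[which_metric[i]]]
    }
  }
  qc$call_count <- dplyr::count(calls, .data$sample) |>
    (\(d) d$n[match(qc$sample, d$sample)])() |>
    (\(v) ifelse(is.na(v), 0L, v))()

  # --- gene and QTL intervals ---------------------------------------------
  chrom_len <- probes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$position) + 1e6, .groups = "drop")
  rand_intervals <- function(n, widths, prefix) {
    chrom <- sample(chrom_len$chrom, n, replace = TRUE)
    len <- chrom_len$len[match(chrom, chrom_len$chrom)]
    start <- floor(stats::runif(n, 1, pmax(2, len - widths)))
    tibble::tibble(name = sprintf("%s%03d", prefix, seq_len(n)), chrom = chrom,
                   start = as.integer(start),
                   end = as.integer(start + widths - 1))
  }
  gene_w <- round(stats::runif(config$n_genes, 2, 20) * config$probe_spacing_bp)
  genes <- rand_intervals(config$n_genes, gene_w, "GENE") |>
    dplyr::mutate(kind = "gene")
  qtl_w <- round(stats::runif(config$n_qtls, 0.1, 8) * 1e6)
  qtls <- rand_intervals(config$n_qtls, qtl_w, "QTL") |>
    dplyr::mutate(kind = "QTL", ci_width_bp = .data$end - .data$start + 1)

  structure(list(config = config, sites = sites, climate = climate,
                 samples = samples, loci = loci, calls = calls, qc = qc,
                 probes = probes, genes = genes, qtls = qtls, truth = truth),
            class = "cnvclim_world")
}

#' @export
print.cnvclim_world <- function(x, ...) {
  cat("Synthetic CNV-climate world:",
      nrow(x$sites), "sites,", nrow(x$samples), "samples,",
      nrow(x$loci), "CNV loci (", sum(x$truth$is_planted), "planted ),",
      nrow(x$calls), "calls\n")
  invisible(x)
}

#' Write a synthetic world to plain-text fixture files
#'
#' Writes the call table (PennCNV-like TSV), climate, probe map, sample, QC
#' and truth tables as TSV, and gene/QTL intervals as BED (0-based half-open,
#' converted from the internal 1-based inclusive coordinates).
#'
#' @param world A [generate_world()] result.
#' @param out_dir Output directory (created if absent).
#' @return A manifest tibble with `file`, `path`, `rows`.
#' @export
write_fixtures <- function(world, out_dir) {
  stopifnot(inherits(world, "cnvclim_world"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  tsv <- function(x, file) {
    path <- file.path(out_dir, file)
    readr::write_tsv(x, path)
    tibble::tibble(file = file, path = path, rows = nrow(x))
  }
  bed <- function(x, file) {
    path <- file.path(out_dir, file)
    write_bed(x, path)
    tibble::tibble(file = file, path = path, rows = nrow(x))
  }
  dplyr::bind_rows(
    tsv(world$calls, "calls.tsv"),
    tsv(world$climate, "climate.tsv"),
    tsv(world$probes, "probes.tsv"),
    tsv(world$samples, "samples.tsv"),
    tsv(world$qc, "qc.tsv"),
    tsv(world$truth, "truth.tsv"),
    bed(world$genes, "genes.bed"),
    bed(dplyr::select(world$qtls, -"ci_width_bp"), "qtls.bed")
  )
}
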