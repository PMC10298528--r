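features_to_granges <- function(x, seqlevels) {
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = x$start, end = x$end)
  )
}

overlap_pairs <- function(regions, features, min_frac, region_id,
                          feature_col = "name") {
  lv <- sort(union(regions$chrom, features$chrom))
  gr_r <- features_to_granges(regions, lv)
  gr_f <- features_to_granges(features, lv)
  hits <- GenomicRanges::findOverlaps(gr_r, gr_f)
  if (length(hits) == 0) {
    return(tibble::tibble(region = character(), feature = character(),
                          overlap_bp = integer(), region_frac = double()))
  }
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_r)[i],
                                           IRanges::ranges(gr_f)[j]))
  frac <- ov / (regions$end[i] - regions$start[i] + 1)
  keep <- frac >= min_frac
  tibble::tibble(
    region = region_id[i][keep],
    feature = features[[feature_col]][j][keep],
    overlap_bp = ov[keep],
    region_frac = frac[keep]
  ) |>
    dplyr::arrange(.data$region, .data$feature)
}

region_ids <- function(regions) {
  sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
}

#' Gene overlap of CNV regions
#'
#' Reports (region, gene) pairs whose overlap covers at least `min_frac`
#' (default 10%) of the region's length. Coordinates are 1-based inclusive.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (e.g. CNVRs).
#' @param genes Feature tibble with `chrom`, `start`, `end`, `name`.
#' @param min_frac Minimum overlapped fraction of the region. Default 0.10.
#' @return Tibble: `region`, `feature`, `overlap_bp`, `region_frac`.
#' @export
gene_overlap <- function(regions, genes, min_frac = 0.10) {
  overlap_pairs(regions, genes, min_frac, region_ids(regions))
}

#' QTL overlap of CNV regions
#'
#' QTLs whose confidence interval is `max_ci_bp` (default 5 Mb) or wider are
#' excluded first (strict `<` retention); remaining (region, QTL) pairs are
#' reported when the overlap covers at least `min_frac` (default 50%) of the
#' region's length, or of the smaller of region and QTL when
#' `reciprocal = TRUE`.
#'
#' @param regions Tibble with `chrom`, `start`, `end`.
#' @param qtls Feature tibble with `chrom`, `start`, `end`, `name` and
#'   `ci_width_bp` (defaults to the interval width when absent).
#' @param max_ci_bp Strict upper bound on QTL confidence-interval width.
#' @param min_frac Minimum overlapped fraction. Default 0.50.
#' @param reciprocal Require the fraction of both intervals. Default FALSE.
#' @return Tibble: `region`, `feature`, `overlap_bp`, `region_frac`.
#' @export
qtl_overlap <- function(regions, qtls, max_ci_bp = 5e6, min_frac = 0.50,
                        reciprocal = FALSE) {
  if (!"ci_width_bp" %in% names(qtls)) {
    qtls$ci_width_bp <- qtls$end - qtls$start + 1
  }
  qtls <- dplyr::filter(qtls, .data$ci_width_bp < max_ci_bp)
  out <- overlap_pairs(regions, qtls, min_frac, region_ids(regions))
  if (reciprocal && nrow(out) > 0) {
    w <- (qtls$end - qtls$start + 1)[match(out$feature, qtls$name)]
    out <- dplyr::filter(out, .data$overlap_bp / w >= min_frac)
  }
  out
}
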