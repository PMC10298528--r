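#' @keywords internal
deletion_states <- c("CN0", "CN1")

#' @keywords internal
duplication_states <- c("CN3", "CN4")

cn_class_labels <- c(
  CN0 = "homozygous_deletion",
  CN1 = "hemizygous_deletion",
  CN3 = "duplication",
  CN4 = "triplication"
)

assert_calls <- function(calls) {
  needed <- c("sample", "chrom", "start", "end", "cn", "num_snps")
  missing <- setdiff(needed, names(calls))
  if (length(missing)) {
    stop("call table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(calls$start > calls$end)) stop("calls with start > end", call. = FALSE)
  bad <- setdiff(unique(calls$cn), names(cn_class_labels))
  if (length(bad)) {
    stop("unknown copy-number class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(calls)
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Per-sample quality control
#'
#' Applies the array-signal quality thresholds used for CNV call sets:
#' a sample passes iff the standard deviation of the log R ratio is below 0.3,
#' B-allele-frequency drift is below 0.01, the waviness factor is below 0.05
#' (all strict), and its CNV call count does not exceed 100 (samples with more
#' than 100 calls indicate poor DNA quality and are removed).
#'
#' @param qc Data frame with columns `sample`, `lrr_sd`, `baf_drift`,
#'   `waviness`, `call_count`.
#' @param max_lrr_sd,max_baf_drift,max_waviness Strict upper bounds.
#' @param max_call_count Samples with `call_count` strictly above this fail.
#' @return A tibble with the input columns plus `pass` (logical) and `reasons`
#'   (comma-separated names of the violated thresholds, `""` when passing).
#' @export
filter_samples <- function(qc, max_lrr_sd = 0.3, max_baf_drift = 0.01,
                           max_waviness = 0.05, max_call_count = 100) {
  needed <- c("sample", "lrr_sd", "baf_drift", "waviness", "call_count")
  missing <- setdiff(needed, names(qc))
  if (length(missing)) {
    stop("QC table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (f in needed[-1]) {
    if (any(is.na(qc[[f]]))) {
      stop("missing QC metric `", f, "` for sample(s): ",
           paste(qc$sample[is.na(qc[[f]])], collapse = ", "), call. = FALSE)
    }
  }
  qc <- tibble::as_tibble(qc)
  fails <- cbind(
    lrr_sd = qc$lrr_sd >= max_lrr_sd,
    baf_drift = qc$baf_drift >= max_baf_drift,
    waviness = qc$waviness >= max_waviness,
    call_count = qc$call_count > max_call_count
  )
  qc$reasons <- apply(fails, 1, function(row) {
    paste(colnames(fails)[row], collapse = ",")
  })
  qc$pass <- qc$reasons == ""
  qc
}

#' Filter CNV calls by probe support and length
#'
#' Keeps calls supported by more than `min_snps_exclusive` consecutive SNPs and
#' spanning at least `min_len_bp` (length = end - start + 1, coordinates
#' 1-based inclusive).
#'
#' @param calls CNV call tibble (`sample`, `chrom`, `start`, `end`, `cn`,
#'   `num_snps`).
#' @param min_snps_exclusive Calls must have `num_snps` strictly greater than
#'   this. Default 3.
#' @param min_len_bp Minimum length in bp (inclusive). Default 1000.
#' @return The retained calls.
#' @export
filter_calls <- function(calls, min_snps_exclusive = 3, min_len_bp = 1000) {
  if (nrow(calls) == 0) return(tibble::as_tibble(calls))
  assert_calls(calls)
  dplyr::filter(tibble::as_tibble(calls),
                .data$num_snps > min_snps_exclusive,
                .data$end - .data$start + 1 >= min_len_bp)
}

#' Merge CNV calls into copy number variable regions (CNVRs)
#'
#' Forms, per chromosome, the union of call intervals: overlapping or
#' book-ended calls (gap 0 between 1-based inclusive intervals) are merged
#' into one region, the semantics of `bedtools merge` at distance 0. Each
#' region is classified `loss` (only deletion-class support), `gain` (only
#' duplication-class) or `mixed` (both).
#'
#' @param calls CNV call tibble.
#' @param n_samples Total number of samples for the carrier frequency
#'   denominator; defaults to the number of distinct samples in `calls`.
#' @return A tibble with `chrom`, `start`, `end`, `cnvr_class`, `n_calls`,
#'   `n_carriers` (distinct samples with an overlapping call) and
#'   `carrier_frequency`.
#' @export
merge_to_cnvrs <- function(calls, n_samples = dplyr::n_distinct(calls$sample)) {
  assert_calls(calls)
  if (nrow(calls) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), cnvr_class = character(),
                          n_calls = integer(), n_carriers = integer(),
                          carrier_frequency = double()))
  }
  calls <- dplyr::arrange(tibble::as_tibble(calls), .data$chrom, .data$start,
                          .data$end)
  calls |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      # new region whenever a call starts beyond the running max end + 1
      region = cumsum(.data$start >
                        dplyr::lag(cummax(as.numeric(.data$end)),
                                   default = -Inf) + 1)
    ) |>
    dplyr::group_by(.data$chrom, .data$region) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      cnvr_class = region_class(.data$cn),
      n_calls = dplyr::n(),
      n_carriers = dplyr::n_distinct(.data$sample),
      .groups = "drop"
    ) |>
    dplyr::mutate(carrier_frequency = .data$n_carriers / n_samples) |>
    dplyr::select(-"region") |>
    dplyr::arrange(.data$chrom, .data$start)
}

region_class <- function(cn) {
  has_del <- any(cn %in% deletion_states)
  has_dup <- any(cn %in% duplication_states)
  if (has_del && has_dup) "mixed" else if (has_del) "loss" else "gain"
}

#' Unique CNVs
#'
#' Collapses calls sharing identical coordinates across samples into unique
#' CNV loci, classed `deletion`, `duplication` or `mixed` according to the set
#' of copy-number classes observed at those exact coordinates.
#'
#' @param calls CNV call tibble.
#' @return A tibble with `chrom`, `start`, `end`, `unique_class`, `n_samples`.
#' @export
dedupe_unique <- function(calls) {
  assert_calls(calls)
  tibble::as_tibble(calls) |>
    dplyr::group_by(.data$chrom, .data$start, .data$end) |>
    dplyr::summarise(
      unique_class = {
        cls <- region_class(.data$cn)
        c(loss = "deletion", gain = "duplication", mixed = "mixed")[[cls]]
      },
      n_samples = dplyr::n_distinct(.data$sample),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Summarise a CNV call set
#'
#' Per-class counts, total lengths (Mb) and percentage frequencies of the
#' calls, together with CNVR and unique-CNV class counts. Percentages are
#' count / total x 100 rounded half-up to 2 decimals.
#'
#' @param calls CNV call tibble (post filtering).
#' @param cnvrs Optional output of [merge_to_cnvrs()].
#' @param uniques Optional output of [dedupe_unique()].
#' @return A list of class `cnv_summary` with tibbles `calls`, `cnvrs`,
#'   `uniques` and scalars `n_calls`, `n_cnvrs`, `n_unique`.
#' @export
summarize_cnvs <- function(calls, cnvrs = NULL, uniques = NULL) {
  assert_calls(calls)
  lvl <- names(cn_class_labels)
  call_tab <- tibble::as_tibble(calls) |>
    dplyr::mutate(cn = factor(.data$cn, levels = lvl)) |>
    dplyr::group_by(.data$cn, .drop = FALSE) |>
    dplyr::summarise(
      count = dplyr::n(),
      length_mb = sum(.data$end - .data$start + 1) / 1e6,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      class = unname(cn_class_labels[as.character(.data$cn)]),
      percent = if (sum(.data$count) > 0) {
        round_half_up(100 * .data$count / sum(.data$count))
      } else 0,
      .before = 1
    ) |>
    dplyr::select("class", "count", "length_mb", "percent")

  count_by <- function(tab, col, levels) {
    if (is.null(tab)) return(NULL)
    tab[[col]] <- factor(tab[[col]], levels = levels)
    dplyr::count(tab, .data[[col]], .drop = FALSE, name = "count")
  }
  structure(list(
    calls = call_tab,
    cnvrs = count_by(cnvrs, "cnvr_class", c("loss", "gain", "mixed")),
    uniques = count_by(uniques, "unique_class",
                       c("deletion", "duplication", "mixed")),
    n_calls = nrow(calls),
    n_cnvrs = if (is.null(cnvrs)) NA_integer_ else nrow(cnvrs),
    n_unique = if (is.null(uniques)) NA_integer_ else nrow(uniques)
  ), class = "cnv_summary")
}

#' @export
print.cnv_summary <- function(x, ...) {
  cat("CNV call set summary\n")
  cat("  calls:", x$n_calls, " CNVRs:", x$n_cnvrs, " unique CNVs:",
      x$n_unique, "\n")
  print(x$calls)
  invisible(x)
}

#' Call-set genotyping concordance
#'
#' Percentage of calls in `set_a` that have at least 1 bp of overlap with a
#' call of the same direction (deletion-class CN0/CN1 vs duplication-class
#' CN3/CN4) in the same sample in `set_b`.
#'
#' @param set_a,set_b CNV call tibbles.
#' @return A percentage in `[0, 100]`.
#' @export
call_concordance <- function(set_a, set_b) {
  assert_calls(set_a)
  assert_calls(set_b)
  if (nrow(set_a) == 0) {
    stop("concordance is undefined for an empty query set", call. = FALSE)
  }
  dir_of <- function(cn) ifelse(cn %in% deletion_states, "del", "dup")
  a <- dplyr::mutate(tibble::as_tibble(set_a), dir = dir_of(.data$cn),
                     .row = dplyr::row_number())
  b <- dplyr::mutate(tibble::as_tibble(set_b), dir = dir_of(.data$cn))
  hits <- dplyr::inner_join(
    a, b,
    by = c("sample", "chrom", "dir"), suffix = c("", ".b"),
    relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$start <= .data$end.b, .data$end >= .data$start.b) |>
    dplyr::distinct(.data$.row)
  100 * nrow(hits) / nrow(a)
}
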