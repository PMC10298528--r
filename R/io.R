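#' Read a PennCNV-style CNV call table
#'
#' Expects a TSV with columns `sample`, `chrom`, `start`, `end`, `cn`,
#' `num_snps` (coordinates 1-based inclusive; `cn` one of CN0/CN1/CN3/CN4).
#'
#' @param path File path.
#' @return A validated call tibble.
#' @export
read_cnv_calls <- function(path) {
  calls <- readr::read_tsv(path, show_col_types = FALSE)
  assert_calls(calls)
  calls
}

#' Write a CNV call table
#' @param calls Call tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(calls, path) {
  assert_calls(calls)
  readr::write_tsv(calls, path)
  invisible(path)
}

#' Read a probe map
#'
#' TSV with columns `probe`, `chrom`, `position` (1-based bp). Probes are
#' sorted by chromosome and position; duplicated positions within a
#' chromosome are an error.
#'
#' @param path File path.
#' @return A probe map tibble.
#' @export
read_probe_map <- function(path) {
  probes <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("probe", "chrom", "position") %in% names(probes)))
  probes <- dplyr::arrange(probes, .data$chrom, .data$position)
  dup <- duplicated(probes[, c("chrom", "position")])
  if (any(dup)) stop("duplicated probe positions within a chromosome",
                     call. = FALSE)
  probes
}

#' Read a site-by-variable climate table
#' @param path File path to a TSV with a `site` column plus numeric variables.
#' @return A tibble.
#' @export
read_climate <- function(path) {
  climate <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot("site" %in% names(climate))
  num <- dplyr::select(climate, -"site")
  if (anyNA(num)) stop("climate table contains missing values", call. = FALSE)
  climate
}

#' Write intervals as BED
#'
#' Converts internal 1-based inclusive coordinates to BED's 0-based half-open
#' convention.
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  bed <- tibble::tibble(chrom = x$chrom,
                        start = as.integer(x$start - 1L),
                        end = as.integer(x$end),
                        name = if ("name" %in% names(x)) x$name else ".")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read feature intervals from GFF3 or BED
#'
#' Both readers normalise to the package's internal 1-based inclusive
#' convention (GFF3 is already 1-based; BED's 0-based half-open starts are
#' shifted by +1). Parsing is delegated to `rtracklayer::import()`.
#'
#' @param path File path.
#' @param kind Feature kind label to attach (`"gene"` or `"QTL"`).
#' @return A tibble with `name`, `chrom`, `start`, `end`, `kind`.
#' @export
read_features_gff <- function(path, kind = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  granges_to_features(gr, kind)
}

#' @rdname read_features_gff
#' @export
read_features_bed <- function(path, kind = "gene") {
  gr <- rtracklayer::import(path, format = "bed")
  granges_to_features(gr, kind)
}

granges_to_features <- function(gr, kind) {
  md <- S4Vectors::mcols(gr)
  name <- if ("Name" %in% names(md)) as.character(md$Name)
          else if ("name" %in% names(md)) as.character(md$name)
          else if ("ID" %in% names(md)) as.character(md$ID)
          else sprintf("feat%04d", seq_along(gr))
  tibble::tibble(
    name = name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    kind = kind
  )
}
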