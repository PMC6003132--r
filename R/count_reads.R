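#' Count usable reads per genomic bin
#'
#' Tallies uniquely mapped reads into the bins of a bin map. "Uniquely mapped"
#' is operationalized as: mapped, primary (not secondary or supplementary),
#' not duplicate-flagged, and mapping quality at least `min_mapq`. Each
#' retained read increments the single bin containing its leftmost aligned
#' base. Excluded reads are tallied by reason in a filter report.
#'
#' @param alignments a BAM or SAM file path, or (mostly for testing) a data
#'   frame with columns `chrom`, `pos` (1-based leftmost position), `mapq`,
#'   and `flag`.
#' @param bin_map bin map tibble from [build_bin_map()].
#' @param min_mapq minimum mapping quality for a read to count. Default 30.
#' @param sample_id label stored on the result; defaults to the file name.
#' @return A `cia_counts` tibble: the bin map columns plus `count`, with
#'   attributes `sample_id`, `total_usable_reads` and `filter_report` (a
#'   tibble of reason/n for excluded reads). Use [filter_report()] to
#'   retrieve the report.
#' @export
count_reads <- function(alignments, bin_map, min_mapq = 30, sample_id = NULL) {
  assert_bin_map(bin_map)
  if (is.character(alignments) && length(alignments) == 1) {
    if (is.null(sample_id)) {
      sample_id <- sub("\\.(bam|sam)$", "", basename(alignments), ignore.case = TRUE)
    }
    alignments <- read_alignment_records(alignments)
  }
  if (!is.data.frame(alignments)) {
    abort("alignments must be a BAM/SAM path or a data frame of records")
  }
  if (is.null(sample_id)) sample_id <- "sample"

  flag <- as.integer(alignments$flag)
  reason <- rep(NA_character_, nrow(alignments))
  take <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  take(bitwAnd(flag, 4L) > 0L, "unmapped")
  take(bitwAnd(flag, 256L) > 0L, "secondary")
  take(bitwAnd(flag, 2048L) > 0L, "supplementary")
  take(bitwAnd(flag, 1024L) > 0L, "duplicate")
  take(is.na(alignments$mapq) | alignments$mapq < min_mapq, "low_mapq")

  kept_chroms <- alignments$chrom[is.na(reason)]
  if (length(kept_chroms) > 0) check_dialect(kept_chroms, unique(bin_map$chrom))
  take(!alignments$chrom %in% bin_map$chrom, "unknown_chrom")

  keep <- is.na(reason)
  bin_size <- attr(bin_map, "bin_size") %||% 1e6

  # bins tile each chromosome contiguously from 0, so the bin index is pure
  # position arithmetic: floor(pos0 / bin_size), offset by the chromosome start row
  map_chroms <- unique(bin_map$chrom)
  first_row <- match(map_chroms, bin_map$chrom)
  offset <- setNames(first_row - 1L, map_chroms)
  idx <- offset[alignments$chrom[keep]] +
    floor((alignments$pos[keep] - 1) / bin_size) + 1L

  counts <- tabulate(idx, nbins = nrow(bin_map))
  tab <- table(reason[!keep])
  report <- tibble(reason = as.character(names(tab)), n = as.integer(tab))

  out <- bin_map
  out$count <- as.integer(counts)
  structure(as_tibble(out),
    sample_id = sample_id,
    total_usable_reads = sum(counts),
    filter_report = as_tibble(report),
    bin_size = bin_size,
    class = c("cia_counts", "tbl_df", "tbl", "data.frame")
  )
}

read_alignment_records <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path,
      destination = tempfile(), overwrite = TRUE,
      indexDestination = FALSE
    )
  }
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "mapq", "flag"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  tibble(
    chrom = as.character(b$rname), pos = b$pos,
    mapq = b$mapq, flag = b$flag
  )
}

#' @rdname count_reads
#' @param counts a `cia_counts` object.
#' @export
filter_report <- function(counts) {
  attr(counts, "filter_report") %||% tibble(reason = character(), n = integer())
}

#' Read / write per-bin count tables
#'
#' Counts on disk are TSV with header `chrom, start, end, count`.
#'
#' @param counts `cia_counts` tibble.
#' @param path file path.
#' @param bin_map optional bin map to re-attach `gc`/`usable` on read.
#' @param sample_id sample label; defaults to the file name.
#' @return `read_counts()` returns a `cia_counts` tibble.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts[, c("chrom", "start", "end", "count")], path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, bin_map = NULL, sample_id = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("chrom", "start", "end", "count") %in% names(raw))) {
    abort(sprintf("%s is not a count table (need columns chrom, start, end, count)", path))
  }
  if (!is.null(bin_map)) {
    assert_bin_aligned(raw, bin_map, "count table and bin map")
    raw$gc <- bin_map$gc
    raw$usable <- bin_map$usable
  } else {
    if (!"gc" %in% names(raw)) raw$gc <- NA_real_
    if (!"usable" %in% names(raw)) raw$usable <- TRUE
  }
  structure(
    as_tibble(raw[, c("chrom", "start", "end", "gc", "usable", "count")]),
    sample_id = sample_id %||% sub("\\.tsv$", "", basename(path)),
    total_usable_reads = sum(raw$count),
    filter_report = tibble(reason = character(), n = integer()),
    bin_size = max(raw$end - raw$start),
    class = c("cia_counts", "tbl_df", "tbl", "data.frame")
  )
}

#' @export
print.cia_counts <- function(x, ...) {
  cat(sprintf(
    "<cia_counts> sample '%s': %s bins, %s usable reads\n",
    attr(x, "sample_id"), nrow(x),
    format(attr(x, "total_usable_reads"), big.mark = ",")
  ))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
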