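#' Build a fixed-width genomic bin map
#'
#' Tiles every chromosome of a genome into non-overlapping windows of
#' `bin_size` bases (default 1 Mb). The last window of a chromosome may be
#' shorter. When the genome is given as sequence (FASTA path or a
#' [Biostrings::DNAStringSet]), each bin's GC fraction is computed from the
#' sequence and bins with more than 50% ambiguous bases (N) are marked
#' unusable. A chromosome-sizes table yields a bin map without GC fractions;
#' such a map supports read counting but not GC normalization.
#'
#' @param genome one of: a path to a FASTA file; a `DNAStringSet`; a path to a
#'   two-column chromosome-sizes TSV (`chrom`, `length`, with header); or a
#'   data frame with columns `chrom` and `length`.
#' @param bin_size window width in bases. Default 1,000,000.
#' @param genome_build label stored on the result (e.g. `"hg19"`).
#' @return A tibble with one row per bin and columns `chrom`, `start`
#'   (0-based, inclusive), `end` (exclusive), `gc` (fraction in `[0,1]`, `NA`
#'   without sequence), and `usable`. Bins are ordered by chromosome then
#'   position; attributes `bin_size` and `genome_build` are set.
#' @examples
#' sizes <- tibble::tibble(chrom = "chr1", length = 2500000)
#' build_bin_map(sizes)
#' @export
build_bin_map <- function(genome, bin_size = 1e6, genome_build = NULL) {
  if (bin_size <= 0) abort("bin_size must be positive")

  if (is.character(genome) && length(genome) == 1) {
    if (looks_like_fasta(genome)) {
      genome <- Biostrings::readDNAStringSet(genome)
    } else {
      genome <- readr::read_tsv(genome, show_col_types = FALSE)
    }
  }

  if (methods::is(genome, "DNAStringSet")) {
    # FASTA headers may carry descriptions after the name
    names(genome) <- sub("\\s.*$", "", names(genome))
    sizes <- tibble(chrom = names(genome), length = Biostrings::width(genome))
    seqs <- genome
  } else if (is.data.frame(genome)) {
    if (!all(c("chrom", "length") %in% names(genome))) {
      abort("chromosome-sizes table needs columns 'chrom' and 'length'")
    }
    sizes <- as_tibble(genome[, c("chrom", "length")])
    seqs <- NULL
  } else {
    abort("genome must be a FASTA path, DNAStringSet, chrom-sizes path, or data frame")
  }
  if (nrow(sizes) == 0) abort("genome lists no chromosomes")
  if (any(sizes$length <= 0)) abort("all chromosome lengths must be positive")

  bins <- purrr::pmap_dfr(sizes, function(chrom, length) {
    starts <- seq(0, length - 1, by = bin_size)
    tibble(chrom = chrom, start = starts, end = pmin(starts + bin_size, length))
  })

  if (!is.null(seqs)) {
    freq <- purrr::map_dfr(split(bins, factor(bins$chrom, levels = sizes$chrom)), function(b) {
      v <- Biostrings::Views(seqs[[b$chrom[[1]]]], start = b$start + 1, end = b$end)
      f <- Biostrings::letterFrequency(v, letters = c("G", "C", "A", "T"))
      acgt <- rowSums(f)
      tibble(
        gc = ifelse(acgt > 0, (f[, "G"] + f[, "C"]) / acgt, NA_real_),
        n_frac = 1 - acgt / (b$end - b$start)
      )
    })
    bins$gc <- freq$gc
    bins$usable <- freq$n_frac <= 0.5 & !is.na(freq$gc)
  } else {
    bins$gc <- NA_real_
    bins$usable <- TRUE
  }

  structure(bins,
    bin_size = bin_size, genome_build = genome_build,
    class = c("cia_bin_map", class(bins))
  )
}

looks_like_fasta <- function(path) {
  first <- readLines(path, n = 1)
  length(first) == 1 && startsWith(first, ">")
}

#' Packaged hg19 chromosome sizes
#'
#' Lengths of the 24 hg19 chromosomes, for building an hg19-scale bin map
#' without the reference sequence (no GC fractions).
#'
#' @return tibble with columns `chrom`, `length`.
#' @export
hg19_chrom_sizes <- function() {
  readr::read_tsv(
    system.file("extdata", "hg19.chrom.sizes.tsv", package = "ciascore"),
    show_col_types = FALSE
  )
}

#' Read / write a bin map as BED
#'
#' On disk a bin map is BED-like: tab-separated, no header, columns
#' `chrom, start, end, name, gc, usable` (gc `.` when absent).
#'
#' @param bin_map a bin map tibble from [build_bin_map()].
#' @param path file path.
#' @return `write_bin_map()` returns `path` invisibly; `read_bin_map()`
#'   returns a bin map tibble.
#' @export
write_bin_map <- function(bin_map, path) {
  assert_bin_map(bin_map)
  out <- tibble(
    chrom = bin_map$chrom, start = bin_map$start, end = bin_map$end,
    name = paste0("bin_", seq_len(nrow(bin_map))),
    gc = ifelse(is.na(bin_map$gc), ".", format(bin_map$gc, digits = 6, trim = TRUE)),
    usable = as.integer(bin_map$usable)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bin_map
#' @export
read_bin_map <- function(path) {
  raw <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "gc", "usable"),
    col_types = "ciicci", show_col_types = FALSE
  )
  bins <- tibble(
    chrom = raw$chrom, start = as.numeric(raw$start), end = as.numeric(raw$end),
    gc = suppressWarnings(as.numeric(ifelse(raw$gc == ".", NA, raw$gc))),
    usable = as.logical(raw$usable)
  )
  sizes <- unique(bins$end - bins$start)
  structure(bins,
    bin_size = max(sizes), genome_build = NULL,
    class = c("cia_bin_map", class(bins))
  )
}
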