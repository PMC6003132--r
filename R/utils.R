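# internal helpers shared across modules

SEX_CHROMS <- c("X", "Y", "chrX", "chrY")

is_sex_chrom <- function(chrom) chrom %in% SEX_CHROMS

strip_chr <- function(x) sub("^chr", "", x)

# "chr1" vs "1" naming must agree between alignments and the bin map
chrom_dialect <- function(chroms) {
  if (all(grepl("^chr", chroms))) "chr-prefixed" else "bare"
}

check_dialect <- function(aln_chroms, map_chroms) {
  aln <- unique(aln_chroms)
  hits <- aln %in% map_chroms
  if (any(hits)) {
    return(invisible(TRUE))
  }
  # none match: if stripping the prefix would reconcile them, it is a dialect clash
  if (any(strip_chr(aln) %in% strip_chr(map_chroms))) {
    abort(sprintf(
      "Chromosome naming mismatch: alignments use the %s dialect (e.g. '%s') but the bin map uses the %s dialect (e.g. '%s'). Rename one of the two.",
      chrom_dialect(aln), aln[[1]], chrom_dialect(map_chroms), map_chroms[[1]]
    ))
  }
  invisible(TRUE)
}

assert_bin_map <- function(bin_map, require_gc = FALSE) {
  need <- c("chrom", "start", "end")
  missing <- setdiff(need, names(bin_map))
  if (length(missing) > 0) {
    abort(paste0("bin map is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (require_gc && (!"gc" %in% names(bin_map) || all(is.na(bin_map$gc)))) {
    abort(paste(
      "bin map has no GC fractions; GC normalization needs them.",
      "Rebuild the bin map from a genome FASTA (build_bin_map(<fasta>))",
      "rather than from a chromosome-sizes table."
    ))
  }
  invisible(bin_map)
}

# same bins, same order
assert_bin_aligned <- function(a, b, what = "profiles") {
  if (nrow(a) != nrow(b) ||
      !identical(a$chrom, b$chrom) ||
      !identical(as.numeric(a$start), as.numeric(b$start))) {
    abort(paste0("bin maps of the ", what, " do not match (different bins or bin order)"))
  }
  invisible(TRUE)
}

# cumulative genome coordinate for whole-genome plots
genome_position <- function(df) {
  lens <- df |>
    group_by(chrom = factor(.data$chrom, levels = unique(.data$chrom))) |>
    summarise(len = max(.data$end), .groups = "drop")
  offset <- setNames(cumsum(c(0, head(lens$len, -1))), as.character(lens$chrom))
  df$genome_pos <- offset[df$chrom] + (df$start + df$end) / 2
  attr(df, "chrom_offsets") <- offset
  df
}

fmt_pct <- function(x) ifelse(is.na(x), "--", sprintf("%.1f%%", 100 * x))

# sub-seed derivation: keeps every stream tied to one user seed, < 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) * 7919L + as.integer(k) * 104729L) %% 2147483629L
}
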