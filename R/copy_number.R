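#' GC-bias correction of bin counts
#'
#' Removes the dependence of read depth on window GC content. A smooth curve
#' `f(gc)` is fitted to count versus GC fraction over usable bins (loess,
#' `span = 0.3`); each bin's corrected depth is
#' `count / f(gc) * median(count over usable bins)`, so the corrected profile
#' keeps the scale of the raw one. With fewer than 100 usable bins the loess
#' fit is replaced by a median-within-GC-decile step function; below that
#' size a local fit is unstable, while a step function cannot flatten smooth
#' trends on larger genomes.
#'
#' @param counts `cia_counts` tibble from [count_reads()] / [read_counts()] /
#'   [simulate_profile()]. Bins must carry GC fractions.
#' @param bin_map optional bin map supplying `gc`/`usable` when `counts`
#'   lacks them.
#' @param span loess span for the GC curve.
#' @return A `cia_depth` tibble: bin columns plus `depth` (GC-corrected,
#'   `NA` on unusable bins), carrying the sample id.
#' @export
gc_normalize <- function(counts, bin_map = NULL, span = 0.3) {
  if (!is.null(bin_map)) {
    assert_bin_map(bin_map, require_gc = TRUE)
    assert_bin_aligned(counts, bin_map, "counts and bin map")
    counts$gc <- bin_map$gc
    counts$usable <- bin_map$usable
  }
  assert_bin_map(counts, require_gc = TRUE)
  usable <- counts$usable & !is.na(counts$gc)
  if (sum(usable) < 50) abort("need at least 50 usable bins with GC fractions")
  cnt <- counts$count
  if (all(cnt[usable] == 0)) abort("all usable bin counts are zero")

  gc <- counts$gc
  if (sum(usable) < 100) {
    # decile medians: piecewise-constant GC response
    br <- unique(quantile(gc[usable], probs = seq(0, 1, 0.1), names = FALSE))
    dec <- cut(gc, breaks = br, include.lowest = TRUE)
    med <- tapply(cnt[usable], dec[usable], median)
    f <- as.numeric(med[dec])
    # bins outside the usable GC range fall back to the global median
    f[is.na(f)] <- median(cnt[usable])
  } else {
    fit <- loess(count ~ gc, data = counts[usable, ], span = span,
                 degree = 2, family = "symmetric")
    f <- predict(fit, newdata = tibble(gc = gc))
    rng <- range(gc[usable])
    f[gc < rng[1]] <- predict(fit, newdata = tibble(gc = rng[1]))
    f[gc > rng[2]] <- predict(fit, newdata = tibble(gc = rng[2]))
  }
  f <- pmax(as.numeric(f), 1e-8)
  depth <- as.numeric(cnt / f * median(cnt[usable]))
  depth[!usable] <- NA_real_

  out <- counts[, c("chrom", "start", "end", "gc", "usable")]
  out$depth <- depth
  structure(as_tibble(out),
    sample_id = attr(counts, "sample_id") %||% "sample",
    class = c("cia_depth", "tbl_df", "tbl", "data.frame")
  )
}

#' Build a panel-of-normals reference profile
#'
#' Combines GC-corrected depth profiles of presumed-diploid samples into a
#' per-bin expected relative depth. Each panel profile is scaled to its own
#' median over usable bins; the reference is the per-bin median across the
#' scaled panel. Bins where the reference is below 0.1, or where the panel
#' coefficient of variation exceeds 0.5, are masked unusable (they reflect
#' unmappable or unstable regions, not copy number).
#'
#' @param panel a list of `cia_depth` tibbles from [gc_normalize()], all on
#'   the same bin map. A single-sample panel works but gives a noisier
#'   reference.
#' @param min_reference mask threshold on the reference value.
#' @param max_cv mask threshold on the across-panel coefficient of variation
#'   (ignored for single-sample panels).
#' @return A `cia_reference` tibble: bin columns plus `reference` and the
#'   updated `usable` mask.
#' @export
build_reference <- function(panel, min_reference = 0.1, max_cv = 0.5) {
  if (inherits(panel, "data.frame")) panel <- list(panel)
  if (length(panel) < 1) abort("panel must contain at least one profile")
  base <- panel[[1]]
  for (p in panel[-1]) assert_bin_aligned(base, p, "panel profiles")

  scaled <- vapply(panel, function(p) {
    m <- median(p$depth[p$usable], na.rm = TRUE)
    if (!is.finite(m) || m <= 0) abort("a panel profile has non-positive median depth")
    p$depth / m
  }, numeric(nrow(base)))
  scaled <- matrix(scaled, nrow = nrow(base))

  ref <- unname(apply(scaled, 1, median))
  usable <- base$usable & is.finite(ref) & ref >= min_reference
  if (length(panel) > 1) {
    cv <- apply(scaled, 1, function(x) {
      m <- mean(x)
      if (!is.finite(m) || m == 0) return(Inf)
      stats::sd(x) / m
    })
    usable <- usable & cv <= max_cv
  }

  out <- base[, c("chrom", "start", "end", "gc")]
  out$reference <- ifelse(usable, ref, NA_real_)
  out$usable <- usable
  structure(as_tibble(out),
    n_panel = length(panel),
    class = c("cia_reference", "tbl_df", "tbl", "data.frame")
  )
}

#' A flat pseudo-reference
#'
#' All-ones reference for running the pipeline without a panel of normals.
#' Locus-specific biases are then NOT cancelled; a warning says so.
#'
#' @param bin_map bin map tibble.
#' @return `cia_reference` tibble with `reference = 1` on usable bins.
#' @export
flat_reference <- function(bin_map) {
  assert_bin_map(bin_map)
  warn("using a flat pseudo-reference: per-bin mappability/amplification bias is not cancelled")
  out <- bin_map[, c("chrom", "start", "end", "gc")]
  out$reference <- ifelse(bin_map$usable, 1, NA_real_)
  out$usable <- bin_map$usable
  structure(as_tibble(out),
    n_panel = 0L,
    class = c("cia_reference", "tbl_df", "tbl", "data.frame")
  )
}

#' Relative copy number per bin
#'
#' Converts GC-corrected depth to the relative copy number `xi` with diploid
#' expectation 2: `xi = 2 * (depth / median depth) / reference` per usable
#' bin, then recentred so the median over usable autosomal bins is exactly 2.
#' Unusable bins get `NA` and are excluded from all downstream computation.
#'
#' @param depth `cia_depth` tibble from [gc_normalize()].
#' @param reference `cia_reference` from [build_reference()] or
#'   [flat_reference()].
#' @return A `cia_copy_number` tibble: bin columns plus `xi`.
#' @export
to_copy_number <- function(depth, reference) {
  assert_bin_aligned(depth, reference, "sample and reference")
  usable <- depth$usable & reference$usable & !is.na(depth$depth)
  if (sum(usable) < 50) abort("reference and sample share fewer than 50 usable bins")
  m <- median(depth$depth[usable])
  if (!is.finite(m) || m <= 0) abort("sample median depth is zero; cannot scale")

  xi <- rep(NA_real_, nrow(depth))
  xi[usable] <- 2 * (depth$depth[usable] / m) / reference$reference[usable]

  auto <- usable & !is_sex_chrom(depth$chrom)
  centre <- if (any(auto)) median(xi[auto]) else median(xi[usable])
  if (centre > 0) xi <- xi * 2 / centre

  out <- depth[, c("chrom", "start", "end", "gc")]
  out$usable <- usable
  out$xi <- xi
  structure(as_tibble(out),
    sample_id = attr(depth, "sample_id") %||% "sample",
    class = c("cia_copy_number", "tbl_df", "tbl", "data.frame")
  )
}

#' Read / write per-bin value profiles
#'
#' Reference and copy-number profiles on disk are TSV with header
#' `chrom, start, end, value, usable`.
#'
#' @param profile a `cia_reference` or `cia_copy_number` tibble.
#' @param path file path.
#' @param value which column holds the value.
#' @export
write_profile <- function(profile, path,
                          value = intersect(c("xi", "reference", "depth"), names(profile))[1]) {
  out <- tibble(
    chrom = profile$chrom, start = profile$start, end = profile$end,
    value = signif(profile[[value]], 6), usable = as.integer(profile$usable)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_reference <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("chrom", "start", "end", "value", "usable") %in% names(raw))) {
    abort(sprintf("%s is not a profile table (need chrom, start, end, value, usable)", path))
  }
  out <- tibble(
    chrom = raw$chrom, start = as.numeric(raw$start), end = as.numeric(raw$end),
    gc = NA_real_, reference = ifelse(raw$usable == 1, raw$value, NA_real_),
    usable = as.logical(raw$usable)
  )
  structure(out, n_panel = NA_integer_,
    class = c("cia_reference", "tbl_df", "tbl", "data.frame")
  )
}
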