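#' Per-bin Z deviation values
#'
#' The Z value of a bin measures its deviation from the diploid state:
#' `Z = sqrt(|log2(xi / 2)|)`. It is 0 exactly at `xi = 2` and 1 at a full
#' single-copy gain (`xi = 4`) or loss (`xi = 1`); the square root compresses
#' large deviations so the score is not dominated by a few extreme bins.
#'
#' @param cn `cia_copy_number` tibble from [to_copy_number()].
#' @return A `cia_z` tibble: bin columns plus `xi` and `z` (`NA` on unusable
#'   bins).
#' @export
z_transform <- function(cn) {
  if (!"xi" %in% names(cn)) abort("expected a copy-number profile with an 'xi' column")
  bad <- which(cn$usable & (!is.finite(cn$xi) | cn$xi <= 0))
  if (length(bad) > 0) {
    abort(sprintf(
      "xi must be positive on usable bins; first offending bin: %s:%d-%d (xi = %s)",
      cn$chrom[bad[1]], cn$start[bad[1]], cn$end[bad[1]], format(cn$xi[bad[1]])
    ))
  }
  out <- cn
  out$z <- ifelse(cn$usable, sqrt(abs(log2(cn$xi / 2))), NA_real_)
  structure(as_tibble(out),
    sample_id = attr(cn, "sample_id") %||% "sample",
    class = c("cia_z", "tbl_df", "tbl", "data.frame")
  )
}

#' The CIA score
#'
#' Summarizes genome-wide chromosomal imbalance as a single number: usable
#' bins are ranked ascending by Z (ties broken by genomic order) and the
#' score is the sum of Z over the bins ranked between the m-th and p-th
#' percentile (1-based ranks `ceil(m/100 * N)` through `floor(p/100 * N)`,
#' inclusive; defaults m = 95, p = 99). The window targets the most deviant
#' bins while excluding the extreme top 1%, which is dominated by outlier
#' bins rather than genuine copy-number events. Sex chromosomes are excluded
#' by default because mixed-sex cohorts would read X dosage as imbalance.
#'
#' @param z a `cia_z` tibble from [z_transform()], or a `cia_copy_number`
#'   (transformed on the fly).
#' @param m,p lower / upper percentile of the rank window, `0 <= m < p <= 100`.
#' @param cutoff score threshold for the binary call; a sample is positive
#'   when its score is strictly above the cutoff. Default 24.
#' @param include_sex_chroms keep X/Y bins in the ranking (only sensible for
#'   same-sex panels). Default `FALSE`.
#' @return A `cia_result` object with fields `sample_id`, `score`, `m`, `p`,
#'   `cutoff`, `call` (`"positive"`/`"negative"`), `n_usable_bins`, and
#'   `window_bins` (tibble of the summed bins). [glance()] gives a one-row
#'   tibble, [tidy()] the window bins.
#' @examples
#' bm <- simulate_bin_map(seed = 1)
#' cnt <- simulate_profile(bm, tumour_fraction = 0, seed = 1)
#' cn <- to_copy_number(gc_normalize(cnt), build_reference(gc_normalize(cnt)))
#' cia_score(cn)
#' @export
cia_score <- function(z, m = 95, p = 99, cutoff = 24, include_sex_chroms = FALSE) {
  if (!"z" %in% names(z)) z <- z_transform(z)
  if (!(m >= 0 && p <= 100 && m < p)) abort("percentiles must satisfy 0 <= m < p <= 100")

  keep <- z$usable & !is.na(z$z)
  if (!include_sex_chroms) keep <- keep & !is_sex_chrom(z$chrom)
  zz <- z[keep, ]
  N <- nrow(zz)
  if (N < 100) {
    abort(sprintf("percentile window needs at least 100 usable bins; have %d", N))
  }

  ord <- order(zz$z) # stable: ties stay in genomic order
  lo <- max(1, ceiling(m / 100 * N))
  hi <- floor(p / 100 * N)
  window <- zz[ord[seq(lo, hi)], ]
  score <- sum(window$z)

  structure(
    list(
      sample_id = attr(z, "sample_id") %||% "sample",
      score = score, m = m, p = p, cutoff = cutoff,
      call = if (score > cutoff) "positive" else "negative",
      n_usable_bins = N,
      window_bins = as_tibble(window[, c("chrom", "start", "end", "xi", "z")])
    ),
    class = "cia_result"
  )
}

#' Classify a CIA score against a cutoff
#'
#' Positive if and only if the score is strictly above the cutoff.
#'
#' @param result a `cia_result`, or a bare numeric score.
#' @param cutoff decision threshold. Default 24.
#' @return For a `cia_result`, the result with `cutoff`/`call` updated;
#'   for a numeric vector, a character vector of calls.
#' @export
classify <- function(result, cutoff = 24) {
  if (!is.finite(cutoff)) abort("cutoff must be finite")
  if (is.numeric(result)) {
    return(if_else(result > cutoff, "positive", "negative"))
  }
  if (!inherits(result, "cia_result")) abort("result must be a cia_result or numeric")
  result$cutoff <- cutoff
  result$call <- if (result$score > cutoff) "positive" else "negative"
  result
}

#' @export
print.cia_result <- function(x, ...) {
  cat(sprintf(
    "<cia_result> sample '%s'\n  CIA score %.3f over %d bins (ranks %g%%-%g%% of %d usable bins)\n  call: %s (cutoff %g, strictly-above rule)\n",
    x$sample_id, x$score, nrow(x$window_bins), x$m, x$p, x$n_usable_bins,
    x$call, x$cutoff
  ))
  invisible(x)
}

#' @method glance cia_result
#' @export
glance.cia_result <- function(x, ...) {
  tibble(
    sample_id = x$sample_id, score = x$score, m = x$m, p = x$p,
    cutoff = x$cutoff, call = x$call, n_usable_bins = x$n_usable_bins,
    n_window_bins = nrow(x$window_bins)
  )
}

#' @method tidy cia_result
#' @export
tidy.cia_result <- function(x, ...) x$window_bins

#' Serialize a CIA result to JSON
#'
#' @param result `cia_result` object.
#' @param path file path.
#' @export
write_cia_result <- function(result, path) {
  jsonlite::write_json(
    list(
      sample_id = result$sample_id, score = result$score,
      m = result$m, p = result$p, cutoff = result$cutoff, call = result$call,
      n_usable_bins = result$n_usable_bins
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Score a raw count profile end to end
#'
#' Convenience wrapper: GC-normalize, divide by the reference, Z-transform,
#' and score. Equivalent to the explicit
#' `gc_normalize() |> to_copy_number() |> cia_score()` chain.
#'
#' @param counts `cia_counts` tibble.
#' @param reference `cia_reference`.
#' @inheritParams cia_score
#' @return `cia_result`.
#' @export
score_sample <- function(counts, reference, m = 95, p = 99, cutoff = 24,
                         include_sex_chroms = FALSE) {
  cn <- to_copy_number(gc_normalize(counts), reference)
  cia_score(cn, m = m, p = p, cutoff = cutoff, include_sex_chroms = include_sex_chroms)
}
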