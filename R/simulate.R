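#' Synthetic bin maps
#'
#' A toy genome for fast tests (default: 10 chromosomes of 30 Mb, i.e. 300
#' 1-Mb bins) or an hg19-scale map built from a chromosome-sizes table. GC
#' fractions are drawn from a Beta distribution matching the human 1-Mb
#' landscape (mean ~0.41, sd ~0.05); real sequence is not needed because the
#' pipeline only consumes the per-bin GC value.
#'
#' @param n_chroms,chrom_length toy-genome shape (ignored when `chrom_sizes`
#'   is given).
#' @param bin_size bin width in bases.
#' @param chrom_sizes optional tibble (`chrom`, `length`), e.g.
#'   [hg19_chrom_sizes()].
#' @param seed RNG seed for the GC draw.
#' @return a bin map tibble as from [build_bin_map()], all bins usable.
#' @export
simulate_bin_map <- function(n_chroms = 10, chrom_length = 3e7, bin_size = 1e6,
                             chrom_sizes = NULL, seed = 1) {
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tibble(
      chrom = paste0("chr", seq_len(n_chroms)),
      length = rep(chrom_length, n_chroms)
    )
  }
  bm <- build_bin_map(chrom_sizes, bin_size = bin_size, genome_build = "synthetic")
  bm$gc <- withr::with_seed(seed, stats::rbeta(nrow(bm), 39.3, 56.5))
  bm$usable <- TRUE
  bm
}

#' Simulate a raw bin-count profile
#'
#' Draws per-bin read counts with the structure the scoring method assumes:
#' the expected count is proportional to bin width times the mixture copy
#' number `(t * c + (1 - t) * 2) / 2` times a smooth GC response, scaled so
#' counts sum to about `total_reads`; noise is negative-binomial with
#' variance `dispersion` times the Poisson variance (Poisson at
#' `dispersion = 1`). Unusable bins get count 0. Identical arguments and
#' seed give identical counts.
#'
#' @param bin_map bin map tibble (e.g. [simulate_bin_map()]).
#' @param events copy-number events as a tibble with columns `chrom`,
#'   `start_bin`, `end_bin` (1-based inclusive per-chromosome bin indices)
#'   and `copy_number` (tumour-cell copies, > 0). `NULL` for a diploid
#'   profile.
#' @param tumour_fraction fraction of tumour-derived reads in `[0,1]`.
#' @param total_reads expected total usable reads. Default 5,000,000,
#'   matching shallow-WGS practice of ~5M reads per sample.
#' @param gc_bias either `c(peak, sd)` of a Gaussian-shaped library GC
#'   response (default peaks at GC 0.45), a function of the GC fraction, or
#'   `NULL` for no GC effect.
#' @param dispersion variance inflation over Poisson (>= 1). Default 1.3.
#' @param seed RNG seed.
#' @param sample_id label on the result.
#' @return `cia_counts` tibble (as from [count_reads()]); the true per-bin
#'   mixture copy number is attached as attribute `true_copy_number`.
#' @export
simulate_profile <- function(bin_map, events = NULL, tumour_fraction = 0,
                             total_reads = 5e6,
                             gc_bias = c(peak = 0.45, sd = 0.25),
                             dispersion = 1.3, seed = 1,
                             sample_id = "sim") {
  assert_bin_map(bin_map)
  if (total_reads <= 0) abort("total_reads must be positive")
  if (tumour_fraction < 0 || tumour_fraction > 1) {
    abort("tumour_fraction must be in [0, 1]")
  }
  if (dispersion < 1) abort("dispersion is a variance inflation factor; must be >= 1")

  cn <- rep(2, nrow(bin_map))
  if (!is.null(events) && nrow(events) > 0) {
    if (any(events$copy_number <= 0)) abort("event copy_number must be positive")
    for (i in seq_len(nrow(events))) {
      rows <- which(bin_map$chrom == events$chrom[i])
      if (length(rows) == 0) abort(sprintf("event chromosome '%s' not in bin map", events$chrom[i]))
      idx <- events$start_bin[i]:events$end_bin[i]
      if (min(idx) < 1 || max(idx) > length(rows)) {
        abort(sprintf("event bins %d-%d outside chromosome '%s' (%d bins)",
                      events$start_bin[i], events$end_bin[i], events$chrom[i], length(rows)))
      }
      cn[rows[idx]] <- events$copy_number[i]
    }
  }
  mix <- (tumour_fraction * cn + (1 - tumour_fraction) * 2) / 2

  resp <- gc_response(gc_bias)
  g <- if (is.null(resp)) rep(1, nrow(bin_map)) else resp(bin_map$gc)
  w <- (bin_map$end - bin_map$start) / max(bin_map$end - bin_map$start)
  mu <- w * mix * g
  mu[!bin_map$usable | !is.finite(mu)] <- 0
  mu <- mu / sum(mu) * total_reads

  counts <- withr::with_seed(seed, {
    if (dispersion == 1) {
      rpois(length(mu), lambda = mu)
    } else {
      size <- mu / (dispersion - 1)
      out <- integer(length(mu))
      pos <- mu > 0
      out[pos] <- rnbinom(sum(pos), mu = mu[pos], size = size[pos])
      out
    }
  })

  out <- bin_map[, c("chrom", "start", "end", "gc", "usable")]
  out$count <- as.integer(counts)
  structure(as_tibble(out),
    sample_id = sample_id,
    total_usable_reads = sum(counts),
    filter_report = tibble(reason = character(), n = integer()),
    bin_size = attr(bin_map, "bin_size") %||% max(out$end - out$start),
    true_copy_number = tumour_fraction * cn + (1 - tumour_fraction) * 2,
    class = c("cia_counts", "tbl_df", "tbl", "data.frame")
  )
}

gc_response <- function(gc_bias) {
  if (is.null(gc_bias)) return(NULL)
  if (is.function(gc_bias)) return(gc_bias)
  peak <- gc_bias[["peak"]]
  sd <- gc_bias[["sd"]]
  function(gc) exp(-0.5 * ((gc - peak) / sd)^2)
}

#' A random contiguous gain for cohort simulation
#'
#' Picks a run of `n_bins` consecutive autosomal bins (uniformly over start
#' positions, possibly spanning chromosome ends) and returns it as event
#' rows for [simulate_profile()].
#'
#' @param bin_map bin map tibble.
#' @param n_bins number of altered bins.
#' @param copy_number tumour-cell copy number over the run. Default 3
#'   (single-copy gain).
#' @return events tibble (`chrom`, `start_bin`, `end_bin`, `copy_number`).
#' @export
random_gain_events <- function(bin_map, n_bins, copy_number = 3) {
  auto <- bin_map[!is_sex_chrom(bin_map$chrom), ]
  if (n_bins > nrow(auto)) abort("event longer than the autosomal genome")
  auto <- auto |>
    group_by(.data$chrom) |>
    mutate(idx = row_number()) |>
    ungroup()
  start <- sample.int(nrow(auto) - n_bins + 1, 1)
  auto[start:(start + n_bins - 1), ] |>
    group_by(chrom = factor(.data$chrom, levels = unique(.data$chrom))) |>
    summarise(start_bin = min(.data$idx), end_bin = max(.data$idx), .groups = "drop") |>
    mutate(chrom = as.character(.data$chrom), copy_number = copy_number)
}

#' Simulate a labelled cohort and score it end to end
#'
#' Generates a panel of normals, diploid controls, and case samples carrying
#' a tumour-fraction-diluted copy-number gain; runs every sample through the
#' full pipeline (GC normalization, panel reference, relative copy number,
#' CIA score) and returns labelled scores plus the ground truth. The default
#' genome is hg19-scale (2,897 autosomal 1-Mb bins) so a 300-bin event is
#' ~10% of the genome.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param bin_map genome to simulate on; default hg19-scale synthetic map.
#' @param event_bins altered bins per case. Default 300 (>= 300 Mb).
#' @param event_copy_number tumour copy number over the event. Default 3.
#' @param tumour_fraction_range cases draw t ~ Uniform(min, max). Default
#'   `c(0.4, 0.9)`.
#' @param n_panel panel-of-normals size. Default 20.
#' @param total_reads,dispersion,gc_bias passed to [simulate_profile()].
#' @param m,p,cutoff scoring parameters, see [cia_score()].
#' @param seed master seed; every per-sample stream derives from it.
#' @return list with `scores` (tibble `sample_id`, `score`, `label`, `call`)
#'   and `truth` (tibble with the tumour fraction and event span per
#'   sample).
#' @export
simulate_cohort <- function(n_cases = 30, n_controls = 30, bin_map = NULL,
                            event_bins = 300, event_copy_number = 3,
                            tumour_fraction_range = c(0.4, 0.9),
                            n_panel = 20, total_reads = 5e6,
                            dispersion = 1.3,
                            gc_bias = c(peak = 0.45, sd = 0.25),
                            m = 95, p = 99, cutoff = 24, seed = 1) {
  if (n_cases < 1 || n_controls < 1) abort("need at least one case and one control")
  if (is.null(bin_map)) {
    bin_map <- simulate_bin_map(chrom_sizes = hg19_chrom_sizes(), seed = derive_seed(seed, 0))
  }

  panel <- purrr::map(seq_len(n_panel), function(i) {
    gc_normalize(simulate_profile(bin_map,
      total_reads = total_reads, dispersion = dispersion, gc_bias = gc_bias,
      seed = derive_seed(seed, i), sample_id = paste0("panel_", i)
    ))
  })
  reference <- build_reference(panel)

  one_sample <- function(id, label, k) {
    if (label == "case") {
      t <- withr::with_seed(derive_seed(seed, 1000 + k), {
        runif(1, tumour_fraction_range[1], tumour_fraction_range[2])
      })
      ev <- withr::with_seed(derive_seed(seed, 2000 + k), {
        random_gain_events(bin_map, event_bins, event_copy_number)
      })
    } else {
      t <- 0
      ev <- NULL
    }
    prof <- simulate_profile(bin_map,
      events = ev, tumour_fraction = t,
      total_reads = total_reads, dispersion = dispersion, gc_bias = gc_bias,
      seed = derive_seed(seed, 3000 + k), sample_id = id
    )
    res <- score_sample(prof, reference, m = m, p = p, cutoff = cutoff)
    list(
      score = tibble(sample_id = id, score = res$score, label = label, call = res$call),
      truth = tibble(
        sample_id = id, label = label, tumour_fraction = t,
        n_event_bins = if (is.null(ev)) 0L else as.integer(event_bins),
        event_copy_number = if (is.null(ev)) NA_real_ else event_copy_number
      )
    )
  }

  rows <- c(
    purrr::map(seq_len(n_cases), ~ one_sample(sprintf("case_%02d", .x), "case", .x)),
    purrr::map(seq_len(n_controls), ~ one_sample(sprintf("control_%02d", .x), "control", n_cases + .x))
  )
  list(
    scores = purrr::map_dfr(rows, "score"),
    truth = purrr::map_dfr(rows, "truth"),
    reference = reference
  )
}

#' Write simulated reads for a count profile as SAM
#'
#' Emits exactly `count` single-end reads per bin, placed uniformly at
#' random within the bin (mapq 60, flag 0, sequence omitted), so that
#' [count_reads()] on the output reproduces the profile exactly. Used for
#' end-to-end tests of the counting stage.
#'
#' @param profile `cia_counts` tibble.
#' @param path output `.sam` path.
#' @param read_length read length in bases; must not exceed the bin size.
#' @param seed RNG seed for read placement.
#' @return `path`, invisibly.
#' @export
simulate_alignments <- function(profile, path, read_length = 50, seed = 1) {
  widths <- profile$end - profile$start
  if (read_length > min(widths)) abort("read_length exceeds the smallest bin")

  chroms <- unique(profile$chrom)
  chrom_len <- vapply(chroms, function(ch) max(profile$end[profile$chrom == ch]), 0)
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(chrom_len))
  )

  body <- withr::with_seed(seed, {
    keep <- profile$count > 0
    purrr::pmap(profile[keep, c("chrom", "start", "end", "count")],
      function(chrom, start, end, count) {
        pos <- sort(start + sample.int(end - start - read_length + 1, count, replace = TRUE))
        sprintf(
          "read_%s_%d_%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
          chrom, start, seq_len(count), chrom, pos, read_length
        )
      }
    )
  })
  readr::write_lines(c(header, unlist(body)), path)
  invisible(path)
}
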