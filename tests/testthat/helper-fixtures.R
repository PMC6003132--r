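# shared fixtures, built in code at test time

toy_map <- function(seed = 1, n_chroms = 10, chrom_length = 3e7) {
  simulate_bin_map(n_chroms = n_chroms, chrom_length = chrom_length, seed = seed)
}

# a panel reference on the toy genome, memoised per (seed, n) within a run
toy_reference <- local({
  cache <- list()
  function(bm, seed = 900, n = 10, total_reads = 5e6) {
    key <- paste(seed, n, nrow(bm), total_reads)
    if (is.null(cache[[key]])) {
      panel <- lapply(seq_len(n), function(i) {
        gc_normalize(simulate_profile(bm, seed = seed + i, total_reads = total_reads,
                                      sample_id = paste0("panel", i)))
      })
      cache[[key]] <<- build_reference(panel)
    }
    cache[[key]]
  }
})

# hand-built alignment records for count_reads()
aln_record <- function(chrom, pos, mapq = 60, flag = 0L) {
  tibble::tibble(chrom = chrom, pos = pos, mapq = mapq, flag = as.integer(flag))
}

# independent AUC oracle: exhaustive case/control pair counting, ties = 1/2
auc_by_pairs <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  total <- 0
  for (a in cs) for (b in ct) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(cs) * length(ct))
}

# independent Fisher oracle: enumerate all r x c tables with the observed
# margins; p = sum of probabilities <= observed table probability
fisher_by_enumeration <- function(tab) {
  r <- rowSums(tab); c <- colSums(tab); n <- sum(tab)
  log_p <- function(m) {
    sum(lfactorial(r)) + sum(lfactorial(c)) - lfactorial(n) - sum(lfactorial(m))
  }
  obs <- log_p(tab)
  tables <- list(matrix(numeric(0), nrow = 0, ncol = ncol(tab)))
  # build row by row over all compositions respecting running column sums
  compositions <- function(total, k) {
    if (k == 1) return(matrix(total, ncol = 1))
    out <- NULL
    for (i in 0:total) out <- rbind(out, cbind(i, compositions(total - i, k - 1)))
    out
  }
  fill <- function(done, rows_left) {
    if (rows_left == 1) {
      last <- c - colSums(done)
      if (any(last < 0)) return(numeric(0))
      return(log_p(rbind(done, last)))
    }
    i <- nrow(done) + 1
    comp <- compositions(r[i], ncol(tab))
    ok <- apply(comp, 1, function(x) all(colSums(rbind(done, x)) <= c))
    unlist(lapply(which(ok), function(j) fill(rbind(done, comp[j, ]), rows_left - 1)))
  }
  lp <- fill(matrix(numeric(0), nrow = 0, ncol = ncol(tab)), nrow(tab))
  sum(exp(lp[lp <= obs + 1e-9]))
}
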