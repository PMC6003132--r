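#' ROC curve, AUC, and Youden-optimal cutoff
#'
#' Builds the ROC over all distinct score thresholds with the
#' strictly-greater call rule (`positive` iff `score > threshold`), computes
#' the area under the curve by the trapezoid rule (identical to the
#' Mann-Whitney concordance probability), and picks the cutoff maximizing
#' Youden's J = sensitivity + specificity - 1. J ties are broken toward the
#' larger cutoff, i.e. toward higher specificity.
#'
#' @param scores a data frame with columns `score` (finite numeric) and
#'   `label` (`"case"`/`"control"`, or a factor/logical coercible to it;
#'   cases are the positive class). Extra columns are ignored.
#' @param cutoff optional fixed cutoff; when given, no cutoff search is done
#'   and metrics are reported at this value.
#' @return A `cia_eval` object: `auc`, `cutoff`, `metrics` (one-row tibble
#'   from [confusion_metrics()]), confusion counts, and `roc` (tibble of
#'   threshold, sensitivity, specificity, fpr). [glance()] gives the one-row
#'   summary, [tidy()] the ROC points.
#' @export
roc_and_cutoff <- function(scores, cutoff = NULL) {
  lab <- normalize_labels(scores$label)
  s <- scores$score
  if (any(!is.finite(s))) abort("all scores must be finite")
  n_case <- sum(lab == "case")
  n_ctrl <- sum(lab == "control")
  if (n_case == 0 || n_ctrl == 0) {
    abort("need at least one case and one control to build a ROC curve")
  }

  # thresholds: one below all scores (everything positive) plus every distinct score
  thr <- c(min(s) - 1, sort(unique(s)))
  sens <- vapply(thr, function(t) sum(s > t & lab == "case") / n_case, 0)
  spec <- vapply(thr, function(t) sum(s <= t & lab == "control") / n_ctrl, 0)
  roc <- tibble(threshold = thr, sensitivity = sens, specificity = spec, fpr = 1 - spec)

  # trapezoid over (fpr, tpr); points ordered from (1,1) down to (0,0)
  o <- order(roc$fpr, roc$sensitivity)
  x <- c(0, roc$fpr[o], 1)
  y <- c(0, roc$sensitivity[o], 1)
  auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)

  if (is.null(cutoff)) {
    j <- sens + spec - 1
    best <- which(j == max(j))
    cutoff <- max(thr[best])
  }
  pos <- s > cutoff
  tp <- sum(pos & lab == "case"); fn <- n_case - tp
  fp <- sum(pos & lab == "control"); tn <- n_ctrl - fp

  structure(
    list(
      auc = auc, cutoff = cutoff,
      tp = tp, fp = fp, tn = tn, fn = fn,
      metrics = confusion_metrics(tp = tp, fp = fp, tn = tn, fn = fn),
      roc = roc, n_case = n_case, n_control = n_ctrl
    ),
    class = "cia_eval"
  )
}

normalize_labels <- function(label) {
  if (is.logical(label)) label <- ifelse(label, "case", "control")
  label <- tolower(as.character(label))
  ok <- label %in% c("case", "control")
  if (!all(ok)) {
    abort(sprintf("labels must be 'case' or 'control'; saw '%s'", label[!ok][1]))
  }
  label
}

#' @export
print.cia_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    paste0(
      "<cia_eval> %d cases vs %d controls\n",
      "  AUC %.3f; cutoff %g (positive iff score > cutoff)\n",
      "  sensitivity %s  specificity %s  accuracy %s  NPV %s  PPV %s\n"
    ),
    x$n_case, x$n_control, x$auc, x$cutoff,
    fmt_pct(m$sensitivity), fmt_pct(m$specificity), fmt_pct(m$accuracy),
    fmt_pct(m$npv), fmt_pct(m$ppv)
  ))
  invisible(x)
}

#' @method glance cia_eval
#' @export
glance.cia_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble(auc = x$auc, cutoff = x$cutoff, tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn),
    x$metrics
  )
}

#' @method tidy cia_eval
#' @export
tidy.cia_eval <- function(x, ...) x$roc

#' Diagnostic performance metrics from confusion counts
#'
#' @param tp,fp,tn,fn non-negative confusion counts (true/false
#'   positive/negative).
#' @return One-row tibble with `sensitivity`, `specificity`, `accuracy`,
#'   `npv`, `ppv` as proportions in `[0,1]`. A metric whose denominator is
#'   zero is `NA` (absent), not 0. Percent display at one decimal is the
#'   print convention, not a rounding of the stored values.
#' @examples
#' confusion_metrics(tp = 59, fp = 4, tn = 70, fn = 12)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) abort("confusion counts must be non-negative")
  if (sum(counts) == 0) abort("confusion table is empty")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tibble(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    accuracy = ratio(tp + tn, sum(counts)),
    npv = ratio(tn, tn + fn),
    ppv = ratio(tp, tp + fp)
  )
}

#' Cohen's kappa for a paired 2x2 agreement table
#'
#' Chance-corrected agreement between two binary raters:
#' `kappa = (po - pe) / (1 - pe)` with observed agreement `po` (diagonal
#' fraction) and chance agreement `pe` from the marginals. A large-sample
#' normal-approximation p-value for kappa = 0 is included for orientation.
#'
#' @param table a 2x2 matrix of counts, rows = rater A (negative, positive),
#'   columns = rater B; or the four counts
#'   `c(both_neg, a_neg_b_pos, a_pos_b_neg, both_pos)` in row-major order.
#' @return One-row tibble: `agreement`, `kappa` (`NA` when the marginals are
#'   degenerate and `pe = 1`), `p_value`, `n`.
#' @examples
#' cohens_kappa(matrix(c(3, 5, 2, 44), nrow = 2, byrow = TRUE))
#' @export
cohens_kappa <- function(table) {
  tab <- as_2x2(table)
  n <- sum(tab)
  if (n == 0) abort("agreement table is empty")
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - pe < .Machine$double.eps) {
    return(tibble(agreement = po, kappa = NA_real_, p_value = NA_real_, n = n))
  }
  kappa <- (po - pe) / (1 - pe)
  # large-sample variance under kappa = 0 (Fleiss), from the marginals alone
  pr <- rowSums(tab) / n
  pc <- colSums(tab) / n
  v0 <- (pe + pe^2 - sum(pr * pc * (pr + pc))) / (n * (1 - pe)^2)
  p <- if (v0 > 0) 2 * pnorm(-abs(kappa / sqrt(v0))) else NA_real_
  tibble(agreement = po, kappa = kappa, p_value = p, n = n)
}

as_2x2 <- function(table) {
  if (is.matrix(table) && all(dim(table) == c(2, 2))) {
    return(table)
  }
  if (is.numeric(table) && length(table) == 4) {
    return(matrix(table, nrow = 2, byrow = TRUE))
  }
  abort("expected a 2x2 matrix or 4 counts in row-major order")
}

#' Exact McNemar test on discordant pairs
#'
#' Tests whether two paired binary assays disagree symmetrically. Only the
#' discordant cells matter: with `b` pairs positive by the first assay only
#' and `c` by the second only, the two-sided exact p-value is
#' `min(1, 2 * P(X <= min(b, c)))` for `X ~ Binomial(b + c, 1/2)`; `p = 1`
#' when there are no discordant pairs.
#'
#' @param b,c the two discordant counts.
#' @return the two-sided exact p-value.
#' @examples
#' mcnemar_exact(5, 2) # 58/128
#' @export
mcnemar_exact <- function(b, c) {
  if (b < 0 || c < 0) abort("discordant counts must be non-negative")
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * pbinom(min(b, c), n, 0.5))
}

#' Fisher's exact test for an r x c contingency table
#'
#' Two-sided exact test of independence. For 2x2 tables the p-value sums
#' hypergeometric point probabilities no larger than the observed table's;
#' general r x c tables are enumerated over all tables with the observed
#' margins (Freeman-Halton). Tables with total count above `exact_limit`
#' switch to Monte Carlo with a fixed seed and the result is flagged.
#'
#' @param table matrix of non-negative counts.
#' @param exact_limit largest total for full enumeration. Default 500.
#' @param mc_replicates Monte Carlo replicates beyond the limit.
#' @param seed Monte Carlo seed.
#' @return One-row tibble: `p_value`, `method` (`"exact"` or `"monte_carlo"`).
#' @export
fisher_exact <- function(table, exact_limit = 500, mc_replicates = 1e5, seed = 1) {
  table <- as.matrix(table)
  if (any(table < 0)) abort("contingency table cells must be non-negative")
  if (sum(table) == 0) abort("contingency table is empty")
  if (sum(table) <= exact_limit) {
    p <- fisher.test(table)$p.value
    tibble(p_value = p, method = "exact")
  } else {
    p <- withr::with_seed(seed, fisher.test(table, simulate.p.value = TRUE, B = mc_replicates)$p.value)
    tibble(p_value = p, method = "monte_carlo")
  }
}

#' Concordance report for two paired binary assays
#'
#' Cross-tabulates paired calls and reports observed agreement, Cohen's
#' kappa, and the exact McNemar p-value — the standard panel for asking
#' whether one assay can stand in for another.
#'
#' @param calls data frame with two call columns (values
#'   `"positive"`/`"negative"`) named by `test_a`/`test_b`, one row per
#'   subject.
#' @param test_a,test_b column names of the two assays.
#' @return A `cia_concordance` object: the 2x2 `table` (rows = `test_a`,
#'   columns = `test_b`, negative first), `agreement`, `kappa`,
#'   `kappa_p_value`, `mcnemar_p_value`, `n`. [glance()] gives a one-row
#'   tibble.
#' @export
concordance <- function(calls, test_a, test_b) {
  a <- factor(tolower(calls[[test_a]]), levels = c("negative", "positive"))
  b <- factor(tolower(calls[[test_b]]), levels = c("negative", "positive"))
  if (anyNA(a) || anyNA(b)) abort("calls must be 'positive' or 'negative'")
  tab <- table(a, b)
  k <- cohens_kappa(as.matrix(unclass(tab)))
  structure(
    list(
      table = tab, agreement = k$agreement, kappa = k$kappa,
      kappa_p_value = k$p_value,
      mcnemar_p_value = mcnemar_exact(tab["negative", "positive"], tab["positive", "negative"]),
      n = sum(tab), test_a = test_a, test_b = test_b
    ),
    class = "cia_concordance"
  )
}

#' @export
print.cia_concordance <- function(x, ...) {
  cat(sprintf(
    "<cia_concordance> %s vs %s (n = %d)\n  agreement %s  kappa %.3f (p = %.3f)  McNemar exact p = %.3f\n",
    x$test_a, x$test_b, x$n, fmt_pct(x$agreement), x$kappa, x$kappa_p_value,
    x$mcnemar_p_value
  ))
  print(x$table)
  invisible(x)
}

#' @method glance cia_concordance
#' @export
glance.cia_concordance <- function(x, ...) {
  tibble(
    n = x$n, agreement = x$agreement, kappa = x$kappa,
    kappa_p_value = x$kappa_p_value, mcnemar_p_value = x$mcnemar_p_value
  )
}
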