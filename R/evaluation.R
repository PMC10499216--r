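# Metrics and the paired resampling significance procedure.
#
# Thresholded metrics follow the standard confusion-matrix definitions
# (accuracy, precision, recall, F1, MCC); ranking metrics are ROC-AUC with
# tie-averaging (Mann-Whitney form) and PR-AUC by step integration over
# recall increments (average-precision convention, tied scores processed
# as one group).

#' Confusion-matrix metrics at a fixed set of binary calls
#'
#' Computes TP/FP/TN/FN and accuracy, precision, recall, F1 and the
#' Matthews correlation coefficient. Any metric whose denominator is zero
#' is reported as 0.
#'
#' @param labels 0/1 truth vector.
#' @param calls 0/1 prediction vector of the same length.
#' @param threshold optional probability cutoff recorded in the report.
#' @return object of class `metrics_report` (a list of counts + metrics).
#' @export
confusion_metrics <- function(labels, calls, threshold = NA_real_) {
  labels <- as.integer(labels)
  calls <- as.integer(calls)
  if (length(labels) != length(calls)) {
    stop("labels and calls differ in length")
  }
  tp <- sum(labels == 1 & calls == 1)
  fp <- sum(labels == 0 & calls == 1)
  tn <- sum(labels == 0 & calls == 0)
  fn <- sum(labels == 1 & calls == 0)
  sdiv <- function(num, den) if (den > 0) num / den else 0
  precision <- sdiv(tp, tp + fp)
  recall <- sdiv(tp, tp + fn)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  structure(list(
    TP = tp, FP = fp, TN = tn, FN = fn,
    accuracy = sdiv(tp + tn, tp + tn + fp + fn),
    precision = precision,
    recall = recall,
    f1 = sdiv(2 * precision * recall, precision + recall),
    mcc = if (mcc_den > 0) (tp * tn - fn * fp) / mcc_den else 0,
    threshold = threshold
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "TP %d FP %d TN %d FN %d | acc %.3f prec %.3f rec %.3f F1 %.3f MCC %.3f\n",
    x$TP, x$FP, x$TN, x$FN, x$accuracy, x$precision, x$recall, x$f1, x$mcc))
  invisible(x)
}

#' F1 score from a precision/recall pair
#'
#' Harmonic mean `2PR/(P+R)`; 0 when both are 0.
#'
#' @param precision,recall scalars in \[0, 1\].
#' @return F1 scalar.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall <= 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Ranking metrics: ROC-AUC and PR-AUC
#'
#' ROC-AUC is computed by the rank (Mann-Whitney) method with midrank
#' tie-averaging; PR-AUC by step integration of the precision-recall
#' curve over recall increments, processing tied scores as a single
#' group (the average-precision convention).
#'
#' @param labels 0/1 truth vector containing both classes.
#' @param probabilities numeric score vector.
#' @return list with `roc_auc` and `pr_auc`.
#' @export
auc_metrics <- function(labels, probabilities) {
  y <- as.integer(labels)
  s <- as.numeric(probabilities)
  if (length(y) != length(s)) stop("labels and probabilities differ in length")
  npos <- sum(y == 1)
  nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) {
    stop("both classes required to compute AUCs")
  }
  r <- rank(s)
  roc <- (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  # PR step integration over unique score groups, high to low
  ord <- order(s, decreasing = TRUE)
  ys <- y[ord]
  ss <- s[ord]
  grp_end <- cumsum(rle(ss)$lengths)
  ctp <- cumsum(ys)[grp_end]
  cn <- grp_end
  prec <- ctp / cn
  rec <- ctp / npos
  pr <- sum(diff(c(0, rec)) * prec)
  list(roc_auc = roc, pr_auc = pr)
}

#' Select the probability threshold maximizing F1
#'
#' Evaluates every cutpoint between observed scores (calls are
#' `p >= threshold`) and returns the lowest threshold attaining the best
#' F1. With single-class labels the fallback 0.5 is returned with a
#' warning.
#'
#' @param labels 0/1 truth vector.
#' @param probabilities score vector.
#' @return scalar threshold.
#' @export
select_threshold <- function(labels, probabilities) {
  y <- as.integer(labels)
  s <- as.numeric(probabilities)
  if (length(unique(y)) < 2) {
    warning("single-class labels; falling back to threshold 0.5")
    return(0.5)
  }
  cand <- sort(unique(s))
  f1s <- vapply(cand, function(t) {
    confusion_metrics(y, as.integer(s >= t))$f1
  }, numeric(1))
  cand[which.max(f1s)]  # which.max takes the first (lowest) maximizer
}

#' Full metric report for probabilistic predictions
#'
#' @param labels 0/1 truth vector.
#' @param probabilities score vector.
#' @param threshold cutoff for the binary calls; chosen by
#'   [select_threshold()] when `NULL`.
#' @return `metrics_report` augmented with `roc_auc` and `pr_auc`.
#' @export
metrics_report <- function(labels, probabilities, threshold = NULL) {
  if (is.null(threshold)) threshold <- select_threshold(labels, probabilities)
  rep_ <- confusion_metrics(labels,
                            as.integer(probabilities >= threshold),
                            threshold = threshold)
  aucs <- auc_metrics(labels, probabilities)
  rep_$roc_auc <- aucs$roc_auc
  rep_$pr_auc <- aucs$pr_auc
  rep_
}

#' Paired resampling significance test between two methods
#'
#' Repeatedly samples a fraction of the targets (the same subset for both
#' methods), pools the residues of the subset, and scores each method by
#' F1, MCC, ROC-AUC and PR-AUC, yielding `reps` paired score pairs per
#' metric. Normality of each method's scores is assessed by the
#' Anderson-Darling test at `alpha`; when both pass, a two-sided paired
#' t-test is used, otherwise a two-sided Wilcoxon test on the paired
#' differences (signed-rank; the rank-sum flavor on the two score lists is
#' available via `wilcoxon = "ranksum"`). Identical scores in every
#' resample (zero-variance differences) give p = 1 with a warning.
#'
#' @param targets list of targets, each a list with `labels` (0/1 vector)
#'   and probability vectors `method_a` and `method_b`.
#' @param fraction fraction of targets drawn per resample (default 0.7).
#' @param reps number of resamples (default 10, must be >= 2).
#' @param alpha normality significance level (default 0.05).
#' @param seed RNG seed for the resampling.
#' @param threshold probability cutoff for the thresholded metrics (F1,
#'   MCC); default 0.5.
#' @param wilcoxon `"signedrank"` (paired, default) or `"ranksum"`.
#' @param pooled pool residues across the subset (default) rather than
#'   averaging per-target scores.
#' @return object of class `significance_result`: a data frame with one
#'   row per metric (means, variances, normality flags, test used,
#'   p-value) plus the raw score matrices as attributes.
#' @export
paired_resample_significance <- function(targets, fraction = 0.7, reps = 10,
                                         alpha = 0.05, seed = 1,
                                         threshold = 0.5,
                                         wilcoxon = c("signedrank",
                                                      "ranksum"),
                                         pooled = TRUE) {
  if (reps < 2) stop("reps must be >= 2")
  wilcoxon <- match.arg(wilcoxon)
  n <- length(targets)
  k <- max(1L, round(fraction * n))
  metric_names <- c("f1", "mcc", "roc_auc", "pr_auc")
  score_one <- function(labels, probs) {
    aucs <- auc_metrics(labels, probs)
    cm <- confusion_metrics(labels, as.integer(probs >= threshold))
    c(f1 = cm$f1, mcc = cm$mcc,
      roc_auc = aucs$roc_auc, pr_auc = aucs$pr_auc)
  }
  sa <- sb <- matrix(NA_real_, reps, length(metric_names),
                     dimnames = list(NULL, metric_names))
  set.seed(seed)
  for (r in seq_len(reps)) {
    sub <- sample(n, k)
    if (pooled) {
      labs <- unlist(lapply(targets[sub], `[[`, "labels"))
      pa <- unlist(lapply(targets[sub], `[[`, "method_a"))
      pb <- unlist(lapply(targets[sub], `[[`, "method_b"))
      sa[r, ] <- score_one(labs, pa)
      sb[r, ] <- score_one(labs, pb)
    } else {
      ma <- t(vapply(targets[sub], function(tg) {
        score_one(tg$labels, tg$method_a)
      }, numeric(4)))
      mb <- t(vapply(targets[sub], function(tg) {
        score_one(tg$labels, tg$method_b)
      }, numeric(4)))
      sa[r, ] <- colMeans(ma)
      sb[r, ] <- colMeans(mb)
    }
  }
  ad_p <- function(v) {
    if (stats::sd(v) < 1e-12) return(NA_real_)
    tryCatch(nortest::ad.test(v)$p.value, error = function(e) NA_real_)
  }
  rows <- lapply(metric_names, function(mn) {
    a <- sa[, mn]; b <- sb[, mn]
    pa <- ad_p(a); pb <- ad_p(b)
    normal <- !is.na(pa) && !is.na(pb) && pa > alpha && pb > alpha
    d <- a - b
    if (all(abs(d) < 1e-15)) {
      warning("zero-variance paired differences for ", mn,
              "; reporting p = 1")
      test <- "none (identical scores)"
      pval <- 1
    } else if (normal) {
      test <- "paired t"
      pval <- stats::t.test(a, b, paired = TRUE)$p.value
    } else if (wilcoxon == "signedrank") {
      test <- "wilcoxon signed-rank"
      pval <- suppressWarnings(
        stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
    } else {
      test <- "wilcoxon rank-sum"
      pval <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }
    data.frame(metric = mn, mean_a = mean(a), var_a = stats::var(a),
               mean_b = mean(b), var_b = stats::var(b),
               normal_a = !is.na(pa) && pa > alpha,
               normal_b = !is.na(pb) && pb > alpha,
               test = test, p_value = pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "scores_a") <- sa
  attr(out, "scores_b") <- sb
  class(out) <- c("significance_result", "data.frame")
  out
}

#' Read a benchmark interface-label file
#'
#' Parses the plain-text format used by published interface benchmarks:
#' repeated triples of a `>id` header line, the amino-acid sequence, and a
#' same-length string of 0/1 interface labels.
#'
#' @param path label file.
#' @return list of entries with `id`, `sequence` and integer `labels`.
#' @export
read_label_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nchar(lines) > 0]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no '>' headers in ", path)
  lapply(heads, function(hi) {
    seq_ <- lines[hi + 1]
    lab <- lines[hi + 2]
    if (nchar(seq_) != nchar(lab) || grepl("[^01]", lab)) {
      stop("malformed entry at line ", hi, " of ", path)
    }
    list(id = sub("^>", "", lines[hi]),
         sequence = strsplit(seq_, "")[[1]],
         labels = as.integer(strsplit(lab, "")[[1]]))
  })
}
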