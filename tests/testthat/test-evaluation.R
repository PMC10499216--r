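test_that("confusion metrics reproduce hand-worked and printed values", {
  # TP=5, FP=5, TN=85, FN=5: MCC = (5*85 - 5*5)/sqrt(10*10*90*90) = 400/900
  labels <- c(rep(1, 10), rep(0, 90))
  calls <- c(rep(1, 5), rep(0, 5), rep(1, 5), rep(0, 85))
  cm <- confusion_metrics(labels, calls)
  expect_equal(c(cm$TP, cm$FP, cm$TN, cm$FN), c(5, 5, 85, 5))
  expect_equal(cm$mcc, 400 / 900)
  expect_equal(cm$precision, 0.5)
  expect_equal(cm$recall, 0.5)
  expect_equal(cm$accuracy, 0.9)

  # published per-target example values: F1 is the harmonic mean of the
  # reported precision/recall pairs. The inputs are printed to 3 decimals,
  # so the recomputed F1 carries about +/- 1e-3 of input-rounding
  # uncertainty (0.8/0.545 -> 0.6483, consistent with the printed 0.649
  # that the unrounded recall, e.g. 6/11 = 0.5455, would give).
  expect_lt(abs(f1_score(0.8, 0.545) - 0.649), 1e-3)
  expect_equal(round(f1_score(0.595, 0.564), 3), 0.579)

  # perfect prediction
  cm1 <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(cm1$accuracy, cm1$precision, cm1$recall, cm1$f1, cm1$mcc),
               rep(1, 5))
  # zero denominators report 0
  cm0 <- confusion_metrics(c(0, 0, 1), c(0, 0, 0))
  expect_equal(cm0$precision, 0)
  expect_equal(cm0$mcc, 0)
  expect_error(confusion_metrics(c(1, 0), c(1)), "length")
})

test_that("confusion metrics match a brute-force recount on random instances", {
  set.seed(10)
  for (k in 1:10) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.3)
    calls <- rbinom(n, 1, 0.5)
    cm <- confusion_metrics(labels, calls)
    ref <- oracle_confusion(labels, calls)
    expect_equal(c(cm$TP, cm$FP, cm$TN, cm$FN), unname(ref))
    expect_gte(cm$mcc, -1)
    expect_lte(cm$mcc, 1)
    # F1 is the harmonic mean of its own precision/recall
    expect_equal(cm$f1, f1_score(cm$precision, cm$recall))
  }
})

test_that("ROC-AUC has the pair-counting interpretation, with tie-averaging", {
  # all positives above all negatives
  expect_equal(auc_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$roc_auc, 1)
  # all scores equal -> 0.5
  expect_equal(auc_metrics(c(1, 0, 1, 0), rep(0.4, 4))$roc_auc, 0.5)
  set.seed(20)
  for (k in 1:8) {
    n <- 40
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)  # force some ties
    a <- auc_metrics(labels, scores)
    expect_lt(abs(a$roc_auc - oracle_roc_auc(labels, scores)), 1e-9)
    expect_gte(a$pr_auc, 0)
    expect_lte(a$pr_auc, 1)
  }
  expect_error(auc_metrics(c(1, 1), c(0.4, 0.2)), "both classes")
})

test_that("PR-AUC is 1 for perfect ranking and the base rate for constant scores", {
  a <- auc_metrics(c(1, 1, 0, 0, 0), c(0.9, 0.8, 0.3, 0.2, 0.1))
  expect_equal(a$pr_auc, 1)
  b <- auc_metrics(c(1, 1, 0, 0, 0), rep(0.5, 5))
  expect_equal(b$pr_auc, 0.4)  # single group: precision = prevalence
})

test_that("threshold selection maximizes F1 with lowest-threshold tie-breaking", {
  # perfectly separated scores: lowest maximizing cutpoint is the smallest
  # positive score
  labels <- c(0, 0, 1, 1)
  scores <- c(0.1, 0.2, 0.9, 0.95)
  thr <- select_threshold(labels, scores)
  expect_equal(thr, 0.9)
  expect_equal(confusion_metrics(labels, as.integer(scores >= thr))$f1, 1)
  # exhaustive optimality on random instances
  set.seed(30)
  for (k in 1:6) {
    n <- 25
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- runif(n)
    thr <- select_threshold(labels, scores)
    f1_at <- function(t) confusion_metrics(labels,
                                           as.integer(scores >= t))$f1
    best <- max(vapply(sort(unique(scores)), f1_at, numeric(1)))
    expect_equal(f1_at(thr), best)
  }
  # monotone transform preserves the calls at the re-selected threshold
  labels <- rbinom(30, 1, 0.3)
  labels[1:2] <- c(0, 1)
  scores <- runif(30)
  t1 <- select_threshold(labels, scores)
  t2 <- select_threshold(labels, sqrt(scores))
  expect_equal(as.integer(scores >= t1), as.integer(sqrt(scores) >= t2))
  expect_warning(thr0 <- select_threshold(rep(1, 5), runif(5)), "single-class")
  expect_equal(thr0, 0.5)
})

test_that("identical methods yield p = 1 under the resampling procedure", {
  set.seed(40)
  targets <- lapply(1:10, function(k) {
    n <- 30
    labels <- rbinom(n, 1, 0.3)
    labels[1:2] <- c(1, 0)
    p <- runif(n)
    list(labels = labels, method_a = p, method_b = p)
  })
  w <- capture_warnings(
    res <- paired_resample_significance(targets, seed = 1))
  expect_match(w, "zero-variance", all = TRUE)
  expect_true(all(res$p_value == 1))
  expect_equal(res$mean_a, res$mean_b)
})

test_that("the paired t-test branch matches a from-scratch t computation", {
  # stipulated score pairs: constant shift + tiny noise (normal case)
  set.seed(50)
  noise <- rnorm(10, sd = 1e-3)
  a <- 0.80 + noise
  b <- 0.78 + noise + rnorm(10, sd = 1e-3)
  d <- a - b
  t_stat <- mean(d) / (sd(d) / sqrt(10))
  p_ref <- 2 * pt(-abs(t_stat), df = 9)
  p_ours <- stats::t.test(a, b, paired = TRUE)$p.value
  expect_lt(abs(p_ours - p_ref), 1e-6)
  # reported variance equals the sample variance of the score list
  targets <- lapply(1:10, function(k) {
    labels <- rbinom(40, 1, 0.3)
    labels[1:2] <- c(1, 0)
    list(labels = labels, method_a = runif(40), method_b = runif(40))
  })
  res <- suppressWarnings(
    paired_resample_significance(targets, reps = 10, seed = 3))
  sa <- attr(res, "scores_a")
  expect_equal(res$var_a, apply(sa, 2, var), ignore_attr = TRUE)
  expect_equal(res$mean_a, colMeans(sa), ignore_attr = TRUE)
  expect_error(paired_resample_significance(targets, reps = 1), "reps")
})

test_that("an informative method beats a noise method with p < 0.05 for ROC-AUC", {
  hits <- 0
  for (rep_seed in 1:10) {
    set.seed(1000 + rep_seed)
    targets <- lapply(1:10, function(k) {
      n <- 50
      labels <- rbinom(n, 1, 0.3)
      labels[1:2] <- c(1, 0)
      informative <- plogis(2 * labels + rnorm(n, sd = 0.8))
      noise <- runif(n)
      list(labels = labels, method_a = informative, method_b = noise)
    })
    res <- suppressWarnings(
      paired_resample_significance(targets, seed = rep_seed))
    p_roc <- res$p_value[res$metric == "roc_auc"]
    if (p_roc < 0.05 && res$mean_a[res$metric == "roc_auc"] >
        res$mean_b[res$metric == "roc_auc"]) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})

test_that("benchmark label files parse into id/sequence/labels triples", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">1abcA", "MKTAYI", "010010",
               ">2xyzB", "GGS", "111"), f)
  entries <- read_label_file(f)
  expect_length(entries, 2)
  expect_equal(entries[[1]]$id, "1abcA")
  expect_equal(entries[[1]]$labels, c(0, 1, 0, 0, 1, 0))
  expect_equal(sum(vapply(entries, function(e) sum(e$labels), 0)), 5)
  writeLines(c(">bad", "MKT", "01"), f)
  expect_error(read_label_file(f), "malformed")
})
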