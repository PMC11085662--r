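# explicit-loop counting oracles
count_topn <- function(pred, targ, thr, n) {
  ok <- 0; tot <- 0
  for (i in seq_len(nrow(pred))) for (k in seq_len(n)) {
    ok <- ok + ((pred[i, k] >= thr) == (targ[i, k] > 0.5))
    tot <- tot + 1
  }
  ok / tot
}

count_cm <- function(pred, targ, thr, k) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(nrow(pred))) {
    d <- pred[i, k] >= thr; p <- targ[i, k] > 0.5
    if (d && p) tp <- tp + 1 else if (d && !p) fp <- fp + 1
    else if (!d && p) fn <- fn + 1 else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

brute_pr_auc <- function(s, t) {
  t <- t > 0.5
  rec <- 0; prec <- NULL; auc <- 0
  for (th in sort(unique(s), decreasing = TRUE)) {
    tp <- sum(s >= th & t); pp <- sum(s >= th)
    r <- tp / sum(t); p <- if (pp == 0) 1 else tp / pp
    if (is.null(prec)) prec <- p                    # anchor at recall 0
    auc <- auc + (r - rec) * (p + prec) / 2
    rec <- r; prec <- p
  }
  auc
}

test_that("top-n accuracy and per-slot confusions equal exhaustive counting", {
  fx <- random_fixture(30, seed = 41)
  for (n in 1:5) {
    expect_equal(topn_accuracy(fx$pred, fx$targ, 0.5, n),
                 count_topn(fx$pred, fx$targ, 0.5, n))
  }
  cms <- confusion_by_slot(fx$pred, fx$targ, 0.5)
  for (k in 1:5) {
    expect_equal(unlist(cms[[k]][c("tp", "fp", "fn", "tn")]),
                 count_cm(fx$pred, fx$targ, 0.5, k))
    expect_equal(sum(unlist(cms[[k]])), 30)
  }
  # a 5 x N matrix (network layout) is accepted and transposed
  expect_equal(topn_accuracy(t(fx$pred), t(fx$targ), 0.5, 3),
               topn_accuracy(fx$pred, fx$targ, 0.5, 3))
})

test_that("derived metrics reproduce hand-computed values for (3,1,1,5)", {
  m <- derived_metrics(confusion_matrix(tp = 3, fp = 1, fn = 1, tn = 5))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$specificity, 5 / 6, tolerance = 1e-12)
  expect_equal(round(m$specificity, 4), 0.8333)
  expect_equal(m$f1, 0.75)
  expect_equal(m$mcc, 14 / 24, tolerance = 1e-12)
  expect_equal(round(m$mcc, 4), 0.5833)
  expect_equal(m$fp_rate, 1 / 6, tolerance = 1e-12)
  expect_equal(m$fn_rate, 0.25)
  expect_length(attr(m, "undefined"), 0)
})

test_that("boundary confusion matrices give the extreme metric values", {
  perfect <- derived_metrics(confusion_matrix(10, 0, 0, 20))
  for (nm in c("accuracy", "precision", "recall", "specificity", "f1", "mcc"))
    expect_equal(perfect[[nm]], 1)
  expect_equal(perfect$fp_rate, 0)
  expect_equal(perfect$fn_rate, 0)
  inverted <- derived_metrics(confusion_matrix(0, 10, 20, 0))
  expect_equal(inverted$mcc, -1)
  expect_equal(inverted$accuracy, 0)
  allneg <- derived_metrics(confusion_matrix(0, 0, 0, 5))
  expect_equal(allneg$precision, 0)
  expect_setequal(attr(allneg, "undefined"),
                  c("precision", "recall", "f1", "mcc", "fn_rate"))
  expect_error(derived_metrics(confusion_matrix(0, 0, 0, 0)), "all-zero")
  expect_error(confusion_matrix(-1, 0, 0, 5), "nonnegative")
})

test_that("MCC stays in [-1, 1] and is class-swap symmetric", {
  set.seed(43)
  for (k in 1:100) {
    cts <- sample(0:20, 4, replace = TRUE)
    if (sum(cts) == 0) next
    a <- derived_metrics(confusion_matrix(cts[1], cts[2], cts[3], cts[4]))
    b <- derived_metrics(confusion_matrix(cts[4], cts[3], cts[2], cts[1]))
    expect_true(a$mcc >= -1 - 1e-12 && a$mcc <= 1 + 1e-12)
    expect_equal(a$mcc, b$mcc, tolerance = 1e-12)
  }
})

test_that("PR curve equals brute-force enumeration on an 8-point fixture", {
  s <- c(0.95, 0.85, 0.7, 0.6, 0.5, 0.35, 0.2, 0.1)
  t <- c(1, 1, 0, 1, 0, 1, 0, 0)
  out <- pr_curve_auc(s, t)
  expect_equal(out$auc, brute_pr_auc(s, t), tolerance = 1e-12)
  expect_equal(nrow(out$curve), 8)
  expect_false(is.unsorted(out$curve$recall))
  # hand-computed 4-point value: 19/24
  expect_equal(pr_curve_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc,
               19 / 24, tolerance = 1e-12)
})

test_that("PR-AUC is 1 under perfect separation, ~prevalence under noise", {
  expect_equal(pr_curve_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_error(pr_curve_auc(c(0.3, 0.6), c(1, 1)), "single class")
  set.seed(47)
  s <- runif(20000)
  t <- rbinom(20000, 1, 0.3)
  expect_lt(abs(pr_curve_auc(s, t)$auc - 0.3), 0.03)
})

test_that("macro averaging skips single-class slots", {
  set.seed(48)
  p <- matrix(runif(40 * 5), 40)
  t <- matrix(rbinom(40 * 5, 1, 0.5), 40)
  t[, 3] <- 1
  macro <- pr_curve_auc(p, t, macro = TRUE)
  manual <- mean(vapply(c(1, 2, 4, 5),
                        function(k) pr_curve_auc(p[, k], t[, k])$auc,
                        numeric(1)))
  expect_equal(macro$auc, manual, tolerance = 1e-12)
})

test_that("the evaluation report is internally consistent", {
  fx <- random_fixture(30, seed = 49)
  rep <- evaluation_report(fx$pred, fx$targ, threshold = 0.4)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$n_images, 30)
  for (n in 1:5) {
    expect_equal(rep$topn$accuracy[n],
                 topn_accuracy(fx$pred, fx$targ, 0.4, n))
    expect_equal(rep$topn$loss[n],
                 bce_loss(fx$pred[, 1:n], fx$targ[, 1:n]))
  }
  expect_equal(rep$pr_auc, pr_curve_auc(fx$pred, fx$targ)$auc)
  expect_output(print(rep), "top-5 accuracy")
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$pr_auc, rep$pr_auc, tolerance = 1e-12)
  expect_equal(back$topn$accuracy, rep$topn$accuracy, tolerance = 1e-12)
})
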