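test_that("confusion matrix counts by true row and predicted column", {
  cm <- confusion_matrix(c("F", "F", "G"), c("F", "G", "G"),
                         frame = c("F", "G"))
  expect_equal(unclass(cm)["F", ], c(F = 1L, G = 1L))
  expect_equal(unclass(cm)["G", ], c(F = 0L, G = 1L))

  perfect <- confusion_matrix(letters[1:10], letters[1:10])
  expect_equal(sum(diag(perfect)), 10)
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)

  expect_error(confusion_matrix("F", "Z", frame = c("F", "G")),
               class = "evidfuse_label_error")
  expect_error(confusion_matrix(c("F", "G"), "F", frame = c("F", "G")),
               class = "evidfuse_validity_error")
})

test_that("confusion row sums track the generator's drawn class counts", {
  sim <- gen_predictions(500, seed = 11)
  fused <- fuse_predictions(sim$predictions, rule = "idset")
  cm <- confusion_matrix(sim$truth$label, fused$decision,
                         frame = names(fundus_class_priors()))
  expect_equal(rowSums(cm), table(factor(sim$truth$label,
                                         levels = rownames(cm))) |>
                 as.numeric() |> setNames(rownames(cm)))
  expect_equal(sum(cm), 500)
})

test_that("per-class rates follow the TP/FP/FN/TN definitions", {
  truth <- rep(c("a", "b"), c(10, 10))
  pred <- c(rep("a", 8), rep("b", 2), rep("a", 1), rep("b", 9))
  cm <- confusion_matrix(truth, pred, frame = c("a", "b"))
  r <- class_rates(cm)
  a <- r[r$class == "a", ]
  expect_equal(a$precision, 8 / 9, tolerance = 1e-12)
  expect_equal(a$recall, 0.8)
  expect_equal(a$specificity, 0.9)
  expect_equal(a$f1, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8), tolerance = 1e-12)
  # f1 is the harmonic mean of its own precision and recall everywhere
  defined <- !is.na(r$f1)
  expect_equal(r$f1[defined],
               2 * r$precision[defined] * r$recall[defined] /
                 (r$precision[defined] + r$recall[defined]),
               tolerance = 1e-12)
})

test_that("all-correct predictions give unit rates; absent classes give NA", {
  cm <- confusion_matrix(rep(c("a", "b"), 5), rep(c("a", "b"), 5),
                         frame = c("a", "b", "c"))
  expect_message(r <- class_rates(cm), "Undefined")
  expect_true(all(r$precision[r$class != "c"] == 1))
  expect_true(all(r$recall[r$class != "c"] == 1))
  cr <- r[r$class == "c", ]
  expect_true(is.na(cr$precision) && is.na(cr$recall) && is.na(cr$f1))
  expect_equal(cr$specificity, 1)  # TN/(TN+FP) is still defined here
})

test_that("accuracy and kappa match hand-derived values", {
  truth <- rep(c("a", "b"), c(50, 50))
  pred <- rep(c("a", "b", "a", "b"), c(45, 5, 10, 40))
  cm <- confusion_matrix(truth, pred)
  expect_equal(accuracy_score(cm), 0.85)
  expect_equal(kappa_score(cm), 0.7, tolerance = 1e-12)  # p_o 0.85, p_e 0.5

  perfect <- confusion_matrix(letters[1:5], letters[1:5])
  expect_equal(accuracy_score(perfect), 1)
  expect_equal(kappa_score(perfect), 1)

  chance <- confusion_matrix(rep(c("a", "a", "b", "b"), 25),
                             rep(c("a", "b", "a", "b"), 25))
  expect_equal(kappa_score(chance), 0)

  degenerate <- confusion_matrix(rep("a", 5), rep("a", 5),
                                 frame = c("a", "b"))
  expect_warning(k <- kappa_score(degenerate),
                 class = "evidfuse_degenerate_warning")
  expect_true(is.na(k))
})

test_that("rates, kappa and accuracy agree with reference implementations", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("caret")
  set.seed(77)
  for (rep in 1:100) {
    phi <- sample(2:6, 1)
    n <- sample(30:120, 1)
    labs <- paste0("k", seq_len(phi))
    truth <- sample(labs, n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.6, truth, sample(labs, n, replace = TRUE))
    cm <- confusion_matrix(truth, pred, frame = labs)
    ref <- e1071::classAgreement(unclass(cm))
    expect_equal(accuracy_score(cm), ref$diag, tolerance = 1e-9)
    expect_equal(kappa_score(cm), ref$kappa, tolerance = 1e-9)
    if (rep <= 20) {
      cref <- caret::confusionMatrix(
        factor(pred, levels = labs), factor(truth, levels = labs),
        mode = "prec_recall")
      by_class <- if (phi == 2) rbind(cref$byClass) else cref$byClass
      r <- suppressMessages(class_rates(cm))
      for (ci in seq_len(nrow(by_class))) {
        expect_equal(r$precision[ci], unname(by_class[ci, "Precision"]),
                     tolerance = 1e-9)
        expect_equal(r$recall[ci], unname(by_class[ci, "Recall"]),
                     tolerance = 1e-9)
        if (!is.na(r$f1[ci])) {
          expect_equal(r$f1[ci], unname(by_class[ci, "F1"]),
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("one-vs-rest AUC matches hand counts and reference on toy data", {
  # 6-point binary toy set with one inversion: 8/9 by concordant-pair count
  truth <- c(1, 1, 0, 1, 0, 0)
  scores <- data.frame(pos = c(0.9, 0.8, 0.7, 0.6, 0.55, 0.1))
  scores$neg <- 1 - scores$pos
  a <- suppressWarnings(auc_ovr(ifelse(truth == 1, "pos", "neg"), scores,
                                frame = c("pos", "neg")))
  expect_equal(a$auc[a$class == "pos"], 8 / 9, tolerance = 1e-12)
  expect_equal(a$auc[a$class == "neg"], 8 / 9, tolerance = 1e-12)

  # perfectly ordered scores give AUC 1 per class
  labs <- c("x", "y", "z")
  tr <- rep(labs, each = 4)
  S <- sapply(labs, function(l) ifelse(tr == l, 0.9, 0.05))
  expect_true(all(auc_ovr(tr, S, frame = labs)$auc == 1))
})

test_that("AUC by rank statistic matches pROC on random seeded data", {
  skip_if_not_installed("pROC")
  set.seed(88)
  for (rep in 1:20) {
    n <- 60
    truth <- sample(c("a", "b", "c"), n, replace = TRUE)
    S <- matrix(runif(3 * n), n, dimnames = list(NULL, c("a", "b", "c")))
    S <- S / rowSums(S)
    mine <- auc_ovr(truth, S)
    for (lb in c("a", "b", "c")) {
      ref <- as.numeric(pROC::auc(pROC::roc(truth == lb, S[, lb],
                                            quiet = TRUE,
                                            direction = "<")))
      expect_equal(mine$auc[mine$class == lb], ref, tolerance = 1e-9)
    }
  }
})

test_that("scores independent of truth give macro AUC near one half", {
  set.seed(3)
  n <- 2000
  truth <- sample(c("a", "b", "c"), n, replace = TRUE)
  S <- matrix(runif(3 * n), n, dimnames = list(NULL, c("a", "b", "c")))
  a <- auc_ovr(truth, S)
  expect_lt(abs(macro_auc(a) - 0.5), 0.03)
})

test_that("classes absent from truth are skipped with a warning", {
  S <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(a <- auc_ovr(rep("a", 10), S, frame = c("a", "b")),
                 class = "evidfuse_absent_class_warning")
  expect_true(is.na(a$auc[a$class == "b"]))
})

test_that("macro F1 from per-class rates matches an independent recomputation", {
  set.seed(99)
  for (rep in 1:20) {
    labs <- paste0("k", 1:4)
    truth <- sample(labs, 80, replace = TRUE)
    pred <- ifelse(runif(80) < 0.7, truth, sample(labs, 80, replace = TRUE))
    cm <- confusion_matrix(truth, pred, frame = labs)
    r <- suppressMessages(class_rates(cm))
    macro <- mean(r$f1, na.rm = TRUE)
    # independent path: recompute each class's F1 from raw counts
    f1s <- sapply(labs, function(lb) {
      tp <- sum(truth == lb & pred == lb)
      fp <- sum(truth != lb & pred == lb)
      fn <- sum(truth == lb & pred != lb)
      if (tp + fp == 0 || tp + fn == 0) return(NA_real_)
      p <- tp / (tp + fp); rc <- tp / (tp + fn)
      if (p + rc == 0) NA_real_ else 2 * p * rc / (p + rc)
    })
    expect_equal(macro, mean(f1s, na.rm = TRUE), tolerance = 1e-12)
  }
})

test_that("metrics_report assembles estimates and bootstrap intervals", {
  sim <- gen_predictions(300, seed = 13)
  fused <- fuse_predictions(sim$predictions, rule = "idset")
  rep <- metrics_report(sim$truth, scores = fused, ci = TRUE, boot = 200,
                        seed = 5)
  expect_s3_class(tidy(rep), "tbl_df")
  g <- glance(rep)
  expect_true(all(c("accuracy", "kappa", "macro_f1", "macro_auc") %in%
                    names(g)))
  expect_true(g$accuracy >= 0 && g$accuracy <= 1)
  expect_true(g$kappa >= -1 && g$kappa <= 1)
  s <- rep$summary
  expect_true(all(s$conf_low <= s$estimate + 1e-12 &
                    s$estimate <= s$conf_high + 1e-12))
  # seeded bootstrap is reproducible
  rep2 <- metrics_report(sim$truth, scores = fused, ci = TRUE, boot = 200,
                         seed = 5)
  expect_equal(rep$summary, rep2$summary)
  js <- jsonlite::fromJSON(report_to_json(rep))
  expect_true(all(c("confusion", "per_class", "summary") %in% names(js)))
})
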