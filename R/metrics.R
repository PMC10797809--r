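#' Multiclass confusion matrix
#'
#' @param truth,predicted Equal-length vectors of labels drawn from the
#'   frame.
#' @param frame Class labels; defaults to the sorted union of the values
#'   seen. Supply it explicitly to fix label order and include classes
#'   absent from the data.
#' @return A `confusion_matrix`: an integer matrix with rows = true class,
#'   columns = predicted class.
#' @examples
#' confusion_matrix(c("F", "F", "G"), c("F", "G", "G"), frame = c("F", "G"))
#' @export
confusion_matrix <- function(truth, predicted, frame = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    abort("truth and predicted must have the same length.",
          class = "evidfuse_validity_error")
  }
  if (is.null(frame)) frame <- sort(unique(c(truth, predicted)))
  frame <- as_frame(frame)
  labs <- unclass(frame)
  outside <- setdiff(unique(c(truth, predicted)), c(labs, NA))
  if (length(outside)) {
    abort(paste0("Label(s) outside the frame: ",
                 paste(outside, collapse = ", ")),
          class = "evidfuse_label_error")
  }
  counts <- table(factor(truth, levels = labs),
                  factor(predicted, levels = labs))
  m <- matrix(as.integer(counts), nrow = length(labs),
              dimnames = list(truth = labs, predicted = labs))
  structure(m, frame = frame, class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> ", sum(x), " samples, ", nrow(x), " classes\n",
      sep = "")
  print(unclass(x))
  invisible(x)
}

# One-vs-rest TP/FP/FN/TN per class.
ovr_counts <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  tibble(class = rownames(cm), tp = as.integer(tp), fp = as.integer(fp),
         fn = as.integer(fn), tn = as.integer(tn))
}

#' Per-class precision, recall, specificity and F1
#'
#' One-vs-rest rates from the confusion matrix:
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' specificity = TN/(TN+FP), F1 = 2PR/(P+R).
#' A rate with a zero denominator is undefined: it is reported as `NA`,
#' excluded from macro averages, and noted via a message (never silently
#' substituted by 0).
#'
#' @param cm A [confusion_matrix()].
#' @return A tibble with one row per class: counts and the four rates.
#' @export
class_rates <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  d <- ovr_counts(cm)
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  d$precision <- safe_div(d$tp, d$tp + d$fp)
  d$recall <- safe_div(d$tp, d$tp + d$fn)
  d$specificity <- safe_div(d$tn, d$tn + d$fp)
  pr <- d$precision + d$recall
  d$f1 <- ifelse(!is.na(pr) & pr > 0, 2 * d$precision * d$recall / pr,
                 NA_real_)
  und <- d$class[is.na(d$precision) | is.na(d$recall) |
                   is.na(d$specificity) | is.na(d$f1)]
  if (length(und)) {
    inform(paste0("Undefined rate(s) for class(es) ",
                  paste(und, collapse = ", "),
                  " (zero denominator); excluded from macro averages."))
  }
  d
}

#' Accuracy and Cohen's kappa from a confusion matrix
#'
#' Accuracy is trace/total. Kappa is the unweighted Cohen's kappa,
#' `(p_o - p_e) / (1 - p_e)`, with expected agreement `p_e` from the
#' row-by-column marginal products; classes are treated as nominal.
#'
#' @param cm A [confusion_matrix()].
#' @return A number; `kappa_score()` returns `NA` with a warning when
#'   `p_e = 1` (degenerate marginals).
#' @examples
#' cm <- confusion_matrix(rep(c("a", "b"), c(50, 50)),
#'                        rep(c("a", "b", "a", "b"), c(45, 5, 10, 40)))
#' accuracy_score(cm)  # 0.85
#' kappa_score(cm)     # 0.70
#' @export
accuracy_score <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"), sum(cm) > 0)
  sum(diag(cm)) / sum(cm)
}

#' @rdname accuracy_score
#' @export
kappa_score <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"), sum(cm) > 0)
  total <- sum(cm)
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < 1e-15) {
    warn("Expected agreement p_e = 1; kappa is undefined.",
         class = "evidfuse_degenerate_warning")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' One-vs-rest AUC per class
#'
#' For each class, the area under the ROC curve of that class's score
#' against membership of that class, computed by the rank (Mann-Whitney)
#' statistic with midranks for ties -- equivalent to trapezoidal
#' integration of the empirical ROC curve. Classes absent from the truth
#' are skipped with a warning. The macro AUC is the unweighted mean over
#' classes present.
#'
#' @param truth Vector of true labels.
#' @param scores A data frame or matrix of per-class scores (fused masses
#'   or probabilities), columns named by class; rows align with `truth`.
#' @param frame Class labels; defaults to the score columns.
#' @return A tibble (`class`, `n_pos`, `auc`) with the macro AUC in
#'   attribute `macro` (also via [macro_auc()]).
#' @export
auc_ovr <- function(truth, scores, frame = NULL) {
  truth <- as.character(truth)
  S <- as.matrix(as.data.frame(scores))
  if (is.null(frame)) frame <- colnames(S)
  frame <- as_frame(frame)
  labs <- unclass(frame)
  if (!all(labs %in% colnames(S))) {
    abort("Score columns must cover every frame label.",
          class = "evidfuse_frame_error")
  }
  if (nrow(S) != length(truth)) {
    abort("scores and truth must have the same number of rows.",
          class = "evidfuse_validity_error")
  }
  auc1 <- function(pos, s) {
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(s, ties.method = "average")
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  res <- purrr::map_dfr(labs, function(lb) {
    pos <- truth == lb
    tibble(class = lb, n_pos = sum(pos), auc = auc1(pos, S[, lb]))
  })
  absent <- res$class[res$n_pos == 0]
  if (length(absent)) {
    warn(paste0("Class(es) absent from truth, AUC skipped: ",
                paste(absent, collapse = ", ")),
         class = "evidfuse_absent_class_warning")
  }
  attr(res, "macro") <- mean(res$auc, na.rm = TRUE)
  res
}

#' @rdname auc_ovr
#' @param x The result of `auc_ovr()`.
#' @export
macro_auc <- function(x) attr(x, "macro")

#' Full multiclass evaluation report
#'
#' Confusion matrix, per-class and macro-averaged precision / recall /
#' specificity / F1, accuracy, unweighted Cohen's kappa, and (when scores
#' are supplied) per-class and macro one-vs-rest AUC. Macro averages are
#' unweighted means over classes with defined rates. Optionally adds
#' percentile-bootstrap confidence intervals (samples resampled with
#' replacement); the interval method is generic plumbing, not tied to any
#' particular published protocol.
#'
#' @param truth True labels, or a data frame with `sample_id` and `label`
#'   columns (as written by the synthetic generator).
#' @param predicted Predicted labels; may be omitted when `x` is a
#'   `fused_predictions` object passed as `scores`.
#' @param scores Optional per-class score table for AUC; a
#'   `fused_predictions` object supplies both decisions and scores.
#' @param frame Class labels (fixes order); defaults per
#'   [confusion_matrix()].
#' @param ci Add bootstrap confidence intervals?
#' @param boot Number of bootstrap replicates (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional seed for the bootstrap resampling.
#' @return A `metrics_report`: list with `confusion`, `per_class` (tibble),
#'   and `summary` (tibble of metric, estimate and, with `ci = TRUE`,
#'   `conf_low`/`conf_high`). `tidy()` returns `per_class`; `glance()`
#'   returns the summary in wide one-row form.
#' @export
metrics_report <- function(truth, predicted = NULL, scores = NULL,
                           frame = NULL, ci = FALSE, boot = 2000,
                           conf = 0.95, seed = NULL) {
  if (is.data.frame(truth) && all(c("sample_id", "label") %in% names(truth))) {
    truth <- truth$label
  }
  truth <- as.character(truth)
  if (inherits(scores, "fused_predictions")) {
    fp <- scores
    if (is.null(predicted)) predicted <- fp$decision
    if (is.null(frame)) frame <- attr(fp, "frame")
    scores <- as_tibble(fp)[, unclass(attr(fp, "frame")), drop = FALSE]
  }
  if (is.null(predicted)) {
    abort("Supply predicted labels or a fused_predictions object.",
          class = "evidfuse_validity_error")
  }
  predicted <- as.character(predicted)

  compute_all <- function(idx) {
    tr <- truth[idx]; pr <- predicted[idx]
    cm <- confusion_matrix(tr, pr, frame = frame %||% sort(unique(c(truth, predicted))))
    rates <- suppressMessages(class_rates(cm))
    out <- c(
      accuracy = accuracy_score(cm),
      kappa = suppressWarnings(kappa_score(cm)),
      macro_precision = mean(rates$precision, na.rm = TRUE),
      macro_recall = mean(rates$recall, na.rm = TRUE),
      macro_specificity = mean(rates$specificity, na.rm = TRUE),
      macro_f1 = mean(rates$f1, na.rm = TRUE)
    )
    if (!is.null(scores)) {
      a <- suppressWarnings(auc_ovr(tr, as.data.frame(scores)[idx, , drop = FALSE],
                                    frame = frame))
      out <- c(out, macro_auc = attr(a, "macro"))
    }
    out
  }

  n <- length(truth)
  cm <- confusion_matrix(truth, predicted, frame = frame)
  per_class <- class_rates(cm)
  if (!is.null(scores)) {
    a <- auc_ovr(truth, scores, frame = frame %||% attr(cm, "frame"))
    per_class <- dplyr::left_join(per_class, a[, c("class", "auc")],
                                  by = "class")
  }
  est <- compute_all(seq_len(n))
  summary <- tibble(metric = names(est), estimate = as.numeric(est))

  if (ci) {
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(seed)
    }
    reps <- vapply(seq_len(boot), function(b) {
      compute_all(sample.int(n, n, replace = TRUE))
    }, est)
    alpha <- (1 - conf) / 2
    qs <- apply(reps, 1, quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE, names = FALSE)
    summary$conf_low <- qs[1, ]
    summary$conf_high <- qs[2, ]
  }

  structure(list(confusion = cm, per_class = per_class, summary = summary,
                 n = n, conf = if (ci) conf else NULL),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> ", x$n, " samples, ", nrow(x$confusion), " classes\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @export
glance.metrics_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary[, c("metric", "estimate")],
                     names_from = "metric", values_from = "estimate")
}

#' Plot a confusion matrix
#'
#' Heatmap of counts, rows = true class, columns = predicted class.
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  d <- as_tibble(as.data.frame.table(unclass(object),
                                     responseName = "count"))
  names(d)[1:2] <- c("truth", "predicted")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::labs(title = "Confusion matrix") +
    ggplot2::theme_minimal()
}

#' Serialize a metrics report to JSON
#'
#' @param x A `metrics_report`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written).
#' @export
report_to_json <- function(x, path = NULL) {
  obj <- list(n = x$n,
              confusion = unclass(x$confusion),
              per_class = x$per_class,
              summary = x$summary)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
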