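#' Fuse per-sample class probabilities from several classifiers
#'
#' Treats each classifier's per-sample class-probability vector as a BPA
#' and fuses across classifiers, sample by sample, with the classical or
#' the softmax-remapped rule. This is decision-level fusion of an
#' ensemble: each member outputs a softmax row per sample, and the fused
#' row plus its argmax become the ensemble decision.
#'
#' With `rule = "classical"`, samples whose evidence is in complete
#' conflict cannot be fused: those rows get `NA` masses and decisions and
#' are collected into `attr(out, "failures")` rather than aborting the
#' batch. The remapped rule (`"idset"`) never fails.
#'
#' @param predictions A list of two or more prediction tables, one per
#'   classifier: each a data frame with a `sample_id` column and one
#'   numeric probability column per class label, rows being valid BPAs.
#'   All tables must share the same labels and the same `sample_id`s in
#'   the same order.
#' @param rule `"idset"` (default) or `"classical"`.
#' @param tolerance,renormalize Row validation, as in [validate_mass()].
#' @param temperature Softmax temperature for the remapped rule.
#' @return A `fused_predictions` tibble: `sample_id`, `decision`, `k`, and
#'   one fused-mass column per class, with attributes `frame`, `rule`,
#'   `n_sources` and `failures` (tibble of unfusable samples, classical
#'   rule only).
#' @examples
#' a <- tibble::tibble(sample_id = "s1", F = 1, G = 0, H = 0)
#' b <- tibble::tibble(sample_id = "s1", F = 0, G = 1, H = 0)
#' fuse_predictions(list(a, b), rule = "idset")
#' @export
fuse_predictions <- function(predictions, rule = c("idset", "classical"),
                             tolerance = 1e-6, renormalize = FALSE,
                             temperature = 1) {
  rule <- match.arg(rule)
  if (!is.list(predictions) || length(predictions) < 2) {
    abort("Provide a list of at least two prediction tables.",
          class = "evidfuse_validity_error")
  }
  parsed <- purrr::imap(predictions, function(p, i) {
    parse_prediction_table(p, sprintf("prediction table %s", i))
  })
  fr <- parsed[[1]]$frame
  ids <- parsed[[1]]$ids
  for (p in parsed[-1]) {
    if (!setequal(unclass(p$frame), unclass(fr))) {
      abort("Prediction tables carry different class labels.",
            class = "evidfuse_frame_error")
    }
    if (!identical(p$ids, ids)) {
      abort("Prediction tables have misaligned sample ids (same ids, same order, required).",
            class = "evidfuse_alignment_error")
    }
  }
  mats <- purrr::map(parsed, function(p) {
    M <- p$matrix[, unclass(fr), drop = FALSE]
    validate_mass_rows(M, fr, tolerance, renormalize, what = "row")
  })
  if (rule == "idset") mats <- purrr::map(mats, softmax_rows, temperature = temperature)

  P <- Reduce(`*`, mats)               # per-sample label-agreement products
  agree <- rowSums(P)
  k <- 1 - agree
  failed <- agree <= 0 | k >= 1 - CONFLICT_TOL
  fused <- P / agree
  fused[failed, ] <- NA_real_

  decisions <- rep(NA_character_, length(ids))
  ok <- which(!failed)
  if (length(ok)) {
    Fok <- fused[ok, , drop = FALSE]
    top <- do.call(pmax, as.data.frame(Fok))
    cand <- Fok >= top - TIE_TOL * pmax(top, 1)
    decisions[ok] <- unclass(fr)[apply(cand, 1, which.max)]
  }

  failures <- tibble(row = which(failed),
                     sample_id = ids[failed],
                     reason = rep("complete conflict (k = 1)", sum(failed)))
  if (rule == "idset" && nrow(failures) > 0) {
    abort("Internal error: remapped batch fusion reported complete conflict.",
          class = "evidfuse_internal_error")
  }

  out <- dplyr::bind_cols(
    tibble(sample_id = ids, decision = decisions, k = k),
    as_tibble(fused, .name_repair = "minimal")
  )
  structure(out, frame = fr, rule = rule, n_sources = length(mats),
            failures = failures,
            class = c("fused_predictions", class(tibble())))
}

# Split a prediction table into ids + numeric matrix + frame.
parse_prediction_table <- function(p, what) {
  if (!is.data.frame(p)) {
    abort(sprintf("%s is not a data frame.", what),
          class = "evidfuse_validity_error")
  }
  p <- as_tibble(p)
  if (!"sample_id" %in% names(p)) {
    abort(sprintf("%s lacks a 'sample_id' column.", what),
          class = "evidfuse_parse_error")
  }
  labels <- setdiff(names(p), "sample_id")
  M <- as.matrix(p[, labels, drop = FALSE])
  if (!is.numeric(M)) {
    bad <- labels[!vapply(p[labels], is.numeric, TRUE)][1]
    abort(sprintf("%s: column '%s' is not numeric.", what, bad),
          class = "evidfuse_parse_error")
  }
  list(ids = as.character(p$sample_id), matrix = M, frame = as_frame(labels))
}

#' @export
print.fused_predictions <- function(x, ...) {
  cat("<fused_predictions> rule = ", attr(x, "rule"), ", ",
      attr(x, "n_sources"), " sources, ", nrow(x), " samples",
      sep = "")
  nf <- nrow(attr(x, "failures"))
  if (nf > 0) cat(" (", nf, " unfusable)", sep = "")
  cat("\n")
  NextMethod()
}

#' @export
glance.fused_predictions <- function(x, ...) {
  tibble(rule = attr(x, "rule"),
         n_samples = nrow(x),
         n_sources = attr(x, "n_sources"),
         n_failures = nrow(attr(x, "failures")),
         mean_k = mean(x$k, na.rm = TRUE))
}

#' @export
tidy.fused_predictions <- function(x, ...) {
  fr <- attr(x, "frame")
  tidyr::pivot_longer(as_tibble(x), cols = dplyr::all_of(unclass(fr)),
                      names_to = "label", values_to = "mass")
}

#' Plot per-sample conflict for fused predictions
#'
#' Histogram of the per-sample conflict factor k, faceted by decision.
#'
#' @param object A `fused_predictions` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fused_predictions <- function(object, bins = 30, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::labs(x = "conflict factor k", y = "samples",
                  title = paste0("Per-sample conflict (",
                                 attr(object, "rule"), " rule)")) +
    ggplot2::theme_minimal()
}

#' Read a classifier's prediction matrix / write fused predictions as CSV
#'
#' The prediction CSV has a `sample_id` column and one probability column
#' per class label; every row must be a valid BPA. The fused CSV has
#' columns `sample_id`, `decision`, `k`, and one mass column per class.
#' Values round-trip at full double precision.
#'
#' @param path File path.
#' @param tolerance,renormalize Row validation, as in [validate_mass()].
#' @return `read_predictions()`: a prediction tibble with attribute
#'   `source_name` (file stem). `write_fused()` returns `path` invisibly.
#' @export
read_predictions <- function(path, tolerance = 1e-6, renormalize = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  parsed <- parse_prediction_table(df, basename(path))
  M <- validate_mass_rows(parsed$matrix, parsed$frame, tolerance, renormalize,
                          what = paste0(basename(path), ": row"))
  out <- dplyr::bind_cols(tibble(sample_id = parsed$ids),
                          as_tibble(M, .name_repair = "minimal"))
  attr(out, "source_name") <- sub("\\.[^.]*$", "", basename(path))
  out
}

#' @rdname read_predictions
#' @param x A `fused_predictions` object (or prediction tibble).
#' @export
write_fused <- function(x, path) {
  readr::write_csv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
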