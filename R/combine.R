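#' Conflict factor of a set of evidence sources
#'
#' The conflict factor k is the total product mass that falls on
#' incompatible hypothesis combinations. For singleton (Bayesian) mass
#' functions the sources agree only when they all name the same label, so
#' \deqn{k = 1 - \sum_{A} \prod_{s} m_s(A),}
#' and `1 - k` is the normalization coefficient of Dempster's rule.
#' `k = 1` means complete conflict: the classical rule's denominator is
#' zero and combination fails.
#'
#' @param evidence Anything accepted by [as_evidence()]: a data frame or
#'   matrix of BPAs (rows = sources) or a list of `mass_function`s. At
#'   least two sources on a common frame.
#' @inheritParams as_evidence
#' @return The conflict factor, a number in \[0, 1\].
#' @examples
#' conflict_factor(rbind(c(F = 0.5, G = 0.2, H = 0.3),
#'                       c(F = 0.5, G = 0.2, H = 0.3),
#'                       c(F = 0.0, G = 0.9, H = 0.1),
#'                       c(F = 0.5, G = 0.2, H = 0.3)))
#' @export
conflict_factor <- function(evidence, tolerance = 1e-6) {
  ev <- as_evidence(evidence, tolerance = tolerance)
  M <- evidence_matrix(ev)
  check_n_sources(M)
  1 - sum(apply(M, 2, prod))
}

check_n_sources <- function(M) {
  if (nrow(M) < 2) {
    abort("Combination needs at least two evidence sources.",
          class = "evidfuse_validity_error")
  }
  invisible(TRUE)
}

# Relative tolerance under which two fused masses count as tied; one-ulp
# asymmetries in the product must not decide between mathematically equal
# hypotheses.
TIE_TOL <- 1e-12

# Threshold for declaring k = 1 (complete conflict).
CONFLICT_TOL <- 1e-12

# Tolerance-aware argmax over a mass vector: lowest frame index wins ties.
decide <- function(masses, frame) {
  top <- max(masses)
  cand <- which(masses >= top - TIE_TOL * max(top, 1))
  if (length(cand) > 1) {
    warn(paste0("Fused masses tie between {",
                paste(unclass(frame)[cand], collapse = ", "),
                "}; picking the lowest frame index ('",
                unclass(frame)[cand[1]], "')."),
         class = "evidfuse_tie_warning")
  }
  unclass(frame)[cand[1]]
}

new_fusion_result <- function(masses, frame, k, rule, n_sources) {
  structure(
    list(frame = frame,
         masses = setNames(as.numeric(masses), unclass(frame)),
         k = k, rule = rule,
         decision = decide(masses, frame),
         n_sources = n_sources),
    class = "fusion_result"
  )
}

#' Classical Dempster combination
#'
#' Fuses two or more singleton mass functions with Dempster's rule:
#' \deqn{(m_1 \oplus \cdots \oplus m_l)(A) = \frac{1}{1-k} \prod_s m_s(A),}
#' with conflict factor k as in [conflict_factor()]. The rule fails when
#' `k = 1` (complete conflict): a zero denominator. It also suffers the
#' one-vote veto: a single source with `m(A) = 0` forces the fused mass of
#' `A` to 0 regardless of the other evidence. [combine_idset()] removes
#' both defects.
#'
#' @inheritParams conflict_factor
#' @return A `fusion_result`: fused masses, conflict `k`, `rule`,
#'   `decision` (argmax label; ties go to the lowest frame index with a
#'   warning) and `n_sources`. See [tidy.fusion_result()],
#'   [glance.fusion_result()], [autoplot.fusion_result()].
#' @examples
#' combine_classical(rbind(c(F = 0.5, G = 0.2, H = 0.3),
#'                         c(F = 0.5, G = 0.2, H = 0.3),
#'                         c(F = 0.0, G = 0.9, H = 0.1),
#'                         c(F = 0.5, G = 0.2, H = 0.3)))
#' @export
combine_classical <- function(evidence, tolerance = 1e-6) {
  ev <- as_evidence(evidence, tolerance = tolerance)
  fr <- attr(ev, "frame")
  M <- evidence_matrix(ev)
  check_n_sources(M)
  res <- fuse_mass_matrix(M)
  if (res$failed) {
    abort(
      paste0("Complete conflict: k = 1 within tolerance, the normalization ",
             "denominator (1 - k) is zero and Dempster's rule cannot combine ",
             "this evidence. Consider the softmax-remapped rule (combine_idset)."),
      class = "evidfuse_complete_conflict"
    )
  }
  new_fusion_result(res$masses, fr, res$k, "classical", nrow(M))
}

# Product-then-normalize over a sources-by-labels matrix. The unnormalized
# agreement products are rescaled by their maximum before normalizing, an
# underflow guard for long products.
fuse_mass_matrix <- function(M) {
  p <- apply(M, 2, prod)
  k <- 1 - sum(p)
  top <- max(p)
  if (top <= 0 || k >= 1 - CONFLICT_TOL) {
    return(list(failed = TRUE, k = min(k, 1), masses = NULL))
  }
  q <- p / top
  list(failed = FALSE, k = k, masses = q / sum(q))
}

#' Softmax-remapped (paradox-free) Dempster combination
#'
#' Each source's BPA is first remapped by exponential normalization
#' ([softmax_remap()]), then the remapped masses are combined with the
#' classical rule. Because every remapped mass is strictly positive, the
#' post-remap conflict factor is strictly below 1 and combination never
#' fails -- the complete-conflict, zero-trust, one-trust and high-conflict
#' paradoxes of the classical rule are all eliminated, as is the one-vote
#' veto. Remapping is applied exactly once per source, to the raw BPAs
#' only; the fused output is not remapped again.
#'
#' @inheritParams conflict_factor
#' @param temperature Softmax temperature, see [softmax_remap()]. Leave at
#'   1 for the standard rule.
#' @return A `fusion_result` with `rule = "idset"` and `k` the post-remap
#'   conflict factor.
#' @examples
#' # Complete conflict: the classical rule fails, the remapped rule does not.
#' ev <- rbind(c(F = 1, G = 0, H = 0),
#'             c(F = 0, G = 1, H = 0),
#'             c(F = 0.8, G = 0.1, H = 0.1),
#'             c(F = 0.8, G = 0.1, H = 0.1))
#' combine_idset(ev)
#' @export
combine_idset <- function(evidence, tolerance = 1e-6, temperature = 1) {
  ev <- as_evidence(evidence, tolerance = tolerance)
  fr <- attr(ev, "frame")
  M <- evidence_matrix(ev)
  check_n_sources(M)
  res <- fuse_mass_matrix(softmax_rows(M, temperature))
  # unreachable for valid input: remapped masses are strictly positive
  if (res$failed) {
    abort("Internal error: remapped combination reported complete conflict.",
          class = "evidfuse_internal_error")
  }
  new_fusion_result(res$masses, fr, res$k, "idset", nrow(M))
}

#' @rdname combine_classical
#' @param rule `"classical"` or `"idset"`.
#' @param ... Passed to the selected rule.
#' @export
combine_evidence <- function(evidence, rule = c("classical", "idset"), ...) {
  rule <- match.arg(rule)
  switch(rule,
         classical = combine_classical(evidence, ...),
         idset = combine_idset(evidence, ...))
}

#' @export
print.fusion_result <- function(x, digits = 4, ...) {
  cat("<fusion_result> rule = ", x$rule, ", ", x$n_sources, " sources, k = ",
      format(round(x$k, digits)), "\n", sep = "")
  print(round(x$masses, digits))
  cat("decision: ", x$decision, "\n", sep = "")
  invisible(x)
}

#' Tidy a fusion result
#'
#' @param x A `fusion_result`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per hypothesis (`label`, `mass`,
#'   `decision` flag). `glance()`: a one-row tibble with `decision`, `k`,
#'   `rule`, `n_sources`.
#' @export
tidy.fusion_result <- function(x, ...) {
  tibble(label = as.character(unclass(x$frame)),
         mass = as.numeric(x$masses),
         decision = as.character(unclass(x$frame)) == x$decision)
}

#' @rdname tidy.fusion_result
#' @export
glance.fusion_result <- function(x, ...) {
  tibble(decision = x$decision, k = x$k, rule = x$rule,
         n_sources = x$n_sources)
}

#' Plot fused masses
#'
#' Bar chart of the fused mass over the frame, with the decision highlighted
#' and the conflict factor in the subtitle.
#'
#' @param object A `fusion_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fusion_result <- function(object, ...) {
  d <- tidy(object)
  d$label <- factor(d$label, levels = d$label)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$mass,
                                  fill = .data$decision)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#D55E00", `FALSE` = "grey55")) +
    ggplot2::labs(
      x = NULL, y = "fused mass",
      title = paste0("Fused evidence (", object$rule, " rule)"),
      subtitle = sprintf("k = %.4g; decision: %s", object$k, object$decision)
    ) +
    ggplot2::theme_minimal()
}

#' Serialize a fusion result to JSON
#'
#' @param x A `fusion_result`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
fusion_to_json <- function(x, path = NULL) {
  obj <- list(labels = as.character(unclass(x$frame)),
              masses = as.numeric(x$masses),
              k = x$k, rule = x$rule, decision = x$decision,
              n_sources = x$n_sources)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
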