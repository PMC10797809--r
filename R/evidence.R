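#' Coerce a table of evidence sources to a validated evidence tibble
#'
#' An evidence set is a tibble with one row per evidence source (classifier,
#' sensor, expert) and one numeric column per frame label, each row a valid
#' BPA. An optional `source` column carries source identifiers.
#'
#' @param x A data frame (optional `source` column plus one numeric column
#'   per label), a numeric matrix (rows = sources), or a list of
#'   `mass_function`s on a common frame.
#' @param frame Frame labels; defaults to the numeric column names of `x`.
#' @param tolerance,renormalize Row validation, as in [validate_mass()].
#' @return A tibble of class `evidence_tbl` with a `source` column, one
#'   column per label, and the frame attached.
#' @examples
#' as_evidence(rbind(m1 = c(F = 0.5, G = 0.2, H = 0.3),
#'                   m2 = c(F = 0.0, G = 0.9, H = 0.1)))
#' @export
as_evidence <- function(x, frame = NULL, tolerance = 1e-6, renormalize = FALSE) {
  if (inherits(x, "evidence_tbl") && is.null(frame)) return(x)
  if (is.list(x) && !is.data.frame(x) && all(vapply(x, inherits, TRUE, "mass_function"))) {
    frames <- lapply(x, mass_frame)
    for (f in frames[-1]) check_same_frame(frames[[1]], f)
    frame <- frames[[1]]
    M <- do.call(rbind, lapply(x, as.numeric))
    rownames(M) <- names(x) %||% paste0("m", seq_along(x))
    return(as_evidence(M, frame = frame, tolerance = tolerance,
                       renormalize = renormalize))
  }
  if (is.matrix(x)) {
    src <- rownames(x) %||% paste0("m", seq_len(nrow(x)))
    df <- as_tibble(x, .name_repair = "minimal")
    if (is.null(frame)) frame <- colnames(x)
    names(df) <- as.character(as_frame(frame))
    df <- dplyr::bind_cols(tibble(source = src), df)
    x <- df
  }
  if (!is.data.frame(x)) {
    abort("Evidence must be a data frame, matrix, or list of mass functions.",
          class = "evidfuse_validity_error")
  }
  x <- as_tibble(x)
  has_source <- "source" %in% names(x)
  label_cols <- setdiff(names(x), "source")
  if (is.null(frame)) frame <- label_cols
  frame <- as_frame(frame)
  missing_cols <- setdiff(unclass(frame), label_cols)
  if (length(missing_cols)) {
    abort(paste0("Evidence table is missing label column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "evidfuse_frame_error")
  }
  M <- as.matrix(x[, unclass(frame), drop = FALSE])
  if (!is.numeric(M)) {
    abort("Label columns must be numeric.", class = "evidfuse_validity_error")
  }
  M <- validate_mass_rows(M, frame, tolerance, renormalize)
  out <- dplyr::bind_cols(
    tibble(source = if (has_source) as.character(x$source)
           else paste0("m", seq_len(nrow(M)))),
    as_tibble(M, .name_repair = "minimal")
  )
  structure(out, frame = frame,
            class = c("evidence_tbl", class(tibble())))
}

# Validate every row of a sources-by-labels matrix; errors name the row.
validate_mass_rows <- function(M, frame, tolerance = 1e-6,
                               renormalize = FALSE, what = "evidence source") {
  if (nrow(M) == 0) {
    abort("At least one row of masses is required.",
          class = "evidfuse_validity_error")
  }
  bad <- which(!is.finite(M) | M < 0 | M > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    abort(
      sprintf("%s %d: mass for label '%s' is %s; masses must lie in [0, 1].",
              what, i, unclass(frame)[j], format(M[i, j])),
      class = "evidfuse_validity_error"
    )
  }
  s <- rowSums(M)
  off <- which(abs(s - 1) > tolerance)
  if (length(off)) {
    abort(
      sprintf("%s %d: masses sum to %.10g, outside tolerance %g of 1.",
              what, off[1], s[off[1]], tolerance),
      class = "evidfuse_normalization_error"
    )
  }
  if (renormalize) M <- M / s
  M
}

# Numeric matrix of masses from an evidence tibble.
evidence_matrix <- function(ev) {
  fr <- attr(ev, "frame")
  M <- as.matrix(ev[, unclass(fr), drop = FALSE])
  rownames(M) <- ev$source
  M
}

#' Read / write BPA tables as CSV
#'
#' The CSV layout is: header row = frame labels (plus an optional leading
#' `source` column), one row per evidence source, comma-delimited, `.`
#' decimal.
#'
#' @param path File path.
#' @param frame,tolerance,renormalize As in [as_evidence()].
#' @return `read_bpa()` returns an `evidence_tbl`; `write_bpa()` returns
#'   `path` invisibly.
#' @export
read_bpa <- function(path, frame = NULL, tolerance = 1e-6, renormalize = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_evidence(df, frame = frame, tolerance = tolerance, renormalize = renormalize)
}

#' @rdname read_bpa
#' @param ev An `evidence_tbl`.
#' @export
write_bpa <- function(ev, path) {
  readr::write_csv(as_tibble(ev), path, progress = FALSE)
  invisible(path)
}
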