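#' Frame of discernment
#'
#' A frame of discernment is the ordered, exhaustive set of mutually
#' exclusive hypotheses (e.g. disease classes) over which mass functions
#' are defined. Label order is fixed: every mass function and prediction
#' matrix on the frame indexes its entries by this order, and the order
#' breaks argmax ties (lowest index wins).
#'
#' @param labels Character vector of distinct, non-empty hypothesis labels;
#'   at least two.
#' @return A `ds_frame` object (a character vector of labels).
#' @examples
#' ds_frame(c("F", "G", "H"))
#' @export
ds_frame <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2) {
    abort("A frame needs at least two hypothesis labels.", class = "evidfuse_frame_error")
  }
  if (anyDuplicated(labels)) {
    abort(
      paste0("Frame labels must be unique; duplicated: ",
             paste(unique(labels[duplicated(labels)]), collapse = ", ")),
      class = "evidfuse_frame_error"
    )
  }
  if (any(is.na(labels) | !nzchar(labels))) {
    abort("Frame labels must be non-empty strings.", class = "evidfuse_frame_error")
  }
  structure(labels, class = "ds_frame")
}

#' @export
print.ds_frame <- function(x, ...) {
  cat("<ds_frame> ", length(x), " hypotheses: ",
      paste(unclass(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
format.ds_frame <- function(x, ...) format(unclass(x), ...)

is_ds_frame <- function(x) inherits(x, "ds_frame")

# Coerce labels to a frame, passing existing frames through.
as_frame <- function(x) {
  if (is_ds_frame(x)) x else ds_frame(x)
}

# Check two frames agree (same labels, same order).
check_same_frame <- function(a, b) {
  if (!identical(unclass(as_frame(a)), unclass(as_frame(b)))) {
    abort("Evidence sources are defined on different frames.",
          class = "evidfuse_frame_error")
  }
  invisible(TRUE)
}
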