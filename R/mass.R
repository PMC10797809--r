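#' Validate a basic probability assignment
#'
#' A basic probability assignment (BPA, or mass function) over a frame
#' assigns each singleton hypothesis a mass in \[0, 1\], with masses summing
#' to 1. This package works with singleton-only ("Bayesian") mass
#' functions, the kind produced by a classifier's softmax layer; mass on
#' composite subsets is out of scope.
#'
#' @param masses Numeric vector, one entry per frame label, in label order.
#'   Names, if present and no `frame` is given, supply the frame.
#' @param frame A [ds_frame()] or character vector of labels. If `NULL`,
#'   taken from `names(masses)`, or defaulted to `A1...An`.
#' @param tolerance Permitted deviation of `sum(masses)` from 1
#'   (default `1e-6`, sized for CSV round-tripping of softmax outputs).
#' @param renormalize If `TRUE` and the sum is within `tolerance` of 1,
#'   divide by the sum so the result sums to 1 exactly.
#' @return A `mass_function`: a named numeric vector with the frame attached.
#' @examples
#' validate_mass(c(F = 0.5, G = 0.2, H = 0.3))
#' @export
validate_mass <- function(masses, frame = NULL, tolerance = 1e-6,
                          renormalize = FALSE) {
  if (inherits(masses, "mass_function") && is.null(frame)) {
    frame <- mass_frame(masses)
  }
  if (is.null(frame)) {
    frame <- names(masses) %||% paste0("A", seq_along(masses))
  }
  masses <- as.numeric(masses)
  frame <- as_frame(frame)
  if (length(masses) != length(frame)) {
    abort(
      sprintf("Mass vector has %d entries but the frame has %d labels.",
              length(masses), length(frame)),
      class = "evidfuse_validity_error"
    )
  }
  bad <- which(!is.finite(masses) | masses < 0 | masses > 1)
  if (length(bad)) {
    abort(
      sprintf("Mass at index %d (label '%s') is %s; masses must lie in [0, 1].",
              bad[1], frame[bad[1]], format(masses[bad[1]])),
      class = "evidfuse_validity_error"
    )
  }
  s <- sum(masses)
  if (abs(s - 1) > tolerance) {
    abort(
      sprintf("Masses must sum to 1 (got %.10g, tolerance %g).", s, tolerance),
      class = "evidfuse_normalization_error"
    )
  }
  if (renormalize) masses <- masses / s
  new_mass_function(masses, frame)
}

new_mass_function <- function(masses, frame, class = character()) {
  structure(setNames(as.numeric(masses), unclass(frame)),
            frame = frame,
            class = c(class, "mass_function"))
}

#' @export
print.mass_function <- function(x, digits = 4, ...) {
  tag <- if (inherits(x, "remapped_mass")) "remapped_mass" else "mass_function"
  cat("<", tag, "> on {", paste(unclass(mass_frame(x)), collapse = ", "), "}\n",
      sep = "")
  print(round(unclass(strip_mass(x)), digits))
  invisible(x)
}

mass_frame <- function(m) attr(m, "frame") %||% as_frame(names(m))

# Drop class/attrs, keep names: plain numeric vector of masses.
strip_mass <- function(m) {
  a <- as.numeric(m)
  names(a) <- names(m)
  a
}

#' @export
tidy.mass_function <- function(x, ...) {
  tibble(label = as.character(unclass(mass_frame(x))), mass = as.numeric(x))
}

#' Softmax remapping of a mass function
#'
#' Remaps a BPA by exponential normalization:
#' \deqn{m'(A_i) = \exp(m(A_i)) / \sum_j \exp(m(A_j)).}
#' The map is strictly increasing, so it preserves the ranking of the
#' hypotheses (ties stay ties), and every remapped mass is strictly
#' positive -- which is what rescues Dempster combination from the
#' conflict paradoxes: no hypothesis can be vetoed by a single zero mass,
#' and the post-remap conflict factor is always below 1. Because inputs
#' lie in \[0, 1\], each remapped entry lies in
#' \eqn{[1/(1 + (n-1)e),\; e/(e + n - 1)]} for a frame of size n.
#'
#' Remapping is applied exactly once per evidence source; passing an
#' already-remapped mass is an error.
#'
#' @param m A `mass_function` (or numeric vector, validated first).
#' @param frame,tolerance Passed to [validate_mass()] when `m` is a bare
#'   numeric vector.
#' @param temperature Divisor of the masses inside the exponential. The
#'   default 1 is the parameter-free map used everywhere in this package;
#'   the argument exists for experimentation only.
#' @return A `remapped_mass` (also a `mass_function`); the raw input is
#'   kept in attribute `raw`.
#' @examples
#' softmax_remap(validate_mass(c(F = 1, G = 0, H = 0)))
#' @export
softmax_remap <- function(m, frame = NULL, tolerance = 1e-6, temperature = 1) {
  if (inherits(m, "remapped_mass")) {
    abort("This mass function has already been softmax-remapped; remapping is applied exactly once per source.",
          class = "evidfuse_remap_error")
  }
  if (!inherits(m, "mass_function")) {
    m <- validate_mass(m, frame = frame, tolerance = tolerance)
  }
  fr <- mass_frame(m)
  e <- exp(as.numeric(m) / temperature)
  out <- new_mass_function(e / sum(e), fr, class = "remapped_mass")
  attr(out, "raw") <- strip_mass(m)
  out
}

# Row-wise softmax of a sources-by-labels matrix (internal fast path).
softmax_rows <- function(M, temperature = 1) {
  E <- exp(M / temperature)
  E / rowSums(E)
}
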