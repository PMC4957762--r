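#' Molecular combing calibration
#'
#' Combed DNA is stretched at a constant extension factor (kb of DNA per
#' micrometer of fiber), and images are acquired with a fixed pixel size.
#' A `calibration` object carries both constants and their product, the
#' kb-per-pixel conversion factor used throughout the package.
#'
#' @param stretch_kb_per_um Stretching factor in kb per micrometer.
#'   Standard combing yields 2 kb/um.
#' @param pixel_um Pixel size of the imaging system in micrometers.
#' @return An object of class `calibration` with fields
#'   `stretch_kb_per_um`, `pixel_um` and the derived `pixel_kb`
#'   (kb per pixel, reported to 4 decimals by `print`).
#' @examples
#' cal <- calibration(2, 0.16125)
#' cal$pixel_kb   # 0.3225
#' @export
calibration <- function(stretch_kb_per_um = 2, pixel_um = 0.16125) {
  if (!is.numeric(stretch_kb_per_um) || length(stretch_kb_per_um) != 1L ||
      !is.finite(stretch_kb_per_um) || stretch_kb_per_um <= 0) {
    stop("`stretch_kb_per_um` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(pixel_um) || length(pixel_um) != 1L ||
      !is.finite(pixel_um) || pixel_um <= 0) {
    stop("`pixel_um` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      stretch_kb_per_um = stretch_kb_per_um,
      pixel_um = pixel_um,
      pixel_kb = stretch_kb_per_um * pixel_um
    ),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat("Combing calibration\n")
  cat(sprintf("  stretch: %g kb/um\n", x$stretch_kb_per_um))
  cat(sprintf("  pixel:   %g um\n", x$pixel_um))
  cat(sprintf("  derived: %.4f kb/pixel\n", x$pixel_kb))
  invisible(x)
}

#' Convert pixel counts to kilobases
#'
#' @param n_pixels Non-negative pixel count(s).
#' @param cal A [calibration()] object.
#' @return Length(s) in kb: `n_pixels * pixel_um * stretch_kb_per_um`.
#' @examples
#' px_to_kb(1, calibration())    # 0.3225
#' px_to_kb(100, calibration())  # 32.25
#' @export
px_to_kb <- function(n_pixels, cal = calibration()) {
  stopifnot(inherits(cal, "calibration"))
  if (!is.numeric(n_pixels) || any(!is.finite(n_pixels)) || any(n_pixels < 0)) {
    stop("`n_pixels` must be non-negative and finite", call. = FALSE)
  }
  n_pixels * cal$pixel_um * cal$stretch_kb_per_um
}

#' Convert micrometers to kilobases
#'
#' @param um Non-negative length(s) in micrometers.
#' @inheritParams px_to_kb
#' @return Length(s) in kb.
#' @export
um_to_kb <- function(um, cal = calibration()) {
  stopifnot(inherits(cal, "calibration"))
  if (!is.numeric(um) || any(!is.finite(um)) || any(um < 0)) {
    stop("`um` must be non-negative and finite", call. = FALSE)
  }
  um * cal$stretch_kb_per_um
}

# internal: convert a coordinate vector from `units` to kb
.to_kb <- function(x, units, cal) {
  switch(units,
    kb = x,
    um = x * cal$stretch_kb_per_um,
    px = x * cal$pixel_um * cal$stretch_kb_per_um,
    stop(sprintf("unknown units '%s' (expected px, um or kb)", units),
         call. = FALSE)
  )
}
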