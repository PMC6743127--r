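#' The seven dry-powder inhalers under comparison
#'
#' Returns the closed set of device names handled by the package, in
#' canonical (alphabetical) order. The canonical order is used wherever a
#' deterministic ordering is required: baseline-device selection within a
#' respondent, tie-breaking of posterior ranks, and column order of the
#' rank-probability matrix.
#'
#' @return A character vector of length 7.
#' @export
#' @examples
#' dpi_devices()
dpi_devices <- function() {
  c("Breezhaler", "Diskus", "Ellipta", "Genuair",
    "Nexthaler", "Spiromax", "Turbohaler")
}

#' Canonicalise device names
#'
#' Trims whitespace and matches case-insensitively against the closed set of
#' seven devices, so that e.g. `"Diskus "` or `"ellipta"` are accepted.
#'
#' @param x Character vector of device names.
#' @return Character vector of canonical device names.
#' @export
match_device <- function(x) {
  canon <- dpi_devices()
  idx <- match(tolower(trimws(x)), tolower(canon))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop_gusnet(
      sprintf("unknown device name(s): %s", paste(sQuote(bad), collapse = ", ")),
      class = "gusnet_parse_error"
    )
  }
  canon[idx]
}

# Device factor in canonical order; used internally for deterministic sorting.
device_factor <- function(x) factor(match_device(x), levels = dpi_devices())

# Shared condition constructor: all package errors carry a gusnet_* class so
# callers (and tests) can distinguish failure modes.
stop_gusnet <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "gusnet_error"), ...)
}

warn_gusnet <- function(message, class, ...) {
  rlang::warn(message, class = c(class, "gusnet_warning"), ...)
}
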