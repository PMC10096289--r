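#' Derive a reproducible child seed from a master seed
#'
#' All randomness in the package flows from a single master seed through named
#' derivations, so that independent pipeline stages (fold splits, negative
#' sampling, per-forest seeds, ...) draw from decorrelated but fully
#' reproducible streams. The derivation is a 31-bit polynomial hash of the
#' master seed and the name parts; no global RNG state is consumed.
#'
#' @param master integer master seed.
#' @param ... character or numeric name parts identifying the consumer
#'   (e.g. `"fold"`, repeat index, fold index).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "fold", 1, 3)
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  key <- paste(c(format(master, scientific = FALSE), vapply(list(...), function(x)
    paste(format(x, scientific = FALSE), collapse = ","), character(1))),
    collapse = ":")
  h <- abs(as.integer(master)) %% 2147483647
  for (b in utf8ToInt(key)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h + 1L)
}

#' @keywords internal
#' @noRd
stop_dtimoa <- function(class, msg, ...) {
  stop(structure(class = c(class, "dtimoa_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' @keywords internal
#' @noRd
assert_numeric_vector <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_dtimoa("dtimoa_invalid_input", "`%s` must be a finite numeric vector", name)
  }
  invisible(x)
}
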