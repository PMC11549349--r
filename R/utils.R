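#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for reported ratios and lengths:
#' ties go away from zero rather than to the even digit.
#'
#' @param x numeric vector.
#' @param digits integer, number of decimal places (>= 0).
#' @return numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.25, 1)  # 0.3, where round() gives 0.2
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_validation <- function(msg, call. = FALSE) {
  stop(structure(class = c("paleosnake_validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
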