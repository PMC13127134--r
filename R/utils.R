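# small shared helpers

# collect validation messages; stop with all of them at once
fail_all <- function(errors, context) {
  if (length(errors)) {
    stop(sprintf("invalid %s:\n%s", context,
                 paste0("  - ", errors, collapse = "\n")), call. = FALSE)
  }
  invisible(TRUE)
}

check_finite <- function(x, what, errors) {
  if (any(!is.finite(x))) {
    errors <- c(errors, sprintf("%s contains non-finite values (NA/NaN/Inf)",
                                what))
  }
  errors
}

#' Round half away from zero at a display precision
#'
#' Base R's `round()` rounds half to even; the printed tables follow the
#' conventional half-up rule (e.g. 76.05 -> 76.1 at one decimal place), so
#' all display rounding in the package goes through this helper. Internal
#' arithmetic is never rounded.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (may be negative).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(76.05, 1)   # 76.1
#' round_half_up(2.5, 0)     # 3
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
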