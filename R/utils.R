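#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), the convention used for
#' the percentage fields of report objects. `base::round` rounds half to even,
#' which disagrees with how panel summaries are conventionally printed.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
roundHalfUp <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Run code with a private, seeded RNG stream, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

.assertNumericSample <- function(x, name) {
  if (length(x) == 0L) stop("sample '", name, "' is empty", call. = FALSE)
  if (!is.numeric(x)) stop("sample '", name, "' must be numeric", call. = FALSE)
  if (anyNA(x)) stop("sample '", name, "' contains NA", call. = FALSE)
  invisible(TRUE)
}
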