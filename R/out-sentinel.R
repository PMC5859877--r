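#' The OUT sentinel for reproductive-fitness values
#'
#' A well's reproductive fitness (RF) cannot be evaluated when the number of
#' parent worms falls outside the validity window (progeny counts scale
#' linearly with parents only within it), or when a replicate failed for
#' technical reasons. Such replicates carry the sentinel value `OUT` rather
#' than a number. Internally `OUT` is encoded as `NaN` so that RF columns stay
#' numeric, while a plain `NA` means a value that was never measured (for
#' example an empty well). On disk the sentinel is written as the literal
#' string `"OUT"`.
#'
#' @return `rf_out()` returns the sentinel (`NaN`). `is_out(x)` returns a
#'   logical vector, `TRUE` where `x` carries the sentinel.
#' @examples
#' x <- c(10, rf_out(), NA)
#' is_out(x)  # FALSE TRUE FALSE
#' @export
rf_out <- function() NaN

#' @rdname rf_out
#' @param x numeric vector of RF values.
#' @export
is_out <- function(x) is.nan(x)

# mean over usable (non-OUT, non-missing) replicates; all unusable -> OUT
mean_rf <- function(x) {
  usable <- x[!is.na(x)]
  if (length(usable) == 0) rf_out() else mean(usable)
}
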