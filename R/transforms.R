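#' Map chronological age to the training response scale
#'
#' Identity for human clocks; the relative-age transform
#' `log(age + offset)` (natural log) for cross-species clocks, where the
#' offset (default 2 years) keeps prenatal/newborn ages finite.
#'
#' @param age Numeric vector of ages in years (non-negative).
#' @param transform An [AgeTransform-class].
#' @return Numeric vector on the response scale.
#' @examples
#' transformAge(c(0, 50), ageTransform("log_offset", 2))
#' @export
transformAge <- function(age, transform = ageTransform("identity")) {
  stopifnot(is(transform, "AgeTransform"))
  if (any(age < 0, na.rm = TRUE))
    stop("ages must be non-negative")
  if (transform@kind == "identity") return(age)
  shifted <- age + transform@offset
  if (any(shifted <= 0, na.rm = TRUE))
    stop("age + offset must be positive for the log_offset transform")
  log(shifted)
}

#' Map a response-scale value back to years
#'
#' Exact inverse of [transformAge()]: identity, or
#' `exp(y) - offset` for the relative-age scale.
#'
#' @param y Numeric vector on the response scale.
#' @param transform An [AgeTransform-class].
#' @return Ages in years.
#' @examples
#' inverseTransformAge(log(2), ageTransform("log_offset", 2))  # 0
#' @export
inverseTransformAge <- function(y, transform = ageTransform("identity")) {
  stopifnot(is(transform, "AgeTransform"))
  if (transform@kind == "identity") return(y)
  exp(y) - transform@offset
}
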