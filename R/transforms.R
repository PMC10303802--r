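#' Age transform specification
#'
#' Epigenetic clock models predict age on a transformed scale. Two transform
#' kinds are supported: `"identity"` (the linear predictor is already in
#' years, as in PhenoAge-style clocks) and `"piecewise_log_linear"` (the
#' Horvath-style calibration, logarithmic below `adult_age` and linear above
#' it, so that childhood methylation change per year is allowed to be faster
#' than adult change).
#'
#' @param kind One of `"piecewise_log_linear"` or `"identity"`.
#' @param adult_age Positive age in years at which the piecewise transform
#'   switches from its logarithmic to its linear branch. Ignored by the
#'   identity transform. Default 20.
#' @return An object of class `"transform_spec"`.
#' @examples
#' sp <- transform_spec("piecewise_log_linear")
#' age_transform(41, sp) # 1
#' inverse_age_transform(0, sp) # 20
#' @export
transform_spec <- function(kind = c("piecewise_log_linear", "identity"),
                           adult_age = 20) {
  kind <- match.arg(kind)
  if (!is.numeric(adult_age) || length(adult_age) != 1L ||
      !is.finite(adult_age) || adult_age <= 0) {
    stop("'adult_age' must be a single positive number")
  }
  structure(list(kind = kind, adult_age = as.numeric(adult_age)),
            class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  if (x$kind == "identity") {
    cat("Age transform: identity\n")
  } else {
    cat(sprintf("Age transform: piecewise log/linear (adult age %g yr)\n",
                x$adult_age))
  }
  invisible(x)
}

#' Forward age transform
#'
#' Maps chronological age onto the clock's transformed scale. For the
#' piecewise transform with adult age \eqn{A}:
#' \deqn{F(a) = \log(a+1) - \log(A+1) \quad (a \le A), \qquad
#'       F(a) = (a-A)/(A+1) \quad (a > A).}
#' F is continuous and strictly increasing; `inverse_age_transform()` is its
#' exact inverse.
#'
#' @param age Numeric vector of ages in years. Must be non-negative for the
#'   piecewise transform.
#' @param spec A [transform_spec()].
#' @return Numeric vector of transformed ages.
#' @export
age_transform <- function(age, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  if (!is.numeric(age)) stop("'age' must be numeric")
  if (spec$kind == "identity") return(as.numeric(age))
  if (any(is.finite(age) & age < 0)) {
    stop("negative age is outside the domain of the piecewise transform")
  }
  A <- spec$adult_age
  ifelse(age <= A, log(age + 1) - log(A + 1), (age - A) / (A + 1))
}

#' Inverse age transform
#'
#' Maps a value on the clock's transformed scale back to years:
#' \eqn{(A+1)e^x - 1} for \eqn{x \le 0}, \eqn{(A+1)x + A} for \eqn{x > 0}.
#'
#' @param x Numeric vector of transformed values.
#' @inheritParams age_transform
#' @return Numeric vector of ages in years.
#' @export
inverse_age_transform <- function(x, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (spec$kind == "identity") return(as.numeric(x))
  A <- spec$adult_age
  ifelse(x <= 0, (A + 1) * exp(x) - 1, (A + 1) * x + A)
}
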