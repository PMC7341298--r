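#' Gompertz parameters, classical form
#'
#' Constructs and validates the parameter set of the classical Gompertz
#' growth equation \eqn{BW(t) = BWa \exp(-b e^{-kt})}.
#'
#' @param BWa asymptotic (adult) body weight, g.
#' @param b dimensionless shape parameter, related to the asymptote and the
#'   hatch weight by \eqn{b = \ln(BWa/BW_0)}.
#' @param k instantaneous relative growth rate, per day.
#' @return An object of class `c("g1_params", "gompertz_params")`.
#' @seealso [g2_params()], [convert_g1_to_g2()], [derive_traits()]
#' @examples
#' p <- g1_params(BWa = 2184, b = 3.32, k = 0.014)
#' predict_g1(p, t = c(0, 86, 180))
#' @export
g1_params <- function(BWa, b, k) {
  check_positive_scalar(BWa, "BWa")
  check_positive_scalar(b, "b")
  check_positive_scalar(k, "k")
  structure(list(BWa = as.numeric(BWa), b = as.numeric(b), k = as.numeric(k)),
            class = c("g1_params", "gompertz_params"))
}

#' Gompertz parameters, lag-time form
#'
#' Constructs and validates the parameter set of the reparameterized
#' Gompertz equation
#' \eqn{BW(t) = BWa \exp\{-\exp[(e\mu/BWa)(\lambda - t) + 1]\}},
#' in which every parameter has a direct biological reading: `mu` is the
#' absolute growth rate at the inflection point (g/day) and `lam` is the
#' lag time (days), the intercept of the inflection tangent with the time
#' axis.
#'
#' @param BWa asymptotic body weight, g.
#' @param mu absolute growth rate at the inflection point, g/day.
#' @param lam lag time, days. Slightly negative values are mathematically
#'   valid (birds growing fast from hatch, shape parameter below e) and are
#'   accepted with a warning.
#' @return An object of class `c("g2_params", "gompertz_params")`.
#' @export
g2_params <- function(BWa, mu, lam) {
  check_positive_scalar(BWa, "BWa")
  check_positive_scalar(mu, "mu")
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam))
    stop("'lam' must be a finite number", call. = FALSE)
  if (lam < 0)
    warning("negative lag time: inflection tangent crosses the time axis before hatch",
            call. = FALSE)
  structure(list(BWa = as.numeric(BWa), mu = as.numeric(mu), lam = as.numeric(lam)),
            class = c("g2_params", "gompertz_params"))
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single finite positive number", name), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.gompertz_params <- function(x, ...) {
  tag <- if (inherits(x, "g1_params")) "classical (asymptote/shape/rate)" else "lag-time"
  cat("Gompertz parameters,", tag, "form\n")
  print(unlist(x), ...)
  invisible(x)
}

#' Predicted weight under the classical Gompertz form
#'
#' @param params a [g1_params()] object.
#' @param t age in days (vectorized).
#' @return Predicted body weight in g, strictly increasing in `t` and
#'   bounded above by `BWa`.
#' @export
predict_g1 <- function(params, t) {
  stopifnot(inherits(params, "g1_params"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric", call. = FALSE)
  params$BWa * exp(-params$b * exp(-params$k * t))
}

#' Predicted weight under the lag-time Gompertz form
#'
#' @param params a [g2_params()] object.
#' @inheritParams predict_g1
#' @return Predicted body weight in g.
#' @export
predict_g2 <- function(params, t) {
  stopifnot(inherits(params, "g2_params"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric", call. = FALSE)
  params$BWa * exp(-exp((exp(1) * params$mu / params$BWa) * (params$lam - t) + 1))
}

#' Convert between the two Gompertz parameterizations
#'
#' The two forms describe the same three-parameter family; equating the
#' exponents gives `mu = BWa*k/e`, `lam = (ln(b) - 1)/k` and, inversely,
#' `k = e*mu/BWa`, `b = exp(k*lam + 1)`. Round trips are identities and the
#' predicted curves are pointwise equal.
#'
#' @param params a [g1_params()] (respectively [g2_params()]) object.
#' @return The equivalent parameter set in the other form.
#' @export
convert_g1_to_g2 <- function(params) {
  stopifnot(inherits(params, "g1_params"))
  mu <- params$BWa * params$k / exp(1)
  lam <- (log(params$b) - 1) / params$k
  g2_params(BWa = params$BWa, mu = mu, lam = lam)
}

#' @rdname convert_g1_to_g2
#' @export
convert_g2_to_g1 <- function(params) {
  stopifnot(inherits(params, "g2_params"))
  k <- exp(1) * params$mu / params$BWa
  b <- exp(k * params$lam + 1)
  g1_params(BWa = params$BWa, b = b, k = k)
}

#' Shape parameter from asymptotic and hatch weight
#'
#' In the classical form the shape parameter equals `ln(BWa/BW0)`, i.e. the
#' model-implied hatch weight is `BWa*exp(-b)`. Fitted shape values need not
#' agree with this when the true hatch weight is known, because the fitted
#' hatch weight is a free consequence of the fit.
#'
#' @param BWa asymptotic body weight, g.
#' @param BW0 hatch (initial) weight, g; must be below `BWa`.
#' @return The dimensionless shape parameter.
#' @export
shape_from_weights <- function(BWa, BW0) {
  check_positive_scalar(BWa, "BWa")
  check_positive_scalar(BW0, "BW0")
  if (BW0 >= BWa)
    stop("'BW0' must be strictly smaller than 'BWa'", call. = FALSE)
  log(BWa / BW0)
}

#' Derived maturity traits of a Gompertz curve
#'
#' Computes the biologically meaningful quantities implied by a Gompertz
#' parameter set: weight and age at the inflection point (where absolute
#' growth rate is maximal), the maximum growth rate, the predicted weight at
#' slaughter age, the degree of maturity and the model-implied hatch weight.
#' The inflection weight is always `BWa/e` (the Gompertz constant, kept at
#' full precision, 0.367879...; rounding to 0.368 happens only at display).
#'
#' For the lag-time form the inflection age has the closed form
#' `lam + BWa/(e*mu)`; it is cross-checked against a numeric root of
#' `BW(t) = BWa/e` and the two must agree to 1e-6 days.
#'
#' @param params a [g1_params()] or [g2_params()] object.
#' @param t_slaughter slaughter age in days (default 180, the customary age
#'   for sale of these slow-growing breeds).
#' @return An object of class `"derived_traits"`: a list with elements
#'   `BWip` (g), `Tip` (days), `MGR` (g/day), `BWs` (g), `Dm`
#'   (dimensionless, in (0,1) for finite slaughter age) and `BW0_implied` (g).
#' @examples
#' derive_traits(g1_params(2184, 3.32, 0.014))
#' @export
derive_traits <- function(params, t_slaughter = 180) {
  UseMethod("derive_traits")
}

#' @export
derive_traits.g1_params <- function(params, t_slaughter = 180) {
  check_positive_scalar(t_slaughter, "t_slaughter")
  BWip <- params$BWa / exp(1)
  Tip <- log(params$b) / params$k
  if (params$b <= 1)
    warning("shape parameter b <= 1: inflection point precedes hatch (Tip <= 0)",
            call. = FALSE)
  BWs <- predict_g1(params, t_slaughter)
  new_derived_traits(
    BWip = BWip, Tip = Tip, MGR = BWip * params$k, BWs = BWs,
    Dm = BWs / params$BWa, BW0_implied = params$BWa * exp(-params$b))
}

#' @export
derive_traits.g2_params <- function(params, t_slaughter = 180) {
  check_positive_scalar(t_slaughter, "t_slaughter")
  if (params$mu < 1e-12 * params$BWa)
    stop("degenerate curve: growth rate at inflection is effectively zero", call. = FALSE)
  BWip <- params$BWa / exp(1)
  Tip <- params$lam + params$BWa / (exp(1) * params$mu)
  # numeric cross-check of the closed form against BW(t) = BWa/e
  root <- stats::uniroot(function(t) predict_g2(params, t) - BWip,
                         lower = Tip - 50, upper = Tip + 50,
                         tol = 1e-9, extendInt = "upX")$root
  if (abs(root - Tip) > 1e-6)
    stop("inflection-age cross-check failed: closed form and numeric root disagree",
         call. = FALSE)
  BWs <- predict_g2(params, t_slaughter)
  new_derived_traits(
    BWip = BWip, Tip = Tip, MGR = params$mu, BWs = BWs,
    Dm = BWs / params$BWa,
    BW0_implied = predict_g2(params, 0))
}

new_derived_traits <- function(BWip, Tip, MGR, BWs, Dm, BW0_implied) {
  structure(list(BWip = BWip, Tip = Tip, MGR = MGR, BWs = BWs, Dm = Dm,
                 BW0_implied = BW0_implied),
            class = "derived_traits")
}

#' @export
print.derived_traits <- function(x, digits = 4, ...) {
  cat("Derived Gompertz traits\n")
  print(round(unlist(x), digits))
  invisible(x)
}
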