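#' Construct a coefficient set for the prediction equations
#'
#' A coefficient set ties a response (`toL` or `carL`) and one or two
#' predictor traits to the intercept `a` and slope(s) `b` (and `b2`) of the
#' log-log prediction equation `Y = exp(a + b ln x1 [+ b2 ln x2])`, with
#' optional 95% credible bounds.
#'
#' @param response Response trait name.
#' @param predictors Character vector of 1-2 predictor trait names.
#' @param a Intercept (log-mm).
#' @param b Slope of the first predictor (dimensionless).
#' @param b2 Slope of the second predictor, or `NULL`.
#' @param bounds Optional list with elements `a`, `b` (and `b2`), each a
#'   length-2 numeric `c(lower, upper)`.
#' @param rmse_mm Optional model RMSE in mm.
#' @param source `"bundled"` or `"fitted"`.
#' @return List of class `"coefficient_set"`.
#' @export
coefficient_set <- function(response, predictors, a, b, b2 = NULL,
                            bounds = NULL, rmse_mm = NA_real_,
                            source = "fitted") {
  stopifnot(is.numeric(a), is.numeric(b), is.finite(a), is.finite(b),
            length(predictors) %in% 1:2)
  if (length(predictors) == 2L && (is.null(b2) || !is.finite(b2))) {
    stop("two predictors require a finite b2")
  }
  structure(list(response = response, predictors = predictors,
                 a = a, b = b, b2 = b2, bounds = bounds,
                 rmse_mm = rmse_mm, source = source),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  eq <- sprintf("%s = exp(%.4g + %.4g ln(%s)%s)", x$response, x$a, x$b,
                x$predictors[1],
                if (!is.null(x$b2))
                  sprintf(" + %.4g ln(%s)", x$b2, x$predictors[2]) else "")
  cat(eq, "  [", x$source, "]\n", sep = "")
  invisible(x)
}

#' Bundled coefficient sets for buthid scorpions
#'
#' The thirteen published single-predictor coefficient sets (posterior
#' means with 95% credible bounds, at the printed two-decimal precision)
#' from Bayesian phylogenetic mixed models fitted to log-transformed
#' species means of 195 buthid species: seven predictors of total length
#' (`toL`) and six of carapace length (`carL`). Stored as
#' `(response, predictor)` pairs keyed `"response|predictor"`.
#'
#' @return Named list of `"coefficient_set"` objects, names
#'   `"response|predictor"`, ordered by ascending RMSE within response.
#' @export
bundled_coefficients <- function() {
  row <- function(response, predictor, rmse, a, a_lo, a_hi, b, b_lo, b_hi) {
    coefficient_set(response, predictor, a = a, b = b,
                    bounds = list(a = c(a_lo, a_hi), b = c(b_lo, b_hi)),
                    rmse_mm = rmse, source = "bundled")
  }
  sets <- list(
    row("toL", "met5L",  6.41, 2.13, 2.03, 2.22, 0.95, 0.91, 0.99),
    row("toL", "carL",   6.46, 2.18, 2.08, 2.27, 1.01, 0.97, 1.05),
    row("toL", "teL",    7.22, 2.32, 2.21, 2.44, 0.90, 0.86, 0.94),
    row("toL", "cheL",   8.84, 2.27, 2.08, 2.50, 0.72, 0.67, 0.78),
    row("toL", "teW",    9.27, 3.29, 3.13, 3.44, 0.82, 0.77, 0.86),
    row("toL", "cheW",  10.70, 3.40, 3.23, 3.57, 0.63, 0.57, 0.69),
    row("toL", "met5W", 12.24, 3.13, 2.94, 3.34, 0.71, 0.65, 0.77),
    row("carL", "teL",   0.68, 0.24, 0.13, 0.34, 0.84, 0.80, 0.87),
    row("carL", "teW",   0.76, 1.12, 0.99, 1.22, 0.78, 0.74, 0.81),
    row("carL", "met5L", 0.96, 0.10, -0.02, 0.22, 0.85, 0.80, 0.90),
    row("carL", "cheL",  0.98, 0.22, 0.04, 0.42, 0.66, 0.61, 0.71),
    row("carL", "met5W", 1.02, 0.95, 0.75, 1.09, 0.71, 0.66, 0.76),
    row("carL", "cheW",  1.06, 1.22, 1.08, 1.39, 0.60, 0.55, 0.65)
  )
  names(sets) <- vapply(sets, function(s)
    paste(s$response, s$predictors[1], sep = "|"), character(1))
  sets
}

# case-insensitive predictor vocabulary of the prediction interface
.normalise_predictor <- function(predictor, response) {
  vocab <- c(met5l = "met5L", met5w = "met5W", carl = "carL", tel = "teL",
             tew = "teW", chel = "cheL", chew = "cheW")
  key <- tolower(predictor)
  if (!key %in% names(vocab)) {
    stop("unknown predictor '", predictor, "'; valid values: ",
         paste(names(vocab), collapse = ", "))
  }
  out <- vocab[[key]]
  if (out == "carL" && response == "carL") {
    stop("'carl' is a valid predictor for total length only")
  }
  out
}

#' Predict body size from a single linear measurement
#'
#' Evaluates the allometric prediction equation `Y = exp(a + b ln(x))` for
#' total length or carapace length, using the bundled buthid coefficient
#' sets by default. Vectorised over `value_mm`.
#'
#' @param value_mm Measurement(s) of the predictor trait, mm (> 0).
#' @param predictor Predictor trait name, one of `met5l`, `met5w`, `carl`
#'   (total length only), `tel`, `tew`, `chel`, `chew` (case-insensitive;
#'   the mixed-case trait vocabulary also works).
#' @param response `"toL"` (default) or `"carL"`.
#' @param coeffs Optional `"coefficient_set"` overriding the bundled one.
#' @return Predicted size(s) in mm.
#' @examples
#' predict_simple(10, "met5l")            # total length from met5L = 10 mm
#' predict_simple(5, "tel", "carL")       # carapace length from teL = 5 mm
#' @export
predict_simple <- function(value_mm, predictor, response = c("toL", "carL"),
                           coeffs = NULL) {
  response <- match.arg(response)
  if (any(!is.finite(value_mm)) || any(value_mm <= 0)) {
    stop("value_mm must be positive")
  }
  if (is.null(coeffs)) {
    trait <- .normalise_predictor(predictor, response)
    key <- paste(response, trait, sep = "|")
    sets <- bundled_coefficients()
    if (!key %in% names(sets)) {
      stop("no bundled coefficients for ", response, " ~ ", trait)
    }
    coeffs <- sets[[key]]
  } else {
    stopifnot(inherits(coeffs, "coefficient_set"))
  }
  exp(coeffs$a + coeffs$b * log(value_mm))
}

#' Predict body size from two linear measurements
#'
#' Evaluates `Y = exp(a + b ln(x1) + b2 ln(x2))`. The published
#' two-predictor models fix the primary predictor to `met5L` for total
#' length and `teL` for carapace length; their coefficient sets are not
#' part of the printed table, so a fitted `"coefficient_set"` (e.g. from
#' [fit_two_predictor()] and [as_coefficient_set()]) must be supplied.
#'
#' @param x1_mm Primary-predictor measurement(s), mm.
#' @param x2_mm Secondary-predictor measurement(s), mm.
#' @param coeffs A two-predictor `"coefficient_set"`.
#' @param response `"toL"` or `"carL"`; must match `coeffs`.
#' @return Predicted size(s) in mm.
#' @export
predict_multi <- function(x1_mm, x2_mm, coeffs,
                          response = c("toL", "carL")) {
  response <- match.arg(response)
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (coeffs$response != response) {
    stop("coefficient set predicts ", coeffs$response, ", not ", response)
  }
  primary_req <- if (response == "toL") "met5L" else "teL"
  if (coeffs$predictors[1] != primary_req) {
    stop("primary predictor for ", response, " must be ", primary_req)
  }
  if (any(x1_mm <= 0) || any(x2_mm <= 0)) stop("measurements must be > 0")
  b2 <- if (is.null(coeffs$b2)) 0 else coeffs$b2
  exp(coeffs$a + coeffs$b * log(x1_mm) + b2 * log(x2_mm))
}

#' Signed prediction deviance
#'
#' Difference between predicted and actual size, `predicted - actual`, in
#' mm; positive values mean over-prediction.
#'
#' @param predicted_mm,actual_mm Numeric vectors, mm.
#' @return `predicted_mm - actual_mm`.
#' @export
deviance_mm <- function(predicted_mm, actual_mm) {
  predicted_mm - actual_mm
}

#' Naive prediction envelope from coefficient credible bounds
#'
#' Propagates the 95% credible bounds of `a` and `b` through the prediction
#' equation as `[exp(a_lo + b_lo ln x), exp(a_hi + b_hi ln x)]` for
#' `x >= 1` mm (bounds swap roles below 1 mm where `ln x < 0`). This is a
#' coefficient-uncertainty envelope only — it ignores residual variation
#' and parameter correlation and is NOT a calibrated prediction interval.
#'
#' @param value_mm Measurement(s), mm.
#' @param coeffs A `"coefficient_set"` with `bounds`.
#' @return Matrix with columns `fit`, `lower`, `upper` (mm).
#' @export
prediction_envelope <- function(value_mm, coeffs) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (is.null(coeffs$bounds)) stop("coefficient set carries no bounds")
  lx <- log(value_mm)
  b <- coeffs$bounds
  lo <- exp(pmin(b$a[1] + b$b[1] * lx, b$a[1] + b$b[2] * lx))
  hi <- exp(pmax(b$a[2] + b$b[2] * lx, b$a[2] + b$b[1] * lx))
  cbind(fit = exp(coeffs$a + coeffs$b * lx), lower = lo, upper = hi)
}

#' Read / write coefficient sets as JSON
#'
#' @param coeffs A `"coefficient_set"`.
#' @param path JSON file path.
#' @return `write_coefficients` returns `path` invisibly;
#'   `read_coefficients` the `"coefficient_set"`.
#' @name coefficient_io
NULL

#' @rdname coefficient_io
#' @export
write_coefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  jsonlite::write_json(unclass(coeffs), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname coefficient_io
#' @export
read_coefficients <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefficient_set(response = x$response, predictors = x$predictors,
                  a = x$a, b = x$b, b2 = x$b2, bounds = x$bounds,
                  rmse_mm = if (is.null(x$rmse_mm)) NA_real_ else x$rmse_mm,
                  source = x$source)
}
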