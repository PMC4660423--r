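#' Construct a biphasic (inverted v-shaped) peak model
#'
#' Inducible whole-cell biosensors typically show biphasic dose-response
#' profiles: the signal rises with dose up to the maximum permissive
#' concentration (MPC) and declines beyond it as toxicity sets in.  Two
#' split-peak model functions describe such curves:
#'
#' \deqn{y(x) = c + (d - c)\,\exp\!\left(-\tfrac{1}{2}(\Delta/w)^2\right)}
#'
#' where for `kind = "gaussian"` the offset is \eqn{\Delta = x - e} on the
#' dose scale, and for `kind = "loggaussian"` it is
#' \eqn{\Delta = \ln x - \ln e} on the log-dose scale.  The width is
#' \eqn{w = b} on the ascending (left) branch (\eqn{\Delta \le 0}) and
#' \eqn{w = b f} on the descending (right) branch, so `f` is the
#' right-to-left width (asymmetry) ratio and `f = 1` gives a curve
#' symmetric about `e` (in dose or log-dose space respectively).
#'
#' @param kind `"gaussian"` or `"loggaussian"`.
#' @param b Left-branch width; dose units for `"gaussian"`, log-dose units
#'   for `"loggaussian"`.  Must be positive.
#' @param c Baseline response (the limit in both tails), `>= 0`.
#' @param d Peak response `E_max`, attained exactly at dose `e`; must
#'   exceed `c`.
#' @param e Peak location, the maximum permissive concentration (MPC);
#'   must be positive for `"loggaussian"`.
#' @param f Asymmetry ratio (right width / left width), positive.
#'
#' @return An object of class `"biphasic_model"`: a list with elements
#'   `kind`, `b`, `c`, `d`, `e`, `f`.
#' @seealso [predict.biphasic_model()], [edp()], [fit_biphasic()]
#' @examples
#' m <- biphasic_model("loggaussian", b = 0.41, c = 2.27, d = 79.31,
#'                     e = 2.43, f = 0.66)
#' predict(m, dose = c(0, 1.5, 2.43, 10))
#' @export
biphasic_model <- function(kind = c("loggaussian", "gaussian"),
                           b, c, d, e, f = 1) {
  kind <- match.arg(kind)
  pars <- c(b = b, c = c, d = d, e = e, f = f)
  if (any(!is.finite(pars)))
    stop("all model parameters must be finite", call. = FALSE)
  if (b <= 0) stop("width 'b' must be positive", call. = FALSE)
  if (f <= 0) stop("asymmetry 'f' must be positive", call. = FALSE)
  if (c < 0) stop("baseline 'c' must be non-negative", call. = FALSE)
  if (d <= c) stop("peak 'd' must exceed baseline 'c'", call. = FALSE)
  if (kind == "loggaussian" && e <= 0)
    stop("peak location 'e' must be positive for a loggaussian model",
         call. = FALSE)
  structure(list(kind = kind, b = b, c = c, d = d, e = e, f = f),
            class = "biphasic_model")
}

is_biphasic_model <- function(x) inherits(x, "biphasic_model")

#' @export
print.biphasic_model <- function(x, digits = 4, ...) {
  cat("Biphasic", x$kind, "model\n")
  cat("  E_max (d):", format(x$d, digits = digits),
      "  MPC (e):", format(x$e, digits = digits), "\n")
  cat("  baseline (c):", format(x$c, digits = digits),
      "  width (b):", format(x$b, digits = digits),
      "  asymmetry (f):", format(x$f, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.biphasic_model <- function(object, ...) {
  unlist(object[c("b", "c", "d", "e", "f")])
}

#' Evaluate a biphasic model at given doses
#'
#' Returns the modelled response (empirical effect scale, e.g. BIF) at the
#' requested doses.  Dose 0 for a loggaussian model is handled as the
#' left-tail limit and returns the baseline `c`.
#'
#' @param object A [biphasic_model()].
#' @param dose Numeric vector of doses, finite and `>= 0`.
#' @param ... Unused.
#' @return Numeric vector of responses.
#' @export
predict.biphasic_model <- function(object, dose, ...) {
  if (missing(dose)) stop("'dose' is required", call. = FALSE)
  if (any(!is.finite(dose)))
    stop("all doses must be finite", call. = FALSE)
  if (any(dose < 0))
    stop("doses must be non-negative", call. = FALSE)
  with(object, {
    if (kind == "gaussian") {
      delta <- dose - e
    } else {
      delta <- ifelse(dose == 0, -Inf, log(dose) - log(e))
    }
    w <- ifelse(delta <= 0, b, b * f)
    z <- delta / w
    out <- c + (d - c) * exp(-0.5 * z^2)
    out[is.infinite(delta)] <- c   # dose 0 limit for loggaussian
    out
  })
}

#' Empirical effect at a fractional effect level
#'
#' The fractional-effect scale `p` runs from -100 to 100: `p < 0` indexes
#' the induction (ascending) branch, `p > 0` the inhibition (descending)
#' branch, and `p = 0` the peak (`E_max` at the MPC).  The empirical
#' effect attained at level `p` interpolates between baseline and peak:
#' \deqn{E_{(p)} = c + (1 - |p|/100)(d - c),}
#' so it depends on `p` only through `|p|` — both branches reach the same
#' response height at the same `|p|`.
#'
#' @param model A [biphasic_model()].
#' @param p Fractional effect(s) in `[-100, 100]`.
#' @return Numeric vector of effects (same scale as the response).
#' @export
effect_at_p <- function(model, p) {
  stopifnot(is_biphasic_model(model))
  if (any(!is.finite(p)) || any(abs(p) > 100))
    stop("fractional effect 'p' must lie in [-100, 100]", call. = FALSE)
  model$c + (1 - abs(p) / 100) * (model$d - model$c)
}

#' Dose required for a fractional effect level
#'
#' Closed-form branch inversion of the biphasic curve at the target effect
#' \eqn{E_{(p)}}.  With \eqn{s = \sqrt{-2\ln(1 - |p|/100)}}, the dose is
#' `e - b*s` (`p < 0`) or `e + b*f*s` (`p > 0`) for a gaussian model, and
#' `e*exp(-b*s)` or `e*exp(b*f*s)` for a loggaussian model; `p = 0`
#' returns the MPC `e`.  `|p| = 100` is excluded (the dose is zero or
#' unbounded there).
#'
#' A gaussian inversion that would fall below dose 0 on the ascending
#' branch is clipped to 0 with a warning of class
#' `"biphasicCI_dose_clipped"`.
#'
#' @inheritParams effect_at_p
#' @param p Fractional effect(s) in `(-100, 100)`.
#' @return Numeric vector of doses.
#' @export
dose_at_p <- function(model, p) {
  stopifnot(is_biphasic_model(model))
  if (any(!is.finite(p)) || any(abs(p) >= 100))
    stop("fractional effect 'p' must lie strictly within (-100, 100)",
         call. = FALSE)
  s <- sqrt(-2 * log(1 - abs(p) / 100))
  w <- ifelse(p < 0, model$b, model$b * model$f)
  if (model$kind == "gaussian") {
    dose <- model$e + sign(p) * w * s
    if (any(dose < 0)) {
      warning(warningCondition(
        "gaussian inversion fell below dose 0; clipped",
        class = "biphasicCI_dose_clipped"))
      dose <- pmax(dose, 0)
    }
  } else {
    dose <- model$e * exp(sign(p) * w * s)
  }
  dose
}

#' Two-dimensional effective dose ED_p = (D_(p), E_(p))
#'
#' Bundles the dose required for fractional effect `p` with the empirical
#' effect attained there.  Unlike the classical scalar ED50, the
#' two-dimensional vector carries both the concentration and the actual
#' signal height, which is what makes curves with differential maximal
#' effects commensurable.
#'
#' @inheritParams dose_at_p
#' @return A data frame of class `"edp"` with columns `p`, `dose`, `effect`.
#' @examples
#' zn <- biphasic_model("loggaussian", b = 0.410, c = 2.27, d = 79.31,
#'                      e = 2.43, f = 0.66)
#' edp(zn, c(-50, 0, 50))
#' @export
edp <- function(model, p) {
  out <- data.frame(p = p,
                    dose = dose_at_p(model, p),
                    effect = effect_at_p(model, p))
  class(out) <- c("edp", "data.frame")
  out
}
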