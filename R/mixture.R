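#' Specify a mixture by component dose fractions
#'
#' A constant-ratio mixture ray is described by the component identities
#' and their dose fractions \eqn{j_i = D_i / D_{mix}} of the total mixture
#' dose, which must sum to 1.
#'
#' @param component_ids Character vector of component labels (length >= 2).
#' @param fractions Positive dose fractions summing to 1 (within 1e-12).
#' @return An object of class `"mixture_spec"`.
#' @seealso [constant_ratio_design()] to build the fractions from
#'   individual effective doses.
#' @export
mixture_spec <- function(component_ids, fractions) {
  if (length(component_ids) < 2)
    stop("a mixture needs at least 2 components", call. = FALSE)
  if (length(fractions) != length(component_ids))
    stop("'fractions' must match 'component_ids' in length", call. = FALSE)
  if (any(!is.finite(fractions)) || any(fractions <= 0))
    stop("all dose fractions must be positive", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-12)
    stop("dose fractions must sum to 1 (within 1e-12)", call. = FALSE)
  structure(list(component_ids = as.character(component_ids),
                 fractions = as.numeric(fractions)),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("Mixture:",
      paste(sprintf("%s (%.4g)", x$component_ids, x$fractions),
            collapse = " + "), "\n")
  invisible(x)
}

check_fits <- function(fits, spec) {
  if (!all(vapply(fits, is_biphasic_model, TRUE)))
    stop("'fits' must be a list of biphasic_model objects", call. = FALSE)
  if (length(fits) != length(spec$component_ids))
    stop("number of component models must match the mixture spec",
         call. = FALSE)
  invisible(TRUE)
}

#' Additive (Loewe) total mixture dose at a fractional effect
#'
#' Under concentration addition along a constant-ratio ray, the total
#' mixture dose producing fractional effect `p` is the fraction-weighted
#' harmonic mean of the component effective doses:
#' \deqn{D_{add}(p) = \left(\sum_i j_i / D_{(p),i}\right)^{-1}.}
#'
#' @param fits List of component [biphasic_model()] objects, in the order
#'   of `spec$component_ids`.
#' @param spec A [mixture_spec()].
#' @param p Fractional effect(s) in `(-100, 100)`.
#' @return Numeric vector of additive total doses.
#' @export
additive_dose <- function(fits, spec, p) {
  check_fits(fits, spec)
  dmat <- vapply(fits, dose_at_p, numeric(length(p)), p = p)
  dmat <- matrix(dmat, nrow = length(p))
  if (any(dmat <= 0))
    stop("component effective dose is not positive; additive dose undefined",
         call. = FALSE)
  1 / as.vector((1 / dmat) %*% spec$fractions)
}

#' Additive (Loewe) mixture effect at a fractional effect
#'
#' Projection of the same concentration-addition structure onto the
#' empirical effect dimension: the fraction-weighted harmonic mean of the
#' component effects \eqn{E_{(p),i}} attained at fractional effect `p`.
#' Dose fractions are reused as the weights (see the package vignette for
#' the rationale); set `weights` to override.
#'
#' @inheritParams additive_dose
#' @param weights Optional weights (positive, summing to 1); defaults to
#'   the dose fractions in `spec`.
#' @return Numeric vector of additive effects (response scale).
#' @export
additive_effect <- function(fits, spec, p, weights = NULL) {
  check_fits(fits, spec)
  w <- if (is.null(weights)) spec$fractions else weights
  if (length(w) != length(fits) || any(w <= 0) ||
      abs(sum(w) - 1) > 1e-9)
    stop("'weights' must be positive and sum to 1", call. = FALSE)
  emat <- vapply(fits, effect_at_p, numeric(length(p)), p = p)
  emat <- matrix(emat, nrow = length(p))
  if (any(emat <= 0))
    stop("component effect is not positive; additive effect undefined",
         call. = FALSE)
  1 / as.vector((1 / emat) %*% w)
}

#' Predict the additive dose-response curve of a mixture
#'
#' Evaluates the two-dimensional Loewe-additive prediction over a grid of
#' fractional effects, returning the curve as (total dose, effect) pairs
#' parameterised by `p`.  For a sham mixture (identical components) the
#' prediction coincides with the single-compound curve identically, the
#' algebraic counterpart of the experimental sham validation.
#'
#' @inheritParams additive_dose
#' @param p_grid Sorted grid of fractional effects in `(-100, 100)`.
#' @return A data frame of class `"predicted_curve"` with columns `p`,
#'   `dose`, `effect`.
#' @examples
#' zn <- biphasic_model("loggaussian", b = 0.41, c = 2.3, d = 79, e = 2.4,
#'                      f = 0.66)
#' sham <- mixture_spec(c("Zn.1", "Zn.2"), c(0.5, 0.5))
#' pc <- predict_curve(list(zn, zn), sham)
#' max(abs(pc$dose - dose_at_p(zn, pc$p)))   # sham identity
#' @export
predict_curve <- function(fits, spec, p_grid = seq(-99, 99, by = 0.5)) {
  if (is.unsorted(p_grid))
    stop("'p_grid' must be sorted increasing", call. = FALSE)
  out <- data.frame(p = p_grid,
                    dose = additive_dose(fits, spec, p_grid),
                    effect = additive_effect(fits, spec, p_grid))
  class(out) <- c("predicted_curve", "data.frame")
  out
}

#' Predict a mixture curve under constant departure from additivity
#'
#' Scales the additive prediction by fixed combination indices: the dose
#' coordinate is multiplied by `ci_d` and the effect coordinate divided by
#' `ci_e` (so a mixture with `ci_e < 1` attains a higher response than
#' additively expected, matching the interpretation orientation of
#' [ci_at_p()]).  With `ci_d = ci_e = 1` this is exactly the additive
#' curve; re-estimating the indices from the generated curve recovers the
#' inputs.
#'
#' @inheritParams predict_curve
#' @param ci_d,ci_e Positive combination-index factors for the dose and
#'   effect dimensions.
#' @return A `"predicted_curve"` data frame.
#' @export
predict_with_interaction <- function(fits, spec,
                                     p_grid = seq(-99, 99, by = 0.5),
                                     ci_d = 1, ci_e = 1) {
  if (!is.finite(ci_d) || !is.finite(ci_e) || ci_d <= 0 || ci_e <= 0)
    stop("'ci_d' and 'ci_e' must be positive", call. = FALSE)
  out <- predict_curve(fits, spec, p_grid)
  out$dose <- ci_d * out$dose
  out$effect <- out$effect / ci_e
  out
}
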