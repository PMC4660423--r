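#' Weighted combination index
#'
#' The overall departure from additivity is summarised by the product of
#' the dose- and effect-dimension indices, \eqn{CI_w = CI_D \cdot CI_E}.
#' It tends to zero when the two dimensions depart in the same synergistic
#' direction and is magnified above 1 when both are antagonistic; opposite
#' departures partially cancel.
#'
#' @param ci_d,ci_e Positive combination indices.
#' @return `ci_d * ci_e`.
#' @examples
#' ci_weighted(0.5, 0.5)   # 0.25: synergism in both dimensions compounds
#' @export
ci_weighted <- function(ci_d, ci_e) {
  if (any(!is.finite(ci_d)) || any(!is.finite(ci_e)) ||
      any(ci_d <= 0) || any(ci_e <= 0))
    stop("combination indices must be positive", call. = FALSE)
  ci_d * ci_e
}

#' Risk-management classification of a weighted combination index
#'
#' Applies the management thresholds: `ci_w < 0.5` is synergism (the
#' observed mixture departs below half the concentration-addition
#' expectation), `ci_w > 2` antagonism, and the band `[0.5, 2]` is treated
#' as additive (boundaries inclusive).
#'
#' @param ci_w Positive weighted combination index (vectorised).
#' @return Factor with levels `synergism`, `additive`, `antagonism`.
#' @export
classify_management <- function(ci_w) {
  if (any(!is.finite(ci_w)) || any(ci_w <= 0))
    stop("'ci_w' must be positive", call. = FALSE)
  factor(ifelse(ci_w < 0.5, "synergism",
                ifelse(ci_w > 2, "antagonism", "additive")),
         levels = c("synergism", "additive", "antagonism"))
}

# D_mix(p)/E_mix(p) from either a fitted biphasic model (usual route) or
# a (p, dose, effect) curve such as a predicted_curve (oracle route).
mix_dose_at_p <- function(mix, p) {
  if (is_biphasic_model(mix)) return(dose_at_p(mix, p))
  if (inherits(mix, "biphasic_fit")) return(dose_at_p(mix$model, p))
  stats::approx(mix$p, mix$dose, xout = p, rule = 1)$y
}

mix_effect_at_p <- function(mix, p) {
  if (is_biphasic_model(mix)) return(effect_at_p(mix, p))
  if (inherits(mix, "biphasic_fit")) return(effect_at_p(mix$model, p))
  stats::approx(mix$p, mix$effect, xout = p, rule = 1)$y
}

#' Two-dimensional combination index at a fractional effect
#'
#' Compares the observed mixture behaviour with the Loewe-additive
#' expectation built from the component curves, in both dimensions:
#' \deqn{CI_{D}(p) = D_{mix}(p) / D_{add}(p)}
#' on the total-dose axis, and in the effect dimension (default
#' "interpretation" orientation)
#' \deqn{CI_{E}(p) = E_{add}(p) / E_{mix}(p),}
#' so that `ci_e < 1` means the mixture attains a *higher* response than
#' additively expected at the same fractional effect level.  The
#' `"literal"` orientation reports the reciprocal.  The weighted index is
#' the product `ci_w = ci_d * ci_e`.
#'
#' @param mix_fit The mixture curve: a [biphasic_model()], a
#'   `"biphasic_fit"`, or a `(p, dose, effect)` curve data frame (the
#'   dose axis must be total mixture dose).
#' @param fits List of component [biphasic_model()] objects.
#' @param spec A [mixture_spec()].
#' @param p Fractional effect(s) in `(-100, 100)`.
#' @param ci_e_orientation `"interpretation"` (default) or `"literal"`.
#' @return A data frame of class `"ci_result"` with columns `p`, `ci_d`,
#'   `ci_e`, `ci_w`, `category`.
#' @export
ci_at_p <- function(mix_fit, fits, spec, p,
                    ci_e_orientation = c("interpretation", "literal")) {
  ci_e_orientation <- match.arg(ci_e_orientation)
  d_mix <- mix_dose_at_p(mix_fit, p)
  e_mix <- mix_effect_at_p(mix_fit, p)
  if (any(is.na(d_mix)) || any(is.na(e_mix)))
    stop("mixture curve does not cover the requested fractional effects",
         call. = FALSE)
  d_add <- additive_dose(fits, spec, p)
  e_add <- additive_effect(fits, spec, p)
  if (any(d_mix <= 0) || any(e_mix <= 0))
    stop("mixture dose/effect must be positive at the requested p",
         call. = FALSE)
  ci_d <- d_mix / d_add
  ci_e <- if (ci_e_orientation == "interpretation") e_add / e_mix
          else e_mix / e_add
  ci_w <- ci_weighted(ci_d, ci_e)
  out <- data.frame(p = p, ci_d = ci_d, ci_e = ci_e, ci_w = ci_w,
                    category = classify_management(ci_w))
  class(out) <- c("ci_result", "data.frame")
  out
}

#' Combination-index profile over a fractional-effect grid
#'
#' Evaluates [ci_at_p()] over a grid of fractional effects, producing the
#' table behind extended p-CI and p-CI_w plots (index against `p` across
#' both branches of the biphasic curve).
#'
#' @inheritParams ci_at_p
#' @param p_grid Grid of fractional effects in `(-100, 100)`.
#' @return A `"ci_result"` data frame, one row per grid point.
#' @seealso [plot_ci_profile()]
#' @export
ci_profile <- function(mix_fit, fits, spec, p_grid = seq(-99, 99, by = 1),
                       ci_e_orientation = c("interpretation", "literal")) {
  ci_at_p(mix_fit, fits, spec, p_grid, match.arg(ci_e_orientation))
}

#' Replicate-level combination indices
#'
#' The replicate protocol behind the departure test: the single-compound
#' reference curves are pooled fits (all replicates together), while each
#' independent mixture experiment is fitted separately, yielding one
#' `(ci_d, ci_e)` pair per replicate per fractional effect.
#'
#' @param mix_data Mixture dataset with columns `dose` (total mixture
#'   dose), `response` and `replicate`.
#' @param fits List of pooled component [biphasic_model()] objects.
#' @param spec A [mixture_spec()].
#' @param p Fractional effect levels.
#' @param kind Model kind for the per-replicate mixture fits; `"auto"`
#'   selects by minimum RSS via [select_model()].
#' @param ... Passed to [fit_biphasic()] / [select_model()].
#' @return Data frame with columns `replicate`, `p`, `ci_d`, `ci_e`,
#'   `ci_w`; non-convergent replicate fits are dropped with a warning.
#' @export
ci_replicates <- function(mix_data, fits, spec, p = c(-50, 0, 50),
                          kind = "auto", ...) {
  reps <- unique(mix_data$replicate)
  if (length(reps) < 2)
    stop("at least 2 mixture replicates are required", call. = FALSE)
  out <- lapply(reps, function(r) {
    sub <- mix_data[mix_data$replicate == r, , drop = FALSE]
    fit <- tryCatch(suppressWarnings(
      if (identical(kind, "auto"))
        select_model(response ~ dose, sub, ...)
      else fit_biphasic(response ~ dose, sub, kind = kind, ...)),
      error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) return(NULL)
    ci <- ci_at_p(fit$model, fits, spec, p)
    cbind(replicate = r, ci[c("p", "ci_d", "ci_e", "ci_w")])
  })
  dropped <- vapply(out, is.null, TRUE)
  if (any(dropped))
    warning(sum(dropped), " replicate fit(s) did not converge and were ",
            "dropped", call. = FALSE)
  if (all(dropped))
    stop("no mixture replicate could be fitted", call. = FALSE)
  do.call(rbind, out[!dropped])
}

#' Test a set of replicate combination indices against additivity
#'
#' One-sample two-sided Student t-test of `H0: CI = null_value`, carried
#' out on the log scale (a combination index is a positive ratio and the
#' null is multiplicative): the test statistic is the mean of `ln(CI)`
#' minus `ln(null_value)` over its standard error, with `n - 1` degrees
#' of freedom.  Degenerate zero-variance inputs return `p = 1` when the
#' replicates sit exactly at the null and `p = 0` (flagged) otherwise.
#'
#' @param replicate_ci Numeric vector of positive replicate CI values,
#'   length >= 2.
#' @param null_value Null CI (default 1, additivity).
#' @return List with elements `t`, `p_value`, `df`, `n`, `estimate`
#'   (geometric mean CI) and `degenerate` (logical flag).
#' @examples
#' test_departure(c(0.5, 0.55, 0.45, 0.5))
#' @export
test_departure <- function(replicate_ci, null_value = 1) {
  if (length(replicate_ci) < 2)
    stop("at least 2 replicate CI values are required", call. = FALSE)
  if (any(!is.finite(replicate_ci)) || any(replicate_ci <= 0))
    stop("replicate CI values must be positive", call. = FALSE)
  x <- log(replicate_ci) - log(null_value)
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0) {
    at_null <- mean(x) == 0
    return(list(t = if (at_null) 0 else sign(mean(x)) * Inf,
                p_value = if (at_null) 1 else 0,
                df = n - 1, n = n,
                estimate = exp(mean(log(replicate_ci))),
                degenerate = TRUE))
  }
  tstat <- mean(x) / (s / sqrt(n))
  list(t = tstat,
       p_value = 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE),
       df = n - 1, n = n,
       estimate = exp(mean(log(replicate_ci))),
       degenerate = FALSE)
}

#' Summarise pairwise interactions for a polygonogram
#'
#' Collects the weighted combination index of every analysed pair at a set
#' of representative fractional effects into a tidy edge table, ready for
#' rendering a polygonogram (a graph whose edge style encodes
#' synergism/additivity/antagonism per pair).
#'
#' @param pair_results Named list; each element holds the `"ci_result"`
#'   rows for one pair and is named `"A:B"` (or supply `component_a` /
#'   `component_b` columns in the element itself).
#' @param p_levels Fractional effect levels to report.
#' @return Data frame `component_a, component_b, p, ci_w, category`; a
#'   requested level missing from a pair's results yields an `NA` row
#'   (flagged, never fabricated).
#' @export
polygonogram_summary <- function(pair_results, p_levels = c(-50, 0, 50)) {
  stopifnot(length(pair_results) >= 1, !is.null(names(pair_results)))
  rows <- lapply(names(pair_results), function(nm) {
    res <- pair_results[[nm]]
    ab <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(ab) != 2)
      stop("pair name '", nm, "' is not of the form 'A:B'", call. = FALSE)
    idx <- match(p_levels, res$p)
    data.frame(component_a = ab[1], component_b = ab[2], p = p_levels,
               ci_w = res$ci_w[idx],
               category = ifelse(is.na(idx), NA_character_,
                                 as.character(res$category[idx])))
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$ci_w))
    warning("some requested p levels were absent and are reported as NA",
            call. = FALSE)
  out
}

#' Extended p-CI plot
#'
#' Plots combination indices against the fractional effect `p` across both
#' branches of the biphasic curve, with the additivity line `CI = 1` and,
#' for the weighted index, the 0.5-2 management band.
#'
#' @param profile A `"ci_result"` data frame from [ci_profile()].
#' @param which `"d"`, `"e"` or `"w"` — which index to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_ci_profile <- function(profile, which = c("w", "d", "e"), ...) {
  which <- match.arg(which)
  y <- profile[[paste0("ci_", which)]]
  lab <- c(d = expression(CI[D]), e = expression(CI[E]),
           w = expression(CI[w]))[[which]]
  graphics::plot(profile$p, y, type = "l", log = "y",
                 xlab = "fractional effect p", ylab = lab, ...)
  graphics::abline(h = 1, lty = 2)
  if (which == "w") graphics::abline(h = c(0.5, 2), lty = 3, col = "grey40")
  invisible(profile)
}
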