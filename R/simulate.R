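#' Two-fold (or general) serial dilution series
#'
#' The standard biosensor exposure design: a geometric series of doses
#' `top_dose / factor^k`, `k = 0, ..., n - 1`, returned in descending
#' order.  The laboratory design this emulates used 7 to 9 two-fold
#' dilutions per compound or mixture ray.
#'
#' @param top_dose Highest dose, positive.
#' @param factor Dilution factor, > 1 (default 2).
#' @param n Number of dilutions, >= 2.
#' @return Numeric vector of `n` doses, descending.
#' @examples
#' dilution_series(10, 2, 4)   # 10 5 2.5 1.25
#' @export
dilution_series <- function(top_dose, factor = 2, n) {
  if (!is.finite(top_dose) || top_dose <= 0)
    stop("'top_dose' must be positive", call. = FALSE)
  if (!is.finite(factor) || factor <= 1)
    stop("'factor' must exceed 1", call. = FALSE)
  if (!is.finite(n) || n < 2)
    stop("'n' must be at least 2", call. = FALSE)
  top_dose / factor^(seq_len(n) - 1)
}

#' Serial-dilution design anchored on a model's inhibition branch
#'
#' Convenience wrapper: places the top dose at the dose giving fractional
#' effect `top_p` on the descending branch of `model`, then runs `n`
#' serial dilutions, so the design straddles the peak the way the
#' laboratory design does.
#'
#' @param model A [biphasic_model()] (or `(p, dose, effect)` curve).
#' @param n Number of dilutions.
#' @param factor Dilution factor.
#' @param top_p Fractional effect anchoring the top dose (default +99,
#'   where the response has decayed to 1% of the peak amplitude, so the
#'   dilution series observes the full inhibition branch).
#' @return Descending dose vector.
#' @export
design_doses <- function(model, n = 8, factor = 2, top_p = 99) {
  top <- if (is_biphasic_model(model)) dose_at_p(model, top_p)
         else stats::approx(model$p, model$dose, xout = top_p)$y
  dilution_series(top, factor, n)
}

#' Constant-ratio mixture design from individual effective doses
#'
#' The "1:1" constant-ratio design mixes the components in proportion to
#' their individual effective doses at a basis fractional effect (by
#' default `p = -50`, the ascending-branch dose giving half the peak
#' effect): dose fractions are \eqn{j_i \propto w_i D_{(basis.p),i}},
#' normalised to 1, so each component is present at an equal multiple of
#' its own potency.  Unequal `weights` (e.g. 75:25) scale those multiples.
#'
#' @param fits List of component [biphasic_model()] objects.
#' @param component_ids Labels for the components; defaults to names of
#'   `fits` or `C1, C2, ...`.
#' @param basis_p Basis fractional effect (default -50).
#' @param weights Relative design weights, one per component (default
#'   equal).
#' @return A [mixture_spec()].
#' @examples
#' a <- biphasic_model("loggaussian", b = 0.4, c = 1, d = 80, e = 2.5)
#' b <- biphasic_model("loggaussian", b = 0.4, c = 1, d = 80, e = 5.0)
#' constant_ratio_design(list(A = a, B = b))
#' @export
constant_ratio_design <- function(fits, component_ids = NULL,
                                  basis_p = -50, weights = NULL) {
  stopifnot(length(fits) >= 2)
  if (is.null(component_ids))
    component_ids <- if (!is.null(names(fits))) names(fits)
                     else paste0("C", seq_along(fits))
  if (is.null(weights)) weights <- rep(1, length(fits))
  if (length(weights) != length(fits) || any(weights <= 0))
    stop("'weights' must be positive, one per component", call. = FALSE)
  d <- vapply(fits, dose_at_p, 0, p = basis_p)
  if (any(d <= 0))
    stop("component effective dose at the basis p is not positive",
         call. = FALSE)
  j <- weights * d
  mixture_spec(component_ids, j / sum(j))
}

add_noise <- function(mu, cv_or_sd, noise = c("lognormal", "gaussian")) {
  noise <- match.arg(noise)
  if (cv_or_sd < 0) stop("noise level must be non-negative", call. = FALSE)
  if (cv_or_sd == 0) return(mu)
  if (noise == "lognormal") {
    # mean-corrected multiplicative lognormal: E[noisy] = mu
    sdlog <- sqrt(log(1 + cv_or_sd^2))
    mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    mu + stats::rnorm(length(mu), sd = cv_or_sd)
  }
}

#' Simulate a single-compound dose-response dataset
#'
#' Draws replicate responses from a biphasic model at the given doses,
#' perturbed by mean-corrected multiplicative lognormal noise (the
#' default; biosensor induction-factor scatter is positive and roughly
#' proportional to the signal) or additive Gaussian noise.
#'
#' @param model A [biphasic_model()].
#' @param doses Non-negative dose vector.
#' @param cv Noise level: coefficient of variation (lognormal) or
#'   standard deviation (gaussian).
#' @param n_rep Number of replicates, >= 1.
#' @param noise `"lognormal"` or `"gaussian"`.
#' @param seed Optional RNG seed; a fixed seed gives an identical dataset.
#' @param series_id Label stored in the `series_id` column.
#' @return Data frame with columns `series_id`, `dose`, `response`,
#'   `replicate`.
#' @export
simulate_single <- function(model, doses, cv = 0.1, n_rep = 3,
                            noise = c("lognormal", "gaussian"),
                            seed = NULL, series_id = "sim") {
  stopifnot(is_biphasic_model(model), n_rep >= 1)
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(model, doses)
  out <- do.call(rbind, lapply(seq_len(n_rep), function(r)
    data.frame(series_id = series_id, dose = doses,
               response = add_noise(mu, cv, noise), replicate = r)))
  rownames(out) <- NULL
  out
}

#' Simulate a mixture dose-response dataset with known interaction
#'
#' Ground truth is the curve from [predict_with_interaction()] evaluated
#' on a dense fractional-effect grid; the true response at each requested
#' total mixture dose is obtained by monotone interpolation of that curve
#' in `p`, then perturbed by the noise model.  `ci_d = ci_e = 1`
#' reproduces pure Loewe additivity.
#'
#' A factor-2 serial-dilution design spans a far wider dose range than the
#' fractional-effect parameterisation can reach (for a loggaussian curve
#' the dose tends to 0 only as `p` tends to -100), so doses below the
#' curve's lowest parameterised dose take the analytic left-tail limit:
#' the fraction-weighted harmonic mean of the component baselines divided
#' by `ci_e`.  Doses above the curve's highest dose are clamped to the
#' endpoint with a warning.
#'
#' @param fits List of component [biphasic_model()] objects.
#' @param spec A [mixture_spec()].
#' @param ci_d,ci_e True (imposed) combination indices, positive.
#' @param doses Total mixture doses.
#' @inheritParams simulate_single
#' @param p_grid Dense interpolation grid in `p`.
#' @return Data frame with columns `series_id`, `dose`, `response`,
#'   `replicate`.
#' @export
simulate_mixture <- function(fits, spec, ci_d = 1, ci_e = 1, doses,
                             cv = 0.1, n_rep = 3,
                             noise = c("lognormal", "gaussian"),
                             seed = NULL, series_id = "mix",
                             p_grid = seq(-99.5, 99.5, by = 0.25)) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  curve <- predict_with_interaction(fits, spec, p_grid, ci_d, ci_e)
  rng <- range(curve$dose)
  if (any(doses > rng[2])) {
    warning("requested dose(s) above the simulated curve's range; ",
            "clamped", call. = FALSE)
    doses <- pmin(doses, rng[2])
  }
  mu <- stats::approx(curve$dose, curve$effect, xout = doses, rule = 2)$y
  low <- doses < rng[1]
  if (any(low)) {
    cs <- vapply(fits, `[[`, 0, "c")
    base <- if (any(cs <= 0)) 0 else 1 / sum(spec$fractions / cs)
    mu[low] <- base / ci_e
  }
  out <- do.call(rbind, lapply(seq_len(n_rep), function(r)
    data.frame(series_id = series_id, dose = doses,
               response = add_noise(mu, cv, noise), replicate = r)))
  rownames(out) <- NULL
  out
}
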