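#' Box-Cox power transform
#'
#' @param y Positive numeric vector.
#' @param lambda Power; `lambda = 0` gives the log transform.
#' @return Transformed vector `(y^lambda - 1)/lambda` (or `log(y)`).
#' @keywords internal
boxcox_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

# Starting values: peak at the dose with the largest mean response,
# baseline at the smallest; left width from the half-height crossing.
start_values <- function(dose, response, kind) {
  mu <- tapply(response, dose, mean)
  dl <- as.numeric(names(mu))
  e0 <- dl[which.max(mu)]
  d0 <- max(mu)
  c0 <- max(min(mu), 0)
  half <- (c0 + d0) / 2
  ax <- function(x) if (kind == "gaussian") x else log(x)
  pos <- dl > 0
  if (kind == "loggaussian" && e0 <= 0) e0 <- min(dl[pos])
  span <- diff(range(ax(if (kind == "gaussian") dl else dl[pos])))
  left <- dl < e0 & mu < half & (kind == "gaussian" | dl > 0)
  b0 <- if (any(left)) {
    (ax(e0) - max(ax(dl[left]))) / 2
  } else {
    span / 4
  }
  if (!is.finite(b0) || b0 <= 0) b0 <- max(span / 4, 1e-3)
  list(b = b0, c = c0, d = d0, e = e0, f = 1)
}

fit_one <- function(dose, response, kind, start, lambda = NULL,
                    max_iter = 200) {
  tbs <- !is.null(lambda)
  obs <- if (tbs) boxcox_transform(pmax(response, 1e-12), lambda) else response
  resid_fun <- function(par) {
    m <- list(kind = kind, b = par[["b"]], c = par[["c"]],
              d = par[["c"]] + par[["a"]], e = par[["e"]], f = par[["f"]])
    class(m) <- "biphasic_model"
    pred <- predict(m, dose)
    if (tbs) pred <- boxcox_transform(pmax(pred, 1e-12), lambda)
    obs - pred
  }
  par0 <- c(b = start$b, c = start$c, a = max(start$d - start$c, 1e-6),
            e = start$e, f = start$f)
  lower <- c(b = 1e-10, c = 0, a = 1e-10,
             e = if (kind == "loggaussian") 1e-12 else -Inf, f = 1e-10)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(
                         maxiter = max_iter, maxfev = 10000L)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  par <- fit$par
  ok <- fit$info %in% 1:3 && par[["a"]] > 1e-8 && all(is.finite(unlist(par)))
  list(par = par, rss = fit$deviance, converged = ok, info = fit$info,
       hessian = fit$hessian, message = fit$message)
}

#' Fit a biphasic dose-response model
#'
#' Least-squares fit of a split Gaussian or log-Gaussian peak model (see
#' [biphasic_model()]) to replicate-level dose-response data, optionally
#' with the variance-stabilising Box-Cox transform-both-sides approach in
#' which the same power transform is applied to the observations and to
#' the model predictions, with the power chosen on a grid by maximum
#' profile likelihood.
#'
#' Parameter bounds `b > 0`, `f > 0`, `d > c >= 0` (and `e > 0` for the
#' loggaussian) are enforced during optimisation.  Starting values place
#' the peak at the dose with the largest mean response; `multistart = TRUE`
#' additionally jitters the starting width and asymmetry by factors
#' 0.5/1/2 and keeps the best fit.
#'
#' @param formula A formula `response ~ dose`.
#' @param data A data frame holding the variables in `formula` (typically
#'   a dataset from [read_dataset()] or [simulate_single()], with one row
#'   per replicate observation).
#' @param kind `"loggaussian"` or `"gaussian"`.
#' @param boxcox Logical; apply the transform-both-sides fit?  Requires
#'   strictly positive responses.
#' @param lambda_grid Candidate Box-Cox powers.
#' @param multistart Logical; jitter starting `(b, f)` over a small grid.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return An object of class `"biphasic_fit"`: a list with components
#'   `model` (a [biphasic_model()]), `rss` (residual sum of squares on the
#'   fitting scale), `n_obs`, `converged`, `boxcox_lambda` (`NA` when
#'   `boxcox = FALSE`), `param_covariance` (may be `NULL`), `data`,
#'   `fitted`, `residuals` and `call`.  Non-convergence is flagged (with
#'   a warning), never silent.
#' @examples
#' zn <- biphasic_model("loggaussian", b = 0.41, c = 2.3, d = 79, e = 2.4,
#'                      f = 0.66)
#' dat <- simulate_single(zn, dilution_series(10, 2, 8), cv = 0.1,
#'                        n_rep = 3, seed = 1)
#' fit <- fit_biphasic(response ~ dose, dat, kind = "loggaussian")
#' coef(fit)
#' edp(fit$model, c(-50, 0, 50))
#' @export
fit_biphasic <- function(formula = response ~ dose, data,
                         kind = c("loggaussian", "gaussian"),
                         boxcox = FALSE,
                         lambda_grid = c(-1, -0.5, 0, 1/3, 0.5, 1),
                         multistart = FALSE, max_iter = 200) {
  kind <- match.arg(kind)
  mf <- stats::model.frame(formula, data)
  response <- mf[[1L]]
  dose <- mf[[2L]]
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("doses must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(response)))
    stop("responses must be finite", call. = FALSE)
  if (length(unique(dose)) < 5)
    stop("at least 5 distinct dose levels are required", call. = FALSE)

  mu <- tapply(response, dose, mean)
  peak_idx <- which.max(mu)
  if (peak_idx == 1L || peak_idx == length(mu))
    warning("doses do not span both sides of the empirical peak; ",
            "the fitted peak location is an extrapolation", call. = FALSE)

  out <- structure(list(model = NULL, rss = NA_real_, n_obs = length(response),
                        converged = FALSE, boxcox_lambda = NA_real_,
                        param_covariance = NULL,
                        data = data.frame(dose = dose, response = response),
                        fitted = NULL, residuals = NULL, kind = kind,
                        call = match.call()),
                   class = "biphasic_fit")

  if (diff(range(mu)) < 1e-12) {
    warning("constant response: degenerate data, model not identifiable",
            call. = FALSE)
    return(out)
  }
  if (boxcox && any(response <= 0))
    stop("Box-Cox fitting requires strictly positive responses",
         call. = FALSE)

  start <- start_values(dose, response, kind)
  starts <- list(start)
  if (multistart) {
    for (kb in c(0.5, 2)) for (kf in c(0.5, 1, 2)) {
      s <- start; s$b <- start$b * kb; s$f <- kf
      starts <- c(starts, list(s))
    }
    for (kf in c(0.5, 2)) {
      s <- start; s$f <- kf
      starts <- c(starts, list(s))
    }
  }

  run_grid <- function(lambda) {
    fits <- lapply(starts, function(s)
      fit_one(dose, response, kind, s, lambda, max_iter))
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) return(NULL)
    conv <- vapply(fits, `[[`, TRUE, "converged")
    pool <- if (any(conv)) fits[conv] else fits
    pool[[which.min(vapply(pool, `[[`, 0, "rss"))]]
  }

  if (!boxcox) {
    best <- run_grid(NULL)
    lambda_hat <- NA_real_
  } else {
    # profile log-likelihood of the transform-both-sides model
    cand <- lapply(lambda_grid, run_grid)
    keep <- !vapply(cand, is.null, TRUE)
    if (!any(keep)) {
      warning("fit failed for every Box-Cox lambda", call. = FALSE)
      return(out)
    }
    lambda_grid <- lambda_grid[keep]; cand <- cand[keep]
    n <- length(response)
    ll <- vapply(seq_along(cand), function(i) {
      -n / 2 * log(cand[[i]]$rss / n) +
        (lambda_grid[i] - 1) * sum(log(response))
    }, 0)
    best <- cand[[which.max(ll)]]
    lambda_hat <- lambda_grid[which.max(ll)]
  }
  if (is.null(best)) {
    warning("biphasic model fit failed", call. = FALSE)
    return(out)
  }

  par <- best$par
  model <- tryCatch(
    biphasic_model(kind, b = par[["b"]], c = par[["c"]],
                   d = par[["c"]] + par[["a"]], e = par[["e"]],
                   f = par[["f"]]),
    error = function(e) NULL)
  if (is.null(model)) {
    warning("fitted parameters violate model constraints; flagged as ",
            "non-converged", call. = FALSE)
    return(out)
  }
  if (!best$converged)
    warning("biphasic model fit did not converge (flagged in the result)",
            call. = FALSE)

  vc <- tryCatch({
    df <- length(response) - 5L
    s2 <- best$rss / max(df, 1L)
    v <- s2 * solve(best$hessian)
    dimnames(v) <- list(c("b", "c", "d", "e", "f"), c("b", "c", "d", "e", "f"))
    v
  }, error = function(e) NULL)

  out$model <- model
  out$rss <- best$rss
  out$converged <- best$converged
  out$boxcox_lambda <- lambda_hat
  out$param_covariance <- vc
  out$fitted <- predict(model, dose)
  out$residuals <- response - out$fitted
  out
}

#' Select the best-fitting biphasic model kind
#'
#' Fits every candidate model kind to the same data on the untransformed
#' scale and returns the converged fit with the smallest residual sum of
#' squares; ties are broken in favour of the loggaussian (the dose-response
#' convention).  Box-Cox fits are never compared by raw RSS (the scales
#' are incommensurable), so selection is always untransformed.
#'
#' @inheritParams fit_biphasic
#' @param candidates Character vector of model kinds to try.
#' @param ... Passed on to [fit_biphasic()] (`boxcox` is forced off).
#' @return The winning `"biphasic_fit"`, with an extra element `selection`
#'   (a data frame of candidate kinds, their RSS and convergence flags).
#' @export
select_model <- function(formula = response ~ dose, data,
                         candidates = c("loggaussian", "gaussian"), ...) {
  stopifnot(length(candidates) >= 1)
  candidates <- match.arg(candidates, c("loggaussian", "gaussian"),
                          several.ok = TRUE)
  # loggaussian first so which.min's first-on-tie rule breaks ties its way
  candidates <- unique(candidates[order(candidates != "loggaussian")])
  fits <- list(); errs <- character()
  for (k in candidates) {
    fits[[k]] <- tryCatch(
      fit_biphasic(formula, data, kind = k, boxcox = FALSE, ...),
      error = function(e) e)
  }
  failed <- vapply(fits, function(f)
    inherits(f, "error") || !isTRUE(f$converged), TRUE)
  if (all(failed)) {
    msgs <- vapply(seq_along(fits), function(i) {
      f <- fits[[i]]
      paste0(names(fits)[i], ": ",
             if (inherits(f, "error")) conditionMessage(f)
             else "did not converge")
    }, "")
    stop("no candidate model could be fitted:\n  ",
         paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  if (any(failed))
    warning("candidate(s) ", paste(names(fits)[failed], collapse = ", "),
            " failed or did not converge; selecting among the rest",
            call. = FALSE)
  ok <- fits[!failed]
  rss <- vapply(ok, `[[`, 0, "rss")
  best <- ok[[which.min(rss)]]
  best$selection <- data.frame(
    kind = names(fits),
    rss = vapply(fits, function(f)
      if (inherits(f, "error")) NA_real_ else f$rss, 0),
    converged = !failed, row.names = NULL)
  best
}

#' @export
print.biphasic_fit <- function(x, digits = 4, ...) {
  cat("Biphasic dose-response fit (", x$kind, ")\n", sep = "")
  if (is.null(x$model)) {
    cat("  <not converged: no valid parameter estimates>\n")
    return(invisible(x))
  }
  print(x$model, digits = digits)
  cat("  RSS:", format(x$rss, digits = digits),
      " n:", x$n_obs,
      " converged:", x$converged, "\n")
  if (!is.na(x$boxcox_lambda))
    cat("  Box-Cox lambda (transform both sides):", x$boxcox_lambda, "\n")
  invisible(x)
}

#' @export
coef.biphasic_fit <- function(object, ...) {
  if (is.null(object$model))
    return(c(b = NA_real_, c = NA_real_, d = NA_real_, e = NA_real_,
             f = NA_real_))
  coef(object$model)
}

#' @export
fitted.biphasic_fit <- function(object, ...) object$fitted

#' @export
residuals.biphasic_fit <- function(object, ...) object$residuals

#' @export
predict.biphasic_fit <- function(object, newdata = NULL, dose = NULL, ...) {
  if (is.null(object$model))
    stop("cannot predict from a non-converged fit", call. = FALSE)
  if (is.null(dose))
    dose <- if (is.null(newdata)) object$data$dose else newdata$dose
  predict(object$model, dose)
}

#' @export
summary.biphasic_fit <- function(object, ...) {
  se <- if (!is.null(object$param_covariance))
    sqrt(diag(object$param_covariance)) else rep(NA_real_, 5)
  tab <- cbind(Estimate = coef(object), `Std. Error` = se)
  structure(list(kind = object$kind, coefficients = tab, rss = object$rss,
                 n_obs = object$n_obs, converged = object$converged,
                 boxcox_lambda = object$boxcox_lambda,
                 sigma = sqrt(object$rss / max(object$n_obs - 5, 1)),
                 edp = if (!is.null(object$model))
                   edp(object$model, c(-50, 0, 50))),
            class = "summary.biphasic_fit")
}

#' @export
print.summary.biphasic_fit <- function(x, digits = 4, ...) {
  cat("Biphasic dose-response fit (", x$kind, ")\n\nParameters:\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat("\nRSS:", format(x$rss, digits = digits),
      " residual sd:", format(x$sigma, digits = digits),
      " n:", x$n_obs, "\n")
  if (!is.na(x$boxcox_lambda))
    cat("Box-Cox lambda:", x$boxcox_lambda,
        "(RSS on the transformed scale)\n")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  if (!is.null(x$edp)) {
    cat("\nEffective-dose vectors ED_p = (D_(p), E_(p)):\n")
    print(x$edp, digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a fitted biphasic dose-response curve
#'
#' Observations plus the fitted curve; log-scaled dose axis for
#' loggaussian fits (dose-0 observations are drawn at half the smallest
#' positive dose on that scale).
#'
#' @param x A `"biphasic_fit"`.
#' @param n_grid Number of curve evaluation points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.biphasic_fit <- function(x, n_grid = 200, ...) {
  if (is.null(x$model)) stop("nothing to plot: fit did not converge",
                             call. = FALSE)
  d <- x$data
  logx <- x$kind == "loggaussian"
  pos <- d$dose[d$dose > 0]
  dmin <- if (logx) min(pos) / 2 else 0
  dshow <- if (logx) pmax(d$dose, dmin) else d$dose
  grid <- if (logx)
    exp(seq(log(dmin), log(max(d$dose)), length.out = n_grid))
  else seq(0, max(d$dose), length.out = n_grid)
  graphics::plot(dshow, d$response, log = if (logx) "x" else "",
                 xlab = "dose", ylab = "response", ...)
  graphics::lines(grid, predict(x$model, grid), col = "steelblue", lwd = 2)
  graphics::points(x$model$e, x$model$d, pch = 4, col = "firebrick")
  invisible(x)
}

#' Simulate replicate datasets from a fitted biphasic model
#'
#' Draws new noisy datasets at the observed doses from the fitted curve,
#' with the noise coefficient of variation estimated from the residuals.
#'
#' @param object A converged `"biphasic_fit"`.
#' @param nsim Number of simulated datasets.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A list of `nsim` data frames (columns `dose`, `response`,
#'   `replicate`).
#' @export
simulate.biphasic_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$model))
    stop("cannot simulate from a non-converged fit", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cv <- stats::sd(object$residuals / pmax(object$fitted, 1e-12))
  doses <- unique(object$data$dose)
  reps <- max(1L, round(nrow(object$data) / length(doses)))
  lapply(seq_len(nsim), function(i)
    simulate_single(object$model, doses, cv = cv, n_rep = reps))
}
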