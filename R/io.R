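#' Read a tidy dose-response dataset
#'
#' Reads a comma-separated file with the required header
#' `series_id,dose,response,replicate` (decimal point, UTF-8) and
#' validates every row; offending rows are named in the error message.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `series_id` (character), `dose`,
#'   `response` (numeric) and `replicate` (integer).
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("series_id", "dose", "response", "replicate")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- raw[need]
  check_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop("non-numeric or non-finite '", col, "' at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    v
  }
  raw$dose <- check_num("dose")
  raw$response <- check_num("response")
  bad <- which(raw$dose < 0)
  if (length(bad))
    stop("negative dose at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  raw$replicate <- as.integer(raw$replicate)
  raw$series_id <- as.character(raw$series_id)
  raw
}

#' Write a tidy dose-response dataset
#'
#' @param data Data frame with columns `series_id`, `dose`, `response`,
#'   `replicate`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data[c("series_id", "dose", "response", "replicate")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a mixture configuration file
#'
#' YAML or JSON (by extension) with either explicit fractions
#' (`components: [{id: Zn, fraction: 0.5}, ...]`) or a constant-ratio
#' design rule (`components: [Zn, Cu]` plus
#' `ratio_design: {basis_p: -50, weights: [1, 1]}`) to be resolved
#' against fitted component curves by [resolve_mixture()].
#'
#' @param path Path to the config file.
#' @return A list with class `"mixture_config"`.
#' @export
read_mixture_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$components))
    stop("mixture config must list 'components'", call. = FALSE)
  structure(cfg, class = "mixture_config")
}

#' Resolve a mixture configuration into a mixture_spec
#'
#' @param cfg A `"mixture_config"` (or plain list of the same shape).
#' @param fits Named list of fitted component [biphasic_model()]s; only
#'   needed for a `ratio_design` rule.
#' @return A [mixture_spec()].
#' @export
resolve_mixture <- function(cfg, fits = NULL) {
  comp <- cfg$components
  if (is.data.frame(comp) || (is.list(comp) && !is.null(comp[[1]]$id)) ||
      (is.list(comp) && is.list(comp[[1]]) && "fraction" %in%
         names(comp[[1]]))) {
    if (is.data.frame(comp))
      return(mixture_spec(comp$id, comp$fraction))
    ids <- vapply(comp, function(x) as.character(x$id), "")
    fr <- vapply(comp, function(x) as.numeric(x$fraction), 0)
    return(mixture_spec(ids, fr))
  }
  ids <- unlist(comp)
  if (is.null(cfg$ratio_design))
    stop("components given without fractions need a 'ratio_design' rule",
         call. = FALSE)
  if (is.null(fits))
    stop("a ratio_design rule needs fitted component models", call. = FALSE)
  missing_ids <- setdiff(ids, names(fits))
  if (length(missing_ids))
    stop("no fit for component(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  constant_ratio_design(
    fits[ids], component_ids = ids,
    basis_p = if (is.null(cfg$ratio_design$basis_p)) -50
              else cfg$ratio_design$basis_p,
    weights = if (is.null(cfg$ratio_design$weights)) NULL
              else unlist(cfg$ratio_design$weights))
}

fit_table_row <- function(id, fit) {
  cf <- coef(fit)
  data.frame(series_id = id, kind = fit$kind,
             b = cf[["b"]], c = cf[["c"]], d = cf[["d"]], e = cf[["e"]],
             f = cf[["f"]], rss = fit$rss, n_obs = fit$n_obs,
             boxcox_lambda = fit$boxcox_lambda, converged = fit$converged)
}

#' Run the full analysis pipeline
#'
#' Drives the complete chain — fit the single-compound curves, tabulate
#' effective-dose vectors, predict additive mixture curves, estimate
#' combination-index profiles with replicate-level departure tests, and
#' summarise pairwise interactions — and writes every product as CSV plus
#' a machine-readable JSON run summary.  All outputs are deterministic
#' given the config and seed.
#'
#' @param config A list (or path to a YAML/JSON file) with entries:
#'   `input` (dataset CSV path, see [read_dataset()]); optional `series`
#'   (single-compound series ids; default: all series not named as a
#'   mixture); `model` (`"auto"`, `"loggaussian"` or `"gaussian"`);
#'   `boxcox`, `multistart` (logicals); `seed`; `p_grid` (either a numeric
#'   vector or `list(from, to, by)`); `p_levels` (reported levels, default
#'   -50/0/+50); `mixtures` — a list of entries with `name`, `series_id`
#'   (mixture data series), `components` (ids) and either `fractions` or
#'   a `ratio_design` rule; `out_dir`; `plots` (logical, default `FALSE`).
#' @return Invisibly, a list with the fits, ED_p table, per-mixture curves
#'   and CI tables, the polygonogram table and the summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config) else jsonlite::read_json(config,
                                                       simplifyVector = TRUE)
  }
  stopifnot(!is.null(config$input), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  p_levels <- if (is.null(config$p_levels)) c(-50, 0, 50)
              else unlist(config$p_levels)
  p_grid <- if (is.null(config$p_grid)) seq(-99, 99, by = 1)
            else if (is.list(config$p_grid))
              seq(config$p_grid$from, config$p_grid$to, by = config$p_grid$by)
            else unlist(config$p_grid)
  model_opt <- if (is.null(config$model)) "auto" else config$model
  status <- list()

  data <- read_dataset(config$input)
  mix_cfgs <- config$mixtures
  mix_series <- vapply(mix_cfgs, function(m)
    if (is.null(m$series_id)) NA_character_ else m$series_id, "")
  series <- if (!is.null(config$series)) unlist(config$series)
            else setdiff(unique(data$series_id), mix_series)
  unknown <- setdiff(c(series, mix_series[!is.na(mix_series)]),
                     unique(data$series_id))
  if (length(unknown))
    stop("series not present in the input data: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  fit_series <- function(sub) {
    if (identical(model_opt, "auto"))
      select_model(response ~ dose, sub,
                   multistart = isTRUE(config$multistart))
    else fit_biphasic(response ~ dose, sub, kind = model_opt,
                      boxcox = isTRUE(config$boxcox),
                      multistart = isTRUE(config$multistart))
  }

  fits <- list()
  for (id in series) {
    fits[[id]] <- fit_series(data[data$series_id == id, , drop = FALSE])
  }
  status$fit <- "ok"
  fit_tab <- do.call(rbind, Map(fit_table_row, names(fits), fits))
  utils::write.csv(fit_tab, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)

  models <- lapply(fits, `[[`, "model")
  edp_tab <- do.call(rbind, lapply(names(models), function(id) {
    if (is.null(models[[id]])) return(NULL)
    cbind(series_id = id, edp(models[[id]], p_levels))
  }))
  utils::write.csv(edp_tab, file.path(out_dir, "edp.csv"), row.names = FALSE)
  status$edp <- "ok"

  curves <- list(); cis <- list(); pair_results <- list()
  for (m in mix_cfgs) {
    nm <- if (is.null(m$name)) paste(unlist(m$components), collapse = "_")
          else m$name
    spec <- resolve_mixture(m, models)
    comp_models <- models[spec$component_ids]
    if (any(vapply(comp_models, is.null, TRUE)))
      stop("mixture '", nm, "' references a non-converged component fit",
           call. = FALSE)
    curve <- predict_curve(comp_models, spec, p_grid)
    utils::write.csv(curve, file.path(out_dir, paste0("curve_", nm, ".csv")),
                     row.names = FALSE)
    curves[[nm]] <- curve

    if (!is.null(m$series_id)) {
      mix_data <- data[data$series_id == m$series_id, , drop = FALSE]
      mix_fit <- fit_series(mix_data)
      prof <- ci_profile(mix_fit$model, comp_models, spec, p_grid)
      prof$p_value_d <- NA_real_
      prof$p_value_e <- NA_real_
      prof$n_replicates <- length(unique(mix_data$replicate))
      if (length(unique(mix_data$replicate)) >= 2) {
        rep_ci <- tryCatch(
          suppressWarnings(ci_replicates(mix_data, comp_models, spec,
                                         p = p_levels,
                                         kind = if (identical(model_opt,
                                                              "auto")) "auto"
                                                else model_opt)),
          error = function(e) NULL)
        if (!is.null(rep_ci)) {
          for (pl in p_levels) {
            v <- rep_ci[rep_ci$p == pl, ]
            if (nrow(v) >= 2) {
              i <- which(prof$p == pl)
              prof$p_value_d[i] <- test_departure(v$ci_d)$p_value
              prof$p_value_e[i] <- test_departure(v$ci_e)$p_value
            }
          }
        }
      }
      out_cols <- c("p", "ci_d", "ci_e", "ci_w", "p_value_d", "p_value_e",
                    "category", "n_replicates")
      utils::write.csv(prof[out_cols],
                       file.path(out_dir, paste0("ci_", nm, ".csv")),
                       row.names = FALSE)
      cis[[nm]] <- prof
      if (length(spec$component_ids) == 2)
        pair_results[[paste(spec$component_ids, collapse = ":")]] <- prof
    }
  }
  status$mixtures <- "ok"

  poly <- NULL
  if (length(pair_results)) {
    poly <- polygonogram_summary(pair_results, p_levels)
    utils::write.csv(poly, file.path(out_dir, "polygonogram.csv"),
                     row.names = FALSE)
  }

  if (isTRUE(config$plots)) {
    status$plots <- tryCatch({
      for (id in names(fits)) {
        if (is.null(fits[[id]]$model)) next
        grDevices::png(file.path(out_dir, paste0("fit_", id, ".png")),
                       width = 700, height = 500)
        plot(fits[[id]], main = id)
        grDevices::dev.off()
      }
      for (nm in names(cis)) {
        grDevices::png(file.path(out_dir, paste0("ci_w_", nm, ".png")),
                       width = 700, height = 500)
        plot_ci_profile(cis[[nm]], "w", main = nm)
        grDevices::dev.off()
      }
      "ok"
    }, error = function(e) paste("failed:", conditionMessage(e)))
  }

  summary <- list(
    package = "biphasicCI",
    version = as.character(utils::packageVersion("biphasicCI")),
    r_version = as.character(getRversion()),
    seed = seed, series = series,
    mixtures = names(curves), stages = status)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fits = fits, edp = edp_tab, curves = curves, ci = cis,
                 polygonogram = poly, summary = summary))
}
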