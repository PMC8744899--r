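#' Hazard-ratio report from coefficient summaries
#'
#' Exponentiates posterior summaries on the coefficient scale into hazard
#' ratios with 95\% intervals and a percent change in hazard: for a
#' protective effect (HR < 1) the percent decrease \eqn{(1 - HR)\cdot 100},
#' otherwise the percent increase \eqn{(HR - 1)\cdot 100}. Hazard ratios and
#' coefficient columns are rounded to 4 decimal places, percent changes to 2.
#'
#' @param summaries data.frame with columns \code{effect} (or
#'   \code{parameter}), \code{mean}, \code{lower}, \code{upper}; e.g. the
#'   beta rows of \code{\link{posterior_summary}} or
#'   \code{\link{u5cm_reference_summary}}.
#' @param labels optional named character vector of display labels.
#' @return data.frame with columns \code{effect}, \code{label}, \code{mean},
#'   \code{lower}, \code{upper}, \code{hazard_ratio}, \code{hr_lower},
#'   \code{hr_upper}, \code{percent_change}, \code{direction}.
#' @examples
#' hazard_ratio_report(u5cm_reference_summary())
#' @export
hazard_ratio_report <- function(summaries, labels = effect_labels()) {
  nm <- if ("effect" %in% names(summaries)) "effect" else "parameter"
  need <- c(nm, "mean", "lower", "upper")
  miss <- setdiff(need, names(summaries))
  if (length(miss)) stop("summaries missing column(s): ", paste(miss, collapse = ", "))
  effect <- sub("^beta\\.", "", summaries[[nm]])
  hr <- round(exp(summaries$mean), 4)
  data.frame(
    effect = effect,
    label = ifelse(effect %in% names(labels), labels[effect], effect),
    mean = round(summaries$mean, 4),
    lower = round(summaries$lower, 4),
    upper = round(summaries$upper, 4),
    hazard_ratio = hr,
    hr_lower = round(exp(summaries$lower), 4),
    hr_upper = round(exp(summaries$upper), 4),
    percent_change = round(ifelse(hr < 1, (1 - hr) * 100, (hr - 1) * 100), 2),
    direction = ifelse(hr < 1, "decrease", ifelse(hr > 1, "increase", "none")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-area posterior frailty export
#'
#' Posterior median (default, as mapped in choropleths of median frailties)
#' or mean frailty per area, as a table keyed by area label; optionally
#' writes a GeoJSON choropleth when a geometry file with matching feature
#' labels is given.
#'
#' @param chains spatial \code{posterior_chains}.
#' @param graph the \code{\link{area_graph}} used in the fit.
#' @param geometry optional path to a GeoJSON FeatureCollection whose
#'   features carry the area label in property \code{label_property}.
#' @param out optional output GeoJSON path (required with \code{geometry});
#'   each feature gains \code{frailty_median} (or \code{frailty_mean}).
#' @param stat \code{"median"} or \code{"mean"}.
#' @param label_property property name holding the area label in the
#'   GeoJSON features.
#' @return data.frame with columns \code{area} and \code{frailty}.
#' @export
frailty_map_export <- function(chains, graph, geometry = NULL, out = NULL,
                               stat = c("median", "mean"),
                               label_property = "name") {
  stat <- match.arg(stat)
  stopifnot(inherits(chains, "posterior_chains"))
  if (!chains$spatial) stop("chains come from a no-frailty model")
  W <- chains$draws$frailties
  if (!identical(colnames(W), graph$area_ids))
    stop("chain areas do not match the supplied graph")
  val <- if (stat == "median") apply(W, 2, stats::median) else colMeans(W)
  tab <- data.frame(area = graph$area_ids, frailty = unname(val),
                    stringsAsFactors = FALSE)
  names(tab)[2] <- paste0("frailty_", stat)
  if (!is.null(geometry)) {
    gj <- jsonlite::read_json(geometry)
    if (is.null(gj$features)) stop("geometry is not a GeoJSON FeatureCollection")
    feat_labels <- vapply(gj$features, function(f)
      as.character(f$properties[[label_property]] %||% NA_character_), character(1))
    mismatch <- union(setdiff(feat_labels, graph$area_ids),
                      setdiff(graph$area_ids, feat_labels))
    if (length(mismatch))
      stop("geometry labels do not match graph areas: ",
           paste(mismatch, collapse = ", "))
    for (i in seq_along(gj$features)) {
      gj$features[[i]]$properties[[paste0("frailty_", stat)]] <-
        tab[[2]][match(feat_labels[i], tab$area)]
    }
    if (is.null(out)) stop("out path required when geometry is given")
    jsonlite::write_json(gj, out, auto_unbox = TRUE, digits = NA, null = "null")
  }
  tab
}

#' Trace plots of selected parameters
#'
#' @param chains a \code{posterior_chains}.
#' @param parameters character vector of parameter names (default: the
#'   coefficients and, if spatial, \code{sigma2}).
#' @param file optional PNG path; when given the plot is written there.
#' @return invisibly, the matrix of plotted series.
#' @export
plot_traces <- function(chains, parameters = NULL, file = NULL) {
  M <- parameter_matrix(chains)
  if (is.null(parameters)) {
    parameters <- grep("^beta\\.", colnames(M), value = TRUE)
    if (chains$spatial) parameters <- c(parameters, "sigma2")
  }
  bad <- setdiff(parameters, colnames(M))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  M <- M[, parameters, drop = FALSE]
  if (!is.null(file)) grDevices::png(file, width = 1200, height = 200 * ncol(M))
  op <- graphics::par(mfrow = c(ncol(M), 1), mar = c(2, 4, 1, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  for (j in seq_len(ncol(M)))
    graphics::plot(M[, j], type = "l", ylab = colnames(M)[j], xlab = "")
  invisible(M)
}

#' Cox-Snell residual plot
#'
#' Nelson-Aalen cumulative hazard of the residuals against the residuals,
#' with the unit-slope reference line.
#'
#' @param gof a \code{\link{residual_gof}} result.
#' @param file optional PNG path.
#' @export
plot_residual_gof <- function(gof, file = NULL) {
  if (!is.null(file)) grDevices::png(file, width = 600, height = 600)
  on.exit(if (!is.null(file)) grDevices::dev.off())
  graphics::plot(gof$curve$r, gof$curve$cumhaz, type = "s",
                 xlab = "Cox-Snell residual",
                 ylab = "Estimated cumulative hazard")
  graphics::abline(0, 1, lty = 2)
  graphics::abline(0, gof$slope, col = "grey40")
  invisible(gof)
}

#' End-to-end analysis pipeline
#'
#' Fits the no-frailty and spatial models on the supplied (or generated)
#' data, writes the model-comparison table, posterior summary and
#' hazard-ratio tables, frailty export, Cox-Snell diagnostics, optional
#' plots and a JSON manifest into one artifact directory. Any stage failure
#' aborts with a stage-named error; artifacts already written are retained.
#'
#' @param records data.frame of records, or \code{NULL} to generate from
#'   \code{sim}.
#' @param graph an \code{\link{area_graph}}; defaults to the generated
#'   dataset's graph.
#' @param sim a \code{\link{sim_config}} used when \code{records} is NULL.
#' @param out_dir artifact directory (created).
#' @param priors a \code{\link{prior_config}}.
#' @param config an \code{\link{mcmc_config}}.
#' @param models which models to fit.
#' @param plots write PNG trace/residual plots.
#' @return invisibly, a list with the fitted chains, comparison table and
#'   artifact paths.
#' @export
run_pipeline <- function(records = NULL, graph = NULL, sim = sim_config(),
                         out_dir, priors = prior_config(),
                         config = mcmc_config(),
                         models = c("no_frailty", "spatial"), plots = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dataset <- NULL
  if (is.null(records)) {
    dataset <- stage("simulate", generate_dataset(sim))
    records <- dataset$records
    if (is.null(graph)) graph <- dataset$graph
    stage("simulate", write_dataset(dataset, file.path(out_dir, "data")))
  }
  if (is.null(graph) && "spatial" %in% models)
    stop("pipeline stage 'setup' failed: spatial model needs a graph")
  design <- stage("design", build_design(records))
  records <- records[attr(design, "kept"), , drop = FALSE]

  fits <- list()
  if ("no_frailty" %in% models)
    fits$no_frailty <- stage("fit_no_frailty",
                             sample_posterior(records, design, NULL, priors, config))
  if ("spatial" %in% models)
    fits$spatial <- stage("fit_spatial",
                          sample_posterior(records, design, graph, priors, config))

  paths <- list()
  if (length(fits) == 2L) {
    cmp <- stage("compare", compare_models(fits$no_frailty, fits$spatial))
    paths$comparison <- file.path(out_dir, "model_comparison.csv")
    utils::write.csv(cmp, paths$comparison, row.names = FALSE)
  } else cmp <- NULL

  main <- fits$spatial %||% fits$no_frailty
  summ <- stage("summarise", posterior_summary(main))
  paths$posterior <- file.path(out_dir, "posterior_summary.csv")
  utils::write.csv(summ, paths$posterior, row.names = FALSE)
  beta_rows <- summ[grepl("^beta\\.", summ$parameter), ]
  hr <- stage("report", hazard_ratio_report(beta_rows))
  paths$hazard_ratios <- file.path(out_dir, "hazard_ratios.csv")
  utils::write.csv(hr, paths$hazard_ratios, row.names = FALSE)

  state <- posterior_mean_state(main)
  res <- stage("residuals", cox_snell_residuals(records, design, state))
  gof <- stage("residuals", residual_gof(res))
  paths$residual_curve <- file.path(out_dir, "coxsnell_curve.csv")
  utils::write.csv(gof$curve, paths$residual_curve, row.names = FALSE)

  if (!is.null(fits$spatial)) {
    fr <- stage("frailty_map", frailty_map_export(fits$spatial, graph))
    paths$frailties <- file.path(out_dir, "frailty_medians.csv")
    utils::write.csv(fr, paths$frailties, row.names = FALSE)
  }
  if (plots) {
    paths$trace_plot <- file.path(out_dir, "traces.png")
    stage("plots", plot_traces(main, file = paths$trace_plot))
    paths$residual_plot <- file.path(out_dir, "coxsnell.png")
    stage("plots", plot_residual_gof(gof, file = paths$residual_plot))
  }
  manifest <- list(
    seed = config$seed,
    n_iterations = config$n_iterations, burn_in = config$burn_in,
    thinning = config$thinning,
    n_records = nrow(records), n_events = sum(records$event),
    models = names(fits),
    acceptance_rates = lapply(fits, function(f) as.list(f$acceptance_rates)),
    coxsnell_slope = gof$slope,
    package_version = as.character(utils::packageVersion("icarsurv"))
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(fits = fits, comparison = cmp, hazard_ratios = hr,
                 gof = gof, dataset = dataset, paths = paths))
}
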