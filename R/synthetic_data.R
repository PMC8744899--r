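#' Approximate adjacency of the 47 Kenyan counties
#'
#' Packaged first-order (queen-like) contiguity fixture for the 47 counties.
#' The neighbour pairs are an approximation drawn from the country's
#' administrative geography, not derived from official shapefiles; the graph
#' is connected, which is what the ICAR prior needs.
#'
#' @return an \code{\link{area_graph}} with 47 areas.
#' @export
kenya_county_graph <- function() {
  path <- system.file("extdata", "kenya47_adjacency.txt", package = "icarsurv")
  if (!nzchar(path)) stop("packaged adjacency fixture not found")
  read_adjacency(path, format = "edgelist")
}

#' Connected lattice graph for arbitrary area counts
#'
#' Rook-contiguity grid with \code{n_areas} nodes (rows x columns chosen near
#' square, surplus tail nodes dropped), used by the generator when a
#' non-default number of areas is requested.
#'
#' @param n_areas number of areas (>= 2).
#' @return an \code{\link{area_graph}} with labels \code{A01, A02, ...}.
#' @export
lattice_graph <- function(n_areas) {
  n_areas <- as.integer(n_areas)
  if (n_areas < 2L) stop("need at least 2 areas")
  nr <- floor(sqrt(n_areas))
  nc <- ceiling(n_areas / nr)
  ig <- igraph::make_lattice(c(nr, nc))
  ig <- igraph::delete_vertices(ig, seq_len(nr * nc)[-seq_len(n_areas)])
  ids <- sprintf("A%02d", seq_len(n_areas))
  edges <- igraph::as_edgelist(ig)
  area_graph(ids, cbind(ids[edges[, 1]], ids[edges[, 2]]))
}

#' Synthetic-data configuration
#'
#' Conditions emulating the KDHS-2014 child-survival structure: 47 areas
#' (counties), around 70 children per area, under-five follow-up with heavy
#' administrative right censoring, the canonical covariate set, true effect
#' sizes defaulting to the published posterior means
#' (\code{\link{u5cm_reference_effects}}) and ICAR frailty variance 0.2.
#' The default baseline hazard uses two intervals splitting infant
#' (0-12 months) from child (12-60 months) risk, with the infant hazard
#' roughly four times the child hazard.
#'
#' @param n_areas number of areas; 47 uses the packaged county fixture,
#'   other values a lattice graph.
#' @param children_per_area Poisson mean of the per-area child count.
#' @param true_beta named effect vector (design columns of
#'   \code{\link{u5cm_variables}}).
#' @param frailty_variance ICAR variance of the true frailties (> 0, or 0
#'   for frailty-free data).
#' @param baseline true \code{\link{piecewise_baseline}} (per-month hazards).
#' @param censoring \code{"dhs"} (age at interview uniform on (0, 60)
#'   months) or \code{"none"} (administrative censoring at 60 only).
#' @param seed RNG seed; generation is deterministic given the config.
#' @param graph optional \code{\link{area_graph}} overriding the default.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_areas = 47L, children_per_area = 70,
                       true_beta = u5cm_reference_effects(),
                       frailty_variance = 0.2,
                       baseline = piecewise_baseline(c(12, 60),
                                                     log(c(0.0025, 0.0006))),
                       censoring = c("dhs", "none"), seed = 1L,
                       graph = NULL) {
  censoring <- match.arg(censoring)
  if (children_per_area <= 0) stop("children_per_area must be positive")
  if (frailty_variance < 0) stop("frailty_variance must be nonnegative")
  structure(list(n_areas = as.integer(n_areas),
                 children_per_area = children_per_area,
                 true_beta = true_beta, frailty_variance = frailty_variance,
                 baseline = baseline, censoring = censoring,
                 seed = as.integer(seed), graph = graph),
            class = "sim_config")
}

#' Draw ICAR frailties on the sum-to-zero contrast space
#'
#' Eigendecomposition of the unscaled precision \eqn{Q}: independent normal
#' scores with variance \eqn{\sigma^2/\lambda_k} on the eigenvectors with
#' \eqn{\lambda_k > 0}; null eigenvectors (constants per component) carry no
#' mass, so the draw sums to zero within each component.
#'
#' @param structure an \code{icar_structure}.
#' @param variance \eqn{\sigma^2 > 0}.
#' @param seed optional RNG seed.
#' @return named numeric vector of frailties (sum ~ 0 to 1e-10).
#' @export
sample_icar_frailties <- function(structure, variance, seed = NULL) {
  stopifnot(inherits(structure, "icar_structure"))
  if (!is.numeric(variance) || variance <= 0) stop("variance must be positive")
  if (!is.null(seed)) set.seed(seed)
  Q <- structure$precision_unscaled
  eg <- eigen(Q, symmetric = TRUE)
  lam <- eg$values
  pos <- lam > max(lam) * 1e-10
  z <- stats::rnorm(sum(pos), 0, sqrt(variance / lam[pos]))
  w <- as.vector(eg$vectors[, pos, drop = FALSE] %*% z)
  names(w) <- rownames(Q)
  w
}

#' Draw a stylised KDHS-like covariate table
#'
#' Marginals: child sex Bernoulli(0.5); rural residence Bernoulli(0.65);
#' female household head Bernoulli(0.3); wealth quintile uniform over five
#' levels; education over (none, primary, secondary, higher) with
#' probabilities (0.25, 0.40, 0.25, 0.10); age at first birth
#' round(N(19, 3)) truncated to [12, 40]; maternal age at birth
#' round(N(26, 6)) truncated to [12, 49]; twin status (single 0.97,
#' 1st multiple 0.02, 2nd multiple 0.01). Covariates are independent across
#' variables and children - a stylised emulation, not survey estimates.
#'
#' @param n number of children (>= 1).
#' @param seed optional RNG seed.
#' @return data.frame with one column per variable of
#'   \code{\link{u5cm_variables}}.
#' @export
sample_covariates <- function(n, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rtruncnorm_round <- function(n, mean, sd, lo, hi) {
    x <- round(stats::rnorm(n, mean, sd))
    while (any(bad <- x < lo | x > hi))
      x[bad] <- round(stats::rnorm(sum(bad), mean, sd))
    x
  }
  data.frame(
    sex = sample(c("male", "female"), n, replace = TRUE),
    residence = sample(c("urban", "rural"), n, replace = TRUE,
                       prob = c(0.35, 0.65)),
    head_sex = sample(c("male", "female"), n, replace = TRUE,
                      prob = c(0.7, 0.3)),
    wealth = sample(c("poorest", "poorer", "middle", "richer", "richest"),
                    n, replace = TRUE),
    education = sample(c("none", "primary", "secondary", "higher"),
                       n, replace = TRUE, prob = c(0.25, 0.40, 0.25, 0.10)),
    age_first_birth = rtruncnorm_round(n, 19, 3, 12, 40),
    maternal_age = rtruncnorm_round(n, 26, 6, 12, 49),
    twin = sample(c("single", "first_multiple", "second_multiple"),
                  n, replace = TRUE, prob = c(0.97, 0.02, 0.01)),
    stringsAsFactors = FALSE
  )
}

## invert the piecewise-constant cumulative hazard: smallest t with H0(t) = e
invert_cumulative <- function(baseline, e) {
  cuts <- baseline$cut_points
  h <- exp(baseline$log_heights)
  lower <- c(0, cuts[-length(cuts)])
  Hc <- cumsum(h * (cuts - lower))
  out <- rep(Inf, length(e))
  for (i in seq_along(e)) {
    k <- which(e[i] <= Hc + 1e-300)[1]
    if (!is.na(k) && e[i] <= Hc[length(Hc)]) {
      H_lo <- if (k == 1) 0 else Hc[k - 1]
      out[i] <- lower[k] + (e[i] - H_lo) / h[k]
    }
  }
  out
}

#' Simulate survival records under the proportional-hazards model
#'
#' Death times are drawn by inverse transform from the piecewise-exponential
#' survival function with hazard multiplier \eqn{e^{x'\beta + w_a}}; under
#' the \code{"dhs"} censoring scheme each child's follow-up is truncated at
#' an interview age drawn uniformly on (0, 60) months, emulating a birth
#' history collected over the five years before the survey.
#'
#' @param covariates data.frame with an \code{area} column plus the model
#'   covariates.
#' @param frailties named per-area frailty vector (use zeros for no spatial
#'   effect).
#' @param truth a \code{\link{model_state}} carrying the true \code{beta}
#'   and \code{baseline} (betas applied on the natural, uncentred scale).
#' @param censoring \code{"dhs"} or \code{"none"}.
#' @param seed optional RNG seed.
#' @return data.frame: \code{covariates} plus \code{time} and \code{event}.
#' @export
simulate_survival <- function(covariates, frailties, truth,
                              censoring = c("dhs", "none"), seed = NULL) {
  censoring <- match.arg(censoring)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(covariates)
  design <- build_design(covariates, center = FALSE)
  xb <- as.vector(unclass(design) %*% truth$beta[colnames(design)])
  w <- frailties[as.character(covariates$area)]
  if (anyNA(w)) stop("covariate area(s) missing from frailty vector")
  m <- exp(xb + as.vector(w))
  e_target <- stats::rexp(n) / m
  death <- invert_cumulative(truth$baseline, e_target)
  horizon <- max(truth$baseline$cut_points)
  cens <- if (censoring == "dhs") stats::runif(n, 0, horizon) else rep(horizon, n)
  time <- pmin(death, cens)
  event <- as.integer(death <= cens)
  ## guard against zero-length follow-up from the continuous draws
  time <- pmax(time, 1e-6)
  out <- covariates
  out$time <- time
  out$event <- event
  out
}

#' Generate a complete synthetic child-survival dataset
#'
#' Composes the areal graph, true ICAR frailties, covariates and survival
#' outcomes into one dataset with recorded ground truth. Deterministic given
#' the configuration seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{synthetic_dataset}: \code{records}
#'   (covariates + \code{area}, \code{time}, \code{event}), \code{graph},
#'   \code{truth} (a \code{\link{model_state}}) and the \code{config} echo.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  graph <- config$graph %||%
    (if (config$n_areas == 47L) kenya_county_graph() else lattice_graph(config$n_areas))
  if (graph$n_areas != config$n_areas)
    stop("graph has ", graph$n_areas, " areas but config asks for ", config$n_areas)
  structure_ <- build_icar_structure(graph)
  w <- if (config$frailty_variance > 0) {
    sample_icar_frailties(structure_, config$frailty_variance)
  } else {
    stats::setNames(rep(0, graph$n_areas), graph$area_ids)
  }
  counts <- stats::rpois(graph$n_areas, config$children_per_area)
  counts <- pmax(counts, 1L)
  area <- rep(graph$area_ids, counts)
  cov <- sample_covariates(sum(counts))
  cov$area <- area
  truth <- model_state(config$true_beta, config$baseline,
                       frailties = if (config$frailty_variance > 0) w,
                       frailty_variance = if (config$frailty_variance > 0)
                         config$frailty_variance)
  records <- simulate_survival(cov, w, truth, censoring = config$censoring)
  structure(list(records = records, graph = graph, truth = truth,
                 true_frailties = w, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset: ", nrow(x$records), " children in ",
      x$graph$n_areas, " areas; ", sum(x$records$event), " deaths (",
      sprintf("%.1f%%", 100 * mean(x$records$event)), ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Writes \code{records.csv}, \code{adjacency.txt} (edge list) and
#' \code{truth.json} (true betas, frailties, variance and baseline).
#'
#' @param dataset a \code{\link{generate_dataset}} result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  write_adjacency(dataset$graph, file.path(dir, "adjacency.txt"))
  truth <- list(
    beta = as.list(dataset$truth$beta),
    frailties = as.list(dataset$true_frailties),
    frailty_variance = dataset$truth$frailty_variance,
    baseline = list(cut_points = dataset$truth$baseline$cut_points,
                    log_heights = dataset$truth$baseline$log_heights),
    seed = dataset$config$seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read child-survival records from delimited text
#'
#' Expects a header with at least \code{time}, \code{event}, \code{area} and
#' the covariate columns of \code{\link{u5cm_variables}}.
#'
#' @param path CSV file path.
#' @return data.frame of records.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_records(rec)
  rec
}
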