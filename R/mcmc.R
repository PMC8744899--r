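#' MCMC configuration
#'
#' Settings for the Metropolis-within-Gibbs sampler. Proposal scales are
#' starting values; with \code{adapt = TRUE} they are tuned by Robbins-Monro
#' recursion toward a 0.44 acceptance rate (single-site updates) during
#' burn-in only, then frozen so the post-burn-in chain satisfies detailed
#' balance.
#'
#' @param n_iterations total sweeps.
#' @param burn_in discarded initial sweeps; must be < \code{n_iterations}.
#' @param thinning keep every \code{thinning}-th post-burn-in sweep.
#' @param seed RNG seed; identical seed + config + data gives identical chains.
#' @param beta_scale,height_scale,frailty_scale initial random-walk proposal
#'   standard deviations per block.
#' @param adapt tune proposal scales during burn-in.
#' @param use_likelihood set \code{FALSE} to sample from the prior only
#'   (likelihood term switched off; used for prior-recovery checks).
#' @param update_beta,update_heights,update_frailties enable individual
#'   update blocks (all \code{TRUE} normally; fixing blocks is useful for
#'   conditional-distribution checks).
#' @param frailty_sweeps number of (frailty sweep, variance draw) cycles per
#'   iteration; the frailty-variance pair mixes slowly under single-site
#'   updates and these extra cheap sub-sweeps raise its effective sample
#'   size substantially.
#' @return object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_iterations = 11000L, burn_in = 1000L, thinning = 10L,
                        seed = 1L, beta_scale = 0.1, height_scale = 0.2,
                        frailty_scale = 0.5, adapt = TRUE,
                        use_likelihood = TRUE, update_beta = TRUE,
                        update_heights = TRUE, update_frailties = TRUE,
                        frailty_sweeps = 3L) {
  n_iterations <- as.integer(n_iterations)
  burn_in <- as.integer(burn_in)
  thinning <- as.integer(thinning)
  if (n_iterations < 1L) stop("n_iterations must be positive")
  if (burn_in < 0L || burn_in >= n_iterations)
    stop("burn_in must satisfy 0 <= burn_in < n_iterations")
  if (thinning < 1L) stop("thinning must be >= 1")
  if (frailty_sweeps < 1L) stop("frailty_sweeps must be >= 1")
  structure(list(n_iterations = n_iterations, burn_in = burn_in,
                 thinning = thinning, seed = as.integer(seed),
                 beta_scale = beta_scale, height_scale = height_scale,
                 frailty_scale = frailty_scale, adapt = adapt,
                 use_likelihood = use_likelihood, update_beta = update_beta,
                 update_heights = update_heights,
                 update_frailties = update_frailties,
                 frailty_sweeps = as.integer(frailty_sweeps)),
            class = "mcmc_config")
}

#' Posterior sampling by Metropolis-within-Gibbs
#'
#' Fits the piecewise-exponential proportional-hazards model, with ICAR
#' areal frailties when \code{graph} is supplied. One sweep updates, in
#' order: each regression coefficient (random-walk Metropolis), each log
#' baseline height (random-walk Metropolis), each area frailty (single-site
#' Metropolis against its ICAR full conditional), after which the frailties
#' are recentred to sum to zero with the mean absorbed into the baseline
#' (likelihood-invariant), and the frailty variance is drawn from its
#' conjugate Inverse-Gamma full conditional
#' \eqn{IG(a + r/2,\; b + w'Qw/2)} with \eqn{r} the ICAR rank.
#'
#' @param records data.frame with \code{time} (months), \code{event},
#'   \code{area}, rows aligned with \code{design}.
#' @param design a \code{\link{build_design}} matrix.
#' @param graph an \code{\link{area_graph}} for the spatial model, or
#'   \code{NULL} for the no-frailty model.
#' @param priors a \code{\link{prior_config}}.
#' @param config an \code{\link{mcmc_config}}.
#' @param baseline optional \code{\link{piecewise_baseline}} grid (heights
#'   are treated as initial values); default decile grid of event times.
#' @param init optional \code{\link{model_state}} supplying initial values.
#' @return object of class \code{posterior_chains}: retained draws
#'   (\code{$draws$beta}, \code{$draws$log_heights}, \code{$draws$frailties},
#'   \code{$draws$sigma2}), the retained-draw-by-record log-likelihood matrix
#'   \code{$per_record_loglik}, total log-likelihood series, per-block
#'   acceptance rates, and echoes of config, priors and data.
#' @export
sample_posterior <- function(records, design, graph = NULL,
                             priors = prior_config(), config = mcmc_config(),
                             baseline = NULL, init = NULL) {
  check_records(records)
  stopifnot(inherits(config, "mcmc_config"), inherits(priors, "prior_config"))
  n <- nrow(records)
  if (nrow(design) != n) stop("records and design have different numbers of rows")
  X <- unclass(design)
  if (anyNA(X)) stop("design matrix contains missing values")
  p <- ncol(X)
  d <- as.numeric(records$event)
  t <- as.numeric(records$time)

  if (is.null(baseline)) baseline <- default_baseline(t, d)
  cuts <- baseline$cut_points
  K <- length(cuts)
  if (max(t) > cuts[K] + 1e-9)
    stop("observed time ", max(t), " beyond last baseline cut ", cuts[K])

  crude <- sum(d) / sum(t)
  m0 <- priors$baseline_log_mean %||% log(crude)
  s0 <- priors$baseline_log_sd
  priors$baseline_log_mean <- m0

  Emat <- interval_exposures(baseline, t)
  evint <- interval_index(baseline, t)
  Dk <- tabulate(evint[d == 1], nbins = K)
  sdx <- as.vector(crossprod(X, d))
  bidx <- lapply(seq_len(p), function(j) which(X[, j] != 0))
  bval <- lapply(seq_len(p), function(j) X[bidx[[j]], j])
  hidx <- lapply(seq_len(K), function(k) which(Emat[, k] > 0))
  hval <- lapply(seq_len(K), function(k) Emat[hidx[[k]], k])

  spatial <- !is.null(graph)
  if (spatial) {
    stopifnot(inherits(graph, "area_graph"))
    structure_ <- build_icar_structure(graph)
    area_idx <- match(as.character(records$area), graph$area_ids)
    if (anyNA(area_idx))
      stop("record area(s) missing from graph: ",
           paste(unique(records$area[is.na(area_idx)]), collapse = ", "))
    A <- graph$n_areas
    nb <- neighbour_list(graph)
    Ad <- tabulate(area_idx[d == 1], nbins = A)
    e1 <- graph$edges[, 1L]; e2 <- graph$edges[, 2L]
    rank_ <- structure_$rank
  } else {
    structure_ <- NULL; area_idx <- NULL; A <- 0L
  }

  ## initial state
  beta <- rep(0, p); names(beta) <- colnames(X)
  logh <- baseline$log_heights
  w <- if (spatial) rep(0, A) else NULL
  sigma2 <- if (spatial) 0.1 else NULL
  if (!is.null(init)) {
    if (!is.null(init$beta)) beta[names(init$beta)] <- init$beta
    if (!is.null(init$baseline)) logh <- init$baseline$log_heights
    if (spatial && !is.null(init$frailties)) {
      w <- unname(init$frailties[graph$area_ids])
      if (anyNA(w)) stop("init frailties do not cover all areas")
    }
    if (spatial && !is.null(init$frailty_variance)) sigma2 <- init$frailty_variance
  }
  if (spatial && (!is.finite(sigma2) || sigma2 <= 0))
    stop("non-finite posterior at init: frailty_variance must be positive")
  if (any(!is.finite(beta))) stop("non-finite posterior at init: beta")
  if (any(!is.finite(logh))) stop("non-finite posterior at init: baseline log heights")
  if (spatial && any(!is.finite(w))) stop("non-finite posterior at init: frailties")

  h <- exp(logh)
  xb <- as.vector(X %*% beta)
  expxb <- exp(xb)
  ew <- if (spatial) exp(w)[area_idx] else rep(1, n)
  H0 <- as.vector(Emat %*% h)

  use_ll <- isTRUE(config$use_likelihood)
  if (use_ll) {
    ll0 <- sum(d * (logh[evint] + xb + if (spatial) w[area_idx] else 0) -
                 H0 * expxb * ew)
    if (!is.finite(ll0)) stop("non-finite posterior at init: likelihood")
  }

  ## proposal log-scales (per component) and Robbins-Monro adaptation
  ls_beta <- rep(log(config$beta_scale), p)
  ls_h <- rep(log(config$height_scale), K)
  ls_w <- if (spatial) rep(log(config$frailty_scale), A) else NULL
  target <- 0.44
  adapt <- isTRUE(config$adapt)
  burn <- config$burn_in
  thin <- config$thinning
  S <- (config$n_iterations - burn) %/% thin
  if (S < 1L) stop("no retained draws: increase n_iterations or reduce thinning")

  beta_draws <- matrix(NA_real_, S, p, dimnames = list(NULL, colnames(X)))
  logh_draws <- matrix(NA_real_, S, K,
                       dimnames = list(NULL, paste0("interval_", seq_len(K))))
  w_draws <- if (spatial) matrix(NA_real_, S, A, dimnames = list(NULL, graph$area_ids))
  sigma2_draws <- if (spatial) numeric(S)
  llmat <- matrix(NA_real_, S, n)
  acc <- c(beta = 0, heights = 0, frailties = 0)
  att <- c(beta = 0, heights = 0, frailties = 0)

  set.seed(config$seed)
  vb <- 1 / (2 * priors$beta_sd^2)
  a0 <- priors$variance_shape; b0 <- priors$variance_rate
  s_i <- 0L

  for (iter in seq_len(config$n_iterations)) {
    gam <- if (adapt && iter <= burn) min(0.5, iter^-0.6) else 0
    post <- iter > burn

    if (config$update_beta) {
      for (j in seq_len(p)) {
        delta <- stats::rnorm(1, 0, exp(ls_beta[j]))
        idx <- bidx[[j]]; xv <- bval[[j]]
        nx <- expxb[idx] * exp(xv * delta)
        dll <- if (use_ll)
          delta * sdx[j] - sum(H0[idx] * ew[idx] * (nx - expxb[idx])) else 0
        dlp <- vb * (beta[j]^2 - (beta[j] + delta)^2)
        ok <- log(stats::runif(1)) < dll + dlp
        if (ok) {
          beta[j] <- beta[j] + delta
          xb[idx] <- xb[idx] + xv * delta
          expxb[idx] <- nx
        }
        if (gam > 0) ls_beta[j] <- ls_beta[j] + gam * ((if (ok) 1 else 0) - target)
        if (post) { att["beta"] <- att["beta"] + 1; acc["beta"] <- acc["beta"] + ok }
      }
    }

    if (config$update_heights) {
      for (k in seq_len(K)) {
        delta <- stats::rnorm(1, 0, exp(ls_h[k]))
        idx <- hidx[[k]]; Ek <- hval[[k]]
        hn <- exp(logh[k] + delta)
        dH <- (hn - h[k]) * Ek
        dll <- if (use_ll)
          Dk[k] * delta - sum(dH * expxb[idx] * ew[idx]) else 0
        dlp <- ((logh[k] - m0)^2 - (logh[k] + delta - m0)^2) / (2 * s0^2)
        ok <- log(stats::runif(1)) < dll + dlp
        if (ok) {
          logh[k] <- logh[k] + delta
          h[k] <- hn
          H0[idx] <- H0[idx] + dH
        }
        if (gam > 0) ls_h[k] <- ls_h[k] + gam * ((if (ok) 1 else 0) - target)
        if (post) { att["heights"] <- att["heights"] + 1; acc["heights"] <- acc["heights"] + ok }
      }
    }

    if (spatial && config$update_frailties) {
      base_i <- H0 * expxb
      T0 <- numeric(A)
      rs <- rowsum(base_i, area_idx)
      T0[as.integer(rownames(rs))] <- rs
      Ta <- T0 * exp(w)
      for (sweep in seq_len(config$frailty_sweeps)) {
        for (a in seq_len(A)) {
          delta <- stats::rnorm(1, 0, exp(ls_w[a]))
          nbv <- w[nb[[a]]]
          dll <- if (use_ll) Ad[a] * delta - Ta[a] * (exp(delta) - 1) else 0
          dlp <- if (length(nbv))
            (sum((w[a] - nbv)^2) - sum((w[a] + delta - nbv)^2)) / (2 * sigma2) else 0
          ok <- log(stats::runif(1)) < dll + dlp
          if (ok) {
            w[a] <- w[a] + delta
            Ta[a] <- Ta[a] * exp(delta)
          }
          if (gam > 0) ls_w[a] <- ls_w[a] + gam * ((if (ok) 1 else 0) - target)
          if (post) { att["frailties"] <- att["frailties"] + 1; acc["frailties"] <- acc["frailties"] + ok }
        }
        quad <- sum((w[e1] - w[e2])^2)
        sigma2 <- 1 / stats::rgamma(1, shape = a0 + rank_ / 2, rate = b0 + quad / 2)
      }
      ## recentre; absorb the level into the baseline (likelihood-invariant)
      cm <- mean(w)
      if (cm != 0) {
        w <- w - cm
        logh <- logh + cm
        h <- exp(logh)
        H0 <- H0 * exp(cm)
      }
      ew <- exp(w)[area_idx]
    } else if (spatial) {
      quad <- sum((w[e1] - w[e2])^2)
      sigma2 <- 1 / stats::rgamma(1, shape = a0 + rank_ / 2, rate = b0 + quad / 2)
    }

    if (post && (iter - burn) %% thin == 0L) {
      s_i <- s_i + 1L
      beta_draws[s_i, ] <- beta
      logh_draws[s_i, ] <- logh
      if (spatial) { w_draws[s_i, ] <- w; sigma2_draws[s_i] <- sigma2 }
      wv <- if (spatial) w[area_idx] else 0
      llmat[s_i, ] <- d * (logh[evint] + xb + wv) - H0 * expxb * ew
    }
  }

  rates <- ifelse(att > 0, acc / att, NA_real_)
  structure(list(
    draws = list(beta = beta_draws, log_heights = logh_draws,
                 frailties = w_draws, sigma2 = sigma2_draws),
    per_record_loglik = llmat,
    total_loglik = rowSums(llmat),
    acceptance_rates = rates,
    spatial = spatial,
    baseline_cuts = cuts,
    structure = structure_,
    priors = priors,
    config = config,
    model_data = list(records = records, design = design, graph = graph),
    n_retained = S
  ), class = "posterior_chains")
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat("posterior_chains: ", x$n_retained, " retained draws, ",
      ncol(x$draws$beta), " coefficients, ",
      if (x$spatial) paste0(ncol(x$draws$frailties), " areas (spatial)") else "no frailty",
      "\n", sep = "")
  cat("acceptance rates:",
      paste(names(x$acceptance_rates),
            sprintf("%.2f", x$acceptance_rates), collapse = ", "), "\n")
  invisible(x)
}

## flatten all scalar parameter series into one S x P matrix
parameter_matrix <- function(chains) {
  stopifnot(inherits(chains, "posterior_chains"))
  out <- cbind(
    `colnames<-`(chains$draws$beta, paste0("beta.", colnames(chains$draws$beta))),
    `colnames<-`(chains$draws$log_heights,
                 paste0("log_height.", seq_len(ncol(chains$draws$log_heights)))))
  if (chains$spatial) {
    out <- cbind(out,
                 `colnames<-`(chains$draws$frailties,
                              paste0("frailty.", colnames(chains$draws$frailties))),
                 sigma2 = chains$draws$sigma2)
  }
  out
}

#' Posterior summaries of parameters
#'
#' Mean, median, standard deviation and equal-tailed 95\% credible interval
#' (2.5\% / 97.5\% sample quantiles) over the retained draws.
#'
#' @param chains a \code{posterior_chains}.
#' @param parameter optional character vector of parameter names (e.g.
#'   \code{"beta.sex_female"}, \code{"sigma2"}, \code{"frailty.Nairobi"});
#'   default all.
#' @return data.frame with columns \code{parameter}, \code{mean},
#'   \code{median}, \code{sd}, \code{lower}, \code{upper}.
#' @export
posterior_summary <- function(chains, parameter = NULL) {
  M <- parameter_matrix(chains)
  if (!is.null(parameter)) {
    bad <- setdiff(parameter, colnames(M))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    M <- M[, parameter, drop = FALSE]
  }
  q <- apply(M, 2, stats::quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  data.frame(parameter = colnames(M),
             mean = colMeans(M),
             median = q[2, ],
             sd = apply(M, 2, stats::sd),
             lower = q[1, ],
             upper = q[3, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Convergence diagnostics for the retained chains
#'
#' Effective sample size and the Geweke z-score (first 10\% vs last 50\% of
#' the chain) for every scalar parameter series. Constant (degenerate)
#' series are flagged rather than throwing.
#'
#' @param chains a \code{posterior_chains} with at least 100 retained draws.
#' @return data.frame with columns \code{parameter}, \code{ess},
#'   \code{geweke_z}, \code{degenerate}; the underlying series matrix is
#'   attached as attribute \code{"series"} for trace plotting.
#' @export
trace_summaries <- function(chains) {
  M <- parameter_matrix(chains)
  if (nrow(M) < 100L) stop("need at least 100 retained draws for diagnostics")
  out <- data.frame(parameter = colnames(M), ess = NA_real_,
                    geweke_z = NA_real_, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(M))) {
    x <- M[, j]
    if (stats::sd(x) == 0) {
      out$degenerate[j] <- TRUE
      next
    }
    out$ess[j] <- as.numeric(coda::effectiveSize(coda::mcmc(x)))
    gz <- tryCatch(coda::geweke.diag(coda::mcmc(x), frac1 = 0.1, frac2 = 0.5)$z,
                   error = function(e) NA_real_)
    out$geweke_z[j] <- as.numeric(gz)
  }
  attr(out, "series") <- M
  out
}

#' Posterior-mean model state
#'
#' Plug-in state built from the posterior mean of every parameter block
#' (frailties recentred to sum to zero); used by DIC and the Cox-Snell
#' residuals. Baseline heights are averaged on the hazard scale - the
#' heights, not their logs, are the parameters, and the geometric mean
#' would systematically understate the cumulative hazard.
#'
#' @param chains a \code{posterior_chains}.
#' @return a \code{\link{model_state}}.
#' @export
posterior_mean_state <- function(chains) {
  stopifnot(inherits(chains, "posterior_chains"))
  beta <- colMeans(chains$draws$beta)
  logh <- log(colMeans(exp(chains$draws$log_heights)))
  bl <- piecewise_baseline(chains$baseline_cuts, logh)
  if (chains$spatial) {
    w <- colMeans(chains$draws$frailties)
    w <- w - mean(w)
    model_state(beta, bl, frailties = w,
                frailty_variance = mean(chains$draws$sigma2))
  } else {
    model_state(beta, bl)
  }
}
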