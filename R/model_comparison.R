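#' DIC from deviance draws
#'
#' Low-level Deviance Information Criterion:
#' \eqn{\bar{D}} = mean over draws of \eqn{-2\,\ell}, \eqn{D(\bar\theta)}
#' the deviance at the posterior-mean state, \eqn{p_D = \bar D - D(\bar\theta)},
#' \eqn{DIC = \bar D + p_D}. When the plug-in deviance is not finite the
#' variance-based penalty \eqn{p_V = \mathrm{var}(D)/2} is used with a
#' warning.
#'
#' @param total_loglik per-draw total log-likelihoods.
#' @param loglik_at_mean total log-likelihood at the posterior-mean state.
#' @return list with \code{dic}, \code{p_d}, \code{mean_deviance} and
#'   \code{penalty} (\code{"pD"} or \code{"pV"}).
#' @export
dic_from_draws <- function(total_loglik, loglik_at_mean) {
  D <- -2 * total_loglik
  Dbar <- mean(D)
  Dhat <- -2 * loglik_at_mean
  if (is.finite(Dhat)) {
    p_d <- Dbar - Dhat
    penalty <- "pD"
  } else {
    warning("non-finite deviance at the posterior mean; using pV = var(D)/2")
    p_d <- stats::var(D) / 2
    penalty <- "pV"
  }
  list(dic = Dbar + p_d, p_d = p_d, mean_deviance = Dbar, penalty = penalty)
}

#' Deviance Information Criterion of a fitted model
#'
#' Plug-in deviance evaluated at the posterior mean of every parameter block
#' (frailties recentred); lower DIC indicates better fit.
#'
#' @param chains a \code{posterior_chains}.
#' @return list as in \code{\link{dic_from_draws}}.
#' @export
compute_dic <- function(chains) {
  stopifnot(inherits(chains, "posterior_chains"))
  state <- posterior_mean_state(chains)
  md <- chains$model_data
  ll_hat <- log_likelihood(md$records, md$design, state)$total
  dic_from_draws(chains$total_loglik, ll_hat)
}

per_record_matrix <- function(x) {
  if (inherits(x, "posterior_chains")) x <- x$per_record_loglik
  if (!is.matrix(x)) stop("expected a posterior_chains or a draws-by-records matrix")
  x
}

#' Watanabe-Akaike information criterion
#'
#' \eqn{\mathrm{lppd} = \sum_i \log\left(\frac1S\sum_s e^{\ell_{si}}\right)},
#' penalty \eqn{p_{WAIC} = \sum_i \mathrm{var}_s(\ell_{si})} (pWAIC2),
#' \eqn{WAIC = -2(\mathrm{lppd} - p_{WAIC})}; lower is better. Computed with
#' log-sum-exp throughout.
#'
#' @param chains a \code{posterior_chains} or a draws-by-records
#'   log-likelihood matrix.
#' @return list with \code{waic}, \code{p_waic}, \code{lppd}.
#' @export
compute_waic <- function(chains) {
  L <- per_record_matrix(chains)
  S <- nrow(L)
  bad <- which(apply(L, 2, function(x) all(!is.finite(x))))
  if (length(bad))
    stop("record(s) with no finite log-likelihood contribution: ",
         paste(bad, collapse = ", "))
  lppd_i <- apply(L, 2, logsumexp) - log(S)
  p_i <- if (S > 1) apply(L, 2, stats::var) else rep(0, ncol(L))
  lppd <- sum(lppd_i)
  p_waic <- sum(p_i)
  list(waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd)
}

#' Log pseudo marginal likelihood and conditional predictive ordinates
#'
#' \eqn{CPO_i} is the harmonic mean of the per-draw likelihoods of record
#' \eqn{i}, computed stably as
#' \eqn{\log CPO_i = \log S - \mathrm{logsumexp}(-\ell_{si})};
#' \eqn{LPML = \sum_i \log CPO_i}. Higher is better.
#'
#' @inheritParams compute_waic
#' @return list with \code{lpml} and \code{log_cpo} (per record).
#' @export
compute_lpml <- function(chains) {
  L <- per_record_matrix(chains)
  S <- nrow(L)
  bad <- which(apply(L, 2, function(x) all(!is.finite(x))))
  if (length(bad))
    stop("record(s) with no finite log-likelihood contribution: ",
         paste(bad, collapse = ", "))
  log_cpo <- log(S) - apply(-L, 2, logsumexp)
  list(lpml = sum(log_cpo), log_cpo = log_cpo)
}

#' Model comparison report
#'
#' DIC (with \eqn{p_D}), WAIC (with \eqn{p_{WAIC}}) and LPML for one fitted
#' model, all computed from the same retained draws.
#'
#' @param chains a \code{posterior_chains}.
#' @return object of class \code{comparison_report}.
#' @export
comparison_report <- function(chains) {
  dic <- compute_dic(chains)
  waic <- compute_waic(chains)
  lpml <- compute_lpml(chains)
  structure(list(dic = dic$dic, p_d = dic$p_d, penalty = dic$penalty,
                 waic = waic$waic, p_waic = waic$p_waic,
                 lpml = lpml$lpml, per_record_cpo = exp(lpml$log_cpo)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("DIC %.1f (p_%s %.1f)  WAIC %.1f (p_waic %.1f)  LPML %.1f\n",
              x$dic, if (x$penalty == "pD") "D" else "V", x$p_d,
              x$waic, x$p_waic, x$lpml))
  invisible(x)
}

#' Two-model comparison table
#'
#' Renders the frailty vs no-frailty comparison as a data.frame with one row
#' per model and columns DIC, LPML, WAIC (lower DIC/WAIC and higher LPML
#' indicate the better model).
#'
#' @param no_frailty,spatial \code{posterior_chains} for the two models.
#' @return data.frame with columns \code{model}, \code{dic}, \code{lpml},
#'   \code{waic}.
#' @export
compare_models <- function(no_frailty, spatial) {
  r1 <- comparison_report(no_frailty)
  r2 <- comparison_report(spatial)
  data.frame(
    model = c("Cox Proportional Hazards (No Frailty)",
              "Proportional Hazard Spatial Frailty Model"),
    dic = c(r1$dic, r2$dic),
    lpml = c(r1$lpml, r2$lpml),
    waic = c(r1$waic, r2$waic),
    stringsAsFactors = FALSE
  )
}
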