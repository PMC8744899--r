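#' Cox-Snell residuals
#'
#' \eqn{r_i = H_0(t_i)\, e^{x_i'\beta + w_{a(i)}}} at a plug-in (normally
#' posterior-mean) state. Under a correctly specified model the residuals of
#' uncensored records behave like a unit-exponential sample; censored records
#' keep their censoring status and enter the residual hazard as censored
#' residual "times".
#'
#' @param records data.frame with \code{time}, \code{event}, \code{area}.
#' @param design the aligned \code{\link{build_design}} matrix.
#' @param state plug-in \code{\link{model_state}}, e.g. from
#'   \code{\link{posterior_mean_state}}.
#' @return object of class \code{residual_set}: data.frame with columns
#'   \code{residual} and \code{event}.
#' @export
cox_snell_residuals <- function(records, design, state) {
  check_records(records)
  eta <- linear_predictor(records, design, state)
  H0 <- cumulative_baseline(state$baseline, records$time)
  structure(data.frame(residual = H0 * exp(eta), event = records$event),
            class = c("residual_set", "data.frame"))
}

#' Goodness of fit from Cox-Snell residuals
#'
#' Nelson-Aalen estimate of the cumulative hazard of the residuals (treating
#' each residual as a survival time with the record's original censoring
#' status), and the least-squares slope through the origin of
#' \eqn{\hat H(r)} against \eqn{r}. A well-fitting model gives an
#' approximately straight curve with slope one.
#'
#' @param residuals a \code{\link{cox_snell_residuals}} result with at least
#'   20 records and 5 events.
#' @return list with \code{slope} and \code{curve}, a data.frame of
#'   \code{(r, cumhaz)} pairs at the distinct event residuals.
#' @export
residual_gof <- function(residuals) {
  stopifnot(inherits(residuals, "residual_set"))
  r <- residuals$residual
  d <- residuals$event
  if (length(r) < 20L) stop("need at least 20 records for the residual fit")
  if (sum(d) < 5L) stop("need at least 5 events for the residual fit")
  fit <- survival::survfit(survival::Surv(r, d) ~ 1, ctype = 1)
  curve <- data.frame(r = fit$time, cumhaz = fit$cumhaz)
  curve <- curve[fit$n.event > 0, , drop = FALSE]
  slope <- sum(curve$cumhaz * curve$r) / sum(curve$r^2)
  list(slope = slope, curve = curve)
}
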