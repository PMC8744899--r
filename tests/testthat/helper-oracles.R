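# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive every quantity with plain scalar loops.

# per-record piecewise-exponential log-likelihood, scalar arithmetic only
oracle_loglik <- function(records, design, state) {
  X <- unclass(design)
  cuts <- state$baseline$cut_points
  h <- exp(state$baseline$log_heights)
  lower <- c(0, cuts[-length(cuts)])
  out <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    t <- records$time[i]
    eta <- 0
    for (j in seq_len(ncol(X))) eta <- eta + X[i, j] * state$beta[[colnames(X)[j]]]
    if (!is.null(state$frailties))
      eta <- eta + state$frailties[[as.character(records$area[i])]]
    H <- 0
    k_t <- NA
    for (k in seq_along(cuts)) {
      H <- H + h[k] * max(0, min(t, cuts[k]) - lower[k])
      if (is.na(k_t) && t <= cuts[k]) k_t <- k
    }
    out[i] <- records$event[i] * (log(h[k_t]) + eta) - H * exp(eta)
  }
  out
}

# sum of squared differences over edges
oracle_quad_form <- function(w, graph) {
  s <- 0
  e <- graph$edges
  for (r in seq_len(nrow(e))) s <- s + (w[e[r, 1]] - w[e[r, 2]])^2
  s
}

# breadth-first-search connected components
oracle_components <- function(graph) {
  n <- graph$n_areas
  nb <- vector("list", n)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    nb[[e[r, 1]]] <- c(nb[[e[r, 1]]], e[r, 2])
    nb[[e[r, 2]]] <- c(nb[[e[r, 2]]], e[r, 1])
  }
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in nb[[v]]) if (comp[u] == 0L) { comp[u] <- cur; queue <- c(queue, u) }
    }
  }
  comp
}

# Anderson-Darling statistic for given CDF values (fully specified null)
oracle_ad_stat <- function(u) {
  u <- sort(pmin(pmax(u, 1e-12), 1 - 1e-12))
  n <- length(u)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

# small aligned record set + design for likelihood-level tests
toy_records <- function(n = 20, seed = 42, n_areas = 4) {
  set.seed(seed)
  cov <- sample_covariates(n)
  cov$area <- sample(sprintf("Z%d", seq_len(n_areas)), n, replace = TRUE)
  cov$time <- round(runif(n, 0.5, 59.5), 2)
  cov$event <- rbinom(n, 1, 0.5)
  cov
}

toy_graph <- function(n_areas = 4) {
  ids <- sprintf("Z%d", seq_len(n_areas))
  area_graph(ids, cbind(ids[-n_areas], ids[-1]))
}

random_state <- function(design, baseline, graph = NULL, seed = 9,
                         variance = 0.3) {
  set.seed(seed)
  beta <- stats::setNames(rnorm(ncol(design), 0, 0.4), colnames(design))
  fr <- NULL
  if (!is.null(graph)) {
    fr <- rnorm(graph$n_areas, 0, 0.4)
    fr <- fr - mean(fr)
    names(fr) <- graph$area_ids
  }
  model_state(beta, baseline, frailties = fr,
              frailty_variance = if (!is.null(fr)) variance)
}
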