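# Simulation studies shared between test files, memoised so each runs once
# per test session. Sizes are scaled-down study conditions (documented in the
# methods vignette): model-selection ordering on 20 areas x ~1500 children,
# recovery on the default 47-area configuration.

.study_cache <- new.env(parent = emptyenv())

# 20 replicate pairs (spatial vs no-frailty fits) on data generated WITH
# ICAR frailty variance 0.2, plus 20 replicates on frailty-free data.
ordering_study <- function() {
  if (!is.null(.study_cache$ordering)) return(.study_cache$ordering)
  fit_pair <- function(frailty_variance, data_seed, chain_seed) {
    ds <- generate_dataset(sim_config(n_areas = 20L, children_per_area = 75,
                                      frailty_variance = frailty_variance,
                                      seed = data_seed))
    design <- build_design(ds$records)
    cfg <- mcmc_config(n_iterations = 6000, burn_in = 2000, thinning = 4,
                       seed = chain_seed)
    sp <- sample_posterior(ds$records, design, ds$graph, config = cfg)
    nf <- sample_posterior(ds$records, design, NULL, config = cfg)
    csp <- comparison_report(sp)
    cnf <- comparison_report(nf)
    s2 <- stats::quantile(sp$draws$sigma2, c(0.025, 0.975))
    data.frame(dic_sp = csp$dic, dic_nf = cnf$dic,
               waic_sp = csp$waic, waic_nf = cnf$waic,
               lpml_sp = csp$lpml, lpml_nf = cnf$lpml,
               s2_lo = s2[[1]], s2_hi = s2[[2]])
  }
  with_frailty <- do.call(rbind, lapply(1:20, function(i)
    fit_pair(0.2, 1000 + i, 2000 + i)))
  without_frailty <- do.call(rbind, lapply(1:20, function(i)
    fit_pair(0, 3000 + i, 4000 + i)))
  .study_cache$ordering <- list(with_frailty = with_frailty,
                                without_frailty = without_frailty)
  .study_cache$ordering
}

# 5-seed parameter-recovery study at the default 47-county scale
recovery_study <- function() {
  if (!is.null(.study_cache$recovery)) return(.study_cache$recovery)
  res <- lapply(c(101, 202, 303, 404, 505), function(seed) {
    ds <- generate_dataset(sim_config(seed = seed))
    design <- build_design(ds$records)
    cfg <- mcmc_config(n_iterations = 15000, burn_in = 2000, thinning = 10,
                       seed = seed + 1)
    ch <- sample_posterior(ds$records, design, ds$graph, config = cfg)
    su <- posterior_summary(ch)
    b <- su[grepl("^beta\\.", su$parameter), ]
    truth <- ds$truth$beta[sub("beta.", "", b$parameter, fixed = TRUE)]
    fr <- su[grepl("^frailty\\.", su$parameter), ]
    truth_w <- ds$true_frailties[sub("frailty.", "", fr$parameter, fixed = TRUE)]
    list(coverage = sum(truth >= b$lower & truth <= b$upper),
         n_effects = nrow(b),
         frailty_r = stats::cor(fr$median, truth_w),
         sigma2_mean = mean(ch$draws$sigma2))
  })
  .study_cache$recovery <- res
  res
}
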