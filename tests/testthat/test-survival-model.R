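test_that("cumulative baseline hazard integrates the step hazard", {
  b1 <- piecewise_baseline(60, log(0.01))
  expect_equal(cumulative_baseline(b1, 10), 0.1)
  expect_equal(cumulative_baseline(b1, 0), 0)

  b2 <- piecewise_baseline(c(12, 60), log(c(0.01, 0.002)))
  expect_equal(cumulative_baseline(b2, 24), 0.01 * 12 + 0.002 * 12)
  ## rectangle-rule numeric integration oracle
  grid <- seq(0, 24, by = 1e-3)
  hstep <- ifelse(grid <= 12, 0.01, 0.002)
  expect_equal(cumulative_baseline(b2, 24), sum(hstep[-1] * diff(grid)),
               tolerance = 1e-5)

  tt <- sort(runif(50, 0, 60))
  expect_true(all(diff(cumulative_baseline(b2, tt)) >= 0))
  expect_error(cumulative_baseline(b2, 61), "beyond")
  expect_error(piecewise_baseline(c(12, 12), c(0, 0)), "strictly increasing")
})

test_that("log-likelihood matches closed forms and the brute-force oracle", {
  ## one record, t = 5, event, beta = 0, single interval h = 0.01
  rec1 <- data.frame(time = 5, event = 1, area = "A", sex = "male")
  spec1 <- u5cm_variables()["sex"]
  d1 <- build_design(rec1, spec1, center = FALSE)
  st1 <- model_state(c(sex_female = 0), piecewise_baseline(60, log(0.01)))
  expect_equal(log_likelihood(rec1, d1, st1)$total, log(0.01) - 0.05)

  ## all censored, beta = 0: total = -sum(H0)
  recs <- toy_records(15, seed = 3)
  recs$event <- 0
  des <- build_design(recs, center = FALSE)
  bl <- piecewise_baseline(c(12, 60), log(c(0.004, 0.001)))
  st0 <- model_state(setNames(rep(0, ncol(des)), colnames(des)), bl)
  expect_equal(log_likelihood(recs, des, st0)$total,
               -sum(cumulative_baseline(bl, recs$time)))

  ## 20 random records, random state with frailties, vs scalar oracle
  g <- toy_graph(4)
  recs <- toy_records(20, seed = 11)
  des <- build_design(recs, center = FALSE)
  st <- random_state(des, bl, graph = g)
  got <- log_likelihood(recs, des, st)
  want <- oracle_loglik(recs, des, st)
  expect_equal(got$per_record, want, tolerance = 1e-10)
  expect_equal(got$total, sum(got$per_record))
})

test_that("hazards scale proportionally in the coefficients", {
  recs <- toy_records(30, seed = 5)
  recs$event <- 0   # isolate the cumulative-hazard term
  des <- build_design(recs, center = FALSE)
  bl <- piecewise_baseline(60, log(0.01))
  st <- random_state(des, bl)
  st2 <- st
  st2$beta["sex_female"] <- st2$beta["sex_female"] + log(2)
  l1 <- -log_likelihood(recs, des, st)$per_record
  l2 <- -log_likelihood(recs, des, st2)$per_record
  is_f <- des[, "sex_female"] == 1
  expect_equal(l2[is_f], 2 * l1[is_f])
  expect_equal(l2[!is_f], l1[!is_f])
})

test_that("single-interval no-frailty model is exponential regression", {
  set.seed(21)
  n <- 400
  rate <- 0.05
  recs <- toy_records(n, seed = 21)
  recs$time <- rexp(n, rate)
  recs$event <- 1
  des <- build_design(recs, center = FALSE)
  bl0 <- piecewise_baseline(max(recs$time) + 1, log(0.01))
  nll <- function(lh) {
    st <- model_state(setNames(rep(0, ncol(des)), colnames(des)),
                      piecewise_baseline(max(recs$time) + 1, lh))
    -log_likelihood(recs, des, st)$total
  }
  opt <- optimize(nll, c(-10, 2))
  expect_equal(exp(opt$minimum), rate, tolerance = 2 / sqrt(n))
})

test_that("the design matrix encodes reference-level contrasts", {
  recs <- data.frame(
    sex = c("female", "male"), residence = c("urban", "urban"),
    head_sex = c("male", "male"), wealth = c("poorest", "poorest"),
    education = c("none", "none"), age_first_birth = c(19, 19),
    maternal_age = c(26, 26), twin = c("single", "single"))
  X <- build_design(recs, center = FALSE)
  expect_equal(X[1, "sex_female"], 1, ignore_attr = TRUE)
  ## child at all reference levels: every dummy column is zero
  dummy_cols <- setdiff(colnames(X), c("age_first_birth", "maternal_age"))
  expect_equal(unname(unclass(X)[2, dummy_cols]), rep(0, length(dummy_cols)))
  ## 4-level education gives 3 columns
  expect_equal(grep("^edu_", colnames(X), value = TRUE),
               c("edu_primary", "edu_secondary", "edu_higher"))
  expect_equal(ncol(X), 14L)

  recs$education[1] <- "postdoc"
  expect_error(build_design(recs), "unseen level")

  recs$education[1] <- NA
  expect_message(X2 <- build_design(recs), "dropping 1 record")
  expect_equal(attr(X2, "kept"), 2L)

  Xc <- build_design(toy_records(50), center = TRUE)
  expect_equal(mean(Xc[, "age_first_birth"]), 0)
  expect_equal(attr(Xc, "centers")[["maternal_age"]],
               mean(toy_records(50)$maternal_age))
})

test_that("the joint log prior is the sum of its component densities", {
  g <- toy_graph(5)
  s <- build_icar_structure(g)
  bl <- piecewise_baseline(c(12, 60), c(-5, -6))
  pr <- prior_config(beta_sd = 10, baseline_log_mean = -5.5)

  ## beta = 0, matching baseline centre contributions
  p <- 3
  st0 <- model_state(setNames(rep(0, p), c("a", "b", "c")), bl)
  expect_equal(log_prior(st0, priors = pr),
               p * (-0.5 * log(2 * pi * 100)) +
                 sum(dnorm(c(-5, -6), -5.5, 2, log = TRUE)))

  ## constant frailties: ICAR contributes only its normalising part
  stc <- suppressWarnings(model_state(setNames(rep(0, p), c("a", "b", "c")), bl,
                                      frailties = rep(1, 5),
                                      frailty_variance = 0.3))
  lp_c <- log_prior(stc, s, pr)
  expect_equal(lp_c - log_prior(st0, priors = pr),
               -(s$rank / 2) * log(2 * pi * 0.3) +
                 dgamma(1 / 0.3, 0.5, rate = 0.01, log = TRUE) - 2 * log(0.3))

  ## arbitrary state vs component-wise oracle
  set.seed(4)
  w <- rnorm(5); w <- w - mean(w); names(w) <- g$area_ids
  st <- model_state(setNames(rnorm(p), c("a", "b", "c")), bl,
                    frailties = w, frailty_variance = 0.7)
  oracle <- sum(dnorm(st$beta, 0, 10, log = TRUE)) +
    sum(dnorm(c(-5, -6), -5.5, 2, log = TRUE)) +
    icar_log_density(w, 0.7, s) +
    dgamma(1 / 0.7, 0.5, rate = 0.01, log = TRUE) - 2 * log(0.7)
  expect_equal(log_prior(st, s, pr), oracle, tolerance = 1e-12)

  expect_error(prior_config(beta_sd = -1), "positive")
  expect_error(log_prior(st0, priors = prior_config()), "baseline_log_mean")
})
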