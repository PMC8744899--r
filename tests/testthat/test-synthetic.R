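test_that("constrained ICAR draws have the eigenstructure-implied law", {
  g2 <- area_graph(c("A", "B"), rbind(c("A", "B")))
  s2 <- build_icar_structure(g2)
  set.seed(31)
  draws <- t(replicate(10000, sample_icar_frailties(s2, 0.6)))
  ## two areas, one edge: w1 = -w2 and Var(w1) = variance / 4
  expect_true(all(abs(rowSums(draws)) < 1e-10))
  expect_equal(unname(draws[, 1]), unname(-draws[, 2]))
  expect_equal(var(draws[, 1]), 0.6 / 4, tolerance = 0.05)

  ## 5-area path: E[w'Qw] = variance * rank
  g5 <- toy_graph(5)
  s5 <- build_icar_structure(g5)
  set.seed(32)
  quads <- replicate(10000, oracle_quad_form(sample_icar_frailties(s5, 0.3), g5))
  expect_equal(mean(quads), 0.3 * s5$rank, tolerance = 0.05)

  ## variance -> 0 limit
  tiny <- sample_icar_frailties(s5, 1e-12, seed = 1)
  expect_lt(max(abs(tiny)), 1e-4)
  expect_error(sample_icar_frailties(s5, 0), "positive")
})

test_that("covariate marginals follow the stylised emulation", {
  cov <- sample_covariates(10000, seed = 5)
  expect_gt(mean(cov$sex == "female"), 0.48)
  expect_lt(mean(cov$sex == "female"), 0.52)
  expect_equal(mean(cov$residence == "rural"), 0.65, tolerance = 0.03)
  ## all levels appear at n >= 1000
  cov1k <- sample_covariates(1000, seed = 6)
  expect_setequal(unique(cov1k$wealth),
                  c("poorest", "poorer", "middle", "richer", "richest"))
  expect_setequal(unique(cov1k$education),
                  c("none", "primary", "secondary", "higher"))
  expect_setequal(unique(cov1k$twin),
                  c("single", "first_multiple", "second_multiple"))
  ## truncation bounds hold
  expect_true(all(cov$age_first_birth >= 12 & cov$age_first_birth <= 40))
  expect_true(all(cov$maternal_age >= 12 & cov$maternal_age <= 49))
  expect_error(sample_covariates(0), ">= 1")
})

test_that("survival times are exponential when the hazard is flat", {
  h <- 0.02
  n <- 5000
  set.seed(41)
  cov <- sample_covariates(n)
  cov$area <- "A1"
  beta0 <- setNames(rep(0, 14), names(u5cm_reference_effects()))
  truth <- model_state(beta0, piecewise_baseline(2000, log(h)))
  recs <- simulate_survival(cov, c(A1 = 0), truth, censoring = "none",
                            seed = 42)
  expect_gt(mean(recs$event), 0.999)   # horizon >> 1/h
  ks <- ks.test(recs$time, pexp, rate = h)
  expect_gt(ks$p.value, 0.01)

  ## multiplier -> infinity: immediate certain events
  fast <- simulate_survival(cov[1:100, ], c(A1 = 30), truth,
                            censoring = "none", seed = 43)
  expect_true(all(fast$event == 1))
  expect_lt(max(fast$time), 0.01)
})

test_that("default datasets emulate under-five mortality structure", {
  for (seed in c(11, 22, 33)) {
    ds <- generate_dataset(sim_config(seed = seed))
    prop <- mean(ds$records$event)
    expect_gt(prop, 0.03)
    expect_lt(prop, 0.12)
    expect_true(all(ds$records$time > 0 & ds$records$time <= 60))
    expect_true(all(ds$records$area %in% ds$graph$area_ids))
    expect_lt(abs(sum(ds$true_frailties)), 1e-8)
  }
  ## deterministic given the seed
  d1 <- generate_dataset(sim_config(seed = 11))
  d2 <- generate_dataset(sim_config(seed = 11))
  expect_identical(d1$records, d2$records)
  expect_identical(d1$true_frailties, d2$true_frailties)

  ## minimal two-area run is valid
  tiny <- generate_dataset(sim_config(n_areas = 2L, children_per_area = 10,
                                      seed = 4))
  expect_equal(tiny$graph$n_areas, 2L)
  expect_true(nrow(tiny$records) >= 2)
})

test_that("datasets round-trip through the plain-text writers", {
  ds <- generate_dataset(sim_config(n_areas = 6L, children_per_area = 25,
                                    seed = 8))
  dir <- file.path(tempdir(), "icarsurv-roundtrip")
  write_dataset(ds, dir)
  rec2 <- read_records(file.path(dir, "records.csv"))
  expect_equal(rec2$time, ds$records$time, tolerance = 1e-12)
  expect_identical(rec2$event, ds$records$event)
  expect_identical(rec2$area, ds$records$area)
  expect_identical(rec2$education, ds$records$education)

  g2 <- read_adjacency(file.path(dir, "adjacency.txt"))
  expect_equal(sort(g2$area_ids), sort(ds$graph$area_ids))
  expect_equal(nrow(g2$edges), nrow(ds$graph$edges))

  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$frailty_variance, 0.2)
  expect_equal(unlist(truth$beta), ds$truth$beta, tolerance = 1e-12)
})

test_that("lattice graphs are connected for assorted sizes", {
  for (n in c(2L, 5L, 12L, 20L, 30L)) {
    g <- lattice_graph(n)
    expect_equal(g$n_areas, n)
    expect_equal(max(oracle_components(g)), 1L)
  }
})
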