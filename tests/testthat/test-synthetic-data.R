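test_that("config validation rejects malformed specifications", {
  bad_cov <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3, 3)  # indefinite
  expect_error(intercept_only_config(5, sigma_c = bad_cov),
               "positive semidefinite")
  expect_error(intercept_only_config(0), "positive")
  expect_error(simulation_config(2, 2, 2,
                                 beta = list(c(0, 1), c(0, 1), c(0, 1))),
               "does not match")
  expect_error(
    simulation_config(2, 2, 2, beta = list(c(0, 1), c(0, 1), c(0, 1)),
                      covariates = list(list(name = "g", type = "categorical",
                                             level = "household",
                                             levels = c("a", "b"),
                                             probs = c(0.6, 0.5)))),
    "sum to 1")
  expect_error(intercept_only_config(5, missing_rate = 1), "missing_rate")
})

test_that("zero-variance intercept-only prevalences match expit closed form", {
  # expit(0) = 0.5
  cfg <- intercept_only_config(10, households = 10, persons = 10, seed = 11)
  y <- as.matrix(simulate_survey(cfg)$dataset$df[, c("y1", "y2", "y3")])
  se <- sqrt(0.25 / 1000)
  for (q in 1:3) expect_lt(abs(mean(y[, q]) - 0.5), 3 * se)

  # intercept at logit(0.134): the HIV-prevalence magnitude
  cfg2 <- intercept_only_config(100, households = 10, persons = 10,
                                intercepts = c(qlogis(0.134), 0, 0),
                                seed = 12)
  y1 <- simulate_survey(cfg2)$dataset$df$y1
  expect_lt(abs(mean(y1) - 0.134), 3 * sqrt(0.134 * 0.866 / 1e4))
})

test_that("simulation is deterministic given the seed", {
  cfg <- default_emulation_config(seed = 99)
  a <- simulate_survey(cfg)
  b <- simulate_survey(cfg)
  expect_identical(a$dataset$df, b$dataset$df)
  expect_identical(a$effects, b$effects)
  c <- simulate_survey(default_emulation_config(seed = 100))
  expect_false(identical(a$dataset$df, c$dataset$df))
})

test_that("cluster random-effect draws have the configured covariance", {
  sigma_c <- dense_cov(c(0.394, 0.696, 0.851), 0.5)
  cfg <- intercept_only_config(2000, households = 1, persons = 1,
                               sigma_c = sigma_c, seed = 5)
  u <- simulate_survey(cfg)$effects$u_c
  emp <- cov(u)
  for (i in 1:3) for (j in 1:3) {
    # MC standard error of a covariance entry
    se <- sqrt((sigma_c[i, i] * sigma_c[j, j] + sigma_c[i, j]^2) / 2000)
    expect_lt(abs(emp[i, j] - sigma_c[i, j]), 4 * se)
  }
})

test_that("within-cluster outcome correlation grows with cluster variance", {
  within_corr <- function(vc, seed = 7) {
    cfg <- intercept_only_config(150, households = 4, persons = 2,
                                 sigma_c = diag(c(vc, 0, 0) + 1e-12),
                                 seed = seed)
    df <- simulate_survey(cfg)$dataset$df
    # correlation between two members of the same cluster, outcome 1
    first <- !duplicated(df$cluster_id)
    a <- df$y1[first][match(df$cluster_id[!first], df$cluster_id[first])]
    cor(a, df$y1[!first])
  }
  rhos <- vapply(c(0.1, 1, 4), within_corr, numeric(1))
  expect_true(all(diff(rhos) > 0))
})

test_that("missingness hits the configured rate and blanks whole triples", {
  cfg <- intercept_only_config(60, households = 5, persons = 3,
                               missing_rate = 0.1, seed = 3)
  df <- simulate_survey(cfg)$dataset$df
  n <- nrow(df)
  miss <- is.na(df$y1)
  expect_identical(miss, is.na(df$y2))
  expect_identical(miss, is.na(df$y3))
  expect_lt(abs(mean(miss) - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("latent ICC of a config follows the 3.29 convention", {
  mk <- function(vc, vh) intercept_only_config(
    2, households = 2, persons = 2,
    sigma_c = diag(c(vc, 0, 0)), sigma_h = diag(c(vh, 0, 0)))
  z <- latent_icc_of_config(mk(0, 0), 1)
  expect_equal(z$icc_cluster, 0)
  expect_equal(z$icc_household_cumulative, 0)
  # variance components at the blood-test magnitudes
  ic <- latent_icc_of_config(mk(0.394, 0.385), 1)
  expect_equal(ic$icc_cluster, 0.394 / (0.394 + 0.385 + 3.29),
               tolerance = 1e-12)
  expect_equal(round(ic$icc_cluster, 4), 0.0968)
  # variance equal to the level-1 constant gives ICC 1/2
  expect_equal(latent_icc_of_config(mk(3.29, 0), 1)$icc_cluster, 0.5)
  expect_error(latent_icc_of_config(mk(1, 1), 4), "outcome")
})

test_that("covariates are generated at their declared level", {
  cfg <- simulation_config(
    n_clusters = 8, households_per_cluster = 4, individuals_per_household = 3,
    beta = list(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)),
    covariates = list(
      list(name = "hh_x", type = "binary", level = "household",
           prevalence = 0.5),
      list(name = "cl_x", type = "continuous", level = "cluster",
           mean = 0, sd = 1)),
    seed = 2)
  df <- simulate_survey(cfg)$dataset$df
  # constant within household / cluster
  expect_true(all(tapply(df$hh_x, df$household_id,
                         function(v) length(unique(v))) == 1))
  expect_true(all(tapply(df$cl_x, df$cluster_id,
                         function(v) length(unique(v))) == 1))
})

test_that("emulation preset reproduces the survey's marginal prevalences", {
  # average over seeds: the cluster-level random intercepts inflate the
  # sampling noise of a single survey's prevalence (design effect), and
  # the intercept calibration itself is a latent-normal approximation
  target <- c(0.134, 0.772, 0.549)
  prev <- sapply(1:6, function(s) {
    cfg <- .emulation_config_at_scale(seed = 20 + s)
    y <- simulate_survey(cfg)$dataset$df[, c("y1", "y2", "y3")]
    colMeans(as.matrix(y), na.rm = TRUE)
  })
  expect_true(all(abs(rowMeans(prev) - target) < 0.025))
})
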