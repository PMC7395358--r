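test_that("intercept-only fit recovers the truth when variances are zero", {
  cfg <- intercept_only_config(50, households = 10, persons = 10,
                               intercepts = c(-1, 0, 0), seed = 41)
  ds <- simulate_survey(cfg)$dataset
  f <- fit_separate(ds, 1, quad_nodes = 3)
  expect_true(f$converged)
  expect_lt(abs(f$beta[["(Intercept)"]] - (-1)), 3 * f$se_beta[["(Intercept)"]])
  expect_lt(f$var_cluster, 0.05)
  expect_lt(f$var_household, 0.05)
})

test_that("variance components at survey magnitudes are recovered", {
  cfg <- simulation_config(
    n_clusters = 300, households_per_cluster = 10,
    individuals_per_household = 3,
    beta = list(-1.9, 1.2, 0.2),
    sigma_c = diag(c(0.394, 0.696, 0.851)),
    sigma_h = diag(c(0.385, 0.039, 0.067)),
    seed = 43)
  ds <- simulate_survey(cfg)$dataset
  f <- fit_separate(ds, 1, quad_nodes = 5)
  expect_true(f$converged)
  expect_true(f$se_available)
  expect_lt(abs(f$var_cluster - 0.394), 3 * f$se_var_cluster)
  expect_lt(abs(f$var_household - 0.385), 3 * f$se_var_household)
  expect_lt(abs(f$beta[["(Intercept)"]] - (-1.9)),
            3 * f$se_beta[["(Intercept)"]])
})

test_that("a constant outcome raises a separation error", {
  df <- data.frame(cluster_id = rep(c("C1", "C2"), each = 4),
                   household_id = rep(c("H1", "H2", "H3", "H4"), each = 2),
                   person_id = paste0("p", 1:8),
                   y1 = 1L, y2 = rep(c(0L, 1L), 4), y3 = rep(c(1L, 0L), 4))
  ds <- survey_dataset(df)
  expect_error(fit_separate(ds, 1), "separation")
  expect_error(fit_separate(survey_dataset(df[1:2, ]), 2),
               "at least 2 clusters")
})

test_that("fitted likelihood dominates the generating parameters", {
  for (seed in c(51, 52, 53)) {
    cfg <- simulation_config(
      30, 5, 3, beta = list(-0.5, 0.5, 0),
      sigma_c = diag(c(0.5, 0.5, 0.5)), sigma_h = diag(c(0.3, 0.3, 0.3)),
      seed = seed)
    ds <- simulate_survey(cfg)$dataset
    f <- fit_separate(ds, 1, quad_nodes = 3, se = FALSE)
    ll_truth <- loglik_separate(-0.5, 0.5, 0.3, ds, 1, quad_nodes = 3)
    expect_gte(f$loglik, ll_truth - 1e-6)
  }
})

test_that("latent-scale ICC arithmetic follows the stated convention", {
  z <- compute_icc(0, 0)
  expect_equal(z$icc_cluster, 0)
  expect_equal(z$icc_household_cumulative, 0)
  expect_equal(z$level1_variance, 3.29)

  ic <- compute_icc(0.394, 0.385)
  expect_equal(round(ic$icc_cluster, 4), 0.0968)
  expect_equal(round(ic$icc_household_cumulative, 4), 0.1914)
  expect_equal(ic$icc_household_cumulative, (0.394 + 0.385) / 4.069,
               tolerance = 1e-12)
  expect_equal(round(compute_icc(0.696, 0.039)$icc_cluster, 4), 0.1729)

  # monotone in the cluster variance
  vals <- vapply(c(0.1, 0.5, 1, 2), function(v)
    compute_icc(v, 0.4)$icc_cluster, numeric(1))
  expect_true(all(diff(vals) > 0))
  # ordering invariant and the exact-constant option
  expect_lte(ic$icc_cluster, ic$icc_household_cumulative)
  expect_equal(compute_icc(3.29, 0)$icc_cluster, 0.5)
  expect_lt(abs(compute_icc(pi^2 / 3, 0, level1 = pi^2 / 3)$icc_cluster - 0.5),
            1e-12)
  expect_error(compute_icc(-1, 0), "nonnegative")
  expect_error(compute_icc(1, 1, level1 = 0), "positive")
})

test_that("wald_table computes two-sided normal p-values", {
  fake <- structure(list(
    outcome = 1,
    beta = c(`(Intercept)` = 0, x = 1.959964),
    se_beta = c(`(Intercept)` = 1, x = 1),
    var_cluster = 0.4, var_household = 0.2,
    se_var_cluster = 0.2, se_var_household = 0.1,
    se_available = TRUE), class = "separate_fit")
  wt <- wald_table(fake)
  expect_equal(wt$p[wt$term == "(Intercept)"], 1)
  expect_equal(wt$p[wt$term == "x"], 0.05, tolerance = 1e-6)
  # variance rows are one-sided
  expect_equal(wt$p[wt$term == "var(cluster)"],
               pnorm(2, lower.tail = FALSE))
})

test_that("Wald p-values for a null coefficient are uniform over seeds", {
  # a covariate with zero true effect; small three-level designs
  pvals <- vapply(1:120, function(s) {
    cfg <- simulation_config(
      20, 3, 2, beta = list(c(0, 0), c(0, 0), c(0, 0)),
      sigma_c = diag(c(0.3, 0.3, 0.3)), sigma_h = diag(c(0.2, 0.2, 0.2)),
      covariates = list(list(name = "x", type = "continuous",
                             level = "individual", mean = 0, sd = 1)),
      seed = 1000 + s)
    ds <- simulate_survey(cfg)$dataset
    f <- fit_separate(ds, 1, quad_nodes = 1)
    wt <- wald_table(f)
    wt$p[wt$term == "x"]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
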