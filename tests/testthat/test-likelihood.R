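test_that("degenerate variances reduce to the plain logistic likelihood", {
  ds <- tiny_dataset(seed = 3)
  X <- ds$X
  y <- ds$df$y1
  beta <- 0.4
  eta <- drop(X %*% beta)
  plain <- sum(y * eta - log1p(exp(eta)))
  expect_equal(loglik_separate(beta, 0, 0, ds, 1, quad_nodes = 7), plain,
               tolerance = 1e-10)
  # beta = 0 gives p = 1/2 everywhere
  expect_equal(loglik_separate(0, 0, 0, ds, 1), -nrow(ds$df) * log(2),
               tolerance = 1e-10)
  # joint with all variances zero = sum of three logistic log-likelihoods
  b <- list(0.4, -0.2, 0.1)
  plain3 <- sum(vapply(1:3, function(q) {
    e <- drop(X %*% b[[q]])
    sum(ds$df[[paste0("y", q)]] * e - log1p(exp(e)))
  }, numeric(1)))
  expect_equal(loglik_joint(b, diag(0, 3), diag(0, 3), ds, quad_nodes = 3),
               plain3, tolerance = 1e-10)
})

test_that("quadrature agrees with the Monte-Carlo oracle on tiny data", {
  ds <- tiny_dataset(seed = 8)
  ll <- loglik_separate(0.5, 0.4, 0.4, ds, 1, quad_nodes = 9)
  mc <- mc_loglik_oracle(0.5, 0.4, 0.4, ds, n_draws = 2e5, seed = 4,
                         outcome = 1)
  expect_lt(abs(ll - mc$estimate), 3 * mc$mc_se)

  b <- list(0.2, -0.3, 0.4)
  Sc <- dense_cov(c(0.4, 0.6, 0.8), 0.5)
  Sh <- dense_cov(c(0.3, 0.2, 0.5), 0.5)
  llj <- loglik_joint(b, Sc, Sh, ds, quad_nodes = 7)
  mcj <- mc_loglik_oracle(b, Sc, Sh, ds, n_draws = 2e5, seed = 4)
  expect_lt(abs(llj - mcj$estimate), 3 * mcj$mc_se)
})

test_that("the joint likelihood factorises exactly for diagonal covariance", {
  ds <- tiny_dataset(seed = 10)
  b <- list(0.2, -0.3, 0.4)
  Sc <- diag(c(0.4, 0.6, 0.8))
  Sh <- diag(c(0.3, 0.2, 0.5))
  for (k in c(1, 3, 5)) {
    lj <- loglik_joint(b, Sc, Sh, ds, quad_nodes = k)
    ls <- sum(vapply(1:3, function(q)
      loglik_separate(b[[q]], Sc[q, q], Sh[q, q], ds, q, quad_nodes = k),
      numeric(1)))
    expect_lt(abs(lj - ls), 1e-8)
  }
})

test_that("log-likelihood is invariant to cluster and household relabeling", {
  cfg <- simulation_config(6, 4, 3, beta = list(0.2, -0.1, 0.3),
                           sigma_c = dense_cov(c(0.5, 0.5, 0.5), 0.4),
                           sigma_h = dense_cov(c(0.3, 0.3, 0.3), 0.4),
                           seed = 17)
  ds <- simulate_survey(cfg)$dataset
  b <- list(0.2, -0.1, 0.3)
  ll <- loglik_joint(b, cfg$sigma_c, cfg$sigma_h, ds, quad_nodes = 3)

  # shuffle record order and relabel ids; the marginal likelihood is a
  # product over clusters, so nothing should change
  df <- ds$df
  set.seed(2)
  df <- df[sample(nrow(df)), ]
  df$cluster_id <- paste0("relabel-", df$cluster_id)
  df$household_id <- paste0("relabel-", df$household_id)
  ds2 <- survey_dataset(df)
  expect_equal(loglik_joint(b, cfg$sigma_c, cfg$sigma_h, ds2,
                            quad_nodes = 3), ll, tolerance = 1e-10)
})

test_that("node ladder converges: deltas shrink as quadrature refines", {
  ds <- tiny_dataset(seed = 12)
  lls <- vapply(c(3, 5, 9), function(k)
    loglik_separate(0.5, 0.6, 0.5, ds, 1, quad_nodes = k), numeric(1))
  expect_lt(abs(lls[3] - lls[2]), abs(lls[2] - lls[1]))

  b <- list(0.2, -0.3, 0.4)
  Sc <- dense_cov(c(0.4, 0.6, 0.8), 0.5)
  Sh <- dense_cov(c(0.3, 0.2, 0.5), 0.5)
  llj <- vapply(c(3, 5, 7), function(k)
    loglik_joint(b, Sc, Sh, ds, quad_nodes = k), numeric(1))
  expect_lt(abs(llj[3] - llj[2]), abs(llj[2] - llj[1]))
})

test_that("the MC oracle is exact at zero variance and scales as 1/sqrt(n)", {
  ds <- tiny_dataset(seed = 5)
  X <- ds$X
  y <- ds$df$y2
  eta <- drop(X %*% -0.3)
  plain <- sum(y * eta - log1p(exp(eta)))
  mc <- mc_loglik_oracle(-0.3, 0, 0, ds, n_draws = 1000, seed = 1,
                         outcome = 2)
  expect_equal(mc$estimate, plain, tolerance = 1e-10)
  expect_equal(mc$mc_se, 0)

  se1 <- mc_loglik_oracle(0.3, 0.5, 0.4, ds, n_draws = 4e4, seed = 2,
                          outcome = 1)$mc_se
  se2 <- mc_loglik_oracle(0.3, 0.5, 0.4, ds, n_draws = 8e4, seed = 3,
                          outcome = 1)$mc_se
  expect_lt(abs(se2 / se1 - 1 / sqrt(2)), 0.2 / sqrt(2))
})
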