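# small reusable generative setups for the test suite

intercept_only_config <- function(n_clusters, households = 6, persons = 3,
                                  intercepts = c(0, 0, 0),
                                  sigma_c = diag(0, 3), sigma_h = diag(0, 3),
                                  missing_rate = 0, seed = 1) {
  simulation_config(
    n_clusters = n_clusters,
    households_per_cluster = households,
    individuals_per_household = persons,
    beta = list(intercepts[1], intercepts[2], intercepts[3]),
    sigma_c = sigma_c, sigma_h = sigma_h,
    missing_rate = missing_rate, seed = seed)
}

# dense covariance with common correlation rho and given diagonal
dense_cov <- function(diag_var, rho) {
  sd <- sqrt(diag_var)
  outer(sd, sd) * (rho + (1 - rho) * diag(length(sd)))
}

# tiny two-cluster dataset used by the oracle-agreement checks
tiny_dataset <- function(seed = 1, sigma_c = dense_cov(c(0.4, 0.6, 0.8), 0.5),
                         sigma_h = dense_cov(c(0.3, 0.2, 0.5), 0.5),
                         beta = list(0.2, -0.3, 0.4)) {
  cfg <- simulation_config(
    n_clusters = 2, households_per_cluster = 2,
    individuals_per_household = 2,
    beta = beta, sigma_c = sigma_c, sigma_h = sigma_h, seed = seed)
  simulate_survey(cfg)$dataset
}

# printed pattern counts used throughout the descriptive checks
survey_pattern_counts <- c("000" = 1910, "010" = 1814, "011" = 4341,
                           "100" = 210, "110" = 267, "111" = 769)

table3_variances <- list(
  blood_test = c(cluster = 0.394, household = 0.385),
  aware_hiv = c(cluster = 0.696, household = 0.039),
  aware_campaign = c(cluster = 0.851, household = 0.067))

# emulation settings at a size large enough to pin down marginal prevalences
.emulation_config_at_scale <- function(seed = 21) {
  cfg <- default_emulation_config(seed = seed)
  cfg$n_clusters <- 150L
  cfg$households_per_cluster <- 8
  cfg
}
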