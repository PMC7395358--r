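#' Specify a synthetic hierarchical survey
#'
#' Builds the full generative specification for a three-level survey
#' (individuals in households in clusters) with three correlated binary
#' outcomes.  Outcome `q` for an individual is Bernoulli with success
#' probability `plogis(x'beta_q + u_c[q] + u_hc[q])`, where the cluster
#' intercepts `u_c ~ N(0, sigma_c)` and household intercepts
#' `u_hc ~ N(0, sigma_h)` are trivariate normal, independent across levels
#' and across units.
#'
#' @param n_clusters number of clusters (primary sampling units).
#' @param households_per_cluster a single count or a vector of length
#'   `n_clusters`.
#' @param individuals_per_household a single count, a vector (one entry per
#'   household, recycled), or a function `f(n)` returning `n` positive
#'   counts (called once, inside the seeded stream).
#' @param beta list of three coefficient vectors on the log-odds scale
#'   (first entry the intercept), one per outcome; all the same length
#'   `1 +` number of encoded covariate columns.
#' @param sigma_c,sigma_h 3x3 symmetric positive-semidefinite covariance
#'   matrices of the cluster- and household-level random intercepts.
#' @param covariates list of covariate descriptors; each a list with
#'   `name`, `type` (`"continuous"`, `"binary"` or `"categorical"`),
#'   `level` (`"individual"`, `"household"` or `"cluster"`), and the
#'   generator parameters `mean`/`sd`, `prevalence`, or `levels`/`probs`
#'   (+ optional `ref`, defaulting to the first level).
#' @param missing_rate probability in `[0, 1)` that a record's whole
#'   outcome triple is replaced by `NA` (missing-at-random).
#' @param seed integer seed; the draw order is fixed (see Details).
#'
#' @details The random-number stream is consumed in a documented, fixed
#' order so datasets are reproducible across versions: cluster random
#' effects, cluster-level covariates, household counts, household random
#' effects, household-level covariates, individual counts, individual-level
#' covariates, outcomes (three per individual, individual-major), and
#' finally the missingness mask.
#'
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_clusters,
                              households_per_cluster,
                              individuals_per_household,
                              beta,
                              sigma_c = diag(0, 3),
                              sigma_h = diag(0, 3),
                              covariates = list(),
                              missing_rate = 0,
                              seed = 1L) {
  if (length(n_clusters) != 1 || n_clusters < 1)
    stop("n_clusters must be a positive integer", call. = FALSE)
  if (is.numeric(households_per_cluster)) {
    if (any(households_per_cluster < 1))
      stop("households_per_cluster must be positive", call. = FALSE)
    if (!length(households_per_cluster) %in% c(1L, n_clusters))
      stop("households_per_cluster must be scalar or length n_clusters",
           call. = FALSE)
  } else stop("households_per_cluster must be numeric", call. = FALSE)
  if (!(is.function(individuals_per_household) ||
        (is.numeric(individuals_per_household) &&
         all(individuals_per_household >= 1))))
    stop("individuals_per_household must be positive counts or a function",
         call. = FALSE)
  .check_psd(sigma_c, "sigma_c")
  .check_psd(sigma_h, "sigma_h")
  if (nrow(sigma_c) != 3 || nrow(sigma_h) != 3)
    stop("sigma_c and sigma_h must be 3x3", call. = FALSE)
  if (!is.list(beta) || length(beta) != 3)
    stop("beta must be a list of three coefficient vectors", call. = FALSE)
  len <- unique(lengths(beta))
  if (length(len) != 1)
    stop("all three beta vectors must have the same length", call. = FALSE)
  p_enc <- sum(vapply(covariates, .covariate_width, integer(1)))
  if (len != 1 + p_enc)
    stop(sprintf("beta length %d does not match 1 + %d encoded covariates",
                 len, p_enc), call. = FALSE)
  for (cv in covariates) .validate_covariate(cv)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)

  structure(list(n_clusters = as.integer(n_clusters),
                 households_per_cluster = households_per_cluster,
                 individuals_per_household = individuals_per_household,
                 beta = lapply(beta, as.numeric),
                 sigma_c = sigma_c, sigma_h = sigma_h,
                 covariates = covariates,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.covariate_width <- function(cv) {
  if (identical(cv$type, "categorical")) length(cv$probs) - 1L else 1L
}

.validate_covariate <- function(cv) {
  if (is.null(cv$name) || is.null(cv$type) || is.null(cv$level))
    stop("each covariate needs name, type and level", call. = FALSE)
  if (!cv$type %in% c("continuous", "binary", "categorical"))
    stop(sprintf("unknown covariate type '%s'", cv$type), call. = FALSE)
  if (!cv$level %in% c("individual", "household", "cluster"))
    stop(sprintf("unknown covariate level '%s'", cv$level), call. = FALSE)
  if (cv$type == "categorical") {
    if (is.null(cv$levels) || is.null(cv$probs) ||
        length(cv$levels) != length(cv$probs))
      stop("categorical covariates need matching levels and probs",
           call. = FALSE)
    if (abs(sum(cv$probs) - 1) > 1e-12)
      stop(sprintf("probs for '%s' must sum to 1", cv$name), call. = FALSE)
  }
  if (cv$type == "binary" &&
      (cv$prevalence < 0 || cv$prevalence > 1))
    stop("binary prevalence must be in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Simulate a survey dataset from its generative specification
#'
#' Draws cluster and household random intercepts from `sigma_c` / `sigma_h`,
#' generates covariates at their declared levels, and samples the three
#' binary outcomes from the logistic model the configuration encodes.  The
#' true random-effect draws are returned alongside the dataset so that
#' recovery can be checked.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `dataset` (a [survey_dataset]) and
#'   `effects` (list of matrices `u_c`, one row per cluster, and `u_h`, one
#'   row per household, both with three columns on the log-odds scale).
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  nc <- config$n_clusters
  cluster_ids <- sprintf("C%03d", seq_len(nc))

  # 1. cluster random effects (3 deviates per cluster, cluster-major)
  u_c <- matrix(rnorm(3L * nc), ncol = 3, byrow = TRUE) %*%
    .sym_sqrt(config$sigma_c)
  rownames(u_c) <- cluster_ids

  # 2. cluster-level covariates
  cl_cov <- .draw_covariates(config$covariates, "cluster", nc)

  # 3. household counts, random effects, household-level covariates
  hpc <- rep(config$households_per_cluster, length.out = nc)
  nh <- sum(hpc)
  hh_cluster <- rep(cluster_ids, hpc)
  hh_ids <- paste0(hh_cluster, sprintf("_H%02d",
                                       sequence(hpc)))
  u_h <- matrix(rnorm(3L * nh), ncol = 3, byrow = TRUE) %*%
    .sym_sqrt(config$sigma_h)
  rownames(u_h) <- hh_ids
  hh_cov <- .draw_covariates(config$covariates, "household", nh)

  # 4. individual counts and individual-level covariates
  iph <- config$individuals_per_household
  if (is.function(iph)) iph <- iph(nh)
  iph <- rep(as.integer(iph), length.out = nh)
  n <- sum(iph)
  ind_hh <- rep(seq_len(nh), iph)
  person_ids <- paste0(hh_ids[ind_hh], sprintf("_P%d", sequence(iph)))
  ind_cov <- .draw_covariates(config$covariates, "individual", n)

  # assemble raw covariate frame in declaration order
  raw <- data.frame(row.names = seq_len(n))
  for (cv in config$covariates) {
    vals <- switch(cv$level,
      cluster = cl_cov[[cv$name]][match(hh_cluster[ind_hh], cluster_ids)],
      household = hh_cov[[cv$name]][ind_hh],
      individual = ind_cov[[cv$name]])
    raw[[cv$name]] <- vals
  }

  # 5. outcomes: three uniforms per individual, individual-major
  X <- .encode_covariates(raw, config$covariates)
  eta <- X %*% cbind(config$beta[[1]], config$beta[[2]], config$beta[[3]])
  eta <- eta + u_c[match(hh_cluster[ind_hh], cluster_ids), , drop = FALSE] +
    u_h[ind_hh, , drop = FALSE]
  uu <- matrix(runif(3L * n), ncol = 3, byrow = TRUE)
  y <- 1L * (uu < .expit(eta))

  # 6. missingness mask (whole triple at once)
  if (config$missing_rate > 0) {
    drop <- runif(n) < config$missing_rate
    y[drop, ] <- NA_integer_
  }

  df <- data.frame(cluster_id = hh_cluster[ind_hh],
                   household_id = hh_ids[ind_hh],
                   person_id = person_ids,
                   y1 = y[, 1], y2 = y[, 2], y3 = y[, 3],
                   raw,
                   stringsAsFactors = FALSE)
  ds <- survey_dataset(df, covariates = config$covariates)
  list(dataset = ds,
       effects = list(u_c = u_c, u_h = u_h))
}

.draw_covariates <- function(covariates, level, n_units) {
  out <- list()
  for (cv in covariates) {
    if (!identical(cv$level, level)) next
    out[[cv$name]] <- switch(cv$type,
      continuous = rnorm(n_units, cv$mean, cv$sd),
      binary = rbinom(n_units, 1L, cv$prevalence),
      categorical = sample(cv$levels, n_units, replace = TRUE,
                           prob = cv$probs))
  }
  out
}

#' Theoretical latent-scale ICC implied by a simulation configuration
#'
#' For outcome `q`, applies the latent-variable intraclass-correlation
#' convention for logistic models (level-1 residual variance fixed at 3.29)
#' to the configured variance components: cluster-level ICC
#' `sigma_c[q,q] / (sigma_c[q,q] + sigma_h[q,q] + 3.29)` and the cumulative
#' household-level ICC `(sigma_c[q,q] + sigma_h[q,q]) / (... + 3.29)`.
#'
#' @param config a [simulation_config()].
#' @param outcome outcome index, 1..3.
#' @param level1 level-1 latent residual variance; `3.29` by default (use
#'   `pi^2 / 3` for the unrounded constant).
#' @return an `icc_result`, as from [compute_icc()].
#' @export
latent_icc_of_config <- function(config, outcome,
                                 level1 = LEVEL1_LOGISTIC_VARIANCE) {
  stopifnot(inherits(config, "simulation_config"))
  if (!outcome %in% 1:3) stop("outcome must be 1, 2 or 3", call. = FALSE)
  compute_icc(config$sigma_c[outcome, outcome],
              config$sigma_h[outcome, outcome],
              level1 = level1)
}

#' Ready-made simulation configurations
#'
#' `default_emulation_config()` is the package's desk-scale emulation of a
#' national HIV survey: 50 clusters x 6 households x 3 adults, outcome
#' variance components at the magnitudes typically reported for such
#' surveys (cluster 0.394/0.696/0.851, household 0.385/0.039/0.067),
#' cross-outcome correlations 0.5 (cluster) and 0.3 (household), and
#' covariates for age, education, sex, household wealth quintile and
#' electricity.  Intercepts are calibrated by a latent-normal
#' approximation so the marginal prevalences are close to 0.134, 0.772 and
#' 0.549.  `survey_scale_config()` is the same generative model at full
#' survey scale (270 clusters, ~23 households each, 1-2 adults per
#' household).  `demo_config()` is a small two-covariate configuration used
#' by the bundled pipeline demo.
#'
#' @param seed integer seed.
#' @name preset_configs
#' @export
default_emulation_config <- function(seed = 1L) {
  .emulation_config(n_clusters = 50, households_per_cluster = 6,
                    individuals_per_household = 3, seed = seed)
}

#' @rdname preset_configs
#' @export
survey_scale_config <- function(seed = 1L) {
  .emulation_config(n_clusters = 270, households_per_cluster = 23,
                    individuals_per_household = function(n)
                      sample(c(1L, 2L), n, replace = TRUE),
                    seed = seed)
}

.emulation_covariates <- function() {
  list(
    list(name = "age", type = "continuous", level = "individual",
         mean = 31, sd = 12.5),
    list(name = "edu_years", type = "continuous", level = "individual",
         mean = 3, sd = 3.69),
    list(name = "male", type = "binary", level = "individual",
         prevalence = 0.42),
    list(name = "wealth", type = "categorical", level = "household",
         levels = c("poorest", "poorer", "middle", "richer", "richest"),
         probs = c(0.122, 0.164, 0.189, 0.218, 0.307),
         ref = "poorest"),
    list(name = "electricity", type = "binary", level = "household",
         prevalence = 0.253)
  )
}

.emulation_config <- function(n_clusters, households_per_cluster,
                              individuals_per_household, seed) {
  covs <- .emulation_covariates()
  # slopes: generic magnitudes for a survey of this kind (not calibrated
  # to any fitted table); order: intercept, age, edu_years, male,
  # wealth poorer/middle/richer/richest, electricity
  slopes <- list(
    c(-0.005, 0.02, -0.1, 0.25, 0.35, 0.6, 0.8, -0.2),
    c(-0.005, 0.10, 0.00, 0.05, 0.15, 0.30, 0.45, 0.45),
    c(-0.005, 0.10, 0.30, 0.05, 0.20, 0.35, 0.50, 0.60))
  target_prev <- c(0.134, 0.772, 0.549)
  sd_c <- sqrt(c(0.394, 0.696, 0.851))
  sd_h <- sqrt(c(0.385, 0.039, 0.067))
  rho_c <- 0.5
  rho_h <- 0.3
  sigma_c <- outer(sd_c, sd_c) * (rho_c + (1 - rho_c) * diag(3))
  sigma_h <- outer(sd_h, sd_h) * (rho_h + (1 - rho_h) * diag(3))

  # latent-normal calibration of the intercepts: marginal prevalence of a
  # logit model with extra latent variance v is approximately
  # plogis(lp_mean / sqrt(1 + v / 3.29))
  mx <- c(31, 3, 0.42, 0.164, 0.189, 0.218, 0.307, 0.253)
  vx <- c(12.5^2, 3.69^2, 0.42 * 0.58,
          0.164 * 0.836, 0.189 * 0.811, 0.218 * 0.782, 0.307 * 0.693,
          0.253 * 0.747)
  beta <- vector("list", 3)
  for (q in 1:3) {
    v_lat <- sigma_c[q, q] + sigma_h[q, q] + sum(slopes[[q]]^2 * vx)
    b0 <- qlogis(target_prev[q]) * sqrt(1 + v_lat / 3.29) -
      sum(slopes[[q]] * mx)
    beta[[q]] <- c(b0, slopes[[q]])
  }
  simulation_config(n_clusters = n_clusters,
                    households_per_cluster = households_per_cluster,
                    individuals_per_household = individuals_per_household,
                    beta = beta, sigma_c = sigma_c, sigma_h = sigma_h,
                    covariates = covs, missing_rate = 0.02, seed = seed)
}

#' @rdname preset_configs
#' @param n_clusters number of clusters.
#' @param households_per_cluster,individuals_per_household hierarchy sizes.
#' @param rho_c,rho_h cross-outcome correlations of the cluster- and
#'   household-level random intercepts.
#' @export
intercept_emulation_config <- function(n_clusters = 200,
                                       households_per_cluster = 6,
                                       individuals_per_household = 3,
                                       rho_c = 0.5, rho_h = 0.3,
                                       seed = 1L) {
  sd_c <- sqrt(c(0.394, 0.696, 0.851))
  sd_h <- sqrt(c(0.385, 0.039, 0.067))
  sigma_c <- outer(sd_c, sd_c) * (rho_c + (1 - rho_c) * diag(3))
  sigma_h <- outer(sd_h, sd_h) * (rho_h + (1 - rho_h) * diag(3))
  target_prev <- c(0.134, 0.772, 0.549)
  beta <- lapply(1:3, function(q)
    qlogis(target_prev[q]) *
      sqrt(1 + (sigma_c[q, q] + sigma_h[q, q]) / 3.29))
  simulation_config(n_clusters = n_clusters,
                    households_per_cluster = households_per_cluster,
                    individuals_per_household = individuals_per_household,
                    beta = beta, sigma_c = sigma_c, sigma_h = sigma_h,
                    seed = seed)
}

#' @rdname preset_configs
#' @export
demo_config <- function(seed = 1L, n_clusters = 40) {
  covs <- list(
    list(name = "age", type = "continuous", level = "individual",
         mean = 31, sd = 12.5),
    list(name = "electricity", type = "binary", level = "household",
         prevalence = 0.253))
  sd_c <- sqrt(c(0.394, 0.696, 0.851))
  sd_h <- sqrt(c(0.385, 0.039, 0.067))
  sigma_c <- outer(sd_c, sd_c) * (0.5 + 0.5 * diag(3))
  sigma_h <- outer(sd_h, sd_h) * (0.3 + 0.7 * diag(3))
  beta <- list(c(-1.9, -0.005, -0.2),
               c(1.3, -0.005, 0.45),
               c(0.2, -0.005, 0.6))
  simulation_config(n_clusters = n_clusters, households_per_cluster = 6,
                    individuals_per_household = 3,
                    beta = beta, sigma_c = sigma_c, sigma_h = sigma_h,
                    covariates = covs, missing_rate = 0.02, seed = seed)
}

#' Read or write a simulation configuration as YAML
#'
#' @param path file path.
#' @param config a [simulation_config()].
#' @return `read_simulation_config()` returns a `simulation_config`;
#'   `write_simulation_config()` returns `path` invisibly.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  simulation_config(
    n_clusters = raw$n_clusters,
    households_per_cluster = unlist(raw$households_per_cluster),
    individuals_per_household = unlist(raw$individuals_per_household),
    beta = lapply(raw$beta, unlist),
    sigma_c = matrix(unlist(raw$sigma_c), 3, 3),
    sigma_h = matrix(unlist(raw$sigma_h), 3, 3),
    covariates = raw$covariates,
    missing_rate = raw$missing_rate %||% 0,
    seed = raw$seed %||% 1L)
}

#' @rdname read_simulation_config
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.function(config$individuals_per_household))
    stop("function-valued individuals_per_household cannot be serialized",
         call. = FALSE)
  out <- unclass(config)
  out$sigma_c <- as.list(as.data.frame(config$sigma_c))
  out$sigma_h <- as.list(as.data.frame(config$sigma_h))
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
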