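# Gauss-Hermite rule (physicists' convention: sum w f(x) ~ int exp(-x^2) f)
.gh_rule <- function(k) {
  stopifnot(k >= 1)
  if (k == 1) return(list(x = 0, w = sqrt(pi)))
  r <- pracma::gaussHermite(k)
  list(x = r$x, w = r$w)
}

# Order complete-outcome records by cluster then household and build the
# 0-based pointer arrays the C++ evaluator expects.
.ll_prep <- function(dataset, outcome = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  keep <- dataset$complete
  if (!any(keep)) stop("no complete-outcome records", call. = FALSE)
  df <- dataset$df[keep, , drop = FALSE]
  X <- dataset$X[keep, , drop = FALSE]
  cl <- factor(df$cluster_id, levels = unique(df$cluster_id))
  hh <- factor(df$household_id, levels = unique(df$household_id))
  ord <- order(as.integer(cl), as.integer(hh))
  df <- df[ord, , drop = FALSE]
  X <- X[ord, , drop = FALSE]
  hh <- hh[ord]
  cl <- cl[ord]
  hh_sizes <- as.integer(table(hh)[unique(as.character(hh))])
  hh_ptr <- c(0L, cumsum(hh_sizes))
  hh_cl <- cl[!duplicated(hh)]
  cl_sizes <- as.integer(table(hh_cl)[unique(as.character(hh_cl))])
  cl_ptr <- c(0L, cumsum(cl_sizes))
  Y <- as.matrix(df[, c("y1", "y2", "y3")])
  if (!is.null(outcome)) Y <- Y[, outcome, drop = FALSE]
  storage.mode(Y) <- "integer"
  list(X = X, Y = Y, hh_ptr = hh_ptr, cl_ptr = cl_ptr,
       n = nrow(df), n_clusters = length(unique(cl)))
}

.data_hash <- function(dataset) {
  keep <- dataset$complete
  rlang::hash(list(dataset$df[keep, , drop = FALSE],
                   dataset$X[keep, , drop = FALSE]))
}

.empty_L <- matrix(numeric(0), 0, 0)

.level_chol <- function(sigma, name) {
  if (is.null(dim(sigma))) sigma <- diag(sigma, length(sigma))
  if (all(abs(sigma) < 1e-12)) return(.empty_L)
  .chol_lower(sigma, name)
}

#' Marginal log-likelihood of a per-outcome three-level logistic model
#'
#' Evaluates, by nested adaptive Gauss-Hermite quadrature, the marginal
#' log-likelihood of a random-intercept logistic model for one outcome:
#' per cluster, the integral over the cluster intercept of the product
#' over households of the integral over the household intercept of the
#' Bernoulli likelihood.  With both variances zero the integrals are
#' degenerate and the value equals the ordinary logistic log-likelihood.
#'
#' @param beta coefficient vector (intercept first), matching the
#'   dataset's encoded model matrix.
#' @param var_c,var_h cluster- and household-level intercept variances
#'   (log-odds scale), `>= 0`.
#' @param dataset a [survey_dataset]; records with missing outcomes are
#'   excluded.
#' @param outcome outcome index 1..3.
#' @param quad_nodes quadrature nodes per dimension (`1` = adaptive
#'   Laplace).
#' @return the marginal log-likelihood (a scalar).
#' @export
loglik_separate <- function(beta, var_c, var_h, dataset, outcome,
                            quad_nodes = 7) {
  if (var_c < 0 || var_h < 0)
    stop("variances must be nonnegative", call. = FALSE)
  if (!outcome %in% 1:3) stop("outcome must be 1, 2 or 3", call. = FALSE)
  prep <- .ll_prep(dataset, outcome = outcome)
  if (length(beta) != ncol(prep$X))
    stop(sprintf("beta has length %d but the model matrix has %d columns",
                 length(beta), ncol(prep$X)), call. = FALSE)
  gh <- .gh_rule(quad_nodes)
  eta <- prep$X %*% matrix(beta, ncol = 1)
  Lc <- .level_chol(matrix(var_c, 1, 1), "var_c")
  Lh <- .level_chol(matrix(var_h, 1, 1), "var_h")
  .nested_aghq_loglik(eta, prep$Y, prep$hh_ptr, prep$cl_ptr, Lc, Lh,
                      gh$x, gh$w)
}

#' Marginal log-likelihood of the simultaneous trivariate model
#'
#' Evaluates the joint marginal log-likelihood of the three binary
#' outcomes: per cluster, a 3-dimensional integral over the trivariate
#' cluster intercept `u_c ~ N(0, sigma_c)` of the product over households
#' of a 3-dimensional integral over the household intercept
#' `u_hc ~ N(0, sigma_h)` of the product of Bernoulli terms.  Nested
#' adaptive Gauss-Hermite quadrature on Cholesky-whitened coordinates.
#' With diagonal `sigma_c` and `sigma_h` the value factorises exactly into
#' the sum of the three per-outcome log-likelihoods.
#'
#' @param beta list of three coefficient vectors (one per outcome).
#' @param sigma_c,sigma_h 3x3 symmetric positive-semidefinite covariance
#'   blocks of the cluster- and household-level intercepts.
#' @inheritParams loglik_separate
#' @return the joint marginal log-likelihood (a scalar).
#' @export
loglik_joint <- function(beta, sigma_c, sigma_h, dataset, quad_nodes = 3) {
  stopifnot(is.list(beta), length(beta) == 3)
  prep <- .ll_prep(dataset)
  for (q in 1:3)
    if (length(beta[[q]]) != ncol(prep$X))
      stop(sprintf("beta[[%d]] does not match the model matrix", q),
           call. = FALSE)
  gh <- .gh_rule(quad_nodes)
  eta <- prep$X %*% cbind(beta[[1]], beta[[2]], beta[[3]])
  Lc <- .level_chol(sigma_c, "sigma_c")
  Lh <- .level_chol(sigma_h, "sigma_h")
  .nested_aghq_loglik(eta, prep$Y, prep$hh_ptr, prep$cl_ptr, Lc, Lh,
                      gh$x, gh$w)
}

#' Simple Monte-Carlo oracle for the marginal log-likelihood
#'
#' Independent verification of the quadrature evaluators: per cluster, the
#' marginal likelihood is estimated by plain Monte Carlo over joint normal
#' draws of the cluster and household intercepts, and the per-cluster logs
#' are summed.  The standard error of the total log-likelihood comes from
#' the delta method applied to each cluster's mean.  Intended for small
#' fixtures in tests; not an estimation routine.
#'
#' @param beta a list of three coefficient vectors (joint model), or a
#'   single vector when `outcome` is given.
#' @param sigma_c,sigma_h covariance blocks (3x3), or scalar variances
#'   when `outcome` is given.
#' @param dataset a [survey_dataset].
#' @param n_draws Monte-Carlo draws per cluster (`>= 1000`).
#' @param seed integer seed for the draws.
#' @param outcome optional outcome index for the univariate model.
#' @return list with `estimate` (log-likelihood) and `mc_se`.
#' @export
mc_loglik_oracle <- function(beta, sigma_c, sigma_h, dataset,
                             n_draws = 1e5, seed = 1, outcome = NULL) {
  if (n_draws < 1000) stop("n_draws must be >= 1000", call. = FALSE)
  prep <- .ll_prep(dataset, outcome = outcome)
  if (is.null(outcome)) {
    stopifnot(is.list(beta), length(beta) == 3)
    eta <- prep$X %*% cbind(beta[[1]], beta[[2]], beta[[3]])
    Sc <- sigma_c
    Sh <- sigma_h
  } else {
    eta <- prep$X %*% matrix(beta, ncol = 1)
    Sc <- matrix(sigma_c, 1, 1)
    Sh <- matrix(sigma_h, 1, 1)
  }
  .check_psd(Sc, "sigma_c")
  .check_psd(Sh, "sigma_h")
  Q <- ncol(eta)
  Ac <- .sym_sqrt(Sc)
  Ah <- .sym_sqrt(Sh)

  set.seed(seed)
  total <- 0
  var_tot <- 0
  n_cl <- length(prep$cl_ptr) - 1L
  for (c in seq_len(n_cl)) {
    hh_idx <- (prep$cl_ptr[c] + 1L):prep$cl_ptr[c + 1L]
    uc <- matrix(rnorm(n_draws * Q), n_draws, Q) %*% Ac
    logf <- numeric(n_draws)
    for (h in hh_idx) {
      rows <- (prep$hh_ptr[h] + 1L):prep$hh_ptr[h + 1L]
      uh <- matrix(rnorm(n_draws * Q), n_draws, Q) %*% Ah
      for (i in rows) {
        for (q in seq_len(Q)) {
          e <- eta[i, q] + uc[, q] + uh[, q]
          logf <- logf + prep$Y[i, q] * e - .log1pexp(e)
        }
      }
    }
    m <- max(logf)
    w <- exp(logf - m)
    mw <- mean(w)
    total <- total + m + log(mw)
    var_tot <- var_tot + stats::var(w) / (n_draws * mw^2)
  }
  list(estimate = total, mc_se = sqrt(var_tot))
}
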