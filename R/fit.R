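# quasi-Newton minimization with central-difference gradients; box
# constraints keep the log-standard-deviations away from -Inf when the
# likelihood is flat at a variance boundary.  `nll` takes (theta, um, vm):
# optional per-cluster / per-household mode matrices that warm-start the
# inner Newton searches.  The gradient refreshes the modes at the base
# point and restarts every perturbed evaluation from them — the
# perturbations are tiny, so those evaluations converge in a step or two.
.optimize_nll <- function(nll, theta0, lower, max_iter = 200, tol = 1e-8,
                          n_cl = 0, n_hh = 0, Q = 1) {
  base_um <- matrix(0, n_cl, Q)
  base_vm <- matrix(0, n_hh, Q)
  fn <- function(theta) nll(theta, base_um, base_vm)
  gr <- function(theta) {
    nll(theta, base_um, base_vm)  # modes written in place at the base point
    h <- 1e-6 * pmax(abs(theta), 1)
    vapply(seq_along(theta), function(i) {
      tp <- tm <- theta
      tp[i] <- tp[i] + h[i]
      tm[i] <- tm[i] - h[i]
      fp <- nll(tp, base_um + 0, base_vm + 0)
      fm <- nll(tm, base_um + 0, base_vm + 0)
      (fp - fm) / (2 * h[i])
    }, numeric(1))
  }
  o <- stats::optim(theta0, fn, gr, method = "L-BFGS-B", lower = lower,
                    control = list(maxit = max_iter,
                                   factr = max(tol / .Machine$double.eps, 10)))
  list(par = o$par, objective = o$value,
       converged = o$convergence == 0, message = o$message)
}

# numerical Hessian sharing the same warm-start trick
.num_hessian_state <- function(nll, theta, n_cl, n_hh, Q, rel = 1e-4) {
  base_um <- matrix(0, n_cl, Q)
  base_vm <- matrix(0, n_hh, Q)
  f0 <- nll(theta, base_um, base_vm)
  fw <- function(th) nll(th, base_um + 0, base_vm + 0)
  p <- length(theta)
  h <- rel * pmax(abs(theta), 1)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ti <- tj <- numeric(p)
      ti[i] <- h[i]
      tj[j] <- h[j]
      if (i == j) {
        H[i, i] <- (fw(theta + ti) - 2 * f0 + fw(theta - ti)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (fw(theta + ti + tj) - fw(theta + ti - tj) -
             fw(theta - ti + tj) + fw(theta - ti - tj)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

.se_from_hessian <- function(H) {
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0)) return(NULL)
  V
}

.check_fittable <- function(prep, yq = NULL) {
  if (prep$n_clusters < 2)
    stop("at least 2 clusters are required", call. = FALSE)
  ys <- if (is.null(yq)) prep$Y else matrix(yq, ncol = 1)
  for (q in seq_len(ncol(ys))) {
    if (length(unique(ys[, q])) < 2)
      stop(sprintf("separation: outcome %d is constant in the complete-case data", q),
           call. = FALSE)
  }
}

#' Fit a per-outcome three-level random-intercept logistic model
#'
#' Maximizes the nested-AGHQ marginal likelihood over the coefficients and
#' the two intercept variances, the latter on the log-standard-deviation
#' scale to enforce positivity.  Standard errors come from the inverse
#' observed information (numerical central-difference Hessian), with the
#' delta method for the variance components.  Variance estimates below
#' `1e-6` are reported as 0 with a boundary flag (their SEs as `NA`).
#'
#' @param dataset a [survey_dataset].
#' @param outcome outcome index 1..3.
#' @param quad_nodes quadrature nodes per dimension (default 7).
#' @param max_iter,tol optimizer iteration cap and relative tolerance.
#' @param start optional start: list with `beta`, `var_c`, `var_h`
#'   (defaults: plain logistic regression for `beta`, 0.1 for both
#'   variances).
#' @param se compute standard errors (set `FALSE` in simulation loops).
#' @return an object of class `separate_fit`.
#' @export
fit_separate <- function(dataset, outcome, quad_nodes = 7,
                         max_iter = 200, tol = 1e-8, start = NULL,
                         se = TRUE) {
  prep <- .ll_prep(dataset, outcome = outcome)
  .check_fittable(prep, prep$Y[, 1])
  gh <- .gh_rule(quad_nodes)
  p <- ncol(prep$X)
  terms <- colnames(prep$X)

  if (is.null(start)) {
    g0 <- stats::glm.fit(prep$X, prep$Y[, 1], family = binomial())
    start <- list(beta = g0$coefficients, var_c = 0.1, var_h = 0.1)
  }
  theta0 <- c(start$beta, log(sqrt(start$var_c)), log(sqrt(start$var_h)))

  n_cl <- length(prep$cl_ptr) - 1L
  n_hh <- length(prep$hh_ptr) - 1L
  nll <- function(theta, um = NULL, vm = NULL) {
    sdc <- exp(theta[p + 1])
    sdh <- exp(theta[p + 2])
    eta <- prep$X %*% matrix(theta[1:p], ncol = 1)
    -.nested_aghq_loglik(eta, prep$Y, prep$hh_ptr, prep$cl_ptr,
                         matrix(sdc, 1, 1), matrix(sdh, 1, 1),
                         gh$x, gh$w, um, vm)
  }
  opt <- .optimize_nll(nll, theta0, lower = c(rep(-Inf, p), -8, -8),
                       max_iter = max_iter, tol = tol,
                       n_cl = n_cl, n_hh = n_hh, Q = 1)
  theta <- opt$par
  beta <- stats::setNames(theta[1:p], terms)
  var_c <- exp(2 * theta[p + 1])
  var_h <- exp(2 * theta[p + 2])
  boundary_c <- var_c < 1e-6
  boundary_h <- var_h < 1e-6

  se_beta <- rep(NA_real_, p)
  se_var_c <- se_var_h <- NA_real_
  se_ok <- FALSE
  if (se) {
    H <- .num_hessian_state(nll, theta, n_cl, n_hh, 1)
    V <- .se_from_hessian(H)
    if (!is.null(V)) {
      se_ok <- TRUE
      se_beta <- sqrt(diag(V)[1:p])
      if (!boundary_c) se_var_c <- 2 * var_c * sqrt(V[p + 1, p + 1])
      if (!boundary_h) se_var_h <- 2 * var_h * sqrt(V[p + 2, p + 2])
    }
  }

  structure(list(outcome = outcome,
                 beta = beta,
                 se_beta = stats::setNames(se_beta, terms),
                 var_cluster = if (boundary_c) 0 else var_c,
                 var_household = if (boundary_h) 0 else var_h,
                 var_cluster_raw = var_c,
                 var_household_raw = var_h,
                 theta = theta,
                 se_var_cluster = se_var_c,
                 se_var_household = se_var_h,
                 boundary = c(cluster = boundary_c, household = boundary_h),
                 loglik = -opt$objective,
                 converged = opt$converged,
                 se_available = se_ok,
                 n_used = prep$n,
                 quad_nodes = quad_nodes,
                 data_hash = .data_hash(dataset)),
            class = "separate_fit")
}

#' @export
print.separate_fit <- function(x, ...) {
  cat(sprintf("three-level logistic fit, outcome %d (n = %d, %d-node AGHQ)\n",
              x$outcome, x$n_used, x$quad_nodes))
  print(round(cbind(estimate = x$beta, se = x$se_beta), 4))
  cat(sprintf("var(cluster) = %.4f (se %.4f), var(household) = %.4f (se %.4f)\n",
              x$var_cluster, x$se_var_cluster, x$var_household,
              x$se_var_household))
  cat(sprintf("loglik = %.4f, converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' Latent-scale intraclass correlations for a three-level logistic model
#'
#' Uses the latent-variable convention for binary multilevel models: the
#' level-1 residual is logistic with variance `pi^2/3`, conventionally
#' rounded to 3.29.  Cluster-level ICC is
#' `var_c / (var_c + var_h + level1)`; the household-level ICC is
#' cumulative, `(var_c + var_h) / (var_c + var_h + level1)`.
#'
#' @param var_c,var_h nonnegative variance components.
#' @param level1 level-1 variance, default `3.29`; pass `pi^2 / 3` for the
#'   unrounded constant (the difference is ~0.003).
#' @return an object of class `icc_result`.
#' @export
compute_icc <- function(var_c, var_h, level1 = LEVEL1_LOGISTIC_VARIANCE) {
  if (var_c < 0 || var_h < 0)
    stop("variances must be nonnegative", call. = FALSE)
  if (level1 <= 0) stop("level1 must be positive", call. = FALSE)
  tot <- var_c + var_h + level1
  structure(list(icc_cluster = var_c / tot,
                 icc_household_cumulative = (var_c + var_h) / tot,
                 level1_variance = level1),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (cluster) = %.4f; ICC (household, cumulative) = %.4f [level-1 variance %.4g]\n",
              x$icc_cluster, x$icc_household_cumulative, x$level1_variance))
  invisible(x)
}

# ---- joint model ----------------------------------------------------------

# log-Cholesky parameterization of a 3x3 covariance block:
# L = [exp(t1) 0 0; t2 exp(t3) 0; t4 t5 exp(t6)], Sigma = L L'
.theta_to_L <- function(th) {
  L <- matrix(0, 3, 3)
  L[1, 1] <- exp(th[1]); L[2, 1] <- th[2]; L[2, 2] <- exp(th[3])
  L[3, 1] <- th[4]; L[3, 2] <- th[5]; L[3, 3] <- exp(th[6])
  L
}

.sigma_to_theta <- function(sigma, floor_sd = 1e-4) {
  L <- tryCatch(t(chol(sigma)), error = function(e) {
    d <- pmax(sqrt(diag(sigma)), floor_sd)
    diag(d, 3)
  })
  diag(L) <- pmax(diag(L), floor_sd)
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]), L[3, 1], L[3, 2], log(L[3, 3]))
}

# covariance start for the joint fit: correlation structure of the
# per-unit posterior modes, scaled to the separate variance estimates and
# shrunk mildly toward independence to stay well inside the PSD cone
.mode_start_cov <- function(modes, vars) {
  sds <- apply(modes, 2, stats::sd)
  R <- diag(3)
  ok <- is.finite(sds) & sds > 1e-8
  if (sum(ok) > 1) {
    Rsub <- stats::cor(modes[, ok, drop = FALSE])
    if (all(is.finite(Rsub))) R[ok, ok] <- Rsub
  }
  R <- 0.8 * R + 0.2 * diag(3)
  diag(sqrt(vars)) %*% R %*% diag(sqrt(vars))
}

.joint_theta_names <- function(terms) {
  c(paste0("y1:", terms), paste0("y2:", terms), paste0("y3:", terms),
    paste0("chol_c", 1:6), paste0("chol_h", 1:6))
}

#' Fit the simultaneous trivariate three-level logistic model
#'
#' Maximizes the joint nested-AGHQ marginal likelihood over the three
#' coefficient vectors and the log-Cholesky factors of the cluster- and
#' household-level 3x3 covariance blocks.  The default start takes the
#' three separate fits (their coefficients and diagonal variances, zero
#' cross-covariances).  With `restrict_cross = TRUE` all off-diagonal
#' (cross-outcome) covariances are fixed at zero; that restricted model
#' factorises exactly into the three per-outcome models, so it is fitted
#' as the three separate fits and its log-likelihood is re-evaluated with
#' the joint machinery (the two agree to numerical tolerance by
#' construction).
#'
#' @param dataset a [survey_dataset].
#' @param quad_nodes quadrature nodes per dimension (default 3, i.e. 27
#'   points per 3-dimensional integral; `1` = adaptive Laplace).
#' @param max_iter,tol optimizer controls.
#' @param start optional list with `beta` (list of 3), `sigma_c`,
#'   `sigma_h`.
#' @param restrict_cross fit the zero-cross-covariance (restricted) model.
#' @param se compute standard errors (numerical observed information plus
#'   delta method for the covariance entries).
#' @return an object of class `joint_fit`.
#' @export
fit_joint <- function(dataset, quad_nodes = 3, max_iter = 400, tol = 1e-8,
                      start = NULL, restrict_cross = FALSE, se = TRUE) {
  prep <- .ll_prep(dataset)
  .check_fittable(prep)
  p <- ncol(prep$X)
  terms <- colnames(prep$X)
  onames <- c("y1", "y2", "y3")

  if (restrict_cross) {
    seps <- lapply(1:3, function(q)
      fit_separate(dataset, q, quad_nodes = quad_nodes,
                   max_iter = max_iter, tol = tol, se = se))
    # raw (unfloored) variances keep the factorisation identity exact when
    # a component sits at the boundary
    sigma_c <- diag(vapply(seps, `[[`, numeric(1), "var_cluster_raw"))
    sigma_h <- diag(vapply(seps, `[[`, numeric(1), "var_household_raw"))
    beta <- lapply(seps, `[[`, "beta")
    ll_joint <- loglik_joint(beta, sigma_c, sigma_h, dataset,
                             quad_nodes = quad_nodes)
    ll_sum <- sum(vapply(seps, `[[`, numeric(1), "loglik"))
    if (abs(ll_joint - ll_sum) > 1e-5 * max(1, abs(ll_sum)))
      warning("joint and factorised log-likelihoods disagree beyond tolerance")
    se_sigma_c <- se_sigma_h <- matrix(NA_real_, 3, 3)
    diag(se_sigma_c) <- vapply(seps, `[[`, numeric(1), "se_var_cluster")
    diag(se_sigma_h) <- vapply(seps, `[[`, numeric(1), "se_var_household")
    fit <- structure(list(
      beta = stats::setNames(beta, onames),
      se_beta = stats::setNames(lapply(seps, `[[`, "se_beta"), onames),
      sigma_c = sigma_c, sigma_h = sigma_h,
      se_sigma_c = se_sigma_c, se_sigma_h = se_sigma_h,
      loglik = ll_joint,
      converged = all(vapply(seps, `[[`, logical(1), "converged")),
      se_available = all(vapply(seps, `[[`, logical(1), "se_available")),
      restricted = TRUE, n_used = prep$n, quad_nodes = quad_nodes,
      data_hash = .data_hash(dataset),
      separate_fits = seps), class = "joint_fit")
    return(fit)
  }

  gh <- .gh_rule(quad_nodes)
  n_cl <- length(prep$cl_ptr) - 1L
  n_hh <- length(prep$hh_ptr) - 1L
  ib <- seq_len(3 * p)
  cov_lower <- rep(c(-8, -Inf, -8, -Inf, -Inf, -8), 2)

  nll <- function(theta, um = NULL, vm = NULL) {
    B <- matrix(theta[ib], ncol = 3)
    Lc <- .theta_to_L(theta[3 * p + 1:6])
    Lh <- .theta_to_L(theta[3 * p + 7:12])
    eta <- prep$X %*% B
    -.nested_aghq_loglik(eta, prep$Y, prep$hh_ptr, prep$cl_ptr, Lc, Lh,
                         gh$x, gh$w, um, vm)
  }

  if (is.null(start)) {
    seps <- lapply(1:3, function(q)
      fit_separate(dataset, q, quad_nodes = quad_nodes,
                   max_iter = max_iter, tol = tol, se = FALSE))
    # start the cross-covariances at the correlation of the per-unit
    # posterior modes of the three separate fits, scaled by the separate
    # variance estimates
    U <- matrix(0, n_cl, 3)
    V <- matrix(0, n_hh, 3)
    for (q in 1:3) {
      um <- matrix(0, n_cl, 1)
      vm <- matrix(0, n_hh, 1)
      prep_q <- .ll_prep(dataset, outcome = q)
      eta_q <- prep_q$X %*% matrix(seps[[q]]$beta, ncol = 1)
      .nested_aghq_loglik(eta_q, prep_q$Y, prep_q$hh_ptr, prep_q$cl_ptr,
                          matrix(max(sqrt(seps[[q]]$var_cluster_raw), 1e-4),
                                 1, 1),
                          matrix(max(sqrt(seps[[q]]$var_household_raw), 1e-4),
                                 1, 1),
                          gh$x, gh$w, um, vm)
      U[, q] <- um
      V[, q] <- vm
    }
    vc <- pmax(vapply(seps, `[[`, numeric(1), "var_cluster_raw"), 2.5e-3)
    vh <- pmax(vapply(seps, `[[`, numeric(1), "var_household_raw"), 2.5e-3)
    start <- list(beta = lapply(seps, `[[`, "beta"),
                  sigma_c = .mode_start_cov(U, vc),
                  sigma_h = .mode_start_cov(V, vh))
  }

  # stage one: covariance parameters with the coefficients frozen
  beta_vec <- unlist(start$beta)
  th_cov0 <- c(.sigma_to_theta(start$sigma_c), .sigma_to_theta(start$sigma_h))
  nll_cov <- function(th, um = NULL, vm = NULL)
    nll(c(beta_vec, th), um, vm)
  opt_a <- .optimize_nll(nll_cov, th_cov0, lower = cov_lower,
                         max_iter = max_iter, tol = tol * 100,
                         n_cl = n_cl, n_hh = n_hh, Q = 3)

  # stage two: all parameters
  theta0 <- c(beta_vec, opt_a$par)
  opt <- .optimize_nll(nll, theta0,
                       lower = c(rep(-Inf, 3 * p), cov_lower),
                       max_iter = max_iter, tol = tol,
                       n_cl = n_cl, n_hh = n_hh, Q = 3)
  theta <- opt$par
  B <- matrix(theta[ib], ncol = 3, dimnames = list(terms, onames))
  Lc <- .theta_to_L(theta[3 * p + 1:6])
  Lh <- .theta_to_L(theta[3 * p + 7:12])
  sigma_c <- Lc %*% t(Lc)
  sigma_h <- Lh %*% t(Lh)
  dimnames(sigma_c) <- dimnames(sigma_h) <- list(onames, onames)

  se_beta <- lapply(1:3, function(q) stats::setNames(rep(NA_real_, p), terms))
  se_sigma_c <- se_sigma_h <- matrix(NA_real_, 3, 3,
                                     dimnames = list(onames, onames))
  se_ok <- FALSE
  if (se) {
    H <- .num_hessian_state(nll, theta, n_cl, n_hh, 3)
    V <- .se_from_hessian(H)
    if (!is.null(V)) {
      se_ok <- TRUE
      sdt <- sqrt(diag(V))
      for (q in 1:3)
        se_beta[[q]] <- stats::setNames(sdt[(q - 1) * p + 1:p], terms)
      # delta method for the covariance entries: numerical jacobian of
      # vech(Sigma) in the 12 Cholesky parameters
      cv_idx <- 3 * p + 1:12
      vech <- function(th) {
        Lc <- .theta_to_L(th[1:6]); Lh <- .theta_to_L(th[7:12])
        Sc <- Lc %*% t(Lc); Sh <- Lh %*% t(Lh)
        c(Sc[lower.tri(Sc, diag = TRUE)], Sh[lower.tri(Sh, diag = TRUE)])
      }
      th_cv <- theta[cv_idx]
      J <- matrix(0, 12, 12)
      hstep <- 1e-5 * pmax(abs(th_cv), 1)
      for (j in 1:12) {
        tp <- tm <- th_cv
        tp[j] <- tp[j] + hstep[j]
        tm[j] <- tm[j] - hstep[j]
        J[, j] <- (vech(tp) - vech(tm)) / (2 * hstep[j])
      }
      Vv <- J %*% V[cv_idx, cv_idx] %*% t(J)
      sev <- sqrt(pmax(diag(Vv), 0))
      lt <- lower.tri(sigma_c, diag = TRUE)
      se_sigma_c[lt] <- sev[1:6]
      se_sigma_c[upper.tri(se_sigma_c)] <- t(se_sigma_c)[upper.tri(se_sigma_c)]
      se_sigma_h[lt] <- sev[7:12]
      se_sigma_h[upper.tri(se_sigma_h)] <- t(se_sigma_h)[upper.tri(se_sigma_h)]
    }
  }

  structure(list(
    beta = stats::setNames(lapply(1:3, function(q)
      stats::setNames(B[, q], terms)), onames),
    se_beta = stats::setNames(se_beta, onames),
    sigma_c = sigma_c, sigma_h = sigma_h,
    se_sigma_c = se_sigma_c, se_sigma_h = se_sigma_h,
    loglik = -opt$objective,
    converged = opt$converged,
    se_available = se_ok,
    restricted = FALSE, n_used = prep$n, quad_nodes = quad_nodes,
    data_hash = .data_hash(dataset)), class = "joint_fit")
}

#' @export
print.joint_fit <- function(x, ...) {
  kind <- if (x$restricted) "restricted (zero cross-covariance)" else "full"
  cat(sprintf("simultaneous trivariate logistic fit, %s (n = %d, %d-node AGHQ)\n",
              kind, x$n_used, x$quad_nodes))
  for (q in 1:3) {
    cat(sprintf("outcome %d coefficients:\n", q))
    print(round(cbind(estimate = x$beta[[q]], se = x$se_beta[[q]]), 4))
  }
  cat("cluster-level covariance:\n"); print(round(x$sigma_c, 4))
  cat("household-level covariance:\n"); print(round(x$sigma_h, 4))
  cat(sprintf("loglik = %.4f, converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' Likelihood-ratio test of the six cross-outcome covariances
#'
#' Compares the full simultaneous fit to the restricted
#' (zero-cross-covariance) fit: statistic `2 * (loglik_full -
#' loglik_restricted)` referred to chi-square with 6 degrees of freedom.
#' The tested parameters are covariances (interior points of the parameter
#' space given positive variances), so no boundary correction is applied.
#' A significant result means the three outcomes share cluster- and/or
#' household-level heterogeneity and should be modeled simultaneously.
#'
#' @param full a full [fit_joint()] fit.
#' @param restricted a `restrict_cross = TRUE` fit on the same data and
#'   node count.
#' @param alpha decision level for the note (default 0.05).
#' @return an object of class `lrt_result` with `statistic`, `df`,
#'   `p_value` and `decision_note`.
#' @export
lrt_cross_covariances <- function(full, restricted, alpha = 0.05) {
  stopifnot(inherits(full, "joint_fit"), inherits(restricted, "joint_fit"))
  if (full$restricted || !restricted$restricted)
    stop("need one full and one restricted fit", call. = FALSE)
  if (!identical(full$data_hash, restricted$data_hash))
    stop("fits are not comparable: different complete-case datasets",
         call. = FALSE)
  if (full$quad_nodes != restricted$quad_nodes)
    stop("fits are not comparable: different quadrature node counts",
         call. = FALSE)
  stat <- 2 * (full$loglik - restricted$loglik)
  if (stat < -1e-6)
    warning(sprintf("full fit loglik below restricted by %.2e; check convergence",
                    -stat))
  stat <- max(stat, 0)
  p <- pchisq(stat, df = 6, lower.tail = FALSE)
  note <- if (p < alpha)
    sprintf("joint model preferred (p = %.4g < %g): cross-outcome covariances are jointly nonzero",
            p, alpha)
  else
    sprintf("separate models suffice (p = %.4g >= %g)", p, alpha)
  structure(list(statistic = stat, df = 6L, p_value = p,
                 alpha = alpha, decision_note = note),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT of the 6 cross-outcome covariances: chi2(%d) = %.4f, p = %.4g\n",
              x$df, x$statistic, x$p_value))
  cat(x$decision_note, "\n")
  invisible(x)
}

#' Wald table of estimates, standard errors and p-values
#'
#' Two-sided normal p-values for the regression coefficients; variance
#' (and covariance) components are reported with one-sided p-values
#' (upper tail), since the alternative of interest is positive
#' heterogeneity — a convention, not a boundary-corrected test.  If
#' standard errors are unavailable the p-values are `NA`.
#'
#' @param fit a `separate_fit` or `joint_fit`.
#' @return data frame with columns `term`, `estimate`, `se`, `z`, `p`,
#'   `type` and (for joint fits) `outcome`.
#' @export
wald_table <- function(fit) {
  row <- function(term, est, se, type, outcome = NA) {
    z <- est / se
    p <- if (type == "coefficient") 2 * pnorm(-abs(z)) else pnorm(z, lower.tail = FALSE)
    data.frame(outcome = outcome, term = term, estimate = est, se = se,
               z = z, p = p, type = type, stringsAsFactors = FALSE)
  }
  if (inherits(fit, "separate_fit")) {
    out <- rbind(
      row(names(fit$beta), fit$beta, fit$se_beta, "coefficient",
          fit$outcome),
      row("var(cluster)", fit$var_cluster, fit$se_var_cluster, "variance",
          fit$outcome),
      row("var(household)", fit$var_household, fit$se_var_household,
          "variance", fit$outcome))
    rownames(out) <- NULL
    return(out)
  }
  if (inherits(fit, "joint_fit")) {
    parts <- lapply(1:3, function(q)
      row(names(fit$beta[[q]]), fit$beta[[q]], fit$se_beta[[q]],
          "coefficient", q))
    onames <- c("y1", "y2", "y3")
    for (lev in c("cluster", "household")) {
      S <- if (lev == "cluster") fit$sigma_c else fit$sigma_h
      SE <- if (lev == "cluster") fit$se_sigma_c else fit$se_sigma_h
      for (i in 1:3) for (j in 1:i) {
        nm <- if (i == j) sprintf("var(%s,%s)", lev, onames[i]) else
          sprintf("cov(%s,%s,%s)", lev, onames[i], onames[j])
        typ <- if (i == j) "variance" else "covariance"
        pp <- if (i == j) pnorm(S[i, j] / SE[i, j], lower.tail = FALSE) else
          2 * pnorm(-abs(S[i, j] / SE[i, j]))
        parts[[length(parts) + 1L]] <-
          data.frame(outcome = NA, term = nm, estimate = S[i, j],
                     se = SE[i, j], z = S[i, j] / SE[i, j], p = pp,
                     type = typ, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    return(out)
  }
  stop("fit must be a separate_fit or joint_fit", call. = FALSE)
}
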