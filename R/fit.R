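#' Fit the kinship binomial mixed model at one CpG site
#'
#' Model: `y_i ~ Binomial(r_i, pi_i)` with
#' `logit(pi_i) = W_i alpha + x_i beta + u_i`,
#' `u ~ MVN(0, sigma_g2 * K + sigma_e2 * I)`. The kinship-structured
#' component absorbs family resemblance in methylation; the independent
#' component absorbs extra-binomial overdispersion (the "beta-binomial"
#' behaviour of RRBS counts). Estimation maximizes the Laplace-approximated
#' marginal likelihood in two nested stages. Variance components are
#' estimated by a REML-type Laplace objective (the fixed effects are
#' integrated out by the same Laplace device as the random effects: joint
#' Newton mode plus the full-Hessian log-determinant), which removes the
#' marked downward bias of per-site maximum-likelihood variance estimates
#' at study-scale sample sizes; the outer search is box-constrained
#' quasi-Newton over the two log variances. The fixed effects are then
#' estimated at those variance components by maximizing the Laplace
#' marginal likelihood over them (the log-determinant term's dependence
#' on the fixed effects is kept, so this is a full Laplace fit, not the
#' penalized-quasi-likelihood shortcut). The Wald test on `beta` uses the
#' linearized covariance `(Z' (D^{-1} + Sigma)^{-1} Z)^{-1}` with a t
#' reference on n - p degrees of freedom.
#'
#' @param y methylated counts (length n)
#' @param r total counts (length n, all >= 1)
#' @param x 0/1 predictor vector (length n, not constant)
#' @param K n x n positive-semidefinite relatedness matrix (default
#'   identity)
#' @param W covariate matrix including the intercept column (default
#'   intercept only)
#' @param fix_sigma optional `c(sigma_g2, sigma_e2)` to hold the variance
#'   components fixed instead of estimating them
#' @param control list: `inner_tol` (gradient norm, default 1e-8),
#'   `outer_tol` (log-likelihood, default 1e-6), `max_outer` (default 100)
#' @return list of class `site_fit`: `beta_hat`, `se_beta`, `alpha_hat`,
#'   `sigma_g2_hat`, `sigma_e2_hat`, `p_value`, `loglik`, `converged`,
#'   `n_used`, `message`
#' @export
fit_site <- function(y, r, x, K = NULL, W = NULL, fix_sigma = NULL,
                     control = list()) {
  ctl <- utils::modifyList(
    list(inner_tol = 1e-8, outer_tol = 1e-6, max_outer = 100), control)
  ok <- !is.na(y) & !is.na(r)
  y <- y[ok]; r <- r[ok]; x <- x[ok]
  n <- length(y)
  if (n < 4) return(unfit(n, "fewer than 4 samples with data"))
  if (length(unique(x)) < 2) stop("inestimable effect: predictor constant")
  stopifnot(all(r >= 1), all(y >= 0), all(y <= r))
  if (is.null(W)) W <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  else W <- as.matrix(W)[ok, , drop = FALSE]
  if (is.null(K)) K <- diag(n) else {
    K <- as.matrix(K)
    if (!all(dim(K) == c(length(ok), length(ok))) && !all(dim(K) == c(n, n)))
      stop("K dimension mismatch")
    if (nrow(K) == length(ok)) K <- K[ok, ok, drop = FALSE]
    ev_min <- min(eigen((K + t(K)) / 2, symmetric = TRUE,
                        only.values = TRUE)$values)
    if (ev_min < -1e-8 * max(abs(K))) stop("K is not positive semidefinite")
  }
  Z <- cbind(W, beta = x)
  p_fix <- ncol(Z)
  lchoose_term <- sum(lchoose(r, y))

  pen_loglik <- function(eta, u, Sigma_inv) {
    # stable log(1 + exp(eta))
    l1p <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    sum(y * eta - r * l1p) -
      0.5 * drop(crossprod(u, Sigma_inv %*% u))
  }

  # inner problem: posterior mode of u for fixed (delta, theta), Newton
  inner <- function(offset, Sigma_inv, u) {
    gn <- Inf
    for (it in 1:60) {
      eta <- offset + u
      mu <- 1 / (1 + exp(-eta))
      d1 <- y - r * mu
      g_u <- d1 - drop(Sigma_inv %*% u)
      gn <- sqrt(sum(g_u^2))
      if (gn < ctl$inner_tol) break
      Dw <- pmax(r * mu * (1 - mu), 1e-12)
      H <- Sigma_inv
      diag(H) <- diag(H) + Dw
      step <- tryCatch(solve(H, g_u), error = function(e) NULL)
      if (is.null(step)) return(list(u = u, converged = FALSE))
      f0 <- pen_loglik(eta, u, Sigma_inv)
      s <- 1
      repeat {
        u_new <- u + s * step
        if (pen_loglik(offset + u_new, u_new, Sigma_inv) >= f0 - 1e-12)
          break
        s <- s / 2
        if (s < 1e-8) break
      }
      u <- u_new
    }
    list(u = u, converged = gn < sqrt(ctl$inner_tol))
  }

  # Laplace marginal log-likelihood at (delta, log sigma_g2, log sigma_e2)
  state <- list(u = rep(0, n))
  laplace <- function(delta, log_s) {
    sg2 <- exp(log_s[1]); se2 <- exp(log_s[2])
    Sigma <- sg2 * K + diag(se2 + 1e-10, n)
    Sigma_inv <- tryCatch(chol2inv(chol(Sigma)), error = function(e) NULL)
    if (is.null(Sigma_inv)) return(list(value = -1e10))
    offset <- drop(Z %*% delta)
    fit <- inner(offset, Sigma_inv, state$u)
    if (!fit$converged) return(list(value = -1e10))
    state$u <<- fit$u
    eta <- offset + fit$u
    mu <- 1 / (1 + exp(-eta))
    Dw <- pmax(r * mu * (1 - mu), 1e-12)
    # log det (I + D^{1/2} Sigma D^{1/2}), symmetric PD form
    Ds <- sqrt(Dw)
    M <- diag(n) + (Ds * t(Ds * Sigma))
    ld <- as.numeric(determinant(M, logarithm = TRUE)$modulus)
    ll <- pen_loglik(eta, fit$u, Sigma_inv) + lchoose_term - 0.5 * ld
    list(value = ll, u = fit$u, Sigma = Sigma, Dw = Dw)
  }

  # joint Newton over (delta, u): mode of the penalized log-likelihood,
  # used by the REML-type variance-component objective
  joint_mode <- function(Sigma_inv, delta, u) {
    gn <- Inf
    for (it in 1:60) {
      eta <- drop(Z %*% delta) + u
      mu <- 1 / (1 + exp(-eta))
      d1 <- y - r * mu
      g <- c(crossprod(Z, d1), d1 - drop(Sigma_inv %*% u))
      gn <- sqrt(sum(g^2))
      if (gn < ctl$inner_tol) break
      Dw <- pmax(r * mu * (1 - mu), 1e-12)
      H11 <- crossprod(Z, Z * Dw)
      H12 <- t(Z * Dw)
      H22 <- Sigma_inv
      diag(H22) <- diag(H22) + Dw
      H <- rbind(cbind(H11, H12), cbind(t(H12), H22))
      step <- tryCatch(solve(H, g), error = function(e)
        solve(H + diag(1e-8, nrow(H)), g))
      f0 <- pen_loglik(eta, u, Sigma_inv)
      s <- 1
      repeat {
        dn <- delta + s * step[seq_len(p_fix)]
        un <- u + s * step[-seq_len(p_fix)]
        if (pen_loglik(drop(Z %*% dn) + un, un, Sigma_inv) >= f0 - 1e-12)
          break
        s <- s / 2
        if (s < 1e-8) break
      }
      delta <- dn; u <- un
    }
    list(delta = delta, u = u, converged = gn < sqrt(ctl$inner_tol))
  }

  # REML-type profile objective over the variance components: fixed
  # effects are integrated out by the same Laplace device as the random
  # effects (joint mode plus full-Hessian log-determinant), removing the
  # downward ML bias of per-site variance estimates
  jstate <- list(delta = c(logit_start(y, r), rep(0, p_fix - 1)),
                 u = rep(0, n))
  reml_obj <- function(log_s) {
    sg2 <- exp(log_s[1]); se2 <- exp(log_s[2])
    Sigma <- sg2 * K + diag(se2 + 1e-10, n)
    Sigma_inv <- tryCatch(chol2inv(chol(Sigma)), error = function(e) NULL)
    if (is.null(Sigma_inv)) return(1e10)
    jm <- joint_mode(Sigma_inv, jstate$delta, jstate$u)
    if (!jm$converged) return(1e10)
    jstate <<- jm
    eta <- drop(Z %*% jm$delta) + jm$u
    mu <- 1 / (1 + exp(-eta))
    Dw <- pmax(r * mu * (1 - mu), 1e-12)
    Ds <- sqrt(Dw)
    M <- diag(n) + (Ds * t(Ds * Sigma))
    ld1 <- as.numeric(determinant(M, logarithm = TRUE)$modulus)
    Minv <- chol2inv(chol(M))
    V <- Ds * t(Ds * Minv)            # (D^{-1} + Sigma)^{-1}
    ld2 <- as.numeric(determinant(crossprod(Z, V %*% Z),
                                  logarithm = TRUE)$modulus)
    -(pen_loglik(eta, jm$u, Sigma_inv) - 0.5 * ld1 - 0.5 * ld2)
  }

  delta0 <- c(logit_start(y, r), rep(0, p_fix - 1))
  if (!is.null(fix_sigma)) {
    log_s <- log(pmax(fix_sigma, 1e-10))
    opt_theta_conv <- TRUE
  } else {
    opt_theta <- tryCatch(
      stats::optim(c(log(0.1), log(0.1)), reml_obj, method = "L-BFGS-B",
                   lower = log(1e-6), upper = log(50),
                   control = list(maxit = ctl$max_outer,
                                  factr = ctl$outer_tol / 1e-15)),
      error = function(e) NULL)
    if (is.null(opt_theta) || opt_theta$value >= 1e10)
      return(unfit(n, "variance-component optimization failed"))
    log_s <- opt_theta$par
    opt_theta_conv <- opt_theta$convergence == 0
    delta0 <- jstate$delta
  }

  # fixed effects at the chosen variance components: maximize the Laplace
  # marginal likelihood over delta (log-determinant dependence included)
  best <- NULL
  track <- function(res, par) {
    if (is.null(best) || res$value > best$value) {
      best <<- res
      best$par <<- par
    }
  }
  obj <- function(par) {
    res <- laplace(par, log_s)
    track(res, par)
    -res$value
  }
  opt <- tryCatch(
    stats::optim(delta0, obj, method = "BFGS",
                 control = list(maxit = ctl$max_outer,
                                reltol = ctl$outer_tol / 10)),
    error = function(e) NULL)
  opt_conv <- !is.null(opt) && opt$convergence == 0 && opt_theta_conv
  if (is.null(best) || best$value <= -1e10)
    return(unfit(n, "inner Newton iterations did not converge"))

  delta <- best$par
  Sigma <- best$Sigma
  Dw <- best$Dw
  # Var(delta_hat) = (Z' (D^{-1} + Sigma)^{-1} Z)^{-1}, computed via the
  # stable form D^{1/2} (I + D^{1/2} Sigma D^{1/2})^{-1} D^{1/2}
  Ds <- sqrt(Dw)
  Minv <- chol2inv(chol(diag(n) + (Ds * t(Ds * Sigma))))
  V <- Ds * t(Ds * Minv)   # (D^{-1} + Sigma)^{-1}
  info <- crossprod(Z, V %*% Z)
  cov_delta <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov_delta)) return(unfit(n, "singular information matrix"))
  beta_hat <- unname(delta[p_fix])
  se_beta <- sqrt(cov_delta[p_fix, p_fix])
  # Wald test with a t reference on n - p degrees of freedom: the normal
  # reference is visibly anticonservative at the study's per-group sizes
  pval <- 2 * stats::pt(-abs(beta_hat / se_beta), df = max(n - p_fix, 1))
  sg2 <- if (!is.null(fix_sigma)) fix_sigma[1] else exp(log_s[1])
  se2 <- if (!is.null(fix_sigma)) fix_sigma[2] else exp(log_s[2])
  # estimates at the lower box bound are reported as zero
  if (is.null(fix_sigma)) {
    if (sg2 <= 1.5e-6) sg2 <- 0
    if (se2 <= 1.5e-6) se2 <- 0
  }
  structure(list(beta_hat = beta_hat, se_beta = se_beta,
                 alpha_hat = delta[seq_len(p_fix - 1)],
                 sigma_g2_hat = sg2, sigma_e2_hat = se2,
                 p_value = max(pval, .Machine$double.xmin),
                 loglik = best$value,
                 converged = opt_conv,
                 n_used = n, message = "ok"),
            class = "site_fit")
}

logit_start <- function(y, r) {
  p <- (sum(y) + 0.5) / (sum(r) + 1)
  log(p / (1 - p))
}

unfit <- function(n, msg) {
  structure(list(beta_hat = NA_real_, se_beta = NA_real_,
                 alpha_hat = NA_real_, sigma_g2_hat = NA_real_,
                 sigma_e2_hat = NA_real_, p_value = NA_real_,
                 loglik = NA_real_, converged = FALSE, n_used = n,
                 message = msg),
            class = "site_fit")
}

#' @export
print.site_fit <- function(x, ...) {
  if (!x$converged) {
    cat("site_fit (NOT converged):", x$message, "\n")
  } else {
    cat(sprintf(
      "site_fit: beta = %.4f (se %.4f), p = %.3g, sigma_g2 = %.3f, sigma_e2 = %.3f, n = %d\n",
      x$beta_hat, x$se_beta, x$p_value, x$sigma_g2_hat, x$sigma_e2_hat,
      x$n_used))
  }
  invisible(x)
}

#' Fit the mixed model at every CpG site of a matrix
#'
#' Per-site complete-case analysis: each site is fitted on the samples
#' with data there, with the kinship matrix sub-extracted to those
#' samples. Sites with fewer than 4 informative samples, a constant
#' predictor among them, or a failed fit are flagged unconverged and
#' excluded from downstream FDR.
#'
#' @param mm a filtered [meth_matrix()]
#' @param K relatedness matrix over all samples of `mm` (dimnames must
#'   cover the sample ids); `NULL` for identity
#' @param predictor sample-metadata column used as the 0/1 predictor
#'   (`"group"`: hatchery = 1; `"timepoint"`: age2 = 1; otherwise the
#'   second factor level = 1)
#' @param covariates character vector of additional sample-metadata
#'   columns entered as fixed covariates
#' @param verbose print progress every 500 sites
#' @return data.frame, one row per site: coordinates, `beta_hat`, `se`,
#'   `sigma_g2`, `sigma_e2`, `p_value`, `n_used`, `converged`
#' @export
fit_all <- function(mm, K = NULL, predictor = "group",
                    covariates = character(0), verbose = FALSE) {
  xs <- predictor_indicator(mm$samples, predictor)
  Wall <- matrix(1, n_samples(mm), 1, dimnames = list(NULL, "intercept"))
  for (cv in covariates)
    Wall <- cbind(Wall, predictor_indicator(mm$samples, cv))
  if (!is.null(K)) {
    K <- as.matrix(K)
    if (!is.null(rownames(K)))
      K <- K[mm$samples$sample_id, mm$samples$sample_id]
    else stopifnot(all(dim(K) == n_samples(mm)))
  }
  m <- n_sites(mm)
  out <- vector("list", m)
  for (s in seq_len(m)) {
    y <- mm$meth[s, ]; r <- mm$total[s, ]
    ok <- !is.na(r)
    res <- if (sum(ok) < 4) {
      unfit(sum(ok), "fewer than 4 samples with data")
    } else if (length(unique(xs[ok])) < 2) {
      unfit(sum(ok), "predictor constant among informative samples")
    } else {
      tryCatch(fit_site(y[ok], r[ok], xs[ok],
                        K = if (is.null(K)) NULL else K[ok, ok],
                        W = Wall[ok, , drop = FALSE]),
               error = function(e) unfit(sum(ok), conditionMessage(e)))
    }
    out[[s]] <- data.frame(beta_hat = res$beta_hat, se = res$se_beta,
                           sigma_g2 = res$sigma_g2_hat,
                           sigma_e2 = res$sigma_e2_hat,
                           p_value = res$p_value, n_used = res$n_used,
                           converged = res$converged)
    if (verbose && s %% 500 == 0)
      message(sprintf("fitted %d / %d sites", s, m))
  }
  cbind(mm$sites, do.call(rbind, out))
}

predictor_indicator <- function(samples, column) {
  v <- samples[[column]]
  if (is.null(v)) stop("no sample column '", column, "'")
  if (is.numeric(v)) return(v)
  lev <- switch(column,
                group = c("stream", "hatchery"),
                timepoint = c("age1", "age2"),
                sort(unique(v)))
  as.numeric(factor(v, levels = lev)) - 1
}
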