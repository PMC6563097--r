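# Independent oracles used across the test suite. These deliberately share
# no code with the package implementation.

# --- Gauss-Hermite nodes/weights (Golub-Welsch) -------------------------
gauss_hermite <- function(n) {
  i <- seq_len(n - 1); b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Exact marginal log-likelihood of the correlated-random-effect binomial
# model by adaptive Gauss-Hermite product quadrature over the n-dim random
# effect (grid centered and scaled at the posterior mode).
agh_loglik <- function(delta, y, r, Z, Sigma, nodes = 6) {
  n <- length(y)
  Sigma_inv <- solve(Sigma)
  off <- drop(Z %*% delta)
  logpost <- function(u) {
    eta <- off + u
    sum(y * eta - r * (pmax(eta, 0) + log1p(exp(-abs(eta))))) -
      0.5 * drop(crossprod(u, Sigma_inv %*% u))
  }
  o <- stats::optim(rep(0, n), function(u) -logpost(u), method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-12))
  uhat <- o$par
  p <- stats::plogis(off + uhat)
  H <- Sigma_inv + diag(r * p * (1 - p))
  A <- solve(H)
  C <- t(chol((A + t(A)) / 2))
  gh <- gauss_hermite(nodes)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nodes)), n)))
  zmat <- matrix(gh$x[grid], nrow(grid), n)
  logw <- rowSums(matrix(log(gh$w[grid]), nrow(grid), n)) + rowSums(zmat^2)
  U <- sweep(sqrt(2) * zmat %*% t(C), 2, uhat, `+`)
  Eta <- sweep(U, 2, off, `+`)
  llbin <- drop(Eta %*% y) -
    drop((pmax(Eta, 0) + log1p(exp(-abs(Eta)))) %*% r) + sum(lchoose(r, y))
  ldetS <- as.numeric(determinant(Sigma)$modulus)
  quad <- rowSums((U %*% Sigma_inv) * U)
  logprior <- -0.5 * (n * log(2 * pi) + ldetS + quad)
  tot <- logw + llbin + logprior + n / 2 * log(2) + sum(log(diag(C)))
  mx <- max(tot)
  mx + log(sum(exp(tot - mx)))
}

# ML fit of (alpha, beta) under the exact marginal likelihood, variance
# components fixed
agh_fit <- function(y, r, x, Sigma, nodes = 6) {
  Z <- cbind(1, x)
  start <- c(stats::qlogis((sum(y) + .5) / (sum(r) + 1)), 0)
  o <- stats::optim(start, function(d) -agh_loglik(d, y, r, Z, Sigma, nodes),
                    method = "BFGS", control = list(reltol = 1e-10))
  list(alpha = o$par[1], beta = o$par[2], loglik = -o$value)
}

# Exact overdispersed-binomial regression oracle for the independent case
# (sigma_g2 = 0, K = I): per-observation 1-D Gauss-Hermite integration of
# the logit-normal binomial likelihood, maximized over (alpha, beta,
# log sigma_e2).
lnbin_loglik <- function(par, y, r, x, nodes = 40) {
  alpha <- par[1]; beta <- par[2]; se <- exp(par[3] / 2)
  gh <- gauss_hermite(nodes)
  ll <- 0
  for (i in seq_along(y)) {
    eta <- alpha + beta * x[i] + sqrt(2) * se * gh$x
    li <- y[i] * eta - r[i] * (pmax(eta, 0) + log1p(exp(-abs(eta))))
    mx <- max(li)
    ll <- ll + mx + log(sum(gh$w / sqrt(pi) * exp(li - mx))) +
      lchoose(r[i], y[i])
  }
  ll
}

lnbin_fit <- function(y, r, x) {
  start <- c(stats::qlogis((sum(y) + .5) / (sum(r) + 1)), 0, log(0.1))
  o <- stats::optim(start, function(p) -lnbin_loglik(p, y, r, x),
                    method = "Nelder-Mead",
                    control = list(maxit = 2000, reltol = 1e-12))
  list(alpha = o$par[1], beta = o$par[2], sigma_e2 = exp(o$par[3]))
}

# --- brute-force DMR oracle ---------------------------------------------
# O(n^2) enumeration of criterion-1 windows and criterion-2 window sets,
# merged by overlapping contributing sites (repeated-pass merging).
dmr_oracle <- function(sites, window_bp = 2000, p_thresh = 0.001) {
  out <- NULL
  for (ch in unique(sites$chrom)) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    cand <- list()
    for (i in seq_len(nrow(s))) {
      # criterion 1: window centered on each DMC with p <= thresh
      if (isTRUE(s$is_dmc[i]) && !is.na(s$p_value[i]) &&
          s$p_value[i] <= p_thresh) {
        idx <- which(!is.na(s$p_value) & s$p_value <= p_thresh &
                       abs(s$pos - s$pos[i]) <= window_bp / 2)
        if (length(idx) >= 2)
          cand[[length(cand) + 1]] <- list(idx = idx, crit = "1")
      }
      # criterion 2: every window [pos_i, pos_i + window] of strict
      # sub-threshold sites
      idx2 <- which(!is.na(s$p_value) & s$p_value < p_thresh &
                      s$pos >= s$pos[i] & s$pos <= s$pos[i] + window_bp)
      if (length(idx2) >= 3 && i %in% idx2)
        cand[[length(cand) + 1]] <- list(idx = idx2, crit = "2")
    }
    if (length(cand) == 0) next
    # merge overlapping candidate site-sets until stable
    repeat {
      merged <- FALSE
      for (a in seq_along(cand)) {
        for (b in seq_along(cand)) {
          if (a >= b) next
          if (length(intersect(cand[[a]]$idx, cand[[b]]$idx))) {
            cand[[a]] <- list(idx = sort(union(cand[[a]]$idx, cand[[b]]$idx)),
                              crit = paste(sort(unique(c(cand[[a]]$crit,
                                                         cand[[b]]$crit))),
                                           collapse = "+"))
            cand[[b]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    rows <- do.call(rbind, lapply(cand, function(cc) {
      crit <- if (cc$crit %in% c("1", "2")) cc$crit else "both"
      data.frame(chrom = ch, start = min(s$pos[cc$idx]),
                 stop = max(s$pos[cc$idx]), n_cg = length(cc$idx),
                 criterion = crit)
    }))
    out <- rbind(out, rows[order(rows$start), , drop = FALSE])
  }
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      stop = integer(), n_cg = integer(),
                      criterion = character())
  rownames(out) <- NULL
  out
}
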