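# Small in-code fixture builders shared by the test files.

# meth_matrix from explicit count matrices with minimal metadata
make_mm <- function(meth, total, group = NULL, chrom = "chr1",
                    pos = NULL, family = NULL, timepoint = "age1",
                    tissue = "liver") {
  meth <- as.matrix(meth); total <- as.matrix(total)
  n <- ncol(meth)
  if (is.null(group)) group <- rep(c("stream", "hatchery"), length.out = n)
  if (is.null(pos)) pos <- seq_len(nrow(meth)) * 100L
  if (is.null(family)) family <- "F01"
  meth_matrix(
    sites = data.frame(chrom = chrom, pos = pos, strand = "*"),
    samples = data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                         group = group,
                         timepoint = rep(timepoint, length.out = n),
                         tissue = rep(tissue, length.out = n),
                         family_id = rep(family, length.out = n)),
    meth = meth, total = total)
}

# block-diagonal full-sib kinship: nf families of size fs
sib_kinship <- function(nf, fs) {
  blk <- matrix(0.5, fs, fs); diag(blk) <- 1
  K <- matrix(0, nf * fs, nf * fs)
  for (f in seq_len(nf)) {
    i <- (f - 1) * fs + seq_len(fs)
    K[i, i] <- blk
  }
  K
}

# simulate one site's counts under the model fit_site assumes
sim_site <- function(n, x, mu, beta, sg2, se2, K, cov_mean = 30,
                     cov_size = 5) {
  Sigma <- sg2 * K + se2 * diag(n)
  u <- drop(t(chol(Sigma + diag(1e-9, n))) %*% stats::rnorm(n))
  r <- pmax(stats::rnbinom(n, mu = cov_mean, size = cov_size), 1)
  y <- stats::rbinom(n, r, stats::plogis(mu + beta * x + u))
  list(y = y, r = r)
}

# sim_site conditioned on an interior likelihood optimum: each predictor
# group must carry both methylated and unmethylated reads, otherwise the
# effect estimate diverges (quasi-separation) and comparisons between
# fitters are meaningless
sim_site_interior <- function(n, x, sg2, se2, K, mu_sd = 1,
                              beta_sd = 0.8, ...) {
  repeat {
    sim <- sim_site(n, x, mu = stats::rnorm(1, 0, mu_sd),
                    beta = stats::rnorm(1, 0, beta_sd),
                    sg2 = sg2, se2 = se2, K = K, ...)
    g0 <- x == 0
    if (sum(sim$y[g0]) > 0 && sum(sim$y[g0]) < sum(sim$r[g0]) &&
        sum(sim$y[!g0]) > 0 && sum(sim$y[!g0]) < sum(sim$r[!g0]))
      return(sim)
  }
}

# temporary bismark coverage file from a record data.frame
write_cov_tmp <- function(df) {
  path <- withr::local_tempfile(fileext = ".cov",
                                .local_envir = parent.frame())
  tot <- df$n_meth + df$n_unmeth
  writeLines(paste(df$chrom, df$pos, df$pos,
                   100 * df$n_meth / tot, df$n_meth, df$n_unmeth,
                   sep = "\t"), path)
  path
}
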