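#' Simulation configuration for the split-family rearing design
#'
#' Defaults emulate the study design the package is built around: 22
#' families of steelhead split evenly between a hatchery and a simulated
#' stream rearing environment, parentage resolved with a 95-SNP panel, and
#' RRBS-like per-CpG counts with family-correlated methylation on the logit
#' scale. The methylome baseline profile is tissue-specific: `"liver"`
#' draws a bimodal mixture of mostly low- and high-methylation CpGs with a
#' minority of intermediate sites, `"sperm"` is constitutively
#' hypermethylated (the large majority of sites above 90% methylation).
#'
#' @param n_families number of families (>= 4 so both half-sib pairs exist)
#' @param offspring_per_family offspring sampled per family
#' @param split fraction of each family assigned to the hatchery group
#' @param n_snps SNP panel size for parentage/kinship
#' @param snp_maf_range range of per-SNP minor-allele frequencies
#' @param n_sites number of CpG sites
#' @param frac_effect_sites fraction of sites carrying a treatment effect
#' @param beta_effect absolute logit-scale treatment effect at effect sites
#'   (sign randomized per site)
#' @param sigma_g2 genetic (kinship-structured) variance on the logit scale
#' @param sigma_e2 independent residual variance on the logit scale
#' @param coverage_mean,coverage_dispersion negative-binomial read-depth
#'   model (mean and size); depths are truncated at >= 1
#' @param dropout probability a (site, sample) cell is missing entirely
#' @param tissue_profile `"liver"` or `"sperm"`
#' @param frac_snp_sites fraction of CpG sites whose signal is overridden by
#'   a segregating C/T SNP (methylation ~0, ~0.5, ~1 by genotype)
#' @param predictor which design factor carries the effect: `"group"`
#'   (hatchery vs stream) or `"timepoint"` (age1 vs age2)
#' @param seed integer seed; all outputs are deterministic given the config
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_families = 22, offspring_per_family = 4,
                       split = 0.5, n_snps = 95,
                       snp_maf_range = c(0.2, 0.5),
                       n_sites = 2000, frac_effect_sites = 0.1,
                       beta_effect = 1.0, sigma_g2 = 0.5, sigma_e2 = 0.3,
                       coverage_mean = 30, coverage_dispersion = 5,
                       dropout = 0.05,
                       tissue_profile = c("liver", "sperm"),
                       frac_snp_sites = 0.02,
                       predictor = c("group", "timepoint"),
                       seed = 1) {
  tissue_profile <- match.arg(tissue_profile)
  predictor <- match.arg(predictor)
  stopifnot(n_families >= 1, offspring_per_family >= 1,
            split >= 0, split <= 1,
            length(snp_maf_range) == 2, all(snp_maf_range > 0),
            all(snp_maf_range <= 0.5),
            frac_effect_sites >= 0, frac_effect_sites <= 1,
            frac_snp_sites >= 0, frac_snp_sites <= 1,
            sigma_g2 >= 0, sigma_e2 >= 0,
            dropout >= 0, dropout < 1,
            coverage_mean > 0, coverage_dispersion > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a split-family pedigree
#'
#' All but four families are single-pair matings; one pair of families
#' shares a sire (paternal half sibs) and one pair shares a dam (maternal
#' half sibs), mirroring the mating design the defaults emulate. Each
#' family's offspring are split between the hatchery and stream rearing
#' groups according to `config$split`.
#'
#' @param config a [sim_config()]
#' @return list with `parents` (data.frame id, sex) and `offspring`
#'   (data.frame sample_id, sire, dam, family_id, group)
#' @export
simulate_pedigree <- function(config) {
  nf <- config$n_families
  if (nf >= 4) {
    # families 1,2 share a sire; families 3,4 share a dam
    sires <- paste0("S", c(1, 1, 2, 3, seq_len(max(0, nf - 4)) + 3))
    dams  <- paste0("D", c(1, 2, 3, 3, seq_len(max(0, nf - 4)) + 3))
  } else {
    sires <- paste0("S", seq_len(nf))
    dams <- paste0("D", seq_len(nf))
  }
  fam <- sprintf("F%02d", seq_len(nf))
  k <- config$offspring_per_family
  n_hatch <- round(config$split * k)
  off <- do.call(rbind, lapply(seq_len(nf), function(f) {
    grp <- c(rep("hatchery", n_hatch), rep("stream", k - n_hatch))
    data.frame(sample_id = sprintf("%s_O%d", fam[f], seq_len(k)),
               sire = sires[f], dam = dams[f], family_id = fam[f],
               group = grp)
  }))
  rownames(off) <- NULL
  parents <- data.frame(id = c(unique(sires), unique(dams)),
                        sex = c(rep("M", length(unique(sires))),
                                rep("F", length(unique(dams)))))
  list(parents = parents, offspring = off)
}

#' Simulate SNP genotypes down a pedigree
#'
#' Per-SNP allele frequencies are drawn uniformly from
#' `config$snp_maf_range`; parents are drawn from Hardy-Weinberg
#' proportions and each offspring receives one allele from each parent
#' (standard gene dropping).
#'
#' @param pedigree from [simulate_pedigree()]
#' @param config a [sim_config()]
#' @return list with matrices `parents`, `offspring` (individuals x SNPs,
#'   values 0/1/2) and vector `maf`
#' @export
simulate_genotypes <- function(pedigree, config) {
  set.seed(config$seed + 1L)
  p <- stats::runif(config$n_snps, config$snp_maf_range[1],
                    config$snp_maf_range[2])
  np <- nrow(pedigree$parents)
  gp <- matrix(stats::rbinom(np * config$n_snps, 2, rep(p, each = np)),
               np, config$n_snps,
               dimnames = list(pedigree$parents$id,
                               paste0("snp", seq_len(config$n_snps))))
  off <- pedigree$offspring
  transmit <- function(parent_ids) {
    g <- gp[parent_ids, , drop = FALSE]
    matrix(stats::rbinom(length(g), 1, g / 2), nrow(g), ncol(g))
  }
  go <- transmit(off$sire) + transmit(off$dam)
  dimnames(go) <- list(off$sample_id, colnames(gp))
  list(parents = gp, offspring = go, maf = p)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

draw_mu <- function(n, profile) {
  # baseline (logit-scale) methylation mixture per tissue
  if (profile == "liver") {
    comp <- sample(c("lo", "hi", "mid"), n, replace = TRUE,
                   prob = c(0.35, 0.40, 0.25))
    mu <- numeric(n)
    mu[comp == "lo"] <- stats::rnorm(sum(comp == "lo"), logit(0.05), 0.5)
    mu[comp == "hi"] <- stats::rnorm(sum(comp == "hi"), logit(0.95), 0.5)
    mu[comp == "mid"] <- stats::runif(sum(comp == "mid"),
                                      logit(0.15), logit(0.85))
  } else {
    comp <- sample(c("lo", "hi", "mid"), n, replace = TRUE,
                   prob = c(0.02, 0.94, 0.04))
    mu <- numeric(n)
    mu[comp == "lo"] <- stats::rnorm(sum(comp == "lo"), logit(0.05), 0.5)
    mu[comp == "hi"] <- stats::rnorm(sum(comp == "hi"), logit(0.97), 0.3)
    mu[comp == "mid"] <- stats::runif(sum(comp == "mid"),
                                      logit(0.15), logit(0.85))
  }
  mu
}

#' Simulate RRBS methylation counts under the fitted model
#'
#' Generative mirror of the model [fit_site()] estimates: for site s and
#' individual i, `logit(pi_si) = mu_s + x_i * beta_s + g_si + e_si` with
#' `g_s ~ MVN(0, sigma_g2 * K)` (K the pedigree numerator relationship
#' matrix over the offspring), `e_si ~ N(0, sigma_e2)`, read depth
#' `r_si` zero-truncated negative binomial with independent dropout, and
#' `y_si ~ Binomial(r_si, pi_si)`. A configurable minority of sites is
#' overridden by a segregating C/T SNP whose genotype pins methylation near
#' 0, 0.5 or 1, emulating the artifact the SNP-masking filter removes.
#'
#' @param pedigree from [simulate_pedigree()]
#' @param config a [sim_config()]
#' @return list with `matrix` (a [meth_matrix()]) and `truth` (list:
#'   `sites` data.frame with per-site `mu`, `beta`, `is_effect`, `is_snp`;
#'   `kinship` the pedigree-expected relationship matrix over offspring)
#' @export
simulate_methylation_counts <- function(pedigree, config) {
  set.seed(config$seed + 2L)
  off <- pedigree$offspring
  n <- nrow(off)
  m <- config$n_sites

  if (config$predictor == "timepoint") {
    # cross timepoint with family and group: alternate within family
    off$timepoint <- rep_len(c("age1", "age2"), n)
    x <- as.numeric(off$timepoint == "age2")
  } else {
    off$timepoint <- if (config$tissue_profile == "sperm") "age2" else "age1"
    x <- as.numeric(off$group == "hatchery")
  }
  off$tissue <- config$tissue_profile

  mu <- draw_mu(m, config$tissue_profile)
  n_eff <- round(config$frac_effect_sites * m)
  effect_sites <- if (n_eff > 0) sort(sample.int(m, n_eff)) else integer(0)
  beta <- numeric(m)
  beta[effect_sites] <- config$beta_effect *
    sample(c(-1, 1), n_eff, replace = TRUE)
  n_snp <- round(config$frac_snp_sites * m)
  snp_sites <- if (n_snp > 0) sort(sample.int(m, n_snp)) else integer(0)

  K <- kinship_from_pedigree(rbind(
    data.frame(id = pedigree$parents$id, sire = NA, dam = NA),
    data.frame(id = off$sample_id, sire = off$sire, dam = off$dam)))
  K <- K[off$sample_id, off$sample_id]

  L <- t(chol(K + diag(1e-8, n)))
  eta <- matrix(mu, m, n) + outer(beta, x)
  if (config$sigma_g2 > 0) {
    g <- sqrt(config$sigma_g2) *
      t(L %*% matrix(stats::rnorm(n * m), n, m))
    eta <- eta + g
  }
  if (config$sigma_e2 > 0)
    eta <- eta + matrix(stats::rnorm(m * n, 0, sqrt(config$sigma_e2)), m, n)
  pi <- inv_logit(eta)

  if (n_snp > 0) {
    # C/T SNP overrides the methylation model: T allele always reads
    # unmethylated; genotype CC/CT/TT -> ~1 / ~0.5 / ~0
    snp_maf <- stats::runif(n_snp, 0.1, 0.5)
    geno <- matrix(stats::rbinom(n_snp * n, 2, rep(snp_maf, n)), n_snp, n)
    pi[snp_sites, ] <- c(0.98, 0.5, 0.02)[geno + 1]
  }

  r <- matrix(stats::rnbinom(m * n, mu = config$coverage_mean,
                             size = config$coverage_dispersion), m, n)
  r[r == 0] <- 1  # zero-truncation: every observed cell has >= 1 read
  if (config$dropout > 0) {
    drop <- matrix(stats::runif(m * n) < config$dropout, m, n)
    r[drop] <- NA
  }
  y <- matrix(NA_real_, m, n)
  ok <- !is.na(r)
  y[ok] <- stats::rbinom(sum(ok), r[ok], pi[ok])

  sites <- data.frame(chrom = "chrSim",
                      pos = sort(sample.int(m * 500L, m)),
                      strand = "+")
  samples <- data.frame(sample_id = off$sample_id, group = off$group,
                        timepoint = off$timepoint, tissue = off$tissue,
                        family_id = off$family_id)
  truth_sites <- data.frame(site_index = seq_len(m),
                            chrom = sites$chrom, pos = sites$pos,
                            mu = mu, beta = beta,
                            is_effect = seq_len(m) %in% effect_sites,
                            is_snp = seq_len(m) %in% snp_sites)
  list(matrix = meth_matrix(sites, samples, y, r),
       truth = list(sites = truth_sites, kinship = K))
}

#' Simulate a complete dataset (pedigree, genotypes, counts)
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [simulate_genotypes()] and [simulate_methylation_counts()].
#'
#' @param config a [sim_config()]
#' @return list with `pedigree`, `genotypes`, `matrix`, `truth`
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  ped <- simulate_pedigree(config)
  gen <- simulate_genotypes(ped, config)
  sim <- simulate_methylation_counts(ped, config)
  list(pedigree = ped, genotypes = gen,
       matrix = sim$matrix, truth = sim$truth)
}

#' Write a simulated dataset to disk in the package's external dialects
#'
#' Emits one Bismark-dialect coverage file per sample, a sample sheet CSV,
#' genotype CSVs, and truth tables; everything round-trips losslessly
#' through the corresponding readers.
#'
#' @param dataset from [simulate_dataset()]
#' @param out_dir output directory
#' @param overwrite allow writing into an existing non-empty directory
#' @return `out_dir`, invisibly
#' @export
write_dataset <- function(dataset, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory exists and is non-empty; set overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mm <- dataset$matrix
  for (j in seq_len(n_samples(mm))) {
    obs <- !is.na(mm$total[, j])
    rec <- data.frame(chrom = mm$sites$chrom[obs], pos = mm$sites$pos[obs],
                      n_meth = mm$meth[obs, j],
                      n_unmeth = mm$total[obs, j] - mm$meth[obs, j])
    write_bismark_coverage(
      rec, file.path(out_dir, paste0(mm$samples$sample_id[j], ".cov")))
  }
  ss <- mm$samples
  ss$path <- paste0(ss$sample_id, ".cov")
  utils::write.csv(ss, file.path(out_dir, "sample_sheet.csv"),
                   row.names = FALSE)
  if (!is.null(dataset$genotypes)) {
    utils::write.csv(dataset$genotypes$parents,
                     file.path(out_dir, "genotypes_parents.csv"))
    utils::write.csv(dataset$genotypes$offspring,
                     file.path(out_dir, "genotypes_offspring.csv"))
  }
  if (!is.null(dataset$truth)) {
    ts <- dataset$truth$sites
    # %.17g keeps doubles exactly re-loadable
    ts$mu <- sprintf("%.17g", ts$mu)
    ts$beta <- sprintf("%.17g", ts$beta)
    utils::write.csv(ts, file.path(out_dir, "truth_sites.csv"),
                     row.names = FALSE)
    utils::write.csv(dataset$truth$kinship,
                     file.path(out_dir, "truth_kinship.csv"))
  }
  invisible(out_dir)
}
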