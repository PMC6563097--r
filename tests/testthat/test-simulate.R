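test_that("pedigree has the split-family design with both half-sib pairs", {
  cfg <- sim_config(n_families = 22, offspring_per_family = 4, split = 0.5)
  ped <- simulate_pedigree(cfg)
  off <- ped$offspring
  expect_equal(nrow(off), 88)
  expect_equal(sum(off$group == "hatchery"), 44)
  expect_equal(sum(off$group == "stream"), 44)
  # one shared sire between two families, one shared dam
  fam_sire <- unique(off[, c("family_id", "sire")])
  fam_dam <- unique(off[, c("family_id", "dam")])
  expect_equal(sum(table(fam_sire$sire) == 2), 1)
  expect_equal(sum(table(fam_dam$dam) == 2), 1)

  ped4 <- simulate_pedigree(sim_config(n_families = 4))
  fs <- unique(ped4$offspring[, c("family_id", "sire")])
  fd <- unique(ped4$offspring[, c("family_id", "dam")])
  expect_equal(sum(table(fs$sire) == 2), 1)
  expect_equal(sum(table(fd$dam) == 2), 1)

  all_one <- simulate_pedigree(sim_config(n_families = 5, split = 1.0))
  expect_true(all(all_one$offspring$group == "hatchery"))
})

test_that("gene dropping respects Mendelian transmission", {
  cfg <- sim_config(n_families = 4, offspring_per_family = 3, n_snps = 30,
                    seed = 5)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  gp <- gen$parents; go <- gen$offspring
  for (i in seq_len(nrow(go))) {
    gs <- gp[ped$offspring$sire[i], ]
    gd <- gp[ped$offspring$dam[i], ]
    # impossible combinations never occur
    expect_false(any(go[i, ] == 0 & (gs == 2 | gd == 2)))
    expect_false(any(go[i, ] == 2 & (gs == 0 | gd == 0)))
  }
  # parents 1 x 1 -> offspring 0/1/2 with probabilities 1/4, 1/2, 1/4
  set.seed(99)
  n <- 10000
  het_par <- matrix(1, 2, 2, dimnames = list(c("S1", "D1"), c("a", "b")))
  draws <- replicate(n, {
    a <- rbinom(1, 1, 0.5); b <- rbinom(1, 1, 0.5); a + b
  })
  frq <- tabulate(draws + 1, 3) / n
  expect_true(all(abs(frq - c(.25, .5, .25)) < 3 * sqrt(.25 * .75 / n) + .01))
  # and the simulator reproduces it across many het x het loci
  cfg2 <- sim_config(n_families = 4, offspring_per_family = 50,
                     n_snps = 200, seed = 17)
  ped2 <- simulate_pedigree(cfg2)
  gen2 <- simulate_genotypes(ped2, cfg2)
  het_cells <- which(gen2$parents[ped2$offspring$sire, ] == 1 &
                       gen2$parents[ped2$offspring$dam, ] == 1)
  og <- gen2$offspring[het_cells]
  frq2 <- tabulate(og + 1, 3) / length(og)
  expect_true(all(abs(frq2 - c(.25, .5, .25)) < 0.02))
})

test_that("degenerate methylation model gives a flat 50% methylome", {
  cfg <- sim_config(n_families = 4, offspring_per_family = 4,
                    n_sites = 400, sigma_g2 = 0, sigma_e2 = 0,
                    frac_effect_sites = 0, frac_snp_sites = 0,
                    dropout = 0, seed = 21)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_methylation_counts(ped, cfg)
  # override mu: cannot inject via config, so instead check the pooled
  # proportion matches the pooled mixture expectation is out of reach;
  # use the truth table itself: with sigma terms and beta zero, cellwise
  # proportions should scatter binomially around plogis(mu_s)
  p <- meth_proportions(sim$matrix)
  mu_p <- plogis(sim$truth$sites$mu)
  site_mean <- rowMeans(p)
  r_mean <- rowMeans(sim$matrix$total)
  tol <- 4 * sqrt(mu_p * (1 - mu_p) / (16 * pmax(r_mean, 1)))
  expect_gt(mean(abs(site_mean - mu_p) < tol + 0.02), 0.95)
})

test_that("sperm profile is constitutively hypermethylated, liver bimodal", {
  cfg <- sim_config(n_families = 6, offspring_per_family = 4,
                    n_sites = 10000, tissue_profile = "sperm",
                    frac_effect_sites = 0, frac_snp_sites = 0, seed = 31)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_methylation_counts(ped, cfg)
  frac_high <- mean(rowMeans(meth_proportions(sim$matrix),
                             na.rm = TRUE) >= 0.9)
  expect_gte(frac_high, 0.9)

  cfg_l <- sim_config(n_families = 6, offspring_per_family = 4,
                      n_sites = 5000, tissue_profile = "liver",
                      frac_effect_sites = 0, frac_snp_sites = 0, seed = 31)
  sim_l <- simulate_methylation_counts(ped, cfg_l)
  means_l <- rowMeans(meth_proportions(sim_l$matrix), na.rm = TRUE)
  expect_lt(mean(means_l >= 0.9), 0.55)
  expect_gt(mean(means_l <= 0.2), 0.2)   # a substantial low mode
})

test_that("SNP-contaminated site count matches the configured fraction", {
  cfg <- sim_config(n_families = 4, offspring_per_family = 4,
                    n_sites = 10000, frac_snp_sites = 0.02, seed = 41)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_methylation_counts(ped, cfg)
  expect_equal(sum(sim$truth$sites$is_snp), 200)
  expect_equal(sum(sim$truth$sites$is_effect),
               round(0.1 * cfg$n_sites))
})

test_that("identical config reproduces identical data; truth kinship is the numerator matrix", {
  cfg <- sim_config(n_families = 5, offspring_per_family = 3,
                    n_sites = 60, seed = 77)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$matrix$meth, d2$matrix$meth)
  expect_identical(d1$genotypes$offspring, d2$genotypes$offspring)
  expect_identical(d1$truth$sites, d2$truth$sites)

  K <- d1$truth$kinship
  off <- d1$pedigree$offspring
  same_fam <- outer(off$family_id, off$family_id, `==`)
  diag(same_fam) <- NA
  expect_true(all(K[which(same_fam)] == 0.5))
  expect_true(all(diag(K) == 1))
  # half-sib pairs across families: exactly the two configured pairs
  expect_equal(sort(unique(K[which(!same_fam)])), c(0, 0.25))
})
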