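test_that("pedigree numerator matrix gives the classical coefficients", {
  ped <- data.frame(
    id = c("S", "D", "S2", "c1", "c2", "h1", "g1"),
    sire = c(NA, NA, NA, "S", "S", "S2", "c1"),
    dam = c(NA, NA, NA, "D", "D", "D", NA))
  A <- kinship_from_pedigree(ped)
  expect_equal(A["c1", "c2"], 0.5)     # full sibs
  expect_equal(A["c1", "h1"], 0.25)    # half sibs (shared dam)
  expect_equal(A["S", "c1"], 0.5)      # parent-offspring
  expect_equal(A["S", "g1"], 0.25)     # grandparent-grandchild
  expect_equal(unname(diag(A)), rep(1, 7))
  expect_equal(A["S", "D"], 0)
  expect_true(isSymmetric(A))

  cyc <- data.frame(id = c("a", "b"), sire = c("b", "a"), dam = NA)
  expect_error(kinship_from_pedigree(cyc), "cycle|ancestor")
})

test_that("genomic relationship matrix follows the centered-genotype formula", {
  # 2 individuals, 1 polymorphic SNP, genotypes 0 and 2: p = 0.5,
  # Z = (-1, 1), denominator 2 * 0.25 = 0.5 -> off-diagonal -1*1/0.5 = -2?
  # hand computation: G_12 = (-1)(1)/0.5 = -2 ... recompute: 2*sum(p(1-p))
  # = 0.5, Z1*Z2 = -1 -> -2. With both SNPs? single SNP: -2.
  G <- matrix(c(0, 2), 2, 1, dimnames = list(c("i1", "i2"), "snp1"))
  K <- kinship_from_genotypes(G, stabilize = FALSE)
  expect_equal(K["i1", "i2"], -2)
  expect_equal(K["i1", "i1"], 2)

  # identical genotype vectors: off-diagonal equals each diagonal
  G2 <- rbind(a = c(0, 2, 1, 2), b = c(0, 2, 1, 2),
              c = c(2, 0, 1, 0))
  colnames(G2) <- paste0("s", 1:4)
  K2 <- kinship_from_genotypes(G2, stabilize = FALSE)
  expect_equal(K2["a", "b"], K2["a", "a"])
  expect_equal(K2["a", "b"], K2["b", "b"])

  expect_error(kinship_from_genotypes(matrix(0, 3, 4)), "monomorphic")
})

test_that("PSD stabilization inflates the diagonal minimally", {
  M <- matrix(c(1, 2, 2, 1), 2, 2)   # eigenvalues 3, -1: needs delta = 1
  S <- stabilize_psd(M)
  ev <- eigen(S, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(attr(S, "delta"), 1)
  I2 <- stabilize_psd(diag(2))
  expect_equal(attr(I2, "delta"), 0)
})

test_that("full-sib GRM entries center on 0.5 and track the pedigree matrix", {
  set.seed(2024)
  # 100 independent full-sib pairs, 95 SNPs, MAF U(0.2, 0.5)
  nf <- 100; n_snps <- 95
  p <- runif(n_snps, 0.2, 0.5)
  sibs <- matrix(NA_real_, 2 * nf, n_snps)
  for (f in seq_len(nf)) {
    gs <- rbinom(n_snps, 2, p); gd <- rbinom(n_snps, 2, p)
    for (k in 1:2)
      sibs[2 * (f - 1) + k, ] <- rbinom(n_snps, 1, gs / 2) +
        rbinom(n_snps, 1, gd / 2)
  }
  K <- kinship_from_genotypes(sibs)
  sib_vals <- vapply(seq_len(nf),
                     function(f) K[2 * f - 1, 2 * f], 0)
  expect_gt(mean(sib_vals), 0.4)
  expect_lt(mean(sib_vals), 0.6)
})

test_that("genotype GRM converges to pedigree expectation with panel size", {
  cfg_small <- sim_config(n_families = 12, offspring_per_family = 3,
                          n_snps = 40, seed = 4)
  cfg_large <- sim_config(n_families = 12, offspring_per_family = 3,
                          n_snps = 500, seed = 4)
  ped <- simulate_pedigree(cfg_small)
  A <- kinship_from_pedigree(rbind(
    data.frame(id = ped$parents$id, sire = NA, dam = NA),
    data.frame(id = ped$offspring$sample_id, sire = ped$offspring$sire,
               dam = ped$offspring$dam)))
  A <- A[ped$offspring$sample_id, ped$offspring$sample_id]
  iu <- upper.tri(A)
  cors <- vapply(list(cfg_small, cfg_large), function(cfg) {
    gen <- simulate_genotypes(ped, cfg)
    G <- kinship_from_genotypes(gen$offspring)
    cor(G[iu], A[iu])
  }, 0)
  expect_gt(cors[2], cors[1])
  expect_gt(cors[2], 0.8)
})

test_that("parentage assignment recovers true pairs and counts exclusions", {
  cfg <- sim_config(n_families = 22, offspring_per_family = 4,
                    n_snps = 95, snp_maf_range = c(0.2, 0.5), seed = 8)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  sires <- gen$parents[unique(ped$offspring$sire), , drop = FALSE]
  dams <- gen$parents[unique(ped$offspring$dam), , drop = FALSE]
  pa <- assign_parentage(gen$offspring, sires, dams, error_rate = 0.01)
  correct <- pa$assigned_sire == ped$offspring$sire &
    pa$assigned_dam == ped$offspring$dam
  expect_gte(mean(correct), 0.99)

  # Mendelian impossibility increments the exclusion count
  off <- matrix(2, 1, 5, dimnames = list("o1", paste0("s", 1:5)))
  sire <- matrix(0, 1, 5, dimnames = list("S1", paste0("s", 1:5)))
  dam <- matrix(0, 1, 5, dimnames = list("D1", paste0("s", 1:5)))
  one <- assign_parentage(off, sire, dam)
  expect_equal(one$n_mendelian_mismatches, 5)
  expect_equal(one$assigned_sire, "S1")  # single candidate still assigned

  expect_error(assign_parentage(off, sire[0, , drop = FALSE], dam),
               "no candidate")
})

test_that("true trio out-scores wrong candidates under brute-force likelihood", {
  set.seed(12)
  n_snps <- 40
  p <- runif(n_snps, 0.2, 0.5)
  gs <- rbinom(n_snps, 2, p); gd <- rbinom(n_snps, 2, p)
  go <- rbinom(n_snps, 1, gs / 2) + rbinom(n_snps, 1, gd / 2)
  sires <- rbind(true = gs, w1 = rbinom(n_snps, 2, p),
                 w2 = rbinom(n_snps, 2, p))
  dams <- rbind(true = gd, w3 = rbinom(n_snps, 2, p))
  pa <- assign_parentage(matrix(go, 1, dimnames = list("o")),
                         sires, dams, error_rate = 0.01)
  expect_equal(pa$assigned_sire, "true")
  expect_equal(pa$assigned_dam, "true")
  expect_equal(pa$n_mendelian_mismatches, 0)

  # independent brute-force likelihood for the winning pair
  trans_prob <- function(gs, gd, go) {
    pa_ <- c((2 - gs) / 2, gs / 2); pb <- c((2 - gd) / 2, gd / 2)
    pr <- c(pa_[1] * pb[1], pa_[1] * pb[2] + pa_[2] * pb[1], pa_[2] * pb[2])
    pr[go + 1]
  }
  ll_pair <- function(gs_v, gd_v) {
    sum(log(vapply(seq_len(n_snps), function(j) {
      t0 <- vapply(0:2, function(g) trans_prob(gs_v[j], gd_v[j], g), 0)
      0.99 * t0[go[j] + 1] + 0.005 * (1 - t0[go[j] + 1])
    }, 0)))
  }
  lls <- outer(seq_len(nrow(sires)), seq_len(nrow(dams)),
               Vectorize(function(i, j) ll_pair(sires[i, ], dams[j, ])))
  expect_equal(unname(which(lls == max(lls), arr.ind = TRUE)[1, ]),
               c(1, 1))
  expect_equal(pa$log_likelihood, max(lls), tolerance = 1e-8)
})
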