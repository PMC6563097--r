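test_that("the two DMR criteria fire on their textbook cases", {
  # criterion 2: three sub-threshold CpGs spanning 800 bp
  s <- data.frame(chrom = "chr1", pos = c(100L, 400L, 900L),
                  p_value = 0.0005, is_dmc = FALSE, meth_diff = 0.2)
  d <- call_dmrs(s)
  expect_equal(nrow(d), 1)
  expect_equal(d$criterion, "2")
  expect_equal(d$n_cg, 3)
  expect_equal(d$start, 100)
  expect_equal(d$stop, 900)
  expect_equal(d$dmr_id, "chr1.100.900")
  expect_equal(d$mean_meth_diff, 0.2)

  # criterion 1: a DMC plus one other CpG at p exactly 0.001 (inclusive)
  s1 <- data.frame(chrom = "chr1", pos = c(5000L, 5900L, 8000L),
                   p_value = c(0.0008, 0.001, 0.5),
                   is_dmc = c(TRUE, FALSE, FALSE),
                   meth_diff = c(0.3, 0.1, 0))
  d1 <- call_dmrs(s1)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$criterion, "1")
  expect_equal(d1$n_cg, 2)

  # two sub-threshold CpGs > 2 kb apart, no DMC window: nothing
  s2 <- data.frame(chrom = "chr1", pos = c(100L, 2600L),
                   p_value = 0.0005, is_dmc = FALSE, meth_diff = 0)
  expect_equal(nrow(call_dmrs(s2)), 0)
})

test_that("criterion boundaries: p = 0.001 and span = 2000 bp", {
  # p exactly 0.001 counts for criterion 1 (<=) but not criterion 2 (<)
  s <- data.frame(chrom = "c", pos = c(100L, 200L, 300L),
                  p_value = c(0.001, 0.001, 0.001),
                  is_dmc = FALSE, meth_diff = 0)
  expect_equal(nrow(call_dmrs(s)), 0)   # criterion 2 needs strict <
  s$is_dmc[1] <- TRUE
  d <- call_dmrs(s)                      # criterion 1 accepts <=
  expect_equal(nrow(d), 1)
  expect_equal(d$criterion, "1")
  expect_equal(d$n_cg, 3)

  # span exactly 2000 qualifies for criterion 2
  s2 <- data.frame(chrom = "c", pos = c(100L, 1000L, 2100L),
                   p_value = 5e-4, is_dmc = FALSE, meth_diff = 0)
  d2 <- call_dmrs(s2)
  expect_equal(nrow(d2), 1)
  expect_equal(d2$stop - d2$start, 2000)
  # span 2001 does not
  s3 <- s2; s3$pos[3] <- 2101L
  expect_equal(nrow(call_dmrs(s3)), 0)

  expect_error(call_dmrs(data.frame(chrom = "c", pos = c(200L, 100L),
                                    p_value = 0.5, is_dmc = FALSE)),
               "sorted")
})

test_that("DMR caller agrees with brute-force enumeration on random instances", {
  set.seed(91)
  for (i in 1:300) {
    m <- sample(5:60, 1)
    s <- data.frame(chrom = sample(c("c1", "c2"), m, replace = TRUE),
                    pos = sample.int(12000, m),
                    p_value = round(10^runif(m, -5, 0), 6),
                    meth_diff = round(rnorm(m), 3))
    # sprinkle exact-boundary p-values and positions
    s$p_value[sample(m, min(3, m))] <- 0.001
    s <- s[order(s$chrom, s$pos), ]
    s <- s[!duplicated(paste(s$chrom, s$pos)), ]
    s$is_dmc <- s$p_value < 0.002 & runif(nrow(s)) < 0.5
    got <- call_dmrs(s)
    want <- dmr_oracle(s)
    expect_equal(got[, c("chrom", "start", "stop", "n_cg", "criterion")],
                 want, info = paste("instance", i))
    # invariants
    if (nrow(got)) {
      expect_true(all(got$n_cg >= 2))
      all_sites <- unlist(got$sites)
      expect_equal(anyDuplicated(paste(rep(got$chrom, got$n_cg),
                                       all_sites)), 0)
    }
  }
})

test_that("gene association distances are signed, strand-aware and bounded", {
  genes <- data.frame(gene_id = c("gplus", "gminus"),
                      chrom = "chr1",
                      start = c(20000L, 60000L), end = c(30000L, 70000L),
                      strand = c("+", "-"))
  # DMC 5 kb upstream of the + gene TSS
  up <- data.frame(chrom = "chr1", pos = 15000L)
  a <- annotate_features(up, genes)
  expect_equal(nrow(a), 1)
  expect_equal(a$signed_distance, -5000)
  # inside the gene body
  inside <- annotate_features(data.frame(chrom = "chr1", pos = 25000L), genes)
  expect_equal(inside$signed_distance, 0)
  # 10001 bp away: not associated
  far <- annotate_features(data.frame(chrom = "chr1", pos = 9999L), genes)
  expect_equal(nrow(far), 0)
  # exactly 10000 away: associated
  edge <- annotate_features(data.frame(chrom = "chr1", pos = 10000L), genes)
  expect_equal(edge$signed_distance, -10000)
  # upstream of a minus-strand gene means beyond its end coordinate
  mup <- annotate_features(data.frame(chrom = "chr1", pos = 75000L), genes)
  expect_equal(mup$gene_id, "gminus")
  expect_equal(mup$signed_distance, -5000)
  mdown <- annotate_features(data.frame(chrom = "chr1", pos = 55000L), genes)
  expect_equal(mdown$gene_id, "gminus")
  expect_equal(mdown$signed_distance, 5000)
})

test_that("annotation agrees with a nested-loop oracle on random fixtures", {
  set.seed(14)
  for (i in 1:20) {
    ng <- sample(3:12, 1); nf <- sample(3:15, 1)
    genes <- data.frame(gene_id = paste0("g", seq_len(ng)),
                        chrom = sample(c("c1", "c2"), ng, replace = TRUE),
                        start = sample.int(5e4, ng),
                        strand = sample(c("+", "-"), ng, replace = TRUE))
    genes$end <- genes$start + sample.int(8000, ng)
    feats <- data.frame(chrom = sample(c("c1", "c2"), nf, replace = TRUE),
                        pos = sample.int(6e4, nf))
    got <- annotate_features(feats, genes, window_bp = 10000)
    # oracle: check every (feature, gene) pair
    hits <- 0
    for (fi in seq_len(nf)) for (gi in seq_len(ng)) {
      if (feats$chrom[fi] != genes$chrom[gi]) next
      d <- max(genes$start[gi] - feats$pos[fi],
               feats$pos[fi] - genes$end[gi], 0)
      if (d <= 10000) {
        hits <- hits + 1
        row <- got[got$feature_id ==
                     paste(feats$chrom[fi], feats$pos[fi], feats$pos[fi],
                           sep = ".") &
                     got$gene_id == genes$gene_id[gi], ]
        expect_equal(nrow(row), 1)
        expect_equal(abs(row$signed_distance), d)
      }
    }
    expect_equal(nrow(got), hits)
  }
})

test_that("enrichment applies the min-hits gate and matches hypergeometric tails", {
  bg <- paste0("g", 1:1000)
  fg <- paste0("g", 1:100)
  sets <- list(strong_but_small = paste0("g", 1:2),
               disjoint = paste0("g", 901:950),
               typical = paste0("g", c(1:5, 500:504)))
  res <- enrich_gene_sets(fg, bg, sets)
  r1 <- res[res$set_id == "strong_but_small", ]
  expect_equal(r1$n_hits, 2)
  expect_false(r1$passes)        # p tiny but hits < 3
  r2 <- res[res$set_id == "disjoint", ]
  expect_equal(r2$n_hits, 0)
  expect_equal(r2$p_value, 1)
  r3 <- res[res$set_id == "typical", ]
  expect_equal(r3$n_hits, 5)
  # independent hypergeometric tail: P(X >= 5), set of 10, fg 100 of 1000
  p_or <- sum(dhyper(5:10, 10, 990, 100))
  expect_equal(r3$p_value, p_or, tolerance = 1e-10)
  expect_true(r3$passes)

  expect_error(enrich_gene_sets(c("zzz"), bg, sets), "subset")
})

test_that("BED export converts 1-based inclusive spans to 0-based half-open", {
  dmrs <- data.frame(dmr_id = "c1.100.900", chrom = "c1",
                     start = 100L, stop = 900L, n_cg = 3L,
                     mean_meth_diff = 0.2, criterion = "2")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_dmrs(dmrs, path_bed = bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(fields[2:3]), c(99L, 900L))
  # and a BED gene read back lands on the same internal coordinates
  gbed <- withr::local_tempfile(fileext = ".bed")
  writeLines("c1\t99\t900\tg1\t0\t+", gbed)
  g <- read_gene_models(gbed, "bed")
  expect_equal(c(g$start, g$end), c(100L, 900L))
})

test_that("GMT round trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg9"), path)
  sets <- read_gmt(path)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
})
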