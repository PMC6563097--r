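#' Coverage filter: depth in at least a fraction of samples per group
#'
#' Retains CpG sites where, within each predictor group separately, at
#' least `min_frac` of the samples have total read depth `>= min_depth`.
#' The defaults encode "covered across half of samples at > 10x coverage",
#' i.e. depth strictly greater than 10.
#'
#' @param mm a [meth_matrix()]
#' @param group_col sample-metadata column defining the groups
#' @param min_frac required fraction of samples per group (default 0.5)
#' @param min_depth minimum total count (default 11, i.e. > 10x)
#' @return list `matrix` (filtered), `n_remaining`
#' @export
filter_coverage <- function(mm, group_col = "group",
                            min_frac = 0.5, min_depth = 11) {
  grp <- mm$samples[[group_col]]
  if (is.null(grp)) stop("no sample column '", group_col, "'")
  levels <- if (is.factor(grp)) levels(grp) else unique(grp)
  counts <- tabulate(factor(grp, levels), nbins = length(levels))
  if (length(levels) < 2 || any(counts == 0))
    stop("coverage rule needs >= 2 predictor groups, each with ",
         "at least one sample (a group has zero samples)")
  keep <- rep(TRUE, n_sites(mm))
  for (g in levels) {
    sel <- grp == g
    cov_ok <- !is.na(mm$total[, sel, drop = FALSE]) &
      mm$total[, sel, drop = FALSE] >= min_depth
    keep <- keep & rowMeans(cov_ok) >= min_frac
  }
  list(matrix = mm_subset(mm, sites = keep), n_remaining = sum(keep))
}

#' Low-variance filter
#'
#' Drops sites whose sample variance of methylation proportions (complete
#' cells only) is at or below the `drop_frac` empirical quantile of the
#' per-site variance distribution; ties at the cutoff are dropped
#' together.
#'
#' @param mm a [meth_matrix()]
#' @param drop_frac fraction of the variance distribution to drop
#'   (default 0.05, the lowest 5%)
#' @return list `matrix`, `n_remaining`
#' @export
filter_low_variance <- function(mm, drop_frac = 0.05) {
  if (drop_frac <= 0)
    return(list(matrix = mm, n_remaining = n_sites(mm)))
  p <- meth_proportions(mm)
  v <- apply(p, 1, stats::var, na.rm = TRUE)
  cut <- stats::quantile(v, drop_frac, na.rm = TRUE, names = FALSE, type = 7)
  keep <- !(v <= cut) & !is.na(v)
  list(matrix = mm_subset(mm, sites = keep), n_remaining = sum(keep))
}

#' Extreme-methylation filter
#'
#' Removes sites whose unweighted mean of per-sample methylation
#' proportions is `<= low` (hypo step) and then sites with mean `>= high`
#' (hyper step); both bounds are inclusive. The two steps are reported
#' separately, mirroring the conventional filter-cascade bookkeeping.
#'
#' @param mm a [meth_matrix()]
#' @param low hypo-methylation bound (default 0.10)
#' @param high hyper-methylation bound (default 0.90)
#' @return list `matrix`, `n_after_hypo`, `n_after_hyper`
#' @export
filter_extreme_methylation <- function(mm, low = 0.10, high = 0.90) {
  p <- meth_proportions(mm)
  site_mean <- rowMeans(p, na.rm = TRUE)
  keep1 <- site_mean > low
  mm1 <- mm_subset(mm, sites = keep1)
  site_mean2 <- site_mean[keep1]
  keep2 <- site_mean2 < high
  list(matrix = mm_subset(mm1, sites = keep2),
       n_after_hypo = sum(keep1), n_after_hyper = sum(keep2))
}

#' Mask CpG sites overlapping known C/T SNPs
#'
#' A bisulfite assay cannot distinguish an unconverted C->T variant from
#' an unmethylated cytosine, so any CpG whose position, or the adjacent
#' position `pos + 1` (the G of the dinucleotide, i.e. the C of the
#' opposite strand), carries a known SNP is removed.
#'
#' @param mm a [meth_matrix()]
#' @param snp_positions data.frame with `chrom`, `pos` (as from
#'   [read_snp_sites()])
#' @return list `matrix`, `n_remaining`
#' @export
mask_snp_sites <- function(mm, snp_positions) {
  if (is.null(snp_positions) || nrow(snp_positions) == 0)
    return(list(matrix = mm, n_remaining = n_sites(mm)))
  snp_key <- paste(snp_positions$chrom, snp_positions$pos, sep = ":")
  hit <- paste(mm$sites$chrom, mm$sites$pos, sep = ":") %in% snp_key |
    paste(mm$sites$chrom, mm$sites$pos + 1, sep = ":") %in% snp_key
  list(matrix = mm_subset(mm, sites = !hit), n_remaining = sum(!hit))
}

#' Run the full pre-modelling filter cascade
#'
#' Applies, in order: the per-group coverage filter, the low-variance
#' filter, the hypo- then hyper-methylation filters, and C/T-SNP masking,
#' recording the number of CpG sites remaining after each step.
#'
#' @param mm a [meth_matrix()]
#' @param snp_positions data.frame `chrom`,`pos` of known SNPs (or NULL)
#' @param group_col grouping column for the coverage filter
#' @param min_frac,min_depth coverage-filter parameters
#' @param var_quantile low-variance drop fraction
#' @param low,high extreme-methylation bounds
#' @return list `matrix` (the analysis-ready matrix) and `report`
#'   (data.frame `step`, `threshold`, `n_remaining`)
#' @export
run_cascade <- function(mm, snp_positions = NULL, group_col = "group",
                        min_frac = 0.5, min_depth = 11,
                        var_quantile = 0.05, low = 0.10, high = 0.90) {
  steps <- character(0); thr <- character(0); n_rem <- integer(0)
  rec <- function(name, threshold, n) {
    steps <<- c(steps, name); thr <<- c(thr, threshold)
    n_rem <<- c(n_rem, n)
  }
  f1 <- filter_coverage(mm, group_col, min_frac, min_depth)
  rec("coverage",
      sprintf(">= %dx in >= %.0f%% of samples per group", min_depth,
              100 * min_frac), f1$n_remaining)
  f2 <- filter_low_variance(f1$matrix, var_quantile)
  rec("low_variance", sprintf("lowest %.0f%% of variance dropped",
                              100 * var_quantile), f2$n_remaining)
  f3 <- filter_extreme_methylation(f2$matrix, low, high)
  rec("hypo_methylation", sprintf("mean methylation <= %.0f%%", 100 * low),
      f3$n_after_hypo)
  rec("hyper_methylation", sprintf("mean methylation >= %.0f%%", 100 * high),
      f3$n_after_hyper)
  f4 <- mask_snp_sites(f3$matrix, snp_positions)
  rec("cg_snp", "CpG overlapping known C/T SNP (either strand position)",
      f4$n_remaining)
  report <- data.frame(step = steps, threshold = thr, n_remaining = n_rem)
  list(matrix = f4$matrix, report = report)
}

#' Write a filter report as TSV
#' @param report from [run_cascade()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bisulfite conversion efficiency from non-CpG counts
#'
#' Non-CpG cytosines are essentially unmethylated in vertebrates, so the
#' fraction of non-CpG reads still reporting methylation estimates the
#' bisulfite non-conversion rate; efficiency is its complement:
#' `1 - sum(methylated) / sum(total)`.
#'
#' @param non_cpg data.frame with columns `n_meth`, `n_unmeth` (one row
#'   per non-CpG cytosine observed in a sample)
#' @return efficiency in `[0, 1]`
#' @export
conversion_efficiency <- function(non_cpg) {
  tot <- sum(non_cpg$n_meth) + sum(non_cpg$n_unmeth)
  if (tot == 0) stop("zero total non-CpG reads: efficiency undefined")
  1 - sum(non_cpg$n_meth) / tot
}

#' Compare conversion efficiencies between two batches
#'
#' Welch two-sided t-test of per-sample efficiencies between two batch
#' labels (e.g. sequencing platforms), the standard screen for a batch
#' effect on bisulfite treatment.
#'
#' @param efficiencies numeric per-sample efficiencies
#' @param batch factor/character of two batch labels
#' @return list `t`, `p_value`, `df`, `means`
#' @export
compare_batches <- function(efficiencies, batch) {
  batch <- as.factor(batch)
  if (nlevels(batch) != 2) stop("need exactly two batches")
  tt <- stats::t.test(efficiencies ~ batch)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       means = tapply(efficiencies, batch, mean))
}
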