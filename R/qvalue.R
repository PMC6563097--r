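#' Storey q-values
#'
#' Estimates the null proportion `pi0` on a lambda grid (default 0.05 to
#' 0.95 in steps of 0.05) as `#\{p > lambda\} / (m (1 - lambda))`, smooths
#' the sequence with a cubic smoothing spline and takes the value
#' extrapolated at the largest lambda, bounded into (0, 1]. The q-value of
#' the i-th order statistic is
#' `pi0 * min_{j >= i} (m * p_(j) / j)`, which is monotone non-decreasing
#' in p. With `pi0 = 1` forced, q-values equal Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param p p-values in (0, 1]
#' @param lambda grid for pi0 estimation
#' @param pi0 optionally force the null proportion (e.g. 1)
#' @return list `qvalue` (aligned with `p`), `pi0`
#' @export
qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 2) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  } else {
    stopifnot(pi0 > 0, pi0 <= 1)
  }
  o <- order(p)
  p_sorted <- p[o]
  q_sorted <- pi0 * pmin(rev(cummin(rev(m * p_sorted / seq_len(m)))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  list(qvalue = q, pi0 = pi0)
}

#' Call differentially methylated cytosines (DMCs)
#'
#' A site is a DMC when its q-value is strictly below the FDR threshold
#' (default 10%). The methylation difference is the unweighted mean of
#' per-sample proportions in the predictor-1 group minus the same in the
#' predictor-0 group, on the proportion scale; direction is hyper/hypo
#' with respect to group 1.
#'
#' @param fits data.frame from [fit_all()] (converged rows are used)
#' @param mm the [meth_matrix()] the fits came from
#' @param predictor sample-metadata column defining the two groups
#' @param fdr FDR threshold (default 0.10, strict `<`)
#' @param pi0 optionally force the q-value null proportion
#' @return list `table` (per-site data.frame with `q_value`, `meth_diff`,
#'   `direction`, `is_dmc`), `dmcs` (the called subset), `pi0`,
#'   `n_unconverged`
#' @export
call_dmcs <- function(fits, mm, predictor = "group", fdr = 0.10,
                      pi0 = NULL) {
  stopifnot(nrow(fits) == n_sites(mm))
  conv <- fits$converged & !is.na(fits$p_value)
  qv <- rep(NA_real_, nrow(fits))
  pi0_hat <- NA_real_
  if (any(conv)) {
    qq <- qvalues(fits$p_value[conv], pi0 = pi0)
    qv[conv] <- qq$qvalue
    pi0_hat <- qq$pi0
  }
  x <- predictor_indicator(mm$samples, predictor)
  props <- meth_proportions(mm)
  mean1 <- rowMeans(props[, x == 1, drop = FALSE], na.rm = TRUE)
  mean0 <- rowMeans(props[, x == 0, drop = FALSE], na.rm = TRUE)
  md <- mean1 - mean0
  tab <- cbind(fits,
               data.frame(q_value = qv, meth_diff = md,
                          direction = ifelse(md >= 0, "hyper", "hypo"),
                          is_dmc = !is.na(qv) & qv < fdr))
  list(table = tab, dmcs = tab[tab$is_dmc, , drop = FALSE],
       pi0 = pi0_hat, n_unconverged = sum(!conv))
}

#' Compare two DMC sets for exact and proximal overlap
#'
#' @param dmcs_a,dmcs_b data.frames with `chrom`, `pos`, `meth_diff`
#' @param proximity_bp proximity window (default 10000, inclusive)
#' @return list: `n_exact`, `exact` (data.frame), `n_proximal`,
#'   `proximal` (pairs within the window on the same chromosome,
#'   excluding exact), `n_concordant` (proximal pairs with the same
#'   methylation-difference sign)
#' @export
compare_dmc_sets <- function(dmcs_a, dmcs_b, proximity_bp = 10000) {
  key <- function(d) paste(d$chrom, d$pos, sep = ":")
  exact_keys <- intersect(key(dmcs_a), key(dmcs_b))
  exact <- dmcs_a[key(dmcs_a) %in% exact_keys,
                  c("chrom", "pos"), drop = FALSE]
  prox <- NULL
  if (nrow(dmcs_a) && nrow(dmcs_b)) {
    for (i in seq_len(nrow(dmcs_a))) {
      same <- dmcs_b$chrom == dmcs_a$chrom[i] &
        abs(dmcs_b$pos - dmcs_a$pos[i]) <= proximity_bp &
        dmcs_b$pos != dmcs_a$pos[i]
      if (any(same)) {
        prox <- rbind(prox, data.frame(
          chrom = dmcs_a$chrom[i], pos_a = dmcs_a$pos[i],
          pos_b = dmcs_b$pos[same],
          concordant = sign(dmcs_b$meth_diff[same]) ==
            sign(dmcs_a$meth_diff[i])))
      }
    }
  }
  list(n_exact = length(exact_keys), exact = exact,
       n_proximal = if (is.null(prox)) 0L else nrow(prox),
       proximal = prox,
       n_concordant = if (is.null(prox)) 0L else sum(prox$concordant))
}

#' Write a DMC table as TSV and BED
#'
#' @param table per-site table from [call_dmcs()]
#' @param path_tsv,path_bed output paths (either may be NULL)
#' @return invisibly, the paths written
#' @export
write_dmc_table <- function(table, path_tsv = NULL, path_bed = NULL) {
  if (!is.null(path_tsv))
    utils::write.table(table, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(path_bed)) {
    d <- table[table$is_dmc, , drop = FALSE]
    bed <- data.frame(d$chrom, d$pos - 1, d$pos,
                      paste0("DMC_", d$chrom, "_", d$pos),
                      round(1000 * pmin(abs(d$meth_diff), 1)),
                      ".")
    utils::write.table(bed, path_bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(path_tsv, path_bed))
}
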