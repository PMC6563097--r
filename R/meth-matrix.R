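#' Construct a sites-by-samples methylation count matrix
#'
#' The central container of the package: per-CpG methylated and total read
#' counts for a set of samples, together with site coordinates and sample
#' metadata. Missing cells (site not observed in a sample's coverage file)
#' are `NA` in both count matrices and are distinct from an observed zero;
#' an observed total of zero is invalid input and rejected.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based integer),
#'   `strand` (one of `"+"`, `"-"`, `"*"`). Rows must be sorted by
#'   (chrom, pos); they are sorted here if not.
#' @param samples data.frame of sample metadata with at least `sample_id`
#'   (unique); typically also `group`, `timepoint`, `tissue`, `family_id`.
#' @param meth,total numeric matrices, `nrow(sites)` x `nrow(samples)`;
#'   `NA` marks a missing cell, and `meth <= total` with `total >= 1`
#'   elsewhere.
#' @return An object of class `meth_matrix`.
#' @export
meth_matrix <- function(sites, samples, meth, total) {
  stopifnot(is.data.frame(sites), is.data.frame(samples))
  stopifnot(all(c("chrom", "pos", "strand") %in% names(sites)))
  stopifnot("sample_id" %in% names(samples))
  if (anyDuplicated(samples$sample_id))
    stop("sample_id values must be unique")
  meth <- as.matrix(meth); total <- as.matrix(total)
  if (!all(dim(meth) == c(nrow(sites), nrow(samples))) ||
      !all(dim(total) == c(nrow(sites), nrow(samples))))
    stop("count matrix dimensions do not match sites x samples")
  if (!identical(unname(is.na(meth)), unname(is.na(total))))
    stop("meth and total must share the same missingness pattern")
  ok <- !is.na(total)
  if (any(total[ok] < 1))
    stop("observed cells must have total count >= 1 (missing is NA, not 0)")
  if (any(meth[ok] < 0) || any(meth[ok] > total[ok]))
    stop("need 0 <= meth <= total at every observed cell")
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  meth <- meth[o, , drop = FALSE]
  total <- total[o, , drop = FALSE]
  rownames(sites) <- NULL
  dimnames(meth) <- dimnames(total) <-
    list(site_key(sites), samples$sample_id)
  structure(list(sites = sites, samples = samples,
                 meth = meth, total = total),
            class = "meth_matrix")
}

site_key <- function(sites) paste(sites$chrom, sites$pos, sep = ":")

#' @export
dim.meth_matrix <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Number of CpG sites / samples in a methylation matrix
#' @param x a `meth_matrix`
#' @return integer count
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname n_sites
#' @export
n_samples <- function(x) nrow(x$samples)

#' Per-cell methylation proportions
#'
#' @param x a `meth_matrix`
#' @return numeric matrix of `meth / total`, `NA` where missing.
#' @export
meth_proportions <- function(x) x$meth / x$total

#' Subset a methylation matrix
#'
#' @param x a `meth_matrix`
#' @param sites logical or integer index over site rows
#' @param samples logical or integer index over samples, or character
#'   vector of sample ids
#' @return a `meth_matrix`
#' @export
mm_subset <- function(x, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(x))
  if (is.null(samples)) samples <- seq_len(n_samples(x))
  if (is.character(samples))
    samples <- match(samples, x$samples$sample_id)
  s <- x$samples[samples, , drop = FALSE]
  rownames(s) <- NULL
  meth_matrix(x$sites[sites, , drop = FALSE], s,
              x$meth[sites, samples, drop = FALSE],
              x$total[sites, samples, drop = FALSE])
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d CpG sites x %d samples\n",
              n_sites(x), n_samples(x)))
  miss <- mean(is.na(x$total))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  if ("group" %in% names(x$samples))
    cat("  groups:", paste(sprintf("%s=%d", names(table(x$samples$group)),
                                   table(x$samples$group)), collapse = ", "), "\n")
  invisible(x)
}
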