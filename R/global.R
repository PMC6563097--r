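#' Sample-by-sample distance matrix of global methylation
#'
#' Restricted to sites observed in every sample (complete cases), on
#' per-sample methylation-proportion vectors. The correlation metric is
#' `1 - Pearson r`; the default, as correlation-based distances are the
#' common choice for methylome clustering.
#'
#' @param mm a [meth_matrix()]
#' @param metric `"correlation"` or `"euclidean"`
#' @return a `dist` object labeled by sample id
#' @export
meth_distance <- function(mm, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  p <- meth_proportions(mm)
  complete <- rowSums(is.na(p)) == 0
  if (sum(complete) < 2)
    stop("fewer than 2 complete-case sites: distance undefined")
  p <- p[complete, , drop = FALSE]
  if (metric == "euclidean") {
    d <- stats::dist(t(p), method = "euclidean")
  } else {
    d <- stats::as.dist(1 - stats::cor(p))
  }
  attr(d, "Labels") <- mm$samples$sample_id
  d
}

#' Hierarchical clustering of a sample distance matrix
#'
#' @param d a `dist` object (e.g. from [meth_distance()])
#' @param linkage `"average"` or `"complete"`
#' @return an `hclust` object
#' @export
meth_hclust <- function(d, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  stats::hclust(d, method = linkage)
}

#' Export a dendrogram as a Newick string
#'
#' @param hc an `hclust` object
#' @param path optional file to write to
#' @return the Newick string, invisibly when written to file
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  tr <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(tr))
  ape::write.tree(tr, file = path)
  invisible(ape::write.tree(tr))
}

#' PCA of global methylation
#'
#' Singular value decomposition of the column-centered complete-case
#' proportion matrix (samples x sites).
#'
#' @param mm a [meth_matrix()]
#' @return list `scores` (samples x components), `var_frac`
#'   (non-increasing fractions of variance, summing to <= 1)
#' @export
meth_pca <- function(mm) {
  p <- meth_proportions(mm)
  complete <- rowSums(is.na(p)) == 0
  if (sum(complete) < 2) stop("fewer than 2 complete-case sites")
  X <- t(p[complete, , drop = FALSE])
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  rownames(scores) <- mm$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  var_frac <- sv$d^2 / sum(sv$d^2)
  list(scores = scores, var_frac = var_frac)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of grouping structure in a distance
#' matrix: with all pairwise distances ranked (mean ranks on ties),
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)`
#' where `M = n (n - 1) / 2`. The permutation p-value uses the +1
#' correction, so with 999 permutations the smallest attainable p is
#' 0.001.
#'
#' @param d a `dist` object
#' @param labels group labels (>= 2 groups, each with >= 2 members)
#' @param n_perm number of label permutations (default 999)
#' @param seed integer seed for the permutations
#' @return list of class `anosim_result`: `R`, `p_value`,
#'   `n_permutations`, `seed`, `perm_R`
#' @export
anosim_test <- function(d, labels, n_perm = 999, seed = 1) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  labels <- as.factor(labels)
  stopifnot(length(labels) == n)
  if (nlevels(labels) < 2) stop("need >= 2 groups")
  if (any(table(labels) < 2)) stop("every group needs >= 2 members")
  iu <- which(upper.tri(dm))
  rk <- rank(dm[iu])
  pair_rows <- row(dm)[iu]
  pair_cols <- col(dm)[iu]
  M <- length(rk)
  stat <- function(lab) {
    within <- lab[pair_rows] == lab[pair_cols]
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
  }
  R_obs <- stat(labels)
  # seed the permutations without disturbing the caller's RNG stream
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  perm_R <- vapply(seq_len(n_perm),
                   function(i) stat(sample(labels)), 0)
  p <- (1 + sum(perm_R >= R_obs)) / (1 + n_perm)
  structure(list(R = R_obs, p_value = p, n_permutations = n_perm,
                 seed = seed, perm_R = perm_R),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, p = %.4g (%d permutations)\n",
              x$R, x$p_value, x$n_permutations))
  invisible(x)
}

#' Mean within- vs between-group cophenetic distance
#'
#' Summary used to ask whether clustering recovers a grouping (e.g.
#' families): lower within-group than between-group mean cophenetic
#' distance indicates the dendrogram groups the labels.
#'
#' @param hc an `hclust` object
#' @param labels group labels in the order of `hc$labels`
#' @return list `within`, `between`
#' @export
cophenetic_group_means <- function(hc, labels) {
  cm <- as.matrix(stats::cophenetic(hc))
  iu <- which(upper.tri(cm))
  same <- labels[row(cm)[iu]] == labels[col(cm)[iu]]
  list(within = mean(cm[iu][same]), between = mean(cm[iu][!same]))
}
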