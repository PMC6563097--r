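#' Numerator relationship matrix from a pedigree
#'
#' Standard recursive tabular method: founders have diagonal 1 and
#' off-diagonal 0; full sibs 0.5, half sibs 0.25, parent-offspring 0.5,
#' grandparent-grandchild 0.25 (no inbreeding in the designs emulated
#' here, but the recursion handles it).
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam` (`NA` for
#'   founders). Parents must be listed or referenced consistently; the
#'   pedigree must be acyclic.
#' @return symmetric relationship matrix with `id` dimnames
#' @export
kinship_from_pedigree <- function(pedigree) {
  ids <- as.character(pedigree$id)
  if (anyDuplicated(ids)) stop("duplicate ids in pedigree")
  sire <- as.character(pedigree$sire)
  dam <- as.character(pedigree$dam)
  # add referenced-but-unlisted parents as founders
  extra <- setdiff(stats::na.omit(c(sire, dam)), ids)
  ids <- c(extra, ids)
  sire <- c(rep(NA_character_, length(extra)), sire)
  dam <- c(rep(NA_character_, length(extra)), dam)
  n <- length(ids)
  si <- match(sire, ids)
  di <- match(dam, ids)
  # topological order: parents before offspring
  depth <- rep(NA_integer_, n)
  calc_depth <- function(i, seen = integer(0)) {
    if (i %in% seen) stop("pedigree cycle: individual is its own ancestor")
    if (!is.na(depth[i])) return(depth[i])
    d <- 0L
    for (p in c(si[i], di[i]))
      if (!is.na(p)) d <- max(d, calc_depth(p, c(seen, i)) + 1L)
    depth[i] <<- d
    d
  }
  for (i in seq_len(n)) calc_depth(i)
  ord <- order(depth)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  parent_rel <- function(A, i, p) if (is.na(p)) rep(0, ncol(A)) else A[p, ]
  for (i in ord) {
    s <- si[i]; d <- di[i]
    rel <- (parent_rel(A, i, s) + parent_rel(A, i, d)) / 2
    A[i, ] <- rel
    A[, i] <- rel
    Asd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[i, i] <- 1 + Asd / 2
  }
  A
}

#' Genomic relationship matrix from SNP genotypes
#'
#' Allele-frequency-centered GRM (VanRaden): with genotype matrix `G`
#' (individuals x SNPs, 0/1/2) and estimated allele frequencies `p`,
#' `K = Z Z' / (2 * sum(p * (1 - p)))` where `Z = G - 2p`. Monomorphic
#' SNPs are dropped. The result is stabilized to positive semidefinite by
#' the smallest diagonal inflation `delta` in `{0, 1e-6, 1e-4, ...}` that
#' makes all eigenvalues >= 0 (numerically), since a mixed model requires
#' a valid covariance.
#'
#' @param genotypes matrix individuals x SNPs with values 0/1/2 (`NA`
#'   tolerated; per-SNP mean imputation for centering)
#' @param stabilize apply the PSD diagonal-inflation step (default TRUE)
#' @return symmetric relatedness matrix with individual dimnames
#' @export
kinship_from_genotypes <- function(genotypes, stabilize = TRUE) {
  G <- as.matrix(genotypes)
  stopifnot(nrow(G) >= 2)
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all SNPs monomorphic: relatedness inestimable")
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(G, 2, 2 * p)
  Z[is.na(Z)] <- 0
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  if (stabilize) K <- stabilize_psd(K)
  K
}

#' Minimal diagonal inflation to positive semidefiniteness
#'
#' @param K symmetric matrix
#' @param deltas candidate inflations tried in order; the first yielding
#'   all eigenvalues >= -1e-10 * max(|eigenvalue|) is used
#' @return stabilized matrix with attribute `"delta"`
#' @export
stabilize_psd <- function(K, deltas = c(0, 10^seq(-6, 0, by = 2))) {
  for (d in deltas) {
    Kd <- K + diag(d, nrow(K))
    ev <- eigen(Kd, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) >= -1e-10 * max(abs(ev), 1)) {
      attr(Kd, "delta") <- d
      return(Kd)
    }
  }
  stop("could not stabilize matrix to positive semidefinite")
}

# P(offspring true genotype | sire, dam genotypes): transmission
# probability table; trans[gs+1, gd+1, go+1]
mendel_table <- function() {
  tr <- array(0, c(3, 3, 3))
  gamete <- function(g) c((2 - g) / 2, g / 2)  # P(transmit 0/1 allele)
  for (gs in 0:2) for (gd in 0:2) {
    gs_g <- gamete(gs); gd_g <- gamete(gd)
    for (as in 0:1) for (ad in 0:1)
      tr[gs + 1, gd + 1, as + ad + 1] <-
        tr[gs + 1, gd + 1, as + ad + 1] + gs_g[as + 1] * gd_g[ad + 1]
  }
  tr
}

#' Maximum-likelihood parentage assignment from SNP genotypes
#'
#' Every dam x sire candidate pair is scored for each offspring by the
#' product over SNPs of Mendelian transmission probabilities under a
#' per-genotype error model: the observed offspring genotype equals the
#' true one with probability `1 - error_rate`, otherwise it is uniform
#' over the other two states. The maximum-likelihood pair is returned with
#' its Mendelian exclusion count (SNPs impossible under error-free
#' transmission). Ties on likelihood are broken by exclusion count, then
#' lexicographic parent ids, and flagged.
#'
#' @param offspring_genotypes matrix offspring x SNPs (0/1/2, `NA` skipped)
#' @param sire_genotypes,dam_genotypes candidate-parent genotype matrices
#'   sharing the SNP panel
#' @param error_rate per-genotype error probability (default 0.01)
#' @return data.frame: `offspring_id`, `assigned_dam`, `assigned_sire`,
#'   `n_mendelian_mismatches`, `log_likelihood`, `tie`
#' @export
assign_parentage <- function(offspring_genotypes, sire_genotypes,
                             dam_genotypes, error_rate = 0.01) {
  O <- as.matrix(offspring_genotypes)
  S <- as.matrix(sire_genotypes)
  D <- as.matrix(dam_genotypes)
  if (nrow(S) == 0 || nrow(D) == 0)
    stop("no candidate parent pairs")
  stopifnot(ncol(O) == ncol(S), ncol(O) == ncol(D))
  eps <- error_rate
  tr <- mendel_table()
  n_off <- nrow(O); n_snp <- ncol(O)
  best_ll <- rep(-Inf, n_off)
  best_excl <- rep(NA_integer_, n_off)
  best_pair <- matrix(NA_character_, n_off, 2)
  tie <- rep(FALSE, n_off)
  sire_ids <- rownames(S) %||% paste0("sire", seq_len(nrow(S)))
  dam_ids <- rownames(D) %||% paste0("dam", seq_len(nrow(D)))
  obs_idx <- O + 1L
  for (is in seq_len(nrow(S))) for (id in seq_len(nrow(D))) {
    # per-SNP 3-vector of true-genotype probs for this pair
    tmat <- matrix(0, n_snp, 3)
    for (go in 0:2)
      tmat[, go + 1] <- tr[cbind(S[is, ] + 1L, D[id, ] + 1L, go + 1L)]
    # lik per offspring per SNP: (1-eps)*t[obs] + eps/2*(1-t[obs])
    t_obs <- matrix(tmat[cbind(rep(seq_len(n_snp), each = n_off),
                               c(obs_idx))],
                    n_off, n_snp)
    lik <- (1 - eps) * t_obs + (eps / 2) * (1 - t_obs)
    lik[is.na(O)] <- 1
    ll <- rowSums(log(lik))
    excl <- rowSums(t_obs == 0, na.rm = TRUE)
    better <- ll > best_ll + 1e-9
    equal <- abs(ll - best_ll) <= 1e-9
    tie[equal] <- TRUE
    # tie-break: exclusion count then lexicographic ids
    tb <- equal & (excl < best_excl |
                     (excl == best_excl &
                        paste(dam_ids[id], sire_ids[is]) <
                          paste(best_pair[, 1], best_pair[, 2])))
    upd <- better | (tb %in% TRUE)
    if (any(upd)) {
      best_ll[upd] <- ll[upd]
      best_excl[upd] <- excl[upd]
      best_pair[upd, 1] <- dam_ids[id]
      best_pair[upd, 2] <- sire_ids[is]
    }
    tie[better] <- FALSE
  }
  data.frame(
    offspring_id = rownames(O) %||% paste0("off", seq_len(n_off)),
    assigned_dam = best_pair[, 1], assigned_sire = best_pair[, 2],
    n_mendelian_mismatches = best_excl,
    log_likelihood = best_ll, tie = tie)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
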