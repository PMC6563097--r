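#' Call differentially methylated regions (DMRs)
#'
#' Two windowed criteria over the analyzed CpG sites of one chromosome
#' set:
#' \itemize{
#'   \item Criterion 1: a 2 kb window centered on a DMC (the site itself
#'     must have p <= `p_thresh`) containing two or more CpGs with
#'     p <= `p_thresh` (DMC included).
#'   \item Criterion 2: three or more CpGs with p < `p_thresh` (strict)
#'     whose positional span is at most `window_bp`; maximal such runs are
#'     found by a sorted sweep.
#' }
#' The inclusive bound in criterion 1 versus the strict bound in
#' criterion 2 is deliberate and pinned by tests. Qualifying windows/runs
#' on the same chromosome whose contributing-CpG sets overlap are merged;
#' the reported span is the min..max position of contributing CpGs.
#'
#' @param sites data.frame with `chrom`, `pos`, `p_value`, `is_dmc`, and
#'   optionally `meth_diff`; must be position-sorted within chromosome
#' @param window_bp window width / maximal span (default 2000)
#' @param p_thresh p-value threshold (default 0.001)
#' @return data.frame, one row per DMR: `dmr_id` ("chrom.start.stop"),
#'   `chrom`, `start`, `stop`, `n_cg`, `mean_meth_diff`, `criterion`
#'   ("1", "2" or "both"), `sites` (list column of contributing positions)
#' @export
call_dmrs <- function(sites, window_bp = 2000, p_thresh = 0.001) {
  stopifnot(all(c("chrom", "pos", "p_value", "is_dmc") %in% names(sites)))
  if (is.null(sites$meth_diff)) sites$meth_diff <- NA_real_
  out <- list()
  for (ch in unique(sites$chrom)) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    if (is.unsorted(s$pos)) stop("sites must be sorted by position")
    cand <- list()   # each: list(idx = contributing row indices, crit)
    half <- window_bp / 2
    sub1 <- which(!is.na(s$p_value) & s$p_value <= p_thresh)
    # criterion 1: DMC-centered windows
    for (i in which(s$is_dmc %in% TRUE)) {
      if (is.na(s$p_value[i]) || s$p_value[i] > p_thresh) next
      inwin <- sub1[abs(s$pos[sub1] - s$pos[i]) <= half]
      if (length(inwin) >= 2)
        cand[[length(cand) + 1]] <- list(idx = inwin, crit = "1")
    }
    # criterion 2: maximal runs of strict sub-threshold CpGs, span <= window
    sub2 <- which(!is.na(s$p_value) & s$p_value < p_thresh)
    if (length(sub2) >= 3) {
      pos2 <- s$pos[sub2]
      j <- 1
      for (i in seq_along(sub2)) {
        while (j < length(sub2) && pos2[j + 1] - pos2[i] <= window_bp)
          j <- j + 1
        # maximal: cannot extend left (i == 1 or would exceed span)
        left_max <- i == 1 || pos2[j] - pos2[i - 1] > window_bp
        if (left_max && j - i + 1 >= 3)
          cand[[length(cand) + 1]] <- list(idx = sub2[i:j], crit = "2")
        if (j == length(sub2) && left_max) break
      }
    }
    out[[ch]] <- merge_candidates(cand, s, ch)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(dmr_id = character(), chrom = character(),
                      start = integer(), stop = integer(),
                      n_cg = integer(), mean_meth_diff = numeric(),
                      criterion = character())
  rownames(res) <- NULL
  res
}

merge_candidates <- function(cand, s, ch) {
  if (length(cand) == 0) return(NULL)
  # merge candidates whose contributing-CpG sets overlap (transitively)
  n <- length(cand)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (comp[i] != comp[j] &&
          length(intersect(cand[[i]]$idx, cand[[j]]$idx)) > 0) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  rows <- lapply(unique(comp), function(cc) {
    members <- cand[comp == cc]
    idx <- sort(unique(unlist(lapply(members, `[[`, "idx"))))
    crit <- unique(vapply(members, `[[`, "", "crit"))
    crit <- if (length(crit) == 2) "both" else crit
    data.frame(chrom = ch, start = min(s$pos[idx]), stop = max(s$pos[idx]),
               n_cg = length(idx),
               mean_meth_diff = mean(s$meth_diff[idx]),
               criterion = crit,
               sites = I(list(s$pos[idx])))
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$start), , drop = FALSE]
  cbind(dmr_id = paste(res$chrom, res$start, res$stop, sep = "."), res)
}

#' Associate DMCs/DMRs with genes within a window
#'
#' A feature is associated with every gene whose interval extended by
#' `window_bp` on both sides it intersects. The signed distance is 0 when
#' the feature overlaps the gene body; otherwise it is the strand-aware
#' distance to the nearer gene edge, negative upstream of the
#' transcription start and positive downstream of the transcription end.
#' A distance of exactly `window_bp` counts as associated.
#'
#' @param features data.frame with `chrom`, `start`, `stop` (point
#'   features such as DMCs may use `pos` instead, taken as start = stop)
#'   and an id column `feature_id` (created from coordinates if absent)
#' @param genes data.frame from [read_gene_models()]
#' @param window_bp association window (default 10000)
#' @return data.frame `feature_id`, `gene_id`, `signed_distance`
#' @export
annotate_features <- function(features, genes, window_bp = 10000) {
  f <- features
  if (is.null(f$start) && !is.null(f$pos)) {
    f$start <- f$pos; f$stop <- f$pos
  }
  if (is.null(f$feature_id))
    f$feature_id <- paste(f$chrom, f$start, f$stop, sep = ".")
  out <- list()
  for (i in seq_len(nrow(f))) {
    g <- genes[genes$chrom == f$chrom[i] &
                 genes$start - window_bp <= f$stop[i] &
                 genes$end + window_bp >= f$start[i], , drop = FALSE]
    if (nrow(g) == 0) next
    dist <- numeric(nrow(g))
    for (k in seq_len(nrow(g))) {
      if (f$stop[i] >= g$start[k] && f$start[i] <= g$end[k]) {
        dist[k] <- 0
      } else if (f$stop[i] < g$start[k]) {
        gap <- g$start[k] - f$stop[i]
        dist[k] <- if (g$strand[k] == "-") gap else -gap
      } else {
        gap <- f$start[i] - g$end[k]
        dist[k] <- if (g$strand[k] == "-") -gap else gap
      }
    }
    out[[length(out) + 1]] <- data.frame(
      feature_id = f$feature_id[i], gene_id = g$gene_id,
      signed_distance = dist)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(feature_id = character(), gene_id = character(),
                      signed_distance = numeric())
  rownames(res) <- NULL
  res
}

#' Fisher's exact gene-set enrichment
#'
#' One-sided (enrichment) Fisher's exact test per gene set on the 2x2
#' table of set membership by foreground membership, against the supplied
#' background. A set passes when p < `alpha` and the number of foreground
#' hits is at least `min_hits`.
#'
#' @param foreground character vector of foreground genes (must be a
#'   subset of `background`)
#' @param background character vector of background genes
#' @param gene_sets named list of character vectors; sets are intersected
#'   with the background before testing
#' @param alpha significance level (default 0.05)
#' @param min_hits minimum foreground hits (default 3)
#' @return data.frame: `set_id`, `n_hits`, `n_set`, `n_foreground`,
#'   `n_background`, `odds_ratio`, `p_value`, `passes`
#' @export
enrich_gene_sets <- function(foreground, background, gene_sets,
                             alpha = 0.05, min_hits = 3) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background))
    stop("foreground genes must be a subset of the background")
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(unique(gene_sets[[id]]), background)
    hits <- length(intersect(set, foreground))
    tab <- matrix(c(hits,
                    length(foreground) - hits,
                    length(set) - hits,
                    length(background) - length(foreground) -
                      length(set) + hits), 2, 2)
    ft <- stats::fisher.test(tab, alternative = "greater")
    data.frame(set_id = id, n_hits = hits, n_set = length(set),
               n_foreground = length(foreground),
               n_background = length(background),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               passes = ft$p.value < alpha && hits >= min_hits)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$p_value), , drop = FALSE]
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated: id, description,
#'   genes...
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1)
  sets
}

#' Write DMRs as BED (0-based half-open) and Table-style TSV
#'
#' @param dmrs from [call_dmrs()]
#' @param path_bed,path_tsv output paths (either may be NULL)
#' @param annotations optional data.frame from [annotate_features()] to
#'   merge gene associations into the TSV
#' @return invisibly, the paths written
#' @export
write_dmrs <- function(dmrs, path_bed = NULL, path_tsv = NULL,
                       annotations = NULL) {
  if (!is.null(path_bed)) {
    bed <- data.frame(dmrs$chrom, dmrs$start - 1, dmrs$stop, dmrs$dmr_id)
    utils::write.table(bed, path_bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(path_tsv)) {
    tab <- dmrs[, c("dmr_id", "n_cg", "mean_meth_diff", "criterion")]
    if (!is.null(annotations) && nrow(annotations)) {
      idx <- match(tab$dmr_id, annotations$feature_id)
      tab$gene <- annotations$gene_id[idx]
      tab$distance_to_gene <- annotations$signed_distance[idx]
    }
    utils::write.table(tab, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(path_bed, path_tsv))
}
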