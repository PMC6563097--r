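#' Read a Bismark-style coverage file
#'
#' Parses the 6-column tab-separated coverage dialect emitted by the Bismark
#' methylation extractor: chrom, start, end, percent methylation, methylated
#' count, unmethylated count. The start column is interpreted as the 1-based
#' CpG position; the percent column is ignored on read (recomputed from the
#' counts) but checked for consistency.
#'
#' @param path path to an (uncompressed) coverage file
#' @param sample_id sample identifier attached to the result
#' @return data.frame with columns `chrom`, `pos`, `strand` (always `"*"`;
#'   the dialect carries no strand), `n_meth`, `n_unmeth`, and attribute
#'   `sample_id`.
#' @export
read_bismark_coverage <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), n_meth = integer(),
                      n_unmeth = integer())
    attr(out, "sample_id") <- sample_id
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6))
    stop(sprintf("parse error at line %d of %s: expected >= 6 tab-separated columns",
                 which(nf < 6)[1], path))
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  pct <- suppressWarnings(as.numeric(m[, 4]))
  n_meth <- suppressWarnings(as.numeric(m[, 5]))
  n_unmeth <- suppressWarnings(as.numeric(m[, 6]))
  bad <- which(is.na(pos) | is.na(pct) | is.na(n_meth) | is.na(n_unmeth) |
                 n_meth != round(n_meth) | n_unmeth != round(n_unmeth) |
                 n_meth < 0 | n_unmeth < 0)
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: non-numeric or non-integer fields",
                 bad[1], path))
  tot <- n_meth + n_unmeth
  pct_chk <- ifelse(tot > 0, 100 * n_meth / tot, 0)
  off <- which(tot > 0 & abs(pct_chk - pct) > 0.1)
  if (length(off))
    stop(sprintf("parse error at line %d of %s: %%methylation inconsistent with counts (%.3f vs %.3f)",
                 off[1], path, pct[off[1]], pct_chk[off[1]]))
  zero <- which(tot == 0)
  if (length(zero))
    stop(sprintf("parse error at line %d of %s: zero-total record (missing sites must be absent, not zero)",
                 zero[1], path))
  out <- data.frame(chrom = m[, 1], pos = pos, strand = "*",
                    n_meth = as.integer(n_meth),
                    n_unmeth = as.integer(n_unmeth))
  attr(out, "sample_id") <- sample_id
  out
}

#' Write per-sample coverage records in the Bismark coverage dialect
#'
#' @param records data.frame as returned by [read_bismark_coverage()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bismark_coverage <- function(records, path) {
  tot <- records$n_meth + records$n_unmeth
  pct <- formatC(100 * records$n_meth / tot, digits = 7, format = "g")
  lines <- paste(records$chrom, records$pos, records$pos, pct,
                 records$n_meth, records$n_unmeth, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Assemble per-sample coverage records into a methylation matrix
#'
#' Takes the union of all observed sites across samples; a cell where a
#' sample has no record for a site is marked missing (`NA`), never zero.
#'
#' @param records named list of per-sample record data.frames (as from
#'   [read_bismark_coverage()]); names are sample ids
#' @param samples sample metadata data.frame with a `sample_id` column
#'   covering every list element
#' @return a [meth_matrix()]
#' @export
assemble_matrix <- function(records, samples) {
  stopifnot(length(records) >= 1)
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("records must be a named list keyed by sample_id")
  if (!all(names(records) %in% samples$sample_id))
    stop("every record set needs a matching sample_id in `samples`")
  samples <- samples[match(names(records), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  keys <- lapply(records, function(r) paste(r$chrom, r$pos, sep = ":"))
  for (i in seq_along(records)) {
    if (anyDuplicated(keys[[i]]))
      stop(sprintf("duplicate site %s in sample %s",
                   keys[[i]][duplicated(keys[[i]])][1], names(records)[i]))
  }
  all_sites <- unique(do.call(rbind, lapply(records, function(r)
    data.frame(chrom = r$chrom, pos = r$pos, strand = r$strand))))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), , drop = FALSE]
  rownames(all_sites) <- NULL
  ukey <- paste(all_sites$chrom, all_sites$pos, sep = ":")
  n <- nrow(all_sites)
  meth <- matrix(NA_real_, n, length(records))
  total <- matrix(NA_real_, n, length(records))
  for (i in seq_along(records)) {
    idx <- match(keys[[i]], ukey)
    meth[idx, i] <- records[[i]]$n_meth
    total[idx, i] <- records[[i]]$n_meth + records[[i]]$n_unmeth
  }
  meth_matrix(all_sites, samples, meth, total)
}

#' Read gene models from BED or GFF3
#'
#' Coordinates are normalized to the package-internal 1-based inclusive
#' convention (BED input is 0-based half-open and converted at this
#' boundary).
#'
#' @param path path to the annotation file
#' @param dialect `"bed"` or `"gff3"`
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive)
#' @export
read_gene_models <- function(path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  gr <- if (dialect == "bed") {
    rtracklayer::import(path, format = "BED")
  } else {
    g <- rtracklayer::import(path, format = "GFF3")
    if ("type" %in% names(S4Vectors::mcols(g)) && any(g$type == "gene"))
      g <- g[g$type == "gene"]
    g
  }
  ids <- if (dialect == "bed") {
    if (is.null(gr$name)) paste0("gene", seq_along(gr)) else as.character(gr$name)
  } else {
    if (!is.null(gr$ID)) as.character(gr$ID)
    else if (!is.null(gr$gene_id)) as.character(gr$gene_id)
    else paste0("gene", seq_along(gr))
  }
  out <- data.frame(gene_id = ids,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)))
  if (any(out$start > out$end))
    stop("gene model with start > end after coordinate normalization (zero-length BED interval?)")
  out
}

#' Read SNP positions from a VCF
#'
#' Returns the set of unique (chrom, pos) coordinates carrying a variant
#' record; multiallelic records contribute their position once. Intended
#' for masking CpG sites that overlap a C/T SNP called from bisulfite
#' reads by an external variant caller.
#'
#' @param path path to a VCF 4.x file (plain text or bgzipped)
#' @return data.frame with columns `chrom`, `pos` (unique rows)
#' @export
read_snp_sites <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0)
    return(data.frame(chrom = character(), pos = integer()))
  out <- unique(data.frame(chrom = as.character(fix[, "CHROM"]),
                           pos = as.integer(fix[, "POS"])))
  rownames(out) <- NULL
  out
}

#' Read a sample sheet
#'
#' Headered CSV with columns `sample_id`, `group`, `timepoint`, `tissue`,
#' `family_id`, and optionally `path` (per-sample coverage file).
#'
#' @param path CSV path
#' @return data.frame of sample metadata
#' @export
read_sample_sheet <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "timepoint", "tissue", "family_id")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(s$sample_id)) stop("duplicate sample_id in sample sheet")
  s
}

#' Load a written dataset directory back into memory
#'
#' Counterpart of [write_dataset()]: reads the sample sheet, per-sample
#' coverage files, genotype tables and truth tables.
#'
#' @param dir dataset directory
#' @return list with elements `matrix` (a `meth_matrix`), `samples`,
#'   `genotypes` (list `parents`, `offspring`), and `truth` when present
#' @export
read_dataset <- function(dir) {
  samples <- read_sample_sheet(file.path(dir, "sample_sheet.csv"))
  recs <- lapply(samples$sample_id, function(id)
    read_bismark_coverage(file.path(dir, paste0(id, ".cov")), id))
  names(recs) <- samples$sample_id
  out <- list(matrix = assemble_matrix(recs, samples), samples = samples)
  gp <- file.path(dir, "genotypes_parents.csv")
  go <- file.path(dir, "genotypes_offspring.csv")
  if (file.exists(gp) && file.exists(go)) {
    out$genotypes <- list(
      parents = as.matrix(utils::read.csv(gp, row.names = 1, check.names = FALSE)),
      offspring = as.matrix(utils::read.csv(go, row.names = 1, check.names = FALSE)))
  }
  ts <- file.path(dir, "truth_sites.csv")
  tk <- file.path(dir, "truth_kinship.csv")
  if (file.exists(ts)) {
    truth_sites <- utils::read.csv(ts, stringsAsFactors = FALSE)
    for (col in c("mu", "beta"))
      truth_sites[[col]] <- as.numeric(truth_sites[[col]])
    out$truth <- list(
      sites = truth_sites,
      kinship = if (file.exists(tk))
        as.matrix(utils::read.csv(tk, row.names = 1, check.names = FALSE)))
  }
  out
}
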