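#' Configuration for one differential-methylation contrast
#'
#' The four study contrasts are: immediate and persistent (liver,
#' hatchery vs stream at age-1 resp. age-2), developmental (liver, age-1
#' vs age-2 with rearing group as covariate), and intergenerational
#' (sperm, hatchery vs stream). A developmental-style contrast must use
#' the timepoint predictor with rearing group among the covariates.
#'
#' @param name contrast name (free text; the four canonical names carry
#'   their conventional designs)
#' @param predictor `"group"` or `"timepoint"`
#' @param covariates character vector of extra fixed covariates
#' @param tissue restrict samples to this tissue (NULL = no restriction)
#' @param timepoint restrict samples to this timepoint (NULL = none)
#' @param min_frac,min_depth,var_quantile,low,high filter-cascade
#'   parameters, see [run_cascade()]
#' @param fdr DMC q-value threshold (default 0.10)
#' @param dmr_window_bp,dmr_p_thresh DMR-caller parameters
#' @param annotation_window_bp gene-association window
#' @param seed seed recorded and used for seeded stages (ANOSIM)
#' @return list of class `contrast_config`
#' @export
contrast_config <- function(name, predictor = c("group", "timepoint"),
                            covariates = character(0), tissue = NULL,
                            timepoint = NULL, min_frac = 0.5,
                            min_depth = 11, var_quantile = 0.05,
                            low = 0.10, high = 0.90, fdr = 0.10,
                            dmr_window_bp = 2000, dmr_p_thresh = 0.001,
                            annotation_window_bp = 10000, seed = 1) {
  predictor <- match.arg(predictor)
  if (predictor == "timepoint" && !("group" %in% covariates))
    stop("a timepoint-predictor (developmental) contrast must include ",
         "'group' among its covariates")
  structure(as.list(environment()), class = "contrast_config")
}

#' The four canonical study contrasts
#'
#' @param ... overrides passed to every [contrast_config()] call
#' @return named list of `contrast_config`s
#' @export
default_contrasts <- function(...) {
  list(
    immediate = contrast_config("immediate", predictor = "group",
                                tissue = "liver", timepoint = "age1", ...),
    persistent = contrast_config("persistent", predictor = "group",
                                 tissue = "liver", timepoint = "age2", ...),
    developmental = contrast_config("developmental",
                                    predictor = "timepoint",
                                    covariates = "group",
                                    tissue = "liver", ...),
    intergenerational = contrast_config("intergenerational",
                                        predictor = "group",
                                        tissue = "sperm", ...))
}

#' Run one contrast end to end
#'
#' Selects the contrast's samples, runs the filter cascade, fits the
#' kinship mixed model at every retained site, computes q-values and DMC
#' calls, calls DMRs, annotates DMCs and DMRs against gene models, runs
#' gene-set enrichment, and computes global-pattern statistics. Every
#' parameter is recorded in the run log; identical inputs reproduce
#' identical outputs.
#'
#' @param config a [contrast_config()]
#' @param dataset list with `matrix` (a [meth_matrix()]), and optionally
#'   `kinship` (matrix with sample-id dimnames), `snp_positions`
#'   (data.frame chrom,pos), `genes` (from [read_gene_models()]),
#'   `gene_sets` (named list)
#' @param out_dir optional directory; when given, all tables are written
#'   there as TSV/BED plus a `run_log.txt`
#' @param verbose log progress via `message()`
#' @return list of class `contrast_bundle`: `config`, `filter_report`,
#'   `site_table`, `dmcs`, `dmrs`, `dmc_annotations`, `dmr_annotations`,
#'   `enrichment`, `global` (distance, hclust, newick, pca, anosim),
#'   `analyzed_sites`, `log`
#' @export
run_contrast <- function(config, dataset, out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "contrast_config"))
  mm <- dataset$matrix
  keep <- rep(TRUE, n_samples(mm))
  if (!is.null(config$tissue))
    keep <- keep & mm$samples$tissue == config$tissue
  if (!is.null(config$timepoint))
    keep <- keep & mm$samples$timepoint == config$timepoint
  mm <- mm_subset(mm, samples = keep)
  x <- predictor_indicator(mm$samples, config$predictor)
  if (length(unique(x)) < 2 || min(table(x)) < 4)
    stop("contrast '", config$name,
         "' selects fewer than 4 samples per predictor level")
  logln <- character(0)
  log_add <- function(...) {
    line <- sprintf(...)
    logln <<- c(logln, line)
    if (verbose) message(line)
  }
  log_add("contrast=%s predictor=%s covariates=[%s] samples=%d",
          config$name, config$predictor,
          paste(config$covariates, collapse = ","), n_samples(mm))
  log_add("params min_depth=%d min_frac=%g var_quantile=%g low=%g high=%g fdr=%g dmr_window=%d dmr_p=%g annot_window=%d seed=%d",
          config$min_depth, config$min_frac, config$var_quantile,
          config$low, config$high, config$fdr, config$dmr_window_bp,
          config$dmr_p_thresh, config$annotation_window_bp, config$seed)

  casc <- run_cascade(mm, dataset$snp_positions,
                      group_col = config$predictor,
                      min_frac = config$min_frac,
                      min_depth = config$min_depth,
                      var_quantile = config$var_quantile,
                      low = config$low, high = config$high)
  for (i in seq_len(nrow(casc$report)))
    log_add("filter %s: %d sites remain", casc$report$step[i],
            casc$report$n_remaining[i])
  fm <- casc$matrix

  fits <- fit_all(fm, K = dataset$kinship, predictor = config$predictor,
                  covariates = config$covariates, verbose = verbose)
  log_add("fitted %d sites, %d non-converged", nrow(fits),
          sum(!fits$converged))
  dmc <- call_dmcs(fits, fm, predictor = config$predictor,
                   fdr = config$fdr)
  log_add("pi0=%.3f DMCs=%d", dmc$pi0, nrow(dmc$dmcs))

  dmrs <- call_dmrs(dmc$table, window_bp = config$dmr_window_bp,
                    p_thresh = config$dmr_p_thresh)
  log_add("DMRs=%d", nrow(dmrs))

  dmc_annot <- dmr_annot <- enr <- NULL
  if (!is.null(dataset$genes)) {
    if (nrow(dmc$dmcs))
      dmc_annot <- annotate_features(dmc$dmcs, dataset$genes,
                                     config$annotation_window_bp)
    if (nrow(dmrs))
      dmr_annot <- annotate_features(dmrs, dataset$genes,
                                     config$annotation_window_bp)
    if (!is.null(dataset$gene_sets)) {
      bg_annot <- annotate_features(dmc$table, dataset$genes,
                                    config$annotation_window_bp)
      background <- unique(bg_annot$gene_id)
      foreground <- unique(dmc_annot$gene_id)
      if (length(foreground))
        enr <- enrich_gene_sets(foreground, background,
                                dataset$gene_sets)
      log_add("enrichment: %d foreground genes, %d background genes",
              length(foreground), length(background))
    }
  }

  glob <- tryCatch({
    d <- meth_distance(fm)
    hc <- meth_hclust(d)
    grp_labels <- interaction(mm$samples$group, mm$samples$timepoint,
                              drop = TRUE)
    an <- if (nlevels(grp_labels) >= 2 && all(table(grp_labels) >= 2))
      anosim_test(d, grp_labels, seed = config$seed)
    list(distance = d, hclust = hc, newick = dendrogram_newick(hc),
         pca = meth_pca(fm), anosim = an)
  }, error = function(e) {
    log_add("global patterns skipped: %s", conditionMessage(e))
    NULL
  })

  bundle <- structure(
    list(config = config, filter_report = casc$report,
         site_table = dmc$table, dmcs = dmc$dmcs, dmrs = dmrs,
         dmc_annotations = dmc_annot, dmr_annotations = dmr_annot,
         enrichment = enr, global = glob,
         analyzed_sites = fm$sites, pi0 = dmc$pi0, log = logln),
    class = "contrast_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  write_filter_report(bundle$filter_report, fp("filter_report.tsv"))
  write_dmc_table(bundle$site_table, fp("site_table.tsv"), fp("dmcs.bed"))
  if (nrow(bundle$dmrs))
    write_dmrs(bundle$dmrs, fp("dmrs.bed"), fp("dmrs.tsv"),
               bundle$dmr_annotations)
  if (!is.null(bundle$enrichment))
    utils::write.table(bundle$enrichment, fp("enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$global)) {
    writeLines(bundle$global$newick, fp("dendrogram.nwk"))
    utils::write.table(
      cbind(sample_id = rownames(bundle$global$pca$scores),
            as.data.frame(bundle$global$pca$scores)),
      fp("pca_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(bundle$log, fp("run_log.txt"))
  invisible(out_dir)
}

#' Compare two contrast bundles
#'
#' Reports exact and proximal (<= `proximity_bp`) DMC overlap with
#' direction concordance, plus the fraction of each contrast's DMCs whose
#' sites were analyzed (passed filtering) in the other contrast.
#'
#' @param bundle_a,bundle_b `contrast_bundle`s from [run_contrast()]
#' @param proximity_bp proximity window (default 10000)
#' @return list: `overlap` (from [compare_dmc_sets()]),
#'   `frac_a_analyzed_in_b`, `frac_b_analyzed_in_a`
#' @export
compare_contrasts <- function(bundle_a, bundle_b, proximity_bp = 10000) {
  ov <- compare_dmc_sets(bundle_a$dmcs, bundle_b$dmcs, proximity_bp)
  key <- function(d) paste(d$chrom, d$pos, sep = ":")
  frac_in <- function(dmcs, sites) {
    if (nrow(dmcs) == 0) return(NA_real_)
    mean(key(dmcs) %in% key(sites))
  }
  list(overlap = ov,
       frac_a_analyzed_in_b = frac_in(bundle_a$dmcs,
                                      bundle_b$analyzed_sites),
       frac_b_analyzed_in_a = frac_in(bundle_b$dmcs,
                                      bundle_a$analyzed_sites))
}
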