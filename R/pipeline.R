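#' Pipeline configuration
#'
#' Collects every stage's parameters with the analysis defaults: QC
#' thresholds (40,000 reads, 80% stitched, 70% aligned, 50% saturation,
#' 1,000 NTC counts, 5%/10% LOQ detection), fold-change 1.5 at FDR 5% for
#' differential expression, |rho| > 0.8 at FDR 1% with |dZ| >= 1.4 for
#' differential correlation, and FDR 5% for the drug screen. Unknown keys
#' are rejected.
#'
#' @param spatial a [spatial_sim_config()] describing the spatial input.
#' @param thresholds a [qc_thresholds()].
#' @param fc_threshold,dgea_fdr differential-expression thresholds.
#' @param diffcorr_rho_min,diffcorr_fdr,diffcorr_min_dz,diffcorr_n_perm
#'   differential-correlation thresholds and permutation count.
#' @param drug_fdr drug-screen FDR.
#' @param seed global seed (stage seeds are derived from it).
#' @param ... rejected; catches misspelled keys.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(spatial = NULL,
                            thresholds = qc_thresholds(),
                            fc_threshold = 1.5, dgea_fdr = 0.05,
                            diffcorr_rho_min = 0.8, diffcorr_fdr = 0.01,
                            diffcorr_min_dz = 1.4, diffcorr_n_perm = 1000,
                            drug_fdr = 0.05, seed = 1L, ...) {
  extra <- list(...)
  if (length(extra) > 0)
    stop("unknown pipeline_config key(s): ",
         paste(names(extra), collapse = ", "))
  if (is.null(spatial)) {
    spatial <- spatial_sim_config(
      planted_signature = data.frame(gene = sprintf("g%04d", 1:28),
                                     fold = 2.5),
      seed = seed)
  }
  structure(list(spatial = spatial, thresholds = thresholds,
                 fc_threshold = fc_threshold, dgea_fdr = dgea_fdr,
                 diffcorr_rho_min = diffcorr_rho_min,
                 diffcorr_fdr = diffcorr_fdr,
                 diffcorr_min_dz = diffcorr_min_dz,
                 diffcorr_n_perm = diffcorr_n_perm,
                 drug_fdr = drug_fdr, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_stage <- function(manifest, stage, files, params) {
  sums <- tools::md5sum(unlist(files))
  names(sums) <- basename(names(sums))  # manifest independent of out_dir
  manifest[[stage]] <- list(outputs = as.list(sums), parameters = params)
  manifest
}

#' Run the end-to-end pipeline on simulated data
#'
#' Executes simulate -> QC (segment filters, LOQ filters, Q3 normalization,
#' case-level aggregation) -> the six bud contrasts -> signature derivation
#' -> scoring and ROC -> enrichment -> differential correlation ->
#' survival/drug evaluation, writing each stage's tables under `out_dir`
#' and a machine-readable JSON manifest with parameters and MD5 checksums.
#' Re-running with an identical config reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed)
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # simulate
  spatial <- step("simulate", generate_spatial(config$spatial))
  f_counts <- file.path(out_dir, "counts_raw.tsv")
  write_matrix_tsv(spatial$counts, f_counts)
  f_meta <- file.path(out_dir, "segment_metadata.tsv")
  utils::write.table(spatial$meta, f_meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- write_stage(manifest, "simulate", c(f_counts, f_meta),
                          list(seed = config$spatial$seed,
                               n_genes = config$spatial$n_genes))

  # qc
  qc <- step("qc", {
    fs <- filter_segments(spatial, config$thresholds)
    post <- filter_by_loq(fs$kept, thresholds = config$thresholds)
    norm <- q3_normalize(post)
    cases <- aggregate_case_level(norm, post$meta)
    list(report = fs$report, post = post, norm = norm, cases = cases)
  })
  f_qc <- file.path(out_dir, "qc_report.tsv")
  utils::write.table(qc$report, f_qc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_norm <- file.path(out_dir, "counts_q3.tsv")
  write_matrix_tsv(qc$norm, f_norm)
  manifest <- write_stage(manifest, "qc", c(f_qc, f_norm),
                          unclass(config$thresholds))

  # dgea + signature
  contrasts <- bud_contrasts(config$fc_threshold, config$dgea_fdr)
  tables <- step("dgea", lapply(contrasts, function(ct)
    run_contrast(qc$cases, ct)))
  dgea_files <- vapply(names(tables), function(nm) {
    f <- file.path(out_dir, paste0("dgea_", nm, ".tsv"))
    utils::write.table(tables[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  }, character(1))
  manifest <- write_stage(manifest, "dgea", dgea_files,
                          list(fc_threshold = config$fc_threshold,
                               fdr = config$dgea_fdr))
  sig <- step("signature", derive_signature(tables))
  if (is.null(sig$up))
    stop("pipeline stage 'signature' failed: empty up-signature")
  f_sig <- file.path(out_dir, "signature_up.txt")
  write_signature(sig$up, f_sig)
  manifest <- write_stage(manifest, "signature",
                          c(f_sig, paste0(f_sig, ".json")),
                          list(n_up = length(sig$up$genes)))

  # scoring + ROC on the spatial segments
  seg_scores <- step("score", score_signature(qc$norm, sig$up))
  is_bud <- qc$post$meta$segment_type[
    match(rownames(qc$norm), qc$post$meta$segment_id)] == "bud"
  roc <- step("score", roc_auc(seg_scores, is_bud))
  f_scores <- file.path(out_dir, "segment_scores.tsv")
  utils::write.table(
    data.frame(segment_id = names(seg_scores),
               score = as.numeric(seg_scores), is_bud = is_bud),
    f_scores, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- write_stage(manifest, "score", f_scores,
                          list(auc = roc$auc))

  # enrichment against a simulated catalog planted with the signature
  catalog <- step("enrich", generate_geneset_catalog(
    colnames(qc$norm), n_sets = 30, planted_set = sig$up$genes,
    planted_set_size = min(100, ncol(qc$norm) %/% 2),
    set_size_range = c(10, 60), seed = config$seed + 1L))
  enr <- step("enrich", enrich(sig$up$genes, catalog))
  f_enr <- file.path(out_dir, "enrichment.tsv")
  utils::write.table(enr, f_enr, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- write_stage(manifest, "enrich", f_enr,
                          list(n_sets = length(catalog)))

  # differential correlation: buds vs budding bulk, tumor compartment,
  # restricted to the signature genes plus a background sample for speed
  dc <- step("diffcorr", {
    a <- qc$cases[["bud.tumor"]]
    b <- qc$cases[["bulk_budding.tumor"]]
    genes <- sig$up$genes
    bg <- setdiff(colnames(a), genes)
    set.seed(config$seed + 2L)
    genes <- c(genes, sample(bg, min(30, length(bg))))
    pr <- compartment_pairing(a[, genes, drop = FALSE],
                              b[, genes, drop = FALSE])
    ca <- condition_correlations(pr, "a")
    cb <- condition_correlations(pr, "b")
    cand <- candidate_pairs(ca, cb, config$diffcorr_rho_min,
                            config$diffcorr_fdr)
    if (nrow(cand) == 0) {
      list(edges = NULL)
    } else {
      ed <- permutation_test(pr, cand, n_perm = config$diffcorr_n_perm,
                             seed = config$seed + 3L)
      list(edges = select_differential(ed, config$diffcorr_fdr,
                                       config$diffcorr_min_dz),
           all_edges = ed)
    }
  })
  f_dc <- file.path(out_dir, "diffcorr_edges.tsv")
  ed_out <- if (is.null(dc$edges)) {
    data.frame(gene_a = character(), gene_b = character())
  } else dc$edges
  utils::write.table(ed_out, f_dc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- write_stage(manifest, "diffcorr", f_dc,
                          list(rho_min = config$diffcorr_rho_min,
                               fdr = config$diffcorr_fdr,
                               min_dz = config$diffcorr_min_dz,
                               n_perm = config$diffcorr_n_perm))

  # evaluation on a simulated survival cohort + drug panel scored with the
  # derived signature
  eval_out <- step("evaluate", {
    cohort_cfg <- cohort_sim_config(n_samples = 300, true_hr = 1.5,
                                    seed = config$seed + 4L)
    bulk <- generate_bulk_survival(cohort_cfg, sig$up)
    bscore <- score_signature(bulk$expr, sig$up)
    labels <- classify(bscore, stats::median(bscore))
    cohort <- bulk$cohort
    cohort$score_high <- as.integer(labels == "high")
    cox <- cox_model(cohort, "score_high")
    km <- km_logrank(cohort, labels)
    panel <- generate_drug_panel(
      effect_map = c(cmpd001 = -0.8), signature = sig$up,
      seed = config$seed + 5L)
    pscore <- score_signature(panel$expr, sig$up)
    screen <- drug_screen(pscore, panel$lfc, fdr = config$drug_fdr)
    list(cox = cox, km_p = km$p, screen = screen)
  })
  f_cox <- file.path(out_dir, "cox_terms.tsv")
  utils::write.table(eval_out$cox, f_cox, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_screen <- file.path(out_dir, "drug_screen.tsv")
  utils::write.table(eval_out$screen, f_screen, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- write_stage(manifest, "evaluate", c(f_cox, f_screen),
                          list(km_logrank_p = eval_out$km_p))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
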