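#' Segment QC thresholds
#'
#' Default values follow GeoMx whole-transcriptome practice: at least 40,000
#' deduplicated reads per segment, 80% of reads successfully stitched, 70%
#' aligned, 50% sequencing saturation, and at most 1,000 counts in the
#' non-template control; segments detecting fewer than 5% of genes above
#' their own LOQ and genes detected above LOQ in fewer than 10% of segments
#' are removed. All comparisons are inclusive at the boundary.
#'
#' @param min_reads minimum deduplicated reads per segment.
#' @param min_stitched minimum stitched-read fraction.
#' @param min_aligned minimum aligned-read fraction.
#' @param min_saturation minimum sequencing saturation.
#' @param max_ntc maximum non-template-control counts.
#' @param min_gene_detect_frac_per_segment minimum fraction of genes a
#'   segment must detect above its LOQ.
#' @param min_segment_detect_frac_per_gene minimum fraction of segments in
#'   which a gene must be detected above LOQ.
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_reads = 40000,
                          min_stitched = 0.80,
                          min_aligned = 0.70,
                          min_saturation = 0.50,
                          max_ntc = 1000,
                          min_gene_detect_frac_per_segment = 0.05,
                          min_segment_detect_frac_per_gene = 0.10) {
  th <- list(min_reads = min_reads, min_stitched = min_stitched,
             min_aligned = min_aligned, min_saturation = min_saturation,
             max_ntc = max_ntc,
             min_gene_detect_frac_per_segment = min_gene_detect_frac_per_segment,
             min_segment_detect_frac_per_gene = min_segment_detect_frac_per_gene)
  if (any(unlist(th) <= 0)) stop("all QC thresholds must be strictly positive")
  structure(th, class = "qc_thresholds")
}

#' Limit of quantification from negative-control probes
#'
#' The LOQ of a segment is `max(2, NegGeoMean * NegGeoSD^2)`: two geometric
#' standard deviations above the geometric mean of the segment's
#' negative-control probe counts, clamped below at 2 counts. Zero counts are
#' floored to 0.5 before taking logs, since the geometric mean is undefined
#' at zero; strictly positive counts are used as-is. The geometric SD is the
#' multiplicative factor `exp(sd(log(counts)))` (natural log; the base
#' cancels in this definition).
#'
#' @param neg_counts nonnegative counts of the negative-control probes for
#'   one segment (length >= 2).
#' @param segment_id optional id used in error messages.
#' @return A list with `neg_geo_mean`, `neg_geo_sd`, and `loq`.
#' @export
compute_loq <- function(neg_counts, segment_id = NULL) {
  if (length(neg_counts) < 2) {
    stop("at least 2 negative-control probes are required",
         if (!is.null(segment_id)) paste0(" (segment ", segment_id, ")"))
  }
  if (any(neg_counts < 0)) stop("negative-probe counts must be nonnegative")
  lx <- log(pmax(neg_counts, 0.5))
  gm <- exp(mean(lx))
  gsd <- exp(stats::sd(lx))
  list(neg_geo_mean = gm, neg_geo_sd = gsd, loq = max(2, gm * gsd^2))
}

# per-segment LOQ table for a segment_counts object
loq_table <- function(x) {
  neg <- x$probes$probe_id[x$probes$is_negative_control]
  if (length(neg) < 2) stop("at least 2 negative-control probes are required")
  recs <- lapply(rownames(x$counts), function(s) {
    r <- compute_loq(x$counts[s, neg], segment_id = s)
    data.frame(segment_id = s, neg_geo_mean = r$neg_geo_mean,
               neg_geo_sd = r$neg_geo_sd, loq = r$loq)
  })
  do.call(rbind, recs)
}

#' Filter segments on sequencing QC metrics
#'
#' A segment is kept iff every metric passes its threshold (inclusive at the
#' boundary): `raw_reads >= min_reads`, `stitched_frac >= min_stitched`,
#' `aligned_frac >= min_aligned`, `saturation_frac >= min_saturation`, and
#' `ntc_count <= max_ntc`. Missing metrics are an error, never a silent pass.
#'
#' @param x a [segment_counts()] object.
#' @param thresholds a [qc_thresholds()] list.
#' @return A list with `kept` (the filtered `segment_counts`) and `report`
#'   (a data.frame with one row per input segment and a logical column per
#'   criterion plus overall `pass`).
#' @export
filter_segments <- function(x, thresholds = qc_thresholds()) {
  m <- x$meta
  metrics <- c("raw_reads", "stitched_frac", "aligned_frac",
               "saturation_frac", "ntc_count")
  missing <- setdiff(metrics, names(m))
  if (length(missing) > 0)
    stop("missing QC metrics in segment metadata: ",
         paste(missing, collapse = ", "))
  if (anyNA(m[metrics]))
    stop("NA QC metric for segment(s): ",
         paste(m$segment_id[!stats::complete.cases(m[metrics])], collapse = ", "))
  report <- data.frame(
    segment_id = m$segment_id,
    min_reads = m$raw_reads >= thresholds$min_reads,
    min_stitched = m$stitched_frac >= thresholds$min_stitched,
    min_aligned = m$aligned_frac >= thresholds$min_aligned,
    min_saturation = m$saturation_frac >= thresholds$min_saturation,
    max_ntc = m$ntc_count <= thresholds$max_ntc
  )
  crit <- c("min_reads", "min_stitched", "min_aligned", "min_saturation", "max_ntc")
  report$pass <- Reduce(`&`, report[crit])
  report$fail_reasons <- apply(report[crit], 1L,
                               function(r) paste(crit[!r], collapse = ";"))
  kept_ids <- report$segment_id[report$pass]
  if (length(kept_ids) == 0) stop("segment QC removed every segment")
  list(kept = subset_segments(x, segments = kept_ids), report = report)
}

#' LOQ-based segment and gene filtering
#'
#' Applies the two detection filters on raw counts, in fixed order: first
#' segments detecting fewer than `min_gene_detect_frac_per_segment` of the
#' genes at or above their own LOQ are dropped; then genes detected at or
#' above LOQ in fewer than `min_segment_detect_frac_per_gene` of the
#' remaining segments are dropped. Detection is inclusive
#' (`count >= LOQ`). Negative-control probes are excluded from the gene
#' universe and from the returned matrix.
#'
#' @param x a [segment_counts()] object.
#' @param loq optional precomputed LOQ table (`segment_id`, `loq`); computed
#'   from the negative probes when `NULL`.
#' @param thresholds a [qc_thresholds()] list.
#' @return A `segment_counts` object restricted to the kept segments and
#'   kept (non-negative-control) genes, with the LOQ table attached as
#'   attribute `"loq"`.
#' @export
filter_by_loq <- function(x, loq = NULL, thresholds = qc_thresholds()) {
  if (is.null(loq)) loq <- loq_table(x)
  if (!all(rownames(x$counts) %in% loq$segment_id))
    stop("need one LOQ record per segment")
  loqv <- loq$loq[match(rownames(x$counts), loq$segment_id)]
  genes <- x$probes$probe_id[!x$probes$is_negative_control]
  gc <- x$counts[, genes, drop = FALSE]
  detected <- gc >= loqv  # recycles loq down rows: segments x genes
  seg_frac <- rowMeans(detected)
  keep_seg <- seg_frac >= thresholds$min_gene_detect_frac_per_segment
  if (!any(keep_seg)) stop("LOQ segment filter removed every segment")
  gene_frac <- colMeans(detected[keep_seg, , drop = FALSE])
  keep_gene <- gene_frac >= thresholds$min_segment_detect_frac_per_gene
  if (!any(keep_gene)) stop("LOQ gene filter removed every gene")
  out <- subset_segments(x, segments = rownames(gc)[keep_seg],
                         probes = genes[keep_gene])
  attr(out, "loq") <- loq
  out
}

#' Upper-quartile (Q3) normalization
#'
#' Each segment is rescaled so that its 75th-percentile gene count equals the
#' geometric mean of all segments' raw 75th percentiles. Percentiles use
#' linear interpolation between order statistics (R's default quantile
#' type 7). The operation is idempotent: normalizing an already-normalized
#' matrix returns it unchanged.
#'
#' @param x a [segment_counts()] object (negative probes already removed) or
#'   a plain numeric matrix, samples x genes.
#' @return An [expression_matrix()] tagged `"q3"`.
#' @export
q3_normalize <- function(x) {
  m <- if (inherits(x, "segment_counts")) {
    if (any(x$probes$is_negative_control))
      stop("remove negative-control probes (filter_by_loq) before normalization")
    x$counts
  } else as.matrix(x)
  q3 <- apply(m, 1L, stats::quantile, probs = 0.75, names = FALSE)
  if (any(q3 <= 0))
    stop("zero upper quartile for segment(s): ",
         paste(rownames(m)[q3 <= 0], collapse = ", "))
  target <- exp(mean(log(q3)))
  expression_matrix(m * (target / q3), normalization = "q3")
}

#' Aggregate normalized segments to case level
#'
#' For each case, the arithmetic mean of the normalized counts is taken over
#' the segments sharing the same `(segment_type, compartment)` group; the
#' result is one case x gene matrix per group. Cases lacking a group are
#' simply absent from that group's matrix.
#'
#' @param norm an [expression_matrix()] (rows = segment ids).
#' @param meta segment metadata with `segment_id`, `case_id`, `segment_type`,
#'   `compartment`.
#' @return A named list of case x gene matrices; names are
#'   `"<segment_type>.<compartment>"`.
#' @export
aggregate_case_level <- function(norm, meta) {
  if (!all(rownames(norm) %in% meta$segment_id))
    stop("metadata missing for some segments")
  meta <- meta[match(rownames(norm), meta$segment_id), , drop = FALSE]
  grp <- paste(meta$segment_type, meta$compartment, sep = ".")
  out <- lapply(split(seq_len(nrow(norm)), grp), function(idx) {
    case <- meta$case_id[idx]
    sub <- norm[idx, , drop = FALSE]
    agg <- rowsum(sub, group = case) / as.vector(table(case)[sort(unique(case))])
    agg[sort(rownames(agg)), , drop = FALSE]
  })
  lapply(out, function(m) expression_matrix(m, normalization = norm_tag(norm)))
}

#' Single-cell preprocessing: cell filters and log-normalization
#'
#' Applies the standard droplet QC filters — cells with fewer than
#' `min_genes` detected genes, more than `max_genes` detected genes, or more
#' than `max_mito_frac` of total UMIs from mitochondrial genes are excluded —
#' then removes genes expressed in fewer than `min_cell_frac` of the
#' remaining cells, and log-normalizes: each cell's counts are divided by the
#' cell total, multiplied by `scale_factor`, and transformed with
#' `log(1 + x)` (natural log, matching the LogNormalize convention).
#'
#' @param umi UMI count matrix, genes x cells (dense or `Matrix` sparse).
#' @param cell_meta optional data.frame with a `cell_id` column matching the
#'   matrix columns; filtered in step with the cells.
#' @param mito_prefix character prefixes identifying mitochondrial genes.
#' @param min_genes,max_genes detected-gene bounds per cell.
#' @param max_mito_frac maximum mitochondrial UMI fraction per cell.
#' @param min_cell_frac minimum fraction of kept cells expressing a gene.
#' @param scale_factor library-size scale factor.
#' @return A list with `mat` (an [expression_matrix()], cells x genes, tagged
#'   `"lognorm_sc"`), `meta` (filtered metadata or `NULL`), and `report`
#'   (named counts of cells/genes removed per filter, plus `mito_skipped`).
#' @export
sc_preprocess <- function(umi, cell_meta = NULL, mito_prefix = "MT-",
                          min_genes = 200, max_genes = 8000,
                          max_mito_frac = 0.10, min_cell_frac = 0.001,
                          scale_factor = 1e4) {
  umi <- methods::as(Matrix::Matrix(umi, sparse = TRUE), "CsparseMatrix")
  if (is.null(rownames(umi)) || is.null(colnames(umi)))
    stop("UMI matrix needs gene rownames and cell colnames")
  detected <- Matrix::colSums(umi > 0)
  totals <- Matrix::colSums(umi)
  mito <- grepl(paste0("^(", paste(mito_prefix, collapse = "|"), ")"),
                rownames(umi))
  mito_skipped <- FALSE
  if (!any(mito)) {
    warning("no mitochondrial genes matched prefix; mito filter skipped")
    mito_frac <- rep(0, ncol(umi))
    mito_skipped <- TRUE
  } else {
    mito_frac <- Matrix::colSums(umi[mito, , drop = FALSE]) / pmax(totals, 1)
  }
  low <- detected < min_genes
  high <- detected > max_genes
  himito <- mito_frac > max_mito_frac
  keep_cell <- !(low | high | himito)
  if (!any(keep_cell)) stop("cell filters removed every cell")
  kept <- umi[, keep_cell, drop = FALSE]
  expr_frac <- Matrix::rowSums(kept > 0) / ncol(kept)
  keep_gene <- expr_frac >= min_cell_frac
  kept <- kept[keep_gene, , drop = FALSE]
  tot <- Matrix::colSums(kept)
  if (any(tot == 0)) stop("cell with zero counts after gene filtering")
  lognorm <- log1p(t(t(as.matrix(kept)) / tot) * scale_factor)
  if (!is.null(cell_meta)) {
    cell_meta <- cell_meta[match(colnames(kept), cell_meta$cell_id), ,
                           drop = FALSE]
    rownames(cell_meta) <- NULL
  }
  list(mat = expression_matrix(t(lognorm), normalization = "lognorm_sc"),
       meta = cell_meta,
       report = list(n_low_genes = sum(low), n_high_genes = sum(high),
                     n_high_mito = sum(himito), n_cells_kept = sum(keep_cell),
                     n_genes_dropped = sum(!keep_gene),
                     n_genes_kept = sum(keep_gene),
                     mito_skipped = mito_skipped))
}
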