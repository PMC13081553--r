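#' Segment-level count matrix with probe annotation and segment metadata
#'
#' Bundles the three tables a GeoMx-style digital spatial profiling run
#' produces after deduplication: an integer count matrix (segments in rows,
#' probes in columns), a probe annotation marking negative-control probes,
#' and per-segment metadata carrying the design labels and sequencing QC
#' metrics.
#'
#' @param counts integer matrix, segments x probes; rownames are segment ids,
#'   colnames are probe ids.
#' @param probes data.frame with columns `probe_id`, `gene_symbol`,
#'   `is_negative_control`.
#' @param meta data.frame with one row per segment: `segment_id`, `case_id`,
#'   `run_id`, `roi_id`, `segment_type`, `compartment`, `raw_reads`,
#'   `stitched_frac`, `aligned_frac`, `saturation_frac`, `ntc_count`.
#' @return An object of class `segment_counts`.
#' @export
segment_counts <- function(counts, probes, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have segment ids as rownames and probe ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate segment ids in counts")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  need <- c("probe_id", "gene_symbol", "is_negative_control")
  if (!all(need %in% names(probes)))
    stop("probe annotation must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe ids in annotation")
  if (!setequal(probes$probe_id, colnames(counts)))
    stop("probe annotation does not match count matrix columns")
  probes <- probes[match(colnames(counts), probes$probe_id), , drop = FALSE]
  rownames(probes) <- NULL
  if (!"segment_id" %in% names(meta))
    stop("segment metadata must have a segment_id column")
  if (!setequal(meta$segment_id, rownames(counts)))
    stop("segment metadata does not match count matrix rows")
  meta <- meta[match(rownames(counts), meta$segment_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, probes = probes, meta = meta),
            class = "segment_counts")
}

#' @export
print.segment_counts <- function(x, ...) {
  cat(sprintf("segment_counts: %d segments x %d probes (%d negative controls)\n",
              nrow(x$counts), ncol(x$counts), sum(x$probes$is_negative_control)))
  invisible(x)
}

#' @export
dim.segment_counts <- function(x) dim(x$counts)

# subset a segment_counts by segment ids and/or probe ids
subset_segments <- function(x, segments = NULL, probes = NULL) {
  if (is.null(segments)) segments <- rownames(x$counts)
  if (is.null(probes)) probes <- colnames(x$counts)
  segment_counts(x$counts[segments, probes, drop = FALSE],
                 x$probes[x$probes$probe_id %in% probes, , drop = FALSE],
                 x$meta[x$meta$segment_id %in% segments, , drop = FALSE])
}

#' Tag a numeric matrix as an expression matrix
#'
#' Expression matrices are plain numeric matrices (samples x genes) carrying a
#' `normalization` attribute that downstream scoring uses to decide whether
#' values are already on a log scale.
#'
#' @param values numeric matrix, samples x genes.
#' @param normalization one of `"raw"`, `"q3"`, `"lognorm_sc"`, `"log2"`.
#' @return The matrix with a `normalization` attribute, class
#'   `expression_matrix`.
#' @export
expression_matrix <- function(values,
                              normalization = c("raw", "q3", "lognorm_sc", "log2")) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("expression values must be finite")
  structure(values, normalization = normalization,
            class = c("expression_matrix", "matrix", "array"))
}

norm_tag <- function(x) {
  tag <- attr(x, "normalization")
  if (is.null(tag)) "raw" else tag
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d samples x %d genes\n",
              norm_tag(x), nrow(x), ncol(x)))
  invisible(x)
}

#' Define a gene signature
#'
#' @param name signature name.
#' @param genes character vector of unique gene symbols.
#' @param direction `"up"` or `"down"`: how the genes move in the condition
#'   the signature marks.
#' @param provenance optional character vector recording the contrasts the
#'   signature was derived from.
#' @return An object of class `signature_def`.
#' @export
signature_def <- function(name, genes, direction = c("up", "down"),
                          provenance = character()) {
  direction <- match.arg(direction)
  genes <- as.character(genes)
  if (length(genes) == 0) stop("signature must contain at least one gene")
  if (anyDuplicated(genes)) stop("signature genes must be unique")
  structure(list(name = name, genes = genes, direction = direction,
                 provenance = provenance),
            class = "signature_def")
}

#' @export
print.signature_def <- function(x, ...) {
  cat(sprintf("signature_def '%s' (%s): %d genes\n",
              x$name, x$direction, length(x$genes)))
  invisible(x)
}
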