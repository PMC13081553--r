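#' Define a differential-expression contrast
#'
#' A contrast compares two `(segment_type, compartment)` groups of the
#' case-level matrices. Paired contrasts (within-tumor comparisons) use the
#' Wilcoxon signed-rank test over cases contributing both groups; unpaired
#' contrasts (between-tumor comparisons) use the rank-sum test.
#'
#' @param name contrast label.
#' @param group_a,group_b length-2 character vectors
#'   `c(segment_type, compartment)`; fold changes are a over b.
#' @param paired logical; pairing unit is the case.
#' @param fc_threshold fold-change threshold on the ratio scale (a gene is
#'   differential only if `|log2 FC| > log2(fc_threshold)`, strict).
#' @param fdr Benjamini-Hochberg FDR level.
#' @return list of class `contrast_spec`.
#' @export
contrast_spec <- function(name, group_a, group_b, paired,
                          fc_threshold = 1.5, fdr = 0.05) {
  stopifnot(length(group_a) == 2, length(group_b) == 2,
            is.logical(paired), fc_threshold > 0, fdr > 0, fdr < 1)
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 paired = paired, fc_threshold = fc_threshold, fdr = fdr),
            class = "contrast_spec")
}

#' The six bud-versus-everything contrasts used for signature derivation
#'
#' Paired: buds against adjacent stroma, against budding tumor bulk, and
#' against the stroma adjacent to budding bulk (all within budding cases).
#' Unpaired: buds against non-budding tumor bulk, against the stroma
#' adjacent to non-budding bulk, and against the pooled immune segments.
#'
#' @param fc_threshold,fdr thresholds passed to every [contrast_spec()].
#' @return named list of six `contrast_spec`s.
#' @export
bud_contrasts <- function(fc_threshold = 1.5, fdr = 0.05) {
  mk <- function(name, b, paired)
    contrast_spec(name, c("bud", "tumor"), b, paired, fc_threshold, fdr)
  list(
    bud_vs_stroma_bud = mk("bud_vs_stroma_bud", c("stroma_bud", "stroma"), TRUE),
    bud_vs_bulk_budding = mk("bud_vs_bulk_budding", c("bulk_budding", "tumor"), TRUE),
    bud_vs_stroma_bulk_budding =
      mk("bud_vs_stroma_bulk_budding", c("stroma_bulk_budding", "stroma"), TRUE),
    bud_vs_bulk_nonbudding =
      mk("bud_vs_bulk_nonbudding", c("bulk_nonbudding", "tumor"), FALSE),
    bud_vs_stroma_bulk_nonbudding =
      mk("bud_vs_stroma_bulk_nonbudding", c("stroma_bulk_nonbudding", "stroma"), FALSE),
    bud_vs_immune = mk("bud_vs_immune", c("immune", "immune"), FALSE)
  )
}

group_key <- function(g) paste(g[1], g[2], sep = ".")

# Exact two-sided signed-rank p by enumeration of all sign assignments,
# using midranks so tied |differences| are handled; used for small paired
# samples where wilcox.test would fall back to the normal approximation.
signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-9)
}

#' Run one Wilcoxon contrast on case-level matrices
#'
#' Per gene, a Wilcoxon test (signed-rank over complete case pairs when
#' `paired`, rank-sum otherwise) on the case-level normalized values, with
#' Benjamini-Hochberg adjustment across all genes tested in the contrast.
#' The fold change is the ratio of per-group arithmetic means with a
#' pseudocount added to both means; a gene is called `up`/`down` only when
#' `q <= fdr` and `|log2 FC| > log2(fc_threshold)` (strict).
#'
#' @param case_matrices named list of case x gene matrices as produced by
#'   [aggregate_case_level()] (names `"<segment_type>.<compartment>"`).
#' @param contrast a [contrast_spec()].
#' @param pseudocount added to both group means before the ratio.
#' @param min_cases minimum cases per group (unpaired) or complete pairs
#'   (paired).
#' @return data.frame of class `dgea_table`: `gene`, `mean_a`, `mean_b`,
#'   `log2_fc`, `p`, `q`, `direction`; the contrast is attached as attribute.
#' @export
run_contrast <- function(case_matrices, contrast, pseudocount = 1,
                         min_cases = 3) {
  ka <- group_key(contrast$group_a); kb <- group_key(contrast$group_b)
  if (!ka %in% names(case_matrices) || !kb %in% names(case_matrices))
    stop("contrast '", contrast$name, "': group matrices not found (",
         ka, ", ", kb, ")")
  a <- case_matrices[[ka]]; b <- case_matrices[[kb]]
  genes <- intersect(colnames(a), colnames(b))
  a <- a[, genes, drop = FALSE]; b <- b[, genes, drop = FALSE]
  if (contrast$paired) {
    cases <- intersect(rownames(a), rownames(b))
    if (length(cases) < min_cases)
      stop("contrast '", contrast$name, "': fewer than ", min_cases,
           " complete case pairs")
    a <- a[cases, , drop = FALSE]; b <- b[cases, , drop = FALSE]
    p <- vapply(genes, function(g) {
      d <- a[, g] - b[, g]
      ties <- anyDuplicated(abs(d[d != 0])) > 0
      if (ties && sum(d != 0) <= 14) {
        signed_rank_exact_p(d)
      } else {
        suppressWarnings(stats::wilcox.test(a[, g], b[, g],
                                            paired = TRUE)$p.value)
      }
    }, numeric(1))
  } else {
    if (nrow(a) < min_cases || nrow(b) < min_cases)
      stop("contrast '", contrast$name, "': fewer than ", min_cases,
           " cases in a group")
    p <- vapply(genes, function(g) {
      suppressWarnings(stats::wilcox.test(a[, g], b[, g],
                                          exact = NULL)$p.value)
    }, numeric(1))
  }
  p[is.nan(p)] <- 1  # all-zero-difference genes
  mean_a <- colMeans(a); mean_b <- colMeans(b)
  log2_fc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  q <- stats::p.adjust(p, method = "BH")
  sig <- q <= contrast$fdr & abs(log2_fc) > log2(contrast$fc_threshold)
  direction <- ifelse(!sig, "ns", ifelse(log2_fc > 0, "up", "down"))
  out <- data.frame(gene = genes, mean_a = mean_a, mean_b = mean_b,
                    log2_fc = log2_fc, p = p, q = q, direction = direction,
                    row.names = NULL)
  class(out) <- c("dgea_table", "data.frame")
  attr(out, "contrast") <- contrast
  out
}

#' Intersection-based signature derivation
#'
#' The up-signature is the set of genes called `up` in every supplied
#' contrast table; the down-signature analogously. Gene order is
#' lexicographic for determinism.
#'
#' @param tables list of [run_contrast()] outputs; by design the six
#'   bud-versus-everything contrasts ([bud_contrasts()]).
#' @param name_prefix signature name prefix.
#' @param min_contrasts minimum number of tables required.
#' @return list with `up` and `down` ([signature_def()] or `NULL` when the
#'   intersection is empty).
#' @export
derive_signature <- function(tables, name_prefix = "TBS",
                             min_contrasts = length(tables)) {
  if (length(tables) < min_contrasts || length(tables) == 0)
    stop("signature derivation requires ", min_contrasts, " contrast tables")
  pick <- function(dir) {
    sets <- lapply(tables, function(t) t$gene[t$direction == dir])
    sort(Reduce(intersect, sets))
  }
  prov <- vapply(tables, function(t) attr(t, "contrast")$name, character(1))
  up <- pick("up"); down <- pick("down")
  list(
    up = if (length(up) > 0)
      signature_def(paste0(name_prefix, "_up"), up, "up", prov) else NULL,
    down = if (length(down) > 0)
      signature_def(paste0(name_prefix, "_down"), down, "down", prov) else NULL
  )
}

#' Fisher overlap test between two gene lists
#'
#' Two-sided Fisher exact test on the 2x2 membership table of two gene lists
#' over a universe, optionally excluding genes (e.g. the signature genes
#' themselves) from the universe and both lists first.
#'
#' @param genes_a,genes_b character vectors.
#' @param universe character vector of all eligible genes.
#' @param exclude genes removed from the universe and both lists.
#' @return list with `n_overlap`, `p`, and `odds_ratio`.
#' @export
overlap_test <- function(genes_a, genes_b, universe, exclude = character()) {
  universe <- setdiff(unique(universe), exclude)
  if (length(universe) == 0) stop("empty gene universe")
  genes_a <- intersect(genes_a, universe)
  genes_b <- intersect(genes_b, universe)
  n11 <- length(intersect(genes_a, genes_b))
  n12 <- length(setdiff(genes_a, genes_b))
  n21 <- length(setdiff(genes_b, genes_a))
  n22 <- length(universe) - n11 - n12 - n21
  ft <- stats::fisher.test(matrix(c(n11, n21, n12, n22), 2), alternative = "two.sided")
  list(n_overlap = n11, p = ft$p.value, odds_ratio = unname(ft$estimate))
}
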