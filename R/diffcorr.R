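#' Pair two conditions' case-level matrices for differential correlation
#'
#' A pairing holds, for each of two conditions (A = tumor buds and adjacent
#' stroma; B = budding bulk and adjacent stroma), the case x gene matrix of
#' the `x` compartment and optionally a second `y` compartment. When `y` is
#' `NULL` the pairing is within-compartment (tumor-tumor or stroma-stroma;
#' gene pairs are unordered, self-pairs excluded); otherwise cross-
#' compartment (tumor-stroma; all gene x gene combinations). Within a
#' condition, `x` and `y` rows must be the same cases in the same order.
#'
#' @param a_x,a_y condition-A matrices (cases x genes); `a_y = NULL` for
#'   within-compartment pairings.
#' @param b_x,b_y condition-B matrices.
#' @param compartment_x,compartment_y compartment labels used in edge
#'   output.
#' @return list of class `compartment_pairing`.
#' @export
compartment_pairing <- function(a_x, b_x, a_y = NULL, b_y = NULL,
                                compartment_x = "tumor",
                                compartment_y = compartment_x) {
  cross <- !is.null(a_y)
  if (cross != !is.null(b_y))
    stop("supply y matrices for both conditions or neither")
  if (cross) {
    if (!identical(rownames(a_x), rownames(a_y)))
      stop("condition A: x and y rows (cases) must align")
    if (!identical(rownames(b_x), rownames(b_y)))
      stop("condition B: x and y rows (cases) must align")
  }
  structure(list(a_x = as.matrix(a_x), a_y = if (cross) as.matrix(a_y),
                 b_x = as.matrix(b_x), b_y = if (cross) as.matrix(b_y),
                 cross = cross,
                 compartment_x = compartment_x,
                 compartment_y = if (cross) compartment_y else compartment_x),
            class = "compartment_pairing")
}

clamp_rho <- function(r, eps = 1e-6) pmin(pmax(r, -1 + eps), 1 - eps)

fisher_z <- function(r) atanh(clamp_rho(r))

# column-wise ranks (average ties)
col_ranks <- function(m) apply(m, 2L, rank)

# two-sided p for Spearman rho via the t approximation
spearman_p <- function(rho, n) {
  t <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' All-pairs Spearman correlations for one condition of a pairing
#'
#' Spearman rho and a two-sided p-value (t approximation on the
#' rank-Pearson statistic) for every gene pair of the pairing: unordered
#' pairs excluding self-pairs within a compartment, the full gene x gene
#' rectangle across compartments. Genes that are constant within the
#' condition yield `NA` and are excluded downstream.
#'
#' @param pairing a [compartment_pairing()].
#' @param condition `"a"` or `"b"`.
#' @return data.frame: `gene_a`, `gene_b`, `rho`, `p`, with attribute `n`
#'   (number of cases).
#' @export
condition_correlations <- function(pairing, condition = c("a", "b")) {
  condition <- match.arg(condition)
  x <- pairing[[paste0(condition, "_x")]]
  y <- if (pairing$cross) pairing[[paste0(condition, "_y")]] else x
  n <- nrow(x)
  if (n < 5) stop("fewer than 5 aligned cases in condition ", condition)
  rx <- col_ranks(x); ry <- col_ranks(y)
  constant_x <- apply(x, 2L, function(v) length(unique(v)) == 1)
  constant_y <- apply(y, 2L, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(stats::cor(rx, ry))
  rho[constant_x, ] <- NA
  rho[, constant_y] <- NA
  if (pairing$cross) {
    pairs <- expand.grid(i = seq_len(ncol(x)), j = seq_len(ncol(y)))
  } else {
    idx <- which(upper.tri(rho), arr.ind = TRUE)
    pairs <- data.frame(i = idx[, 1], j = idx[, 2])
  }
  r <- rho[cbind(pairs$i, pairs$j)]
  out <- data.frame(gene_a = colnames(x)[pairs$i],
                    gene_b = colnames(y)[pairs$j],
                    rho = r, p = spearman_p(clamp_rho(r), n))
  attr(out, "n") <- n
  out
}

#' Candidate differentially-correlated gene pairs
#'
#' Keeps the pairs with a significant strong correlation in at least one
#' condition: `|rho| > rho_min` (strict) and BH-adjusted `q <= fdr`, with
#' BH applied within each condition over all testable pairs. Pairs with an
#' undefined correlation in either condition are dropped.
#'
#' @param corr_a,corr_b outputs of [condition_correlations()] for the two
#'   conditions (same pair universe).
#' @param rho_min absolute-correlation threshold (strict inequality).
#' @param fdr BH FDR level per condition.
#' @return data.frame: `gene_a`, `gene_b`, `rho_a`, `q_a`, `rho_b`, `q_b`.
#' @export
candidate_pairs <- function(corr_a, corr_b, rho_min = 0.8, fdr = 0.01) {
  key_a <- paste(corr_a$gene_a, corr_a$gene_b, sep = "\r")
  key_b <- paste(corr_b$gene_a, corr_b$gene_b, sep = "\r")
  if (!identical(sort(key_a), sort(key_b)))
    stop("the two conditions cover different pair universes")
  corr_b <- corr_b[match(key_a, key_b), , drop = FALSE]
  ok <- !is.na(corr_a$rho) & !is.na(corr_b$rho)
  a <- corr_a[ok, , drop = FALSE]; b <- corr_b[ok, , drop = FALSE]
  q_a <- stats::p.adjust(a$p, method = "BH")
  q_b <- stats::p.adjust(b$p, method = "BH")
  keep <- (abs(a$rho) > rho_min & q_a <= fdr) |
    (abs(b$rho) > rho_min & q_b <= fdr)
  data.frame(gene_a = a$gene_a, gene_b = a$gene_b,
             rho_a = a$rho, q_a = q_a,
             rho_b = b$rho, q_b = q_b)[keep, , drop = FALSE]
}

# Spearman rho for a list of (i, j) gene-column pairs on given case rows
rho_candidates <- function(X, Y, rows, gi, gj) {
  rx <- col_ranks(X[rows, , drop = FALSE])
  ry <- if (is.null(Y)) rx else col_ranks(Y[rows, , drop = FALSE])
  rx <- scale(rx); ry <- scale(ry)
  n <- length(rows)
  colSums(rx[, gi, drop = FALSE] * ry[, gj, drop = FALSE]) / (n - 1)
}

#' Permutation test on Fisher-Z correlation differences
#'
#' For each candidate pair, the observed statistic is
#' `dz = atanh(rho_A) - atanh(rho_B)`. Under the null, case profiles are
#' exchangeable between the two conditions: each permutation shuffles the
#' pooled case profiles between conditions (preserving group sizes; the
#' case, not the segment, is the permutation unit), recomputes every
#' candidate's `dz`, and the empirical p-value is
#' `(1 + #(|dz_perm| >= |dz_obs|)) / (n_perm + 1)` from the pair's own
#' permutation distribution. BH adjustment is applied across candidates.
#' One shared shuffle sequence drives all pairs.
#'
#' @param pairing a [compartment_pairing()].
#' @param candidates output of [candidate_pairs()] (nonempty).
#' @param n_perm number of permutations (>= 100; analysis default 100,000,
#'   reduce for exploration).
#' @param seed integer seed; fixed seed gives identical output.
#' @return data.frame of class `diffcorr_edges`: `gene_a`, `comp_a`,
#'   `gene_b`, `comp_b`, `rho_a`, `rho_b`, `z_a`, `z_b`, `dz`, `p_emp`, `q`.
#' @export
permutation_test <- function(pairing, candidates, n_perm = 1e5, seed = 1L) {
  if (nrow(candidates) == 0) stop("no candidate pairs")
  if (n_perm < 100) stop("n_perm must be at least 100")
  n_a <- nrow(pairing$a_x); n_b <- nrow(pairing$b_x)
  if (n_a < 4 || n_b < 4) stop("need at least 4 cases per condition")
  X <- rbind(pairing$a_x, pairing$b_x)
  Y <- if (pairing$cross) rbind(pairing$a_y, pairing$b_y) else NULL
  gi <- match(candidates$gene_a, colnames(pairing$a_x))
  gj <- match(candidates$gene_b,
              colnames(if (pairing$cross) pairing$a_y else pairing$a_x))
  if (anyNA(gi) || anyNA(gj)) stop("candidate gene not found in matrices")
  obs_a <- rho_candidates(X, Y, seq_len(n_a), gi, gj)
  obs_b <- rho_candidates(X, Y, n_a + seq_len(n_b), gi, gj)
  dz_obs <- fisher_z(obs_a) - fisher_z(obs_b)
  set.seed(seed)
  exceed <- numeric(nrow(candidates))
  for (p in seq_len(n_perm)) {
    ia <- sample.int(n_a + n_b, n_a)
    ib <- setdiff(seq_len(n_a + n_b), ia)
    dz_p <- fisher_z(rho_candidates(X, Y, ia, gi, gj)) -
      fisher_z(rho_candidates(X, Y, ib, gi, gj))
    exceed <- exceed + (abs(dz_p) >= abs(dz_obs))
  }
  p_emp <- (1 + exceed) / (n_perm + 1)
  out <- data.frame(
    gene_a = candidates$gene_a, comp_a = pairing$compartment_x,
    gene_b = candidates$gene_b, comp_b = pairing$compartment_y,
    rho_a = obs_a, rho_b = obs_b,
    z_a = fisher_z(obs_a), z_b = fisher_z(obs_b),
    dz = dz_obs, p_emp = p_emp,
    q = stats::p.adjust(p_emp, method = "BH"))
  class(out) <- c("diffcorr_edges", "data.frame")
  out
}

#' Select differential edges and label the direction of change
#'
#' Keeps edges with `q <= fdr` and `|dz| >= min_abs_dz` (inclusive). The
#' change label is `sign_flip` when the two correlations are of opposite
#' sign and both substantial (|rho| >= 0.3); otherwise `gained` when the
#' correlation is stronger in condition A (buds) and `lost` when stronger
#' in condition B.
#'
#' @param edges a `diffcorr_edges` data.frame from [permutation_test()].
#' @param fdr FDR threshold on the BH-adjusted empirical p.
#' @param min_abs_dz minimum absolute Fisher-Z difference (inclusive).
#' @return the filtered edges with a `change` column.
#' @export
select_differential <- function(edges, fdr = 0.01, min_abs_dz = 1.4) {
  keep <- edges$q <= fdr & abs(edges$dz) >= min_abs_dz
  out <- edges[keep, , drop = FALSE]
  flip <- out$rho_a * out$rho_b < 0 &
    pmin(abs(out$rho_a), abs(out$rho_b)) >= 0.3
  out$change <- ifelse(flip, "sign_flip",
                       ifelse(abs(out$rho_a) > abs(out$rho_b),
                              "gained", "lost"))
  out
}

#' Build the annotated differential-correlation network
#'
#' Nodes are `(gene, compartment)` pairs — the same gene measured in tumor
#' and in stroma is two nodes; edges are the differential correlations.
#' Nodes are annotated as transcription factor / ligand / receptor from
#' supplied symbol lists, and with a differential-expression status; edges
#' are flagged when the gene pair has a known interaction. Connected
#' components are enumerated and partitioned by size.
#'
#' @param edges a (filtered) `diffcorr_edges` data.frame.
#' @param annotations optional list with any of: `tf`, `ligand`, `receptor`
#'   (character vectors of symbols), `deg_status` (named vector with values
#'   `up`/`down`/`ns`), `interactions` (two-column data.frame of known
#'   gene-gene interactions). Symbols are matched case-insensitively.
#' @return list with `graph` (igraph), `nodes` (annotated node table),
#'   `edges` (input plus `known_interaction`), and `components`
#'   (data.frame: `component`, `size`, `size_class` in
#'   `pair` (2) / `small` (3-8) / `large` (>8)).
#' @export
build_network <- function(edges, annotations = NULL) {
  if (nrow(edges) == 0) stop("no edges to build a network from")
  node_a <- paste0(edges$gene_a, "@", edges$comp_a)
  node_b <- paste0(edges$gene_b, "@", edges$comp_b)
  el <- data.frame(from = node_a, to = node_b, edges, check.names = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  comp <- igraph::components(g)
  nodes <- data.frame(name = igraph::V(g)$name)
  parts <- strsplit(nodes$name, "@", fixed = TRUE)
  nodes$gene <- vapply(parts, `[`, character(1), 1)
  nodes$compartment <- vapply(parts, `[`, character(1), 2)
  has <- function(lst, genes) {
    if (is.null(lst)) rep(FALSE, length(genes))
    else toupper(genes) %in% toupper(lst)
  }
  nodes$is_tf <- has(annotations$tf, nodes$gene)
  nodes$is_ligand <- has(annotations$ligand, nodes$gene)
  nodes$is_receptor <- has(annotations$receptor, nodes$gene)
  nodes$deg_status <- "ns"
  if (!is.null(annotations$deg_status)) {
    m <- match(toupper(nodes$gene), toupper(names(annotations$deg_status)))
    nodes$deg_status[!is.na(m)] <- annotations$deg_status[m[!is.na(m)]]
  }
  nodes$component <- comp$membership[nodes$name]
  nodes$component_size <- comp$csize[nodes$component]
  known <- rep(FALSE, nrow(edges))
  if (!is.null(annotations$interactions)) {
    ia <- toupper(annotations$interactions[[1]])
    ib <- toupper(annotations$interactions[[2]])
    known_keys <- unique(c(paste(ia, ib), paste(ib, ia)))
    known <- paste(toupper(edges$gene_a), toupper(edges$gene_b)) %in% known_keys
  }
  out_edges <- edges
  out_edges$known_interaction <- known
  components <- data.frame(component = seq_along(comp$csize),
                           size = comp$csize)
  components$size_class <- cut(components$size, breaks = c(1, 2, 8, Inf),
                               labels = c("pair", "small", "large"))
  list(graph = g, nodes = nodes, edges = out_edges, components = components)
}
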