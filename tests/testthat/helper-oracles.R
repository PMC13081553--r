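# Independent brute-force oracles used across test files. These deliberately
# re-derive each quantity from first principles, never through the package's
# own code paths.

# AUC by enumeration of all (positive, negative) pairs, ties counted half
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(pos) * length(neg))
}

# Spearman rho as Pearson on ranks
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# one-sided (upper) hypergeometric tail: P(overlap >= n) drawing K from a
# universe of N containing k set members
brute_hyper_upper <- function(n, k, K, N) {
  sum(stats::dhyper(n:min(k, K), k, N - k, K))
}

# two-sided Fisher p by enumeration: sum of probabilities of tables as or
# less probable than the observed one (fisher.test's definition)
brute_fisher_two_sided <- function(n11, k, K, N) {
  support <- max(0, K + k - N):min(k, K)
  probs <- stats::dhyper(support, k, N - k, K)
  p_obs <- stats::dhyper(n11, k, N - k, K)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# connected components by union-find over an edge list of node labels
brute_components <- function(a, b) {
  nodes <- unique(c(a, b))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_along(a)) {
    ra <- find(a[i]); rb <- find(b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  as.integer(table(factor(roots, levels = unique(roots))))
}

# tiny segment_counts fixture: `n_seg` segments, `genes` biological probes
# plus two negative probes, all QC metrics passing unless overridden
make_fixture_counts <- function(counts, segment_type = "bud",
                                compartment = "tumor",
                                case_id = NULL,
                                raw_reads = 1e5, stitched = 0.9,
                                aligned = 0.85, saturation = 0.7,
                                ntc = 100) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("seg%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("gene%02d", seq_len(ncol(counts)))
  n <- nrow(counts)
  if (is.null(case_id)) case_id <- sprintf("case%02d", seq_len(n))
  probes <- data.frame(probe_id = colnames(counts),
                       gene_symbol = colnames(counts),
                       is_negative_control = grepl("^NP", colnames(counts)))
  meta <- data.frame(segment_id = rownames(counts),
                     case_id = rep_len(case_id, n),
                     run_id = "run1", roi_id = rownames(counts),
                     segment_type = rep_len(segment_type, n),
                     compartment = rep_len(compartment, n),
                     raw_reads = rep_len(raw_reads, n),
                     stitched_frac = rep_len(stitched, n),
                     aligned_frac = rep_len(aligned, n),
                     saturation_frac = rep_len(saturation, n),
                     ntc_count = rep_len(ntc, n))
  segment_counts(counts, probes, meta)
}

# a small spatial dataset pushed through QC/normalization/aggregation;
# memoised so several test files can reuse it
spatial_case_matrices <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- spatial_sim_config(
        planted_signature = data.frame(gene = sprintf("g%04d", 1:28),
                                       fold = 2.5),
        seed = 1L)
      sp <- generate_spatial(cfg)
      post <- filter_by_loq(filter_segments(sp)$kept)
      norm <- q3_normalize(post)
      cache <<- list(spatial = sp, post = post, norm = norm,
                     cases = aggregate_case_level(norm, post$meta))
    }
    cache
  }
})
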