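#' Read a GMT gene-set catalog
#'
#' Standard tab-separated GMT: one set per line, fields are set name,
#' description, then member genes. Gene symbols are de-duplicated within a
#' set and case-preserved.
#'
#' @param path GMT file path.
#' @return named list of gene sets (class `gene_set_catalog`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed GMT line ", i, ": expected name, description, genes")
    nm <- fields[1]
    if (nm %in% names(sets))
      stop("duplicate gene-set name '", nm, "' at line ", i)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("empty gene set '", nm, "' at line ", i)
    sets[[nm]] <- genes
  }
  structure(sets, class = "gene_set_catalog")
}

#' Write a GMT gene-set catalog
#'
#' @param catalog named list of gene sets.
#' @param path output path.
#' @param descriptions optional per-set description column (defaults to the
#'   set name).
#' @export
write_gmt <- function(catalog, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(catalog)
  lines <- vapply(seq_along(catalog), function(i) {
    paste(c(names(catalog)[i], descriptions[i], catalog[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set enrichment: fold change of percentages plus Fisher exact test
#'
#' For each catalog set, the enrichment score is the overlap fraction of the
#' query over the set's universe fraction: `fc = (n/K)/(k/N)` with `n` the
#' overlap, `K` the query size, `k` the set size, and `N` the universe size
#' (all after restriction to the universe). Significance is a one-sided
#' Fisher exact test on the 2x2 membership table, with Benjamini-Hochberg
#' adjustment across the catalog. Run the analysis separately for up- and
#' down-regulated gene lists.
#'
#' @param query_genes character vector (e.g. one direction's DEGs); genes
#'   outside the universe are dropped with a warning.
#' @param catalog a `gene_set_catalog` (named list of gene sets).
#' @param universe `NULL` (union of catalog genes) or an explicit universe,
#'   e.g. catalog genes intersected with the measured genes.
#' @param formula `"corrected"` (the default above) or `"printed"`, the
#'   reciprocal form `(k/K)/(n/N)` kept for comparability (returns `Inf`
#'   at zero overlap).
#' @return data.frame: `set`, `k` (set size), `K` (query size), `n`
#'   (overlap), `N` (universe), `fc`, `p`, `q`, ordered by `p`.
#' @export
enrich <- function(query_genes, catalog, universe = NULL,
                   formula = c("corrected", "printed")) {
  formula <- match.arg(formula)
  if (is.null(universe)) universe <- unique(unlist(catalog))
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop("empty universe")
  query0 <- unique(query_genes)
  query <- intersect(query0, universe)
  if (length(query) < length(query0))
    warning(length(query0) - length(query),
            " query gene(s) outside the universe dropped")
  if (length(query) == 0) stop("no query gene in the universe")
  K <- length(query)
  rows <- lapply(names(catalog), function(nm) {
    set <- intersect(catalog[[nm]], universe)
    k <- length(set)
    n <- length(intersect(query, set))
    fc <- if (formula == "corrected") {
      if (k == 0) NA_real_ else (n / K) / (k / N)
    } else {
      if (n == 0) Inf else (k / K) / (n / N)
    }
    p <- stats::fisher.test(matrix(c(n, K - n, k - n, N - K - k + n), 2),
                            alternative = "greater")$p.value
    data.frame(set = nm, k = k, K = K, n = n, N = N, fc = fc, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$set), , drop = FALSE]
}
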