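#' Score a gene signature on an expression matrix
#'
#' For matrices on a linear normalized scale (tags `"raw"` or `"q3"`), the
#' score of a sample is the mean over the signature genes of
#' `log2(value + pseudocount)`. For matrices already on a log scale (tags
#' `"lognorm_sc"`, `"log2"`), the values are averaged directly. Signature
#' genes missing from the matrix are handled per `missing_policy`: the
#' default drops them and averages over the genes present (recorded in the
#' result's attributes).
#'
#' @param mat an [expression_matrix()] (samples x genes).
#' @param signature a [signature_def()].
#' @param missing_policy `"drop"` (average over present genes) or `"error"`.
#' @param pseudocount added before log2 on linear-scale matrices.
#' @param aggregate `"mean"` (default) or `"sum"` over the signature genes.
#' @return named numeric vector of per-sample scores (class `score_set`),
#'   with attributes `signature`, `transform`, and `genes_used`.
#' @export
score_signature <- function(mat, signature,
                            missing_policy = c("drop", "error"),
                            pseudocount = 1,
                            aggregate = c("mean", "sum")) {
  missing_policy <- match.arg(missing_policy)
  aggregate <- match.arg(aggregate)
  present <- intersect(signature$genes, colnames(mat))
  if (length(present) == 0)
    stop("no signature gene present in the matrix")
  if (missing_policy == "error" && length(present) < length(signature$genes))
    stop("signature gene(s) missing from matrix: ",
         paste(setdiff(signature$genes, present), collapse = ", "))
  sub <- mat[, present, drop = FALSE]
  logscale <- norm_tag(mat) %in% c("lognorm_sc", "log2")
  vals <- if (logscale) sub else log2(sub + pseudocount)
  s <- if (aggregate == "mean") rowMeans(vals) else rowSums(vals)
  structure(s, class = "score_set",
            signature = signature$name,
            transform = if (logscale) "mean_of_lognorm" else "log2_of_norm",
            genes_used = present)
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("score_set '%s' (%s): %d samples\n",
              attr(x, "signature"), attr(x, "transform"), length(x)))
  print(utils::head(unclass(x)))
  invisible(x)
}

#' The 15-gene partial-EMT program
#'
#' Genes of the hybrid epithelial-mesenchymal program used for the pEMT
#' score.
#' @export
pemt_genes <- c("SERPINE1", "TGFBI", "MMP10", "LAMC2", "P4HA2", "PDPN",
                "ITGA5", "LAMA3", "CDH13", "TNC", "MMP2", "EMP3", "INHBA",
                "LAMB3", "VIM")

#' Partial-EMT score
#'
#' Mean of the log2-transformed expression of the fixed 15-gene pEMT program
#' ([pemt_genes]); identical mechanics to [score_signature()].
#'
#' @inheritParams score_signature
#' @return a `score_set`.
#' @export
score_pemt <- function(mat, missing_policy = c("drop", "error"),
                       pseudocount = 1) {
  score_signature(mat, signature_def("pEMT", pemt_genes, "up"),
                  missing_policy = match.arg(missing_policy),
                  pseudocount = pseudocount)
}

#' Fit a two-component Gaussian mixture and locate the density crossing
#'
#' Fits a two-component univariate Gaussian mixture by EM and returns the
#' cutoff where the two weighted component densities intersect between the
#' component means — the point where a score is equally likely under either
#' component. The fit is flagged non-bimodal (`converged = FALSE`) when the
#' components are not separable, judged by Ashman's
#' `D = sqrt(2) |mu2 - mu1| / sqrt(sd1^2 + sd2^2) < 2`.
#'
#' @param scores numeric vector (>= 50 values).
#' @param seed integer seed (EM initialization is deterministic given the
#'   data; the seed guards any stochastic initialization fallback).
#' @return list of class `mixture_cutoff`: `mu1 < mu2`, `sd1`, `sd2`, `w1`,
#'   `w2`, `cutoff`, `converged`, `ashman_d`.
#' @export
fit_bimodal_cutoff <- function(scores, seed = 1L) {
  scores <- as.numeric(scores)
  if (length(scores) < 50)
    stop("need at least 50 scores to fit a mixture cutoff")
  if (any(!is.finite(scores))) stop("scores must be finite")
  set.seed(seed)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  fit <- mclust::Mclust(scores, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit))
    stop("EM failed to fit a two-component mixture; scores may be degenerate")
  mu <- fit$parameters$mean
  sdv <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sdv) == 1) sdv <- rep(sdv, 2)
  w <- fit$parameters$pro
  o <- order(mu)
  mu <- mu[o]; sdv <- sdv[o]; w <- w[o]
  d <- sqrt(2) * abs(mu[2] - mu[1]) / sqrt(sdv[1]^2 + sdv[2]^2)
  f <- function(x) w[1] * stats::dnorm(x, mu[1], sdv[1]) -
    w[2] * stats::dnorm(x, mu[2], sdv[2])
  cutoff <- if (mu[2] - mu[1] < 1e-8 || f(mu[1]) * f(mu[2]) > 0) {
    (w[1] * mu[2] + w[2] * mu[1]) / (w[1] + w[2])  # overlap fallback
  } else {
    stats::uniroot(f, c(mu[1], mu[2]), tol = 1e-9)$root
  }
  structure(list(mu1 = mu[1], mu2 = mu[2], sd1 = sdv[1], sd2 = sdv[2],
                 w1 = w[1], w2 = w[2], cutoff = cutoff,
                 converged = d >= 2, ashman_d = d),
            class = "mixture_cutoff")
}

#' @export
print.mixture_cutoff <- function(x, ...) {
  cat(sprintf(paste0("mixture_cutoff: %.3g | components N(%.3g, %.3g) ",
                     "w=%.2f and N(%.3g, %.3g) w=%.2f | %s (Ashman D %.2f)\n"),
              x$cutoff, x$mu1, x$sd1, x$w1, x$mu2, x$sd2, x$w2,
              if (x$converged) "bimodal" else "NOT separable", x$ashman_d))
  invisible(x)
}

#' Classify scores against a cutoff
#'
#' Scores strictly above the cutoff are `"high"`; scores at or below it are
#' `"low"` (boundary goes to low).
#'
#' @param scores numeric (a `score_set` or plain vector).
#' @param cutoff finite numeric cutoff.
#' @return factor with levels `low`, `high`, named like `scores`.
#' @export
classify <- function(scores, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  factor(ifelse(as.numeric(scores) > cutoff, "high", "low"),
         levels = c("low", "high")) -> f
  names(f) <- names(scores)
  f
}

#' Spearman correlation between two score sets
#'
#' @param a,b named numeric score vectors; correlated over shared names
#'   (>= 3 required).
#' @return list with `rho`, `p`, `n`.
#' @export
correlate_scores <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  ct <- suppressWarnings(
    stats::cor.test(as.numeric(a[shared]), as.numeric(b[shared]),
                    method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Classify samples by tumor-bud count
#'
#' Histology rule: `TB = 0` is non-budding; `TB > 0` is budding, split into
#' low-budding (`0 < TB < 6`) and high-budding (`TB >= 6`).
#'
#' @param tb nonnegative integer tumor-bud counts (named).
#' @return data.frame with `tb`, `budding` (two-way factor:
#'   `non_budding`/`budding`) and `level` (three-way factor:
#'   `non_budding`/`low_budding`/`high_budding`).
#' @export
classify_budding_bulk <- function(tb) {
  if (any(tb < 0)) stop("tumor-bud counts must be nonnegative")
  if (any(tb != round(tb))) stop("tumor-bud counts must be integers")
  two <- factor(ifelse(tb > 0, "budding", "non_budding"),
                levels = c("non_budding", "budding"))
  three <- factor(ifelse(tb == 0, "non_budding",
                         ifelse(tb < 6, "low_budding", "high_budding")),
                  levels = c("non_budding", "low_budding", "high_budding"))
  data.frame(sample = if (is.null(names(tb))) seq_along(tb) else names(tb),
             tb = as.integer(tb), budding = two, level = three,
             row.names = NULL)
}
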