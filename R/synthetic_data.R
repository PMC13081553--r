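#' Configuration for the spatial transcriptomics simulator
#'
#' Defaults mirror the study design the pipeline targets: 24 budding and 19
#' non-budding cases, seven segment types spanning tumor buds, budding and
#' non-budding bulk, their adjacent stroma, and a pooled immune compartment.
#' Counts are negative-binomial around segment-library-scaled gene means;
#' negative-control probes are pure background with no biological signal.
#'
#' @param n_budding_cases,n_nonbudding_cases numbers of cases per arm.
#' @param n_genes number of biological probes (one probe per gene).
#' @param n_negative_probes number of negative-control probes.
#' @param segments_per_type segments sampled per case per segment type.
#' @param segment_types data.frame with columns `type`, `compartment`,
#'   `arm` (`"budding"`, `"nonbudding"` or `"both"`); the default mirrors
#'   the bud / bulk-budding / bulk-nonbudding design with adjacent stroma
#'   and a shared immune type.
#' @param baseline_log_mean_sd length-2 numeric: mean and sd of per-gene
#'   natural-log baseline expression.
#' @param library_size_log_sd sd of the per-segment log library-size factor.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0.
#' @param neg_probe_mean mean background count of negative probes.
#' @param case_effect_sd sd of the per-case, per-gene random effect on the
#'   log mean (induces the within-case pairing the paired tests exploit).
#' @param planted_signature `NULL`, or data.frame with columns `gene` and
#'   `fold` (fold >= 1) applied in bud segments of budding cases only.
#' @param planted_corr_pairs `NULL`, or data.frame with columns `gene_a`,
#'   `gene_b`, `condition` (`"bud_only"` or `"bulk_only"`), `target_rho`;
#'   correlation is planted through a shared per-case latent Gaussian
#'   factor, active only in the gated condition's segments.
#' @param corr_effect_sd sd of the latent factor used for correlation
#'   planting (larger values push the realized Spearman rho toward
#'   `target_rho`).
#' @param qc_fail_frac per-metric probability that a segment's QC metric is
#'   drawn from the failing range.
#' @param seed integer seed; identical seeds give identical output.
#' @return A list of class `spatial_sim_config`.
#' @export
spatial_sim_config <- function(n_budding_cases = 24,
                               n_nonbudding_cases = 19,
                               n_genes = 300,
                               n_negative_probes = 30,
                               segments_per_type = 2,
                               segment_types = default_segment_types(),
                               baseline_log_mean_sd = c(3.5, 1.0),
                               library_size_log_sd = 0.25,
                               nb_dispersion = 0.15,
                               neg_probe_mean = 4,
                               case_effect_sd = 0.25,
                               planted_signature = NULL,
                               planted_corr_pairs = NULL,
                               corr_effect_sd = 1.2,
                               qc_fail_frac = 0.05,
                               seed = 1L) {
  stopifnot(n_budding_cases >= 1, n_nonbudding_cases >= 1, n_genes >= 1,
            n_negative_probes >= 2, segments_per_type >= 1,
            nb_dispersion > 0, neg_probe_mean > 0)
  if (!is.null(planted_signature)) {
    if (!all(c("gene", "fold") %in% names(planted_signature)))
      stop("planted_signature needs columns gene, fold")
    if (any(planted_signature$fold < 1))
      stop("planted fold effects must be >= 1")
  }
  if (!is.null(planted_corr_pairs)) {
    need <- c("gene_a", "gene_b", "condition", "target_rho")
    if (!all(need %in% names(planted_corr_pairs)))
      stop("planted_corr_pairs needs columns ", paste(need, collapse = ", "))
    if (!all(planted_corr_pairs$condition %in% c("bud_only", "bulk_only")))
      stop("planted_corr_pairs$condition must be 'bud_only' or 'bulk_only'")
  }
  structure(as.list(environment()), class = "spatial_sim_config")
}

#' Default segment-type design
#'
#' @return data.frame of (type, compartment, arm) rows: tumor buds with
#'   adjacent stroma and budding bulk with adjacent stroma in budding cases,
#'   non-budding bulk with adjacent stroma in non-budding cases, and an
#'   immune type present in both arms.
#' @export
default_segment_types <- function() {
  data.frame(
    type = c("bud", "stroma_bud", "bulk_budding", "stroma_bulk_budding",
             "bulk_nonbudding", "stroma_bulk_nonbudding", "immune"),
    compartment = c("tumor", "stroma", "tumor", "stroma",
                    "tumor", "stroma", "immune"),
    arm = c("budding", "budding", "budding", "budding",
            "nonbudding", "nonbudding", "both")
  )
}

#' Simulate a segment-level spatial transcriptomics experiment
#'
#' @param config a [spatial_sim_config()].
#' @return A [segment_counts()] object; the generating latent quantities are
#'   attached as attribute `"truth"` (gene baseline means, case latent
#'   factors, planted definitions).
#' @export
generate_spatial <- function(config = spatial_sim_config()) {
  stopifnot(inherits(config, "spatial_sim_config"))
  set.seed(config$seed)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  negs <- sprintf("NegPrb%03d", seq_len(config$n_negative_probes))
  if (!is.null(config$planted_signature)) {
    bad <- setdiff(config$planted_signature$gene, genes)
    if (length(bad) > 0)
      stop("planted signature gene(s) not in gene universe: ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(config$planted_corr_pairs)) {
    bad <- setdiff(c(config$planted_corr_pairs$gene_a,
                     config$planted_corr_pairs$gene_b), genes)
    if (length(bad) > 0)
      stop("planted correlation gene(s) not in gene universe: ",
           paste(bad, collapse = ", "))
  }

  base_log_mean <- stats::rnorm(config$n_genes,
                                config$baseline_log_mean_sd[1],
                                config$baseline_log_mean_sd[2])
  names(base_log_mean) <- genes

  cases <- c(sprintf("B%02d", seq_len(config$n_budding_cases)),
             sprintf("N%02d", seq_len(config$n_nonbudding_cases)))
  arm <- rep(c("budding", "nonbudding"),
             c(config$n_budding_cases, config$n_nonbudding_cases))
  names(arm) <- cases

  # per-case per-gene random effect: shared by all of a case's segments
  case_eff <- matrix(stats::rnorm(length(cases) * config$n_genes,
                                  0, config$case_effect_sd),
                     nrow = length(cases),
                     dimnames = list(cases, genes))

  # latent factors for planted correlations: per case, per pair, a bivariate
  # normal draw with the target correlation, added to the two genes' log
  # means in the gated condition's segments only
  corr_latent <- NULL
  if (!is.null(config$planted_corr_pairs) &&
      nrow(config$planted_corr_pairs) > 0) {
    pcp <- config$planted_corr_pairs
    corr_latent <- lapply(seq_len(nrow(pcp)), function(i) {
      rho <- pcp$target_rho[i]
      u <- stats::rnorm(length(cases), 0, config$corr_effect_sd)
      v <- rho * u + sqrt(1 - rho^2) *
        stats::rnorm(length(cases), 0, config$corr_effect_sd)
      cbind(u = u, v = v)
    })
  }

  st <- config$segment_types
  rows <- list()
  meta <- list()
  for (ci in seq_along(cases)) {
    case <- cases[ci]
    types <- st[st$arm %in% c("both", arm[case]), , drop = FALSE]
    for (ti in seq_len(nrow(types))) {
      for (k in seq_len(config$segments_per_type)) {
        seg_id <- sprintf("%s_%s_%d", case, types$type[ti], k)
        lib <- exp(stats::rnorm(1, 0, config$library_size_log_sd))
        lmu <- base_log_mean + case_eff[case, ]
        if (types$type[ti] == "bud" && !is.null(config$planted_signature)) {
          ps <- config$planted_signature
          lmu[ps$gene] <- lmu[ps$gene] + log(ps$fold)
        }
        if (!is.null(corr_latent)) {
          pcp <- config$planted_corr_pairs
          gate <- ifelse(pcp$condition == "bud_only", "bud", "bulk_budding")
          act <- which(gate == types$type[ti])
          for (pi in act) {
            lmu[pcp$gene_a[pi]] <- lmu[pcp$gene_a[pi]] + corr_latent[[pi]][ci, "u"]
            lmu[pcp$gene_b[pi]] <- lmu[pcp$gene_b[pi]] + corr_latent[[pi]][ci, "v"]
          }
        }
        mu <- lib * exp(lmu)
        cnt <- stats::rnbinom(config$n_genes, mu = mu,
                              size = 1 / config$nb_dispersion)
        neg <- stats::rnbinom(config$n_negative_probes,
                              mu = lib * config$neg_probe_mean,
                              size = 1 / config$nb_dispersion)
        rows[[seg_id]] <- c(cnt, neg)
        meta[[seg_id]] <- data.frame(
          segment_id = seg_id, case_id = case,
          run_id = sprintf("run%d", 1 + (ci - 1) %% 3),
          roi_id = sprintf("%s_roi%d", case, ti),
          segment_type = types$type[ti], compartment = types$compartment[ti],
          raw_reads = NA_real_, stitched_frac = NA_real_,
          aligned_frac = NA_real_, saturation_frac = NA_real_,
          ntc_count = NA_real_)
      }
    }
  }
  counts <- do.call(rbind, rows)
  colnames(counts) <- c(genes, negs)
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  n <- nrow(meta)

  # QC metrics: passing values by default, each metric independently drawn
  # from a failing range with probability qc_fail_frac
  fail_mask <- function() stats::runif(n) < config$qc_fail_frac
  m1 <- fail_mask(); m2 <- fail_mask(); m3 <- fail_mask()
  m4 <- fail_mask(); m5 <- fail_mask()
  meta$raw_reads <- round(exp(stats::rnorm(n, log(2e5), 0.25)))
  meta$raw_reads[m1] <- round(stats::runif(sum(m1), 5e3, 39000))
  meta$stitched_frac <- stats::runif(n, 0.85, 0.99)
  meta$stitched_frac[m2] <- stats::runif(sum(m2), 0.50, 0.79)
  meta$aligned_frac <- stats::runif(n, 0.75, 0.97)
  meta$aligned_frac[m3] <- stats::runif(sum(m3), 0.40, 0.69)
  meta$saturation_frac <- stats::runif(n, 0.55, 0.95)
  meta$saturation_frac[m4] <- stats::runif(sum(m4), 0.15, 0.49)
  meta$ntc_count <- stats::rpois(n, 150)
  meta$ntc_count[m5] <- round(stats::runif(sum(m5), 1001, 5000))

  probes <- data.frame(
    probe_id = c(genes, negs),
    gene_symbol = c(genes, negs),
    is_negative_control = rep(c(FALSE, TRUE),
                              c(config$n_genes, config$n_negative_probes)))
  out <- segment_counts(counts, probes, meta)
  attr(out, "truth") <- list(base_log_mean = base_log_mean, arm = arm,
                             planted_signature = config$planted_signature,
                             planted_corr_pairs = config$planted_corr_pairs)
  out
}

#' Simulate a single-cell UMI experiment with a bimodal signature state
#'
#' Malignant cells carry a latent signature state drawn from a two-component
#' Gaussian mixture; the state drives the expression rate of the signature
#' genes, so per-cell signature scores inherit the bimodality. Non-malignant
#' cells sit at a low baseline. A configurable fraction of low-quality cells
#' (tiny libraries, hence few detected genes) and cells with elevated
#' mitochondrial fractions is injected so the droplet filters are exercised.
#'
#' @param n_cells number of cells.
#' @param cell_type_mix named proportions over cell types; must include
#'   `"malignant"` and sum to 1.
#' @param bimodal_params list with `means`, `sds`, `weights` (each length 2)
#'   on the latent signature scale; weights must sum to 1.
#' @param signature_genes gene symbols whose expression tracks the latent
#'   state.
#' @param n_genes total number of genes (signature + background +
#'   mitochondrial).
#' @param n_mito_genes number of `MT-` prefixed genes.
#' @param mean_library mean UMI count per healthy cell.
#' @param low_quality_frac fraction of cells with ~100-count libraries.
#' @param high_mito_frac fraction of cells with mitochondrial fraction
#'   above 10%.
#' @param seed integer seed.
#' @return A list with `umi` (sparse genes x cells matrix) and `meta`
#'   (data.frame: `cell_id`, `cell_type`, `latent_state`).
#' @export
generate_single_cell <- function(n_cells = 1000,
                                 cell_type_mix = c(malignant = 0.5,
                                                   fibroblast = 0.25,
                                                   immune = 0.25),
                                 bimodal_params = list(means = c(0, 5),
                                                       sds = c(1, 1),
                                                       weights = c(0.5, 0.5)),
                                 signature_genes = sprintf("SIG%02d", 1:28),
                                 n_genes = 400,
                                 n_mito_genes = 10,
                                 mean_library = 5000,
                                 low_quality_frac = 0.03,
                                 high_mito_frac = 0.03,
                                 seed = 1L) {
  if (abs(sum(cell_type_mix) - 1) > 1e-8)
    stop("cell_type_mix proportions must sum to 1")
  if (abs(sum(bimodal_params$weights) - 1) > 1e-8)
    stop("bimodal component weights must sum to 1")
  if (!"malignant" %in% names(cell_type_mix))
    stop("cell_type_mix must include a 'malignant' component")
  set.seed(seed)
  n_bg <- n_genes - length(signature_genes) - n_mito_genes
  if (n_bg < 1) stop("n_genes too small for signature + mito genes")
  genes <- c(signature_genes, sprintf("BG%04d", seq_len(n_bg)),
             sprintf("MT-%02d", seq_len(n_mito_genes)))
  types <- sample(names(cell_type_mix), n_cells, replace = TRUE,
                  prob = cell_type_mix)
  comp <- sample(1:2, n_cells, replace = TRUE, prob = bimodal_params$weights)
  latent <- stats::rnorm(n_cells, bimodal_params$means[comp],
                         bimodal_params$sds[comp])
  latent[types != "malignant"] <- stats::rnorm(sum(types != "malignant"),
                                               min(bimodal_params$means) - 1,
                                               0.5)
  # relative expression rates per gene per cell
  base_rate <- stats::rexp(length(genes), rate = 1) + 0.05
  names(base_rate) <- genes
  lib <- round(stats::rlnorm(n_cells, log(mean_library), 0.3))
  lowq <- stats::runif(n_cells) < low_quality_frac
  lib[lowq] <- round(stats::runif(sum(lowq), 50, 150))
  mito_boost <- rep(1, n_cells)
  himito <- stats::runif(n_cells) < high_mito_frac
  mito_boost[himito] <- stats::runif(sum(himito), 8, 20)

  rates <- matrix(base_rate, nrow = length(genes), ncol = n_cells,
                  dimnames = list(genes, NULL))
  sig_idx <- match(signature_genes, genes)
  rates[sig_idx, ] <- rates[sig_idx, ] *
    rep(exp(0.6 * latent), each = length(sig_idx))
  mito_idx <- grep("^MT-", genes)
  rates[mito_idx, ] <- rates[mito_idx, ] *
    rep(mito_boost, each = length(mito_idx))
  rates <- sweep(rates, 2, colSums(rates), "/")
  counts <- matrix(stats::rpois(length(genes) * n_cells,
                                lambda = sweep(rates, 2, lib, "*")),
                   nrow = length(genes), dimnames = list(genes, NULL))
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  colnames(counts) <- cell_ids
  list(umi = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       meta = data.frame(cell_id = cell_ids, cell_type = types,
                         latent_state = latent))
}

#' Configuration for the bulk survival cohort simulator
#'
#' @param n_samples cohort size.
#' @param true_hr hazard ratio of the high latent-budding state versus low.
#' @param baseline_hazard exponential baseline hazard (events per month).
#' @param censoring_rate expected fraction of samples censored; each sample
#'   is independently censored with this probability at a uniform fraction
#'   of its event time.
#' @param budding_score_link slope linking the latent bud fraction to the
#'   log mean of the Poisson tumor-bud count.
#' @param seed integer seed.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_samples = 300, true_hr = 1.5,
                              baseline_hazard = 0.02, censoring_rate = 0.3,
                              budding_score_link = 1.0, seed = 1L) {
  stopifnot(n_samples >= 2, true_hr > 0, baseline_hazard > 0,
            censoring_rate >= 0, censoring_rate < 1)
  structure(as.list(environment()), class = "cohort_sim_config")
}

#' Simulate a bulk expression cohort with survival and tumor-bud counts
#'
#' A per-sample latent bud fraction drives three observables: expression of
#' the signature genes (log-linear in the latent state), a Poisson tumor-bud
#' count through `budding_score_link`, and exponential survival with hazard
#' `baseline_hazard * true_hr^(high state)`, where the high state is a
#' positive latent value.
#'
#' @param config a [cohort_sim_config()].
#' @param signature a [signature_def()]; its genes are planted in the
#'   expression matrix.
#' @param n_background_genes unrelated genes added to the matrix.
#' @return list with `expr` (an [expression_matrix()], samples x genes,
#'   positive normalized-scale values), `cohort` (data.frame: `sample`,
#'   `time` in months, `event`, `age`, `sex`, `stage`, plus the latent
#'   `high` state), and `tb` (named integer tumor-bud counts).
#' @export
generate_bulk_survival <- function(config = cohort_sim_config(),
                                   signature = signature_def(
                                     "TBS", sprintf("SIG%02d", 1:28), "up"),
                                   n_background_genes = 100) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  b <- stats::rnorm(n)            # latent bud fraction (standardized)
  high <- as.integer(b > 0)
  genes <- c(signature$genes, sprintf("BG%04d", seq_len(n_background_genes)))
  base <- stats::runif(length(genes), 4, 8)
  lm <- matrix(base, nrow = n, ncol = length(genes), byrow = TRUE,
               dimnames = list(ids, genes))
  sig_idx <- seq_along(signature$genes)
  lm[, sig_idx] <- lm[, sig_idx] + b     # one log2 unit per latent sd
  expr <- 2^(lm + matrix(stats::rnorm(n * length(genes), 0, 0.4), nrow = n))
  tb <- stats::rpois(n, lambda = exp(0.5 + config$budding_score_link * b))
  names(tb) <- ids
  ev_time <- stats::rexp(n, rate = config$baseline_hazard *
                           config$true_hr^high)
  cens <- stats::runif(n) < config$censoring_rate
  time <- ifelse(cens, stats::runif(n) * ev_time, ev_time)
  event <- as.integer(!cens)
  cohort <- data.frame(sample = ids, time = time, event = event,
                       age = round(stats::runif(n, 40, 85)),
                       sex = sample(c("m", "f"), n, replace = TRUE),
                       stage = sample(c("I", "II", "III", "IV"), n,
                                      replace = TRUE),
                       high = high)
  list(expr = expression_matrix(expr, "raw"), cohort = cohort, tb = tb)
}

#' Simulate a pharmacogenomic drug-response panel
#'
#' Cell-line expression drives a per-line signature score; each compound's
#' viability log-fold-change is linear in that score plus Gaussian noise:
#' `LFC = intercept + slope * score + N(0, noise_sd)`. Entries can be set
#' missing at random.
#'
#' @param n_lines number of cell lines.
#' @param n_compounds number of compounds.
#' @param effect_map named numeric of per-compound slopes; compounds absent
#'   from the map get slope 0. Negative slopes mean higher-scoring lines are
#'   more sensitive (lower viability).
#' @param noise_sd residual sd of the LFC.
#' @param missing_rate probability an LFC entry is missing.
#' @param signature a [signature_def()] planted in the expression matrix.
#' @param seed integer seed.
#' @return list with `expr` (an [expression_matrix()], log2 scale, tagged
#'   `"log2"`), `lfc` (lines x compounds matrix, possibly with NAs), and
#'   `score` (the generating per-line signature score).
#' @export
generate_drug_panel <- function(n_lines = 60, n_compounds = 20,
                                effect_map = NULL, noise_sd = 0.2,
                                missing_rate = 0,
                                signature = signature_def(
                                  "TBS", sprintf("SIG%02d", 1:28), "up"),
                                seed = 1L) {
  set.seed(seed)
  lines <- sprintf("L%03d", seq_len(n_lines))
  compounds <- sprintf("cmpd%03d", seq_len(n_compounds))
  slopes <- stats::setNames(rep(0, n_compounds), compounds)
  if (!is.null(effect_map)) {
    bad <- setdiff(names(effect_map), compounds)
    if (length(bad) > 0) stop("unknown compound(s) in effect_map: ",
                              paste(bad, collapse = ", "))
    slopes[names(effect_map)] <- effect_map
  }
  latent <- stats::rnorm(n_lines)
  genes <- c(signature$genes, sprintf("BG%04d", 1:50))
  base <- stats::runif(length(genes), 3, 7)
  lm <- matrix(base, nrow = n_lines, ncol = length(genes), byrow = TRUE,
               dimnames = list(lines, genes))
  lm[, seq_along(signature$genes)] <- lm[, seq_along(signature$genes)] + latent
  expr <- lm + matrix(stats::rnorm(length(lm), 0, 0.3), nrow = n_lines)
  score <- rowMeans(expr[, signature$genes, drop = FALSE])
  lfc <- outer(score, slopes) +
    matrix(stats::rnorm(n_lines * n_compounds, 0, noise_sd), nrow = n_lines)
  dimnames(lfc) <- list(lines, compounds)
  if (missing_rate > 0)
    lfc[stats::runif(length(lfc)) < missing_rate] <- NA
  list(expr = expression_matrix(expr, "log2"), lfc = lfc, score = score)
}

#' Simulate a gene-set catalog with one planted set
#'
#' @param gene_universe character vector of gene symbols.
#' @param n_sets number of random sets.
#' @param planted_set `NULL`, or genes to embed in a dedicated set named
#'   `"PLANTED_SET"` (padded with random genes to `planted_set_size`).
#' @param planted_set_size size of the planted set.
#' @param set_size_range size range of the random sets.
#' @param seed integer seed.
#' @return A named list of gene sets (class `gene_set_catalog`).
#' @export
generate_geneset_catalog <- function(gene_universe, n_sets = 50,
                                     planted_set = NULL,
                                     planted_set_size = 200,
                                     set_size_range = c(20, 200),
                                     seed = 1L) {
  set.seed(seed)
  if (!is.null(planted_set)) {
    bad <- setdiff(planted_set, gene_universe)
    if (length(bad) > 0) stop("planted genes outside the universe: ",
                              paste(bad, collapse = ", "))
  }
  sizes <- pmin(sample(set_size_range[1]:set_size_range[2], n_sets,
                       replace = TRUE),
                length(gene_universe))
  catalog <- lapply(sizes, function(s) sample(gene_universe, s))
  names(catalog) <- sprintf("RANDOM_SET_%03d", seq_len(n_sets))
  if (!is.null(planted_set)) {
    pad <- sample(setdiff(gene_universe, planted_set),
                  max(0, planted_set_size - length(planted_set)))
    catalog$PLANTED_SET <- c(planted_set, pad)
  }
  structure(catalog, class = "gene_set_catalog")
}
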