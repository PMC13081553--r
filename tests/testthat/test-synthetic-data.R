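test_that("every generator is deterministic under a fixed seed", {
  cfg <- spatial_sim_config(n_genes = 40, n_negative_probes = 5,
                            n_budding_cases = 4, n_nonbudding_cases = 3,
                            seed = 1)
  s1 <- generate_spatial(cfg); s2 <- generate_spatial(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$meta, s2$meta)

  sc1 <- generate_single_cell(n_cells = 100, seed = 4)
  sc2 <- generate_single_cell(n_cells = 100, seed = 4)
  expect_identical(as.matrix(sc1$umi), as.matrix(sc2$umi))
  expect_identical(sc1$meta, sc2$meta)

  bs1 <- generate_bulk_survival(cohort_sim_config(n_samples = 50, seed = 2))
  bs2 <- generate_bulk_survival(cohort_sim_config(n_samples = 50, seed = 2))
  expect_identical(bs1$cohort, bs2$cohort)
  expect_identical(unclass(bs1$expr), unclass(bs2$expr))

  dp1 <- generate_drug_panel(n_lines = 15, n_compounds = 5, seed = 3)
  dp2 <- generate_drug_panel(n_lines = 15, n_compounds = 5, seed = 3)
  expect_identical(dp1$lfc, dp2$lfc)

  gc1 <- generate_geneset_catalog(letters, n_sets = 5, seed = 6)
  gc2 <- generate_geneset_catalog(letters, n_sets = 5, seed = 6)
  expect_identical(unclass(gc1), unclass(gc2))
})

test_that("spatial counts are nonnegative integers with valid metadata", {
  sp <- generate_spatial(spatial_sim_config(n_genes = 50,
                                            n_negative_probes = 6, seed = 3))
  expect_true(all(sp$counts >= 0))
  expect_true(all(sp$counts == round(sp$counts)))
  expect_true(all(sp$meta$stitched_frac >= 0 & sp$meta$stitched_frac <= 1))
  # budding-arm-only segment types never appear in non-budding cases
  nb_cases <- grepl("^N", sp$meta$case_id)
  expect_false(any(sp$meta$segment_type[nb_cases] %in%
                     c("bud", "stroma_bud", "bulk_budding")))
  expect_error(
    generate_spatial(spatial_sim_config(
      n_genes = 10, planted_signature = data.frame(gene = "g9999", fold = 2))),
    "not in gene universe")
})

test_that("negative probes carry no biological signal", {
  sp <- generate_spatial(spatial_sim_config(
    n_genes = 60, n_negative_probes = 10,
    planted_signature = data.frame(gene = sprintf("g%04d", 1:10), fold = 3),
    seed = 5))
  negs <- sp$probes$probe_id[sp$probes$is_negative_control]
  neg_mean <- rowMeans(sp$counts[, negs])
  # Kruskal-Wallis across segment types on per-segment negative-probe means
  kw <- kruskal.test(neg_mean, factor(sp$meta$segment_type))
  expect_gt(kw$p.value, 0.001)
})

test_that("unit planted fold leaves bud vs bulk at the null", {
  cfg <- spatial_sim_config(
    n_genes = 60, n_negative_probes = 5,
    planted_signature = data.frame(gene = sprintf("g%04d", 1:20), fold = 1),
    qc_fail_frac = 0, seed = 8)
  sp <- generate_spatial(cfg)
  m <- sp$meta
  genes <- sp$probes$probe_id[!sp$probes$is_negative_control]
  case_mean <- function(type) {
    sub <- sp$counts[m$segment_type == type, genes]
    rowsum(sub, m$case_id[m$segment_type == type]) /
      as.vector(table(m$case_id[m$segment_type == type]))
  }
  a <- case_mean("bud"); b <- case_mean("bulk_budding")
  p <- sapply(genes, function(g)
    suppressWarnings(wilcox.test(a[, g], b[rownames(a), g],
                                 paired = TRUE)$p.value))
  expect_gte(mean(p > 0.05), 0.95)
})

test_that("planted fold effects are recovered in the case-level moments", {
  # fold 2.5 on 28 genes at the default design: the mean log2 ratio of bud
  # vs budding-bulk case means lies within 0.25 of log2(2.5)
  sp <- spatial_case_matrices()$spatial
  m <- sp$meta
  planted <- sprintf("g%04d", 1:28)
  case_mean <- function(type) {
    sub <- sp$counts[m$segment_type == type, planted]
    rowsum(sub, m$case_id[m$segment_type == type]) /
      as.vector(table(m$case_id[m$segment_type == type]))
  }
  a <- case_mean("bud"); b <- case_mean("bulk_budding")
  ratio <- mean(log2(colMeans(a) / colMeans(b[rownames(a), ])))
  expect_lt(abs(ratio - log2(2.5)), 0.25)
})

test_that("single-cell generator produces a bimodal malignant signature", {
  sc <- generate_single_cell(n_cells = 1500, seed = 9)
  pre <- sc_preprocess(sc$umi, sc$meta, min_genes = 50)
  sig <- signature_def("TBS", sprintf("SIG%02d", 1:28), "up")
  scores <- score_signature(pre$mat, sig)
  mal <- scores[pre$meta$cell_type == "malignant"]
  # model-selection oracle: two components beat one by BIC
  mclustBIC <- mclust::mclustBIC
  b1 <- mclust::Mclust(as.numeric(mal), G = 1, verbose = FALSE)$bic
  b2 <- mclust::Mclust(as.numeric(mal), G = 2, modelNames = "V",
                       verbose = FALSE)$bic
  expect_gt(b2, b1)   # mclust BIC: larger is better
  # and the fitted cutoff splits the cells into two sizeable groups
  fit <- fit_bimodal_cutoff(mal, seed = 1)
  expect_true(fit$converged)
  cl <- classify(mal, fit$cutoff)
  expect_gt(min(table(cl)) / length(cl), 0.15)

  # degenerate identical components are flagged non-bimodal downstream
  sc0 <- generate_single_cell(
    n_cells = 600,
    bimodal_params = list(means = c(2, 2), sds = c(1, 1),
                          weights = c(0.5, 0.5)), seed = 10)
  pre0 <- sc_preprocess(sc0$umi, sc0$meta, min_genes = 50)
  mal0 <- score_signature(pre0$mat, sig)[pre0$meta$cell_type == "malignant"]
  expect_false(fit_bimodal_cutoff(mal0, seed = 1)$converged)

  expect_error(generate_single_cell(
    bimodal_params = list(means = c(0, 5), sds = c(1, 1),
                          weights = c(0.6, 0.6))), "sum to 1")
  expect_error(generate_single_cell(cell_type_mix = c(fibroblast = 1)),
               "malignant")
})

test_that("bulk survival cohorts honor censoring and the bud-count link", {
  # censoring_rate = 0: every event observed
  bs <- generate_bulk_survival(cohort_sim_config(n_samples = 80,
                                                 censoring_rate = 0, seed = 3))
  expect_true(all(bs$cohort$event == 1))
  expect_true(all(bs$cohort$time > 0))

  # budding_score_link = 0: TB counts independent of the signature
  bs0 <- generate_bulk_survival(cohort_sim_config(n_samples = 300,
                                                  budding_score_link = 0,
                                                  seed = 4))
  sig <- signature_def("TBS", sprintf("SIG%02d", 1:28), "up")
  s <- score_signature(bs0$expr, sig)
  rho <- suppressWarnings(cor(as.numeric(s), bs0$tb, method = "spearman"))
  expect_lt(abs(rho), 0.1)

  # a strong link makes TB track the signature
  bs1 <- generate_bulk_survival(cohort_sim_config(n_samples = 300,
                                                  budding_score_link = 1,
                                                  seed = 5))
  s1 <- score_signature(bs1$expr, sig)
  rho1 <- suppressWarnings(cor(as.numeric(s1), bs1$tb, method = "spearman"))
  expect_gt(rho1, 0.4)
})

test_that("null-hazard cohorts give calibrated Cox confidence intervals", {
  # true HR 1 between latent states: the 95% CI covers 1 in most replicates
  cover <- sapply(1:100, function(s) {
    bs <- generate_bulk_survival(cohort_sim_config(n_samples = 120,
                                                   true_hr = 1, seed = s))
    res <- suppressWarnings(cox_model(bs$cohort, "high"))
    res$ci_low <= 1 && 1 <= res$ci_high
  })
  expect_gte(mean(cover), 0.90)
})

test_that("drug panel nulls and planted slopes behave as configured", {
  sig <- signature_def("TBS", sprintf("SIG%02d", 1:28), "up")
  # all slopes zero: no FDR-significant compound in most runs
  hits <- sapply(1:5, function(s) {
    dp <- generate_drug_panel(n_lines = 40, n_compounds = 15, seed = s)
    sc <- score_signature(dp$expr, sig)
    sum(drug_screen(sc, dp$lfc)$q <= 0.05)
  })
  expect_lte(mean(hits > 0), 0.2)

  # slope -0.8, noise 0.2, 60 lines: flagged at FDR 5% with rho < -0.6
  dp <- generate_drug_panel(n_lines = 60, n_compounds = 15,
                            effect_map = c(cmpd003 = -0.8),
                            noise_sd = 0.2, seed = 11)
  sc <- score_signature(dp$expr, sig)
  res <- drug_screen(sc, dp$lfc)
  hit <- res[res$compound == "cmpd003", ]
  expect_true(hit$sensitive)
  expect_lt(hit$rho, -0.6)

  # missingness is honored
  dpm <- generate_drug_panel(n_lines = 30, n_compounds = 5,
                             missing_rate = 0.2, seed = 12)
  expect_gt(sum(is.na(dpm$lfc)), 0)
})

test_that("planted correlation pairs appear only in the gated condition", {
  cfg <- spatial_sim_config(
    n_genes = 40, n_negative_probes = 5, qc_fail_frac = 0,
    planted_corr_pairs = data.frame(gene_a = "g0001", gene_b = "g0002",
                                    condition = "bud_only",
                                    target_rho = 0.9),
    seed = 13)
  sp <- generate_spatial(cfg)
  m <- sp$meta
  case_mean <- function(type, g) {
    sub <- sp$counts[m$segment_type == type, g]
    rowsum(sub, m$case_id[m$segment_type == type]) /
      as.vector(table(m$case_id[m$segment_type == type]))
  }
  rho_bud <- cor(case_mean("bud", "g0001"), case_mean("bud", "g0002"),
                 method = "spearman")
  rho_bulk <- cor(case_mean("bulk_budding", "g0001"),
                  case_mean("bulk_budding", "g0002"), method = "spearman")
  expect_gt(rho_bud, 0.6)
  expect_lt(abs(rho_bulk), 0.5)
})

test_that("generated inputs round-trip through the text formats", {
  sp <- generate_spatial(spatial_sim_config(n_genes = 20,
                                            n_negative_probes = 3,
                                            n_budding_cases = 2,
                                            n_nonbudding_cases = 2, seed = 14))
  d <- withr::local_tempdir()
  f <- file.path(d, "counts.tsv")
  write_matrix_tsv(sp$counts, f)
  expect_equal(read_matrix_tsv(f), sp$counts)

  sc <- generate_single_cell(n_cells = 40, n_genes = 60, seed = 15)
  write_mtx_triplet(sc$umi, file.path(d, "mtx"))
  back <- read_mtx_triplet(file.path(d, "mtx"))
  expect_equal(as.matrix(back), as.matrix(sc$umi))

  cat_path <- file.path(d, "sets.gmt")
  catalog <- generate_geneset_catalog(sprintf("g%03d", 1:100), n_sets = 4,
                                      planted_set = sprintf("g%03d", 1:10),
                                      planted_set_size = 20,
                                      set_size_range = c(5, 15), seed = 16)
  write_gmt(catalog, cat_path)
  expect_equal(unclass(read_gmt(cat_path)), unclass(catalog),
               ignore_attr = TRUE)

  sig <- signature_def("TBS", sprintf("SIG%02d", 1:5), "up", "contrast1")
  sig_path <- file.path(d, "sig.txt")
  write_signature(sig, sig_path)
  back_sig <- read_signature(sig_path)
  expect_equal(back_sig$genes, sig$genes)
  expect_equal(back_sig$direction, "up")
})
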