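test_that("LOQ formula matches its definition and clamps at 2", {
  # zero-variance negatives: geometric sd 1, clamp keeps the floor
  r <- compute_loq(c(2, 2, 2))
  expect_equal(r$neg_geo_mean, 2)
  expect_equal(r$neg_geo_sd, 1)
  expect_equal(r$loq, 2)

  # all-equal counts c >= 2 give loq = c
  expect_equal(compute_loq(c(7, 7, 7, 7))$loq, 7)

  # literal re-evaluation of the formula on [1, 9]
  r <- compute_loq(c(1, 9))
  gm <- exp(mean(log(c(1, 9))))
  gsd <- exp(sd(log(c(1, 9))))
  expect_equal(r$neg_geo_mean, 3)
  expect_equal(r$neg_geo_sd, gsd)
  expect_equal(r$loq, max(2, gm * gsd^2))

  # zeros floored to 0.5 before the log
  r0 <- compute_loq(c(0, 4))
  expect_equal(r0$neg_geo_mean, exp(mean(log(c(0.5, 4)))))

  expect_error(compute_loq(c(5)), "at least 2")
  expect_error(compute_loq(c(5), segment_id = "segX"), "segX")
})

test_that("LOQ is always at least 2 on random negative-probe draws", {
  set.seed(42)
  for (i in 1:100) {
    x <- rpois(sample(2:10, 1), lambda = runif(1, 0, 5))
    expect_gte(compute_loq(x)$loq, 2)
  }
})

test_that("segment QC filters are inclusive at the stated boundaries", {
  counts <- matrix(rpois(5 * 4, 20), 5, 4,
                   dimnames = list(paste0("s", 1:5),
                                   c("g1", "g2", "NP1", "NP2")))
  x <- make_fixture_counts(counts)
  x$meta$raw_reads <- c(39999, 40000, 1e5, 1e5, 1e5)
  x$meta$ntc_count <- c(100, 100, 1000, 1001, 100)
  x$meta$stitched_frac <- c(0.9, 0.80, 0.9, 0.9, 0.9)
  x$meta$aligned_frac <- c(0.9, 0.70, 0.9, 0.9, 0.9)
  x$meta$saturation_frac <- c(0.9, 0.50, 0.9, 0.9, 0.9)
  res <- filter_segments(x)
  # s1 fails reads only; s2 sits exactly at every threshold and passes;
  # s4 fails the NTC cap
  expect_equal(res$report$pass, c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(res$report$fail_reasons[1], "min_reads")
  expect_equal(res$report$fail_reasons[4], "max_ntc")
  expect_equal(rownames(res$kept$counts), c("s2", "s3", "s5"))

  x$meta$raw_reads[3] <- NA
  expect_error(filter_segments(x), "s3")
})

test_that("raising any QC threshold never enlarges the kept set", {
  set.seed(7)
  sp <- generate_spatial(spatial_sim_config(n_genes = 40,
                                            n_negative_probes = 5,
                                            qc_fail_frac = 0.3, seed = 7))
  base <- filter_segments(sp)$report
  strict <- filter_segments(sp, qc_thresholds(min_reads = 80000,
                                              min_saturation = 0.7))$report
  expect_true(all(base$pass[strict$pass]))
})

test_that("LOQ filtering drops background-only genes and empty segments", {
  set.seed(11)
  n_seg <- 20; n_gene <- 100
  counts <- matrix(rpois(n_seg * n_gene, 60), n_seg, n_gene,
                   dimnames = list(sprintf("s%02d", 1:n_seg),
                                   sprintf("g%03d", 1:n_gene)))
  # three planted always-background genes among 100
  bg_genes <- c("g003", "g050", "g099")
  counts[, bg_genes] <- matrix(rpois(n_seg * 3, 1), n_seg, 3)
  neg <- matrix(rpois(n_seg * 4, 4), n_seg, 4,
                dimnames = list(rownames(counts), paste0("NP", 1:4)))
  x <- make_fixture_counts(cbind(counts, neg))
  out <- filter_by_loq(x)
  expect_setequal(setdiff(colnames(counts), colnames(out$counts)), bg_genes)

  # independent loop-based recount of both filters
  loq <- sapply(rownames(x$counts), function(s) {
    v <- pmax(x$counts[s, paste0("NP", 1:4)], 0.5)
    max(2, exp(mean(log(v))) * exp(sd(log(v)))^2)
  })
  keep_seg <- sapply(rownames(counts), function(s)
    mean(counts[s, ] >= loq[s]) >= 0.05)
  keep_gene <- sapply(colnames(counts), function(g)
    mean(counts[keep_seg, g] >= loq[keep_seg]) >= 0.10)
  expect_setequal(rownames(out$counts), names(which(keep_seg)))
  expect_setequal(colnames(out$counts), names(which(keep_gene)))

  # a segment with zero counts everywhere is dropped (0% above LOQ)
  x$counts["s01", ] <- 0
  out2 <- filter_by_loq(x)
  expect_false("s01" %in% rownames(out2$counts))
})

test_that("gene detected in exactly 10% of segments is kept (inclusive)", {
  n_seg <- 10
  counts <- matrix(50, n_seg, 20,
                   dimnames = list(sprintf("s%02d", 1:n_seg),
                                   sprintf("g%02d", 1:20)))
  counts[, "g01"] <- 0
  counts["s01", "g01"] <- 50      # detected in exactly 1/10 segments
  neg <- matrix(2, n_seg, 2, dimnames = list(rownames(counts), c("NP1", "NP2")))
  x <- make_fixture_counts(cbind(counts, neg))   # LOQ = 2 everywhere
  out <- filter_by_loq(x)
  expect_true("g01" %in% colnames(out$counts))
})

test_that("Q3 normalization equalizes upper quartiles and is idempotent", {
  # single segment: identity
  m1 <- matrix(rpois(50, 30), 1, dimnames = list("s1", sprintf("g%02d", 1:50)))
  expect_equal(unclass(q3_normalize(m1))[, ], m1[, ],
               ignore_attr = TRUE)

  # one segment exactly 2x the other: identical rows afterwards
  base <- rpois(50, 30) + 1
  m2 <- rbind(s1 = base, s2 = 2 * base)
  colnames(m2) <- sprintf("g%02d", 1:50)
  n2 <- q3_normalize(m2)
  expect_equal(unname(n2["s1", ]), unname(n2["s2", ]))

  # random matrix: per-segment Q3 all equal after normalization
  set.seed(3)
  m <- matrix(rpois(500, 40), 10, 50,
              dimnames = list(paste0("s", 1:10), paste0("g", 1:50)))
  n <- q3_normalize(m)
  q3 <- apply(n, 1, quantile, 0.75, names = FALSE)
  expect_lt(max(q3) - min(q3), 1e-9)
  expect_equal(attr(n, "normalization"), "q3")

  # idempotence
  expect_equal(unclass(q3_normalize(n)), unclass(n), tolerance = 1e-12)

  expect_error(q3_normalize(rbind(a = rep(0, 10), b = rep(1, 10))), "zero upper quartile")
})

test_that("case-level aggregation equals loop-based group means", {
  # one segment per group: identity
  m <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
  meta <- data.frame(segment_id = c("s1", "s2"), case_id = c("c1", "c2"),
                     segment_type = "bud", compartment = "tumor")
  agg <- aggregate_case_level(expression_matrix(m, "q3"), meta)
  expect_equal(names(agg), "bud.tumor")
  expect_equal(unclass(agg[["bud.tumor"]])[, ], m[, ], ignore_attr = TRUE)

  # two segments v and 3v average to 2v
  v <- c(g1 = 2, g2 = 10)
  m2 <- rbind(s1 = v, s2 = 3 * v)
  meta2 <- data.frame(segment_id = c("s1", "s2"), case_id = "c1",
                      segment_type = "bud", compartment = "tumor")
  agg2 <- aggregate_case_level(expression_matrix(m2, "q3"), meta2)
  expect_equal(unname(agg2[["bud.tumor"]]["c1", ]), unname(2 * v))

  # randomized grouping vs an explicit loop
  set.seed(9)
  n_seg <- 30
  m3 <- matrix(runif(n_seg * 5, 0, 100), n_seg, 5,
               dimnames = list(sprintf("s%02d", 1:n_seg), paste0("g", 1:5)))
  meta3 <- data.frame(
    segment_id = rownames(m3),
    case_id = sample(paste0("c", 1:6), n_seg, replace = TRUE),
    segment_type = sample(c("bud", "bulk_budding"), n_seg, replace = TRUE),
    compartment = sample(c("tumor", "stroma"), n_seg, replace = TRUE))
  agg3 <- aggregate_case_level(expression_matrix(m3, "q3"), meta3)
  for (key in names(agg3)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    sel <- meta3$segment_type == parts[1] & meta3$compartment == parts[2]
    for (case in rownames(agg3[[key]])) {
      idx <- sel & meta3$case_id == case
      expect_equal(unname(agg3[[key]][case, ]),
                   unname(colMeans(m3[idx, , drop = FALSE])))
    }
  }
})

test_that("single-cell preprocessing applies the stated filters and transform", {
  set.seed(21)
  n_gene <- 250; n_cell <- 60
  umi <- matrix(rpois(n_gene * n_cell, 3), n_gene, n_cell,
                dimnames = list(c(sprintf("G%03d", 1:(n_gene - 5)),
                                  paste0("MT-", 1:5)),
                                sprintf("c%02d", 1:n_cell)))
  # cell 1: exactly 199 detected genes -> excluded
  umi[, 1] <- 0
  umi[1:199, 1] <- 1
  # cell 2: high mito fraction
  umi[paste0("MT-", 1:5), 2] <- 500
  res <- sc_preprocess(umi, min_genes = 200, max_genes = 240,
                       max_mito_frac = 0.10, min_cell_frac = 0.001)
  expect_false("c01" %in% rownames(res$mat))
  expect_false("c02" %in% rownames(res$mat))

  # independent loop-based recount of the three filters
  det <- colSums(umi > 0)
  mito <- colSums(umi[paste0("MT-", 1:5), ]) / colSums(umi)
  keep <- det >= 200 & det <= 240 & mito <= 0.10
  expect_equal(res$report$n_cells_kept, sum(keep))
  expect_equal(res$report$n_low_genes, sum(det < 200))
  expect_equal(res$report$n_high_genes, sum(det > 240))

  # closed-form value: all counts in one gene, total 10,000
  umi2 <- matrix(0, 3, 55, dimnames = list(c("GA", "GB", "MT-1"),
                                           paste0("c", 1:55)))
  umi2["GA", ] <- 10000
  umi2["GB", ] <- 0
  umi2["GA", 1] <- 10000
  res2 <- sc_preprocess(umi2, min_genes = 1, max_genes = 8000)
  expect_equal(unname(res2$mat[1, "GA"]), log(1 + 10000))
  expect_equal(attr(res2$mat, "normalization"), "lognorm_sc")
})

test_that("missing mitochondrial genes produce a warning, not an error", {
  umi <- matrix(rpois(100 * 55, 5), 100, 55,
                dimnames = list(sprintf("G%03d", 1:100), paste0("c", 1:55)))
  expect_warning(res <- sc_preprocess(umi, min_genes = 10),
                 "mito filter skipped")
  expect_true(res$report$mito_skipped)
})
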