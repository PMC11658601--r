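toy_geno <- function() {
  dosage <- matrix(c(0, 1, 2, 1, 0, 2,
                     2, 2, 1, 0, 0, 1), 6, 2,
                   dimnames = list(sprintf("V%03d", 1:6), NULL))
  genotype_matrix(dosage, data.frame(id = c("s1", "s2"),
                                     chrom = c("chr1", "chr2"),
                                     pos = c(100L, 200L)))
}

test_that("VCF and CSV genotype round trips agree", {
  g <- toy_geno()
  g$dosage[2, 1] <- NA
  f_vcf <- withr::local_tempfile(fileext = ".vcf")
  f_csv <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(g, f_vcf)
  write_genotypes(g, f_csv)
  from_vcf <- read_genotypes(f_vcf)
  from_csv <- read_genotypes(f_csv)
  expect_equal(from_vcf$dosage, g$dosage, ignore_attr = TRUE)
  expect_equal(from_csv$dosage, g$dosage, ignore_attr = TRUE)
  expect_equal(from_vcf$snp_info$pos, g$snp_info$pos)
  # ./. became NA
  expect_true(is.na(from_vcf$dosage[2, 1]))
  # cross-format identity
  expect_equal(unname(from_vcf$dosage), unname(from_csv$dosage))
})

test_that("QC boundaries: >10% missing and <5% MAF removed, boundaries kept", {
  set.seed(30)
  n <- 20
  base <- matrix(rbinom(n * 4, 2, 0.4), n, 4,
                 dimnames = list(sprintf("V%03d", 1:n), NULL))
  base[1:3, 1] <- NA                       # 15% missing -> dropped
  base[1:2, 2] <- NA                       # exactly 10% -> kept
  base[, 3] <- c(rep(1, 2), rep(0, 18))    # freq 2/40 = 0.05 -> kept
  base[, 4] <- c(1, 1, rep(0, 18))
  base[1, 4] <- 0                          # freq 1/40 = 0.025 -> dropped
  g <- genotype_matrix(base, data.frame(id = paste0("s", 1:4),
                                        chrom = "chr1", pos = 1:4 * 10L))
  q <- qc_filter(g)
  expect_equal(q$snp_info$id, c("s2", "s3"))
  expect_equal(attr(q, "qc_counts"),
               c(removed_missing = 1L, removed_maf = 1L))
  # idempotent
  q2 <- qc_filter(q)
  expect_equal(q2$dosage, q$dosage)
  # a clean matrix passes unchanged
  clean <- genotype_matrix(matrix(rbinom(40, 2, 0.5), 20, 2,
                                  dimnames = list(sprintf("V%03d", 1:20), NULL)),
                           data.frame(id = c("a", "b"), chrom = "chr1",
                                      pos = c(1L, 2L)))
  expect_equal(qc_filter(clean)$dosage, clean$dosage)
})

test_that("PCA covariates separate planted subpopulations and match eigen", {
  gg <- generate_genotypes(60, 400, missing_rate = 0.02, seed = 31,
                           n_subpop = 2, subpop_divergence = 0.35)
  pcs <- pca_covariates(gg$genotypes, n_pc = 3)
  pop <- rep_len(1:2, 60)
  expect_true(max(pcs[pop == 1, 1]) < min(pcs[pop == 2, 1]) ||
                min(pcs[pop == 1, 1]) > max(pcs[pop == 2, 1]))

  # against a direct eigendecomposition of the centered imputed matrix
  d <- gg$genotypes$dosage
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- mean(d[, j], na.rm = TRUE)
  X <- scale(d, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(X), symmetric = TRUE)
  for (j in 1:3) {
    ref <- X %*% ev$vectors[, j]
    err <- min(max(abs(pcs[, j] - ref)), max(abs(pcs[, j] + ref)))
    expect_lt(err, 1e-8)
  }
  expect_equal(ncol(pca_covariates(gg$genotypes, 0)), 0)
  expect_error(pca_covariates(gg$genotypes, 60), "n_pc")
})

test_that("association scan matches lm and flags edge cases", {
  set.seed(32)
  gg <- generate_genotypes(80, 20, missing_rate = 0.05, seed = 33)
  G <- gg$genotypes
  y <- setNames(rnorm(80), rownames(G$dosage))
  res <- assoc_scan(G, y)
  # independent per-SNP check via stats::lm
  for (j in c(1, 7, 19)) {
    d <- G$dosage[, j]
    fit <- summary(lm(y ~ d))
    expect_equal(res$beta[j], fit$coefficients["d", 1], tolerance = 1e-10)
    expect_equal(res$se[j], fit$coefficients["d", 2], tolerance = 1e-10)
    expect_equal(res$p[j], fit$coefficients["d", 4], tolerance = 1e-10)
    expect_equal(res$n_used[j], sum(!is.na(d)))
  }
  # perfect fit: phenotype equals a SNP's dosage
  y2 <- setNames(as.numeric(G$dosage[, 5]), rownames(G$dosage))
  y2[is.na(y2)] <- 0
  G5 <- G; G5$dosage[, 5][is.na(G5$dosage[, 5])] <- 0
  res2 <- assoc_scan(G5, y2)
  expect_equal(res2$beta[5], 1, tolerance = 1e-8)
  expect_lt(res2$p[5], 1e-100)

  # affine phenotype rescaling leaves p untouched
  res3 <- assoc_scan(G, 3 * y + 10)
  expect_equal(res3$p, res$p, tolerance = 1e-9)

  # covariates are honored (matches lm with the same design)
  pcs <- pca_covariates(G, 2)
  resc <- assoc_scan(G, y, pcs)
  d <- G$dosage[, 3]
  fitc <- summary(lm(y ~ d + pcs[, 1] + pcs[, 2]))
  expect_equal(resc$p[3], fitc$coefficients["d", 4], tolerance = 1e-9)

  expect_error(assoc_scan(G, setNames(rep(1, 80), rownames(G$dosage))),
               "constant")
})

test_that("type-I error of the null scan is nominal", {
  gg <- generate_genotypes(200, 1000, missing_rate = 0, seed = 34)
  set.seed(35)
  y <- setNames(rnorm(200), rownames(gg$genotypes$dosage))
  res <- assoc_scan(gg$genotypes, y)
  frac <- mean(res$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("significance flagging is boundary-inclusive at 3.5", {
  res <- structure(data.frame(snp_id = c("a", "b", "c"), chrom = "chr1",
                              pos = c(1L, 2L, 3L),
                              beta = 0, se = 1,
                              p = 10^-c(3.4, 3.5, 3.6),
                              neg_log10_p = c(3.4, 3.5, 3.6),
                              n_used = 10L, flag = "ok",
                              stringsAsFactors = FALSE),
                   class = c("gwas_result", "data.frame"))
  hits <- flag_significant(res)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$snp_id, c("c", "b"))               # sorted by p
  expect_equal(nrow(flag_significant(res, Inf)), 0)
  # brute-force filter equivalence
  expect_setequal(hits$snp_id, res$snp_id[res$neg_log10_p >= 3.5])
})

test_that("Manhattan and QQ exports have one row per SNP and sane quantiles", {
  gg <- generate_genotypes(100, 300, missing_rate = 0, seed = 36)
  set.seed(37)
  y <- setNames(rnorm(100), rownames(gg$genotypes$dosage))
  res <- assoc_scan(gg$genotypes, y)
  md <- manhattan_data(res)
  qd <- qq_data(res)
  expect_equal(nrow(md), 300)
  expect_equal(nrow(qd), 300)
  # cumulative coordinate is increasing within each chromosome
  for (ch in unique(md$chrom))
    expect_true(all(diff(md$cum_pos[md$chrom == ch]) > 0))
  # under the null, ~95% of QQ points sit inside the pointwise 95% band
  n <- 300
  p_sorted <- sort(10^-qd$observed)
  lo <- qbeta(0.025, seq_len(n), n + 1 - seq_len(n))
  hi <- qbeta(0.975, seq_len(n), n + 1 - seq_len(n))
  inside <- mean(p_sorted >= lo & p_sorted <= hi)
  expect_gt(inside, 0.85)

  dir <- withr::local_tempdir()
  paths <- export_gwas_plots(res, dir)
  expect_true(file.exists(file.path(dir, "manhattan.csv")))
  expect_true(file.exists(file.path(dir, "qq.csv")))
  expect_equal(nrow(read.csv(file.path(dir, "manhattan.csv"))), 300)

  # missing positions: Manhattan skipped with a warning, QQ still written
  res_nopos <- res
  res_nopos$pos <- NA_integer_
  dir2 <- withr::local_tempdir()
  expect_warning(export_gwas_plots(res_nopos, dir2), "positions")
  expect_false(file.exists(file.path(dir2, "manhattan.csv")))
  expect_true(file.exists(file.path(dir2, "qq.csv")))
})

test_that("planted QTLs are recovered as the top hit on their chromosome", {
  n_rep <- 20
  hits <- 0
  for (r in seq_len(n_rep)) {
    gg <- generate_genotypes(150, 90, missing_rate = 0.02, seed = 400 + r,
                             qtl_spec = data.frame(snp_index = 45,
                                                   parameter = "a", effect = 5))
    ve <- qtl_variety_effects(gg$genotypes, gg$qtl_map)
    lay <- generate_layout(trial_design(n_varieties = 150,
                                        treatments = c(N240 = 240),
                                        n_replicates = 1))
    tr <- simulate_trajectories(lay, growth_config(), seed = 500 + r,
                                variety_effects = ve)
    tr$value <- tr$true_height_cm
    tt <- trait_table(tr, grouping = "variety_treatment")
    pheno <- setNames(tt$v_max, tt$variety_id)
    G <- qc_filter(gg$genotypes)
    res <- assoc_scan(G, pheno[rownames(G$dosage)], pca_covariates(G, 3))
    causal_chrom <- gg$genotypes$snp_info$chrom[45]
    on_chrom <- res[res$chrom == causal_chrom, ]
    if (on_chrom$snp_id[which.min(on_chrom$p)] == "snp00045") hits <- hits + 1
  }
  expect_gte(hits, 0.8 * n_rep)
})
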