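#' Read and write genotype matrices
#'
#' Two interchange formats:
#' * `vcf` — biallelic VCF 4.2 with GT fields; dosage counts alternate
#'   alleles (0/0 -> 0, 0/1 -> 1, 1/1 -> 2, ./. -> NA). Reading uses the
#'   vcfR parser; multiallelic records are skipped with a warning and
#'   counted in attribute `"n_skipped"`. Writing emits plain-text VCF.
#' * `csv` — dosage matrix (rows = varieties, header = SNP ids) plus a
#'   companion map `<path>.map.csv` with columns id, chrom, pos.
#'
#' @param path file path.
#' @param format `"vcf"` or `"csv"`; default guessed from the extension.
#' @param genotypes a [genotype_matrix()].
#' @return `read_genotypes` returns a [genotype_matrix()];
#'   `write_genotypes` returns `path` invisibly.
#' @export
read_genotypes <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (format == "vcf") read_geno_vcf(path)
  else if (format == "csv") read_geno_csv(path)
  else stop("unsupported genotype format: ", format, call. = FALSE)
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(genotypes, path, format = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (format == "vcf") write_geno_vcf(genotypes, path)
  else if (format == "csv") write_geno_csv(genotypes, path)
  else stop("unsupported genotype format: ", format, call. = FALSE)
  invisible(path)
}

write_geno_vcf <- function(genotypes, path) {
  d <- genotypes$dosage
  info <- genotypes$snp_info
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1], nrow(d), ncol(d))
  gt[is.na(d)] <- "./."
  for (j in seq_len(ncol(d))) {
    writeLines(paste(c(info$chrom[j], info$pos[j], info$id[j], "A", "G", ".",
                       "PASS", ".", "GT", gt[, j]), collapse = "\t"), con)
  }
}

read_geno_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    warning(sum(multi), " multiallelic record(s) skipped", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  alt_count <- function(s) {
    ifelse(is.na(s) | grepl("\\.", s), NA_real_,
           vapply(strsplit(gsub("\\|", "/", s), "/"),
                  function(a) sum(a == "1"), numeric(1)))
  }
  d <- t(apply(gt, 2, alt_count))
  if (nrow(fix) == 1) d <- matrix(d, ncol = 1, dimnames = list(colnames(gt), NULL))
  out <- genotype_matrix(d, data.frame(id = fix$ID, chrom = fix$CHROM,
                                       pos = as.integer(fix$POS),
                                       stringsAsFactors = FALSE))
  attr(out, "n_skipped") <- sum(multi)
  out
}

write_geno_csv <- function(genotypes, path) {
  utils::write.csv(as.data.frame(genotypes$dosage), path, row.names = TRUE)
  utils::write.csv(genotypes$snp_info, paste0(path, ".map.csv"),
                   row.names = FALSE)
}

read_geno_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  info <- utils::read.csv(paste0(path, ".map.csv"), stringsAsFactors = FALSE)
  genotype_matrix(as.matrix(d), info)
}

snp_maf <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Genotype quality control
#'
#' Removes SNPs with more than `max_missing` missing calls, then SNPs
#' whose minor allele frequency (on non-missing dosages) falls below
#' `min_maf`. Both boundaries are kept: exactly 10% missing or exactly
#' 5% MAF survives. SNP order is preserved; counts removed by each rule
#' are attached as attribute `"qc_counts"`.
#'
#' @param genotypes a non-empty [genotype_matrix()].
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @param min_maf minimum tolerated MAF (default 0.05).
#' @return The filtered [genotype_matrix()].
#' @export
qc_filter <- function(genotypes, max_missing = 0.10, min_maf = 0.05) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (max_missing < 0 || max_missing >= 1 || min_maf < 0 || min_maf >= 1)
    stop("thresholds must lie in [0, 1)", call. = FALSE)
  d <- genotypes$dosage
  if (ncol(d) == 0 || nrow(d) == 0) stop("empty genotype matrix", call. = FALSE)
  missing_frac <- colMeans(is.na(d))
  keep1 <- missing_frac <= max_missing
  maf <- snp_maf(d[, keep1, drop = FALSE])
  keep2 <- maf >= min_maf
  keep <- which(keep1)[keep2]
  out <- genotype_matrix(d[, keep, drop = FALSE],
                         genotypes$snp_info[keep, , drop = FALSE])
  attr(out, "qc_counts") <- c(removed_missing = sum(!keep1),
                              removed_maf = sum(!keep2))
  out
}

#' Principal-component covariates for population structure
#'
#' Mean-imputes missing dosages per SNP, centers columns and returns the
#' top `n_pc` principal-component scores per variety. Signs follow the
#' convention that each component's first nonzero loading is positive.
#'
#' @param genotypes a QC'd [genotype_matrix()].
#' @param n_pc number of components (default 3); 0 returns a 0-column
#'   matrix (intercept-only downstream design).
#' @return Numeric matrix varieties x n_pc with rownames = variety ids.
#' @export
pca_covariates <- function(genotypes, n_pc = 3) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosage
  if (n_pc <= 0)
    return(matrix(numeric(0), nrow(d), 0, dimnames = list(rownames(d), NULL)))
  if (n_pc >= nrow(d)) stop("n_pc must be < number of varieties", call. = FALSE)
  for (j in seq_len(ncol(d))) {
    m <- is.na(d[, j])
    if (any(m)) d[m, j] <- mean(d[, j], na.rm = TRUE)
  }
  pr <- stats::prcomp(d, center = TRUE, scale. = FALSE)
  k <- min(n_pc, ncol(pr$rotation))
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pr$rotation[, j]
    nz <- which(abs(load) > 1e-12)[1]
    if (!is.na(nz) && load[nz] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(d)
  scores
}

#' Single-marker association scan
#'
#' Per-SNP ordinary least squares of the phenotype on dosage plus an
#' intercept and optional covariates (typically principal-component
#' scores), with a two-sided t test on the dosage coefficient.
#' Varieties with a missing dosage at a SNP are dropped for that SNP
#' (`n_used` records the count). SNPs monomorphic after drops report
#' beta = 0, p = 1 and flag `"monomorphic"`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotype named numeric vector (names = variety ids) or
#'   data.frame (variety_id, value).
#' @param covariates optional numeric matrix with rownames = variety ids.
#' @return A `gwas_result`: data.frame (snp_id, chrom, pos, beta, se, p,
#'   neg_log10_p, n_used, flag) with the covariate description attached.
#' @export
assoc_scan <- function(genotypes, phenotype, covariates = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.data.frame(phenotype))
    phenotype <- stats::setNames(phenotype$value, phenotype$variety_id)
  ids <- rownames(genotypes$dosage)
  y <- phenotype[ids]
  if (anyNA(y)) stop("phenotype missing for some varieties", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant phenotype", call. = FALSE)
  C <- if (is.null(covariates)) matrix(numeric(0), length(ids), 0)
  else as.matrix(covariates)[ids, , drop = FALSE]
  n_cov <- ncol(C)
  d <- genotypes$dosage
  m <- ncol(d)
  beta <- se <- p <- rep(NA_real_, m)
  n_used <- integer(m)
  flag <- rep("ok", m)
  for (j in seq_len(m)) {
    g <- d[, j]
    keep <- !is.na(g)
    n <- sum(keep)
    n_used[j] <- n
    if (n < n_cov + 3 || stats::sd(g[keep]) == 0) {
      beta[j] <- 0; se[j] <- NA; p[j] <- 1
      flag[j] <- if (n >= n_cov + 3) "monomorphic" else "insufficient-n"
      next
    }
    X <- cbind(1, g[keep], C[keep, , drop = FALSE])
    fit <- stats::lm.fit(X, y[keep])
    df <- n - fit$rank
    XtXinv <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
    if (df <= 0 || is.na(fit$coefficients[2]) || is.null(XtXinv)) {
      beta[j] <- 0; se[j] <- NA; p[j] <- 1; flag[j] <- "collinear"
      next
    }
    sigma2 <- sum(fit$residuals^2) / df
    se[j] <- sqrt(sigma2 * XtXinv[2, 2])
    beta[j] <- fit$coefficients[2]
    tstat <- beta[j] / se[j]
    p[j] <- 2 * stats::pt(-abs(tstat), df)
  }
  p <- pmax(p, .Machine$double.xmin)
  out <- data.frame(snp_id = genotypes$snp_info$id,
                    chrom = genotypes$snp_info$chrom,
                    pos = genotypes$snp_info$pos,
                    beta = beta, se = se, p = p,
                    neg_log10_p = -log10(p), n_used = n_used, flag = flag,
                    stringsAsFactors = FALSE)
  attr(out, "covariates") <- if (n_cov) sprintf("%d PC covariate(s)", n_cov)
  else "intercept only"
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Flag significant markers
#'
#' Returns the SNPs whose -log10(p) reaches `neg_log10_threshold`
#' (boundary inclusive; default 3.5), sorted by ascending p.
#'
#' @param result a `gwas_result`.
#' @param neg_log10_threshold significance cutoff on the -log10(p) scale.
#' @return The flagged subset of `result` with attribute `"threshold"`.
#' @export
flag_significant <- function(result, neg_log10_threshold = 3.5) {
  stopifnot(inherits(result, "gwas_result"))
  hit <- result[result$neg_log10_p >= neg_log10_threshold, , drop = FALSE]
  hit <- hit[order(hit$p), , drop = FALSE]
  attr(hit, "threshold") <- neg_log10_threshold
  hit
}

#' Manhattan and QQ plot data
#'
#' `manhattan_data` adds a cumulative genome coordinate (chromosomes laid
#' end to end in order of appearance); `qq_data` pairs sorted observed
#' -log10(p) with uniform expected quantiles -log10((i - 0.5) / n).
#'
#' @param result a `gwas_result`.
#' @return A data.frame (one row per SNP).
#' @export
manhattan_data <- function(result) {
  stopifnot(inherits(result, "gwas_result"))
  if (any(is.na(result$pos)))
    stop("SNP positions missing; Manhattan data unavailable", call. = FALSE)
  chroms <- unique(result$chrom)
  offset <- 0
  cum <- numeric(nrow(result))
  for (ch in chroms) {
    sel <- result$chrom == ch
    cum[sel] <- offset + result$pos[sel]
    offset <- offset + max(result$pos[sel])
  }
  data.frame(snp_id = result$snp_id, chrom = result$chrom,
             cum_pos = cum, neg_log10_p = result$neg_log10_p,
             stringsAsFactors = FALSE)
}

#' @rdname manhattan_data
#' @export
qq_data <- function(result) {
  stopifnot(inherits(result, "gwas_result"))
  n <- nrow(result)
  obs <- sort(result$neg_log10_p, decreasing = TRUE)
  expd <- -log10((seq_len(n) - 0.5) / n)
  data.frame(expected = expd, observed = obs)
}

#' Export Manhattan and QQ plots
#'
#' Writes `manhattan.csv` / `qq.csv` and, with ggplot2, `manhattan.png` /
#' `qq.png` into `dir`. When SNP positions are missing the Manhattan
#' outputs are skipped with a warning and the QQ outputs still produced.
#'
#' @param result a `gwas_result`.
#' @param dir output directory (created if needed).
#' @param neg_log10_threshold threshold line for the Manhattan plot.
#' @return Invisibly, the paths written.
#' @export
export_gwas_plots <- function(result, dir, neg_log10_threshold = 3.5) {
  stopifnot(inherits(result, "gwas_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  qd <- qq_data(result)
  qq_csv <- file.path(dir, "qq.csv")
  utils::write.csv(qd, qq_csv, row.names = FALSE)
  paths <- c(paths, qq_csv)
  gq <- ggplot2::ggplot(qd, ggplot2::aes(expected, observed)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "expected -log10(p)", y = "observed -log10(p)") +
    ggplot2::theme_minimal()
  qq_png <- file.path(dir, "qq.png")
  ggplot2::ggsave(qq_png, gq, width = 4, height = 4, dpi = 120)
  paths <- c(paths, qq_png)
  md <- tryCatch(manhattan_data(result), error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    NULL
  })
  if (!is.null(md)) {
    man_csv <- file.path(dir, "manhattan.csv")
    utils::write.csv(md, man_csv, row.names = FALSE)
    gm <- ggplot2::ggplot(md, ggplot2::aes(cum_pos, neg_log10_p,
                                           color = chrom)) +
      ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
      ggplot2::geom_hline(yintercept = neg_log10_threshold,
                          linetype = 2, color = "orange") +
      ggplot2::labs(x = "genome position", y = "-log10(p)") +
      ggplot2::theme_minimal()
    man_png <- file.path(dir, "manhattan.png")
    ggplot2::ggsave(man_png, gm, width = 6, height = 3, dpi = 120)
    paths <- c(paths, man_csv, man_png)
  }
  invisible(paths)
}
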