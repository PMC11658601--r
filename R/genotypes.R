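#' Construct a genotype matrix
#'
#' Varieties x biallelic SNPs dosage matrix with entries 0/1/2 and NA
#' for missing calls, plus SNP metadata (id, chromosome, position).
#'
#' @param dosage numeric matrix, rows = varieties (rownames = variety
#'   ids), cols = SNPs (colnames = SNP ids), entries in \{0, 1, 2, NA\}.
#' @param snp_info data.frame with columns id, chrom, pos matching the
#'   dosage columns.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snp_info) {
  dosage <- as.matrix(dosage)
  if (nrow(snp_info) != ncol(dosage))
    stop("snp_info must have one row per SNP column", call. = FALSE)
  if (anyDuplicated(snp_info$id) || anyDuplicated(rownames(dosage)))
    stop("SNP ids and variety ids must be unique", call. = FALSE)
  colnames(dosage) <- snp_info$id
  structure(list(dosage = dosage, snp_info = snp_info),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotypes: %d varieties x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage), 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Simulate biallelic genotypes with optional planted QTLs
#'
#' Draws per-SNP minor allele frequencies uniformly in
#' \[maf_low, maf_high\], samples Hardy-Weinberg dosages per variety and
#' masks entries missing independently at `missing_rate`. SNPs are
#' spread evenly over `n_chromosomes`. With `n_subpop = 2`, varieties
#' split into two subpopulations whose allele frequencies diverge by
#' `subpop_divergence` on a random half of the SNPs, creating simple
#' population structure.
#'
#' `qtl_spec` plants causal SNPs: a data.frame with columns `parameter`
#' (one of a, mu, sigma, c — the growth-curve parameter the QTL
#' perturbs) and `effect` (additive effect per alternate allele, in the
#' parameter's units), plus optionally `snp_index`; missing indices are
#' assigned to distinct random SNPs.
#'
#' @param n_varieties,n_snps matrix dimensions.
#' @param maf_low,maf_high allele-frequency bounds, 0 < low <= high <= 0.5.
#' @param missing_rate per-entry missing probability in \[0, 1).
#' @param qtl_spec optional planted-QTL specification (see above).
#' @param seed integer seed.
#' @param n_chromosomes chromosomes to spread SNPs over.
#' @param n_subpop 1 or 2.
#' @param subpop_divergence allele-frequency offset between subpopulations.
#' @return List with `genotypes` (a [genotype_matrix()]) and `qtl_map`
#'   (data.frame snp_index, snp_id, parameter, effect; empty when no
#'   QTLs were requested).
#' @export
generate_genotypes <- function(n_varieties, n_snps, maf_low = 0.05,
                               maf_high = 0.5, missing_rate = 0.02,
                               qtl_spec = NULL, seed = 1L,
                               n_chromosomes = 3, n_subpop = 1,
                               subpop_divergence = 0.2) {
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("need 0 < maf_low <= maf_high <= 0.5", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  set.seed(as.integer(seed))
  ids <- sprintf("V%03d", seq_len(n_varieties))
  chrom_of <- rep(seq_len(n_chromosomes),
                  each = ceiling(n_snps / n_chromosomes))[seq_len(n_snps)]
  pos_of <- integer(n_snps)
  for (ch in unique(chrom_of)) {
    k <- sum(chrom_of == ch)
    pos_of[chrom_of == ch] <- as.integer(seq_len(k) * 1e4)
  }
  snp_info <- data.frame(
    id = sprintf("snp%05d", seq_len(n_snps)),
    chrom = if (n_snps > 0) paste0("chr", chrom_of) else character(0),
    pos = pos_of,
    stringsAsFactors = FALSE
  )
  if (n_snps == 0) {
    g <- genotype_matrix(matrix(numeric(0), n_varieties, 0,
                                dimnames = list(ids, NULL)), snp_info)
    return(list(genotypes = g,
                qtl_map = data.frame(snp_index = integer(0), snp_id = character(0),
                                     parameter = character(0), effect = numeric(0))))
  }
  maf <- stats::runif(n_snps, maf_low, maf_high)
  pop <- if (n_subpop == 2) rep_len(1:2, n_varieties) else rep(1L, n_varieties)
  div_snp <- if (n_subpop == 2) sample(n_snps, n_snps %/% 2) else integer(0)
  p1 <- maf; p2 <- maf
  p2[div_snp] <- pmin(0.95, p1[div_snp] + subpop_divergence)
  pmat <- rbind(p1, p2)[pop, , drop = FALSE]
  dosage <- matrix(stats::rbinom(n_varieties * n_snps, 2, as.vector(pmat)),
                   n_varieties, n_snps, dimnames = list(ids, snp_info$id))
  if (missing_rate > 0) {
    miss <- stats::runif(n_varieties * n_snps) < missing_rate
    dosage[miss] <- NA
  }
  qtl_map <- data.frame(snp_index = integer(0), snp_id = character(0),
                        parameter = character(0), effect = numeric(0))
  if (!is.null(qtl_spec) && nrow(qtl_spec) > 0) {
    idx <- if ("snp_index" %in% names(qtl_spec)) qtl_spec$snp_index
    else rep(NA_integer_, nrow(qtl_spec))
    free <- setdiff(seq_len(n_snps), idx[!is.na(idx)])
    idx[is.na(idx)] <- sample(free, sum(is.na(idx)))
    if (any(idx < 1 | idx > n_snps)) stop("invalid QTL snp_index", call. = FALSE)
    if (any(!is.finite(qtl_spec$effect))) stop("QTL effects must be finite", call. = FALSE)
    qtl_map <- data.frame(snp_index = idx, snp_id = snp_info$id[idx],
                          parameter = qtl_spec$parameter,
                          effect = qtl_spec$effect, stringsAsFactors = FALSE)
  }
  list(genotypes = genotype_matrix(dosage, snp_info), qtl_map = qtl_map)
}

#' Convert planted QTLs into per-variety growth-parameter shifts
#'
#' For each QTL, the variety's (mean-imputed, centered) dosage times the
#' additive effect is added to the affected growth-curve parameter.
#' The result plugs into [simulate_trajectories()] as `variety_effects`,
#' closing the loop between genotype and phenotype simulation.
#'
#' @param genotypes a [genotype_matrix()].
#' @param qtl_map data.frame from [generate_genotypes()].
#' @return data.frame (variety_id, d_a, d_mu, d_sigma, d_c).
#' @export
qtl_variety_effects <- function(genotypes, qtl_map) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ids <- rownames(genotypes$dosage)
  out <- data.frame(variety_id = ids, d_a = 0, d_mu = 0, d_sigma = 0, d_c = 0)
  for (i in seq_len(nrow(qtl_map))) {
    d <- genotypes$dosage[, qtl_map$snp_index[i]]
    d[is.na(d)] <- mean(d, na.rm = TRUE)
    shift <- qtl_map$effect[i] * (d - mean(d))
    col <- paste0("d_", qtl_map$parameter[i])
    out[[col]] <- out[[col]] + shift
  }
  out
}
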