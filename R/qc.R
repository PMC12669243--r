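# Variant and sample quality control: missingness, Hardy-Weinberg exact
# test, heterozygosity outliers, minor allele frequency, applied in that
# order with an auditable per-step report.

#' QC thresholds
#'
#' Defaults mirror a standard WGS cohort-QC recipe: variant missingness
#' > 0.02 dropped, sample missingness > 0.1 dropped, HWE exact p <= 5e-8
#' dropped, per-sample heterozygosity outside mean +/- 3 SD dropped, then
#' MAF < 0.05 dropped.
#'
#' @param geno_max_missing maximum variant missingness fraction.
#' @param mind_max_missing maximum sample missingness fraction.
#' @param hwe_min_p variants kept iff exact HWE p strictly exceeds this.
#' @param het_sd half-width of the heterozygosity window in SDs.
#' @param maf_min minimum minor allele frequency (kept iff MAF >= maf_min).
#' @return list of thresholds, class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(geno_max_missing = 0.02, mind_max_missing = 0.1,
                          hwe_min_p = 5e-8, het_sd = 3, maf_min = 0.05) {
  stopifnot(geno_max_missing >= 0, geno_max_missing <= 1,
            mind_max_missing >= 0, mind_max_missing <= 1,
            hwe_min_p >= 0, hwe_min_p <= 1, het_sd > 0,
            maf_min >= 0, maf_min <= 0.5)
  structure(list(geno_max_missing = geno_max_missing,
                 mind_max_missing = mind_max_missing,
                 hwe_min_p = hwe_min_p, het_sd = het_sd, maf_min = maf_min),
            class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test on one variant's genotype counts. With
#' the minor-allele count fixed, the number of heterozygotes follows
#' P(n_het) proportional to N! / (n1! n_het! n2!) * 2^n_het; the p-value
#' sums the probabilities of all heterozygote counts whose probability does
#' not exceed that of the observed count (no mid-p correction). Monomorphic
#' variants return 1. Vectorised over the three count vectors.
#'
#' @param n_hom1,n_het,n_hom2 non-negative genotype counts (hom allele1,
#'   het, hom allele2); recycled to a common length.
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' hwe_exact(3, 0, 3)   # 20/924
#' @export
hwe_exact <- function(n_hom1, n_het, n_hom2) {
  k <- max(length(n_hom1), length(n_het), length(n_hom2))
  n_hom1 <- rep_len(n_hom1, k); n_het <- rep_len(n_het, k)
  n_hom2 <- rep_len(n_hom2, k)
  if (any(n_hom1 < 0 | n_het < 0 | n_hom2 < 0)) stop("negative genotype count")
  if (any(n_hom1 + n_het + n_hom2 == 0)) stop("all genotype counts zero")
  vapply(seq_len(k), function(i)
    .hwe_exact_one(n_hom1[i], n_het[i], n_hom2[i]), numeric(1))
}

.hwe_exact_one <- function(n1, nh, n2) {
  n <- n1 + nh + n2
  nm <- 2 * min(n1, n2) + nh            # minor allele count (symmetric)
  if (nm == 0 || nm == 2 * n) return(1)
  hets <- seq(nm %% 2, nm, by = 2)      # feasible het counts, same parity
  ha <- (nm - hets) / 2                 # minor-hom counts
  hb <- n - hets - ha
  logp <- lgamma(n + 1) - lgamma(ha + 1) - lgamma(hets + 1) - lgamma(hb + 1) +
    hets * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(nh, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

#' Apply cohort quality control
#'
#' Filters in order: (1) variants with missingness above
#' \code{geno_max_missing}; (2) samples with missingness above
#' \code{mind_max_missing}; (3) variants failing the exact HWE test at
#' \code{hwe_min_p}; (4) samples whose heterozygosity rate (het calls /
#' non-missing calls, computed once on the variants current at this step)
#' lies outside mean +/- \code{het_sd} SD; (5) variants with MAF below
#' \code{maf_min}. The report records removals per step so the order is
#' auditable.
#'
#' @param g a \code{genotype_matrix}.
#' @param thresholds a \code{\link{qc_thresholds}} object.
#' @return list with elements \code{genotypes} (the filtered matrix) and
#'   \code{report} (named list of per-step removal counts plus final
#'   dimensions). Errors, with the report attached as a condition field, if
#'   every sample is removed.
#' @export
apply_qc <- function(g, thresholds = qc_thresholds()) {
  validate_genotype_matrix(g)
  report <- list()

  vmiss <- colMeans(is.na(g$calls))
  drop_v <- vmiss > thresholds$geno_max_missing
  report$variants_missingness <- sum(drop_v)
  g <- subset_genotypes(g, variants = !drop_v)

  smiss <- rowMeans(is.na(g$calls))
  if (n_variants(g) == 0) smiss <- rep(0, n_samples(g))
  drop_s <- smiss > thresholds$mind_max_missing
  report$samples_missingness <- sum(drop_s)
  g <- subset_genotypes(g, samples = !drop_s)
  if (n_samples(g) == 0) .qc_abort(report)

  counts <- genotype_counts(g)
  pvals <- hwe_exact(counts[, "n_hom1"], counts[, "n_het"], counts[, "n_hom2"])
  drop_v <- !(pvals > thresholds$hwe_min_p)
  report$variants_hwe <- sum(drop_v)
  g <- subset_genotypes(g, variants = !drop_v)

  het <- rowSums(g$calls == 1L, na.rm = TRUE) / rowSums(!is.na(g$calls))
  mu <- mean(het); sdev <- stats::sd(het)
  drop_s <- if (is.na(sdev) || sdev == 0) rep(FALSE, length(het)) else
    het < mu - thresholds$het_sd * sdev | het > mu + thresholds$het_sd * sdev
  report$samples_heterozygosity <- sum(drop_s)
  g <- subset_genotypes(g, samples = !drop_s)
  if (n_samples(g) == 0) .qc_abort(report)

  drop_v <- maf(g) < thresholds$maf_min | is.na(maf(g))
  report$variants_maf <- sum(drop_v)
  g <- subset_genotypes(g, variants = !drop_v)

  report$n_samples <- n_samples(g)
  report$n_variants <- n_variants(g)
  list(genotypes = g, report = report)
}

.qc_abort <- function(report) {
  cond <- structure(class = c("qc_all_samples_removed", "error", "condition"),
                    list(message = "QC removed every sample",
                         call = sys.call(-1), report = report))
  stop(cond)
}

# per-variant genotype counts (hom allele1 / het / hom allele2)
genotype_counts <- function(g) {
  cbind(n_hom1 = colSums(g$calls == 2L, na.rm = TRUE),
        n_het = colSums(g$calls == 1L, na.rm = TRUE),
        n_hom2 = colSums(g$calls == 0L, na.rm = TRUE))
}
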