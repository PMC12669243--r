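# Population-structure machinery feeding the association model: merging of
# shared common variants across cohorts, sliding-window LD pruning,
# principal components on standardized dosages, and the VanRaden genomic
# relationship matrix.

#' Merge two cohorts on shared common variants
#'
#' Keeps variants present in both matrices (matched by chromosome, position
#' and allele pair, allowing a swapped allele1/allele2 orientation, in which
#' case B's calls are recoded 0 <-> 2) whose minor allele frequency exceeds
#' \code{af_min} in each cohort separately. Samples are concatenated;
#' cohort membership is returned alongside.
#'
#' @param a,b QC'd \code{genotype_matrix} objects with disjoint sample ids.
#' @param af_min allele-frequency floor applied per cohort (default 0.05).
#' @param labels length-2 character, cohort labels for a and b.
#' @return list with \code{genotypes} (merged matrix, variant map taken from
#'   \code{a}) and \code{cohort} (factor, one entry per merged sample).
#' @export
intersect_common <- function(a, b, af_min = 0.05,
                             labels = c("cohort_a", "cohort_b")) {
  key_a <- paste(a$variants$chrom, a$variants$pos)
  key_b <- paste(b$variants$chrom, b$variants$pos)
  ib <- match(key_a, key_b)
  same <- !is.na(ib) &
    a$variants$allele1 == b$variants$allele1[ib] &
    a$variants$allele2 == b$variants$allele2[ib]
  swapped <- !is.na(ib) &
    a$variants$allele1 == b$variants$allele2[ib] &
    a$variants$allele2 == b$variants$allele1[ib]
  shared <- same | swapped
  if (!any(shared)) stop("no shared variants between cohorts")
  ia <- which(shared)
  ib <- ib[shared]
  calls_b <- b$calls[, ib, drop = FALSE]
  flip <- swapped[shared]
  calls_b[, flip] <- 2L - calls_b[, flip]
  sub_a <- subset_genotypes(a, variants = ia)
  gb <- genotype_matrix(calls_b, a$variants[ia, , drop = FALSE], b$samples)
  common <- maf(sub_a) > af_min & maf(gb) > af_min
  common[is.na(common)] <- FALSE
  if (!any(common)) stop("no shared variants pass the frequency filter")
  merged <- genotype_matrix(rbind(sub_a$calls[, common, drop = FALSE],
                                  gb$calls[, common, drop = FALSE]),
                            sub_a$variants[common, , drop = FALSE],
                            c(a$samples, b$samples))
  list(genotypes = merged,
       cohort = factor(rep(labels, c(n_samples(a), n_samples(b)))))
}

#' LD pruning by pairwise r-squared
#'
#' Greedy sliding-window pruning: windows of \code{window_snps} variants per
#' chromosome, advanced by \code{step_snps}; within a window, while any pair
#' of retained variants has squared Pearson dosage correlation above
#' \code{r2_max}, the worst pair's member with the lower MAF is removed
#' (position-later member on an exact tie). r-squared is computed on
#' pairwise-complete samples.
#'
#' @param g a \code{genotype_matrix} (map-sorted, as the class guarantees).
#' @param window_snps,step_snps,r2_max pruning parameters (defaults 50, 5,
#'   0.2, the usual independence-pruning recipe).
#' @return integer vector of retained variant indices (ascending).
#' @export
ld_prune <- function(g, window_snps = 50, step_snps = 5, r2_max = 0.2) {
  validate_genotype_matrix(g)
  keep <- rep(TRUE, n_variants(g))
  freq <- maf(g)
  for (ch in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == ch)
    s <- length(idx)
    starts <- if (s <= window_snps) 1L else
      unique(c(seq(1L, s - window_snps + 1L, by = step_snps),
               s - window_snps + 1L))
    for (st in starts) {
      win <- idx[st:min(st + window_snps - 1L, s)]
      win <- win[keep[win]]
      if (length(win) < 2) next
      d <- g$calls[, win, drop = FALSE]
      r2 <- suppressWarnings(
        stats::cor(d, use = "pairwise.complete.obs"))^2
      r2[is.na(r2)] <- 0
      diag(r2) <- 0
      while (max(r2) > r2_max) {
        worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        i <- win[worst[1]]; j <- win[worst[2]]
        drop <- if (freq[i] < freq[j]) worst[1]
          else if (freq[j] < freq[i]) worst[2]
          else max(worst)                       # equal MAF: later in map
        keep[win[drop]] <- FALSE
        r2[drop, ] <- 0; r2[, drop] <- 0
      }
    }
  }
  which(keep)
}

#' Principal components of standardized genotypes
#'
#' Mean-imputes missing calls per variant, standardizes each variant to mean
#' 0 using 2p(1-p) as its variance, and returns the top-k eigenvectors of the
#' sample-by-sample covariance as scores, with per-component fractions of
#' total variance.
#'
#' @param g a (typically LD-pruned) \code{genotype_matrix}.
#' @param k number of components, at most \code{min(N, M)}.
#' @return list of class \code{pc_result}: \code{components} (N x k matrix,
#'   unit-norm columns, rownames = sample ids) and \code{variance_fraction}.
#' @export
pca_genotypes <- function(g, k = 10) {
  validate_genotype_matrix(g)
  if (k > min(n_samples(g), n_variants(g)))
    stop("k exceeds min(n_samples, n_variants)")
  z <- standardize_dosages(g)
  cov_s <- tcrossprod(z) / ncol(z)
  eg <- eigen(cov_s, symmetric = TRUE)
  comp <- eg$vectors[, seq_len(k), drop = FALSE]
  rownames(comp) <- g$samples
  colnames(comp) <- paste0("PC", seq_len(k))
  structure(list(components = comp,
                 variance_fraction = eg$values[seq_len(k)] /
                   sum(pmax(eg$values, 0))),
            class = "pc_result")
}

#' Genomic relationship matrix
#'
#' VanRaden form: G = Z Z' / sum(2 p_j (1 - p_j)) with Z the column-centered
#' (by 2p) mean-imputed dosage matrix. Monomorphic variants carry no
#' relationship information and are excluded with a message.
#'
#' @param g a QC'd \code{genotype_matrix}.
#' @return N x N symmetric matrix with sample ids as dimnames.
#' @export
grm <- function(g) {
  validate_genotype_matrix(g)
  p <- allele_freq(g)
  mono <- is.na(p) | p == 0 | p == 1
  if (any(mono)) {
    message("grm: excluded ", sum(mono), " monomorphic variant(s)")
    g <- subset_genotypes(g, variants = !mono)
    p <- p[!mono]
  }
  z <- apply_impute_center(g$calls, 2 * p)
  k <- tcrossprod(z) / sum(2 * p * (1 - p))
  dimnames(k) <- list(g$samples, g$samples)
  (k + t(k)) / 2
}

# mean-impute missing to 2p and subtract 2p (so missing -> 0 after centering)
apply_impute_center <- function(calls, mu) {
  z <- sweep(calls, 2, mu, check.margin = FALSE)
  z[is.na(z)] <- 0
  z
}

# mean 0, variance 2p(1-p) standardization used by the PCA
standardize_dosages <- function(g) {
  p <- allele_freq(g)
  sdv <- sqrt(2 * p * (1 - p))
  ok <- !is.na(sdv) & sdv > 0
  z <- apply_impute_center(g$calls[, ok, drop = FALSE], 2 * p[ok])
  sweep(z, 2, sdv[ok], "/", check.margin = FALSE)
}
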