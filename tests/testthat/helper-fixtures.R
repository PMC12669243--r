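# Small in-code fixtures shared across test files.

random_genotypes <- function(n = 10, m = 20, missing_rate = 0.05,
                             n_chrom = 2, seed = 1) {
  set.seed(seed)
  per <- ceiling(m / n_chrom)
  chrom <- rep(as.character(seq_len(n_chrom)), each = per)[seq_len(m)]
  pos <- unlist(lapply(split(seq_len(m), factor(chrom, unique(chrom))),
                       function(ix) sort(sample.int(1e6, length(ix)))),
                use.names = FALSE)
  variants <- data.frame(chrom = chrom,
                         id = paste0("v", seq_len(m)), cm = 0,
                         pos = pos,
                         allele1 = "A", allele2 = "C",
                         stringsAsFactors = FALSE)
  calls <- matrix(sample(c(0L, 1L, 2L), n * m, replace = TRUE), n, m)
  calls[matrix(runif(n * m) < missing_rate, n, m)] <- NA
  genotype_matrix(calls, variants, sprintf("s%02d", seq_len(n)))
}

# one-chromosome matrix from an explicit call matrix
chrom_fixture <- function(calls, pos = NULL, spacing = 1e4) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * spacing
  genotype_matrix(calls,
                  data.frame(chrom = "1", id = paste0("v", seq_len(m)),
                             cm = 0, pos = pos, allele1 = "A", allele2 = "C"),
                  sprintf("s%02d", seq_len(nrow(calls))))
}

# genotype matrix drawn from exact HWE proportions
hwe_genotypes <- function(n, m, maf = NULL, seed = 1, n_chrom = 1) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.05, 0.5)
  calls <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), n, m)
  per <- ceiling(m / n_chrom)
  chrom <- rep(as.character(seq_len(n_chrom)), each = per)[seq_len(m)]
  pos <- unlist(lapply(split(seq_len(m), factor(chrom, unique(chrom))),
                       function(ix) seq_along(ix) * 1e4), use.names = FALSE)
  genotype_matrix(calls,
                  data.frame(chrom = chrom, id = paste0("v", seq_len(m)),
                             cm = 0, pos = pos, allele1 = "A", allele2 = "C"),
                  sprintf("s%04d", seq_len(n)))
}

# block-family kinship with f families of size fs (within-family 0.5)
family_kinship <- function(n_families, family_size) {
  n <- n_families * family_size
  k <- matrix(0, n, n)
  for (f in seq_len(n_families)) {
    ix <- ((f - 1) * family_size + 1):(f * family_size)
    k[ix, ix] <- 0.5
  }
  diag(k) <- 1
  k
}

# draw y = Xb + g + e with g ~ N(0, var_g K)
draw_lmm_trait <- function(x, kinship, beta, var_g, var_e, seed) {
  set.seed(seed)
  n <- nrow(kinship)
  ev <- eigen(kinship, symmetric = TRUE)
  g <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(n)) * sqrt(var_g)
  as.numeric(cbind(1, x) %*% beta + g + rnorm(n, sd = sqrt(var_e)))
}
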