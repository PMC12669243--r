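#' Construct a genotype matrix
#'
#' The central container of the package: diploid biallelic genotype calls for
#' N samples at M autosomal variants, coded as the number of copies of
#' \code{allele1} (0, 1, 2) with \code{NA} for missing. Variants are kept in
#' map order: sorted by chromosome, strictly increasing position within a
#' chromosome.
#'
#' @param calls integer matrix, samples in rows, variants in columns; entries
#'   in \code{c(0L, 1L, 2L, NA)}.
#' @param variants data.frame with columns \code{chrom}, \code{id}, \code{cm},
#'   \code{pos}, \code{allele1}, \code{allele2}. \code{allele1} is the counted
#'   (effect) allele.
#' @param samples character vector of unique sample ids, one per row.
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{calls}, \code{variants}, \code{samples}.
#' @examples
#' v <- data.frame(chrom = "1", id = "snp1", cm = 0, pos = 100,
#'                 allele1 = "A", allele2 = "C")
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L), 3, 1), v, c("s1", "s2", "s3"))
#' n_samples(g)
#' @export
genotype_matrix <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (!"cm" %in% names(variants)) variants$cm <- 0
  variants <- variants[, c("chrom", "id", "cm", "pos", "allele1", "allele2")]
  variants$chrom <- as.character(variants$chrom)
  variants$id <- as.character(variants$id)
  variants$pos <- as.numeric(variants$pos)
  rownames(variants) <- NULL
  g <- structure(list(calls = calls,
                      variants = variants,
                      samples = as.character(samples)),
                 class = "genotype_matrix")
  validate_genotype_matrix(g)
  g
}

#' Validate a genotype matrix
#'
#' Checks the container invariants: consistent dimensions, legal call codes,
#' unique sample and variant ids, positions >= 1 strictly increasing within
#' each chromosome, and distinct alleles per variant.
#'
#' @param g a \code{genotype_matrix}.
#' @return \code{g}, invisibly. Errors on any violated invariant.
#' @export
validate_genotype_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- length(g$samples)
  m <- nrow(g$variants)
  if (nrow(g$calls) != n || ncol(g$calls) != m)
    stop("calls dimensions (", nrow(g$calls), "x", ncol(g$calls),
         ") do not match ", n, " samples x ", m, " variants")
  bad <- !(g$calls %in% c(0L, 1L, 2L)) & !is.na(g$calls)
  if (any(bad)) stop("calls contain codes outside {0, 1, 2, NA}")
  if (anyDuplicated(g$samples)) stop("duplicate sample ids")
  if (m > 0) {
    if (anyDuplicated(g$variants$id)) stop("duplicate variant ids")
    if (any(g$variants$pos < 1)) stop("variant positions must be >= 1")
    if (any(g$variants$allele1 == g$variants$allele2))
      stop("allele1 must differ from allele2")
    for (ch in unique(g$variants$chrom)) {
      p <- g$variants$pos[g$variants$chrom == ch]
      if (length(p) > 1 && any(diff(p) <= 0))
        stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  invisible(g)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants on",
      length(unique(x$variants$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Number of samples / variants
#' @param g a \code{genotype_matrix}.
#' @return integer count.
#' @export
n_samples <- function(g) length(g$samples)

#' @rdname n_samples
#' @export
n_variants <- function(g) nrow(g$variants)

#' Subset a genotype matrix
#'
#' @param g a \code{genotype_matrix}.
#' @param samples integer or logical index over samples (default all).
#' @param variants integer or logical index over variants (default all).
#' @return The subsetted \code{genotype_matrix}.
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  if (is.null(samples)) samples <- seq_along(g$samples)
  if (is.null(variants)) variants <- seq_len(nrow(g$variants))
  genotype_matrix(g$calls[samples, variants, drop = FALSE],
                  g$variants[variants, , drop = FALSE],
                  g$samples[samples])
}

#' Allele-1 frequency per variant
#'
#' Frequency of the counted allele, computed on non-missing calls only.
#'
#' @param g a \code{genotype_matrix}.
#' @return numeric vector of length \code{n_variants(g)}; \code{NaN} where a
#'   variant has no non-missing calls.
#' @export
allele_freq <- function(g) {
  colSums(g$calls, na.rm = TRUE) / (2 * colSums(!is.na(g$calls)))
}

#' Minor allele frequency per variant
#' @param g a \code{genotype_matrix}.
#' @return numeric vector, \code{pmin(p, 1 - p)} of the allele-1 frequency.
#' @export
maf <- function(g) {
  p <- allele_freq(g)
  pmin(p, 1 - p)
}

# Chromosome labels treated as autosomal. Anything else (X, Y, MT, PLINK
# numeric codes 23-26) is dropped by the readers with a logged count.
is_autosome <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  suppressWarnings(num <- as.numeric(ch))
  !is.na(num) & num >= 1 & num <= 22 & num == floor(num)
}

# Flip orientation so allele1 is the minor allele wherever the computed
# allele-1 frequency exceeds 0.5. Returns g with attribute "n_flipped".
orient_to_minor <- function(g) {
  p <- allele_freq(g)
  flip <- !is.na(p) & p > 0.5
  if (any(flip)) {
    g$calls[, flip] <- 2L - g$calls[, flip]
    a1 <- g$variants$allele1[flip]
    g$variants$allele1[flip] <- g$variants$allele2[flip]
    g$variants$allele2[flip] <- a1
  }
  attr(g, "n_flipped") <- sum(flip)
  g
}
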