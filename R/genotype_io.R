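# PLINK 1 binary (.bed/.bim/.fam), VCF (GT only), .hom segment tables and the
# phenotype TSV dialect. The .bed codec is written here because no installed
# package reads the format; it follows the variant-major 2-bit layout:
# magic 0x6c 0x1b 0x01, then ceil(N/4) bytes per variant, samples packed from
# the least significant bit pair, codes 00 = hom allele1, 01 = missing,
# 10 = het, 11 = hom allele2.

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: byte value + slot -> call code (counting allele1)
.bed_decode_lut <- local({
  lut <- matrix(NA_integer_, 256, 4)
  code_map <- c(`0` = 2L, `1` = NA, `2` = 1L, `3` = 0L)
  for (b in 0:255) for (k in 1:4) {
    two_bits <- bitwAnd(bitwShiftR(b, 2L * (k - 1L)), 3L)
    lut[b + 1L, k] <- code_map[[as.character(two_bits)]]
  }
  lut
})

#' Read PLINK binary genotypes
#'
#' Reads a variant-major PLINK 1 fileset (.bed/.bim/.fam) into a
#' \code{\link{genotype_matrix}}. Calls count copies of the .bim A1 allele
#' (so the 2-bit code 00, "homozygous A1", decodes to 2). Non-autosomal
#' variants are dropped with a message.
#'
#' @param bed_path,bim_path,fam_path paths to the three files. \code{bim_path}
#'   and \code{fam_path} default to the .bed path with the extension swapped.
#' @param orient_minor if \code{TRUE}, swap alleles (and recode calls) so that
#'   allele1 is the minor allele wherever frequencies are computable. The
#'   default \code{FALSE} preserves file order, which makes
#'   \code{read_bed(write_bed(g))} an exact identity.
#' @return A \code{genotype_matrix}.
#' @export
read_bed <- function(bed_path,
                     bim_path = sub("\\.bed$", ".bim", bed_path),
                     fam_path = sub("\\.bed$", ".fam", bed_path),
                     orient_minor = FALSE) {
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) stop("file not found: ", f)
  bim <- utils::read.table(bim_path, header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos",
                                         "allele1", "allele2"),
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "character", "character"))
  fam <- utils::read.table(fam_path, header = FALSE,
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "pheno"),
                           colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || !identical(raw[1:3], BED_MAGIC))
    stop("not a variant-major PLINK .bed file (bad magic bytes): ", bed_path)
  payload <- raw[-(1:3)]
  bpv <- ceiling(n / 4)
  if (length(payload) != bpv * m)
    stop("truncated .bed payload: expected ", bpv * m, " bytes for ",
         n, " samples x ", m, " variants, found ", length(payload))
  calls <- matrix(NA_integer_, nrow = n, ncol = m)
  if (m > 0 && n > 0) {
    bytes <- as.integer(payload) + 1L
    # expand each byte to 4 codes; rows = 4*bpv sample slots, cols = variants
    expanded <- matrix(NA_integer_, nrow = 4L * bpv, ncol = m)
    bytes_mat <- matrix(bytes, nrow = bpv, ncol = m)
    for (k in 1:4)
      expanded[seq(k, by = 4L, length.out = bpv), ] <-
        .bed_decode_lut[bytes_mat, k]
    calls <- expanded[seq_len(n), , drop = FALSE]
  }
  keep <- is_autosome(bim$chrom)
  if (any(!keep))
    message("read_bed: dropped ", sum(!keep), " non-autosomal variant(s)")
  g <- genotype_matrix(calls[, keep, drop = FALSE], bim[keep, , drop = FALSE],
                       fam$iid)
  if (orient_minor) g <- orient_to_minor(g)
  g
}

#' Write PLINK binary genotypes
#'
#' Writes \code{prefix.bed} (variant-major), \code{prefix.bim} and
#' \code{prefix.fam}. The fileset round-trips bit-exactly through
#' \code{\link{read_bed}}: file size is \code{3 + M * ceiling(N/4)} bytes.
#'
#' @param g a valid \code{genotype_matrix} (unsorted variants are refused).
#' @param prefix output path prefix.
#' @param sex optional numeric vector for the .fam sex column (1 = male,
#'   2 = female, 0 = unknown); defaults to 0.
#' @return The three file paths, invisibly.
#' @export
write_bed <- function(g, prefix, sex = NULL) {
  validate_genotype_matrix(g)
  n <- n_samples(g)
  m <- n_variants(g)
  bpv <- ceiling(n / 4)
  # code map: call -> 2-bit value
  enc <- matrix(1L, nrow = 4L * bpv, ncol = max(m, 1L))  # pad slots: missing
  if (n > 0 && m > 0) {
    two_bit <- matrix(0L, nrow = 4L * bpv, ncol = m)     # pad bits are 00
    v <- g$calls
    code <- ifelse(is.na(v), 1L, c(3L, 2L, 0L)[v + 1L])  # 0->3, 1->2, 2->0
    two_bit[seq_len(n), ] <- code
    shifted <- two_bit * rep(c(1L, 4L, 16L, 64L), times = bpv)
    bytes <- rowsum(shifted, group = rep(seq_len(bpv), each = 4L),
                    reorder = FALSE)
    payload <- as.raw(as.vector(bytes))
  } else payload <- raw(0)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(BED_MAGIC, con)
  writeBin(payload, con)
  if (is.null(sex)) sex <- rep(0L, n)
  fam <- data.frame(g$samples, g$samples, 0L, 0L, sex, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- g$variants[, c("chrom", "id", "cm", "pos", "allele1", "allele2")]
  utils::write.table(format(bim, scientific = FALSE, trim = TRUE),
                     paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read genotypes from a VCF
#'
#' Parses the GT field of a VCF 4.x file into a \code{\link{genotype_matrix}}.
#' Convention: allele1 is the ALT allele, so GT 1/1 decodes to 2, 0/1 to 1,
#' 0/0 to 0 and ./. to missing. Multiallelic records and non-autosomal
#' records are skipped with logged counts.
#'
#' @param path VCF file (plain or bgzipped).
#' @param orient_minor as in \code{\link{read_bed}}.
#' @return A \code{genotype_matrix}.
#' @export
read_vcf <- function(path, orient_minor = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(vcf@gt) == 0 || !all(grepl("GT", vcf@gt[, "FORMAT"])))
    stop("VCF lacks a GT FORMAT key")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    message("read_vcf: skipped ", sum(multi), " multiallelic record(s)")
  auto <- is_autosome(fix$CHROM)
  if (any(!auto & !multi))
    message("read_vcf: dropped ", sum(!auto & !multi),
            " non-autosomal record(s)")
  keep <- !multi & auto
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt == "0/0"] <- 0L
  code[gt == "0/1" | gt == "1/0"] <- 1L
  code[gt == "1/1"] <- 2L
  fixk <- fix[keep, , drop = FALSE]
  variants <- data.frame(chrom = fixk$CHROM,
                         id = ifelse(is.na(fixk$ID) | fixk$ID == ".",
                                     paste0(fixk$CHROM, ":", fixk$POS),
                                     fixk$ID),
                         cm = 0,
                         pos = as.numeric(fixk$POS),
                         allele1 = fixk$ALT,   # counted allele = ALT
                         allele2 = fixk$REF,
                         stringsAsFactors = FALSE)
  g <- genotype_matrix(t(code), variants, colnames(gt))
  if (orient_minor) g <- orient_to_minor(g)
  g
}

#' Write ROH segments as a .hom table
#'
#' One row per called segment, in the homozygosity-scan output dialect:
#' columns FID IID PHE CHR SNP1 SNP2 POS1 POS2 KB NSNP DENSITY PHOM PHET,
#' with KB = (POS2 - POS1 + 1) / 1000 and DENSITY = KB / NSNP.
#'
#' @param segments segment data.frame from \code{\link{call_roh}} (columns
#'   \code{sample_id}, \code{chrom}, \code{pos_start}, \code{pos_end},
#'   \code{n_snps}, \code{length_kb}, and optionally \code{snp_start},
#'   \code{snp_end}, \code{phom}, \code{phet}).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_hom <- function(segments, path) {
  validate_segments(segments)
  z <- function(col, default) {
    if (col %in% names(segments)) segments[[col]] else
      rep(default, nrow(segments))
  }
  out <- data.frame(FID = segments$sample_id,
                    IID = segments$sample_id,
                    PHE = rep(-9, nrow(segments)),
                    CHR = segments$chrom,
                    SNP1 = z("snp_start", "."),
                    SNP2 = z("snp_end", "."),
                    POS1 = segments$pos_start,
                    POS2 = segments$pos_end,
                    KB = round((segments$pos_end - segments$pos_start + 1) /
                                 1000, 3),
                    NSNP = segments$n_snps,
                    DENSITY = round((segments$pos_end - segments$pos_start +
                                       1) / 1000 / segments$n_snps, 4),
                    PHOM = round(z("phom", NA_real_), 4),
                    PHET = round(z("phet", NA_real_), 4))
  utils::write.table(format(out, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a .hom segment table
#'
#' Inverse of \code{\link{write_hom}} up to column rounding: reconstructs the
#' segment data.frame (intervals, SNP counts) from the tabular dialect.
#'
#' @param path .hom file.
#' @return segment data.frame as used by the roh functions.
#' @export
read_hom <- function(path) {
  tab <- utils::read.table(path, header = TRUE, colClasses = "character")
  data.frame(sample_id = tab$IID,
             chrom = tab$CHR,
             pos_start = as.numeric(tab$POS1),
             pos_end = as.numeric(tab$POS2),
             n_snps = as.integer(tab$NSNP),
             length_kb = (as.numeric(tab$POS2) - as.numeric(tab$POS1) + 1) /
               1000,
             snp_start = tab$SNP1,
             snp_end = tab$SNP2,
             phom = suppressWarnings(as.numeric(tab$PHOM)),
             phet = suppressWarnings(as.numeric(tab$PHET)),
             stringsAsFactors = FALSE)
}

#' Read / write the phenotype-covariate table
#'
#' Tab-separated with a header; required columns \code{sample_id},
#' \code{sex} (\code{"female"}/\code{"male"}), \code{age} (years); every
#' further column is a quantitative trait (missing allowed, encoded NA).
#'
#' @param path TSV file.
#' @return data.frame with one row per sample.
#' @export
read_pheno <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("sample_id", "sex", "age")
  miss <- setdiff(req, names(ph))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ph$sample_id)) stop("duplicate sample ids in phenotypes")
  if (!all(ph$sex %in% c("female", "male", NA)))
    stop("sex must be 'female' or 'male'")
  if (any(ph$age < 0, na.rm = TRUE)) stop("negative age")
  ph
}

#' @rdname read_pheno
#' @param pheno phenotype data.frame.
#' @export
write_pheno <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
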