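# Runs-of-homozygosity detection by the classic sliding-window genotype
# scan, plus everything derived from the called segments: the per-SNP
# ROH-inclusion matrix, the genomic inbreeding coefficient F_ROH, cohort
# summaries, and the per-SNP ROH frequency / enriched-region tables.

#' ROH calling parameters
#'
#' The defaults are the widely used window-scan defaults of the PLINK v1.9
#' \code{--homozyg} family: 50-SNP windows tolerating at most 1 heterozygous
#' and 5 missing calls, a SNP declared eligible when at least 5\% of the
#' windows containing it pass, and segments of eligible SNPs emitted when
#' they hold >= 100 SNPs, span >= 1000 kb, have a density of at most
#' 50 kb/SNP and contain no inter-SNP gap above 1000 kb. \code{long_cutoff_kb}
#' (1.6 Mb) splits segments into a short and a long class in the summaries;
#' \code{genome_length_bp} (3e9, the autosomal genome) is the F_ROH
#' denominator.
#'
#' @param window_snp,window_het_max,window_missing_max,window_threshold
#'   window-scan parameters.
#' @param min_snp,min_kb,max_density_kb_per_snp,max_gap_kb segment filters.
#' @param long_cutoff_kb length cutoff for the long-segment class.
#' @param genome_length_bp denominator of F_ROH.
#' @return list of class \code{roh_params}.
#' @export
roh_params <- function(window_snp = 50, window_het_max = 1,
                       window_missing_max = 5, window_threshold = 0.05,
                       min_snp = 100, min_kb = 1000,
                       max_density_kb_per_snp = 50, max_gap_kb = 1000,
                       long_cutoff_kb = 1600, genome_length_bp = 3e9) {
  stopifnot(window_snp >= 1, window_het_max >= 0, window_missing_max >= 0,
            window_threshold > 0, window_threshold <= 1,
            min_snp >= 1, min_kb > 0, max_density_kb_per_snp > 0,
            max_gap_kb > 0, long_cutoff_kb > 0,
            is.na(genome_length_bp) || genome_length_bp > 0)
  structure(as.list(environment()), class = "roh_params")
}

#' Sliding-window homozygosity scan of one chromosome
#'
#' Slides a window of \code{window_snp} consecutive SNPs along one sample's
#' calls; a window passes iff it contains at most \code{window_het_max}
#' heterozygous and at most \code{window_missing_max} missing calls. Each
#' SNP's hit fraction is the share of windows containing it (windows fully
#' inside the chromosome) that pass; the SNP is eligible iff the fraction
#' reaches \code{window_threshold} (inclusive). A chromosome shorter than
#' one window is judged by a single truncated window.
#'
#' @param calls integer vector of one sample's calls on one chromosome, in
#'   map order (\code{NA} = missing).
#' @param params a \code{\link{roh_params}} object.
#' @return logical vector of per-SNP eligibility flags.
#' @export
window_scan <- function(calls, params = roh_params()) {
  s <- length(calls)
  if (s == 0) return(logical(0))
  het <- !is.na(calls) & calls == 1L
  mis <- is.na(calls)
  w <- params$window_snp
  if (s < w) {
    pass <- sum(het) <= params$window_het_max &&
      sum(mis) <= params$window_missing_max
    return(rep(pass, s))
  }
  ch <- c(0L, cumsum(het))
  cm <- c(0L, cumsum(mis))
  nw <- s - w + 1L
  i <- seq_len(nw)
  pass <- (ch[i + w] - ch[i]) <= params$window_het_max &
    (cm[i + w] - cm[i]) <= params$window_missing_max
  cp <- c(0L, cumsum(pass))
  j <- seq_len(s)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, nw)
  (cp[hi + 1L] - cp[lo]) / (hi - lo + 1L) >= params$window_threshold
}

#' Assemble ROH segments from eligibility flags
#'
#' Takes maximal runs of consecutive eligible SNPs, splits them wherever the
#' gap between adjacent SNPs exceeds \code{max_gap_kb}, and emits each run
#' that holds at least \code{min_snp} SNPs, spans at least \code{min_kb} kb
#' (length = last - first position + 1) and whose kb-per-SNP density does
#' not exceed \code{max_density_kb_per_snp}. Segment bounds are the first
#' and last eligible SNP positions.
#'
#' @param eligible logical flags from \code{\link{window_scan}}.
#' @param pos,ids positions (bp) and ids of the chromosome's variants.
#' @param calls the sample's calls (for the segment PHOM/PHET fractions).
#' @param params a \code{\link{roh_params}} object.
#' @param chrom,sample_id labels copied into the output.
#' @return data.frame of segments (possibly 0 rows) with columns
#'   \code{sample_id}, \code{chrom}, \code{pos_start}, \code{pos_end},
#'   \code{n_snps}, \code{length_kb}, \code{snp_start}, \code{snp_end},
#'   \code{phom}, \code{phet}.
#' @export
call_segments <- function(eligible, pos, calls, params = roh_params(),
                          chrom = "1", sample_id = "sample") {
  empty <- data.frame(sample_id = character(), chrom = character(),
                      pos_start = numeric(), pos_end = numeric(),
                      n_snps = integer(), length_kb = numeric(),
                      snp_start = character(), snp_end = character(),
                      phom = numeric(), phet = numeric(),
                      stringsAsFactors = FALSE)
  s <- length(eligible)
  if (s == 0 || !any(eligible)) return(empty)
  if (is.null(ids <- names(pos))) ids <- paste0(chrom, ":", pos)
  # run starts: eligible SNP that is first, follows an ineligible SNP, or
  # follows a gap > max_gap_kb
  big_gap <- c(FALSE, diff(pos) / 1000 > params$max_gap_kb)
  prev_elig <- c(FALSE, eligible[-s])
  start <- eligible & (!prev_elig | big_gap)
  run_id <- cumsum(start)
  run_id[!eligible] <- 0L
  out <- lapply(seq_len(max(run_id)), function(r) {
    sel <- which(run_id == r)
    i1 <- sel[1]; i2 <- sel[length(sel)]
    n <- length(sel)
    len_kb <- (pos[i2] - pos[i1] + 1) / 1000
    if (n < params$min_snp || len_kb < params$min_kb ||
        len_kb / n > params$max_density_kb_per_snp) return(NULL)
    cc <- calls[sel]
    nn <- sum(!is.na(cc))
    data.frame(sample_id = sample_id, chrom = chrom,
               pos_start = pos[i1], pos_end = pos[i2],
               n_snps = n, length_kb = len_kb,
               snp_start = ids[i1], snp_end = ids[i2],
               phom = if (nn) sum(cc != 1L, na.rm = TRUE) / nn else NA_real_,
               phet = if (nn) sum(cc == 1L, na.rm = TRUE) / nn else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call runs of homozygosity for a cohort
#'
#' Runs \code{\link{window_scan}} and \code{\link{call_segments}} per sample
#' and chromosome. Windows never span chromosomes.
#'
#' @param g a \code{genotype_matrix}.
#' @param params a \code{\link{roh_params}} object.
#' @return segment data.frame (see \code{\link{call_segments}}).
#' @export
call_roh <- function(g, params = roh_params()) {
  validate_genotype_matrix(g)
  chroms <- unique(g$variants$chrom)
  res <- list()
  for (ch in chroms) {
    idx <- which(g$variants$chrom == ch)
    pos <- g$variants$pos[idx]
    names(pos) <- g$variants$id[idx]
    for (i in seq_along(g$samples)) {
      cc <- g$calls[i, idx]
      flags <- window_scan(cc, params)
      if (any(flags))
        res[[length(res) + 1L]] <-
          call_segments(flags, pos, cc, params, ch, g$samples[i])
    }
  }
  if (!length(res))
    return(call_segments(logical(0), numeric(0), integer(0), params))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

validate_segments <- function(segments) {
  req <- c("sample_id", "chrom", "pos_start", "pos_end", "n_snps")
  miss <- setdiff(req, names(segments))
  if (length(miss)) stop("segment table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(segments$pos_end < segments$pos_start))
    stop("segment with pos_end < pos_start")
  invisible(segments)
}

#' Per-SNP ROH-inclusion (regional autozygosity) matrix
#'
#' Binary N x M matrix: entry (i, j) is 1 iff variant j lies within some
#' called ROH segment of sample i on the same chromosome. Boundary SNPs
#' (position equal to a segment endpoint) are inside.
#'
#' @param segments segment data.frame.
#' @param variants variant map (data.frame with \code{chrom}, \code{pos},
#'   \code{id}).
#' @param samples character vector of cohort sample ids (rows of the output;
#'   samples without segments get all-zero rows).
#' @return integer 0/1 matrix with sample ids as rownames and variant ids as
#'   colnames.
#' @export
inclusion_matrix <- function(segments, variants, samples) {
  validate_segments(segments)
  unknown <- setdiff(segments$sample_id, samples)
  if (length(unknown))
    stop("segments reference unknown sample(s): ",
         paste(unique(unknown), collapse = ", "))
  r <- matrix(0L, nrow = length(samples), ncol = nrow(variants),
              dimnames = list(samples, variants$id))
  chrom_idx <- split(seq_len(nrow(variants)), variants$chrom)
  for (k in seq_len(nrow(segments))) {
    idx <- chrom_idx[[as.character(segments$chrom[k])]]
    if (is.null(idx)) next
    p <- variants$pos[idx]
    a <- findInterval(segments$pos_start[k] - 0.5, p) + 1L
    b <- findInterval(segments$pos_end[k] + 0.5, p)
    if (b >= a)
      r[match(segments$sample_id[k], samples), idx[a:b]] <- 1L
  }
  r
}

#' Genomic inbreeding coefficient F_ROH
#'
#' Per-sample autozygosity estimate: total length of called ROH (bp, with
#' segment length = pos_end - pos_start + 1) divided by the genome length
#' covered by SNPs (\code{params$genome_length_bp}).
#'
#' @param segments segment data.frame.
#' @param samples cohort sample ids (samples without segments get 0).
#' @param params a \code{\link{roh_params}} object.
#' @return named numeric vector of F_ROH values in [0, 1].
#' @export
froh <- function(segments, samples, params = roh_params()) {
  validate_segments(segments)
  bp <- segments$pos_end - segments$pos_start + 1
  tot <- tapply(bp, factor(segments$sample_id, levels = samples), sum)
  tot[is.na(tot)] <- 0
  f <- as.numeric(tot) / params$genome_length_bp
  names(f) <- samples
  f
}

#' Cohort ROH summary
#'
#' Per-sample segment counts, total lengths and F_ROH, and the cohort-level
#' homozygosity measures: average number of ROH (total runs / N), average
#' total ROH length (total bp / N) — each reported for all segments and for
#' the long class (> \code{long_cutoff_kb}) alone — plus the classification
#' of samples into \{no ROH, only short segments, any long segment\} with
#' percentages to one decimal.
#'
#' @param segments segment data.frame.
#' @param samples cohort sample ids.
#' @param params a \code{\link{roh_params}} object.
#' @return list with \code{per_sample} (data.frame) and \code{cohort}
#'   (named list).
#' @export
summarize_roh <- function(segments, samples, params = roh_params()) {
  n <- length(samples)
  if (n == 0) stop("no samples")
  validate_segments(segments)
  sid <- factor(segments$sample_id, levels = samples)
  bp <- segments$pos_end - segments$pos_start + 1
  long <- bp / 1000 > params$long_cutoff_kb
  cnt <- function(f) { x <- tapply(f, sid, sum); x[is.na(x)] <- 0; as.numeric(x) }
  per_sample <- data.frame(
    sample_id = samples,
    n_segments = cnt(rep(1, nrow(segments))),
    total_length_bp = cnt(bp),
    n_segments_long = cnt(as.numeric(long)),
    total_length_bp_long = cnt(bp * long),
    froh = froh(segments, samples, params),
    stringsAsFactors = FALSE, row.names = NULL)
  class_of <- ifelse(per_sample$n_segments == 0, "none",
                     ifelse(per_sample$n_segments_long > 0, "long", "short_only"))
  n_none <- sum(class_of == "none")
  n_short <- sum(class_of == "short_only")
  n_long <- sum(class_of == "long")
  cohort <- list(
    n_samples = n,
    avg_n_roh = nrow(segments) / n,
    avg_total_length_bp = sum(bp) / n,
    avg_n_roh_long = sum(long) / n,
    avg_total_length_bp_long = sum(bp[long]) / n,
    n_no_roh = n_none, pct_no_roh = round(100 * n_none / n, 1),
    n_short_only = n_short, pct_short_only = round(100 * n_short / n, 1),
    n_any_long = n_long, pct_any_long = round(100 * n_long / n, 1))
  list(per_sample = per_sample, cohort = cohort)
}

#' Carrier percentage
#'
#' Share of the cohort carrying a region, to one decimal: e.g. 96 carriers
#' among 455 samples is 21.1.
#'
#' @param n_carriers,n_samples counts.
#' @return numeric, \code{round(100 * n_carriers / n_samples, 1)}.
#' @export
carrier_pct <- function(n_carriers, n_samples) {
  stopifnot(n_samples > 0, n_carriers >= 0, n_carriers <= n_samples)
  round(100 * n_carriers / n_samples, 1)
}

#' Per-SNP ROH frequency and enriched regions
#'
#' Computes each variant's ROH frequency (column mean of the inclusion
#' matrix) and, for each threshold, merges contiguous runs of SNPs at or
#' above the threshold into regions. A sample is counted as a carrier of a
#' region if its ROH covers at least one SNP of the region.
#'
#' @param r inclusion matrix from \code{\link{inclusion_matrix}}.
#' @param variants variant map aligned to the columns of \code{r}.
#' @param thresholds frequency thresholds reported separately
#'   (default \code{c(0.20, 0.15)}).
#' @return list with \code{frequency} (data.frame chrom, pos, id, freq — a
#'   Manhattan-ready table) and \code{regions} (data.frame with threshold,
#'   chrom, start, end, n_snps, n_carriers, carrier_pct).
#' @export
region_frequency <- function(r, variants, thresholds = c(0.20, 0.15)) {
  stopifnot(ncol(r) == nrow(variants))
  freq <- colMeans(r)
  freq_tab <- data.frame(chrom = variants$chrom, pos = variants$pos,
                         id = variants$id, freq = freq,
                         stringsAsFactors = FALSE, row.names = NULL)
  regions <- list()
  for (thr in thresholds) {
    for (ch in unique(variants$chrom)) {
      idx <- which(variants$chrom == ch)
      above <- freq[idx] >= thr
      if (!any(above)) next
      rl <- rle(above)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      for (k in which(rl$values)) {
        cols <- idx[starts[k]:ends[k]]
        carriers <- sum(rowSums(r[, cols, drop = FALSE]) > 0)
        regions[[length(regions) + 1L]] <- data.frame(
          threshold = thr, chrom = ch,
          start = variants$pos[cols[1]],
          end = variants$pos[cols[length(cols)]],
          n_snps = length(cols), n_carriers = carriers,
          carrier_pct = carrier_pct(carriers, nrow(r)),
          stringsAsFactors = FALSE)
      }
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(threshold = numeric(), chrom = character(), start = numeric(),
               end = numeric(), n_snps = integer(), n_carriers = integer(),
               carrier_pct = numeric())
  rownames(regions) <- NULL
  list(frequency = freq_tab, regions = regions)
}
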