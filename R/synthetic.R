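# Synthetic cohorts with the statistical structure the analysis assumes:
# a SNP map with exponential spacings, Hardy-Weinberg background genotypes,
# planted autozygous segments (duplicated haplotypes), spurious-heterozygote
# genotyping error, missingness, and quantitative traits with covariate
# effects, a GRM-structured polygenic component and an optional causal term
# that is linear in autozygosity, regional, or recessive in genotype.

#' Simulation configuration
#'
#' Defaults describe a desk-scale model of an isolated cohort: 200 samples,
#' 20 chromosomes of 1000 SNPs at 10 kb mean spacing (a 200 Mb genome), MAF
#' uniform on [0.05, 0.5] (common variants only), and on average 3 planted
#' autozygous segments per genome with lengths 1.6 Mb + Exp(1.4 Mb) — i.e.
#' mean 3 Mb. Scaled to genome size this matches a heavily autozygous
#' isolate with roughly 4-5\% of the genome in long ROH. Genotyping error is
#' spurious heterozygosity inside planted segments at rate
#' \code{genotype_error_rate}.
#'
#' @param n_samples,n_chrom,snps_per_chrom,mean_spacing_bp map/cohort shape.
#' @param maf_range allele-frequency range (low >= 0.05 by default).
#' @param segment_rate expected planted segments per genome (Poisson rate).
#' @param segment_length_min_bp,segment_length_mean_bp shifted-exponential
#'   segment length distribution (min and mean).
#' @param genotype_error_rate probability a call inside a planted segment is
#'   corrupted to heterozygous.
#' @param missing_rate per-call missingness probability.
#' @param trait_model one of \code{"null"}, \code{"froh_linear"},
#'   \code{"regional"}, \code{"recessive"}.
#' @param beta_effect causal effect size (trait units per unit regressor).
#' @param causal_carrier_freq carrier frequency of the planted causal region
#'   (regional model).
#' @param causal_maf allele frequency forced at the causal variant
#'   (recessive model).
#' @param var_polygenic,var_noise variance of the GRM-structured polygenic
#'   component and of the independent noise.
#' @param beta_age,beta_sex fixed covariate effects (age in years,
#'   sex coded male = 1).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 200, n_chrom = 20, snps_per_chrom = 1000,
                       mean_spacing_bp = 1e4, maf_range = c(0.05, 0.5),
                       segment_rate = 3, segment_length_min_bp = 1.6e6,
                       segment_length_mean_bp = 3e6,
                       genotype_error_rate = 0.002, missing_rate = 0.01,
                       trait_model = c("null", "froh_linear", "regional",
                                       "recessive"),
                       beta_effect = 0, causal_carrier_freq = 0.25,
                       causal_maf = 0.5,
                       var_polygenic = 1, var_noise = 1,
                       beta_age = 0.01, beta_sex = 0.2, seed = 1) {
  trait_model <- match.arg(trait_model)
  stopifnot(n_samples >= 1, n_chrom >= 1, snps_per_chrom >= 2,
            mean_spacing_bp > 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            segment_rate >= 0, segment_length_min_bp > 0,
            segment_length_mean_bp >= segment_length_min_bp,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            causal_carrier_freq >= 0, causal_carrier_freq <= 1,
            causal_maf > 0, causal_maf <= 0.5,
            var_polygenic >= 0, var_noise > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a variant map
#'
#' Per chromosome, positions are cumulative sums of positive spacings drawn
#' as 1 + Exp(mean_spacing_bp - 1), rounded; ids are unique
#' \code{chr<k>_<index>} labels. Deterministic for a given config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return variant map data.frame (chrom, id, cm, pos, allele1, allele2).
#' @export
simulate_map <- function(config) {
  set.seed(config$seed)
  maps <- lapply(seq_len(config$n_chrom), function(ch) {
    sp <- 1 + round(stats::rexp(config$snps_per_chrom,
                                1 / (config$mean_spacing_bp - 1)))
    pos <- cumsum(sp)
    data.frame(chrom = as.character(ch),
               id = sprintf("chr%d_%d", ch, seq_along(pos)),
               cm = 0, pos = pos, allele1 = "A", allele2 = "C",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

#' Simulate genotypes with planted autozygous segments
#'
#' Allele-1 frequencies are uniform on \code{maf_range}. For each sample a
#' Poisson(\code{segment_rate}) number of autozygous segments is planted
#' (uniform chromosome weighted by length, uniform start, truncated at the
#' chromosome end, overlaps merged); inside a segment one haplotype is drawn
#' per site from the allele frequency and duplicated (calls 0 or 2), outside
#' calls follow Hardy-Weinberg proportions. Calls inside planted segments
#' are then corrupted to heterozygous with probability
#' \code{genotype_error_rate}; finally every call is set missing with
#' probability \code{missing_rate}. Under \code{trait_model = "regional"} a
#' fixed causal region on chromosome 1 is additionally planted in a random
#' \code{causal_carrier_freq} share of samples; under \code{"recessive"} the
#' variant nearest the middle of chromosome 1 has its frequency forced to
#' \code{causal_maf} and its error/missing-free genotype recorded.
#'
#' @param config a \code{\link{sim_config}}.
#' @param map variant map from \code{\link{simulate_map}}.
#' @return list with \code{genotypes} (a \code{genotype_matrix}) and
#'   \code{truth} (planted segments, per-sample true autozygous fraction,
#'   causal-region/variant record, simulated genome length).
#' @export
simulate_genotypes <- function(config, map) {
  set.seed(config$seed + 1L)
  n <- config$n_samples
  m <- nrow(map)
  samples <- sprintf("s%03d", seq_len(n))
  chroms <- unique(map$chrom)
  chrom_len <- vapply(chroms, function(ch) max(map$pos[map$chrom == ch]),
                      numeric(1))
  genome_bp <- sum(chrom_len)

  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  causal <- NULL
  if (config$trait_model == "recessive") {
    idx1 <- which(map$chrom == chroms[1])
    ci <- idx1[which.min(abs(map$pos[idx1] - chrom_len[1] / 2))]
    p[ci] <- config$causal_maf
    causal <- list(model = "recessive", variant_id = map$id[ci],
                   chrom = map$chrom[ci], pos = map$pos[ci], index = ci)
  }
  calls <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n)

  causal_region <- NULL
  carrier <- rep(FALSE, n)
  if (config$trait_model == "regional") {
    len <- 1.5 * config$segment_length_min_bp
    start <- max(1, round(chrom_len[1] / 2 - len / 2))
    causal_region <- c(start = start, end = start + len - 1)
    carrier <- stats::runif(n) < config$causal_carrier_freq
    causal <- list(model = "regional", chrom = chroms[1],
                   start = unname(causal_region["start"]),
                   end = unname(causal_region["end"]))
  }

  seg_list <- vector("list", n)
  for (i in seq_len(n)) {
    k <- stats::rpois(1, config$segment_rate)
    segs <- NULL
    if (k > 0) {
      ch <- sample(seq_along(chroms), k, replace = TRUE,
                   prob = chrom_len / genome_bp)
      len <- config$segment_length_min_bp +
        stats::rexp(k, 1 / (config$segment_length_mean_bp -
                              config$segment_length_min_bp))
      st <- floor(stats::runif(k, 1, pmax(1, chrom_len[ch] - len + 1) + 1))
      en <- pmin(st + len - 1, chrom_len[ch])
      segs <- data.frame(chrom = chroms[ch], start = st, end = floor(en),
                         stringsAsFactors = FALSE)
    }
    if (carrier[i])
      segs <- rbind(segs, data.frame(chrom = chroms[1],
                                     start = unname(causal_region["start"]),
                                     end = unname(causal_region["end"]),
                                     stringsAsFactors = FALSE))
    if (!is.null(segs) && nrow(segs)) {
      segs <- merge_intervals(segs)
      segs$sample_id <- samples[i]
      seg_list[[i]] <- segs
    }
  }
  truth_segments <- do.call(rbind, c(seg_list[!vapply(seg_list, is.null,
                                                      logical(1))],
                                     list(data.frame(chrom = character(),
                                                     start = numeric(),
                                                     end = numeric(),
                                                     sample_id = character()))))
  true_fraction <- numeric(n)
  names(true_fraction) <- samples

  # overwrite planted segments with duplicated haplotypes + error
  if (nrow(truth_segments)) {
    chrom_cols <- split(seq_len(m), map$chrom)
    for (k in seq_len(nrow(truth_segments))) {
      idx <- chrom_cols[[truth_segments$chrom[k]]]
      pp <- map$pos[idx]
      a <- findInterval(truth_segments$start[k] - 0.5, pp) + 1L
      b <- findInterval(truth_segments$end[k] + 0.5, pp)
      i <- match(truth_segments$sample_id[k], samples)
      if (b >= a) {
        cols <- idx[a:b]
        hom <- 2L * stats::rbinom(length(cols), 1L, p[cols])
        err <- stats::runif(length(cols)) < config$genotype_error_rate
        hom[err] <- 1L
        calls[i, cols] <- hom
      }
    }
    bp <- truth_segments$end - truth_segments$start + 1
    tot <- tapply(bp, factor(truth_segments$sample_id, levels = samples), sum)
    tot[is.na(tot)] <- 0
    true_fraction <- as.numeric(tot) / genome_bp
    names(true_fraction) <- samples
  }

  if (!is.null(causal) && causal$model == "recessive")
    causal$genotype <- calls[, causal$index]
  if (!is.null(causal) && causal$model == "regional") {
    # regional autozygosity status: 1 iff the sample's (merged) autozygous
    # segments cover the causal-region midpoint, i.e. planted carriers plus
    # background segments that happen to span the region
    mid <- (causal$start + causal$end) / 2
    status <- rep(0L, n)
    if (nrow(truth_segments)) {
      hit <- truth_segments$chrom == causal$chrom &
        truth_segments$start <= mid & truth_segments$end >= mid
      status[match(unique(truth_segments$sample_id[hit]), samples)] <- 1L
    }
    causal$carrier <- status
  }

  if (config$missing_rate > 0)
    calls[matrix(stats::runif(n * m) < config$missing_rate, n, m)] <- NA

  truth <- list(segments = truth_segments[, c("sample_id", "chrom",
                                              "start", "end")],
                true_fraction = true_fraction,
                causal = causal,
                effect = config$beta_effect,
                genome_length_bp = genome_bp)
  list(genotypes = genotype_matrix(calls, map, samples), truth = truth)
}

# sort and union overlapping intervals within one sample, per chromosome
merge_intervals <- function(segs) {
  out <- lapply(split(segs, segs$chrom), function(s) {
    s <- s[order(s$start), , drop = FALSE]
    keep_start <- s$start[1]; keep_end <- s$end[1]
    res <- NULL
    for (k in seq_len(nrow(s))[-1]) {
      if (s$start[k] <= keep_end + 1) keep_end <- max(keep_end, s$end[k])
      else {
        res <- rbind(res, data.frame(chrom = s$chrom[1], start = keep_start,
                                     end = keep_end))
        keep_start <- s$start[k]; keep_end <- s$end[k]
      }
    }
    rbind(res, data.frame(chrom = s$chrom[1], start = keep_start,
                          end = keep_end))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a quantitative trait
#'
#' trait = intercept + beta_age * age + beta_sex * sex + causal term +
#' polygenic draw with covariance \code{var_polygenic * GRM} + independent
#' N(0, var_noise) noise. The causal term is \code{beta_effect} times the
#' true autozygous fraction (\code{froh_linear}), the regional autozygosity
#' status at the causal region — any true autozygous segment covering its
#' midpoint (\code{regional}) — or the indicator genotype == 2 at the
#' causal variant (\code{recessive}). Ages are uniform on [18, 80], sexes
#' Bernoulli(0.5).
#'
#' @param config a \code{\link{sim_config}}.
#' @param geno the simulated \code{genotype_matrix} (sample ids).
#' @param truth truth record from \code{\link{simulate_genotypes}}.
#' @param kinship GRM, required when \code{var_polygenic > 0}.
#' @param kinship_eigen optional precomputed \code{eigen()} of the GRM;
#'   avoids redecomposing when many trait replicates are drawn on one
#'   cohort.
#' @return data.frame (sample_id, sex, age, trait).
#' @export
simulate_trait <- function(config, geno, truth, kinship = NULL,
                           kinship_eigen = NULL) {
  set.seed(config$seed + 2L)
  n <- n_samples(geno)
  age <- stats::runif(n, 18, 80)
  sex <- stats::rbinom(n, 1, 0.5)
  causal_x <- switch(config$trait_model,
    null = rep(0, n),
    froh_linear = truth$true_fraction,
    regional = {
      if (is.null(truth$causal) || truth$causal$model != "regional")
        stop("truth record lacks a regional causal term")
      truth$causal$carrier
    },
    recessive = {
      if (is.null(truth$causal) || truth$causal$model != "recessive")
        stop("truth record lacks a recessive causal variant")
      as.integer(truth$causal$genotype == 2L)
    },
    stop("unknown trait_model: ", config$trait_model))
  poly <- rep(0, n)
  if (config$var_polygenic > 0) {
    ev <- kinship_eigen
    if (is.null(ev)) {
      if (is.null(kinship))
        stop("kinship (GRM) required when var_polygenic > 0")
      ev <- eigen((kinship + t(kinship)) / 2, symmetric = TRUE)
    }
    lam <- pmax(ev$values, 0)
    poly <- sqrt(config$var_polygenic) *
      as.vector(ev$vectors %*% (sqrt(lam) * stats::rnorm(n)))
  }
  y <- 10 + config$beta_age * age + config$beta_sex * sex +
    config$beta_effect * causal_x + poly +
    stats::rnorm(n, sd = sqrt(config$var_noise))
  data.frame(sample_id = geno$samples,
             sex = c("female", "male")[sex + 1],
             age = age, trait = y, stringsAsFactors = FALSE)
}

#' Simulate a full cohort
#'
#' Convenience wrapper: map, genotypes with planted segments, GRM and trait,
#' all driven by one config.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{genotypes}, \code{truth}, \code{pheno},
#'   \code{grm}.
#' @export
simulate_cohort <- function(config) {
  map <- simulate_map(config)
  sim <- simulate_genotypes(config, map)
  kin <- grm(sim$genotypes)
  pheno <- simulate_trait(config, sim$genotypes, sim$truth, kin)
  list(genotypes = sim$genotypes, truth = sim$truth, pheno = pheno, grm = kin)
}
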